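# Analytic parameter and FLOP accounting. Parameter counts are exact integer
# counts of learnable scalars taken from the instantiated parameter tree, so
# ablations are reflected automatically. FLOPs use the convention
# 1 multiply-accumulate = 2 FLOPs, exclude nonlinearities, and are reported
# per forward pass of a single window of length T.

#' Count learnable parameters per module
#'
#' @param model a `spasm_model`.
#' @return tibble of class `efficiency_report` with columns `module` and
#'   `params`, including the (parameter-free) scalogram front end and a
#'   `total` row.
#' @export
count_parameters <- function(model) {
  p <- model$params
  rows <- list()
  add <- function(name, subtree) {
    n <- if (is.null(subtree)) 0L else as.integer(tree_count(subtree))
    rows[[length(rows) + 1]] <<- tibble::tibble(module = name, params = n)
  }
  act <- branch_active(model$config)
  if (model$config$use_cwt) add("cwt", NULL)
  if (act$eeg && model$config$use_stconv) add("stconv_eeg", p$eeg_stconv)
  if (act$emg && model$config$use_stconv) add("stconv_emg", p$emg_stconv)
  if (act$eeg && model$config$use_bimamba) add("bimamba_eeg", p$eeg_mamba)
  if (act$emg && model$config$use_bimamba) add("bimamba_emg", p$emg_mamba)
  if (act$eeg) add("proj_eeg", p$proj_eeg)
  if (act$emg) add("proj_emg", p$proj_emg)
  if (model$config$fusion == "cross_time_mixing") {
    add("cross_time_mixing", p$ctm)
  } else if (model$config$fusion == "concat") {
    add("fusion_concat", p$fuse_cat)
  }
  add("classifier", p$head)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(module = "total",
                                              params = sum(out$params)))
  class(out) <- c("efficiency_report", class(out))
  out
}

flops_stconv <- function(cfg, T) {
  C <- cfg$channels
  2 * T * C * (cfg$f_mid * cfg$f_in * cfg$kt +      # temporal conv
                 cfg$f_out * cfg$f_mid * cfg$ks +   # spatial conv
                 cfg$f_out * cfg$f_in)              # 1x1 residual
}

flops_bimamba <- function(cfg, T) {
  e <- cfg$e; n <- cfg$n
  streams <- if (cfg$bidirectional) 2 else 1
  per_stream <- 2 * T * e * cfg$k +        # causal depthwise conv
    2 * T * e * (e + 2 * n) +              # parameter projection
    10 * T * e * n + 2 * T * e +           # discretize + scan + skip
    2 * T * e * e + T * e                  # gate projection + gating
  2 * T * cfg$d * streams * e +            # input expansion
    streams * per_stream +
    2 * T * e * cfg$d                      # output projection
}

flops_ctm <- function(cfg, T) {
  d <- cfg$d
  mix <- if (cfg$mix_mode == "matrix") 2 * T * d * d else 3 * T * d
  per_dir <- 3 * (mix + 2 * T * d * d) +   # r/k/v token-shift + projection
    12 * T * d +                           # WKV recurrence
    T * d +                                # sigmoid gate product
    2 * T * d * d                          # output projection
  2 * per_dir + 4 * 3 * T * d              # two directions + four RMSNorms
}

#' Analytic FLOPs of a quadratic cross-attention reference
#'
#' Standard single-head cross-attention with Q/K/V/output projections in both
#' conditioning directions; the score and mixing matrices grow as `T^2 * D`,
#' against which the linear WKV recurrence is compared.
#'
#' @param T sequence length.
#' @param d feature width.
#' @return FLOP count (MAC = 2 FLOPs).
#' @export
flops_quadratic_attention <- function(T, d) {
  2 * (4 * 2 * T * d * d + 2 * 2 * T * T * d)
}

#' Analytic FLOPs per forward pass
#'
#' @param model a `spasm_model`.
#' @param T window length in samples.
#' @return tibble of class `efficiency_report` with columns `module` and
#'   `flops`, plus a `total` row. Scan-based stages grow linearly in `T`.
#' @export
estimate_flops <- function(model, T) {
  cfg <- model$config
  act <- branch_active(cfg)
  rows <- list()
  add <- function(name, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(module = name,
                                                flops = as.numeric(value))
  }
  d <- cfg$d_model
  if (act$eeg && cfg$use_stconv) {
    add("stconv_eeg", flops_stconv(cfg$stconv_eeg, T))
  }
  if (act$emg && cfg$use_stconv) {
    add("stconv_emg", flops_stconv(cfg$stconv_emg, T))
  }
  if (act$eeg && cfg$use_bimamba) {
    add("bimamba_eeg", flops_bimamba(cfg$mamba_eeg, T))
  }
  if (act$emg && cfg$use_bimamba) {
    add("bimamba_emg", flops_bimamba(cfg$mamba_emg, T))
  }
  if (act$eeg) add("proj_eeg", 2 * T * cfg$d_eeg * d)
  if (act$emg) add("proj_emg", 2 * T * cfg$d_emg * d)
  if (cfg$fusion == "cross_time_mixing") {
    add("cross_time_mixing", flops_ctm(cfg$ctm, T))
  } else if (cfg$fusion == "concat") {
    add("fusion_concat", 2 * T * 2 * d * d)
  }
  add("classifier", T * d + 2 * (d / 2) * d + 2 * 2 * (d / 2))
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(module = "total",
                                              flops = sum(out$flops)))
  class(out) <- c("efficiency_report", class(out))
  out
}
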