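# End-to-end assembly: two unimodal encoders (CWT -> ST-Conv -> Bi-Mamba),
# per-modality linear projections to a common width, a fusion stage, and a
# pooled two-layer MLP head. Ablation flags replace a disabled stage by the
# identity on compatible shapes; fusion variants (concatenation, averaging,
# single-modality) operate on the same projected sequences.

#' Model configuration
#'
#' Collects every architectural choice of the dual-stream detector. Defaults
#' reproduce the reference architecture: 25 EEG + 4 EMG channels, four
#' scalogram bands per modality, temporal kernel 25 and spatial kernels 13/3,
#' state size 32, fused width 128 with full-matrix token-shift mixing.
#'
#' @param fs sampling rate of the analysis windows (Hz).
#' @param eeg_channels,emg_channels channel counts.
#' @param d_model fused feature width (must be even; the MLP hidden width is
#'   `d_model / 2`).
#' @param use_cwt,use_stconv,use_bimamba ablation flags; a disabled stage is
#'   replaced by an identity of compatible shape (`use_cwt = FALSE` tiles the
#'   raw window into the four band rows).
#' @param fusion one of `"cross_time_mixing"`, `"concat"`, `"average"`,
#'   `"none_eeg_only"`, `"none_emg_only"`.
#' @param bands_eeg,bands_emg scalogram bands; defaults from [default_bands()].
#' @param omega0,scales_per_band,boundary CWT front-end settings.
#' @param kt,ks_eeg,ks_emg,f_mid,f_out,leaky_slope ST-Conv settings.
#' @param n_state,conv_kernel,expand,bidirectional Bi-Mamba settings.
#' @param mix_mode,wkv_order,reverse_scan cross time-mixing settings.
#' @return a `model_config` list.
#' @export
model_config <- function(fs = 1024, eeg_channels = 25, emg_channels = 4,
                         d_model = 128,
                         use_cwt = TRUE, use_stconv = TRUE, use_bimamba = TRUE,
                         fusion = c("cross_time_mixing", "concat", "average",
                                    "none_eeg_only", "none_emg_only"),
                         bands_eeg = default_bands("eeg"),
                         bands_emg = default_bands("emg", fs),
                         omega0 = 6, scales_per_band = 8, boundary = "reflect",
                         kt = 25, ks_eeg = 13, ks_emg = 3, f_mid = 16,
                         f_out = 4, leaky_slope = 0.01,
                         n_state = 32, conv_kernel = 4, expand = 2,
                         bidirectional = TRUE,
                         mix_mode = "matrix", wkv_order = "rwkv",
                         reverse_scan = FALSE) {
  fusion <- match.arg(fusion)
  if (d_model %% 2 != 0) stop("d_model must be even")
  cfg <- list(
    fs = fs, eeg_channels = eeg_channels, emg_channels = emg_channels,
    d_model = d_model, use_cwt = use_cwt, use_stconv = use_stconv,
    use_bimamba = use_bimamba, fusion = fusion,
    bands_eeg = bands_eeg, bands_emg = bands_emg, omega0 = omega0,
    scales_per_band = scales_per_band, boundary = boundary,
    n_bands = 4
  )
  cfg$stconv_eeg <- stconv_config(eeg_channels, "eeg", kt = kt, ks = ks_eeg,
                                  f_mid = f_mid, f_out = f_out,
                                  leaky_slope = leaky_slope)
  cfg$stconv_emg <- stconv_config(emg_channels, "emg", kt = kt, ks = ks_emg,
                                  f_mid = f_mid, f_out = f_out,
                                  leaky_slope = leaky_slope)
  f_seq <- if (use_stconv) f_out else cfg$n_bands
  cfg$d_eeg <- f_seq * eeg_channels
  cfg$d_emg <- f_seq * emg_channels
  cfg$mamba_eeg <- mamba_config(cfg$d_eeg, n_state, conv_kernel, expand,
                                bidirectional)
  cfg$mamba_emg <- mamba_config(cfg$d_emg, n_state, conv_kernel, expand,
                                bidirectional)
  cfg$ctm <- ctm_config(d_model, mix_mode, wkv_order, reverse_scan)
  cfg$leaky_slope <- leaky_slope
  structure(cfg, class = "model_config")
}

branch_active <- function(cfg) {
  list(eeg = cfg$fusion != "none_emg_only",
       emg = cfg$fusion != "none_eeg_only")
}

#' Build a detector model
#'
#' Initializes all learnable parameters (Glorot-uniform matrices, unit BN
#' gains, softplus-domain step-size biases drawn so initial step sizes lie in
#' \[0.001, 0.1\]) under a single seed, so construction is bit-reproducible.
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling initialization.
#' @return a `spasm_model`: list with `config`, `params`, `buffers`, `seed`.
#' @export
build_model <- function(config, seed = 1L) {
  act <- branch_active(config)
  params <- with_seed(seed, {
    p <- list()
    if (act$eeg) {
      if (config$use_stconv) p$eeg_stconv <- stconv_init(config$stconv_eeg)
      if (config$use_bimamba) p$eeg_mamba <- bimamba_init(config$mamba_eeg)
      p$proj_eeg <- list(W = glorot(config$d_model, config$d_eeg),
                         b = rep(0, config$d_model))
    }
    if (act$emg) {
      if (config$use_stconv) p$emg_stconv <- stconv_init(config$stconv_emg)
      if (config$use_bimamba) p$emg_mamba <- bimamba_init(config$mamba_emg)
      p$proj_emg <- list(W = glorot(config$d_model, config$d_emg),
                         b = rep(0, config$d_model))
    }
    if (config$fusion == "cross_time_mixing") {
      p$ctm <- ctm_init(config$ctm)
    } else if (config$fusion == "concat") {
      p$fuse_cat <- list(W = glorot(config$d_model, 2 * config$d_model),
                         b = rep(0, config$d_model))
    }
    h <- config$d_model / 2
    p$head <- list(W1 = glorot(h, config$d_model), b1 = rep(0, h),
                   W2 = glorot(2, h), b2 = rep(0, 2))
    p
  })
  buffers <- list()
  if (act$eeg && config$use_stconv) {
    buffers$eeg_stconv <- stconv_buffers(config$stconv_eeg)
  }
  if (act$emg && config$use_stconv) {
    buffers$emg_stconv <- stconv_buffers(config$stconv_emg)
  }
  structure(list(config = config, params = params, buffers = buffers,
                 seed = seed),
            class = "spasm_model")
}

#' @export
print.spasm_model <- function(x, ...) {
  n <- tree_count(x$params)
  cat(sprintf(
    "<spasm_model: fusion=%s, d_model=%d, %s params>\n",
    x$config$fusion, x$config$d_model, format(n, big.mark = ",")
  ))
  invisible(x)
}

# One encoder branch. scal: [F, C, T, B]. Returns projected sequence
# [d_model, T*B] plus cache.
branch_fwd <- function(scal, params, buffers, cfg, which, train) {
  d <- dim(scal)
  T <- d[3]; B <- d[4]
  cache <- list(T = T, B = B)
  if (cfg$use_stconv) {
    sc <- stconv_fwd(scal, params[[paste0(which, "_stconv")]],
                     buffers[[paste0(which, "_stconv")]],
                     cfg[[paste0("stconv_", which)]], train)
    cache$stconv <- sc$cache
    cache$stconv_buf <- sc$buf
    feat <- sc$y
  } else {
    feat <- scal
  }
  x <- flatten_seq_batch(feat)
  if (cfg$use_bimamba) {
    bm <- bimamba_fwd(x, params[[paste0(which, "_mamba")]],
                      cfg[[paste0("mamba_", which)]], T, B)
    cache$mamba <- bm$cache
    seq <- bm$y
  } else {
    seq <- x
  }
  pr <- params[[paste0("proj_", which)]]
  proj <- linear_fwd(pr$W, seq, pr$b)
  cache$seq <- seq
  list(y = proj, cache = cache)
}

branch_bwd <- function(dproj, params, cfg, which, cache, grads) {
  T <- cache$T; B <- cache$B
  pr <- params[[paste0("proj_", which)]]
  pb <- linear_bwd(pr$W, cache$seq, dproj)
  grads[[paste0("proj_", which)]] <- list(W = pb$dW, b = pb$db)
  dseq <- pb$dx
  if (cfg$use_bimamba) {
    mb <- bimamba_bwd(dseq, params[[paste0(which, "_mamba")]],
                      cfg[[paste0("mamba_", which)]], T, B, cache$mamba)
    grads[[paste0(which, "_mamba")]] <- mb$grads
    dx <- mb$dx
  } else {
    dx <- dseq
  }
  if (cfg$use_stconv) {
    scfg <- cfg[[paste0("stconv_", which)]]
    dfeat <- unflatten_seq_batch(dx, scfg$f_out, scfg$channels, T, B)
    sb <- stconv_bwd(dfeat, params[[paste0(which, "_stconv")]], scfg,
                     cache$stconv)
    grads[[paste0(which, "_stconv")]] <- sb$grads
  }
  grads
}

# Full forward over a feature batch (band tensors per modality).
model_forward <- function(model, eeg_scal, emg_scal, train = FALSE) {
  cfg <- model$config
  act <- branch_active(cfg)
  cache <- list()
  pe <- pm <- NULL
  if (act$eeg) {
    be <- branch_fwd(eeg_scal, model$params, model$buffers, cfg, "eeg", train)
    pe <- be$y
    cache$eeg <- be$cache
  }
  if (act$emg) {
    bm <- branch_fwd(emg_scal, model$params, model$buffers, cfg, "emg", train)
    pm <- bm$y
    cache$emg <- bm$cache
  }
  TT <- if (act$eeg) cache$eeg$T else cache$emg$T
  B <- if (act$eeg) cache$eeg$B else cache$emg$B
  fused <- switch(
    cfg$fusion,
    cross_time_mixing = {
      fc <- ctm_fuse_fwd(pe, pm, model$params$ctm, cfg$ctm, TT, B)
      cache$ctm <- fc$cache
      fc$y
    },
    concat = linear_fwd(model$params$fuse_cat$W, rbind(pe, pm),
                        model$params$fuse_cat$b),
    average = (pe + pm) / 2,
    none_eeg_only = pe,
    none_emg_only = pm
  )
  cache$pe <- pe
  cache$pm <- pm
  cache$T <- TT
  cache$B <- B
  # global average pooling over time, then the two-layer head
  pool <- t(rowsum(t(fused), rep(seq_len(B), each = TT))) / TT
  hpre <- linear_fwd(model$params$head$W1, pool, model$params$head$b1)
  h <- leaky_relu(hpre, cfg$leaky_slope)
  logits <- linear_fwd(model$params$head$W2, h, model$params$head$b2)
  cache$fused <- fused
  cache$pool <- pool
  cache$hpre <- hpre
  cache$h <- h
  # updated BN running statistics (training mode only)
  if (train && cfg$use_stconv) {
    bufs <- model$buffers
    if (act$eeg) bufs$eeg_stconv <- cache$eeg$stconv_buf
    if (act$emg) bufs$emg_stconv <- cache$emg$stconv_buf
    cache$buffers <- bufs
  }
  list(logits = logits, cache = cache)
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  act <- branch_active(cfg)
  grads <- tree_zeros(model$params)
  TT <- cache$T; B <- cache$B
  hb <- linear_bwd(model$params$head$W2, cache$h, dlogits)
  grads$head$W2 <- hb$dW
  grads$head$b2 <- hb$db
  dh <- hb$dx * leaky_relu_grad(cache$hpre, cfg$leaky_slope)
  h1 <- linear_bwd(model$params$head$W1, cache$pool, dh)
  grads$head$W1 <- h1$dW
  grads$head$b1 <- h1$db
  dpool <- h1$dx
  dfused <- dpool[, rep(seq_len(B), each = TT), drop = FALSE] / TT
  dpe <- dpm <- NULL
  if (cfg$fusion == "cross_time_mixing") {
    fb <- ctm_fuse_bwd(dfused, cache$pe, cache$pm, model$params$ctm, cfg$ctm,
                       TT, B, cache$ctm)
    grads$ctm <- fb$grads
    dpe <- fb$dx_eeg
    dpm <- fb$dx_emg
  } else if (cfg$fusion == "concat") {
    cb <- linear_bwd(model$params$fuse_cat$W, rbind(cache$pe, cache$pm),
                     dfused)
    grads$fuse_cat <- list(W = cb$dW, b = cb$db)
    dpe <- cb$dx[seq_len(cfg$d_model), , drop = FALSE]
    dpm <- cb$dx[cfg$d_model + seq_len(cfg$d_model), , drop = FALSE]
  } else if (cfg$fusion == "average") {
    dpe <- dfused / 2
    dpm <- dfused / 2
  } else if (cfg$fusion == "none_eeg_only") {
    dpe <- dfused
  } else {
    dpm <- dfused
  }
  if (act$eeg) {
    grads <- branch_bwd(dpe, model$params, cfg, "eeg", cache$eeg, grads)
  }
  if (act$emg) {
    grads <- branch_bwd(dpm, model$params, cfg, "emg", cache$emg, grads)
  }
  grads
}

#' Classifier head over a fused sequence
#'
#' Global average pooling over time followed by the two-layer MLP:
#' `h = LeakyReLU(W1 pooled + b1)` (hidden width `d_model/2`) and
#' `z = W2 h + b2` giving two class logits.
#'
#' @param fused numeric matrix `[T x d_model]`.
#' @param head_params list with `W1`, `b1`, `W2`, `b2`.
#' @param leaky_slope negative slope of the hidden activation.
#' @return numeric vector of 2 logits (non-spasm, spasm).
#' @export
classify <- function(fused, head_params, leaky_slope = 0.01) {
  pooled <- colMeans(fused)
  h <- leaky_relu(head_params$W1 %*% pooled + head_params$b1, leaky_slope)
  as.numeric(head_params$W2 %*% h + head_params$b2)
}

#' Two-class cross-entropy loss
#'
#' Softmax over the two logits and negative log-likelihood of the true class
#' (the two-logit realization of binary cross-entropy).
#'
#' @param logits numeric vector of length 2.
#' @param label 0 (non-spasm) or 1 (spasm).
#' @return scalar loss.
#' @export
cross_entropy <- function(logits, label) {
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  z <- logits - max(logits)
  lse <- log(sum(exp(z)))
  -(z[label + 1] - lse)
}

# Batched loss + gradient. logits: [2, B]; labels in {0,1}.
ce_loss_batch <- function(logits, labels) {
  B <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  p <- exp(z)
  p <- sweep(p, 2, colSums(p), "/")
  idx <- cbind(labels + 1, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dz <- p
  dz[idx] <- dz[idx] - 1
  list(loss = loss, dlogits = dz / B)
}

# Deterministic forward over a prepared feature set in minibatches;
# returns logits [2, n].
model_predict <- function(model, feats, batch_size = 32) {
  n <- dim(feats$eeg)[4]
  out <- matrix(0, 2, n)
  i <- 1
  while (i <= n) {
    j <- min(i + batch_size - 1, n)
    fw <- model_forward(model,
                        feats$eeg[, , , i:j, drop = FALSE],
                        feats$emg[, , , i:j, drop = FALSE], train = FALSE)
    out[, i:j] <- fw$logits
    i <- j + 1
  }
  out
}

#' Prepare model input features from a window set
#'
#' Applies the (parameter-free) scalogram front end to every window of both
#' modalities, or tiles the raw windows into the four band rows when the
#' model ablates the CWT. Computed once per dataset since the front end is
#' fixed.
#'
#' @param ws a `window_set`.
#' @param config a [model_config()].
#' @return list with band tensors `eeg` `[4, C_eeg, T, n]`, `emg`
#'   `[4, C_emg, T, n]`, integer `labels`, and the window `meta` tibble.
#' @export
prepare_features <- function(ws, config) {
  tile <- function(x) {
    d <- dim(x)
    arr <- array(0, dim = c(config$n_bands, d[1], d[2], d[3]))
    for (f in seq_len(config$n_bands)) arr[f, , , ] <- x
    arr
  }
  act <- branch_active(config)
  eeg <- if (!act$eeg) {
    array(0, dim = c(config$n_bands, dim(ws$eeg)[1], dim(ws$eeg)[2],
                     dim(ws$eeg)[3]))
  } else if (config$use_cwt) {
    scalogram_batch(ws$eeg, ws$fs, config$bands_eeg, config$omega0,
                    config$scales_per_band, config$boundary)
  } else {
    tile(ws$eeg)
  }
  emg <- if (!act$emg) {
    array(0, dim = c(config$n_bands, dim(ws$emg)[1], dim(ws$emg)[2],
                     dim(ws$emg)[3]))
  } else if (config$use_cwt) {
    scalogram_batch(ws$emg, ws$fs, config$bands_emg, config$omega0,
                    config$scales_per_band, config$boundary)
  } else {
    tile(ws$emg)
  }
  list(eeg = eeg, emg = emg, labels = ws$meta$label, meta = ws$meta)
}
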