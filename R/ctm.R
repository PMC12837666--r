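# Cross Time-Mixing: linear recurrent cross-modal attention. Each modality
# sequence is RMS-normalized; a receptance vector is derived from the query
# stream and key/value vectors from the context stream via token-shift
# interpolation (full D x D mixing matrices by default); a channel-wise
# weighted key-value recurrence with learnable decay omega and current-token
# bonus u produces the fused context, which is sigmoid-gated and projected.
# The two conditioning directions (EEG|EMG and EMG|EEG) use independent
# parameters; fusion adds the gated outputs residually under output RMSNorms.

#' Configuration of the cross time-mixing fusion module
#'
#' @param d fused feature width (default 128).
#' @param mix_mode `"matrix"` (full `D x D` token-shift coefficients, default)
#'   or `"vector"` (elementwise coefficients, the RWKV convention).
#' @param wkv_order `"rwkv"` (state holds history through `t-1`; the current
#'   token enters via the bonus only, default) or `"literal"` (state updated
#'   before use, counting the current token in both state and bonus).
#' @param reverse_scan also run the recurrence backwards in time (off by
#'   default: the temporal scan is causal; bidirectionality here refers to the
#'   two modal conditioning directions).
#' @return a config list.
#' @export
ctm_config <- function(d = 128, mix_mode = c("matrix", "vector"),
                       wkv_order = c("rwkv", "literal"),
                       reverse_scan = FALSE) {
  list(d = d, mix_mode = match.arg(mix_mode),
       wkv_order = match.arg(wkv_order), reverse_scan = reverse_scan)
}

ctm_direction_init <- function(cfg) {
  d <- cfg$d
  mix <- function() {
    if (cfg$mix_mode == "matrix") {
      0.5 * diag(d) + matrix(rnorm(d * d, sd = 0.02), d, d)
    } else {
      runif(d, 0.3, 0.7)
    }
  }
  list(
    Mr = mix(), Mk = mix(), Mv = mix(),
    Wr = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
    Wo = glorot(d, d),
    omega = runif(d, 0.1, 1),
    u = rnorm(d, sd = 0.1)
  )
}

ctm_init <- function(cfg) {
  d <- cfg$d
  list(
    g_in_eeg = rep(1, d), g_in_emg = rep(1, d),
    dir_eeg = ctm_direction_init(cfg),
    dir_emg = ctm_direction_init(cfg),
    g_out_eeg = rep(1, d), g_out_emg = rep(1, d)
  )
}

# ---- RMSNorm --------------------------------------------------------------
# x: [D, M] columns are time steps; eps fixed at 1e-8.

rmsnorm_fwd <- function(x, gain, eps = 1e-8) {
  D <- nrow(x)
  out <- cpp_rmsnorm_fwd(x, gain, D, ncol(x), eps)
  y <- out$y
  dim(y) <- dim(x)
  list(y = y, cache = list(x = x, r = out$r))
}

rmsnorm_bwd <- function(dy, gain, cache) {
  D <- nrow(cache$x)
  out <- cpp_rmsnorm_bwd(cache$x, cache$r, gain, dy, D, ncol(cache$x))
  dx <- out$dx
  dim(dx) <- dim(cache$x)
  list(dx = dx, dgain = out$dgain)
}

# ---- token shift ----------------------------------------------------------
# Right-shift each window along t with a zero first column.

shift_right <- function(x, T, B) {
  D <- nrow(x)
  xs <- matrix(0, D, T * B)
  if (T > 1) {
    keep <- which(rep(seq_len(T), B) > 1)   # all but each window's first step
    xs[, keep] <- x[, keep - 1L, drop = FALSE]
  }
  xs
}

# Adjoint of shift_right: left shift, discarding the first column's grad.
shift_left_adjoint <- function(dxs, T, B) {
  D <- nrow(dxs)
  dx <- matrix(0, D, T * B)
  if (T > 1) {
    keep <- which(rep(seq_len(T), B) > 1)
    dx[, keep - 1L] <- dxs[, keep, drop = FALSE]
  }
  dx
}

tsmix_fwd <- function(x, M, W, cfg, T, B) {
  xs <- shift_right(x, T, B)
  if (cfg$mix_mode == "matrix") {
    blend <- M %*% (x - xs) + xs
  } else {
    blend <- M * x + (1 - M) * xs
  }
  list(y = W %*% blend, cache = list(x = x, xs = xs, blend = blend))
}

tsmix_bwd <- function(dy, M, W, cfg, T, B, cache) {
  dblend <- crossprod(W, dy)
  dW <- tcrossprod(dy, cache$blend)
  if (cfg$mix_mode == "matrix") {
    dM <- tcrossprod(dblend, cache$x - cache$xs)
    dx <- crossprod(M, dblend)
    dxs <- dblend - dx
  } else {
    dM <- rowSums(dblend * (cache$x - cache$xs))
    dx <- M * dblend
    dxs <- (1 - M) * dblend
  }
  list(dx = dx + shift_left_adjoint(dxs, T, B), dM = dM, dW = dW)
}

# ---- WKV ------------------------------------------------------------------

wkv_fwd_batch <- function(k, v, omega, u, cfg, T, B) {
  lit <- as.integer(cfg$wkv_order == "literal")
  if (cfg$reverse_scan) {
    k2 <- rev_time(k, T, B)
    v2 <- rev_time(v, T, B)
    fwd <- cpp_wkv_fwd(k, v, omega, u, nrow(k), T, B, lit)
    dim(fwd) <- dim(k)
    bwd <- cpp_wkv_fwd(k2, v2, omega, u, nrow(k), T, B, lit)
    dim(bwd) <- dim(k)
    0.5 * (fwd + rev_time(bwd, T, B))
  } else {
    out <- cpp_wkv_fwd(k, v, omega, u, nrow(k), T, B, lit)
    dim(out) <- dim(k)
    out
  }
}

wkv_bwd_batch <- function(k, v, omega, u, cfg, T, B, dwkv) {
  lit <- as.integer(cfg$wkv_order == "literal")
  D <- nrow(k)
  if (cfg$reverse_scan) {
    g1 <- cpp_wkv_bwd(k, v, omega, u, D, T, B, lit, 0.5 * dwkv)
    dr <- rev_time(0.5 * dwkv, T, B)
    g2 <- cpp_wkv_bwd(rev_time(k, T, B), rev_time(v, T, B), omega, u, D, T, B,
                      lit, dr)
    dk1 <- g1$dk; dim(dk1) <- dim(k)
    dk2 <- g2$dk; dim(dk2) <- dim(k)
    dv1 <- g1$dv; dim(dv1) <- dim(k)
    dv2 <- g2$dv; dim(dv2) <- dim(k)
    list(dk = dk1 + rev_time(dk2, T, B), dv = dv1 + rev_time(dv2, T, B),
         domega = g1$domega + g2$domega, du = g1$du + g2$du)
  } else {
    g <- cpp_wkv_bwd(k, v, omega, u, D, T, B, lit, dwkv)
    dk <- g$dk; dim(dk) <- dim(k)
    dv <- g$dv; dim(dv) <- dim(k)
    list(dk = dk, dv = dv, domega = g$domega, du = g$du)
  }
}

# ---- one conditioning direction ------------------------------------------
# q, ctx: RMS-normalized sequences [D, T*B].

ctm_dir_fwd <- function(q, ctx, par, cfg, T, B) {
  r <- tsmix_fwd(q, par$Mr, par$Wr, cfg, T, B)
  k <- tsmix_fwd(ctx, par$Mk, par$Wk, cfg, T, B)
  v <- tsmix_fwd(ctx, par$Mv, par$Wv, cfg, T, B)
  wkv <- wkv_fwd_batch(k$y, v$y, par$omega, par$u, cfg, T, B)
  sr <- cpp_sigmoid(r$y)
  dim(sr) <- dim(r$y)
  gated <- sr * wkv
  o <- par$Wo %*% gated
  list(o = o, cache = list(r = r, k = k, v = v, wkv = wkv, sr = sr,
                           gated = gated))
}

ctm_dir_bwd <- function(do, q, ctx, par, cfg, T, B, cache) {
  dgated <- crossprod(par$Wo, do)
  dWo <- tcrossprod(do, cache$gated)
  dsr <- dgated * cache$wkv
  dwkv <- dgated * cache$sr
  dr_y <- dsr * cache$sr * (1 - cache$sr)
  wg <- wkv_bwd_batch(cache$k$y, cache$v$y, par$omega, par$u, cfg, T, B, dwkv)
  rb <- tsmix_bwd(dr_y, par$Mr, par$Wr, cfg, T, B, cache$r$cache)
  kb <- tsmix_bwd(wg$dk, par$Mk, par$Wk, cfg, T, B, cache$k$cache)
  vb <- tsmix_bwd(wg$dv, par$Mv, par$Wv, cfg, T, B, cache$v$cache)
  list(
    dq = rb$dx, dctx = kb$dx + vb$dx,
    grads = list(Mr = rb$dM, Mk = kb$dM, Mv = vb$dM,
                 Wr = rb$dW, Wk = kb$dW, Wv = vb$dW, Wo = dWo,
                 omega = wg$domega, u = wg$du)
  )
}

# ---- full fusion ----------------------------------------------------------
# x_eeg, x_emg: [D, T*B].

ctm_fuse_fwd <- function(x_eeg, x_emg, par, cfg, T, B) {
  ne <- rmsnorm_fwd(x_eeg, par$g_in_eeg)
  nm <- rmsnorm_fwd(x_emg, par$g_in_emg)
  de <- ctm_dir_fwd(ne$y, nm$y, par$dir_eeg, cfg, T, B)
  dm <- ctm_dir_fwd(nm$y, ne$y, par$dir_emg, cfg, T, B)
  oe <- rmsnorm_fwd(x_eeg + de$o, par$g_out_eeg)
  om <- rmsnorm_fwd(x_emg + dm$o, par$g_out_emg)
  list(y = oe$y + om$y,
       cache = list(ne = ne, nm = nm, de = de, dm = dm, oe = oe, om = om))
}

ctm_fuse_bwd <- function(dy, x_eeg, x_emg, par, cfg, T, B, cache) {
  oeb <- rmsnorm_bwd(dy, par$g_out_eeg, cache$oe$cache)
  omb <- rmsnorm_bwd(dy, par$g_out_emg, cache$om$cache)
  deb <- ctm_dir_bwd(oeb$dx, cache$ne$y, cache$nm$y, par$dir_eeg, cfg, T, B,
                     cache$de$cache)
  dmb <- ctm_dir_bwd(omb$dx, cache$nm$y, cache$ne$y, par$dir_emg, cfg, T, B,
                     cache$dm$cache)
  dne <- deb$dq + dmb$dctx
  dnm <- dmb$dq + deb$dctx
  neb <- rmsnorm_bwd(dne, par$g_in_eeg, cache$ne$cache)
  nmb <- rmsnorm_bwd(dnm, par$g_in_emg, cache$nm$cache)
  list(
    dx_eeg = oeb$dx + neb$dx,
    dx_emg = omb$dx + nmb$dx,
    grads = list(
      g_in_eeg = neb$dgain, g_in_emg = nmb$dgain,
      dir_eeg = deb$grads, dir_emg = dmb$grads,
      g_out_eeg = oeb$dgain, g_out_emg = omb$dgain
    )
  )
}

# ---- exported single-window interfaces ------------------------------------

#' Root-mean-square normalization of a sequence
#'
#' Per time step `t`: `x_t * gain / sqrt(mean(x_t^2) + 1e-8)`.
#'
#' @param x numeric matrix `[T x D]`.
#' @param gain learnable gain vector of length D (default all ones).
#' @return normalized matrix `[T x D]`.
#' @export
rmsnorm <- function(x, gain = rep(1, ncol(x))) {
  t(rmsnorm_fwd(t(x), gain)$y)
}

#' Token-shift interpolation followed by projection
#'
#' Blends each time step with its predecessor (zero vector before the first
#' step) and projects: in matrix mode `W (M x_t + (I - M) x_{t-1})`, in
#' vector mode the blend is elementwise.
#'
#' @param x numeric matrix `[T x D]`.
#' @param M mixing coefficients: `D x D` matrix or length-D vector.
#' @param W projection matrix `[D x D]`.
#' @return projected sequence `[T x D]`.
#' @export
token_shift_mix <- function(x, M, W) {
  cfg <- ctm_config(d = ncol(x),
                    mix_mode = if (is.matrix(M)) "matrix" else "vector")
  t(tsmix_fwd(t(x), M, W, cfg, nrow(x), 1L)$y)
}

#' Weighted key-value recurrence
#'
#' The channel-wise linear attention recurrence with learnable decay
#' `lambda = exp(-omega)` and current-token bonus `u`:
#' `s_t = lambda s_{t-1} + e^{k_t}`, `p_t = lambda p_{t-1} + e^{k_t} v_t`,
#' and output `(p + e^{u+k_t} v_t) / (s + e^{u+k_t})` where `p, s` are the
#' states through `t-1` (`order = "rwkv"`, default) or through `t`
#' (`order = "literal"`, which counts the current token twice). Executed in
#' log space with a running maximum, so exponents far beyond overflow are
#' handled; every output channel is a convex combination of the value history.
#'
#' @param k,v key and value sequences `[T x D]`.
#' @param omega decay rates, length D (larger = faster forgetting).
#' @param u bonus weights, length D.
#' @param order `"rwkv"` or `"literal"`.
#' @return fused context `[T x D]`.
#' @export
wkv_scan <- function(k, v, omega, u, order = c("rwkv", "literal")) {
  order <- match.arg(order)
  D <- ncol(k)
  out <- cpp_wkv_fwd(t(k), t(v), omega, u, D, nrow(k), 1L,
                     as.integer(order == "literal"))
  t(matrix(out, D, nrow(k)))
}

#' One cross-modal conditioning direction
#'
#' Receptance from the (normalized) query stream, key/value from the context
#' stream, WKV recurrence, sigmoid gate and output projection.
#'
#' @param x_query,x_ctx normalized sequences `[T x D]` of equal shape.
#' @param params one direction's parameter list (`Mr`, `Mk`, `Mv`, `Wr`,
#'   `Wk`, `Wv`, `Wo`, `omega`, `u`).
#' @param cfg a [ctm_config()].
#' @return gated, projected output `[T x D]`.
#' @export
ctm_direction_forward <- function(x_query, x_ctx, params,
                                  cfg = ctm_config(d = ncol(x_query))) {
  if (!all(dim(x_query) == dim(x_ctx))) {
    stop("query and context sequences must have equal shape")
  }
  out <- ctm_dir_fwd(t(x_query), t(x_ctx), params, cfg, nrow(x_query), 1L)
  t(out$o)
}

#' Symmetric cross-modal fusion of two encoded sequences
#'
#' `RMSNorm(x_eeg + o_eeg) + RMSNorm(x_emg + o_emg)`, where `o_eeg`
#' conditions the EEG stream on EMG and `o_emg` the converse, with
#' independent parameters per direction.
#'
#' @param x_eeg,x_emg encoded sequences `[T x D]` of equal shape.
#' @param params full fusion parameter list (see the internal initializer; a
#'   fitted model exposes it as `model$params$ctm`).
#' @param cfg a [ctm_config()].
#' @return fused sequence `[T x D]`.
#' @export
ctm_fuse <- function(x_eeg, x_emg, params, cfg = ctm_config(d = ncol(x_eeg))) {
  if (!all(dim(x_eeg) == dim(x_emg))) stop("sequence shapes differ")
  out <- ctm_fuse_fwd(t(x_eeg), t(x_emg), params, cfg, nrow(x_eeg), 1L)
  t(out$y)
}
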