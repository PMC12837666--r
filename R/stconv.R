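# Spatio-temporal convolution block. A temporal convolution (kernel 1 x Kt,
# full over the 4 band rows) -> BN -> LeakyReLU, a spatial convolution over
# electrodes (kernel Ks x 1) -> BN -> LeakyReLU, and a 1x1 residual path from
# the input; C and T are preserved by symmetric same-padding. Kernels are full
# (not depthwise-factorized) convolutions with biases.

stconv_config <- function(channels, modality = c("eeg", "emg"), f_in = 4,
                          f_mid = 16, f_out = 4, kt = 25, ks = NULL,
                          leaky_slope = 0.01) {
  modality <- match.arg(modality)
  if (is.null(ks)) ks <- if (modality == "eeg") 13 else 3
  if (kt %% 2 == 0 || ks %% 2 == 0) {
    stop("convolution kernels must be odd for symmetric same-padding")
  }
  if (channels < 1) stop("need at least one channel")
  list(channels = channels, f_in = f_in, f_mid = f_mid, f_out = f_out,
       kt = kt, ks = ks, leaky_slope = leaky_slope)
}

stconv_init <- function(cfg) {
  list(
    Wt = array(glorot(cfg$f_mid, cfg$f_in * cfg$kt),
               dim = c(cfg$f_mid, cfg$f_in, cfg$kt)),
    bt = rep(0, cfg$f_mid),
    bn1 = bn_init(cfg$f_mid),
    Ws = array(glorot(cfg$f_out, cfg$f_mid * cfg$ks),
               dim = c(cfg$f_out, cfg$f_mid, cfg$ks)),
    bs = rep(0, cfg$f_out),
    bn2 = bn_init(cfg$f_out),
    Wr = glorot(cfg$f_out, cfg$f_in),
    br = rep(0, cfg$f_out)
  )
}

stconv_buffers <- function(cfg) {
  list(bn1 = bn_buffers(cfg$f_mid), bn2 = bn_buffers(cfg$f_out))
}

# x: [F_in, C, T, B]  ->  y: [F_out, C, T, B]
stconv_fwd <- function(x, par, buf, cfg, train = FALSE) {
  d <- dim(x)
  C <- d[2]; T <- d[3]; B <- d[4]
  stopifnot(d[1] == cfg$f_in, C == cfg$channels)
  z1 <- cpp_conv_time_fwd(x, cfg$f_in, C, T, B, par$Wt, cfg$f_mid, cfg$kt,
                          par$bt)
  dim(z1) <- c(cfg$f_mid, C * T * B)
  bn1 <- bn_fwd(z1, par$bn1, buf$bn1, train)
  a1 <- leaky_relu(bn1$y, cfg$leaky_slope)
  dim(a1) <- c(cfg$f_mid, C, T, B)
  z2 <- cpp_conv_space_fwd(a1, cfg$f_mid, C, T, B, par$Ws, cfg$f_out, cfg$ks,
                           par$bs)
  dim(z2) <- c(cfg$f_out, C * T * B)
  bn2 <- bn_fwd(z2, par$bn2, buf$bn2, train)
  a2 <- leaky_relu(bn2$y, cfg$leaky_slope)
  xmat <- x
  dim(xmat) <- c(cfg$f_in, C * T * B)
  res <- linear_fwd(par$Wr, xmat, par$br)
  y <- a2 + res
  dim(y) <- c(cfg$f_out, C, T, B)
  list(
    y = y,
    buf = list(bn1 = bn1$buf, bn2 = bn2$buf),
    # BN outputs (the activations' pre-images) are recomputed in the backward
    # pass from the cached normalized values to halve cache memory
    cache = list(x = x, a1 = a1,
                 bn1_cache = bn1$cache, bn2_cache = bn2$cache,
                 dims = c(C = C, T = T, B = B))
  )
}

stconv_bwd <- function(dy, par, cfg, cache) {
  C <- cache$dims["C"]; T <- cache$dims["T"]; B <- cache$dims["B"]
  dym <- dy
  dim(dym) <- c(cfg$f_out, C * T * B)
  xmat <- cache$x
  dim(xmat) <- c(cfg$f_in, C * T * B)
  res_bwd <- linear_bwd(par$Wr, xmat, dym)
  dx <- res_bwd$dx

  bn2_pre <- par$bn2$gamma * cache$bn2_cache$xhat + par$bn2$beta
  da2 <- dym * leaky_relu_grad(bn2_pre, cfg$leaky_slope)
  bn2_bwd <- bn_bwd(da2, par$bn2, cache$bn2_cache)
  dz2 <- bn2_bwd$dx
  dim(dz2) <- c(cfg$f_out, C, T, B)
  sp <- cpp_conv_space_bwd(cache$a1, cfg$f_mid, C, T, B, par$Ws, cfg$f_out,
                           cfg$ks, dz2)
  da1 <- sp$dx
  dim(da1) <- c(cfg$f_mid, C * T * B)
  bn1_pre <- par$bn1$gamma * cache$bn1_cache$xhat + par$bn1$beta
  dz1 <- da1 * leaky_relu_grad(bn1_pre, cfg$leaky_slope)
  bn1_bwd <- bn_bwd(dz1, par$bn1, cache$bn1_cache)
  dz0 <- bn1_bwd$dx
  dim(dz0) <- c(cfg$f_mid, C, T, B)
  tc <- cpp_conv_time_bwd(cache$x, cfg$f_in, C, T, B, par$Wt, cfg$f_mid,
                          cfg$kt, dz0)
  dx <- dx + tc$dx
  dim(dx) <- c(cfg$f_in, C, T, B)
  list(
    dx = dx,
    grads = list(
      Wt = array(tc$dW, dim = dim(par$Wt)),
      bt = tc$db,
      bn1 = bn1_bwd$grads,
      Ws = array(sp$dW, dim = dim(par$Ws)),
      bs = sp$db,
      bn2 = bn2_bwd$grads,
      Wr = res_bwd$dW,
      br = res_bwd$db
    )
  )
}

#' Flatten a feature tensor into a time-major sequence
#'
#' Converts a `[F x C x T]` feature tensor into the `[T x D]` sequence
#' consumed by the sequence models, with `D = F * C` and element
#' `(t, f*C + c) = features[f, c, t]` (frequency-major ordering, 0-based
#' index arithmetic).
#'
#' @param features numeric array `[F x C x T]`.
#' @return numeric matrix `[T x D]`.
#' @export
flatten_to_sequence <- function(features) {
  d <- dim(features)
  m <- matrix(aperm(features, c(2, 1, 3)), d[1] * d[2], d[3]) # rows c + C*f
  t(m)
}

#' Inverse of [flatten_to_sequence()]
#' @param x numeric matrix `[T x D]`.
#' @param f,c the band and channel counts with `D = f * c`.
#' @return numeric array `[f x c x T]`.
#' @export
unflatten_sequence <- function(x, f, c) {
  T <- nrow(x)
  arr <- array(t(x), dim = c(c, f, T))
  aperm(arr, c(2, 1, 3))
}

# Batch flatten: [F, C, T, B] -> [D, T*B]. Internally the D axis is ordered
# f + F*c (a fixed permutation of the exported frequency-major convention;
# equivalent up to a relabeling absorbed by the next learnable map, and free:
# a plain reshape instead of a transpose).
flatten_seq_batch <- function(features) {
  d <- dim(features)
  dim(features) <- c(d[1] * d[2], d[3] * d[4])
  features
}

# Inverse: [D, T*B] -> [F, C, T, B]
unflatten_seq_batch <- function(x, f, c, T, B) {
  dim(x) <- c(f, c, T, B)
  x
}
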