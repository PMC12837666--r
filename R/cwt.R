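#' Default physiological analysis bands
#'
#' EEG bands follow the clinical convention delta (1-4 Hz), theta-alpha
#' (4-13 Hz), beta (13-30 Hz), gamma (30-70 Hz). EMG bands cover 5-500 Hz in
#' four rows at the native 1024 Hz rate; for decimated recordings whose
#' Nyquist frequency falls below 500 Hz a compressed set (5-30, 30-60, 60-90,
#' 90-125 Hz) is used so that all four rows stay below Nyquist.
#'
#' @param modality `"eeg"` or `"emg"`.
#' @param fs sampling rate in Hz (matters only for EMG).
#' @return list of four `c(f_low, f_high)` pairs in Hz.
#' @export
default_bands <- function(modality = c("eeg", "emg"), fs = 1024) {
  modality <- match.arg(modality)
  if (modality == "eeg") {
    list(c(1, 4), c(4, 13), c(13, 30), c(30, 70))
  } else if (fs / 2 > 500) {
    list(c(5, 70), c(70, 150), c(150, 250), c(250, 500))
  } else {
    list(c(5, 30), c(30, 60), c(60, 90), c(90, min(125, floor(fs / 2) - 2)))
  }
}

#' Sampled complex Morlet wavelet kernel
#'
#' The analysis kernel at scale `a`: `conj(psi)(t/a) / sqrt(a)` sampled at the
#' signal rate on a symmetric grid truncated where the Gaussian envelope falls
#' to `exp(-12.5)` (`|t/a| <= 5`), with `psi(t) = pi^(-1/4) exp(i w0 t)
#' exp(-t^2/2)`. The center sample has magnitude `pi^(-1/4)/sqrt(a)`; doubling
#' the scale halves the peak by `sqrt(2)` and doubles the support.
#'
#' @param scale wavelet scale `a` in seconds.
#' @param omega0 dimensionless Morlet center parameter (default 6).
#' @param fs sampling rate in Hz.
#' @return complex vector of length `2L+1` with attribute `half_length = L`.
#' @export
morlet_kernel <- function(scale, omega0 = 6, fs = 1024) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  L <- ceiling(5 * scale * fs)
  t <- (-L:L) / fs
  x <- t / scale
  k <- pi^(-1 / 4) * exp(-1i * omega0 * x) * exp(-x^2 / 2) / sqrt(scale)
  attr(k, "half_length") <- L
  k
}

# Frequency -> scale map: f = omega0 / (2 pi a), a in seconds.
scale_for_frequency <- function(f, omega0 = 6) omega0 / (2 * pi * f)

# Per band, `n` log-spaced center frequencies strictly inside (f_low, f_high].
band_center_frequencies <- function(band, n) {
  r <- (band[2] / band[1])^(1 / n)
  band[1] * r^(seq_len(n))
}

# Reflect (mirror, no edge repetition) index into 1..T, tiling as needed.
reflect_index <- function(m, T) {
  if (T == 1) return(rep(1L, length(m)))
  m0 <- (m - 1) %% (2 * T - 2)
  ifelse(m0 < T, m0 + 1, 2 * T - m0 - 1)
}

# Precompute kernel spectra for a fixed (fs, T) geometry so that batches of
# windows reuse the FFTs. Kernel taps carry the quadrature weight dt, with the
# two endpoint taps halved (trapezoidal rule on the truncated support).
cwt_plan <- function(fs, T, bands, omega0 = 6, scales_per_band = 8,
                     boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  for (b in bands) {
    if (b[1] >= b[2]) stop("band edges must be strictly increasing")
    if (b[2] > fs / 2) {
      stop("band (", b[1], ", ", b[2], ") Hz lies above Nyquist (",
           fs / 2, " Hz)")
    }
  }
  freqs <- lapply(bands, band_center_frequencies, n = scales_per_band)
  scales <- lapply(freqs, scale_for_frequency, omega0 = omega0)
  Lmax <- max(vapply(unlist(scales), function(a) ceiling(5 * a * fs),
                     numeric(1)))
  Tpad <- T + 2 * Lmax
  nfft <- stats::nextn(Tpad, c(2, 3, 5))
  dt <- 1 / fs
  kernel_fft <- lapply(unlist(scales), function(a) {
    k <- morlet_kernel(a, omega0, fs)
    L <- attr(k, "half_length")
    w <- rep(dt, 2 * L + 1)
    w[c(1, 2 * L + 1)] <- dt / 2
    k <- k * w
    g <- complex(length.out = nfft)
    g[1] <- k[L + 1]
    if (L > 0) {
      g[1 + seq_len(L)] <- k[L + 1 + seq_len(L)]
      g[nfft + 1 - seq_len(L)] <- k[L + 1 - seq_len(L)]
    }
    fft(g)
  })
  list(
    fs = fs, T = T, bands = bands, omega0 = omega0,
    scales_per_band = scales_per_band, boundary = boundary,
    freqs = freqs, Lmax = Lmax, Tpad = Tpad, nfft = nfft,
    kernel_fft = kernel_fft,
    band_of_scale = rep(seq_along(bands), each = scales_per_band)
  )
}

# Apply a plan to one window [C x T]; returns |CWT| magnitudes averaged over
# the scales of each band: [F x C x T].
cwt_apply <- function(x, plan) {
  C <- nrow(x)
  T <- ncol(x)
  pad_idx <- if (plan$boundary == "reflect") {
    reflect_index(seq(1 - plan$Lmax, T + plan$Lmax), T)
  } else {
    NULL
  }
  xp <- matrix(0, plan$nfft, C)
  if (is.null(pad_idx)) {
    xp[plan$Lmax + seq_len(T), ] <- t(x)
  } else {
    xp[seq_len(plan$Tpad), ] <- t(x[, pad_idx, drop = FALSE])
  }
  Xf <- mvfft(xp)
  F <- length(plan$bands)
  out <- array(0, dim = c(F, C, T))
  sel <- plan$Lmax + seq_len(T)
  for (s in seq_along(plan$kernel_fft)) {
    conv <- mvfft(Xf * plan$kernel_fft[[s]], inverse = TRUE) / plan$nfft
    mag <- Mod(conv[sel, , drop = FALSE]) # [T x C]
    f <- plan$band_of_scale[s]
    out[f, , ] <- out[f, , ] + t(mag)
  }
  out / plan$scales_per_band
}

#' Compute a band scalogram of a multichannel window
#'
#' Applies the continuous wavelet transform with a complex Morlet mother
#' wavelet independently to each channel (FFT convolution with the truncated,
#' trapezoid-weighted kernel) and aggregates coefficient magnitudes into four
#' physiological band rows: each row is the mean magnitude over
#' `scales_per_band` log-spaced center frequencies strictly inside its band.
#'
#' @param x numeric matrix `[C x T]`, one analysis window.
#' @param fs sampling rate in Hz.
#' @param bands list of four `c(f_low, f_high)` pairs (see [default_bands()]).
#' @param omega0 Morlet center parameter.
#' @param scales_per_band number of log-spaced scales aggregated per band.
#' @param boundary `"reflect"` (mirror padding, default) or `"zero"`.
#' @return a `scalogram`: list with nonnegative `values` `[4 x C x T]`,
#'   `band_edges`, and `fs`.
#' @export
compute_scalogram <- function(x, fs, bands = default_bands("eeg"),
                              omega0 = 6, scales_per_band = 8,
                              boundary = c("reflect", "zero")) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("window contains non-finite values")
  plan <- cwt_plan(fs, ncol(x), bands, omega0, scales_per_band,
                   match.arg(boundary))
  structure(
    list(values = cwt_apply(x, plan), band_edges = bands, fs = fs),
    class = "scalogram"
  )
}

#' Scalograms for a batch of windows
#'
#' Vectorized front end used when preparing datasets: one FFT plan is shared
#' by all windows.
#'
#' @param x numeric array `[C x T x n]`.
#' @inheritParams compute_scalogram
#' @return numeric array `[4 x C x T x n]` of band magnitudes.
#' @export
scalogram_batch <- function(x, fs, bands = default_bands("eeg"), omega0 = 6,
                            scales_per_band = 8,
                            boundary = c("reflect", "zero")) {
  d <- dim(x)
  plan <- cwt_plan(fs, d[2], bands, omega0, scales_per_band,
                   match.arg(boundary))
  out <- array(0, dim = c(length(bands), d[1], d[2], d[3]))
  for (i in seq_len(d[3])) {
    out[, , , i] <- cwt_apply(x[, , i, drop = TRUE], plan)
  }
  out
}

#' Per-band time-averaged energy of a scalogram
#'
#' Diagnostic summary: for each band row, the squared magnitudes averaged over
#' time and channels. For a sinusoid at a band's center frequency the bulk of
#' the energy concentrates in that band's entry.
#'
#' @param scal a `scalogram`.
#' @return nonnegative numeric vector of length 4.
#' @export
band_energy_profile <- function(scal) {
  v <- scal$values
  apply(v^2, 1, mean)
}
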