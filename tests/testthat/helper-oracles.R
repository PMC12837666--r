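# Independent reference implementations (oracles) and small utilities used
# across the suite. Oracles are deliberately naive - direct summation, dense
# matrix exponentials, explicit loops - and share no code with the package's
# optimized paths.

relerr <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}

# O(T^2) direct-summation WKV oracle, both state orderings.
wkv_direct_sum <- function(k, v, omega, u, order = "rwkv") {
  Tn <- nrow(k)
  D <- ncol(k)
  out <- k * 0
  hist_end <- if (order == "rwkv") function(t) t - 1 else function(t) t
  for (t in seq_len(Tn)) {
    for (d in seq_len(D)) {
      num <- 0
      den <- 0
      he <- hist_end(t)
      if (he >= 1) {
        for (i in seq_len(he)) {
          w <- exp(-(he - i) * omega[d] + k[i, d])
          num <- num + w * v[i, d]
          den <- den + w
        }
      }
      b <- exp(u[d] + k[t, d])
      out[t, d] <- (num + b * v[t, d]) / (den + b)
    }
  }
  out
}

# Naive real-space WKV recurrence (no log-space stabilization).
wkv_naive_recurrence <- function(k, v, omega, u, order = "rwkv") {
  Tn <- nrow(k)
  D <- ncol(k)
  out <- k * 0
  lam <- exp(-omega)
  s <- rep(0, D)
  p <- rep(0, D)
  for (t in seq_len(Tn)) {
    ek <- exp(k[t, ])
    eb <- exp(u + k[t, ])
    if (order == "literal") {
      s <- lam * s + ek
      p <- lam * p + ek * v[t, ]
      out[t, ] <- (p + eb * v[t, ]) / (s + eb)
    } else {
      out[t, ] <- (p + eb * v[t, ]) / (s + eb)
      s <- lam * s + ek
      p <- lam * p + ek * v[t, ]
    }
  }
  out
}

# Naive SSM scan: per-step dense matrix-exponential discretization.
naive_mamba_scan <- function(u, deltas, B_seq, C_seq, D_skip) {
  Tn <- nrow(u)
  E <- ncol(u)
  N <- ncol(B_seq)
  A <- -diag(seq_len(N))
  h <- matrix(0, E, N)
  y <- u * 0
  for (t in seq_len(Tn)) {
    for (e in seq_len(E)) {
      eA <- as.matrix(Matrix::expm(deltas[t, e] * A))
      Bbar <- (eA - diag(N)) %*% solve(A) %*% B_seq[t, ]
      h[e, ] <- diag(eA) * h[e, ] + as.numeric(Bbar) * u[t, e]
      y[t, e] <- sum(C_seq[t, ] * h[e, ]) + D_skip[e] * u[t, e]
    }
  }
  y
}

# Direct trapezoidal quadrature of the Morlet CWT (zero extension), per
# center frequency; returns [n_freq x T] coefficient magnitudes.
cwt_quadrature <- function(x, fs, freqs, omega0 = 6) {
  Tn <- length(x)
  out <- matrix(0, length(freqs), Tn)
  for (j in seq_along(freqs)) {
    a <- omega0 / (2 * pi * freqs[j])
    L <- ceiling(5 * a * fs)
    for (b in seq_len(Tn)) {
      idx <- (b - L):(b + L)
      tt <- (idx - b) / fs
      xv <- ifelse(idx >= 1 & idx <= Tn, x[pmin(pmax(idx, 1), Tn)], 0)
      psi <- pi^(-1 / 4) * exp(1i * omega0 * tt / a) * exp(-(tt / a)^2 / 2)
      w <- rep(1 / fs, length(idx))
      w[c(1, length(idx))] <- 0.5 / fs
      out[j, b] <- Mod(sum(xv * Conj(psi) * w / sqrt(a)))
    }
  }
  out
}

# Central finite differences of a scalar function of a parameter vector.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x
    x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Small geometry used by model-level tests: 3 EEG + 2 EMG channels at 64 Hz.
tiny_model_config <- function(...) {
  model_config(
    fs = 64, eeg_channels = 3, emg_channels = 2, d_model = 16,
    bands_eeg = list(c(1, 4), c(4, 8), c(8, 16), c(16, 30)),
    bands_emg = list(c(2, 6), c(6, 12), c(12, 20), c(20, 30)),
    scales_per_band = 2, ...
  )
}

# Tiny synthetic cohort for pipeline tests.
tiny_synth_config <- function(n_subjects = 4, recording_seconds = 30, ...) {
  synth_config(n_subjects = n_subjects,
               recording_seconds = recording_seconds, fs = 64,
               n_eeg = 3, n_emg = 2,
               emg_event = list(lag_mean_s = 0.15, lag_sd_s = 0.05,
                                burst_band_hz = c(5, 25), decay_tau_s = 0.4,
                                burst_gain = 4),
               noise = list(pink_exponent = 1, line_hz = 50, line_amp = 0,
                            artifact_rate = 2, artifact_gain = 3.5),
               ...)
}

# A deterministic sinusoid-mixture recording for I/O and filter tests.
toy_recording <- function(fs = 1024, seconds = 4, n_eeg = 3, n_emg = 2,
                          seed = 1) {
  set.seed(seed)
  n <- fs * seconds
  t <- (seq_len(n) - 1) / fs
  eeg <- t(sapply(seq_len(n_eeg), function(c) {
    sin(2 * pi * (4 + c) * t) + 0.3 * rnorm(n)
  }))
  emg <- t(sapply(seq_len(n_emg), function(c) {
    sin(2 * pi * (40 + 5 * c) * t) + 0.3 * rnorm(n)
  }))
  multimodal_recording(eeg, emg, fs = fs, subject_id = "toy",
                       recording_id = "toy_r1")
}
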