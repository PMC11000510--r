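# Wavelet transform coherence dFC (the TF method): Morlet continuous
# wavelet transform, smoothed cross/auto spectra, scale-averaged coherence
# with cone-of-influence masking.

MORLET_OMEGA0 <- 6
# Relation between Morlet scale and Fourier period for omega0.
morlet_fourier_factor <- function(omega0 = MORLET_OMEGA0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# Continuous Morlet wavelet transform via FFT; returns n_scales x T complex.
cwt_morlet <- function(x, scales, dt, omega0 = MORLET_OMEGA0) {
  N <- length(x)
  npad <- 2^ceiling(log2(N))
  xp <- c(x - mean(x), rep(0, npad - N))
  fx <- stats::fft(xp)
  k <- seq_len(npad) - 1
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  out <- matrix(0i, length(scales), N)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    pos <- omega > 0
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    wj <- stats::fft(fx * psi, inverse = TRUE) / npad
    out[j, ] <- wj[seq_len(N)]
  }
  out
}

# Gaussian time smoothing per scale (kernel sd = scale, in time units),
# FFT-based, vectorized across scales. M is n_scales x T (complex ok).
smooth_time_by_scale <- function(M, scales, dt) {
  N <- ncol(M)
  max_half <- min(N, max(3, ceiling(3 * max(scales) / dt)))
  npad <- 2^ceiling(log2(N + 2 * max_half + 1))
  # signals in columns: npad x n_scales
  S <- matrix(0i, npad, nrow(M))
  S[seq_len(N), ] <- t(M)
  FS <- stats::mvfft(S)
  Kmat <- matrix(0, npad, nrow(M))
  for (j in seq_along(scales)) {
    half <- min(npad %/% 2 - 1, max(1, ceiling(3 * scales[j] / dt)))
    tt <- seq(-half, half)
    g <- exp(-(tt * dt)^2 / (2 * scales[j]^2))
    g <- g / sum(g)
    kern <- numeric(npad)
    kern[1] <- g[half + 1]
    kern[1 + seq_len(half)] <- g[half + 1 + seq_len(half)]
    kern[npad + 1 - seq_len(half)] <- g[half + 1 - seq_len(half)]
    Kmat[, j] <- kern
  }
  FK <- stats::mvfft(Kmat)
  sm <- stats::mvfft(FS * FK, inverse = TRUE) / npad
  t(sm[seq_len(N), , drop = FALSE])
}

# Boxcar smoothing along the scale axis (decorrelation width 0.6 scale
# octaves for the Morlet), edge-normalized.
smooth_across_scales <- function(M, scales, width_octaves = 0.6) {
  n <- nrow(M)
  if (n < 3) return(M)
  dj <- log2(scales[n] / scales[1]) / (n - 1)
  half <- floor(width_octaves / (2 * dj))
  if (half < 1) return(M)
  cs <- rbind(0, apply(M, 2, cumsum))
  out <- M
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i, ] <- (cs[hi + 1, ] - cs[lo, ]) / (hi - lo + 1)
  }
  out
}

smooth_spectrum <- function(M, scales, dt) {
  smooth_across_scales(smooth_time_by_scale(M / scales, scales, dt), scales)
}

#' Wavelet-coherence dFC (method TF)
#'
#' For each ROI pair, computes the continuous Morlet wavelet transform at
#' `n_scales` logarithmically spaced scales (Fourier periods from `2*TR` to
#' `T*TR/4`), forms the magnitude-squared wavelet transform coherence from
#' smoothed cross- and auto-spectra (Gaussian time smoothing with width
#' proportional to scale, boxcar smoothing of 0.6 octaves across scales),
#' and averages the coherence across scales at each time point. With
#' `coi_mask = TRUE` only scales whose cone of influence (e-folding distance
#' `sqrt(2) * scale`) admits the time point enter the average; edge points
#' admitting no scale fall back to the smallest scale. The result is a
#' per-TR dFC matrix with values in \[0, 1\] (1 on the diagonal and for
#' identical inputs).
#'
#' @param ts A z-standardized [parcellated_ts()].
#' @param n_scales Number of wavelet scales (default 101).
#' @param coi_mask Exclude scales inside the cone of influence from the
#'   per-time-point average (default TRUE).
#' @param omega0 Morlet center frequency (default 6).
#' @return A [dfc_matrix()] with `method_id = "TF"` and T' = T.
#' @export
wavelet_coherence_dfc <- function(ts, n_scales = 101, coi_mask = TRUE,
                                  omega0 = MORLET_OMEGA0) {
  stopifnot(inherits(ts, "parcellated_ts"))
  X <- ts$values
  T <- nrow(X)
  R <- ncol(X)
  dt <- ts$tr_seconds
  if (T < 8) {
    stop_fmt("series too short (%d points) for wavelet analysis; need T >= 8 or fewer scales",
             T)
  }
  if (!is_count(n_scales) || n_scales < 2) {
    stop_fmt("n_scales must be an integer >= 2")
  }
  periods <- exp(seq(log(2 * dt), log(T * dt / 4), length.out = n_scales))
  scales <- periods / morlet_fourier_factor(omega0)

  Wl <- lapply(seq_len(R), function(r) cwt_morlet(X[, r], scales, dt, omega0))
  Sauto <- lapply(Wl, function(w) {
    pmax(Re(smooth_spectrum(abs(w)^2, scales, dt)), 1e-300)
  })

  # COI admissibility: scale j valid at time t when sqrt(2)*s_j <= distance
  # to the nearer series edge.
  edge_dist <- dt * pmin(seq_len(T) - 1, T - seq_len(T))
  if (coi_mask) {
    valid <- outer(sqrt(2) * scales, edge_dist, `<=`)
    none <- colSums(valid) == 0
    valid[1, none] <- TRUE  # least edge-affected scale as fallback
  } else {
    valid <- matrix(TRUE, n_scales, T)
  }
  nvalid <- colSums(valid)

  vals <- array(0, c(T, R, R))
  for (t in seq_len(T)) vals[t, , ] <- diag(R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (j >= i) next
      S12 <- smooth_spectrum(Wl[[i]] * Conj(Wl[[j]]), scales, dt)
      wtc <- Mod(S12)^2 / (Sauto[[i]] * Sauto[[j]])
      wtc <- pmin(pmax(wtc, 0), 1)
      avg <- colSums(wtc * valid) / nvalid
      vals[, i, j] <- avg
      vals[, j, i] <- avg
    }
  }
  dfc_matrix(vals, seq_len(T), ts$subject_id, "TF",
             ts$roi_labels, ts$rsn_labels)
}

#' Scale-resolved wavelet coherence for one signal pair
#'
#' Lower-level access to the smoothed magnitude-squared coherence on the
#' full scale x time plane, e.g. to inspect coherence at a known frequency.
#'
#' @param x,y Equal-length numeric signals.
#' @param dt Sampling interval in seconds.
#' @param n_scales Number of scales.
#' @param omega0 Morlet center frequency.
#' @return List with `periods` (seconds), `scales`, and `wtc`
#'   (n_scales x T matrix in \[0, 1\]).
#' @export
wavelet_coherence_pair <- function(x, y, dt, n_scales = 101,
                                   omega0 = MORLET_OMEGA0) {
  stopifnot(length(x) == length(y))
  T <- length(x)
  periods <- exp(seq(log(2 * dt), log(T * dt / 4), length.out = n_scales))
  scales <- periods / morlet_fourier_factor(omega0)
  Wx <- cwt_morlet(x, scales, dt, omega0)
  Wy <- cwt_morlet(y, scales, dt, omega0)
  Sx <- pmax(Re(smooth_spectrum(abs(Wx)^2, scales, dt)), 1e-300)
  Sy <- pmax(Re(smooth_spectrum(abs(Wy)^2, scales, dt)), 1e-300)
  S12 <- smooth_spectrum(Wx * Conj(Wy), scales, dt)
  wtc <- pmin(pmax(Mod(S12)^2 / (Sx * Sy), 0), 1)
  list(periods = periods, scales = scales, wtc = wtc)
}
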