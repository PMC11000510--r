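# Tapered sliding-window correlation (the SW method).

#' Build a tapered sliding window
#'
#' The taper is the full discrete convolution of a rectangle of
#' `nominal_len_tr` samples with a Gaussian kernel of standard deviation
#' `sigma_tr` truncated at +/- 3 sigma (kernel length `2*3*sigma + 1`), then
#' normalized to sum 1. With the defaults (60-TR rectangle, sigma = 3) the
#' effective support is W = 60 + 19 - 1 = 78 TRs, which together with a
#' 30-TR step yields 38 fully contained windows on a 1200-TR series. With
#' `sigma_tr = 0` the window is the plain rectangle.
#'
#' @param nominal_len_tr Rectangle length in TRs (default 60, i.e. 44 s at
#'   TR = 0.72 s).
#' @param sigma_tr Gaussian taper sigma in TRs (default 3; 0 disables the
#'   taper).
#' @param step_tr Window step in TRs (default 30, 50% nominal overlap).
#' @return An object of class `tapered_window` with fields `weights`,
#'   `nominal_len_tr`, `sigma_tr`, `step_tr`.
#' @export
make_tapered_window <- function(nominal_len_tr = 60, sigma_tr = 3,
                                step_tr = 30) {
  if (!is_count(nominal_len_tr) || nominal_len_tr < 2) {
    stop_fmt("nominal_len_tr must be an integer >= 2")
  }
  if (!is.numeric(sigma_tr) || sigma_tr < 0) stop_fmt("sigma_tr must be >= 0")
  if (!is_count(step_tr)) stop_fmt("step_tr must be a positive integer")
  rect <- rep(1, nominal_len_tr)
  if (sigma_tr > 0) {
    half <- 3 * ceiling(sigma_tr)
    g <- stats::dnorm(seq(-half, half), sd = sigma_tr)
    w <- conv_full(rect, g)
  } else {
    w <- rect
  }
  w <- w / sum(w)
  structure(list(weights = w, nominal_len_tr = as.integer(nominal_len_tr),
                 sigma_tr = sigma_tr, step_tr = as.integer(step_tr)),
            class = "tapered_window")
}

# Full ("open") discrete convolution, length(a) + length(b) - 1.
conv_full <- function(a, b) {
  out <- stats::convolve(a, rev(b), type = "open")
  # convolve can leave tiny negative round-off; the taper is nonnegative.
  pmax(out, 0)
}

# Number of fully contained window positions.
n_windows <- function(T, W, step) {
  if (T < W) stop_fmt("series length (%d) shorter than window (%d)", T, W)
  as.integer((T - W) %/% step + 1L)
}

# Weighted Pearson correlation matrix of segment X (W x R) with weights w
# (sum 1).
weighted_corr <- function(X, w) {
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc * w, Xc)          # weighted covariance
  d <- sqrt(diag(C))
  corr <- C / outer(d, d)
  corr[!is.finite(corr)] <- 0         # zero-variance ROI within a window
  diag(corr) <- 1
  (corr + t(corr)) / 2
}

#' Sliding-window dFC (method SW)
#'
#' Computes, for every fully contained window position, the weighted
#' Pearson correlation between all ROI pairs using the taper weights as
#' observation weights. Window starts are 1, 1+step, 1+2*step, ...; the time
#' stamp of each window is its center TR, and the number of windows is
#' `floor((T - W)/step) + 1` (38 for the defaults on 1200 TRs).
#'
#' @param ts A z-standardized [parcellated_ts()].
#' @param window A [make_tapered_window()].
#' @return A [dfc_matrix()] with `method_id = "SW"`.
#' @export
sliding_window_dfc <- function(ts, window = make_tapered_window()) {
  stopifnot(inherits(ts, "parcellated_ts"), inherits(window, "tapered_window"))
  X <- ts$values
  T <- nrow(X)
  W <- length(window$weights)
  step <- window$step_tr
  nw <- n_windows(T, W, step)
  R <- ncol(X)
  vals <- array(0, c(nw, R, R))
  starts <- 1L + (seq_len(nw) - 1L) * step
  for (i in seq_len(nw)) {
    seg <- X[starts[i]:(starts[i] + W - 1L), , drop = FALSE]
    vals[i, , ] <- weighted_corr(seg, window$weights)
  }
  centers <- starts + (W - 1) / 2
  dfc_matrix(vals, centers, ts$subject_id, "SW",
             ts$roi_labels, ts$rsn_labels)
}

#' The sliding-window time grid for a series of length T
#'
#' @param T Number of TRs.
#' @param window A [make_tapered_window()].
#' @return Numeric vector of window-center time stamps.
#' @export
sliding_window_grid <- function(T, window = make_tapered_window()) {
  W <- length(window$weights)
  nw <- n_windows(T, W, window$step_tr)
  1L + (seq_len(nw) - 1L) * window$step_tr + (W - 1) / 2
}
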