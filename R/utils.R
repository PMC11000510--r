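# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The seven dFC method identifiers
#'
#' Canonical identifiers of the implemented dFC estimators: sliding window
#' (SW), time-frequency / wavelet coherence (TF), coactivation patterns (CAP),
#' sliding-window clustering (SWC), continuous HMM (CHMM), discrete HMM
#' (DHMM), and window-less k-SVD (WL).
#'
#' @format Character vector of length 7.
#' @export
DFC_METHODS <- c("SW", "TF", "CAP", "SWC", "CHMM", "DHMM", "WL")

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_fmt("%s must be a square matrix", what)
  }
  d <- max(abs(m - t(m)))
  if (d > tol) {
    stop_fmt("%s is asymmetric beyond tolerance (max |A - t(A)| = %.3g)", what, d)
  }
  invisible(TRUE)
}

# Population standard deviation (1/n denominator); the package-wide
# standardization convention.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Optimal one-to-one state matching
#'
#' Finds the permutation of columns minimizing the total assignment cost,
#' by exhaustive enumeration. Used to align recovered states with planted
#' ground-truth states before scoring parameter recovery; exact for the
#' small state counts (K <= 9) used in validation.
#'
#' @param cost K x K matrix; `cost[i, j]` is the cost of assigning
#'   recovered state `i` to reference state `j`.
#' @return Integer vector `p` of length K: recovered state `i` is matched to
#'   reference state `p[i]`.
#' @export
match_states <- function(cost) {
  K <- nrow(cost)
  if (ncol(cost) != K) stop_fmt("cost matrix must be square")
  if (K > 9) stop_fmt("exhaustive matching supports K <= 9")
  perms <- all_permutations(K)
  best <- NULL
  best_cost <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    tc <- sum(cost[cbind(seq_len(K), p)])
    if (tc < best_cost) {
      best_cost <- tc
      best <- p
    }
  }
  best
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    rest <- setdiff(seq_len(n), k)
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# Derive a reproducible sub-seed from a base seed; kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}
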