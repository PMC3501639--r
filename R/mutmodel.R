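# HKY+Gamma mutation model for sequence simulation on genealogies.

#' Construct an HKY(+Gamma) mutation model
#'
#' Hasegawa-Kishino-Yano substitution model: unequal base frequencies and a
#' transition/transversion rate ratio `kappa`, with optional continuous
#' Gamma-distributed among-site rate variation (shape `alpha`, mean 1).
#' The rate matrix is normalised to one expected substitution per site per
#' unit of evolutionary distance, so branch lengths scale directly with the
#' per-site mutation rate.
#'
#' @param kappa Transition/transversion rate ratio (>0). `kappa = 1` with
#'   equal frequencies reduces to Jukes-Cantor.
#' @param base_freqs Numeric length-4 `(pi_A, pi_C, pi_G, pi_T)`, summing
#'   to 1. The default is a control-region-like AT-rich composition.
#' @param gamma_shape Shape `alpha` of the Gamma rate heterogeneity
#'   (default 0.5); `NULL` disables rate variation.
#' @param rate_per_site_per_my Substitution rate per site per million years
#'   per lineage: a single value, or `c(lo, hi)` for a uniform prior drawn
#'   once per simulated replicate. "2% per my" is `0.02`.
#' @return Object of class `mutation_model`.
#' @export
hky_model <- function(kappa = 10, base_freqs = c(0.31, 0.23, 0.14, 0.32),
                      gamma_shape = 0.5,
                      rate_per_site_per_my = c(0.02, 0.063)) {
  if (kappa <= 0) stop("kappa must be positive")
  if (length(base_freqs) != 4L || abs(sum(base_freqs) - 1) > 1e-8 ||
      any(base_freqs <= 0))
    stop("base_freqs must be 4 positive values summing to 1")
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be > 0")
  r <- rate_per_site_per_my
  if (!length(r) %in% 1:2 || any(r <= 0) || (length(r) == 2L && r[1] > r[2]))
    stop("rate_per_site_per_my must be a positive value or c(lo, hi), lo <= hi")
  structure(list(kind = "HKY", kappa = kappa, base_freqs = base_freqs,
                 gamma_shape = gamma_shape, rate_per_site_per_my = r),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("HKY", if (!is.null(x$gamma_shape)) "+G" else "", " model: kappa = ",
      x$kappa, ", freqs = (", paste(x$base_freqs, collapse = ", "),
      ")", sep = "")
  if (!is.null(x$gamma_shape)) cat(", alpha =", x$gamma_shape)
  r <- x$rate_per_site_per_my
  cat("; rate ", if (length(r) == 2L)
    paste0("U(", r[1], ", ", r[2], ")") else r, " /site/my\n", sep = "")
  invisible(x)
}

# Spectral decomposition of the normalised HKY rate matrix, via the
# pi-symmetrised form (the model is reversible, so eigenvalues are real):
#   P(t) = U diag(exp(lambda t)) Uinv.
hky_eigen <- function(model) {
  pi <- model$base_freqs
  k <- model$kappa
  is_transition <- function(i, j) (i == 1 & j == 3) | (i == 3 & j == 1) |
    (i == 2 & j == 4) | (i == 4 & j == 2)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- pi[j] * if (is_transition(i, j)) k else 1
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))
  Q <- Q / mean_rate
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- diag(1 / s) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(s)
  list(U = U, Uinv = Uinv, lambda = e$values, freqs = pi, Q = Q)
}

# Per-site rate multipliers (mean 1); alpha = NULL means no heterogeneity.
gamma_site_rates <- function(L, alpha) {
  if (is.null(alpha)) rep(1, L) else rgamma(L, shape = alpha, rate = alpha)
}
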