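#' GTR+Gamma nucleotide model parameters
#'
#' General time-reversible nucleotide model with discrete-Gamma rate
#' variation across sites (equal-probability categories with mean-1 rates).
#'
#' @param exchangeabilities Six relative rates in the order AC, AG, AT, CG,
#'   CT, GT (all > 0).
#' @param base_freqs Frequencies of A, C, G, T summing to 1.
#' @param alpha Gamma shape (> 0); smaller means stronger rate heterogeneity.
#' @param n_cat Number of discrete rate categories (default 4).
#' @return Object of class `gtr_gamma_params`.
#' @export
gtr_gamma_params <- function(exchangeabilities = rep(1, 6),
                             base_freqs = rep(0.25, 4),
                             alpha = 1, n_cat = 4) {
  if (length(exchangeabilities) != 6 || any(exchangeabilities <= 0))
    stop("need 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  if (length(base_freqs) != 4 || any(base_freqs < 0))
    stop("need 4 nonnegative base frequencies")
  if (alpha <= 0) stop("alpha must be > 0")
  base_freqs <- .floor_frequencies(base_freqs)
  structure(list(exchangeabilities = exchangeabilities,
                 base_freqs = stats::setNames(base_freqs, c("A", "C", "G", "T")),
                 alpha = alpha, n_cat = as.integer(n_cat)),
            class = "gtr_gamma_params")
}

#' GTR rate matrix
#'
#' @param params A [gtr_gamma_params()].
#' @param scale Scale to mean rate 1 (default TRUE).
#' @return 4x4 rate matrix over A, C, G, T.
#' @export
gtr_rate_matrix <- function(params, scale = TRUE) {
  r <- params$exchangeabilities
  pi <- params$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mr <- sum(pi * -diag(Q))
  if (scale && mr > 0) Q <- Q / mr
  attr(Q, "mean_rate") <- mr
  Q
}

#' Discrete-Gamma category rates
#'
#' Mean rates of `n_cat` equal-probability categories of a Gamma(alpha, alpha)
#' distribution; the category rates average exactly 1.
#'
#' @param alpha Shape parameter (> 0).
#' @param n_cat Number of categories.
#' @return Numeric vector of length `n_cat`.
#' @export
discrete_gamma_rates <- function(alpha, n_cat = 4) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (n_cat == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = n_cat + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- n_cat * diff(p)
  r / mean(r)
}

# IUPAC nucleotide ambiguity sets used to build tip partial likelihoods
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"))
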