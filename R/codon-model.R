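#' Codon substitution model parameters
#'
#' Parameters of the Goldman-Yang-style codon model: transition/transversion
#' rate ratio kappa, nonsynonymous/synonymous rate ratio omega (dN/dS), and
#' the stationary frequencies of the 61 sense codons.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega dN/dS ratio, >= 0 (< 1 purifying, 1 neutral, > 1 adaptive).
#' @param pi Numeric vector of 61 sense-codon frequencies summing to 1;
#'   default uniform.
#' @return Object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa = 2, omega = 0.5, pi = NULL) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  if (length(pi) != 61 || any(pi < 0)) stop("pi must be 61 nonnegative frequencies")
  pi <- .floor_frequencies(pi)
  structure(list(kappa = kappa, omega = omega, pi = pi),
            class = "codon_model_params")
}

# Epsilon-floor zero frequencies (degenerate pi would disconnect states),
# then renormalize.
.floor_frequencies <- function(pi, eps = 1e-8) {
  pi <- pmax(pi, eps)
  pi / sum(pi)
}

#' GY94 codon rate matrix
#'
#' Builds the 61x61 instantaneous rate matrix: zero for multi-nucleotide
#' changes, proportional to the target-codon frequency, multiplied by kappa
#' for transitions and omega for nonsynonymous changes. Rows sum to zero.
#'
#' @param params A [codon_model_params()].
#' @param code A [genetic_code()].
#' @param scale If `TRUE` (default) the matrix is scaled so the mean rate
#'   `sum(pi * -diag(Q))` equals 1 (branch lengths in expected substitutions
#'   per codon).
#' @return 61x61 rate matrix with sense codons as dimnames; the pre-scaling
#'   mean rate is attached as attribute `"mean_rate"`.
#' @export
build_codon_rate_matrix <- function(params, code = genetic_code(), scale = TRUE) {
  ps <- codon_pair_structure(code)
  n <- length(code$sense_codons)
  Q <- matrix(0, n, n, dimnames = list(code$sense_codons, code$sense_codons))
  rate <- params$pi[ps$j] *
    ifelse(ps$transition, params$kappa, 1) *
    ifelse(ps$nonsyn, params$omega, 1)
  Q[cbind(ps$i, ps$j)] <- rate
  diag(Q) <- -rowSums(Q)
  mean_rate <- sum(params$pi * -diag(Q))
  if (scale && mean_rate > 0) Q <- Q / mean_rate
  attr(Q, "mean_rate") <- mean_rate
  Q
}

#' F3x4 codon frequencies from an alignment
#'
#' Estimates sense-codon stationary frequencies as the product of
#' position-specific nucleotide frequencies (codon positions 1..3),
#' renormalized over the 61 sense codons — the common default frequency
#' model of codon-model software.
#'
#' @param aln A [codon_alignment()].
#' @param code A [genetic_code()].
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
estimate_codon_frequencies_f3x4 <- function(aln, code = genetic_code()) {
  stopifnot(inherits(aln, "codon_alignment"))
  cells <- as.vector(aln$codons)
  cells <- cells[grepl("^[ACGT]{3}$", cells)]
  if (!length(cells)) stop("alignment has no unambiguous codons")
  posfreq <- vapply(1:3, function(p) {
    nt <- substr(cells, p, p)
    tab <- table(factor(nt, levels = c("A", "C", "G", "T")))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(posfreq) <- c("A", "C", "G", "T")
  pi <- vapply(code$sense_codons, function(cd) {
    posfreq[substr(cd, 1, 1), 1] * posfreq[substr(cd, 2, 2), 2] *
      posfreq[substr(cd, 3, 3), 3]
  }, numeric(1))
  .floor_frequencies(pi / sum(pi))
}

#' Site-class mixtures for site and branch-site models
#'
#' Defines the omega site-class structure of the standard codon models:
#' \describe{
#'   \item{M0}{one class, one omega everywhere.}
#'   \item{M1a}{nearly neutral: class 0 (omega0 < 1) and class 1 (omega = 1).}
#'   \item{M2a}{positive selection: M1a plus class 2 with omega2 >= 1 on all
#'     branches.}
#'   \item{modelA}{branch-site model A: classes 0 and 1 as M1a; classes 2a/2b
#'     evolve like 0 and 1 on background branches but share omega2 on
#'     foreground branches, with proportions
#'     `p2a = (1-p0-p1) p0/(p0+p1)`, `p2b = (1-p0-p1) p1/(p0+p1)`.}
#'   \item{modelA_null}{model A with omega2 fixed at 1.}
#' }
#'
#' @param model_tag One of `"M0"`, `"M1a"`, `"M2a"`, `"modelA"`,
#'   `"modelA_null"`.
#' @param p0,p1 Class proportions (p1 ignored where not needed).
#' @param omega0 Purifying-class omega (0 <= omega0, typically < 1).
#' @param omega2 Selected-class omega (>= 1 for M2a/model A).
#' @param omega Single omega for M0.
#' @return Object of class `site_class_mixture`: tibble `classes` with columns
#'   `class`, `proportion`, `omega_background`, `omega_foreground`, plus
#'   `model_tag` and the free mixture parameter count `df_mixture`.
#' @export
site_class_mixture <- function(model_tag, p0 = 0.5, p1 = 0.3, omega0 = 0.1,
                               omega2 = 2, omega = 0.5) {
  raw <- .mixture_raw(model_tag, p0 = p0, p1 = p1, omega0 = omega0,
                      omega2 = omega2, omega = omega, validate = TRUE)
  cls <- tibble::tibble(class = raw$class, proportion = raw$proportion,
                        omega_background = raw$omega_bg,
                        omega_foreground = raw$omega_fg)
  structure(list(classes = cls, model_tag = raw$model_tag,
                 df_mixture = raw$df_mixture),
            class = "site_class_mixture")
}

# Lightweight mixture representation (plain vectors) used in optimizer inner
# loops, where tibble construction per evaluation would dominate.
.mixture_raw <- function(model_tag, p0 = 0.5, p1 = 0.3, omega0 = 0.1,
                         omega2 = 2, omega = 0.5, validate = FALSE) {
  if (validate) {
    model_tag <- match.arg(model_tag,
                           c("M0", "M1a", "M2a", "modelA", "modelA_null"))
    chk <- function(x, nm) if (x < 0 || x > 1) stop(nm, " must be in [0, 1]")
    if (model_tag != "M0") chk(p0, "p0")
    if (model_tag %in% c("M2a", "modelA", "modelA_null")) {
      chk(p1, "p1")
      if (p0 + p1 > 1 + 1e-12) stop("p0 + p1 must be <= 1")
      if (model_tag != "M2a" && p0 + p1 <= 0)
        stop("model A requires p0 + p1 > 0")
    }
  }
  out <- switch(model_tag,
    M0 = list(class = "0", proportion = 1, omega_bg = omega, omega_fg = omega,
              df_mixture = 1L),
    M1a = list(class = c("0", "1"), proportion = c(p0, 1 - p0),
               omega_bg = c(omega0, 1), omega_fg = c(omega0, 1),
               df_mixture = 2L),
    M2a = list(class = c("0", "1", "2"),
               proportion = c(p0, p1, max(0, 1 - p0 - p1)),
               omega_bg = c(omega0, 1, omega2),
               omega_fg = c(omega0, 1, omega2), df_mixture = 4L),
    {
      if (model_tag == "modelA_null") omega2 <- 1
      p2 <- max(0, 1 - p0 - p1)
      list(class = c("0", "1", "2a", "2b"),
           proportion = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
           omega_bg = c(omega0, 1, omega0, 1),
           omega_fg = c(omega0, 1, omega2, omega2),
           df_mixture = if (model_tag == "modelA_null") 3L else 4L)
    })
  out$model_tag <- model_tag
  out
}

.as_raw_mixture <- function(x) {
  if (inherits(x, "site_class_mixture")) {
    list(class = x$classes$class, proportion = x$classes$proportion,
         omega_bg = x$classes$omega_background,
         omega_fg = x$classes$omega_foreground,
         df_mixture = x$df_mixture, model_tag = x$model_tag)
  } else x
}

#' @export
print.site_class_mixture <- function(x, ...) {
  cat("site-class mixture (", x$model_tag, ")\n", sep = "")
  print(x$classes)
  invisible(x)
}

# Spectral decomposition of a reversible generator Q with stationary pi:
# P(t) = A exp(Lambda t) B with A = D^{-1/2} V, B = V' D^{1/2}.
spectral_decomposition <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(A = es$vectors / d, B = t(es$vectors) * rep(d, each = length(d)),
       lambda = es$values)
}

#' Transition probabilities over a branch
#'
#' Computes `expm(Q t)` for a reversible rate matrix via eigendecomposition in
#' the frequency-symmetrized basis.
#'
#' @param Q Rate matrix (rows summing to 0), reversible with respect to `pi`.
#' @param t Branch length, >= 0.
#' @param pi Stationary frequencies; if `NULL`, recovered from `Q`'s
#'   left null vector.
#' @return Stochastic matrix of the same dimension (rows sum to 1).
#' @export
transition_probabilities <- function(Q, t, pi = NULL) {
  if (!is.numeric(t) || length(t) != 1 || t < 0) stop("t must be a scalar >= 0")
  if (is.null(pi)) pi <- stationary_frequencies(Q)
  sd <- spectral_decomposition(Q, pi)
  P <- pmat_cube(sd$A, sd$B, sd$lambda, t)[, , 1]
  dimnames(P) <- dimnames(Q)
  P / rowSums(P)
}

#' Stationary frequencies of a reversible rate matrix
#' @param Q Rate matrix with rows summing to zero.
#' @return Frequency vector.
#' @export
stationary_frequencies <- function(Q) {
  es <- eigen(t(Q))
  v <- Re(es$vectors[, which.min(abs(es$values))])
  v <- abs(v)
  v / sum(v)
}
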