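# Maximum-likelihood fitting of site and branch-site codon models, plus the
# LRT / AIC model-comparison layer built on the fits.

#' Fitting options
#'
#' @param seed Integer seed controlling restart jitter (fits are reproducible
#'   given the same inputs, seed and restarts).
#' @param restarts Number of optimizer starts for mixture models (default 3:
#'   one informed start plus seeded random jitters).
#' @param m0_fit Optional precomputed M0 fit whose branch lengths (and kappa
#'   start) the mixture fits reuse; computed on demand if `NULL`.
#' @param optimize_branch_lengths For M0: jointly optimize branch lengths
#'   (default TRUE). If FALSE the tree's lengths are used as-is.
#' @param kappa_bounds,omega_bounds Box bounds for kappa and omega.
#' @param control Passed to [stats::nlminb()].
#' @return List of class `fit_opts`.
#' @export
fit_opts <- function(seed = 1, restarts = 3, m0_fit = NULL,
                     optimize_branch_lengths = TRUE,
                     kappa_bounds = c(0.01, 100), omega_bounds = c(1e-4, 50),
                     control = list(eval.max = 2000, iter.max = 500,
                                    rel.tol = 1e-8)) {
  structure(list(seed = seed, restarts = restarts, m0_fit = m0_fit,
                 optimize_branch_lengths = optimize_branch_lengths,
                 kappa_bounds = kappa_bounds, omega_bounds = omega_bounds,
                 control = control),
            class = "fit_opts")
}

# Run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Small bounded cache of spectral decompositions keyed by (kappa, omega)
.new_decomp_cache <- function(max_entries = 12) {
  e <- new.env(parent = emptyenv())
  attr(e, "max") <- max_entries
  e
}
.cache_trim <- function(cache) {
  keys <- ls(cache)
  if (length(keys) > attr(cache, "max")) rm(list = keys, envir = cache)
}

# Shared fit state: pattern-compressed data and tree structures
.prep_fit <- function(aln, tree) {
  code <- genetic_code()
  pre <- .prep_tree(tree, aln$taxa)
  pat <- .compress_patterns(aln$codons)
  tip_states <- .codon_tip_states(aln, pre, pat$cols, code)
  pi <- estimate_codon_frequencies_f3x4(aln, code)
  list(code = code, pre = pre, pat = pat, tip_states = tip_states, pi = pi,
       n_edges = nrow(pre$edges), aln = aln)
}

.loglik_state <- function(state, mixture, kappa, blen, cache) {
  per_pat <- .codon_mixture_loglik(state$tip_states, state$pre, mixture, kappa,
                                   state$pi, blen, state$code, cache)
  sum(per_pat * state$pat$weights)
}

# Crude but robust branch-length initialization: per-site codon mismatch
# proportion between the two most divergent taxa, spread over the tree depth.
.init_branch_lengths <- function(aln, n_edges) {
  n <- length(aln$taxa)
  p <- 0
  pairs <- utils::combn(min(n, 6), 2)
  for (c in seq_len(ncol(pairs))) {
    a <- aln$codons[pairs[1, c], ]; b <- aln$codons[pairs[2, c], ]
    ok <- grepl("^[ACGT]{3}$", a) & grepl("^[ACGT]{3}$", b)
    if (any(ok)) p <- max(p, mean(a[ok] != b[ok]))
  }
  depth <- max(2, 2 * log2(max(2, n)))
  rep(max(0.02, min(2, -log(max(1 - p, 0.05)) * 2 / depth)), n_edges)
}

#' Fit a site codon model by maximum likelihood
#'
#' Fits M0, M1a or M2a to a codon alignment on a fixed topology. Under M0 the
#' branch lengths are optimized jointly with kappa and omega; the mixture
#' models (M1a, M2a) keep the M0 branch lengths fixed and optimize kappa and
#' the mixture parameters, with multiple seeded starts. Codon frequencies are
#' F3x4 estimates from the alignment, held fixed.
#'
#' The free-parameter count `k` follows the usual codon-model convention:
#' branch lengths + 9 F3x4 frequency parameters + kappa + the mixture's free
#' parameters (1 for M0, 2 for M1a, 4 for M2a and model A).
#'
#' @param aln A [codon_alignment()].
#' @param tree A [labeled_tree()].
#' @param model_tag `"M0"`, `"M1a"` or `"M2a"`.
#' @param opts A [fit_opts()].
#' @return Object of class `model_fit`.
#' @export
fit_model <- function(aln, tree, model_tag = c("M0", "M1a", "M2a"),
                      opts = fit_opts()) {
  model_tag <- match.arg(model_tag)
  state <- .prep_fit(aln, tree)
  if (model_tag == "M0") return(.fit_m0(state, tree, opts))
  m0 <- opts$m0_fit
  if (is.null(m0)) m0 <- .fit_m0(state, tree, opts)
  .fit_mixture(state, tree, model_tag, m0, opts,
               foreground_set_name = NULL)
}

.fit_m0 <- function(state, tree, opts) {
  cache <- .new_decomp_cache()
  kb <- log(opts$kappa_bounds); ob <- log(opts$omega_bounds)
  ne <- state$n_edges
  if (opts$optimize_branch_lengths) {
    t0 <- .init_branch_lengths(state$aln, ne)
    # stage 1: common branch length + kappa + omega (3 parameters), a cheap
    # start for the joint optimization
    obj1 <- function(par) {
      .cache_trim(cache)
      mix <- .mixture_raw("M0", omega = exp(par[3]))
      -.loglik_state(state, mix, exp(par[2]), rep(exp(par[1]), ne), cache)
    }
    s1 <- stats::nlminb(c(log(t0[1]), log(2), log(0.3)), obj1,
                        lower = c(log(1e-7), kb[1], ob[1]),
                        upper = c(log(10), kb[2], ob[2]),
                        control = list(rel.tol = 1e-6, iter.max = 100))
    # stage 2: joint branch lengths + kappa + omega
    par0 <- c(rep(s1$par[1], ne), s1$par[2], s1$par[3])
    lower <- c(rep(log(1e-7), ne), kb[1], ob[1])
    upper <- c(rep(log(10), ne), kb[2], ob[2])
    obj <- function(par) {
      .cache_trim(cache)
      mix <- .mixture_raw("M0", omega = exp(par[ne + 2]))
      -.loglik_state(state, mix, exp(par[ne + 1]), exp(par[1:ne]), cache)
    }
    binary <- all(tabulate(state$pre$edges[, 1]) %in% c(0L, 2L))
    grad <- if (binary) function(par) .m0_gradient(state, par, ne, obj)
            else NULL
    fit <- stats::nlminb(par0, obj, gradient = grad, lower = lower,
                         upper = upper, control = opts$control)
    blen <- exp(fit$par[1:ne]); kappa <- exp(fit$par[ne + 1])
    omega <- exp(fit$par[ne + 2])
  } else {
    blen <- state$pre$blen
    par0 <- c(log(2), log(0.3))
    obj <- function(par) {
      .cache_trim(cache)
      mix <- .mixture_raw("M0", omega = exp(par[2]))
      -.loglik_state(state, mix, exp(par[1]), blen, cache)
    }
    fit <- stats::nlminb(par0, obj, lower = c(kb[1], ob[1]),
                         upper = c(kb[2], ob[2]), control = opts$control)
    kappa <- exp(fit$par[1]); omega <- exp(fit$par[2])
  }
  lnL <- -fit$objective
  k <- ne + 9L + 1L + 1L
  .model_fit("M0", lnL = lnL, k = k,
             estimates = list(kappa = kappa, omega = omega,
                              proportions = c(`0` = 1),
                              branch_lengths = tibble::tibble(
                                branch_id = state$pre$branch_id, length = blen),
                              pi = state$pi),
             converged = fit$convergence == 0, seed = opts$seed,
             tree = tree, foreground_set_name = NULL)
}

# Gradient of the negative M0 log-likelihood over (log branch lengths,
# log kappa, log omega): analytic for branch lengths (two-pass algorithm on
# binary trees), forward finite differences for kappa and omega.
.m0_gradient <- function(state, par, ne, obj) {
  kappa <- exp(par[ne + 1]); omega <- exp(par[ne + 2])
  blen <- exp(par[1:ne])
  flux <- .codon_flux(kappa, state$pi, state$code)
  rho <- flux[["a"]] + flux[["b"]] * omega
  tvec <- blen / rho
  ps <- codon_pair_structure(state$code)
  sd <- gy94_decomp(state$pi, kappa, omega, ps$i - 1L, ps$j - 1L,
                    as.integer(ps$transition), as.integer(ps$nonsyn))
  P <- pmat_cube(sd$A, sd$B, sd$lambda, tvec)
  lam <- as.numeric(sd$lambda)
  QP <- array(0, dim(P))
  for (e in seq_len(ne))
    QP[, , e] <- sd$A %*% ((lam * exp(lam * tvec[e])) * sd$B)
  res <- m0_loglik_grad(P, QP, state$pre$edges, state$tip_states,
                        state$pre$nnode, state$pre$root, state$pi,
                        state$pat$weights)
  g_logt <- -res$gradient * tvec          # d(-lnL)/d log t_e
  f0 <- -res$loglik
  h <- 1e-6
  gk <- (obj(replace(par, ne + 1, par[ne + 1] + h)) - f0) / h
  gw <- (obj(replace(par, ne + 2, par[ne + 2] + h)) - f0) / h
  c(g_logt, gk, gw)
}

# Mixture-model parameter boxes and mappings. Parameters are optimized on
# their natural scale under box constraints; proportions use the
# (s = p0 + p1, r = p0 / s) square so the simplex becomes a box.
.mixture_spec <- function(model_tag, omega_bounds) {
  eps <- 1e-6
  w2hi <- omega_bounds[2]
  switch(model_tag,
    M1a = list(
      names = c("omega0", "p0"),
      lower = c(1e-4, eps), upper = c(1, 1 - eps),
      start = function(j) c(stats::runif(1, 0.05, 0.5), stats::runif(1, 0.4, 0.9)),
      start0 = c(0.2, 0.7),
      mix = function(v, tag) .mixture_raw("M1a", p0 = v[2], omega0 = v[1])),
    M2a = list(
      names = c("omega0", "omega2", "s", "r"),
      lower = c(1e-4, 1, eps, eps), upper = c(1, w2hi, 1 - eps, 1 - eps),
      start = function(j) c(stats::runif(1, 0.05, 0.5), stats::runif(1, 1.2, 4),
                            stats::runif(1, 0.6, 0.95), stats::runif(1, 0.3, 0.9)),
      start0 = c(0.2, 2, 0.85, 0.7),
      mix = function(v, tag) .mixture_raw("M2a", p0 = v[3] * v[4],
                                                p1 = v[3] * (1 - v[4]),
                                                omega0 = v[1], omega2 = v[2])),
    modelA = list(
      names = c("omega0", "omega2", "s", "r"),
      lower = c(1e-4, 1, eps, eps), upper = c(1, w2hi, 1 - eps, 1 - eps),
      start = function(j) c(stats::runif(1, 0.05, 0.5), stats::runif(1, 1.2, 4),
                            stats::runif(1, 0.6, 0.95), stats::runif(1, 0.3, 0.9)),
      start0 = c(0.2, 2, 0.85, 0.7),
      mix = function(v, tag) .mixture_raw(tag, p0 = v[3] * v[4],
                                                p1 = v[3] * (1 - v[4]),
                                                omega0 = v[1], omega2 = v[2])),
    modelA_null = list(
      names = c("omega0", "s", "r"),
      lower = c(1e-4, eps, eps), upper = c(1, 1 - eps, 1 - eps),
      start = function(j) c(stats::runif(1, 0.05, 0.5),
                            stats::runif(1, 0.6, 0.95), stats::runif(1, 0.3, 0.9)),
      start0 = c(0.2, 0.85, 0.7),
      mix = function(v, tag) .mixture_raw("modelA_null", p0 = v[2] * v[3],
                                                p1 = v[2] * (1 - v[3]),
                                                omega0 = v[1])))
}

.fit_mixture <- function(state, tree, model_tag, m0, opts, foreground_set_name) {
  cache <- .new_decomp_cache()
  blen <- m0$estimates$branch_lengths$length
  spec <- .mixture_spec(model_tag, opts$omega_bounds)
  kb <- opts$kappa_bounds
  kappa0 <- m0$estimates$kappa
  obj <- function(par) {
    .cache_trim(cache)
    mix <- spec$mix(par[-1], model_tag)
    -.loglik_state(state, mix, par[1], blen, cache)
  }
  lower <- c(kb[1], spec$lower); upper <- c(kb[2], spec$upper)
  starts <- .with_seed(opts$seed, {
    c(list(c(kappa0, spec$start0)),
      lapply(seq_len(max(0, opts$restarts - 1)), function(j)
        c(stats::runif(1, max(kb[1], kappa0 / 2), min(kb[2], kappa0 * 2)),
          spec$start(j))))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(stats::nlminb(p0, obj, lower = lower, upper = upper,
                                  control = opts$control),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed for ", model_tag)
  v <- best$par
  mix <- spec$mix(v[-1], model_tag)
  props <- stats::setNames(mix$proportion, mix$class)
  est <- list(kappa = v[1],
              omega = stats::setNames(mix$omega_fg, mix$class),
              omega0 = v[2],
              proportions = props,
              branch_lengths = m0$estimates$branch_lengths,
              pi = state$pi)
  if (model_tag %in% c("M2a", "modelA")) est$omega2 <- v[3]
  if (model_tag == "modelA_null") est$omega2 <- 1
  k <- state$n_edges + 9L + 1L + mix$df_mixture
  .model_fit(model_tag, lnL = -best$objective, k = k, estimates = est,
             converged = best$convergence == 0, seed = opts$seed, tree = tree,
             foreground_set_name = foreground_set_name)
}

.model_fit <- function(model_tag, lnL, k, estimates, converged, seed, tree,
                       foreground_set_name = NULL) {
  structure(list(model_tag = model_tag, lnL = lnL, k = as.integer(k),
                 aic = 2 * k - 2 * lnL, estimates = estimates,
                 converged = converged, seed = seed,
                 foreground_set_name = foreground_set_name,
                 tree = tree),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AIC = %.4f%s\n", x$model_tag,
              x$lnL, x$k, x$aic,
              if (isTRUE(x$converged)) "" else "  [did not converge]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a codon-model fit
#'
#' @param x A `model_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.model_fit <- function(x, ...) {
  e <- x$estimates
  terms <- c(kappa = e$kappa)
  if (!is.null(e$omega0)) terms <- c(terms, omega0 = e$omega0)
  if (!is.null(e$omega2)) terms <- c(terms, omega2 = e$omega2)
  if (x$model_tag == "M0") terms <- c(terms, omega = e$omega)
  props <- stats::setNames(e$proportions, paste0("p", names(e$proportions)))
  tibble::tibble(term = c(names(terms), names(props)),
                 estimate = c(unname(terms), unname(props)))
}

#' One-row summary of a codon-model fit
#'
#' @param x A `model_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `foreground`, `k`, `logLik`, `AIC`,
#'   `converged`.
#' @export
glance.model_fit <- function(x, ...) {
  tibble::tibble(model = x$model_tag,
                 foreground = x$foreground_set_name %||% NA_character_,
                 k = x$k, logLik = x$lnL, AIC = x$aic,
                 converged = isTRUE(x$converged))
}

#' @importFrom rlang %||%
NULL

#' A named a-priori foreground-branch hypothesis
#'
#' @param name Short label for the hypothesis (e.g. `"a"`..`"e"`).
#' @param branches Character vector of branch ids.
#' @param clades Character vector of clade (gene-lineage) names; a clade
#'   contributes its stem and all nested branches.
#' @return Object of class `hypothesis_set`.
#' @export
hypothesis_set <- function(name, branches = character(), clades = character()) {
  if (!nzchar(name)) stop("hypothesis needs a name")
  if (!length(branches) && !length(clades))
    stop("hypothesis '", name, "' names no foreground branches or clades")
  structure(list(name = name, branches = branches, clades = clades),
            class = "hypothesis_set")
}

#' Fit branch-site model A for a foreground hypothesis
#'
#' Model A lets a fraction of sites (classes 2a/2b) switch to a shared omega2
#' on the hypothesis's foreground branches while evolving like the M1a
#' classes elsewhere. With `fix_omega2 = TRUE` the null variant (omega2 = 1)
#' is fitted instead. Branch lengths come from an M0 fit and are held fixed.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [labeled_tree()].
#' @param hyp A [hypothesis_set()] resolvable on `tree`.
#' @param fix_omega2 Fit the omega2 = 1 null (default FALSE).
#' @param opts A [fit_opts()].
#' @return Object of class `model_fit`.
#' @export
fit_branch_site_A <- function(aln, tree, hyp, fix_omega2 = FALSE,
                              opts = fit_opts()) {
  stopifnot(inherits(hyp, "hypothesis_set"))
  fg <- foreground_flags(tree, hyp$branches, hyp$clades)
  tree_fg <- tree
  tree_fg$foreground <- fg
  state <- .prep_fit(aln, tree_fg)
  m0 <- opts$m0_fit
  if (is.null(m0)) m0 <- .fit_m0(state, tree_fg, opts)
  tag <- if (fix_omega2) "modelA_null" else "modelA"
  .fit_mixture(state, tree_fg, tag, m0, opts, foreground_set_name = hyp$name)
}

#' Likelihood-ratio test between nested fits
#'
#' @param null_fit,alt_fit `model_fit` objects (or lists with `lnL`); the
#'   caller asserts nesting.
#' @param df Degrees of freedom (>= 1).
#' @return Tibble with `statistic`, `df`, `p_value`. The statistic is clamped
#'   at zero (boundary cases where the alternative optimum does not exceed
#'   the null).
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, df) {
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  tibble::tibble(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Akaike information criterion of a fit
#'
#' @param fit A `model_fit`, or any list with elements `lnL` and `k`.
#' @return `2 k - 2 lnL` (lower is better).
#' @export
aic_score <- function(fit) {
  if (is.null(fit$lnL) || is.null(fit$k)) stop("fit must carry lnL and k")
  2 * fit$k - 2 * fit$lnL
}

#' Fit and rank foreground-branch hypotheses by AIC
#'
#' Fits branch-site model A for every hypothesis (sharing one M0 fit for
#' branch lengths), optionally adds the M1a and M2a site-model baselines, and
#' returns the fits ranked by AIC with a delta-AIC column. A hypothesis whose
#' fit fails is reported with `NA` values rather than aborting the ranking.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [labeled_tree()].
#' @param hypotheses List of [hypothesis_set()] objects (at least one).
#' @param include_site_models Add M1a and M2a baselines (default TRUE).
#' @param opts A [fit_opts()].
#' @param decisive_delta Delta-AIC above which the ranking is annotated
#'   decisive against a model (default 10).
#' @return Tibble sorted by ascending AIC: `model`, `foreground`,
#'   `n_foreground_branches`, `k`, `lnL`, `AIC`, `delta_AIC`, `decisive`,
#'   with the fit objects in a list column `fit`. Ties are broken by fewer
#'   foreground branches, then name.
#' @export
rank_hypotheses <- function(aln, tree, hypotheses, include_site_models = TRUE,
                            opts = fit_opts(), decisive_delta = 10) {
  if (!length(hypotheses)) stop("need at least one hypothesis")
  state <- .prep_fit(aln, tree)
  m0 <- opts$m0_fit
  if (is.null(m0)) m0 <- .fit_m0(state, tree, opts)
  opts$m0_fit <- m0
  rows <- purrr::map(hypotheses, function(h) {
    fit <- tryCatch(fit_branch_site_A(aln, tree, h, opts = opts),
                    error = function(e) NULL)
    nfg <- tryCatch(sum(foreground_flags(tree, h$branches, h$clades)),
                    error = function(e) NA_integer_)
    tibble::tibble(model = "modelA", foreground = h$name,
                   n_foreground_branches = nfg,
                   k = if (is.null(fit)) NA_integer_ else fit$k,
                   lnL = if (is.null(fit)) NA_real_ else fit$lnL,
                   AIC = if (is.null(fit)) NA_real_ else fit$aic,
                   fit = list(fit))
  })
  if (include_site_models) {
    for (tag in c("M1a", "M2a")) {
      opts2 <- opts
      fit <- .fit_mixture(state, tree, tag, m0, opts2, NULL)
      rows <- c(rows, list(tibble::tibble(
        model = tag, foreground = "-", n_foreground_branches = 0L,
        k = fit$k, lnL = fit$lnL, AIC = fit$aic, fit = list(fit))))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$AIC, .data$n_foreground_branches,
                        .data$foreground)
  out$delta_AIC <- out$AIC - min(out$AIC, na.rm = TRUE)
  out$decisive <- out$delta_AIC > decisive_delta
  out
}

#' Estimated fraction of sites under foreground selection
#'
#' For a branch-site model A fit, the proportion of sites in classes 2a + 2b
#' (equivalently `1 - p0 - p1`) — the headline "fraction of sites undergoing
#' more nonsynonymous change on the foreground branches".
#'
#' @param fit A `model_fit` with `model_tag` `"modelA"` or `"modelA_null"`.
#' @return Numeric proportion in `[0, 1]`.
#' @export
foreground_site_fraction <- function(fit) {
  if (!inherits(fit, "model_fit") ||
      !fit$model_tag %in% c("modelA", "modelA_null"))
    stop("foreground_site_fraction() needs a branch-site model A fit")
  p <- fit$estimates$proportions
  unname(max(0, 1 - p[["0"]] - p[["1"]]))
}
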