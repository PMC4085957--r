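# Likelihood engine shared by the codon and nucleotide models: site-pattern
# compression, postorder tree preparation, and class-mixture combination on
# top of the compiled pruning kernel.

# Collapse identical alignment columns; returns first-occurrence column
# indices and multiplicities.
.compress_patterns <- function(mat) {
  key <- apply(mat, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  idx <- which(first)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(cols = idx, weights = weights, map = match(key, key[first]))
}

# Postorder edge structure of a labeled tree, restricted/pruned to `taxa`.
# Returns edges (parent, child), branch lengths, foreground flags and ids in
# postorder, plus node bookkeeping for the pruning kernel.
.prep_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "labeled_tree"))
  miss <- setdiff(taxa, tree$phy$tip.label)
  if (length(miss))
    stop("taxon missing from tree: ", paste(miss, collapse = ", "))
  if (length(setdiff(tree$phy$tip.label, taxa)))
    tree <- prune_labeled_tree(tree, taxa)
  phy <- tree$phy
  po <- stats::reorder(phy, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(po$edge), key(phy$edge))
  ntip <- length(phy$tip.label)
  list(edges = po$edge,
       blen = phy$edge.length[perm],
       fg = tree$foreground[perm],
       branch_id = tree$branch_id[perm],
       ntip = ntip,
       nnode = ntip + phy$Nnode,
       root = ntip + 1L,
       tip_label = phy$tip.label,
       tree = tree)
}

#' Restrict a labeled tree to a subset of tips
#'
#' Drops all other tips; a retained branch is flagged foreground if any
#' original branch on the path it collapses was foreground. Clade labels are
#' restricted to the kept tips.
#'
#' @param tree A [labeled_tree()].
#' @param keep Character vector of tip labels to keep.
#' @return A [labeled_tree()].
#' @export
prune_labeled_tree <- function(tree, keep) {
  phy <- tree$phy
  if (setequal(keep, phy$tip.label)) return(tree)
  new_phy <- ape::keep.tip(phy, keep)
  ntip_o <- length(phy$tip.label); ntip_n <- length(new_phy$tip.label)
  # counterpart of each new node in the original tree
  new_tipsets <- vector("list", ntip_n + new_phy$Nnode)
  for (i in seq_len(ntip_n)) new_tipsets[[i]] <- new_phy$tip.label[i]
  for (n in (ntip_n + 1):(ntip_n + new_phy$Nnode)) {
    desc <- .descendant_nodes(new_phy, n)
    new_tipsets[[n]] <- new_phy$tip.label[desc[desc <= ntip_n]]
  }
  counterpart <- function(tips) {
    if (length(tips) == 1) match(tips, phy$tip.label) else ape::getMRCA(phy, tips)
  }
  cp <- vapply(new_tipsets, counterpart, numeric(1))
  parent_of <- function(node) {
    e <- which(phy$edge[, 2] == node)
    if (length(e)) phy$edge[e, 1] else NA_integer_
  }
  fg <- logical(nrow(new_phy$edge))
  for (e in seq_len(nrow(new_phy$edge))) {
    top <- cp[new_phy$edge[e, 1]]; node <- cp[new_phy$edge[e, 2]]
    while (!is.na(node) && node != top) {
      orig_e <- which(phy$edge[, 2] == node)
      if (length(orig_e) && tree$foreground[orig_e]) { fg[e] <- TRUE; break }
      node <- parent_of(node)
    }
  }
  clades <- lapply(tree$clades, intersect, keep)
  clades <- clades[vapply(clades, length, integer(1)) > 0]
  labeled_tree(new_phy, foreground = fg, clades = clades)
}

# Codon tip states as an ntip x npat integer matrix (rows in the pruned
# tree's tip order): sense codon index 1..61, or 0 for gap/stop/ambiguous
# codons (fully missing).
.codon_tip_states <- function(aln, pre, pat_cols, code) {
  m <- t(vapply(pre$tip_label, function(tx) {
    idx <- code$codon_index[aln$codons[tx, pat_cols, drop = TRUE]]
    idx[is.na(idx)] <- 0L
    as.integer(idx)
  }, integer(length(pat_cols))))
  if (length(pat_cols) == 1) m <- matrix(m, ncol = 1)
  m
}

# Nucleotide tips are coded as indices into the IUPAC lookup matrix
# (columns of partial-likelihood indicators; ambiguity codes give partial
# information, gaps and unknown characters full missingness).
.iupac_lookup <- function() {
  bases <- c("A", "C", "G", "T")
  vapply(.iupac_sets, function(s) as.numeric(bases %in% s), numeric(4))
}

.nt_tip_codes <- function(states, pre, pat_cols) {
  alphabet <- names(.iupac_sets)
  n_col <- length(pat_cols)
  m <- t(vapply(pre$tip_label, function(tx) {
    i <- match(states[tx, pat_cols, drop = TRUE], alphabet)
    i[is.na(i)] <- match("N", alphabet)
    as.integer(i)
  }, integer(n_col)))
  if (n_col == 1) m <- matrix(m, ncol = 1)
  m
}

# log(sum_c w_c exp(x_c)) across a list of per-pattern log-likelihood vectors
.logsumexp_mix <- function(loglik_list, weights) {
  m <- Reduce(pmax, loglik_list)
  acc <- 0
  for (i in seq_along(loglik_list))
    acc <- acc + weights[i] * exp(loglik_list[[i]] - m)
  m + log(acc)
}

# Synonymous/nonsynonymous flux coefficients: the mean rate of the unscaled
# GY94 matrix is a + b * omega, linear in omega.
.codon_flux <- function(kappa, pi, code = genetic_code()) {
  ps <- codon_pair_structure(code)
  base <- pi[ps$i] * pi[ps$j] * ifelse(ps$transition, kappa, 1)
  c(a = sum(base[!ps$nonsyn]), b = sum(base[ps$nonsyn]))
}

# Core mixture likelihood given prepared structures. `mixture` may be a
# site_class_mixture or the raw vector form; `tip_states` is the integer
# state matrix. Branch lengths are in expected substitutions per codon under
# the mixture (background scaling).
.codon_mixture_loglik <- function(tip_states, pre, mixture, kappa, pi, blen,
                                  code = genetic_code(), cache = NULL) {
  mix <- .as_raw_mixture(mixture)
  flux <- .codon_flux(kappa, pi, code)
  rho <- sum(mix$proportion * (flux[["a"]] + flux[["b"]] * mix$omega_bg))
  if (rho <= 0) return(-Inf)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ps <- codon_pair_structure(code)
  decomp <- function(omega) {
    key <- sprintf("w%ak%a", omega, kappa)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    sd <- gy94_decomp(pi, kappa, omega, ps$i - 1L, ps$j - 1L,
                      as.integer(ps$transition), as.integer(ps$nonsyn))
    cache[[key]] <- sd
    sd
  }
  tvec <- blen / rho
  fg <- pre$fg
  # one transition-probability cube per distinct omega: full cubes for
  # background use, foreground-only slices where an omega is foreground-only
  full_for <- unique(mix$omega_bg)
  cubes <- lapply(full_for, function(w) {
    sd <- decomp(w)
    pmat_cube(sd$A, sd$B, sd$lambda, tvec)
  })
  names(cubes) <- sprintf("%a", full_for)
  fg_slices <- list()
  if (any(fg)) {
    for (w in unique(mix$omega_fg[mix$omega_fg != mix$omega_bg])) {
      kw <- sprintf("%a", w)
      if (!is.null(cubes[[kw]])) {
        fg_slices[[kw]] <- cubes[[kw]][, , fg, drop = FALSE]
      } else {
        sd <- decomp(w)
        fg_slices[[kw]] <- pmat_cube(sd$A, sd$B, sd$lambda, tvec[fg])
      }
    }
  }
  per_class <- lapply(seq_along(mix$proportion), function(c) {
    if (mix$proportion[c] <= 0) return(NULL)
    wb <- mix$omega_bg[c]; wf <- mix$omega_fg[c]
    if (wb == wf || !any(fg)) {
      P <- cubes[[sprintf("%a", wb)]]
    } else {
      P <- cubes[[sprintf("%a", wb)]]
      P[, , fg] <- fg_slices[[sprintf("%a", wf)]]
    }
    pruning_loglik_states(P, pre$edges, tip_states, pre$nnode, pre$root, pi)
  })
  keep <- mix$proportion > 0
  .logsumexp_mix(per_class[keep], mix$proportion[keep])
}

#' Codon-model log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a labeled tree under a
#' site-class mixture (M0, M1a, M2a or branch-site model A). Site likelihoods
#' mix the classes' pruning likelihoods; for branch-site classes, foreground
#' branches use the class's foreground omega. Gaps, stop codons and ambiguous
#' codons contribute all-ones partials (fully missing).
#'
#' @param aln A [codon_alignment()]; its taxa must be a subset of the tree's
#'   tips (extra tips are pruned).
#' @param tree A [labeled_tree()]; branch lengths in expected substitutions
#'   per codon.
#' @param mixture A [site_class_mixture()].
#' @param params A [codon_model_params()] supplying kappa and pi (the omega
#'   field is ignored; omegas come from the mixture).
#' @return List with `total` (log-likelihood) and `per_site` (numeric vector,
#'   one entry per codon site).
#' @export
pruning_log_likelihood <- function(aln, tree, mixture, params) {
  stopifnot(inherits(aln, "codon_alignment"),
            inherits(mixture, "site_class_mixture"))
  if (nrow(mixture$classes) == 0) stop("empty mixture")
  code <- genetic_code()
  pre <- .prep_tree(tree, aln$taxa)
  pat <- .compress_patterns(aln$codons)
  tip_states <- .codon_tip_states(aln, pre, pat$cols, code)
  per_pat <- .codon_mixture_loglik(tip_states, pre, mixture, params$kappa,
                                   params$pi, pre$blen, code)
  list(total = sum(per_pat * pat$weights), per_site = per_pat[pat$map])
}

#' GTR+Gamma log-likelihood of a nucleotide alignment
#'
#' @param aln A [nucleotide_alignment()]; taxa must be a subset of the tree's
#'   tips (extra tips are pruned).
#' @param tree A [labeled_tree()]; branch lengths in expected substitutions
#'   per site.
#' @param params A [gtr_gamma_params()].
#' @return List with `total` and `per_site`.
#' @export
gtr_gamma_log_likelihood <- function(aln, tree, params) {
  stopifnot(inherits(aln, "nucleotide_alignment"),
            inherits(params, "gtr_gamma_params"))
  pre <- .prep_tree(tree, aln$taxa)
  pat <- .compress_patterns(aln$states)
  tip_codes <- .nt_tip_codes(aln$states, pre, pat$cols)
  per_pat <- .gtr_loglik_prepped(tip_codes, pre, params, pre$blen)
  list(total = sum(per_pat * pat$weights), per_site = per_pat[pat$map])
}

#' Write per-site log-likelihoods to JSON
#'
#' @param loglik Result of [pruning_log_likelihood()] or
#'   [gtr_gamma_log_likelihood()] (any list with `total` and `per_site`).
#' @param path Output file path.
#' @export
write_site_loglik_json <- function(loglik, path) {
  jsonlite::write_json(list(total = loglik$total,
                            per_site = loglik$per_site),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.gtr_loglik_prepped <- function(tip_codes, pre, params, blen) {
  Q <- gtr_rate_matrix(params, scale = TRUE)
  pi <- params$base_freqs
  sd <- spectral_decomposition(Q, pi)
  rates <- discrete_gamma_rates(params$alpha, params$n_cat)
  L <- .iupac_lookup()
  per_class <- lapply(rates, function(r) {
    P <- pmat_cube(sd$A, sd$B, sd$lambda, blen * r)
    pruning_loglik_lookup(P, pre$edges, tip_codes, L, pre$nnode, pre$root, pi)
  })
  .logsumexp_mix(per_class, rep(1 / length(rates), length(rates)))
}
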