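# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: rate matrices are built by direct codon
# comparison, matrix exponentials by a general (non-symmetrized)
# eigendecomposition, and tree likelihoods by exhaustive summation over all
# internal-node state assignments.

oracle_codons <- function() {
  tab <- Biostrings::GENETIC_CODE
  names(tab)[tab != "*"]
}

# GY94 rate matrix by brute-force comparison of codon strings
oracle_codon_Q <- function(kappa, omega, pi, scale = FALSE) {
  sense <- oracle_codons()
  n <- length(sense)
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  tab <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- strsplit(sense[i], "")[[1]]; cj <- strsplit(sense[j], "")[[1]]
      d <- which(ci != cj)
      if (length(d) != 1) next
      r <- pi[j]
      ts <- paste0(sort(c(ci[d], cj[d])), collapse = "")
      if (ts %in% c("AG", "CT")) r <- r * kappa
      if (tab[[sense[i]]] != tab[[sense[j]]]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  if (scale) Q <- Q / sum(pi * -diag(Q))
  Q
}

# expm(Q t) via a general eigendecomposition (not the symmetrized route)
oracle_expm <- function(Q, t) {
  es <- eigen(Q)
  P <- Re(es$vectors %*% diag(exp(es$values * t)) %*% solve(es$vectors))
  pmax(P, 0)
}

# Factory caching the (general, non-symmetrized) eigendecomposition of Q so
# repeated P(t) evaluations do not refactorize
oracle_P_factory <- function(Q) {
  es <- eigen(Q)
  Vinv <- solve(es$vectors)
  function(t) {
    P <- Re(es$vectors %*% (exp(es$values * t) * Vinv))
    pmax(P, 0)
  }
}

# Exhaustive tree likelihood: sums over every assignment of states to the
# internal nodes. P_edges is a list of k x k matrices in the order of the
# postorder edge rows given in `edges`; tip_states an ntip x nsites integer
# matrix (0 = missing).
oracle_enum_loglik <- function(edges, P_edges, tip_states, pi, root) {
  ntip <- nrow(tip_states)
  nodes <- sort(unique(as.vector(edges)))
  internal <- nodes[nodes > ntip]
  k <- length(pi)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  idx_of <- function(node) match(node, internal)
  per_site <- vapply(seq_len(ncol(tip_states)), function(s) {
    p <- pi[combos[, idx_of(root)]]
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      pv <- combos[, idx_of(parent)]
      if (child <= ntip) {
        st <- tip_states[child, s]
        if (st == 0) next
        p <- p * P_edges[[e]][cbind(pv, st)]
      } else {
        p <- p * P_edges[[e]][cbind(pv, combos[, idx_of(child)])]
      }
    }
    log(sum(p))
  }, numeric(1))
  per_site
}

# Exhaustive mixture codon likelihood for a labeled tree (<= 4 tips).
oracle_mixture_loglik <- function(aln, tree, mixture, params) {
  code <- genetic_code()
  phy <- stats::reorder(tree$phy, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(phy$edge), key(tree$phy$edge))
  blen <- tree$phy$edge.length[perm]
  fg <- tree$foreground[perm]
  ntip <- length(phy$tip.label)
  cls <- mixture$classes
  omega_cache <- new.env()
  get_model <- function(w) {
    key <- format(w, digits = 15)
    if (is.null(omega_cache[[key]])) {
      Q <- oracle_codon_Q(params$kappa, w, params$pi)
      omega_cache[[key]] <- list(rate = sum(params$pi * -diag(Q)),
                                 P_of = oracle_P_factory(Q))
    }
    omega_cache[[key]]
  }
  rho <- sum(cls$proportion *
               vapply(cls$omega_background, function(w) get_model(w)$rate, 1))
  tip_states <- t(vapply(phy$tip.label, function(tx) {
    i <- match(aln$codons[tx, ], oracle_codons())
    i[is.na(i)] <- 0L
    as.integer(i)
  }, integer(aln$n_sites)))
  if (aln$n_sites == 1) tip_states <- matrix(tip_states, ncol = 1)
  per_class <- lapply(seq_len(nrow(cls)), function(c) {
    P_edges <- lapply(seq_along(blen), function(e) {
      w <- if (fg[e]) cls$omega_foreground[c] else cls$omega_background[c]
      get_model(w)$P_of(blen[e] / rho)
    })
    exp(oracle_enum_loglik(phy$edge, P_edges, tip_states, params$pi,
                           ntip + 1L))
  })
  site_lik <- Reduce(`+`, Map(function(L, p) p * L, per_class,
                              cls$proportion))
  sum(log(site_lik))
}

# Exhaustive GTR+Gamma likelihood for small nucleotide alignments.
oracle_gtr_loglik <- function(aln, tree, gtr) {
  phy <- stats::reorder(tree$phy, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(phy$edge), key(tree$phy$edge))
  blen <- tree$phy$edge.length[perm]
  ntip <- length(phy$tip.label)
  Q <- gtr_rate_matrix(gtr, scale = TRUE)
  rates <- discrete_gamma_rates(gtr$alpha, gtr$n_cat)
  bases <- c("A", "C", "G", "T")
  tip_states <- t(vapply(phy$tip.label, function(tx) {
    i <- match(aln$states[tx, ], bases)
    i[is.na(i)] <- 0L
    as.integer(i)
  }, integer(aln$n_sites)))
  if (aln$n_sites == 1) tip_states <- matrix(tip_states, ncol = 1)
  per_cat <- lapply(rates, function(r) {
    P_edges <- lapply(seq_along(blen), function(e) oracle_expm(Q, blen[e] * r))
    exp(oracle_enum_loglik(phy$edge, P_edges, tip_states, gtr$base_freqs,
                           ntip + 1L))
  })
  site_lik <- Reduce(`+`, per_cat) / length(rates)
  sum(log(site_lik))
}

# Smith-Waterman local alignment score/region oracle (linear gap cost would
# differ; affine matches the implementation's scoring scheme).
oracle_local_align <- function(query, subject, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  nq <- length(q); ns <- length(s)
  M <- matrix(0, nq + 1, ns + 1)
  X <- matrix(-Inf, nq + 1, ns + 1)  # gap in subject
  Y <- matrix(-Inf, nq + 1, ns + 1)  # gap in query
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(nq + 1)) {
    for (j in 2:(ns + 1)) {
      sc <- if (q[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      if (M[i, j] > best) { best <- M[i, j]; bi <- i - 1; bj <- j - 1 }
    }
  }
  list(score = best, end_query = bi, end_subject = bj)
}

random_protein <- function(n, seed) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- oracle_codons()
  no_stop_start <- sense  # sense codons only, so no internal stops
  paste(sample(no_stop_start, n_codons, replace = TRUE), collapse = "")
}
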