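# Simulation studies at the analysis's working conditions: LRT calibration
# and power for the branch-site test, recovery of the foreground site
# fraction at a weak effect size, and placement/quantification accuracy of
# the annotation pipeline. These are the package's reference experiments;
# the vignette discusses the chosen conditions.

.study_conditions <- list(
  kappa = 2.5,
  omega0 = 0.1,
  null_p0 = 0.7,
  power_p0 = 0.5, power_p1 = 0.3,
  recovery_p0 = 0.6, recovery_p1 = 0.293
)

# Two (or more) longest internal branches of a tree: the a-priori foreground
# set used by the simulation studies (long internal branches carry the most
# substitution signal, mirroring how foreground clades are chosen in
# practice).
.longest_internal_branches <- function(tree, n = 2) {
  ntip <- length(tree$phy$tip.label)
  internal <- tree$phy$edge[, 2] > ntip
  len <- tree$phy$edge.length * internal
  branch_ids(tree)[order(-len)[seq_len(n)]]
}

.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2^31 - 2, n))
}

#' Null calibration of the branch-site LRT
#'
#' Simulates alignments under the nearly-neutral site model (M1a; no
#' branch-site effect), fits M1a and branch-site model A with a fixed
#' two-branch foreground hypothesis, and records the model A vs M1a LRT
#' (df = 2) p-value per replicate. Under the null the test is expected to be
#' conservative (the omega2 >= 1 boundary), so the rejection rate at
#' alpha = 0.05 should not exceed it by much.
#'
#' @param n_reps Number of replicates (default 200).
#' @param n_codons Alignment length in codons (default 300).
#' @param n_taxa Tips (default 8).
#' @param seed Integer seed.
#' @param alpha Nominal level used for the summary rejection rate.
#' @return List: `results` (tibble with `replicate`, `statistic`, `p_value`)
#'   and `rejection_rate`.
#' @export
study_lrt_null_calibration <- function(n_reps = 200, n_codons = 300,
                                       n_taxa = 8, seed = 1, alpha = 0.05) {
  sc <- .study_conditions
  tree <- simulate_tree(n_taxa, seed = seed)
  hyp <- hypothesis_set("planted",
                        branches = .longest_internal_branches(tree, 2))
  kpar <- codon_model_params(kappa = sc$kappa, omega = 1)
  mix <- site_class_mixture("M1a", p0 = sc$null_p0, omega0 = sc$omega0)
  seeds <- .derive_seeds(seed, n_reps)
  rows <- lapply(seq_len(n_reps), function(i) {
    aln <- simulate_codon_alignment(tree, mix, kpar, n_codons,
                                    seed = seeds[i])
    m0 <- fit_model(aln, tree, "M0", fit_opts(seed = seeds[i]))
    op <- fit_opts(seed = seeds[i], m0_fit = m0, restarts = 1)
    m1 <- fit_model(aln, tree, "M1a", op)
    ma <- fit_branch_site_A(aln, tree, hyp, opts = op)
    lrt <- likelihood_ratio_test(m1, ma, df = 2)
    tibble::tibble(replicate = i, statistic = lrt$statistic,
                   p_value = lrt$p_value)
  })
  results <- dplyr::bind_rows(rows)
  list(results = results,
       rejection_rate = mean(results$p_value < alpha))
}

#' Power of the branch-site LRT against a planted foreground effect
#'
#' Simulates under branch-site model A with omega2 planted on two foreground
#' branches and records how often the model A vs M1a LRT (df = 2) rejects at
#' the nominal level.
#'
#' @param n_reps Replicates (default 50).
#' @param n_codons Codons (default 500).
#' @param n_taxa Tips (default 8).
#' @param omega2 Planted foreground omega (default 2).
#' @param seed Integer seed.
#' @param alpha Nominal level (default 0.05).
#' @return List: `results` tibble and `power`.
#' @export
study_lrt_power <- function(n_reps = 50, n_codons = 500, n_taxa = 8,
                            omega2 = 2, seed = 1, alpha = 0.05) {
  sc <- .study_conditions
  tree <- simulate_tree(n_taxa, seed = seed)
  fg <- .longest_internal_branches(tree, 2)
  hyp <- hypothesis_set("planted", branches = fg)
  sim_tree <- tree
  sim_tree$foreground <- branch_ids(tree) %in% fg
  kpar <- codon_model_params(kappa = sc$kappa, omega = 1)
  mix <- site_class_mixture("modelA", p0 = sc$power_p0, p1 = sc$power_p1,
                            omega0 = sc$omega0, omega2 = omega2)
  seeds <- .derive_seeds(seed, n_reps)
  rows <- lapply(seq_len(n_reps), function(i) {
    aln <- simulate_codon_alignment(sim_tree, mix, kpar, n_codons,
                                    seed = seeds[i])
    m0 <- fit_model(aln, sim_tree, "M0", fit_opts(seed = seeds[i]))
    op <- fit_opts(seed = seeds[i], m0_fit = m0, restarts = 1)
    m1 <- fit_model(aln, sim_tree, "M1a", op)
    ma <- fit_branch_site_A(aln, sim_tree, hyp, opts = op)
    lrt <- likelihood_ratio_test(m1, ma, df = 2)
    tibble::tibble(replicate = i, statistic = lrt$statistic,
                   p_value = lrt$p_value)
  })
  results <- dplyr::bind_rows(rows)
  list(results = results, power = mean(results$p_value < alpha))
}

#' Recovery of the foreground site fraction at a weak effect size
#'
#' Simulates branch-site model A data with a planted fraction of sites under
#' weak foreground selection, refits model A, and summarizes the estimated
#' fraction (classes 2a + 2b). The default effect (fraction 0.107,
#' omega2 = 1.35) matches the magnitude reported for adaptive PEPC evolution
#' at the base of C4 clades.
#'
#' @param n_reps Replicates (default 20).
#' @param n_codons Codons (default 600).
#' @param n_taxa Tips (default 12).
#' @param fraction Planted foreground site fraction (default 0.107).
#' @param omega2 Planted foreground omega (default 1.35).
#' @param seed Integer seed.
#' @return List: `results` tibble (`replicate`, `fraction_hat`),
#'   `median_fraction`, `planted_fraction`.
#' @export
study_fraction_recovery <- function(n_reps = 20, n_codons = 600, n_taxa = 12,
                                    fraction = 0.107, omega2 = 1.35,
                                    seed = 1) {
  sc <- .study_conditions
  p0 <- sc$recovery_p0 * (1 - fraction) / (1 - 0.107)
  p1 <- (1 - fraction) - p0
  tree <- simulate_tree(n_taxa, seed = seed)
  fg <- .longest_internal_branches(tree, 3)
  hyp <- hypothesis_set("planted", branches = fg)
  sim_tree <- tree
  sim_tree$foreground <- branch_ids(tree) %in% fg
  kpar <- codon_model_params(kappa = sc$kappa, omega = 1)
  mix <- site_class_mixture("modelA", p0 = p0, p1 = p1,
                            omega0 = sc$omega0, omega2 = omega2)
  seeds <- .derive_seeds(seed, n_reps)
  rows <- lapply(seq_len(n_reps), function(i) {
    aln <- simulate_codon_alignment(sim_tree, mix, kpar, n_codons,
                                    seed = seeds[i])
    m0 <- fit_model(aln, sim_tree, "M0", fit_opts(seed = seeds[i]))
    ma <- fit_branch_site_A(aln, sim_tree, hyp,
                            opts = fit_opts(seed = seeds[i], m0_fit = m0,
                                            restarts = 1))
    tibble::tibble(replicate = i,
                   fraction_hat = foreground_site_fraction(ma))
  })
  results <- dplyr::bind_rows(rows)
  list(results = results, median_fraction = stats::median(results$fraction_hat),
       planted_fraction = fraction)
}

#' Placement accuracy of simulated queries on a lineage panel
#'
#' Builds a reference panel of nested gene lineages, simulates queries by
#' evolving random panel sequences to a moderate divergence (0.05-0.2
#' substitutions/site), and runs each query through profile alignment,
#' placement and lineage assignment.
#'
#' @param n_queries Queries (default 100).
#' @param n_lineages Panel lineages (default 5).
#' @param taxa_per_lineage Tips per lineage (default 4).
#' @param divergence_range Query divergence from its source sequence.
#' @param lwr_threshold Assignment threshold (default 0.8).
#' @param seed Integer seed.
#' @return List: `results` tibble (`query`, `true_lineage`,
#'   `assigned_lineage`), `accuracy` (fraction assigned to the true
#'   lineage), `panel`.
#' @export
study_placement_accuracy <- function(n_queries = 100, n_lineages = 5,
                                     taxa_per_lineage = 4,
                                     divergence_range = c(0.05, 0.2),
                                     lwr_threshold = 0.8, seed = 1) {
  sim <- simulate_reference_panel(n_lineages = n_lineages,
                                  taxa_per_lineage = taxa_per_lineage,
                                  seed = seed)
  panel <- sim$panel
  Q <- gtr_rate_matrix(panel$gtr_params, scale = TRUE)
  pi <- panel$gtr_params$base_freqs
  bases <- c("A", "C", "G", "T")
  queries <- .with_seed(seed + 1, {
    lapply(seq_len(n_queries), function(i) {
      src <- sample(panel$ref_alignment$taxa, 1)
      d <- stats::runif(1, divergence_range[1], divergence_range[2])
      P <- transition_probabilities(Q, d, pi)
      row <- panel$ref_alignment$states[src, ]
      idx <- match(row, bases)
      evolved <- row
      ok <- !is.na(idx)
      evolved[ok] <- vapply(idx[ok], function(s)
        bases[sample.int(4, 1, prob = P[s, ])], character(1))
      lineage <- sub("^(L\\d+)_.*$", "\\1", src)
      list(seq = paste(evolved[evolved != "-"], collapse = ""),
           true_lineage = paste0("lineage_", sub("^L", "", lineage)))
    })
  })
  rows <- lapply(seq_along(queries), function(i) {
    q <- queries[[i]]
    assigned <- tryCatch({
      aug <- profile_align_query(q$seq, panel$ref_alignment, query_id = "q")
      pl <- place_query(aug, panel)
      assign_lineage(pl, panel, lwr_threshold)
    }, error = function(e) "unassigned")
    tibble::tibble(query = i, true_lineage = q$true_lineage,
                   assigned_lineage = assigned)
  })
  results <- dplyr::bind_rows(rows)
  list(results = results,
       accuracy = mean(results$assigned_lineage == results$true_lineage),
       panel = panel)
}
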