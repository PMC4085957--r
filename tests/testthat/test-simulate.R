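# The synthetic-data generators: structural guarantees, determinism, and
# agreement between what is planted and what the models see.

test_that("simulated trees have the right shape and stay within bounds", {
  tr <- simulate_tree(8, seed = 1)
  expect_equal(length(tr$phy$tip.label), 8)
  expect_equal(nrow(tr$phy$edge), 14)  # 2n - 2 for a rooted binary tree
  expect_true(all(tr$phy$edge.length >= 0.02 & tr$phy$edge.length <= 0.3))
  expect_identical(write_labeled_tree(simulate_tree(8, seed = 9)),
                   write_labeled_tree(simulate_tree(8, seed = 9)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("zero branch lengths give identical sequences", {
  tr <- simulate_tree(5, seed = 2)
  tr$phy$edge.length[] <- 0
  aln <- simulate_codon_alignment(tr, site_class_mixture("M0"),
                                  codon_model_params(), 20, seed = 3)
  expect_equal(nrow(unique(aln$codons)), 1)
})

test_that("long M0 simulations reproduce the stationary codon frequencies", {
  tr <- simulate_tree(4, seed = 4)
  set.seed(44)
  pi <- ccmphylo:::.floor_frequencies(stats::runif(61, 0.5, 1.5))
  p <- codon_model_params(kappa = 2, omega = 0.5, pi = pi)
  aln <- simulate_codon_alignment(tr, site_class_mixture("M0", omega = 0.5),
                                  p, 10000, seed = 5)
  # one tip row is an iid stationary sample (rows are tree-correlated with
  # each other, so the pooled counts would overdisperse the test)
  counts <- table(factor(aln$codons["t1", ],
                         levels = genetic_code()$sense_codons))
  gof <- stats::chisq.test(as.numeric(counts), p = pi)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulations separate low from high omega under an M0 fit", {
  wins <- 0
  for (s in 1:6) {
    tr <- simulate_tree(4, seed = 100 + s)
    lo <- simulate_codon_alignment(tr, site_class_mixture("M0", omega = 0.2),
                                   codon_model_params(omega = 0.2), 200,
                                   seed = 200 + s)
    hi <- simulate_codon_alignment(tr, site_class_mixture("M0", omega = 5),
                                   codon_model_params(omega = 5), 200,
                                   seed = 300 + s)
    flo <- fit_model(lo, tr, "M0")
    fhi <- fit_model(hi, tr, "M0")
    if (flo$estimates$omega < fhi$estimates$omega) wins <- wins + 1
  }
  expect_equal(wins, 6)
})

test_that("simulated site classes drive the planted foreground signal", {
  tr <- simulate_tree(6, seed = 6)
  tr$foreground <- seq_len(14) %in% c(3, 8)
  mix <- site_class_mixture("modelA", p0 = 0.4, p1 = 0.3, omega0 = 0.1,
                            omega2 = 4)
  aln <- simulate_codon_alignment(tr, mix, codon_model_params(kappa = 2),
                                  500, seed = 7)
  cls <- attr(aln, "site_class")
  expect_equal(sort(unique(cls)), c("0", "1", "2a", "2b"))
  frac <- mean(cls %in% c("2a", "2b"))
  expect_lt(abs(frac - 0.3), 0.08)
})

test_that("reference panels have monophyletic, well-separated lineages", {
  sim <- simulate_reference_panel(n_lineages = 5, taxa_per_lineage = 4,
                                  seed = 8)
  p <- sim$panel
  expect_length(p$ref_tree$clades, 5)
  for (ln in names(p$ref_tree$clades))
    expect_true(is_monophyletic_clade(p$ref_tree, ln))
  d <- ape::cophenetic.phylo(p$ref_tree$phy)
  within <- c(); between <- c()
  lin <- sim$truth$lineage[match(rownames(d), sim$truth$taxon)]
  for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
    if (lin[i] == lin[j]) within <- c(within, d[i, j])
    else between <- c(between, d[i, j])
  }
  expect_gt(min(between), max(within))
  expect_error(simulate_reference_panel(divergence = list(between = 0,
                                                          within = 0.1)),
               "> 0")
})

test_that("diel experiments conserve totals and are seed-reproducible", {
  sim <- simulate_reference_panel(seed = 9)
  e1 <- simulate_diel_experiment(sim$panel, seed = 10)
  e2 <- simulate_diel_experiment(sim$panel, seed = 10)
  expect_identical(e1$contigs, e2$contigs)
  expect_identical(e1$counts, e2$counts)
  per_sample <- tapply(e1$counts$count, e1$counts$sample, sum)
  expect_true(all(per_sample <= 1e6))
  # expected rpm equals the planted design within multinomial noise
  d <- e1$truth$design
  joined <- merge(merge(e1$counts, e1$truth$contig_lineage,
                        by.x = "contig", by.y = "id"),
                  d, by = c("lineage", "sample"))
  agg <- aggregate(count ~ lineage + sample + rpm, joined, sum)
  agg$obs_rpm <- agg$count  # library size 1e6 so counts are rpm
  big <- agg[agg$rpm >= 500, ]
  expect_true(all(abs(big$obs_rpm - big$rpm) / big$rpm < 0.2))
  expect_error(
    simulate_diel_experiment(sim$panel,
      design = tibble::tibble(lineage = "lineage_1", sample = "s1", rpm = 0)),
    "all-zero")
})

test_that("the default diel design encodes the day/night contrast", {
  d <- example_diel_design()
  cam <- d[d$lineage == "lineage_4", ]
  c4 <- d[d$lineage == "lineage_5", ]
  drought_night <- cam$rpm[cam$condition == "watered_occasionally" &
                             cam$time == "night"]
  drought_day <- cam$rpm[cam$condition == "watered_occasionally" &
                           cam$time == "day"]
  expect_gt(min(drought_night) / max(drought_day), 20)
  watered_day <- c4$rpm[c4$condition == "watered_frequently" &
                          c4$time == "day"]
  expect_gt(min(watered_day), 4000)
})
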