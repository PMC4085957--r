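# Pruning engine checks against closed forms and exhaustive enumeration.

make_star2 <- function(t1, t2) {
  phy <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t1, t2))
  labeled_tree(phy)
}

test_that("single taxon, single site gives log pi of the observed codon", {
  phy <- ape::read.tree(text = "(a:0.1,b:0.1);")
  tree <- labeled_tree(phy)
  p <- codon_model_params(kappa = 2, omega = 0.5)
  aln <- codon_alignment(matrix(c("ATG", "---"), nrow = 2,
                                dimnames = list(c("a", "b"), NULL)))
  ll <- pruning_log_likelihood(aln, tree, site_class_mixture("M0"), p)
  i <- match("ATG", genetic_code()$sense_codons)
  expect_equal(ll$total, log(p$pi[i]), tolerance = 1e-10)
})

test_that("a degenerate one-class mixture equals plain M0", {
  tree <- simulate_tree(5, seed = 31)
  p <- codon_model_params(kappa = 2, omega = 0.5)
  aln <- simulate_codon_alignment(tree, site_class_mixture("M0", omega = 0.5),
                                  p, 40, seed = 32)
  m0 <- pruning_log_likelihood(aln, tree, site_class_mixture("M0", omega = 0.5), p)
  # M1a with p0 = 1 collapses to M0 with omega = omega0
  degen <- site_class_mixture("M1a", p0 = 1 - 1e-12, omega0 = 0.5)
  m1 <- pruning_log_likelihood(aln, tree, degen, p)
  expect_equal(m1$total, m0$total, tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(33)
  for (rep in 1:6) {
    n <- sample(3:4, 1)
    tree <- simulate_tree(n, seed = 330 + rep)
    pi <- ccmphylo:::.floor_frequencies(stats::runif(61, 0.3, 1))
    p <- codon_model_params(kappa = stats::runif(1, 1, 4),
                            omega = 1, pi = pi)
    tag <- sample(c("M0", "M1a", "M2a", "modelA"), 1)
    if (tag == "modelA") {
      tree$foreground <- seq_len(nrow(tree$phy$edge)) %in%
        sample(nrow(tree$phy$edge), 2)
    }
    mix <- site_class_mixture(tag, p0 = 0.5, p1 = 0.3, omega0 = 0.2,
                              omega2 = 3, omega = 0.6)
    aln <- simulate_codon_alignment(tree, mix, p, 5, seed = 340 + rep)
    got <- pruning_log_likelihood(aln, tree, mix, p)$total
    want <- oracle_mixture_loglik(aln, tree, mix, p)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to taxon row order", {
  tree <- simulate_tree(6, seed = 35)
  p <- codon_model_params(kappa = 2, omega = 0.4)
  mix <- site_class_mixture("M1a", p0 = 0.7, omega0 = 0.1)
  aln <- simulate_codon_alignment(tree, mix, p, 50, seed = 36)
  perm <- sample(length(aln$taxa))
  aln2 <- codon_alignment(aln$codons[perm, , drop = FALSE])
  expect_equal(pruning_log_likelihood(aln2, tree, mix, p)$total,
               pruning_log_likelihood(aln, tree, mix, p)$total,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting under a reversible model", {
  tree <- simulate_tree(6, seed = 37)
  p <- codon_model_params(kappa = 2, omega = 0.4)
  mix <- site_class_mixture("M0", omega = 0.4)
  aln <- simulate_codon_alignment(tree, mix, p, 30, seed = 38)
  base <- pruning_log_likelihood(aln, tree, mix, p)$total
  rerooted <- ape::root(ape::unroot(tree$phy), outgroup = "t3",
                        resolve.root = TRUE)
  expect_equal(pruning_log_likelihood(aln, labeled_tree(rerooted), mix, p)$total,
               base, tolerance = 1e-8)
})

test_that("a zero-length branch does not change the likelihood", {
  tree <- simulate_tree(5, seed = 39)
  p <- codon_model_params(kappa = 2, omega = 0.4)
  mix <- site_class_mixture("M0", omega = 0.4)
  aln <- simulate_codon_alignment(tree, mix, p, 30, seed = 40)
  base <- pruning_log_likelihood(aln, tree, mix, p)$total
  # graft an extra degree-2-resolving zero branch by splitting an edge
  phy <- tree$phy
  qtip <- structure(list(edge = matrix(c(2L, 1L), 1), tip.label = "extra",
                         edge.length = 0, Nnode = 1L), class = "phylo")
  phy2 <- ape::bind.tree(phy, qtip, where = phy$edge[3, 2],
                         position = phy$edge.length[3] / 2)
  aln2 <- codon_alignment(rbind(aln$codons,
                                extra = rep("---", aln$n_sites)))
  got <- pruning_log_likelihood(aln2, labeled_tree(phy2), mix, p)$total
  expect_equal(got, base, tolerance = 1e-10)
})

test_that("alignment taxa must be present in the tree", {
  tree <- simulate_tree(4, seed = 41)
  p <- codon_model_params()
  m <- matrix("ATG", nrow = 1, dimnames = list("absent", NULL))
  expect_error(pruning_log_likelihood(codon_alignment(m), tree,
                                      site_class_mixture("M0"), p),
               "taxon missing from tree")
})

test_that("GTR+Gamma matches the Jukes-Cantor closed form on two taxa", {
  for (t_tot in c(0.1, 0.5, 1.2)) {
    tree <- make_star2(t_tot / 2, t_tot / 2)
    gtr <- gtr_gamma_params(alpha = 1e6)  # effectively rate-homogeneous
    set.seed(42)
    n <- 500
    states <- matrix(sample(c("A", "C", "G", "T"), 2 * n, TRUE), nrow = 2,
                     dimnames = list(c("a", "b"), NULL))
    aln <- nucleotide_alignment(states)
    got <- gtr_gamma_log_likelihood(aln, tree, gtr)$total
    p_same <- 1 / 4 + 3 / 4 * exp(-4 * t_tot / 3)
    p_diff <- (1 - p_same) / 3
    same <- states[1, ] == states[2, ]
    want <- sum(log(1 / 4 * ifelse(same, p_same, p_diff)))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("GTR+Gamma equals exhaustive enumeration on three taxa", {
  tree <- simulate_tree(3, seed = 43)
  gtr <- gtr_gamma_params(exchangeabilities = c(1, 3, 0.5, 0.8, 4, 1),
                          base_freqs = c(0.35, 0.2, 0.15, 0.3), alpha = 0.7)
  aln <- simulate_nucleotide_alignment(tree, gtr, 25, seed = 44)
  got <- gtr_gamma_log_likelihood(aln, tree, gtr)$total
  expect_equal(got, oracle_gtr_loglik(aln, tree, gtr), tolerance = 1e-8)
})

test_that("GTR+Gamma agrees with phangorn on a larger alignment", {
  skip_if_not_installed("phangorn")
  tree <- simulate_tree(6, seed = 45)
  gtr <- gtr_gamma_params(exchangeabilities = c(1.2, 3.5, 0.6, 1.1, 4.2, 1),
                          base_freqs = c(0.3, 0.2, 0.22, 0.28), alpha = 0.9)
  aln <- simulate_nucleotide_alignment(tree, gtr, 400, seed = 46)
  got <- gtr_gamma_log_likelihood(aln, tree, gtr)$total
  dat <- phangorn::phyDat(aln$states, type = "DNA")
  fit <- phangorn::pml(tree$phy, dat, bf = gtr$base_freqs,
                       Q = gtr$exchangeabilities / tail(gtr$exchangeabilities, 1),
                       shape = gtr$alpha, k = 4)
  expect_equal(got, as.numeric(stats::logLik(fit)), tolerance = 1e-4)
})

test_that("per-site log-likelihoods round-trip through JSON", {
  tree <- simulate_tree(4, seed = 47)
  p <- codon_model_params(kappa = 2, omega = 0.4)
  mix <- site_class_mixture("M0", omega = 0.4)
  aln <- simulate_codon_alignment(tree, mix, p, 12, seed = 48)
  ll <- pruning_log_likelihood(aln, tree, mix, p)
  f <- tempfile(fileext = ".json")
  write_site_loglik_json(ll, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$total, ll$total, tolerance = 1e-12)
  expect_equal(back$per_site, ll$per_site, tolerance = 1e-12)
  expect_equal(sum(back$per_site), back$total, tolerance = 1e-8)
})

test_that("IUPAC ambiguity codes act as partial information", {
  tree <- make_star2(0.1, 0.1)
  gtr <- gtr_gamma_params()
  aR <- nucleotide_alignment(matrix(c("R", "A"), 2, 1,
                                    dimnames = list(c("a", "b"), NULL)))
  aA <- nucleotide_alignment(matrix(c("A", "A"), 2, 1,
                                    dimnames = list(c("a", "b"), NULL)))
  aG <- nucleotide_alignment(matrix(c("G", "A"), 2, 1,
                                    dimnames = list(c("a", "b"), NULL)))
  lR <- gtr_gamma_log_likelihood(aR, tree, gtr)$total
  lA <- gtr_gamma_log_likelihood(aA, tree, gtr)$total
  lG <- gtr_gamma_log_likelihood(aG, tree, gtr)$total
  expect_equal(exp(lR), exp(lA) + exp(lG), tolerance = 1e-10)
})
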