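# Contig annotation: homology extraction, profile alignment, placement,
# lineage assignment and rpm bookkeeping.

panel_fixture <- function() {
  if (is.null(.ann_env$panel)) {
    sim <- simulate_reference_panel(n_lineages = 4, taxa_per_lineage = 3,
                                    n_sites = 600, seed = 81)
    .ann_env$panel <- sim$panel
    .ann_env$truth <- sim$truth
  }
  list(panel = .ann_env$panel, truth = .ann_env$truth)
}
.ann_env <- new.env()

ref_ungapped <- function(panel, taxon) {
  s <- panel$ref_alignment$states[taxon, ]
  paste(s[s != "-"], collapse = "")
}

test_that("find_homologous_segment recovers an exact reference copy", {
  p <- panel_fixture()$panel
  full <- ref_ungapped(p, "L1_t1")
  contig <- substr(full, 1, 600)
  hit <- find_homologous_segment(contig, p)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, nchar(contig))
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$ref_taxon, "L1_t1")
})

test_that("matches at or below min_len are rejected", {
  p <- panel_fixture()$panel
  short <- substr(ref_ungapped(p, "L2_t1"), 10, 49)  # 40 bp
  set.seed(82)
  noise <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  expect_null(find_homologous_segment(paste0(short, "X"), p, min_len = 50))
  expect_null(find_homologous_segment(noise, p, min_len = 50))
  # the same 40 bp insert passes a permissive threshold
  expect_false(is.null(find_homologous_segment(short, p, min_len = 30)))
})

test_that("reverse-strand inserts are found with forward coordinates", {
  p <- panel_fixture()$panel
  insert <- substr(ref_ungapped(p, "L3_t2"), 101, 400)
  rc <- ccmphylo:::.revcomp(insert)
  set.seed(83)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  contig <- paste0(pad(50), rc, pad(30))
  hit <- find_homologous_segment(contig, p)
  expect_equal(hit$orientation, "reverse")
  # the local alignment may extend a little into chance-matching padding
  expect_true(grepl(insert, hit$segment, fixed = TRUE))
  expect_gte(hit$start, 1)
  expect_lte(hit$end, nchar(contig))
  # score equals a quadratic-time local-alignment oracle on the same pair
  osw <- oracle_local_align(ccmphylo:::.revcomp(contig),
                            ref_ungapped(p, "L3_t2"))
  expect_equal(hit$score, osw$score)
})

test_that("profile alignment reproduces a reference row's gap pattern", {
  p <- panel_fixture()$panel
  taxon <- "L2_t2"
  seg <- ref_ungapped(p, taxon)
  aug <- profile_align_query(seg, p$ref_alignment, query_id = "q")
  expect_equal(aug$n_sites, p$ref_alignment$n_sites)  # columns frozen
  expect_equal(unname(aug$states["q", ]),
               unname(p$ref_alignment$states[taxon, ]))
  expect_equal(attr(aug, "dropped"), 0)
})

test_that("profile alignment places an internal deletion optimally", {
  rows <- c("ACGTACGTTCGT", "ACGTACGTTCGT", "ACGAACGTTCGT")
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- paste0("r", 1:3)
  ref <- nucleotide_alignment(m)
  q <- "ACGTCGTTCGT"  # base 5 deleted relative to the references
  aug <- profile_align_query(q, ref, query_id = "q")
  qrow <- aug$states["q", ]
  expect_equal(sum(qrow == "-"), 1)
  expect_equal(paste(qrow[qrow != "-"], collapse = ""), q)
  # exhaustive scan over all single-gap placements under the same scoring
  # (internal gaps cost gap_open; end gaps on the profile side are free)
  bases <- strsplit(q, "")[[1]]
  scores <- vapply(1:12, function(g) {
    cand <- append(bases, "-", after = g - 1)
    match_score <- sum(vapply(1:12, function(j) {
      if (cand[j] == "-") return(0)
      mean(ifelse(ref$states[, j] == cand[j], 1, -2))
    }, numeric(1)))
    match_score - 5 * !(g %in% c(1, 12))
  }, numeric(1))
  expect_equal(which(qrow == "-"), which.max(scores))
})

test_that("segments that mostly drop out are reported unalignable", {
  tiny <- nucleotide_alignment(matrix(c("A", "C", "G"), nrow = 1,
                                      dimnames = list("r1", NULL)))
  set.seed(84)
  long_q <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  expect_error(profile_align_query(long_q, tiny), "unalignable")
})

test_that("a reference leaf's own sequence places on its pendant branch", {
  p <- panel_fixture()$panel
  for (taxon in c("L1_t2", "L4_t1")) {
    aug <- profile_align_query(ref_ungapped(p, taxon), p$ref_alignment,
                               query_id = "q")
    pl <- place_query(aug, p)
    expect_equal(pl$best_branch, taxon)
    ln <- sub("^(L\\d+)_.*", "lineage_\\1", taxon)
    ln <- sub("lineage_L", "lineage_", ln)
    expect_equal(assign_lineage(pl, p, lwr_threshold = min(0.8, pl$lwr)), ln)
  }
})

test_that("placement scores are invariant to reference taxon order", {
  p <- panel_fixture()$panel
  aug <- profile_align_query(ref_ungapped(p, "L2_t1"), p$ref_alignment,
                             query_id = "q")
  pl1 <- place_query(aug, p)
  perm <- sample(nrow(aug$states))
  aug2 <- nucleotide_alignment(aug$states[perm, , drop = FALSE])
  pl2 <- place_query(aug2, p)
  s1 <- pl1$scores[order(pl1$scores$branch_id), ]
  s2 <- pl2$scores[order(pl2$scores$branch_id), ]
  expect_equal(s1$lnL, s2$lnL, tolerance = 1e-6)
  expect_equal(pl1$best_branch, pl2$best_branch)
})

test_that("assignment demands nesting strictly inside the clade", {
  p <- panel_fixture()$panel
  aug <- profile_align_query(ref_ungapped(p, "L1_t1"), p$ref_alignment,
                             query_id = "q")
  pl <- place_query(aug, p)
  # force the best branch onto a backbone stem: stem of lineage_2
  stem_edge <- setdiff(clade_edges(p$ref_tree, "lineage_2", TRUE),
                       clade_edges(p$ref_tree, "lineage_2", FALSE))
  pl_stem <- pl
  pl_stem$best_branch <- p$ref_tree$branch_id[stem_edge]
  pl_stem$lwr <- 0.99
  expect_equal(assign_lineage(pl_stem, p), "unassigned")
  # low-confidence placements stay unassigned
  pl_low <- pl
  pl_low$lwr <- 0.5
  expect_equal(assign_lineage(pl_low, p, lwr_threshold = 0.8), "unassigned")
})

test_that("raising the lwr threshold only shrinks the assigned set", {
  p <- panel_fixture()$panel
  set.seed(85)
  lwrs <- c(0.999, 0.95, 0.5, 0.2)
  pls <- lapply(c("L1_t1", "L2_t2", "L3_t1"), function(tx) {
    aug <- profile_align_query(ref_ungapped(p, tx), p$ref_alignment, "q")
    place_query(aug, p)
  })
  prev <- NULL
  for (th in sort(lwrs)) {
    assigned <- vapply(pls, function(pl)
      assign_lineage(pl, p, th) != "unassigned", logical(1))
    if (!is.null(prev)) expect_true(all(assigned <= prev))
    prev <- assigned
  }
})

test_that("compute_rpm scales counts per million alignable reads", {
  r <- compute_rpm(c(a = 5, b = 0), 1e6)
  expect_equal(r$rpm, c(5, 0))
  counts <- c(x = 120, y = 280, z = 600)
  r2 <- compute_rpm(counts, sum(counts))
  expect_equal(sum(r2$rpm), 1e6)  # conservation when counts cover the library
  r3 <- compute_rpm(counts * 2, 2 * sum(counts))
  expect_equal(r2$rpm, r3$rpm)    # scale invariance
  expect_error(compute_rpm(c(a = 1), 0), "> 0")
  expect_error(compute_rpm(c(a = 10), 5), "exceed")
})

test_that("aggregate_lineage_abundance sums per lineage and conserves totals", {
  asg <- tibble::tibble(
    contig = c("c1", "c2", "c3", "c4"),
    sample = c("s1", "s1", "s1", "s1"),
    lineage = c("X", "X", "unassigned", "Y"),
    rpm = c(3, 4, 2.5, 7))
  et <- aggregate_lineage_abundance(asg, lineages = c("X", "Y", "Z"))
  wide <- tidyr::pivot_wider(et, names_from = "sample", values_from = "rpm")
  expect_equal(wide$s1[wide$lineage == "X"], 7)
  expect_equal(wide$s1[wide$lineage == "Y"], 7)
  expect_equal(wide$s1[wide$lineage == "Z"], 0)
  expect_equal(wide$s1[wide$lineage == "unassigned"], 2.5)
  expect_equal(sum(et$rpm), sum(asg$rpm))
  expect_error(aggregate_lineage_abundance(asg, lineages = "X"),
               "unknown lineage")
})

test_that("expression tables plot without error", {
  asg <- tibble::tibble(contig = "c1", sample = c("s1", "s2"),
                        lineage = "X", rpm = c(1, 2))
  et <- aggregate_lineage_abundance(asg)
  pl <- ggplot2::autoplot(et)
  expect_s3_class(pl, "ggplot")
})
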