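test_that("genetic code has 61 sense and 3 stop codons, all 64 mapped", {
  gc <- genetic_code()
  expect_length(gc$sense_codons, 61)
  expect_length(gc$stop_codons, 3)
  expect_length(gc$table, 64)
  expect_setequal(c(gc$sense_codons, gc$stop_codons), names(gc$table))
})

test_that("translate_cds handles standard codons, stops and ambiguity", {
  expect_equal(translate_cds("ATGGCT"), "MA")
  expect_error(translate_cds("ATGTAAGCT", mask_internal_stops = FALSE),
               "internal stop at codon 2")
  expect_equal(translate_cds("ATGTAAGCT", mask_internal_stops = TRUE), "MXA")
  expect_equal(translate_cds("ATGTAA"), "M")      # terminal stop dropped
  expect_equal(translate_cds("ATGNNNGCT"), "MXA") # ambiguity -> X
  expect_error(translate_cds("ATGGC"), "divisible by 3")
  expect_error(translate_cds(""), "nonempty")
})

test_that("translate_cds matches an independent per-codon oracle", {
  for (seed in 1:5) {
    cds <- random_cds(30, seed)
    got <- translate_cds(cds)
    exp_aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    exp_aa <- sub("\\*$", "", exp_aa)
    expect_equal(got, exp_aa)
  }
})

test_that("back_translate_alignment threads codons through protein gaps", {
  prot <- c(a = "MA-", b = "M-A")
  cds <- c(a = "ATGGCT", b = "ATGGCA")
  aln <- back_translate_alignment(prot, cds)
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$n_sites, 3)
  expect_equal(unname(aln$codons["a", ]), c("ATG", "GCT", "---"))
  expect_equal(unname(aln$codons["b", ]), c("ATG", "---", "GCA"))
})

test_that("back_translate round trip is the identity on ungapped input", {
  for (seed in 6:8) {
    cds <- c(x = random_cds(20, seed), y = random_cds(20, seed + 100))
    prot <- vapply(cds, translate_cds, character(1))
    aln <- back_translate_alignment(prot, cds)
    rebuilt <- apply(aln$codons, 1, paste, collapse = "")
    expect_equal(unname(rebuilt[c("x", "y")]), unname(cds))
  }
})

test_that("back_translate reports the first mismatching residue", {
  cds <- c(a = "ATGGCTAAA")
  prot <- c(a = translate_cds(cds[["a"]]))
  bad <- cds
  bad[["a"]] <- "ATGCCTAAA"  # codon 2 edited: A != P
  expect_error(back_translate_alignment(prot, bad), "residue 2")
  expect_error(back_translate_alignment(prot, c(b = "ATG")), "missing CDS")
})

test_that("extract_codon_positions pulls the requested positions in order", {
  aln <- as_codon_alignment(c(a = "ATGGCT", b = "ATGGCA"))
  third <- extract_codon_positions(aln, 3)
  expect_equal(unname(third$states["a", ]), c("G", "T"))
  expect_equal(unname(third$states["b", ]), c("G", "A"))
  all3 <- extract_codon_positions(aln, c(1, 2, 3))
  expect_equal(paste(all3$states["a", ], collapse = ""), "ATGGCT")
  expect_error(extract_codon_positions(aln, integer(0)), "nonempty")
})

test_that("codon positions 1/2/3 re-interleave to the original alignment", {
  cds <- c(u = random_cds(15, 11), v = random_cds(15, 12),
           w = random_cds(15, 13))
  aln <- as_codon_alignment(cds)
  parts <- lapply(1:3, function(p) extract_codon_positions(aln, p)$states)
  rebuilt <- matrix("", nrow = 3, ncol = 45,
                    dimnames = list(names(cds), NULL))
  for (s in 1:15) for (p in 1:3)
    rebuilt[, 3 * (s - 1) + p] <- parts[[p]][, s]
  orig <- do.call(rbind, strsplit(unname(cds), ""))
  expect_equal(unname(rebuilt), orig)
  # row order and count preserved for every position choice
  expect_equal(extract_codon_positions(aln, c(1, 3))$taxa, aln$taxa)
})

test_that("gap codons propagate into extracted positions", {
  prot <- c(a = "MA", b = "M-")
  cds <- c(a = "ATGGCT", b = "ATG")
  aln <- back_translate_alignment(prot, cds)
  third <- extract_codon_positions(aln, 3)
  expect_equal(unname(third$states["b", ]), c("G", "-"))
})

test_that("dedupe_keep_longest keeps the longest of substring groups", {
  out <- dedupe_keep_longest(tibble::tibble(id = c("x", "y"),
                                            seq = c("AAA", "AAA")))
  expect_equal(nrow(out), 1)
  expect_equal(out$id, "x")  # equal length: lexicographic id
  out2 <- dedupe_keep_longest(tibble::tibble(id = c("p", "q"),
                                             seq = c("AAAT", "AAA")))
  expect_equal(out2$seq, "AAAT")
  expect_equal(nrow(dedupe_keep_longest(tibble::tibble(id = character(),
                                                       seq = character()))), 0)
})

test_that("dedupe_keep_longest matches a brute-force containment scan", {
  set.seed(21)
  for (rep in 1:5) {
    base <- vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
            collapse = ""), character(1))
    planted <- unlist(lapply(base[1:3], function(s)
      substr(s, 1, nchar(s) - sample(0:4, 1))))
    seqs <- tibble::tibble(id = sprintf("s%02d", seq_along(c(base, planted))),
                           seq = c(base, planted))
    out <- dedupe_keep_longest(seqs)
    # survivors must be pairwise containment-free
    for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
      if (i == j) next
      expect_false(grepl(out$seq[i], out$seq[j], fixed = TRUE) &&
                     nchar(out$seq[i]) <= nchar(out$seq[j]))
    }
    # every dropped sequence is contained in some survivor
    dropped <- setdiff(seqs$id, out$id)
    for (id in dropped) {
      s <- seqs$seq[seqs$id == id]
      expect_true(any(vapply(out$seq, function(t)
        grepl(s, t, fixed = TRUE), logical(1))))
    }
    # idempotence
    expect_equal(dedupe_keep_longest(out), out)
  }
})

test_that("FASTA and relaxed PHYLIP round-trip sequences", {
  seqs <- tibble::tibble(id = c("taxon_with_long_name", "b"),
                         seq = c("ATGGCTAAA", "ATGGCAAAA"))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, seqs$id)
  expect_equal(back$seq, seqs$seq)
  expect_equal(back$alphabet[1], "dna")
  ph <- tempfile(fileext = ".phy")
  write_phylip(seqs, ph)
  back2 <- read_phylip(ph)
  expect_equal(back2$seq, seqs$seq)
  expect_equal(back2$id, seqs$id)
  prot <- tibble::tibble(id = "p", seq = "MKLV")
  fa2 <- tempfile(fileext = ".fasta")
  write_fasta(prot, fa2)
  expect_equal(read_fasta(fa2)$alphabet, "protein")
})
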