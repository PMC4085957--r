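#' Standard genetic code
#'
#' Returns the standard nuclear genetic code as used throughout the package:
#' the full 64-codon translation table, the 61 sense codons in a fixed order
#' (the order in which codon states are indexed everywhere, including rate
#' matrices and stationary frequencies), and the stop codons.
#'
#' @return A list of class `genetic_code` with elements `table` (named
#'   character vector over all 64 codons, stops as `"*"`), `sense_codons`
#'   (character vector, length 61), `stop_codons` (length 3) and
#'   `codon_index` (named integer vector mapping sense codon to state index).
#' @export
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
genetic_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  sense <- names(tab)[tab != "*"]
  stops <- names(tab)[tab == "*"]
  structure(
    list(table = tab,
         sense_codons = sense,
         stop_codons = stops,
         codon_index = stats::setNames(seq_along(sense), sense)),
    class = "genetic_code")
}

# purine <-> purine or pyrimidine <-> pyrimidine single-nucleotide change
.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

# Precomputed structure of single-nucleotide codon pairs: for each ordered
# pair (i, j) of sense codons differing at exactly one position, whether the
# change is a transition and whether it is nonsynonymous. Computed once per
# session; this is the skeleton every GY94 rate matrix is filled into.
.codon_pairs_env <- new.env(parent = emptyenv())

codon_pair_structure <- function(code = genetic_code()) {
  if (!is.null(.codon_pairs_env$pairs)) return(.codon_pairs_env$pairs)
  sense <- code$sense_codons
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  ii <- integer(0); jj <- integer(0); ts <- logical(0); ns <- logical(0)
  for (i in seq_len(n)) {
    diffs <- (mat[i, 1] != t(mat[, 1])) + (mat[i, 2] != t(mat[, 2])) +
      (mat[i, 3] != t(mat[, 3]))
    j <- which(diffs == 1)
    if (!length(j)) next
    pos <- vapply(j, function(k) which(mat[i, ] != mat[k, ]), integer(1))
    from <- mat[cbind(i, pos)]
    to <- mat[cbind(j, pos)]
    ii <- c(ii, rep.int(i, length(j))); jj <- c(jj, j)
    ts <- c(ts, .is_transition(from, to))
    ns <- c(ns, code$table[sense[i]] != code$table[sense[j]])
  }
  out <- list(i = ii, j = jj, transition = ts, nonsyn = ns)
  .codon_pairs_env$pairs <- out
  out
}

#' Translate a coding sequence
#'
#' Translates an in-frame CDS under a genetic code. Codons containing IUPAC
#' ambiguity characters (or gaps) translate to `"X"`. A terminal stop codon is
#' dropped; internal stops either raise an error or are masked to `"X"`,
#' matching how putative pseudogenes carrying stop codons can be retained in
#' gene-family alignments.
#'
#' @param cds Character scalar, nucleotide sequence with length divisible by 3.
#' @param code A [genetic_code()].
#' @param mask_internal_stops If `TRUE` (default) internal stop codons become
#'   `"X"`; if `FALSE` they are an error.
#' @return Character scalar protein sequence.
#' @export
#' @examples
#' translate_cds("ATGGCT")  # "MA"
translate_cds <- function(cds, code = genetic_code(), mask_internal_stops = TRUE) {
  if (!is.character(cds) || length(cds) != 1 || !nzchar(cds))
    stop("`cds` must be a nonempty character scalar")
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"  # ambiguity or gap characters in the codon
  n <- length(aa)
  if (aa[n] == "*") { aa <- aa[-n]; codons <- codons[-n] }
  internal <- which(aa == "*")
  if (length(internal)) {
    if (!mask_internal_stops)
      stop("internal stop at codon ", internal[1])
    aa[internal] <- "X"
  }
  paste(aa, collapse = "")
}
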