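#' Codon alignment container
#'
#' A codon alignment stores taxa by in-frame codon columns: each cell is a
#' 3-character codon, the codon gap `"---"`, or a codon containing ambiguity
#' characters. It is the unit of all codon-model likelihood computation.
#'
#' @param codons Character matrix (taxa in rows, codon sites in columns) of
#'   3-character strings, with row names giving taxon ids.
#' @return An object of class `codon_alignment` with elements `codons`,
#'   `taxa`, `n_sites`.
#' @export
codon_alignment <- function(codons) {
  stopifnot(is.matrix(codons), is.character(codons))
  if (is.null(rownames(codons))) stop("codon matrix must have taxon row names")
  if (ncol(codons) < 1) stop("alignment must have at least one codon site")
  if (any(nchar(codons) != 3)) stop("every cell must be a 3-character codon")
  codons[] <- toupper(codons)
  structure(list(codons = codons, taxa = rownames(codons), n_sites = ncol(codons)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$taxa), "taxa x", x$n_sites, "codon sites\n")
  invisible(x)
}

#' Build a codon alignment from aligned coding sequences
#'
#' @param seqs Named character vector (or tibble with `id`, `seq`) of aligned
#'   nucleotide sequences whose common length is divisible by 3.
#' @return A [codon_alignment()].
#' @export
as_codon_alignment <- function(seqs) {
  seqs <- .as_named_seqs(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1) stop("sequences must be aligned (equal length)")
  if (len %% 3 != 0) stop("alignment length not divisible by 3")
  m <- t(vapply(seqs, function(s)
    substring(toupper(s), seq(1, len, 3), seq(3, len, 3)),
    character(len / 3)))
  if (len / 3 == 1) m <- matrix(m, ncol = 1, dimnames = list(names(seqs), NULL))
  rownames(m) <- names(seqs)
  codon_alignment(m)
}

.as_named_seqs <- function(seqs) {
  if (is.data.frame(seqs)) {
    stopifnot(all(c("id", "seq") %in% names(seqs)))
    seqs <- stats::setNames(seqs$seq, seqs$id)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named (nonempty ids)")
  seqs
}

#' Nucleotide alignment container
#'
#' @param states Character matrix of single-nucleotide states (taxa in rows),
#'   using `A C G T`, gap `-`, `N`/`?` or IUPAC ambiguity codes.
#' @return An object of class `nucleotide_alignment`.
#' @export
nucleotide_alignment <- function(states) {
  stopifnot(is.matrix(states), is.character(states))
  if (is.null(rownames(states))) stop("matrix must have taxon row names")
  states[] <- toupper(states)
  structure(list(states = states, taxa = rownames(states), n_sites = ncol(states)),
            class = "nucleotide_alignment")
}

#' @export
print.nucleotide_alignment <- function(x, ...) {
  cat("nucleotide alignment:", length(x$taxa), "taxa x", x$n_sites, "sites\n")
  invisible(x)
}

#' Back-translate an aligned protein set onto its coding sequences
#'
#' Replaces each aligned amino acid by the corresponding codon of the
#' unaligned CDS, turning protein gaps into codon gaps — the standard
#' protein-alignment-guided construction of codon alignments.
#'
#' @param protein_aln Named character vector (or tibble with `id`, `seq`) of
#'   aligned protein sequences (gaps as `-`).
#' @param cds_map Named character vector (or tibble with `id`, `seq`) mapping
#'   each id to its in-frame CDS.
#' @param code A [genetic_code()].
#' @return A [codon_alignment()] whose non-gap codons, concatenated, equal
#'   each input CDS (minus a terminal stop).
#' @export
back_translate_alignment <- function(protein_aln, cds_map, code = genetic_code()) {
  protein_aln <- .as_named_seqs(protein_aln)
  cds_map <- .as_named_seqs(cds_map)
  len <- unique(nchar(protein_aln))
  if (length(len) != 1) stop("protein alignment rows must have equal length")
  rows <- lapply(names(protein_aln), function(id) {
    if (is.na(cds_map[id])) stop("missing CDS for row '", id, "'")
    cds <- toupper(cds_map[[id]])
    prot <- translate_cds(cds, code, mask_internal_stops = TRUE)
    n_cod <- nchar(prot)
    codons <- substring(cds, seq(1, 3 * n_cod, 3), seq(3, 3 * n_cod, 3))
    aa_aln <- strsplit(toupper(protein_aln[[id]]), "")[[1]]
    ungapped <- aa_aln[aa_aln != "-"]
    if (length(ungapped) != n_cod || any(ungapped != strsplit(prot, "")[[1]])) {
      bad <- which(ungapped != strsplit(prot, "")[[1]] |
                     seq_along(ungapped) > n_cod)[1]
      if (is.na(bad)) bad <- min(length(ungapped), n_cod) + 1
      stop("row '", id, "' does not translate to its aligned protein ",
           "(first mismatch at residue ", bad, ")")
    }
    out <- rep("---", len)
    out[aa_aln != "-"] <- codons
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(protein_aln)
  codon_alignment(m)
}

#' Extract codon positions as a nucleotide alignment
#'
#' Pulls the requested within-codon positions (1..3) from every codon site —
#' e.g. third positions only, the classic trick for reducing the footprint of
#' protein-level convergence on tree inference.
#'
#' @param aln A [codon_alignment()].
#' @param positions Nonempty subset of `c(1, 2, 3)`.
#' @return A [nucleotide_alignment()] with `n_sites * length(positions)`
#'   columns, ordered by codon site then position; gaps propagate.
#' @export
extract_codon_positions <- function(aln, positions = 3) {
  stopifnot(inherits(aln, "codon_alignment"))
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions) || any(!positions %in% 1:3))
    stop("`positions` must be a nonempty subset of 1:3")
  nt <- lapply(seq_len(aln$n_sites), function(s) {
    cell <- aln$codons[, s, drop = TRUE]
    sapply(positions, function(p) substr(cell, p, p))
  })
  m <- do.call(cbind, lapply(nt, function(x) matrix(x, nrow = length(aln$taxa))))
  rownames(m) <- aln$taxa
  nucleotide_alignment(m)
}

#' Collapse a sequence set to the longest representative of identical groups
#'
#' Two sequences are "identical" when one is an exact substring of the other
#' (or they are equal): within each such group only the longest sequence is
#' kept, with ties broken by lexicographic id. This is the screening rule used
#' when folding redundant transcriptome assemblies into a reference set.
#'
#' @param seqs Tibble with columns `id`, `seq` (or a named character vector).
#' @return Tibble of survivors, in the original order.
#' @export
dedupe_keep_longest <- function(seqs) {
  if (!is.data.frame(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), seq = unname(seqs))
  }
  seqs <- tibble::as_tibble(seqs)
  n <- nrow(seqs)
  if (n == 0) return(seqs)
  s <- toupper(seqs$seq)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (drop[i]) next
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      contained <- grepl(s[j], s[i], fixed = TRUE) || grepl(s[i], s[j], fixed = TRUE)
      if (!contained) next
      li <- nchar(s[i]); lj <- nchar(s[j])
      # keep the longer; on equal length the lexicographically smaller id
      if (lj > li || (lj == li && seqs$id[j] < seqs$id[i])) {
        drop[i] <- TRUE; break
      } else {
        drop[j] <- TRUE
      }
    }
  }
  seqs[!drop, , drop = FALSE]
}

#' Read sequences from a FASTA file
#'
#' @param path File path.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`.
#' @return Tibble with columns `id`, `seq`, `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  ids <- sub("\\s.*$", "", names(x))
  if (alphabet == "auto") {
    chars <- unique(strsplit(toupper(paste(seqs, collapse = "")), "")[[1]])
    dna_chars <- c("A", "C", "G", "T", "U", "N", "-", "?", "R", "Y", "S", "W",
                   "K", "M", "B", "D", "H", "V")
    alphabet <- if (all(chars %in% dna_chars)) "dna" else "protein"
  }
  tibble::tibble(id = ids, seq = unname(seqs), alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with `id`, `seq` (or named character vector).
#' @param path File path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- .as_named_seqs(seqs)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Relaxed PHYLIP (whitespace-delimited names, sequential) read/write for
# alignments; name length is unrestricted, which the strict format forbids.

#' Read a relaxed sequential PHYLIP alignment
#' @param path File path.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n <- hdr[1]; len <- hdr[2]
  ids <- character(n); seqs <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    ids[i] <- parts[1]
    seqs[i] <- paste(parts[-1], collapse = "")
  }
  if (any(nchar(seqs) != len))
    stop("sequence length disagrees with PHYLIP header")
  tibble::tibble(id = ids, seq = seqs)
}

#' Write a relaxed sequential PHYLIP alignment
#' @param seqs Tibble with `id`, `seq` (or named character vector), aligned.
#' @param path File path.
#' @export
write_phylip <- function(seqs, path) {
  seqs <- .as_named_seqs(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1) stop("sequences must be aligned")
  writeLines(c(paste(length(seqs), len),
               paste(names(seqs), unname(seqs))), path)
  invisible(path)
}
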