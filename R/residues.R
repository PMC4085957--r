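# Diagnostic-residue screening: map query proteins onto a reference
# numbering and classify the residue at positions known to distinguish
# C4/CAM-recruited PEPC from its non-photosynthetic relatives. The key
# marker is position 780 (numbering on the maize PEPC protein, accession
# CAA33317): serine there is the recurrent C4/CAM-associated state, alanine
# the conserved state of PEPCs not involved in carbon-concentrating
# mechanisms.

#' Map reference protein positions onto a query
#'
#' Globally aligns query and reference proteins (affine gaps, BLOSUM62) and
#' reports, for every reference position, the aligned query residue and its
#' 1-based index in the ungapped query (or gap). Numbering is 1-based on the
#' ungapped reference.
#'
#' @param query Character scalar, protein sequence.
#' @param reference Character scalar, protein sequence defining the
#'   numbering.
#' @return Tibble with columns `ref_pos`, `ref_residue`, `query_residue`
#'   (`"-"` for gap), `query_pos` (`NA` for gap); attribute `identity` holds
#'   the alignment identity, and attribute `unreliable` is `TRUE` when
#'   identity < 30% (numbering likely meaningless).
#' @export
map_reference_positions <- function(query, reference) {
  stopifnot(is.character(query), nzchar(query),
            is.character(reference), nzchar(reference))
  query <- toupper(gsub("[-*]", "", query))
  reference <- toupper(gsub("[-*]", "", reference))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = get("BLOSUM62"),
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(ra != "-")
  q_pos <- cumsum(qa != "-")
  keep <- ra != "-"
  out <- tibble::tibble(
    ref_pos = ref_pos[keep],
    ref_residue = ra[keep],
    query_residue = qa[keep],
    query_pos = ifelse(qa[keep] == "-", NA_integer_, q_pos[keep]))
  ident <- mean(qa == ra & qa != "-")
  attr(out, "identity") <- ident
  attr(out, "unreliable") <- ident < 0.30
  out
}

#' Report diagnostic residues of a query protein
#'
#' Maps the requested reference positions onto the query and reports the
#' aligned residue at each. Position 780 is classified:
#' serine = `"C4/CAM-associated"`, alanine = `"non-CCM-like"`, anything else
#' (including a gap) = `"other"`. Other positions (e.g. 531, 572, 665, 761,
#' sites of recurrent C4-associated substitutions) are reported
#' descriptively without classification.
#'
#' @param query Character scalar, protein sequence (or CDS; see `translate`).
#' @param reference Character scalar, the reference protein providing the
#'   numbering.
#' @param positions Integer vector of reference positions (default 780).
#' @param translate If `TRUE`, `query` is an in-frame CDS and is translated
#'   first.
#' @return Tibble of class `residue_report`: `position`, `ref_residue`,
#'   `query_residue`, `query_pos`, `classification` (`NA` for positions
#'   without a classification rule); attribute `unreliable` as in
#'   [map_reference_positions()].
#' @export
diagnose_residues <- function(query, reference, positions = 780,
                              translate = FALSE) {
  if (translate) query <- translate_cds(query)
  reference <- toupper(gsub("[-*]", "", reference))
  if (any(positions < 1 | positions > nchar(reference)))
    stop("position out of range of the reference (length ",
         nchar(reference), ")")
  map <- map_reference_positions(query, reference)
  rows <- map[match(positions, map$ref_pos), ]
  classify <- function(pos, res) {
    if (pos != 780) return(NA_character_)
    switch(res, S = "C4/CAM-associated", A = "non-CCM-like", "other")
  }
  out <- tibble::tibble(
    position = positions,
    ref_residue = rows$ref_residue,
    query_residue = rows$query_residue,
    query_pos = rows$query_pos,
    classification = mapply(classify, positions, rows$query_residue))
  class(out) <- c("residue_report", class(out))
  attr(out, "identity") <- attr(map, "identity")
  attr(out, "unreliable") <- attr(map, "unreliable")
  out
}

#' Screen many query proteins for diagnostic residues
#'
#' @param queries Tibble with `id`, `seq` (proteins, or CDS with
#'   `translate = TRUE`).
#' @param reference Reference protein sequence.
#' @param positions Reference positions (default 780).
#' @param translate Translate queries first (default FALSE).
#' @return Tibble: one row per query x position, with the columns of
#'   [diagnose_residues()] plus `id` and `unreliable`.
#' @export
screen_residues <- function(queries, reference, positions = 780,
                            translate = FALSE) {
  dplyr::bind_rows(lapply(seq_len(nrow(queries)), function(i) {
    rep <- diagnose_residues(queries$seq[i], reference, positions, translate)
    rep$id <- queries$id[i]
    rep$unreliable <- attr(rep, "unreliable")
    rep[, c("id", "position", "ref_residue", "query_residue", "query_pos",
            "classification", "unreliable")]
  }))
}
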