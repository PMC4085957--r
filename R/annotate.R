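# Phylogenetic annotation of transcriptome contigs: extract the homologous
# segment, align it into the fixed reference alignment, place it on the
# reference tree by maximum likelihood, assign it to a gene lineage, and
# aggregate rpm per lineage.

# match/mismatch matrix over A,C,G,T plus a neutral N
.nt_submat <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Find the homologous segment of a contig against a reference panel
#'
#' Scans the contig (both strands if requested) against every ungapped
#' reference sequence with local alignment (match +1, mismatch -2, affine
#' gaps 5/2) and reports the longest best-scoring matched region when it
#' exceeds `min_len` — the rule used to decide whether a contig carries
#' usable homologous sequence (50 bp for within-study contigs; 500 bp for
#' screening external transcriptome assemblies).
#'
#' @param contig Character scalar, nucleotide sequence.
#' @param panel A [reference_panel()].
#' @param min_len Minimum matched-region length in bp; a region must be
#'   strictly longer to be reported (default 50).
#' @param check_reverse Also search the reverse complement (default TRUE).
#' @return `NULL` if no qualifying match; otherwise a list with `start`,
#'   `end` (1-based inclusive, forward-strand contig coordinates),
#'   `orientation` (`"forward"`/`"reverse"`), `ref_taxon`, `score`, and
#'   `segment` (the matched contig substring, reverse-complemented to the
#'   reference orientation when needed).
#' @export
find_homologous_segment <- function(contig, panel, min_len = 50,
                                    check_reverse = TRUE) {
  stopifnot(is.character(contig), length(contig) == 1)
  if (min_len < 1) stop("min_len must be >= 1")
  contig <- toupper(contig)
  refs <- apply(panel$ref_alignment$states, 1, function(r)
    paste(r[r != "-"], collapse = ""))
  sub <- .nt_submat()
  best <- NULL
  strands <- if (check_reverse) c("forward", "reverse") else "forward"
  for (strand in strands) {
    qry <- if (strand == "forward") contig else .revcomp(contig)
    qry_clean <- gsub("[^ACGT]", "N", qry)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rep(qry_clean, length(refs))),
      Biostrings::DNAStringSet(unname(refs)),
      type = "local", substitutionMatrix = sub,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(pa)
    i <- which.max(sc)
    if (is.null(best) || sc[i] > best$score) {
      st <- Biostrings::start(Biostrings::pattern(pa))[i]
      en <- Biostrings::end(Biostrings::pattern(pa))[i]
      best <- list(score = sc[i], strand = strand, ref = names(refs)[i],
                   st = st, en = en,
                   segment = substr(qry, st, en))
    }
  }
  if (is.null(best) || (best$en - best$st + 1) <= min_len) return(NULL)
  n <- nchar(contig)
  if (best$strand == "reverse") {
    fwd <- c(n - best$en + 1, n - best$st + 1)
  } else {
    fwd <- c(best$st, best$en)
  }
  list(start = fwd[1], end = fwd[2], orientation = best$strand,
       ref_taxon = best$ref, score = best$score, segment = best$segment)
}

#' Align a query segment into a fixed-column reference alignment
#'
#' Profile alignment with frozen reference columns: the query's characters
#' are distributed over the existing columns by affine-gap alignment against
#' position-specific nucleotide frequencies; query characters that would
#' need new columns (query-only insertions) are dropped and counted, so all
#' augmented alignments share the reference coordinate system.
#'
#' @param segment Character scalar, the (homologous) query sequence.
#' @param ref_alignment A [nucleotide_alignment()].
#' @param query_id Row name for the query (default `"query"`).
#' @param match,mismatch,gap_open,gap_ext Alignment scoring (defaults +1, -2,
#'   5, 2, penalties positive).
#' @param max_gap_fraction Error threshold: if more than this fraction of the
#'   query is dropped or the query covers almost nothing, it is reported
#'   unalignable (default 0.8).
#' @return A [nucleotide_alignment()] with the reference rows unchanged plus
#'   the query row; attribute `dropped` counts discarded query characters.
#' @export
profile_align_query <- function(segment, ref_alignment, query_id = "query",
                                match = 1, mismatch = -2, gap_open = 5,
                                gap_ext = 2, max_gap_fraction = 0.8) {
  stopifnot(is.character(segment), length(segment) == 1, nzchar(segment))
  if (query_id %in% ref_alignment$taxa)
    stop("query id collides with a reference taxon")
  bases <- c("A", "C", "G", "T")
  q <- strsplit(toupper(segment), "")[[1]]
  np <- ref_alignment$n_sites
  # position-specific base frequencies (gaps excluded)
  freq <- vapply(seq_len(np), function(j) {
    col <- ref_alignment$states[, j]
    col <- col[col %in% bases]
    if (!length(col)) return(rep(0, 4))
    as.numeric(table(factor(col, levels = bases))) / length(col)
  }, numeric(4))
  scores <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
  diag(scores) <- match
  qi <- match(q, bases)
  S <- matrix(0, length(q), np)
  known <- !is.na(qi)
  S[known, ] <- scores[qi[known], , drop = FALSE] %*% freq
  cols <- profile_align_dp(S, gap_open, gap_ext)
  dropped <- sum(cols == 0)
  if (dropped > max_gap_fraction * length(q) ||
      sum(cols > 0) < (1 - max_gap_fraction) * length(q))
    stop("query '", query_id, "' is unalignable against the profile")
  row <- rep("-", np)
  row[cols[cols > 0]] <- q[cols > 0]
  m <- rbind(ref_alignment$states, row)
  rownames(m) <- c(ref_alignment$taxa, query_id)
  out <- nucleotide_alignment(m)
  attr(out, "dropped") <- dropped
  out
}

#' Place a query on every branch of the reference tree
#'
#' For each branch of the panel tree the query is attached by a pendant edge
#' at the branch midpoint, the pendant length is optimized under GTR+Gamma,
#' and the log-likelihood recorded. The best attachment branch and its
#' likelihood weight ratio (softmax of per-branch log-likelihoods) summarize
#' where the query belongs; ties go to the shorter pendant, then the smaller
#' branch id.
#'
#' @param aug_alignment A [nucleotide_alignment()] containing all panel taxa
#'   plus exactly one query row (from [profile_align_query()]).
#' @param panel A [reference_panel()].
#' @param pendant_bounds Search interval for the pendant length (expected
#'   substitutions/site).
#' @return Object of class `placement`: list with `query`, `scores` (tibble
#'   `branch_id`, `lnL`, `pendant`, `lwr`), `best_branch`, `lwr`.
#' @export
place_query <- function(aug_alignment, panel, pendant_bounds = c(1e-8, 5)) {
  ref_taxa <- panel$ref_tree$phy$tip.label
  query <- setdiff(aug_alignment$taxa, ref_taxa)
  if (length(query) != 1)
    stop("augmented alignment must contain exactly one non-reference row")
  if (all(!aug_alignment$states[query, ] %in% c("A", "C", "G", "T")))
    stop("query row '", query, "' has no informative states")
  params <- panel$gtr_params
  pre <- .prep_tree(panel$ref_tree, ref_taxa)
  all_cols <- seq_len(aug_alignment$n_sites)
  tip_codes <- .nt_tip_codes(aug_alignment$states, pre, all_cols)
  alphabet <- names(.iupac_sets)
  qcodes <- match(aug_alignment$states[query, ], alphabet)
  qcodes[is.na(qcodes)] <- match("N", alphabet)
  L <- .iupac_lookup()
  Q <- gtr_rate_matrix(params, scale = TRUE)
  pi <- params$base_freqs
  sd <- spectral_decomposition(Q, pi)
  lam <- as.numeric(sd$lambda)
  rates <- discrete_gamma_rates(params$alpha, params$n_cat)
  # per rate category: docking partials at every edge midpoint, so each
  # pendant-length evaluation is a per-column dot product, not a re-pruning
  D <- lapply(rates, function(r) {
    P <- pmat_cube(sd$A, sd$B, lam, pre$blen * r)
    Ph <- pmat_cube(sd$A, sd$B, lam, pre$blen * r / 2)
    placement_docking(P, Ph, pre$edges, tip_codes, L, pre$nnode, pre$root, pi)
  })
  grid <- exp(seq(log(max(pendant_bounds[1], 1e-6)),
                  log(pendant_bounds[2]), length.out = 16))
  rows <- lapply(seq_len(nrow(pre$edges)), function(e) {
    D_e <- lapply(D, function(d) d[, , e])
    lnls <- pendant_scan(D_e, sd$A, sd$B, lam, rates, qcodes, L, grid)
    i <- which.max(lnls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(x)
      -pendant_scan(D_e, sd$A, sd$B, lam, rates, qcodes, L, x),
      c(lo, hi), tol = 1e-4)
    tibble::tibble(branch_id = pre$branch_id[e], lnL = -opt$objective,
                   pendant = opt$minimum)
  })
  scores <- dplyr::bind_rows(rows)
  w <- exp(scores$lnL - max(scores$lnL))
  scores$lwr <- w / sum(w)
  ord <- order(-scores$lnL, scores$pendant, scores$branch_id)
  best <- scores$branch_id[ord[1]]
  structure(list(query = query, scores = scores, best_branch = best,
                 lwr = scores$lwr[ord[1]]),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("placement of '%s': best branch %s (lwr %.3f)\n",
              x$query, x$best_branch, x$lwr))
  invisible(x)
}

#' Assign a placed query to a gene lineage
#'
#' A query belongs to lineage L only when its best attachment branch lies
#' strictly within L's clade (not on the stem) and the placement is confident
#' (likelihood weight ratio at or above the threshold) — the operational
#' version of "clearly nested within" a lineage.
#'
#' @param placement A [place_query()] result.
#' @param panel A [reference_panel()].
#' @param lwr_threshold Confidence threshold in (0, 1] (default 0.8).
#' @return Character scalar: a lineage name or `"unassigned"`.
#' @export
assign_lineage <- function(placement, panel, lwr_threshold = 0.8) {
  if (lwr_threshold <= 0 || lwr_threshold > 1)
    stop("lwr_threshold must be in (0, 1]")
  if (placement$lwr < lwr_threshold) return("unassigned")
  tree <- panel$ref_tree
  for (ln in names(tree$clades)) {
    inside <- tree$branch_id[clade_edges(tree, ln, include_stem = FALSE)]
    if (placement$best_branch %in% inside) return(ln)
  }
  "unassigned"
}

#' Reads per million alignable reads
#'
#' @param counts Named numeric vector or tibble with columns `contig`,
#'   `count`: reads aligned to each contig.
#' @param total_alignable Total alignable reads in the library; must be at
#'   least `sum(counts)` and positive.
#' @return Tibble with `contig`, `rpm` where
#'   `rpm = count / total_alignable * 1e6`.
#' @export
compute_rpm <- function(counts, total_alignable) {
  if (is.data.frame(counts)) counts <- stats::setNames(counts$count, counts$contig)
  if (total_alignable <= 0) stop("total_alignable must be > 0")
  if (sum(counts) > total_alignable + 1e-9)
    stop("counts exceed total_alignable")
  tibble::tibble(contig = names(counts),
                 rpm = unname(counts) / total_alignable * 1e6)
}

#' Aggregate contig rpm into a lineage-by-sample expression table
#'
#' Sums the rpm of all contigs assigned to each gene lineage within each
#' sample; rpm of unassigned contigs is kept in an `"unassigned"` row so the
#' per-sample total is conserved exactly.
#'
#' @param assignments Tibble with columns `contig`, `sample`, `lineage`
#'   (lineage name or `"unassigned"`), `rpm`.
#' @param lineages Optional character vector fixing the lineage rows (zero
#'   rows are reported for lineages with no contigs).
#' @param samples Optional tibble of per-sample metadata (column `sample`
#'   plus e.g. `individual`, `condition`, `time`), joined onto the result.
#' @return Tibble of class `expression_table`: `lineage`, `sample`, `rpm`
#'   (long form; use [tidyr::pivot_wider()] for the matrix layout).
#' @export
aggregate_lineage_abundance <- function(assignments, lineages = NULL,
                                        samples = NULL) {
  stopifnot(all(c("contig", "sample", "lineage", "rpm") %in%
                  names(assignments)))
  if (is.null(lineages))
    lineages <- setdiff(unique(assignments$lineage), "unassigned")
  bad <- setdiff(unique(assignments$lineage), c(lineages, "unassigned"))
  if (length(bad)) stop("unknown lineage label(s): ", paste(bad, collapse = ", "))
  grid <- tidyr::expand_grid(lineage = c(lineages, "unassigned"),
                             sample = unique(assignments$sample))
  agg <- dplyr::summarise(
    dplyr::group_by(assignments, .data$lineage, .data$sample),
    rpm = sum(.data$rpm), .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = c("lineage", "sample"))
  out$rpm[is.na(out$rpm)] <- 0
  if (!is.null(samples)) out <- dplyr::left_join(out, samples, by = "sample")
  class(out) <- c("expression_table", class(out))
  out
}

#' Annotate contigs end to end and quantify lineage abundance
#'
#' Runs the whole annotation pipeline: homologous-segment extraction, profile
#' alignment, likelihood placement, lineage assignment, rpm computation and
#' per-lineage aggregation.
#'
#' @param contigs Tibble with `id`, `seq`.
#' @param panel A [reference_panel()].
#' @param counts Tibble with `contig`, `sample`, `count`, `total_alignable`.
#' @param min_len Minimum homologous-segment length (default 50 bp).
#' @param lwr_threshold Assignment confidence threshold (default 0.8).
#' @return List with `assignments` (tibble `contig`, `sample`, `lineage`,
#'   `rpm`, one row per contig x sample; contigs without a usable segment or
#'   confident placement are `"unassigned"`) and `expression`
#'   (an `expression_table`).
#' @export
annotate_contigs <- function(contigs, panel, counts, min_len = 50,
                             lwr_threshold = 0.8) {
  lineage_of <- vapply(contigs$id, function(id) {
    seq <- contigs$seq[contigs$id == id]
    hit <- find_homologous_segment(seq, panel, min_len = min_len)
    if (is.null(hit)) return("unassigned")
    aug <- tryCatch(
      profile_align_query(hit$segment, panel$ref_alignment, query_id = "query"),
      error = function(e) NULL)
    if (is.null(aug)) return("unassigned")
    pl <- place_query(aug, panel)
    assign_lineage(pl, panel, lwr_threshold)
  }, character(1))
  rpm_tbl <- dplyr::bind_rows(lapply(split(counts, counts$sample), function(d) {
    r <- compute_rpm(stats::setNames(d$count, d$contig),
                     d$total_alignable[1])
    r$sample <- d$sample[1]
    r
  }))
  assignments <- dplyr::mutate(
    rpm_tbl, lineage = unname(lineage_of[.data$contig]))
  assignments <- assignments[, c("contig", "sample", "lineage", "rpm")]
  expression <- aggregate_lineage_abundance(
    assignments, lineages = names(panel$ref_tree$clades))
  list(assignments = assignments, expression = expression)
}
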