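# Forward simulators: every input the analysis pipeline consumes can be
# generated here, so the whole pipeline is testable end to end without any
# sequence downloads. All generators are pure functions of (arguments, seed).

#' Simulate a random binary tree
#'
#' Random topology with branch lengths drawn uniformly from a range chosen to
#' resemble within-gene-family divergences (expected substitutions per site).
#'
#' @param n Number of tips (>= 2).
#' @param seed Integer seed.
#' @param branch_range Min/max branch length (default 0.02-0.3).
#' @return A [labeled_tree()] with tips `t1..tn`.
#' @export
simulate_tree <- function(n, seed = 1, branch_range = c(0.02, 0.3)) {
  if (n < 2) stop("need at least 2 taxa")
  .with_seed(seed, {
    phy <- ape::rtree(n, rooted = TRUE, br = NULL)
    phy$tip.label <- paste0("t", seq_len(n))
    phy$edge.length <- stats::runif(nrow(phy$edge), branch_range[1],
                                    branch_range[2])
    labeled_tree(phy)
  })
}

# Sample child states along one edge: states are integers 1..k, P a k x k
# stochastic matrix.
.evolve_states <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    sel <- states == s
    out[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a codon alignment under a site-class mixture
#'
#' Forward simulation of the GY94-family models used for fitting: each site
#' draws a class from the mixture; root codons come from the stationary
#' frequencies; evolution along each branch uses the class's omega —
#' foreground omega on foreground-flagged branches, background omega
#' elsewhere. Branch lengths are interpreted exactly as in
#' [pruning_log_likelihood()] (expected substitutions per codon under the
#' mixture, background scaling), so simulation and fitting close the loop.
#'
#' @param tree A [labeled_tree()] (foreground flags used by branch-site
#'   classes).
#' @param mixture A [site_class_mixture()].
#' @param params A [codon_model_params()] (kappa and pi; omegas come from the
#'   mixture).
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Integer seed.
#' @return A [codon_alignment()] with attribute `site_class` (character
#'   vector of true per-site classes).
#' @export
simulate_codon_alignment <- function(tree, mixture, params, n_sites,
                                     seed = 1) {
  stopifnot(inherits(tree, "labeled_tree"),
            inherits(mixture, "site_class_mixture"), n_sites >= 1)
  code <- genetic_code()
  cls <- mixture$classes
  if (any(cls$proportion < 0) || abs(sum(cls$proportion) - 1) > 1e-8)
    stop("invalid mixture proportions")
  pre <- .prep_tree(tree, tree$phy$tip.label)
  flux <- .codon_flux(params$kappa, params$pi, code)
  rho <- sum(cls$proportion * (flux["a"] + flux["b"] * cls$omega_background))
  decomp_cache <- list()
  decomp <- function(omega) {
    key <- format(omega, digits = 17)
    if (!is.null(decomp_cache[[key]])) return(decomp_cache[[key]])
    Q <- build_codon_rate_matrix(codon_model_params(params$kappa, omega,
                                                    params$pi),
                                 code, scale = FALSE)
    sd <- spectral_decomposition(Q, params$pi)
    decomp_cache[[key]] <<- sd
    sd
  }
  .with_seed(seed, {
    site_class <- sample(cls$class, n_sites, replace = TRUE,
                         prob = cls$proportion)
    states <- matrix(0L, pre$nnode, n_sites)
    states[pre$root, ] <- sample.int(61, n_sites, replace = TRUE,
                                     prob = params$pi)
    # preorder = reversed postorder edge list
    for (e in rev(seq_len(nrow(pre$edges)))) {
      parent <- pre$edges[e, 1]; child <- pre$edges[e, 2]
      t_eff <- pre$blen[e] / rho
      child_states <- integer(n_sites)
      for (c in seq_len(nrow(cls))) {
        sel <- site_class == cls$class[c]
        if (!any(sel)) next
        w <- if (pre$fg[e]) cls$omega_foreground[c] else cls$omega_background[c]
        sd <- decomp(w)
        P <- pmat_cube(sd$A, sd$B, sd$lambda, t_eff)[, , 1]
        P <- P / rowSums(P)
        child_states[sel] <- .evolve_states(states[parent, sel], P)
      }
      states[child, ] <- child_states
    }
    m <- matrix(code$sense_codons[states[seq_len(pre$ntip), ]],
                nrow = pre$ntip)
    rownames(m) <- pre$tip_label
    aln <- codon_alignment(m)
    attr(aln, "site_class") <- site_class
    aln
  })
}

#' Simulate a nucleotide alignment under GTR+Gamma
#'
#' @param tree A [labeled_tree()].
#' @param params A [gtr_gamma_params()]; each site draws one of the discrete
#'   Gamma rate categories.
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return A [nucleotide_alignment()].
#' @export
simulate_nucleotide_alignment <- function(tree, params, n_sites, seed = 1) {
  stopifnot(inherits(params, "gtr_gamma_params"), n_sites >= 1)
  pre <- .prep_tree(tree, tree$phy$tip.label)
  Q <- gtr_rate_matrix(params, scale = TRUE)
  pi <- params$base_freqs
  sd <- spectral_decomposition(Q, pi)
  rates <- discrete_gamma_rates(params$alpha, params$n_cat)
  .with_seed(seed, {
    site_rate <- rates[sample.int(length(rates), n_sites, replace = TRUE)]
    states <- matrix(0L, pre$nnode, n_sites)
    states[pre$root, ] <- sample.int(4, n_sites, replace = TRUE, prob = pi)
    for (e in rev(seq_len(nrow(pre$edges)))) {
      parent <- pre$edges[e, 1]; child <- pre$edges[e, 2]
      child_states <- integer(n_sites)
      for (r in unique(site_rate)) {
        sel <- site_rate == r
        P <- pmat_cube(sd$A, sd$B, sd$lambda, pre$blen[e] * r)[, , 1]
        P <- P / rowSums(P)
        child_states[sel] <- .evolve_states(states[parent, sel], P)
      }
      states[child, ] <- child_states
    }
    m <- matrix(c("A", "C", "G", "T")[states[seq_len(pre$ntip), ]],
                nrow = pre$ntip)
    rownames(m) <- pre$tip_label
    nucleotide_alignment(m)
  })
}

#' Reference panel: alignment, lineage-labeled tree, GTR parameters
#'
#' @param ref_alignment A [nucleotide_alignment()] whose taxa equal the tree
#'   tips.
#' @param ref_tree A [labeled_tree()] whose named clades are the gene
#'   lineages (each must be monophyletic).
#' @param gtr_params A [gtr_gamma_params()] for placement likelihoods.
#' @return Object of class `reference_panel`.
#' @export
reference_panel <- function(ref_alignment, ref_tree, gtr_params) {
  stopifnot(inherits(ref_alignment, "nucleotide_alignment"),
            inherits(ref_tree, "labeled_tree"),
            inherits(gtr_params, "gtr_gamma_params"))
  if (!setequal(ref_alignment$taxa, ref_tree$phy$tip.label))
    stop("alignment taxa must equal tree tips")
  if (!length(ref_tree$clades)) stop("reference tree has no lineage clades")
  for (nm in names(ref_tree$clades)) {
    if (!is_monophyletic_clade(ref_tree, nm))
      stop("lineage '", nm, "' is not monophyletic on the reference tree")
  }
  structure(list(ref_alignment = ref_alignment, ref_tree = ref_tree,
                 gtr_params = gtr_params),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference panel:", length(x$ref_alignment$taxa), "taxa,",
      x$ref_alignment$n_sites, "columns,",
      length(x$ref_tree$clades), "lineages\n")
  invisible(x)
}

#' Simulate a gene-family reference panel with nested lineage clades
#'
#' Builds a tree whose tips fall into monophyletic gene-lineage clades
#' (deep stems, shallow within-lineage divergence — the topology of a
#' multigene family shaped by ancient duplications), simulates the reference
#' alignment under GTR+Gamma, and labels the lineages on the tree.
#'
#' @param n_lineages Number of gene lineages (>= 2).
#' @param taxa_per_lineage Tips per lineage (default 4).
#' @param divergence List with `between` (lineage stem length, default 0.5)
#'   and `within` (max within-lineage branch length, default 0.08), expected
#'   substitutions per site; both must be > 0.
#' @param n_sites Alignment columns (default 1200).
#' @param gtr_params A [gtr_gamma_params()] (default: moderately uneven base
#'   frequencies, kappa-like exchangeabilities, alpha = 1).
#' @param seed Integer seed.
#' @return List with `panel` (a [reference_panel()]) and `truth` (tibble
#'   `taxon`, `lineage`).
#' @export
simulate_reference_panel <- function(n_lineages = 5, taxa_per_lineage = 4,
                                     divergence = list(between = 0.5,
                                                       within = 0.08),
                                     n_sites = 1200,
                                     gtr_params = gtr_gamma_params(
                                       exchangeabilities = c(1, 4, 1, 1, 4, 1),
                                       base_freqs = c(0.3, 0.2, 0.25, 0.25),
                                       alpha = 1),
                                     seed = 1) {
  if (n_lineages < 2) stop("need at least 2 lineages")
  if (divergence$between <= 0 || divergence$within <= 0)
    stop("divergence levels must be > 0")
  .with_seed(seed, {
    backbone <- ape::rtree(n_lineages, rooted = TRUE, br = NULL)
    backbone$tip.label <- paste0("L", seq_len(n_lineages))
    backbone$edge.length <- stats::runif(nrow(backbone$edge),
                                         divergence$between * 0.5,
                                         divergence$between)
    tree <- backbone
    for (i in seq_len(n_lineages)) {
      sub <- ape::rtree(taxa_per_lineage, rooted = TRUE, br = NULL)
      sub$tip.label <- paste0("L", i, "_t", seq_len(taxa_per_lineage))
      sub$edge.length <- stats::runif(nrow(sub$edge),
                                      divergence$within * 0.2,
                                      divergence$within)
      sub$root.edge <- 0
      where <- match(paste0("L", i), tree$tip.label)
      tree <- ape::bind.tree(tree, sub, where = where)
    }
    clades <- stats::setNames(
      lapply(seq_len(n_lineages), function(i)
        grep(paste0("^L", i, "_"), tree$tip.label, value = TRUE)),
      paste0("lineage_", seq_len(n_lineages)))
    ltree <- labeled_tree(tree, clades = clades)
    aln <- simulate_nucleotide_alignment(
      ltree, gtr_params, n_sites,
      seed = sample.int(.Machine$integer.max %/% 2, 1))
    truth <- tibble::tibble(
      taxon = aln$taxa,
      lineage = sub("^(L\\d+)_.*$", "lineage_\\1", aln$taxa))
    truth$lineage <- sub("lineage_L", "lineage_", truth$lineage)
    list(panel = reference_panel(aln, ltree, gtr_params), truth = truth)
  })
}

#' A realistic diel/drought expression design
#'
#' Default planted rpm design for [simulate_diel_experiment()]: eight samples
#' (two individuals per watering regime, sampled day and night), five gene
#' lineages. One lineage is a C4-like form with high daytime abundance, one a
#' CAM-like form with strong nocturnal induction under infrequent watering
#' (> 100-fold night/day contrast), and the rest sit at low, flat abundance —
#' the qualitative structure seen in diel transcriptome profiles of a
#' facultative CAM plant using C4 photosynthesis.
#'
#' @param lineages Character vector of 5 lineage names the design rows map to.
#' @return Tibble with columns `lineage`, `sample`, `individual`,
#'   `condition`, `time`, `rpm`.
#' @export
example_diel_design <- function(lineages = paste0("lineage_", 1:5)) {
  stopifnot(length(lineages) == 5)
  samples <- tibble::tibble(
    sample = paste0("s", 1:8),
    individual = c(1, 2, 1, 2, 3, 4, 3, 4),
    condition = rep(c("watered_frequently", "watered_occasionally"), each = 4),
    time = rep(rep(c("day", "night"), each = 2), 2))
  rpm <- rbind(
    c(13, 14, 6, 1, 5, 30, 7, 17),              # low, flat
    c(44, 41, 40, 29, 14, 10, 5, 14),           # low, flat
    c(131, 139, 157, 192, 167, 196, 185, 173),  # moderate, flat
    c(3, 0, 820, 1180, 277, 338, 7602, 6823),   # CAM-like: night-induced under drought
    c(9916, 4697, 6710, 6052, 7339, 1868, 1421, 869))  # C4-like: day-dominant
  dplyr::bind_rows(lapply(seq_along(lineages), function(i) {
    d <- samples
    d$lineage <- lineages[i]
    d$rpm <- rpm[i, ]
    d
  }))[, c("lineage", "sample", "individual", "condition", "time", "rpm")]
}

#' Simulate a diel/drought transcriptome experiment
#'
#' Generates transcript contigs from the panel's lineage sequences (uniform
#' start, clamped-normal fragment length, point mutations, random strand) and
#' per-sample read counts drawn multinomially so that expected rpm equals the
#' planted design (fixed library of alignable reads; the remainder of each
#' library is an unassigned bucket).
#'
#' @param panel A [reference_panel()] whose lineage names cover the design.
#' @param design Tibble with columns `lineage`, `sample`, `rpm` (plus any
#'   metadata columns, carried through); see [example_diel_design()].
#' @param contigs_per_lineage Contigs generated per lineage (default 3).
#' @param library_size Alignable reads per sample (default 1e6, so rpm and
#'   expected counts coincide).
#' @param frag List: `mean`, `sd`, `min` fragment length in bp.
#' @param mut_rate Per-base contig mutation rate (default 0.02).
#' @param seed Integer seed.
#' @return List with `contigs` (tibble `id`, `seq`), `counts` (tibble
#'   `contig`, `sample`, `count`, `total_alignable`), and `truth` (list:
#'   `contig_lineage` tibble and the planted `design`).
#' @export
simulate_diel_experiment <- function(panel, design = example_diel_design(
                                       names(panel$ref_tree$clades)),
                                     contigs_per_lineage = 3,
                                     library_size = 1e6,
                                     frag = list(mean = 500, sd = 150, min = 80),
                                     mut_rate = 0.02, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  if (any(design$rpm < 0)) stop("planted rpm must be >= 0")
  per_sample <- tapply(design$rpm, design$sample, sum)
  if (any(per_sample > 1e6 + 1e-9))
    stop("per-sample design rpm exceeds 1e6")
  if (any(per_sample == 0)) stop("all-zero design column (sample)")
  lineages <- unique(design$lineage)
  miss <- setdiff(lineages, names(panel$ref_tree$clades))
  if (length(miss)) stop("design lineages absent from panel: ",
                         paste(miss, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    contig_rows <- list()
    for (ln in lineages) {
      members <- panel$ref_tree$clades[[ln]]
      for (j in seq_len(contigs_per_lineage)) {
        src <- sample(members, 1)
        full <- paste(panel$ref_alignment$states[src, ], collapse = "")
        full <- gsub("-", "", full)
        len <- max(frag$min, min(nchar(full),
                                 round(stats::rnorm(1, frag$mean, frag$sd))))
        start <- sample.int(max(1, nchar(full) - len + 1), 1)
        s <- strsplit(substr(full, start, start + len - 1), "")[[1]]
        nmut <- stats::rbinom(1, length(s), mut_rate)
        if (nmut > 0) {
          pos <- sample.int(length(s), nmut)
          s[pos] <- vapply(s[pos], function(b)
            sample(setdiff(bases, b), 1), character(1))
        }
        seq <- paste(s, collapse = "")
        if (stats::runif(1) < 0.25) seq <- .revcomp(seq)
        contig_rows[[length(contig_rows) + 1]] <-
          tibble::tibble(id = sprintf("%s_c%d", ln, j), seq = seq,
                         lineage = ln)
      }
    }
    contigs <- dplyr::bind_rows(contig_rows)
    counts <- dplyr::bind_rows(lapply(unique(design$sample), function(sm) {
      d <- design[design$sample == sm, ]
      rpm_by_lineage <- stats::setNames(d$rpm, d$lineage)
      per_contig <- unlist(lapply(lineages, function(ln) {
        ids <- contigs$id[contigs$lineage == ln]
        rep(rpm_by_lineage[[ln]] / length(ids), length(ids))
      }))
      names(per_contig) <- contigs$id
      p_other <- max(0, 1 - sum(per_contig) / 1e6)
      draws <- stats::rmultinom(1, library_size,
                                c(per_contig / 1e6, other = p_other))[, 1]
      tibble::tibble(contig = contigs$id, sample = sm,
                     count = as.numeric(draws[contigs$id]),
                     total_alignable = library_size)
    }))
    list(contigs = contigs[, c("id", "seq")],
         counts = counts,
         truth = list(contig_lineage = contigs[, c("id", "lineage")],
                      design = design))
  })
}

.revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  x <- comp[strsplit(toupper(seq), "")[[1]]]
  x[is.na(x)] <- "N"
  paste(rev(x), collapse = "")
}
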