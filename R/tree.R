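#' Labeled phylogeny with foreground branches and lineage clades
#'
#' Wraps an `ape::phylo` tree with the two annotations branch-site analyses
#' need: per-branch foreground flags (the branches hypothesized a priori to
#' have experienced adaptive evolution) and named clades (gene lineages).
#' Branches are identified by their child node: a tip's branch carries the tip
#' label, an internal branch the node label if present, else `"node<k>"`.
#'
#' @param phy An `ape::phylo` tree with unique tip labels and branch lengths.
#' @param foreground Optional: character vector of branch ids, or logical
#'   vector along `phy$edge` rows, marking foreground branches.
#' @param clades Optional named list mapping clade (gene-lineage) names to
#'   character vectors of tip labels.
#' @return An object of class `labeled_tree`: list with `phy`, `branch_id`
#'   (character per edge row), `foreground` (logical per edge row), `clades`.
#' @export
labeled_tree <- function(phy, foreground = NULL, clades = list()) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  bid <- .branch_ids(phy)
  fg <- rep(FALSE, nrow(phy$edge))
  if (is.logical(foreground)) {
    stopifnot(length(foreground) == nrow(phy$edge))
    fg <- foreground
  } else if (is.character(foreground) && length(foreground)) {
    miss <- setdiff(foreground, bid)
    if (length(miss)) stop("unknown branch id(s): ", paste(miss, collapse = ", "))
    fg <- bid %in% foreground
  }
  if (length(clades)) {
    bad <- names(clades)[!vapply(clades, function(l)
      all(l %in% phy$tip.label), logical(1))]
    if (length(bad))
      stop("clade(s) with tips absent from the tree: ", paste(bad, collapse = ", "))
  }
  structure(list(phy = phy, branch_id = bid, foreground = fg,
                 clades = as.list(clades)),
            class = "labeled_tree")
}

.branch_ids <- function(phy) {
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  ids <- character(length(child))
  tipsel <- child <= ntip
  ids[tipsel] <- phy$tip.label[child[tipsel]]
  nl <- phy$node.label
  ids[!tipsel] <- vapply(child[!tipsel], function(k) {
    lab <- if (!is.null(nl)) nl[k - ntip] else ""
    if (is.na(lab) || !nzchar(lab)) paste0("node", k) else lab
  }, character(1))
  ids
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("labeled tree:", length(x$phy$tip.label), "tips,",
      nrow(x$phy$edge), "branches,", sum(x$foreground), "foreground,",
      length(x$clades), "named clade(s)\n")
  invisible(x)
}

#' Branch ids of a labeled tree
#' @param tree A [labeled_tree()].
#' @return Character vector along the tree's edge rows.
#' @export
branch_ids <- function(tree) tree$branch_id

#' Edges belonging to a named clade
#'
#' @param tree A [labeled_tree()].
#' @param name Clade name.
#' @param include_stem Include the branch subtending the clade (default TRUE;
#'   set FALSE to ask for branches strictly nested within the clade).
#' @return Integer vector of edge-row indices.
#' @export
clade_edges <- function(tree, name, include_stem = TRUE) {
  if (!name %in% names(tree$clades)) stop("unknown clade: ", name)
  phy <- tree$phy
  tips <- match(tree$clades[[name]], phy$tip.label)
  if (length(tips) == 1) {
    mrca_node <- tips
  } else {
    mrca_node <- ape::getMRCA(phy, tips)
  }
  desc <- .descendant_nodes(phy, mrca_node)
  inside <- which(phy$edge[, 1] %in% c(mrca_node, desc))
  if (include_stem) {
    stem <- which(phy$edge[, 2] == mrca_node)
    inside <- sort(unique(c(inside, stem)))
  }
  inside
}

.descendant_nodes <- function(phy, node) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    n <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- phy$edge[phy$edge[, 1] == n, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(phy$tip.label)])
  }
  out
}

#' Is a named clade monophyletic?
#' @param tree A [labeled_tree()].
#' @param name Clade name.
#' @return Logical.
#' @export
is_monophyletic_clade <- function(tree, name) {
  if (!name %in% names(tree$clades)) stop("unknown clade: ", name)
  tips <- tree$clades[[name]]
  if (length(tips) <= 1) return(TRUE)
  ape::is.monophyletic(tree$phy, tips)
}

#' Resolve a foreground hypothesis to edge flags
#'
#' A hypothesis names foreground branches directly (by branch id) and/or by
#' clade: naming a clade marks its stem branch and every branch nested within
#' it (the "entire gene lineage" reading).
#'
#' @param tree A [labeled_tree()].
#' @param branches Character vector of branch ids (may be empty).
#' @param clades Character vector of clade names (may be empty).
#' @return Logical vector along the tree's edge rows.
#' @export
foreground_flags <- function(tree, branches = character(), clades = character()) {
  if (!length(branches) && !length(clades))
    stop("a foreground hypothesis must name at least one branch or clade")
  fg <- rep(FALSE, nrow(tree$phy$edge))
  if (length(branches)) {
    miss <- setdiff(branches, tree$branch_id)
    if (length(miss)) stop("unknown branch id(s): ", paste(miss, collapse = ", "))
    fg[tree$branch_id %in% branches] <- TRUE
  }
  for (cl in clades) fg[clade_edges(tree, cl, include_stem = TRUE)] <- TRUE
  fg
}

#' Read a labeled tree from Newick
#'
#' Foreground branches are marked codeml-style with a `#1` suffix on the tip
#' or internal-node label; any remaining nonempty internal label names the
#' clade of tips it subtends.
#'
#' @param text Newick string, or `file` a path.
#' @param file Optional file path (used if `text` is missing).
#' @return A [labeled_tree()].
#' @export
read_labeled_tree <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  ntip <- length(phy$tip.label)
  fg_nodes <- integer(0)
  strip <- function(labs, offset) {
    hit <- grepl("\\s*#\\s*1$", labs)
    fg_nodes <<- c(fg_nodes, which(hit) + offset)
    sub("\\s*#\\s*1$", "", labs)
  }
  phy$tip.label <- strip(phy$tip.label, 0L)
  if (!is.null(phy$node.label)) phy$node.label <- strip(phy$node.label, ntip)
  fg <- phy$edge[, 2] %in% fg_nodes
  clades <- list()
  if (!is.null(phy$node.label)) {
    for (k in which(nzchar(phy$node.label) & !is.na(phy$node.label))) {
      node <- ntip + k
      desc <- .descendant_nodes(phy, node)
      clades[[phy$node.label[k]]] <- phy$tip.label[desc[desc <= ntip]]
    }
  }
  labeled_tree(phy, foreground = fg, clades = clades)
}

#' Write a labeled tree to Newick
#'
#' Foreground branches are written with `#1` suffixes on their child labels.
#'
#' @param tree A [labeled_tree()].
#' @param file Optional path; if `NULL`, the Newick string is returned.
#' @export
write_labeled_tree <- function(tree, file = NULL) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  fg_children <- phy$edge[tree$foreground, 2]
  if (length(fg_children)) {
    tips <- fg_children[fg_children <= ntip]
    phy$tip.label[tips] <- paste0(phy$tip.label[tips], "#1")
    nodes <- fg_children[fg_children > ntip]
    if (length(nodes)) {
      if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
      phy$node.label[nodes - ntip] <- paste0(phy$node.label[nodes - ntip], "#1")
    }
  }
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}
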