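#' Parse and validate a dated phylogeny
#'
#' Reads a Newick string into an [ape::phylo] object and checks the
#' invariants every downstream analysis in this package relies on: the tree
#' is singly rooted and strictly binary, every non-root edge carries a
#' positive branch length (in Ma), tip labels are unique, and the tree is
#' ultrametric to within a relative tolerance (root-to-tip path sums are
#' allowed to disagree by at most `tol * root age`, absorbing the rounding
#' noise typical of maximum clade credibility trees).
#'
#' Internal node labels (e.g. posterior support values) are preserved
#' verbatim in `$node.label`.
#'
#' @param text a Newick string (or a file path when `file = TRUE`).
#' @param tol relative ultrametricity tolerance (default `1e-6`).
#' @param file logical; treat `text` as a path.
#' @return a validated `phylo` object.
#' @export
parse_newick <- function(text, tol = 1e-6, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree found")
  validate_timetree(phy, tol = tol)
}

#' Validate a phylo object as a dated binary tree
#'
#' @param phy a `phylo` object.
#' @param tol relative ultrametricity tolerance.
#' @return `phy`, invisibly reordered in cladewise order.
#' @export
validate_timetree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label: ",
         phy$tip.label[duplicated(phy$tip.label)][1L])
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge))
    stop("missing branch lengths")
  if (!ape::is.binary(phy)) {
    deg <- tabulate(phy$edge[, 1L])
    bad <- which(deg > 2L)[1L]
    stop("non-binary internal node (node ", bad, " has ", deg[bad],
         " children); polytomies are rejected, resolve them upstream")
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (any(phy$edge.length <= 0)) {
    i <- which(phy$edge.length <= 0)[1L]
    stop("non-positive branch length on edge to node ", phy$edge[i, 2L],
         " (", phy$edge.length[i], "); add an epsilon explicitly if needed")
  }
  depths <- ape::node.depth.edgelength(phy)
  root_age <- max(depths[seq_len(n_tip)])
  dev <- max(abs(depths[seq_len(n_tip)] - root_age))
  if (dev > tol * root_age)
    stop("tree not ultrametric: max root-to-tip deviation ",
         format(dev), " exceeds tolerance ", format(tol * root_age))
  phy
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured backwards from the present: all tips are clamped to
#' age 0 and `age(parent) = age(child) + branch_length(child)`.
#'
#' @param phy a validated `phylo`.
#' @param tol relative ultrametricity tolerance (revalidated).
#' @return numeric vector of ages (Ma) indexed by ape node number
#'   (`1..Ntip` tips, then internal nodes).
#' @export
node_ages <- function(phy, tol = 1e-6) {
  validate_timetree(phy, tol = tol)
  n_tip <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  root_age <- max(depths[seq_len(n_tip)])
  ages <- root_age - depths
  ages[seq_len(n_tip)] <- 0
  ages
}

#' Age of the root (tree depth, Ma)
#' @param phy a validated `phylo`.
#' @export
root_age <- function(phy) max(node_ages(phy))

#' Build a stratification from epoch boundary ages
#'
#' Boundaries are ages (Ma) at which the dispersal regime changes, ordered
#' root side to present (strictly decreasing, all positive). An empty
#' vector means a single stratum. Stratum 1 is the oldest.
#'
#' @param boundary_ages numeric vector of boundary ages (Ma).
#' @return an object of class `stratification`.
#' @export
stratification <- function(boundary_ages = numeric(0)) {
  boundary_ages <- as.numeric(boundary_ages)
  if (length(boundary_ages)) {
    if (any(!is.finite(boundary_ages)) || any(boundary_ages <= 0))
      stop("boundary ages must be finite and > 0")
    if (any(diff(boundary_ages) >= 0))
      stop("boundary ages must be strictly decreasing (oldest first)")
  }
  structure(list(boundaries = boundary_ages,
                 n_strata = length(boundary_ages) + 1L),
            class = "stratification")
}

#' Slice a branch into per-stratum segments
#'
#' Splits the time interval `[child_age, parent_age]` at the stratification
#' boundaries. Segments are returned oldest first; their durations are
#' non-negative and sum exactly to the branch length.
#'
#' @param parent_age,child_age ages (Ma), `parent_age > child_age >= 0`.
#' @param strat a [stratification()].
#' @return data.frame with columns `stratum` (1-based, 1 = oldest) and
#'   `duration` (Ma).
#' @export
slice_branch_by_strata <- function(parent_age, child_age, strat) {
  if (!inherits(strat, "stratification")) strat <- stratification(strat)
  if (!(parent_age > child_age) || child_age < 0)
    stop("need parent_age > child_age >= 0")
  # cut points within the open interval, oldest to youngest
  b <- strat$boundaries
  cuts <- b[b < parent_age & b > child_age]
  edges <- c(parent_age, cuts, child_age)
  durations <- -diff(edges)
  starts <- edges[-length(edges)]
  # stratum index of a segment = 1 + number of boundaries >= its start age
  stratum <- vapply(starts, function(a) sum(b >= a), 0L) + 1L
  if (any(durations < 0)) stop("internal error: negative segment duration")
  # exact sum: adjust the last segment for accumulated rounding
  durations[length(durations)] <- (parent_age - child_age) -
    sum(durations[-length(durations)])
  data.frame(stratum = stratum, duration = durations)
}

#' Serialize a tree to Newick with 10 significant digits
#' @param phy a `phylo`.
#' @param path optional file path; if `NULL` the string is returned.
#' @export
write_newick <- function(phy, path = NULL) {
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Rescale a tree so its root age equals a target
#' @param phy a validated `phylo`.
#' @param target_age desired root age (Ma).
#' @export
rescale_tree_age <- function(phy, target_age) {
  stopifnot(target_age > 0)
  phy$edge.length <- phy$edge.length * (target_age / root_age(phy))
  phy
}
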