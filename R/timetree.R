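#' Read a time-calibrated species tree
#'
#' The tree supplies the divergence time (MRCA age, in MY) for every
#' species pair, the quantity TimeTree reports. Two Newick dialects are
#' supported: ultrametric branch lengths (default), where node ages fall
#' out of leaf-to-node depths, or internal-node labels carrying ages
#' directly (`dialect = "labels"`).
#'
#' @param path Newick file path (or a Newick string).
#' @param dialect `"branch_lengths"` (ultrametric) or `"labels"`.
#' @param tol Relative ultrametricity tolerance, as a fraction of root age.
#' @return An object of class `time_tree`: list with `phy` (`ape::phylo`)
#'   and `ages` (numeric vector of length `Nnode`, MYA, indexed by internal
#'   node number minus the tip count).
#' @export
read_timetree <- function(path, dialect = c("branch_lengths", "labels"),
                          tol = 1e-6) {
  dialect <- match.arg(dialect)
  phy <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(phy)) stop(sprintf("cannot parse Newick: %s", path), call. = FALSE)
  time_tree(phy, dialect = dialect, tol = tol)
}

#' Build a time tree from an `ape::phylo` object
#'
#' @inheritParams read_timetree
#' @param phy A rooted `ape::phylo`.
#' @return A `time_tree` object.
#' @export
time_tree <- function(phy, dialect = c("branch_lengths", "labels"), tol = 1e-6) {
  dialect <- match.arg(dialect)
  ntip <- length(phy$tip.label)
  if (dialect == "branch_lengths") {
    if (is.null(phy$edge.length))
      stop("time-tree error: no branch lengths in branch_lengths dialect", call. = FALSE)
    depth <- ape::node.depth.edgelength(phy)       # root-to-node path length
    root_age <- max(depth)
    tip_depth <- depth[seq_len(ntip)]
    if (any(abs(tip_depth - root_age) > tol * root_age))
      stop(sprintf(
        "time-tree error: tree is not ultrametric (max tip-depth deviation %.3g vs tolerance %.3g)",
        max(abs(tip_depth - root_age)), tol * root_age
      ), call. = FALSE)
    ages <- root_age - depth[(ntip + 1):(ntip + phy$Nnode)]
  } else {
    labs <- phy$node.label
    if (is.null(labs) || any(labs == "" | is.na(labs)))
      stop("time-tree parse error: unlabeled internal node in label dialect", call. = FALSE)
    ages <- suppressWarnings(as.numeric(labs))
    if (any(is.na(ages)))
      stop("time-tree parse error: non-numeric internal node label", call. = FALSE)
  }
  # every parent must be at least as old as its children
  node_age <- c(rep(0, ntip), ages)
  parent_age <- node_age[phy$edge[, 1]]
  child_age <- node_age[phy$edge[, 2]]
  if (any(parent_age - child_age < -tol * max(node_age)))
    stop("time-tree error: a node is younger than its child", call. = FALSE)
  structure(list(phy = phy, ages = ages), class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree: %d taxa, root age %.6g MYA>\n",
              length(x$phy$tip.label), root_age(x)))
  invisible(x)
}

#' Root age of a time tree (MYA)
#' @param tree A `time_tree`.
#' @return Numeric age of the root node.
#' @export
root_age <- function(tree) {
  ntip <- length(tree$phy$tip.label)
  root <- ntip + 1L
  node_age(tree, root)
}

#' Age of a node (MYA); leaves have age 0
#' @param tree A `time_tree`.
#' @param node Node number in `ape` convention.
#' @return Numeric age.
#' @export
node_age <- function(tree, node) {
  ntip <- length(tree$phy$tip.label)
  out <- numeric(length(node))
  internal <- node > ntip
  out[internal] <- tree$ages[node[internal] - ntip]
  dim(out) <- dim(node)
  out
}

#' Divergence time between two taxa
#'
#' The age of the most recent common ancestor, in MY — the standard
#' TimeTree pairwise quantity. `divergence_time(tree, a, a)` is 0.
#'
#' @param tree A `time_tree`.
#' @param a,b Taxon names.
#' @return Numeric divergence time (MYA).
#' @export
divergence_time <- function(tree, a, b) {
  tips <- tree$phy$tip.label
  missing <- setdiff(c(a, b), tips)
  if (length(missing) > 0)
    stop(sprintf("lookup error: taxa not in time tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (a == b) return(0)
  mrca <- ape::getMRCA(tree$phy, c(a, b))
  node_age(tree, mrca)
}

#' All pairwise divergence times
#'
#' @param tree A `time_tree`.
#' @param taxa Taxa to include (default: all tips).
#' @return Symmetric numeric matrix of MRCA ages (MYA).
#' @export
divergence_time_matrix <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- tree$phy$tip.label
  missing <- setdiff(taxa, tree$phy$tip.label)
  if (length(missing) > 0)
    stop(sprintf("lookup error: taxa not in time tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  # MRCA age = half the cophenetic (path) distance on an ultrametric tree,
  # but label-dialect trees may lack usable branch lengths, so go through
  # the MRCA node table instead.
  phy <- tree$phy
  mrcas <- ape::mrca(phy)
  idx <- match(taxa, phy$tip.label)
  m <- matrix(node_age(tree, mrcas[idx, idx, drop = FALSE]),
              nrow = length(taxa), dimnames = list(taxa, taxa))
  diag(m) <- 0
  m
}
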