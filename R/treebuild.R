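# Distance-tree construction: Saitou-Nei neighbor-joining with explicit,
# deterministic tie-breaking, plus bootstrap bipartition support computed
# by column resampling of the concatenated alignment.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion `Q_ij = (n-2) d_ij - r_i - r_j`. Ties broken by the
#' smallest `(i, j)` index pair in the current taxon ordering, so output
#' is deterministic given input order. Negative branch lengths are clamped
#' to 0 with the deficit transferred to the sister branch.
#'
#' @param dm A `dist_matrix` (or plain symmetric numeric matrix with
#'   dimnames) with no missing entries and >= 3 taxa.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$values else as.matrix(dm)
  if (any(is.na(d)))
    stop("incomplete-matrix error: NJ requires a complete distance matrix",
         call. = FALSE)
  n <- nrow(d)
  if (n < 3) stop("nj_tree: need >= 3 taxa", call. = FALSE)
  # node strings accumulate newick subtrees as taxa are joined
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels

  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # smallest (i, j), i < j, among minimizers
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_node <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], vi, nodes[j], vj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                   c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    rownames(d_new) <- colnames(d_new) <- NULL
    d <- d_new
  }

  # final three nodes joined at an unresolved (trifurcating) root
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    nodes[1], va, nodes[2], vb, nodes[3], vc)
  ape::read.tree(text = newick)
}

# Canonical key for one internal bipartition: the sorted leaf set on the
# side NOT containing the reference taxon (lexicographically smallest leaf
# overall), collapsed to a single string.
canonical_split <- function(members, all_taxa) {
  ref <- min(all_taxa)
  side <- sort(members)
  if (ref %in% side) side <- sort(setdiff(all_taxa, side))
  paste(side, collapse = ";")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Every internal edge splits the leaves in two; trivial splits (single
#' leaf vs rest) are excluded. Keys are canonical so that the same split
#' compares equal across trees over the same leaf set.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of canonical split keys, named by the internal
#'   node (child end of the edge) that induces each split.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  all_taxa <- tree$tip.label
  parts <- ape::prop.part(tree)   # leaf sets descending from each internal node
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    members <- all_taxa[parts[[k]]]
    size <- length(members)
    if (size <= 1 || size >= ntip - 1) next   # trivial or whole-tree split
    keys <- c(keys, canonical_split(members, all_taxa))
    nodes <- c(nodes, ntip + k)
  }
  stats::setNames(keys, nodes)
}

#' Compare the bipartition sets of two trees
#'
#' Robinson-Foulds-style counts over the same leaf set.
#'
#' @param treeA,treeB `ape::phylo` trees on identical leaf sets.
#' @return List with `shared`, `unique_A`, `unique_B`, `rf_distance`.
#' @export
compare_bipartitions <- function(treeA, treeB) {
  if (!setequal(treeA$tip.label, treeB$tip.label))
    stop("compare_bipartitions: leaf sets differ", call. = FALSE)
  a <- unique(unname(tree_bipartitions(treeA)))
  b <- unique(unname(tree_bipartitions(treeB)))
  shared <- length(intersect(a, b))
  list(shared = shared,
       unique_A = length(a) - shared,
       unique_B = length(b) - shared,
       rf_distance = (length(a) - shared) + (length(b) - shared))
}

# Resample alignment columns with replacement; optionally stratified
# within locus partitions so each locus keeps its column count.
resample_columns <- function(m, partitions = NULL, stratified = FALSE) {
  L <- ncol(m)
  if (stratified && !is.null(partitions)) {
    idx <- unlist(lapply(seq_len(nrow(partitions)), function(k) {
      cols <- (partitions$start[k] + 1):partitions$end[k]
      sample(cols, length(cols), replace = TRUE)
    }))
  } else {
    idx <- sample.int(L, L, replace = TRUE)
  }
  m[, idx, drop = FALSE]
}

#' Neighbor-joining tree with bootstrap bipartition support
#'
#' Builds the point-estimate NJ tree from the full alignment, then `B`
#' bootstrap replicates each resampling alignment columns with replacement
#' (same total length), recomputing the distance matrix and NJ tree.
#' Support of each internal bipartition of the point tree is the
#' percentage of replicates containing it, stored in `tree$node.label`.
#' Replicate `r` reseeds its own stream from (`seed`, `r`) so any single
#' replicate is individually reproducible.
#'
#' @param aln A `concat_alignment` (or `locus_alignment`).
#' @param model,deletion Passed to [distance_matrix].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (required: bootstrap is Monte-Carlo).
#' @param stratified Resample within locus partitions instead of across
#'   the whole supermatrix.
#' @param gamma_shape Shape for `model = "gamma"`.
#' @return List with `tree` (point NJ `phylo`, supports as node labels),
#'   `support` (named numeric vector, canonical split -> percentage),
#'   `B_used`, `B_dropped`.
#' @export
bootstrap_support <- function(aln, model = "p_distance", deletion = "pairwise",
                              B = 500, seed, stratified = FALSE,
                              gamma_shape = 1) {
  if (missing(seed)) stop("bootstrap_support: seed is required", call. = FALSE)
  if (B < 1) stop("bootstrap_support: B must be >= 1", call. = FALSE)
  partitions <- if (inherits(aln, "concat_alignment")) aln$partitions else NULL
  point_dm <- distance_matrix(aln, model = model, deletion = deletion,
                              gamma_shape = gamma_shape)
  if (any(is.na(point_dm$values)))
    stop("bootstrap_support: point-estimate matrix has missing pairs", call. = FALSE)
  point_tree <- nj_tree(point_dm)
  point_splits <- tree_bipartitions(point_tree)
  counts <- stats::setNames(numeric(length(point_splits)), unname(point_splits))

  m <- alignment_matrix(aln)
  dropped <- 0L
  used <- 0L
  for (r in seq_len(B)) {
    set.seed((seed + r) %% .Machine$integer.max)
    mb <- resample_columns(m, partitions, stratified)
    dmb <- tryCatch(
      suppressWarnings(matrix_distance_from_chars(mb, model, deletion, gamma_shape)),
      error = function(e) NULL
    )
    if (is.null(dmb) || any(is.na(dmb))) { dropped <- dropped + 1L; next }
    tb <- nj_tree(dmb)
    used <- used + 1L
    splits_b <- unique(unname(tree_bipartitions(tb)))
    hit <- names(counts) %in% splits_b
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > 0.1 * B)
    stop(sprintf("bootstrap-failure error: %d of %d replicates dropped", dropped, B),
         call. = FALSE)
  support <- if (used > 0) 100 * counts / used else counts * NA_real_
  ntip <- length(point_tree$tip.label)
  labels <- rep("", point_tree$Nnode)
  node_ids <- as.integer(names(point_splits))
  labels[node_ids - ntip] <- sprintf("%g", round(support[unname(point_splits)], 1))
  point_tree$node.label <- labels
  list(tree = point_tree, support = support, B_used = used, B_dropped = dropped)
}

# Distance matrix straight from a residue character matrix (bootstrap
# inner loop; skips alignment-object overhead).
matrix_distance_from_chars <- function(m, model, deletion, gamma_shape = 1) {
  if (deletion == "complete") {
    keep <- apply(m, 2, function(col) all(residue_valid(col)))
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0) stop("no columns after complete deletion", call. = FALSE)
  }
  n <- nrow(m)
  valid <- residue_valid(m)
  dim(valid) <- dim(m)
  values <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      ns <- sum(ok)
      if (ns == 0) { values[i, j] <- values[j, i] <- NA_real_; next }
      p <- sum(m[i, ok] != m[j, ok]) / ns
      d <- switch(model,
        p_distance = p,
        poisson = if (p >= 1) NA_real_ else -log(1 - p),
        gamma = if (p >= 1) NA_real_ else gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1)
      )
      values[i, j] <- values[j, i] <- d
    }
  }
  values
}
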