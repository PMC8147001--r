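# Pairwise amino-acid distance estimation on aligned protein sequences.
# This replaces the usual distance-software call with an in-package
# implementation so that every estimator choice (model, deletion scheme)
# is explicit and testable.

# Columns comparable for a pair: both residues among the 20 standard
# amino acids. '-' (gap) and 'X' (unknown) are missing data, never
# mismatches.
residue_valid <- function(chars) chars %in% AA_LETTERS

#' Proportion of differing residues between two aligned sequences
#'
#' With `deletion = "pairwise"` only columns where both residues are
#' standard amino acids are compared; `"complete"` requires the caller to
#' have pre-masked columns containing any gap/unknown in any taxon (see
#' [mask_complete_deletion]) and then behaves identically.
#'
#' @param rowA,rowB Equal-length residue strings.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return List with `p` (proportion in \[0,1\]) and `n_sites`
#'   (comparable columns).
#' @export
p_distance <- function(rowA, rowB, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  a <- strsplit(toupper(rowA), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(rowB), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("p_distance: sequences have unequal lengths", call. = FALSE)
  ok <- residue_valid(a) & residue_valid(b)
  n_sites <- sum(ok)
  if (n_sites == 0)
    stop("incomparable-pair error: no shared comparable sites", call. = FALSE)
  list(p = sum(a[ok] != b[ok]) / n_sites, n_sites = as.integer(n_sites))
}

#' Poisson-corrected amino-acid distance
#'
#' Multiple-hit correction `d = -ln(1 - p)`; always `>= p`, with equality
#' only at `p = 0`.
#'
#' @param p Proportion of differences, `0 <= p < 1`.
#' @return Corrected distance.
#' @export
poisson_distance <- function(p) {
  if (any(p < 0)) stop("poisson_distance: p < 0", call. = FALSE)
  if (any(p >= 1))
    stop("saturation error: p >= 1, Poisson distance undefined", call. = FALSE)
  -log(1 - p)
}

#' Gamma-corrected amino-acid distance
#'
#' `d = a * ((1 - p)^(-1/a) - 1)` with gamma shape `a`; converges to the
#' Poisson correction as `a -> Inf`.
#'
#' @param p Proportion of differences, `0 <= p < 1`.
#' @param shape Gamma shape parameter `a > 0`.
#' @return Corrected distance.
#' @export
gamma_distance <- function(p, shape) {
  if (shape <= 0) stop("gamma_distance: shape must be > 0", call. = FALSE)
  if (any(p < 0)) stop("gamma_distance: p < 0", call. = FALSE)
  if (any(p >= 1))
    stop("saturation error: p >= 1, gamma distance undefined", call. = FALSE)
  shape * ((1 - p)^(-1 / shape) - 1)
}

#' Mask columns containing any gap or unknown residue
#'
#' Complete-deletion pre-processing: drops every column in which any taxon
#' has `-` or `X`.
#'
#' @param aln A `locus_alignment` or `concat_alignment`.
#' @return A residue character matrix (taxa x retained columns).
#' @export
mask_complete_deletion <- function(aln) {
  m <- alignment_matrix(aln)
  keep <- apply(m, 2, function(col) all(residue_valid(col)))
  m[, keep, drop = FALSE]
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all unordered pairs once (the matrix is symmetric by
#' construction with an exact zero diagonal). Pairs with no comparable
#' sites are recorded as `NA` with a warning — never silently zero.
#'
#' @param aln A `locus_alignment` or `concat_alignment`.
#' @param model `"p_distance"`, `"poisson"` or `"gamma"`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @param gamma_shape Shape for `model = "gamma"`.
#' @return An object of class `dist_matrix`: list with `taxa`, `values`
#'   (symmetric numeric matrix), `sites_used` (integer matrix of
#'   comparable sites per pair), `model`, `deletion`.
#' @export
distance_matrix <- function(aln, model = c("p_distance", "poisson", "gamma"),
                            deletion = c("pairwise", "complete"),
                            gamma_shape = 1) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- if (deletion == "complete") mask_complete_deletion(aln) else alignment_matrix(aln)
  if (nrow(m) < 2) stop("distance_matrix: need >= 2 taxa", call. = FALSE)
  if (ncol(m) == 0)
    stop("distance_matrix: no columns left after complete deletion", call. = FALSE)
  taxa <- rownames(m)
  n <- length(taxa)
  valid <- residue_valid(m)
  dim(valid) <- dim(m)
  values <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sites <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  diag(sites) <- as.integer(ncol(m))
  n_missing <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      ns <- sum(ok)
      if (ns == 0) {
        values[i, j] <- values[j, i] <- NA_real_
        sites[i, j] <- sites[j, i] <- 0L
        n_missing <- n_missing + 1L
        next
      }
      p <- sum(m[i, ok] != m[j, ok]) / ns
      d <- switch(model,
        p_distance = p,
        poisson = if (p >= 1) NA_real_ else -log(1 - p),
        gamma = if (p >= 1) NA_real_ else gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1)
      )
      if (is.na(d) && p >= 1) n_missing <- n_missing + 1L
      values[i, j] <- values[j, i] <- d
      sites[i, j] <- sites[j, i] <- as.integer(ns)
    }
  }
  if (n_missing > 0)
    warning(sprintf("distance_matrix: %d pair(s) missing (no comparable sites or saturated)",
                    n_missing), call. = FALSE)
  structure(
    list(taxa = taxa, values = values, sites_used = sites,
         model = if (model == "gamma") sprintf("gamma(%g)", gamma_shape) else model,
         deletion = deletion),
    class = "dist_matrix"
  )
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d taxa, model %s, %s deletion>\n",
              length(x$taxa), x$model, x$deletion))
  invisible(x)
}

#' Clip a distance matrix for display
#'
#' Entries above `cap` are set to `cap`. Display-only: statistics and tree
#' building always use the unclipped matrix.
#'
#' @param matrix A `dist_matrix` or plain numeric matrix.
#' @param cap Display ceiling (default 0.6).
#' @return A copy with clipped values.
#' @export
clip_for_display <- function(matrix, cap = 0.6) {
  if (cap <= 0) stop("clip_for_display: cap must be > 0", call. = FALSE)
  if (inherits(matrix, "dist_matrix")) {
    matrix$values <- pmin(matrix$values, cap)
    matrix
  } else {
    pmin(matrix, cap)
  }
}

#' Write a distance matrix as square TSV
#'
#' Taxa appear as both header row and first column.
#'
#' @param dm A `dist_matrix`.
#' @param path Output path.
#' @export
write_distance_tsv <- function(dm, path) {
  tab <- data.frame(taxon = dm$taxa, dm$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
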