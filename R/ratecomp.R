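# Divergence-time normalization of pairwise distances and clade-level
# rate comparison. The normalized distance D_raw / (T/100) — distance per
# 100 MY — is the rate proxy that separates "divergent because distant in
# time" from "divergent because fast-evolving".

#' Normalize a pairwise distance by divergence time
#'
#' Convention: 100 MYA = 1, i.e. `D_norm = D_raw / (T/100)`, so a pair
#' diverged exactly 100 MY ago keeps its raw distance.
#'
#' @param D_raw Raw pairwise distance(s).
#' @param T_mya Divergence time(s), MY; must be `> 0`.
#' @return Normalized distance (distance per 100 MY).
#' @export
normalize_distance <- function(D_raw, T_mya) {
  if (any(T_mya <= 0))
    stop("normalization error: divergence time must be > 0", call. = FALSE)
  D_raw / (T_mya / 100)
}

# Canonical unordered clade-pair label, e.g. "marsupials|rodents".
clade_pair_label <- function(cladeA, cladeB) {
  paste(pmin(cladeA, cladeB), pmax(cladeA, cladeB), sep = "|")
}

#' Per-pair table of raw and time-normalized distances
#'
#' One record per unordered taxon pair: raw distance, MRCA age, normalized
#' distance and the unordered clade-pair label. Pairs with a missing
#' distance are excluded with a message reporting the count.
#'
#' @param dm A `dist_matrix`.
#' @param tree A `time_tree` covering all matrix taxa.
#' @param clades Named character vector, taxon -> clade label.
#' @return Data frame with columns `taxonA`, `taxonB`, `cladeA`, `cladeB`,
#'   `clade_pair`, `D_raw`, `T_mya`, `D_norm`.
#' @export
build_pair_table <- function(dm, tree, clades) {
  taxa <- dm$taxa
  not_in_tree <- setdiff(taxa, tree$phy$tip.label)
  not_in_map <- setdiff(taxa, names(clades))
  if (length(not_in_tree) > 0 || length(not_in_map) > 0)
    stop(sprintf(
      "coverage error: missing from tree [%s]; missing from clade map [%s]",
      paste(not_in_tree, collapse = ", "), paste(not_in_map, collapse = ", ")
    ), call. = FALSE)
  tmat <- divergence_time_matrix(tree, taxa)
  idx <- which(upper.tri(dm$values), arr.ind = TRUE)
  tab <- data.frame(
    taxonA = taxa[idx[, 1]],
    taxonB = taxa[idx[, 2]],
    cladeA = unname(clades[taxa[idx[, 1]]]),
    cladeB = unname(clades[taxa[idx[, 2]]]),
    D_raw = dm$values[idx],
    T_mya = tmat[idx],
    stringsAsFactors = FALSE
  )
  tab$clade_pair <- clade_pair_label(tab$cladeA, tab$cladeB)
  n_missing <- sum(is.na(tab$D_raw))
  if (n_missing > 0) {
    message(sprintf("build_pair_table: excluded %d pair(s) with missing distances",
                    n_missing))
    tab <- tab[!is.na(tab$D_raw), , drop = FALSE]
  }
  tab$D_norm <- normalize_distance(tab$D_raw, tab$T_mya)
  rownames(tab) <- NULL
  tab[, c("taxonA", "taxonB", "cladeA", "cladeB", "clade_pair",
          "D_raw", "T_mya", "D_norm")]
}

#' Distribution of pairwise distances for one clade pair
#'
#' Selects all pairs with the given unordered clade-pair label
#' (`cladeA == cladeB` selects within-clade pairs) and summarizes them the
#' way violin plots are annotated: median with quartiles, plus mean and SD.
#'
#' @param table Pair table from [build_pair_table].
#' @param cladeA,cladeB Clade labels (order irrelevant).
#' @param which `"raw"` or `"normalized"`.
#' @return List with `values`, `mean`, `sd`, `median`, `q1`, `q3`, `n`.
#' @export
interclade_distribution <- function(table, cladeA, cladeB,
                                    which = c("raw", "normalized")) {
  which <- match.arg(which)
  label <- clade_pair_label(cladeA, cladeB)
  sel <- table[table$clade_pair == label, , drop = FALSE]
  if (nrow(sel) == 0)
    stop(sprintf("empty-group error: no pairs for clade pair '%s'", label),
         call. = FALSE)
  values <- if (which == "raw") sel$D_raw else sel$D_norm
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(values = values, mean = mean(values), sd = stats::sd(values),
       median = qs[2], q1 = qs[1], q3 = qs[3], n = length(values))
}

#' Summary table over all clade pairs present in a pair table
#'
#' @param table Pair table from [build_pair_table].
#' @param which `"raw"` or `"normalized"`.
#' @return Data frame with one row per clade pair: n, mean, sd, median, q1, q3.
#' @export
clade_summary <- function(table, which = c("raw", "normalized")) {
  which <- match.arg(which)
  labels <- sort(unique(table$clade_pair))
  do.call(rbind, lapply(labels, function(lab) {
    parts <- strsplit(lab, "|", fixed = TRUE)[[1]]
    d <- interclade_distribution(table, parts[1], parts[2], which)
    data.frame(clade_pair = lab, which = which, n = d$n, mean = d$mean,
               sd = d$sd, median = d$median, q1 = d$q1, q3 = d$q3,
               stringsAsFactors = FALSE)
  }))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' One-way ANOVA with Tukey HSD post hoc test
#'
#' Classical one-way ANOVA across the supplied groups followed by Tukey's
#' honestly-significant-difference test (Tukey–Kramer for unequal group
#' sizes). Significance stars follow * p<0.05, ** p<0.01, *** p<0.001.
#'
#' Caveat for distance data: pairwise distances sharing a taxon are not
#' independent observations, so p-values on pair tables are descriptive;
#' see [jackknife_anova] for a taxon-level sensitivity check.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return List with `F`, `df_between`, `df_within`, `p_value` and `tukey`
#'   (data frame: comparison, diff, p_adj, stars).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2)
    stop("anova_tukey: need >= 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("degrees-of-freedom error: every group needs >= 2 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    stars = significance_stars(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  rownames(tukey) <- NULL
  list(
    F = s[["F value"]][1],
    df_between = s[["Df"]][1],
    df_within = s[["Df"]][2],
    p_value = s[["Pr(>F)"]][1],
    tukey = tukey
  )
}

#' Taxon-level jackknife sensitivity for the clade ANOVA
#'
#' Pairwise distances are non-independent; this drops one taxon at a time,
#' rebuilds the interclade groups and re-runs the ANOVA, reporting the
#' spread of the resulting p-values.
#'
#' @param table Pair table from [build_pair_table].
#' @param group_labels Clade-pair labels defining the ANOVA groups.
#' @param which `"raw"` or `"normalized"`.
#' @return Data frame: dropped taxon, F, p_value.
#' @export
jackknife_anova <- function(table, group_labels, which = c("raw", "normalized")) {
  which <- match.arg(which)
  col <- if (which == "raw") "D_raw" else "D_norm"
  taxa <- unique(c(table$taxonA, table$taxonB))
  res <- lapply(taxa, function(tx) {
    sub <- table[table$taxonA != tx & table$taxonB != tx, , drop = FALSE]
    groups <- lapply(group_labels, function(lab) sub[[col]][sub$clade_pair == lab])
    names(groups) <- group_labels
    if (any(lengths(groups) < 2)) return(NULL)
    a <- anova_tukey(groups)
    data.frame(dropped = tx, F = a$F, p_value = a$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
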