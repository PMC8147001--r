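# End-to-end orchestration: from per-locus alignments + time tree + clade
# map to distance matrices, the pair table, clade summaries, the ANOVA
# report, the bootstrap NJ tree, figures and a manifest. All randomness
# flows through the single seed recorded in the manifest, so every numeric
# artifact is re-derivable from the manifest alone.

#' Run the full comparative-rate pipeline
#'
#' @param config Either a YAML file path or a list with elements:
#'   `loci` (named character vector or list: locus name -> FASTA path, or
#'   a pre-built list of `locus_alignment`s under `loci_alignments`),
#'   `order` (concatenation order; default: order of `loci`),
#'   `missing_policy` (`"drop_taxon"`/`"gap_fill"`), `timetree` (path or
#'   `time_tree`), `timetree_dialect`, `clademap` (path or named vector),
#'   `model` (`"p_distance"`/`"poisson"`/`"gamma"`), `deletion`,
#'   `gamma_shape`, `display_cap` (default 0.6), `bootstrap_B` (default
#'   500), `seed`, `anova_groups` (clade-pair labels; default: all
#'   between-clade pairs present), `out_dir`, `make_plots` (default TRUE).
#' @return The output directory path (invisibly), after writing:
#'   `distances_raw.tsv`, `pair_table.tsv`, `clade_summary.tsv`,
#'   `anova.tsv`, `anova_log.txt`, `nj_tree.nwk`, `bootstrap_support.tsv`,
#'   `manifest.yaml`, and (optionally) `heatmap_raw.png`,
#'   `heatmap_normalized.png`, `violin_raw.png`, `violin_normalized.png`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- config
  cfg$missing_policy <- cfg$missing_policy %||% "drop_taxon"
  cfg$model <- cfg$model %||% "p_distance"
  cfg$deletion <- cfg$deletion %||% "pairwise"
  cfg$gamma_shape <- cfg$gamma_shape %||% 1
  cfg$display_cap <- cfg$display_cap %||% 0.6
  cfg$bootstrap_B <- cfg$bootstrap_B %||% 500
  cfg$seed <- cfg$seed %||% 1
  cfg$make_plots <- cfg$make_plots %||% TRUE
  if (is.null(cfg$out_dir)) stop("run_pipeline: out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  loci <- stage("read_loci", {
    if (!is.null(cfg$loci_alignments)) cfg$loci_alignments
    else lapply(names(cfg$loci), function(nm) read_fasta(cfg$loci[[nm]], locus = nm))
  })
  order <- cfg$order %||% vapply(loci, function(a) a$locus, character(1))
  aln <- stage("concatenate",
               concatenate(loci, order = order, missing_policy = cfg$missing_policy))
  tree <- stage("read_timetree", {
    if (inherits(cfg$timetree, "time_tree")) cfg$timetree
    else read_timetree(cfg$timetree,
                       dialect = cfg$timetree_dialect %||% "branch_lengths")
  })
  clades <- stage("read_clademap", {
    if (is.character(cfg$clademap) && length(cfg$clademap) == 1 &&
        file.exists(cfg$clademap)) read_clademap(cfg$clademap)
    else cfg$clademap
  })

  dm <- stage("distance_matrix",
              distance_matrix(aln, model = cfg$model, deletion = cfg$deletion,
                              gamma_shape = cfg$gamma_shape))
  write_distance_tsv(dm, file.path(cfg$out_dir, "distances_raw.tsv"))

  pair_table <- stage("pair_table", build_pair_table(dm, tree, clades))
  write_tsv(pair_table, file.path(cfg$out_dir, "pair_table.tsv"))

  summaries <- stage("clade_summary",
                     rbind(clade_summary(pair_table, "raw"),
                           clade_summary(pair_table, "normalized")))
  write_tsv(summaries, file.path(cfg$out_dir, "clade_summary.tsv"))

  interclade <- pair_table[pair_table$cladeA != pair_table$cladeB, , drop = FALSE]
  group_labels <- cfg$anova_groups %||% sort(unique(interclade$clade_pair))
  anova_res <- stage("anova", {
    groups <- lapply(group_labels, function(lab)
      interclade$D_norm[interclade$clade_pair == lab])
    names(groups) <- group_labels
    groups <- groups[lengths(groups) >= 2]
    anova_tukey(groups)
  })
  write_tsv(anova_res$tukey, file.path(cfg$out_dir, "anova.tsv"))
  writeLines(sprintf(
    "one-way ANOVA on normalized distances: F(%d, %d) = %.4f, p = %.4g",
    anova_res$df_between, anova_res$df_within, anova_res$F, anova_res$p_value
  ), file.path(cfg$out_dir, "anova_log.txt"))

  boot <- stage("bootstrap_nj",
                bootstrap_support(aln, model = cfg$model, deletion = cfg$deletion,
                                  B = cfg$bootstrap_B, seed = cfg$seed,
                                  gamma_shape = cfg$gamma_shape))
  write_newick(boot$tree, file.path(cfg$out_dir, "nj_tree.nwk"))
  write_tsv(data.frame(bipartition = names(boot$support),
                       support_pct = unname(boot$support)),
            file.path(cfg$out_dir, "bootstrap_support.tsv"))

  if (isTRUE(cfg$make_plots)) {
    stage("figures", {
      norm_values <- dm$values
      tmat <- divergence_time_matrix(tree, dm$taxa)
      off <- upper.tri(tmat) | lower.tri(tmat)
      norm_values[off] <- dm$values[off] / (tmat[off] / 100)
      render_heatmap(dm$values, cfg$display_cap,
                     file.path(cfg$out_dir, "heatmap_raw.png"))
      render_heatmap(norm_values, cfg$display_cap,
                     file.path(cfg$out_dir, "heatmap_normalized.png"))
      render_violin(pair_table, "raw",
                    file.path(cfg$out_dir, "violin_raw.png"))
      render_violin(pair_table, "normalized",
                    file.path(cfg$out_dir, "violin_normalized.png"))
    })
  }

  manifest <- list(
    seed = cfg$seed, order = order, missing_policy = cfg$missing_policy,
    model = cfg$model, deletion = cfg$deletion, gamma_shape = cfg$gamma_shape,
    display_cap = cfg$display_cap, bootstrap_B = cfg$bootstrap_B,
    anova_groups = group_labels,
    n_taxa = length(aln$taxa), n_columns = alignment_length(aln),
    order_hash = order_hash(order),
    r_version = as.character(getRversion())
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("colt", "rowt", "value", "clade_pair"))

# Stable hash of the concatenation order (simple polynomial hash; enough
# to detect a changed locus set/order in the manifest).
order_hash <- function(order) {
  s <- paste(order, collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}

#' Render a distance heatmap with display clipping
#'
#' Values above `cap` are clipped to `cap` (display only); the fill scale
#' tops out at the cap color.
#'
#' @param values Symmetric numeric matrix with dimnames.
#' @param cap Display ceiling.
#' @param path Output PNG path.
#' @export
render_heatmap <- function(values, cap, path) {
  if (is.null(values) || length(values) == 0)
    stop("render_heatmap: empty input", call. = FALSE)
  clipped <- clip_for_display(values, cap)
  df <- expand.grid(rowt = rownames(clipped), colt = colnames(clipped),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(clipped)
  df$rowt <- factor(df$rowt, levels = rownames(clipped))
  df$colt <- factor(df$colt, levels = colnames(clipped))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = colt, y = rowt, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colors = c("#2c7bb6", "#ffffbf", "#d7191c"),
      limits = c(0, cap), name = "distance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
  ggplot2::ggsave(path, g, width = 6, height = 5, dpi = 120)
  invisible(path)
}

#' Render violin plots of interclade distance distributions
#'
#' Median drawn solid, quartiles dotted, matching the usual violin
#' annotation convention.
#'
#' @param pair_table Pair table from [build_pair_table].
#' @param which `"raw"` or `"normalized"`.
#' @param path Output PNG path.
#' @export
render_violin <- function(pair_table, which = c("raw", "normalized"), path) {
  which <- match.arg(which)
  if (nrow(pair_table) == 0) stop("render_violin: empty input", call. = FALSE)
  df <- data.frame(
    clade_pair = pair_table$clade_pair,
    value = if (which == "raw") pair_table$D_raw else pair_table$D_norm
  )
  # a violin needs a distribution: drop clade pairs with a single value
  counts <- table(df$clade_pair)
  df <- df[df$clade_pair %in% names(counts[counts >= 2]), , drop = FALSE]
  if (nrow(df) == 0) stop("render_violin: empty input", call. = FALSE)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = clade_pair, y = value)) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.75), linetype = "dotted",
                         fill = "grey85") +
    ggplot2::geom_violin(draw_quantiles = 0.5, alpha = 0, linetype = "solid") +
    ggplot2::labs(x = NULL,
                  y = if (which == "raw") "pairwise distance"
                      else "distance per 100 MY") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, g, width = 6, height = 4, dpi = 120)
  invisible(path)
}

#' Write simulated loci, tree and manifest to a directory
#'
#' Emits per-locus FASTA files, the (node-named) time tree as Newick and
#' a YAML manifest sufficient to regenerate the dataset bit-identically.
#'
#' @param sim A `sim_result` from [simulate_alignments].
#' @param dir Output directory.
#' @return The directory (invisibly).
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in sim$loci)
    write_fasta(aln, file.path(dir, paste0(aln$locus, ".fasta")))
  write_newick(sim$tree$phy, file.path(dir, "timetree.nwk"))
  manifest <- sim$manifest
  manifest$loci <- as.list(manifest$loci)
  manifest$dropout <- if (is.null(manifest$dropout)) NULL else as.list(manifest$dropout)
  manifest$branch_rate <- as.list(manifest$branch_rate)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
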