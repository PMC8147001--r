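#!/usr/bin/env Rscript
# Stage 2 — concatenated supermatrices and pairwise distances.
#
# Builds the two concatenation sets (all ten subunits, which drops the
# taxon lacking CatSperZ, and the nine-subunit set without CatSperZ that
# retains it), computes p-distance matrices under pairwise deletion, and
# renders display-clipped heatmaps (cap 0.6).

library(protrate)

dataset <- "results/dataset"
order_full <- c("CatSper1", "CatSper2", "CatSper3", "CatSper4", "CatSperB",
                "CatSperG", "CatSperD", "CatSperE", "CatSperZ", "EFCAB9")
order_nozeta <- setdiff(order_full, "CatSperZ")

loci <- lapply(order_full, function(nm)
  read_fasta(file.path(dataset, paste0(nm, ".fasta")), locus = nm))
tree <- read_timetree(file.path(dataset, "timetree.nwk"))

dir.create("results/distances", showWarnings = FALSE, recursive = TRUE)
for (set in list(list(name = "full", order = order_full),
                 list(name = "nozeta", order = order_nozeta))) {
  aln <- concatenate(loci, order = set$order, missing_policy = "drop_taxon")
  dm <- distance_matrix(aln, model = "p_distance", deletion = "pairwise")
  write_distance_tsv(dm, sprintf("results/distances/pdist_%s.tsv", set$name))
  render_heatmap(dm$values, cap = 0.6,
                 sprintf("results/distances/heatmap_%s.png", set$name))
  message(sprintf(
    "%s set (%s): %d taxa x %d columns, max p-distance %.3f (%d pairs > 0.6 clipped for display)",
    set$name, paste(set$order, collapse = "-"), length(aln$taxa),
    alignment_length(aln), max(dm$values),
    sum(dm$values > 0.6) / 2))
}
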