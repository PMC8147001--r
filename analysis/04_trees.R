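#!/usr/bin/env Rscript
# Stage 4 — neighbor-joining tree with bootstrap support.
#
# Builds the NJ tree from the nine-subunit supermatrix (all taxa
# retained), attaches bootstrap bipartition support from 500
# column-resampling replicates, and counts the topological conflicts
# between the protein tree and the species time tree — the protein tree
# need not recapitulate taxonomy when rates differ between lineages.

library(protrate)

dataset <- "results/dataset"
order_nozeta <- c("CatSper1", "CatSper2", "CatSper3", "CatSper4", "CatSperB",
                  "CatSperG", "CatSperD", "CatSperE", "EFCAB9")
loci <- lapply(order_nozeta, function(nm)
  read_fasta(file.path(dataset, paste0(nm, ".fasta")), locus = nm))
tree <- read_timetree(file.path(dataset, "timetree.nwk"))

aln <- concatenate(loci, order = order_nozeta, missing_policy = "drop_taxon")
boot <- bootstrap_support(aln, model = "p_distance", deletion = "pairwise",
                          B = 500, seed = 429)

dir.create("results/trees", showWarnings = FALSE, recursive = TRUE)
write_newick(boot$tree, "results/trees/nj_catsper.nwk")
write_tsv(data.frame(bipartition = names(boot$support),
                     support_pct = unname(boot$support)),
          "results/trees/bootstrap_support.tsv")

message(sprintf("NJ tree over %d taxa; %d internal splits, support %d-%d%%",
                length(boot$tree$tip.label), length(boot$support),
                round(min(boot$support)), round(max(boot$support))))

cmp <- compare_bipartitions(boot$tree, tree$phy)
message(sprintf(
  "protein tree vs species time tree: %d shared splits, %d + %d unique (RF = %d)",
  cmp$shared, cmp$unique_A, cmp$unique_B, cmp$rf_distance))
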