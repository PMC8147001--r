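#!/usr/bin/env Rscript
# Stage 5 — IQ-like calmodulin-binding motif scan.
#
# Scans CatSperZ sequences for IQ-like motifs and flags hits whose
# anchor dipeptide falls in the final 21 residues, the window probed by
# C-terminal truncation. The simulated CatSperZ locus carries no real
# motif, so a synthetic full-length analog (194 residues, anchor at
# 0-based 173) is scanned alongside it as a positive control.

library(protrate)

dataset <- "results/dataset"
dir.create("results/motifs", showWarnings = FALSE, recursive = TRUE)

# positive control: synthetic CatSperZ-like protein, motif at the C-terminus
control <- locus_alignment("synthetic_catsperz", c(
  synthetic_full_length = paste0(strrep("A", 173), "LQAGYKRWTNE", strrep("G", 10))
))
control_path <- "results/motifs/synthetic_catsperz.fasta"
write_fasta(control, control_path)

hits_control <- scan_fasta_iq(control_path, window = 21)
write_tsv(hits_control, "results/motifs/synthetic_hits.tsv")
message(sprintf("synthetic control: %d hit(s), class %s, anchor %d, C-terminal %s",
                nrow(hits_control), hits_control$class, hits_control$anchor,
                hits_control$c_terminal))

# simulated CatSperZ orthologs (equal-rates simulation: any hit is chance)
sim_path <- file.path(dataset, "CatSperZ.fasta")
hits_sim <- scan_fasta_iq(sim_path, window = 21)
write_tsv(hits_sim, "results/motifs/simulated_catsperz_hits.tsv")
message(sprintf("simulated CatSperZ orthologs: %d chance hit(s) across %d taxa",
                nrow(hits_sim),
                length(read_fasta(sim_path, locus = "CatSperZ")$members)))
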