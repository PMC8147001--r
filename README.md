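# protrate

Comparative molecular-evolution toolkit for multi-locus orthologous
protein sets, built around the question that motivates it: how fast have
the ten subunits of the sperm-specific CatSper Ca²⁺ channel (CatSper1–4,
β, γ, δ, ε, ζ, EFCAB9) evolved across therian mammals, once raw sequence
divergence is corrected for how long ago each pair of species split?

A deeply diverged lineage (a marsupial, say, 160 MY from any eutherian)
can look extremely divergent in a raw distance matrix while actually
evolving slowly. The package's core statistic separates the two:

- **p-distance** `p = mismatches / comparable sites` on a concatenated
  (supermatrix) protein alignment, with pairwise deletion of gaps and
  unknown residues; Poisson (`d = −ln(1−p)`) and gamma
  (`d = a[(1−p)^(−1/a) − 1]`) corrections available.
- **Time-normalized distance** `D_norm = D_raw / (T / 100)`, where `T` is
  the pair's divergence time (MRCA age, MY) from a time-calibrated
  species tree — distance per 100 MY, a rate proxy (100 MYA = 1).
- Clade-level comparison of the normalized distributions by one-way
  ANOVA with Tukey HSD, neighbor-joining trees with bootstrap
  bipartition support, and an IQ-like calmodulin-binding motif scanner
  for the CatSperζ C-terminus.

Because no curated alignment set ships with the package, a first-class
protein-evolution simulator provides ground truth: sites evolve along a
time tree under a 20-state Markov chain with per-branch rate
multipliers, per-locus scalars, optional gamma site-rate heterogeneity
and per-locus taxon dropout. Its equal-rates default has a closed-form
expected p-distance, so every downstream stage is validated against
analytic oracles.

Intended users: molecular evolutionists comparing lineage-specific rates
on protein supermatrices, and anyone needing a tested, deterministic
distance/rate/tree pipeline with simulated ground truth.

## Worked example

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `05_motifs.R`). Running them in order from the
repository root simulates the 15-taxon therian dataset (five clades,
rodent branches 2× the baseline rate, marsupial branches 0.5×, one
taxon missing CatSperζ), then reproduces the full analysis. Stage 3
prints the headline result:

```
mean raw interclade distance, most divergent first:
         rodents       marsupials     Afrotherians         primates Laurasiatherians
          0.5033           0.4732           0.4338           0.4293           0.4260
mean normalized interclade distance (per 100 MY), fastest first:
         rodents         primates     Afrotherians Laurasiatherians       marsupials
          0.4921           0.4239           0.4118           0.4114           0.2958
one-way ANOVA on normalized distances: F(9,78) = 1150.68, p = 4.45e-79
```

(First block: raw distances — marsupials sit in the top divergence tier
with rodents, an artifact of their 160-MY split. Second block: after
time normalization the ranking reverses and marsupials are the
slowest-evolving clade, at ~0.30 substitutions-proportion per 100 MY
versus ~0.49 for rodents. The ANOVA confirms the clade separation.)

The same computation in code:

```r
library(protrate)
ds  <- make_paper_like_dataset(seed = 429)
aln <- concatenate(ds$sim$loci, missing_policy = "gap_fill")
dm  <- distance_matrix(aln, model = "p_distance", deletion = "pairwise")
tab <- build_pair_table(dm, ds$tree, ds$clades)
clade_summary(tab, "normalized")
```

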