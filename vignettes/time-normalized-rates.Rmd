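---
title: "Time-normalized protein divergence: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-normalized protein divergence: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrate)
```

# The question and the statistic

Raw sequence divergence confounds two things: how long two lineages have
been apart, and how fast they have been changing. For the CatSper
channel this matters concretely — a marsupial ortholog is separated from
any eutherian one by roughly 160 MY, so it will look highly divergent in
any raw distance matrix even if the protein has barely changed per unit
time. The package's central quantity removes the time component:

$$D_\mathrm{norm} = \frac{D_\mathrm{raw}}{T / 100},$$

where $T$ is the divergence time of the pair (the age of their most
recent common ancestor, in MY) and the constant 100 sets the convention
that a pair separated exactly 100 MY ago keeps its raw distance
(100 MYA = 1). $D_\mathrm{norm}$ is a per-lineage-pair rate proxy:
substitution proportion accumulated per 100 MY.

Two conventions are baked in deliberately:

* **Divergence time is the MRCA age, not twice it.** "Divergence time
  between two species" is the quantity time-calibrated databases report.
  Using path time ($2T$) would divide every value by 2 and cancel in
  every clade comparison, so the choice is cosmetic — but it must be
  stated once and used everywhere, and it is.
* **Normalization requires $T > 0$.** Self-pairs are excluded; a zero or
  negative time is an input error, never silently skipped.

# Distance estimation

`distance_matrix()` computes, for every unordered pair once (symmetry is
by construction, the diagonal exactly zero):

* **p-distance** (default): mismatches over comparable columns. A column
  is comparable under *pairwise deletion* when both residues are among
  the 20 standard amino acids — `-` (gap) and `X` (unknown) are missing
  data and can never count as mismatches. *Complete deletion* first
  masks every column containing any gap or unknown in any taxon.
* **Poisson correction** $d = -\ln(1-p)$ and **gamma correction**
  $d = a\,[(1-p)^{-1/a} - 1]$ as options. Both diverge as $p \to 1$;
  saturated pairs are flagged undefined rather than clamped.

The upstream distance software this replaces ("default options" of a GUI
package) does not pin down the model, so the default here is the most
conservative reading — p-distance with pairwise deletion — and the
corrections and both deletion schemes are exposed as configuration
rather than guessed at. The empirical heatmap scale (capped at 0.6 on a
proportion-like axis) is consistent with this reading.

A pair with **zero comparable sites** is reported as missing with a
warning, and propagates as an explicit `NA`: tree building refuses
incomplete matrices rather than inventing a value.

`clip_for_display(m, cap = 0.6)` is exactly what its name says: a
display transform for heatmaps. No statistic or tree ever consumes
clipped values.

# The simulator is the ground truth

No curated ortholog set ships with the package, so validation rests on
`simulate_alignments()`: protein sites evolving along a time tree under
a 20-state continuous-time Markov chain. The default equal-rates chain
was chosen because it admits closed forms,

$$P(\text{same} \mid d) = \tfrac{1}{20} + \tfrac{19}{20}
  e^{-\frac{20}{19} d}, \qquad
  \mathbb{E}[p] = \tfrac{19}{20}\bigl(1 - e^{-\frac{20}{19}
  d_\mathrm{path}}\bigr),$$

so the expected p-distance between any two leaves is known analytically
(`expected_p()`) and the whole pipeline can be checked against it. A
general reversible model (20×20 exchangeability matrix + equilibrium
frequencies) is supported via eigendecomposition, but then only
Monte-Carlo comparison is available and `expected_p()` refuses to
answer.

Branch expected distance factorizes as
$d_e = \mu \cdot (t_e/100) \cdot r_\mathrm{branch} \cdot
s_\mathrm{locus} \cdot g_\mathrm{site}$:

* $\mu$ — baseline rate, substitutions/site/100 MY. The study dataset
  uses $\mu = 0.25$, which puts raw p-distances for the deepest therian
  pairs near (but under) the 0.6 display cap — the empirically observed
  range for this protein family.
* $r_\mathrm{branch}$ — lineage multipliers keyed by child-node name
  (unnamed internal nodes are auto-named deterministically in
  post-order, so a multiplier can target a stem branch).
* $s_\mathrm{locus}$ — per-locus scalar (CatSperζ is the fastest subunit
  in the family; the study dataset gives it 1.3).
* $g_\mathrm{site}$ — optional discrete-gamma site rate (four
  equal-probability categories with exact category means, the standard
  discretization; mean renormalized to exactly 1).

**What the simulator does not emulate — and what that implies about the
tests.** No indels: the true alignment is exact, and gaps enter only
through locus dropout and gap-fill concatenation. No selection, no
site-specific profiles, no alignment error, no annotation error beyond
whole-locus dropout. Passing tests therefore demonstrate that the
*pipeline arithmetic* is correct and that the rate statistic recovers
*known* lineage effects; they say nothing about alignment quality or
model misspecification on real data, which the alignment-as-input
contract deliberately leaves to the user's aligner.

# The study dataset

`make_paper_like_dataset()` fixes the simulation the analysis scripts
and acceptance checks run on: 15 taxa in five clades (4 primates, 4
rodents, 3 Laurasiatherians, 2 Afrotherians, 2 marsupials), a
time-calibrated tree with the marsupial–eutherian split at 160 MYA and
the marsupial crown at 82 MYA, ten loci named after the CatSper
subunits with lengths proportional to the real proteins (scaled to a
~2,600-column supermatrix), rodent stem-and-crown branches at
$r = 2.0$, marsupial branches at $r = 0.5$, and the opossum-like taxon
missing the CatSperζ locus — mirroring genomes where that subunit is
simply not annotated. Clade ages within eutherians follow standard
time-tree estimates (Euarchontoglires 90, Boreoeutheria 96, root of
eutherians 99 MYA).

One consequence of these conditions is worth stating precisely, because
it shapes what the tests assert. Every rodent pair accrues the 2×
multiplier over the rodents' entire 90-MY root-to-tip span, so the
rodent clade's mean interclade **raw** distance algebraically exceeds
the marsupials' — the marsupial clade lands *second*, above every
non-rodent clade. That matches the empirical picture (marsupial and
rodent orthologs are both flagged as highly divergent) and so the
headline check asserts "top tier": marsupials rank ≤ 2 in raw
divergence and above all non-rodent clades, while their **normalized**
divergence falls strictly below the rodents'. The stronger statement —
the slow clade as the *single* most divergent raw clade — does hold
when the fast clade is shallow, and is asserted on a dedicated
three-clade tree in which the slow clade diverged earliest and the fast
clade radiated recently.

# Trees

`nj_tree()` is the Saitou–Nei agglomeration: join the pair minimizing
$Q_{ij} = (n-2)d_{ij} - r_i - r_j$. Numerical choices:

* **Tie-break**: smallest $(i, j)$ index pair in the current taxon
  ordering — deterministic given input order.
* **Negative branch lengths** (possible on non-additive matrices) are
  clamped to 0 with the deficit transferred to the sister branch, so
  the joined pair's path length is preserved.
* On additive matrices the reconstruction is exact (round-trip checked
  to $10^{-10}$), and for $n \le 6$ the topology agrees with exhaustive
  least-squares search over all unrooted topologies.

Maximum-likelihood tree search is deliberately **not** implemented: the
analysis this package supports draws only a qualitative clustering
claim from its trees, the original ML settings (substitution model,
rate classes) are unrecorded, and distance-based NJ with bootstrap
support is sufficient for that claim. The rooted display tree is always
the input time tree; no rooting is inferred.

`bootstrap_support()` resamples alignment columns with replacement
(same total length; optionally stratified within locus partitions),
recomputes the matrix and tree, and reports for each internal
bipartition of the point tree the percentage of replicates containing
it. Replicate $r$ reseeds from (seed, $r$), so any single replicate is
individually reproducible. Replicates producing an incomparable pair
are dropped and counted; more than 10% dropped is an error, not a
silent degradation.

# Clade statistics

`anova_tukey()` is classical one-way ANOVA followed by Tukey HSD, in
the Tukey–Kramer form (interclade groups have unequal pair counts), with
significance stars at p < 0.05 / 0.01 / 0.001. Two caveats are part of
the design rather than afterthoughts:

* **Pairwise distances are not independent** — every taxon contributes
  to many pairs. The analysis applies ANOVA to them anyway because that
  is the established practice this pipeline reproduces; the p-values on
  pair tables are descriptive. `jackknife_anova()` is provided as the
  sensitivity check: drop each taxon in turn, rebuild the groups, and
  inspect the spread of p-values.
* The **nominal-size check** of the test (type-I error ≈ 5% over 1,000
  null replicates) is run on independent Gaussian samples, because that
  is the property the function itself can guarantee; on exchangeable
  but dependent distance values the nominal level is not a theorem.

Which clade pairs enter the ANOVA is configuration
(`anova_groups`), defaulting to all between-clade groups present — the
original group selection is not recoverable, so it is not hard-coded.

# Motif scanning

`find_iq_like()` reports two consensus classes, longest first:
`IQ_full` = `[FILV]Q` $x_3$ `[RK]G` $x_3$ `[RK]` (11 residues) and the
relaxed `IQ_like` = `[FILVM]Q` $x_3$ `[RK]` $x_4$ (10 residues), placed
greedily left-to-right with full-class matches taking precedence and no
overlaps. The relaxed class exists because the CatSperζ motif lacks the
canonical G — it is "IQ-like", not IQ. The numeric propensity score of
the original web database is unpublished and is not re-implemented;
consensus-class membership and coordinates are what the scanner
reports. `report_cterminal()` flags hits whose anchor dipeptide lies in
the final 21 residues, the window probed experimentally by C-terminal
truncation (a 194-residue full-length protein with the anchor at
0-based 173 is flagged; deleting those 21 residues removes it).

# Degenerate inputs and tolerances

* Alphabet: 20 amino acids + `-` + `X`, case-normalized; anything else
  errors with the offending position.
* Ultrametricity tolerance for time trees: relative $10^{-6}$ of root
  age; internal-node-label ages are an explicit dialect, and a node
  older than its parent is an error in either dialect.
* Concatenation: `drop_taxon` (default, keeps only taxa present in
  every listed locus) vs `gap_fill` (pads absent loci with gaps).
  Dropping a locus that some taxa lack — rather than dropping those
  taxa — is what the nine-subunit concatenation set is for.
* Empty taxon intersection, empty clade-pair selections, groups with
  fewer than two values, missing matrix entries: all hard errors with
  named offenders.

# Problem sizes

The shipped analyses and checks use the 15-taxon / ~2,600-column study
dataset (50 seeded replicates for the reversal rate), 20,000-site
two-leaf alignments for simulator calibration, B = 500 bootstrap
replicates, 100 random 5–6-taxon additive matrices for the exhaustive
NJ comparison, and 1,000 random 200-mers for the motif-scanner oracle —
sizes chosen so the complete suite exercises every claim at comfortable
statistical resolution while remaining quick to run on a laptop.

# Known limitations

* Rate comparison is purely distance-based: no relative-rate tests, no
  branch-model ML rate estimation, no codon-level selection analysis.
* The normalized distance inherits every bias of its inputs — alignment
  errors inflate it, divergence-time errors shift whole clades.
* NJ is a point estimate; only bootstrap proportions qualify its
  uncertainty.
* The simulator's equal-rates default is a calibration device, not a
  realistic amino-acid replacement model; supply an exchangeability
  matrix for realism at the cost of closed-form oracles.
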