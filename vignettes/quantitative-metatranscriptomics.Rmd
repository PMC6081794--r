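---
title: "Quantitative metatranscriptomics of the rumen microbiome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative metatranscriptomics of the rumen microbiome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumiquant)
```

## The quantification model

Metatranscriptome read counts are compositional: they say what fraction of
the sequenced RNA pool a transcript occupies, not how many copies of it sit
in a gram of rumen fluid. `rumiquant` converts one into the other by
anchoring the composition to a measured mass — the total RNA yield per gram
of rumen fluid — and to molecular constants:

\[
A \;=\; \mathrm{RNA} \times \frac{x}{x+y} \times \frac{A_r}{n_{sub}}
\times \frac{N_A}{M(\mathrm{Nt}) \times L_A}
\]

reading left to right: micrograms of total RNA per gram, the fraction of
that RNA belonging to the read class of interest (mRNA or SSU rRNA), the
fraction of the classified subsample assigned to transcript \(A\), and the
conversion from micrograms of a transcript of average length \(L_A\) into
copy numbers via the Avogadro constant \(N_A\) and the average
single-stranded nucleotide mass \(M(\mathrm{Nt}) = 330 \times 10^6\)
ug/mol. The first three factors are a mass bookkeeping (so the sum over
entities that partition a subsample returns exactly the class mass — a
tested invariant); the last factor is a unit conversion.

Assumptions worth stating:

* **Class fractions.** The library protocol's polyadenylation step enriches
  mRNA, so the observed mRNA read share overstates the mRNA mass share. The
  default policy (`class_fraction_policy("fixed_ratio")`) therefore fixes
  the mRNA share of total RNA at 1:25, an externally calibrated value for
  this protocol and sample type; `"observed"` uses the sequenced share
  instead. SSU rRNA always uses its observed share of total reads — the
  fixed ratio corrects the mRNA enrichment specifically, and rRNA is not
  polyadenylation-enriched. Whether the rRNA denominator should exclude LSU
  reads is ambiguous; using total reads is the one consistent reading
  adopted here, and LSU rRNA itself is never quantified (no defensible
  average length), it only contributes to read totals.
* **Average lengths.** 1,000 nt (mRNA), 1,500 nt (prokaryotic SSU rRNA),
  1,900 nt (eukaryotic SSU rRNA). Taxa without a domain assignment fall
  back to the prokaryotic length and are flagged in the
  `length_defaulted` output column rather than silently guessed.
* **Concentrations, not counts.** Outputs are doubles in copies per gram;
  they are never rounded to integers.

The consequence that matters scientifically: scaling the total RNA yield by
\(k\) scales every quantified abundance by \(k\) and leaves every relative
abundance unchanged. A community that responds to feeding by growing as a
whole is invisible in relative profiles and obvious in quantified ones.

## What the synthetic generator emulates

`simulate_study()` produces the complete post-classification table set of a
diurnal feeding trial — SSU taxon counts, annotated mRNA counts, read-class
totals, RNA yields, VFA/pH records and gas series — for a default design of
4 cows sampled before feeding (t0) and 1, 3 and 5 h after feeding started
(t1/t3/t5).

The community model is hierarchical-compositional. Per cow, the
eukaryote/bacteria split is Beta-distributed with concentration
`cow_individuality` (default 16, giving a between-cow SD of the eukaryote
share of about 10 percentage points); the small archaeal share has its own
much tighter Beta (concentration 3000, i.e. roughly 0.3% +- 0.1% across
animals — a flat Dirichlet at concentration 16 would extinguish taxa this
rare in most cows); within-domain compositions are Dirichlet with
concentration `3 * cow_individuality`. Per timepoint the cow's domain
structure is held fixed and the within-domain compositions drift with
Dirichlet concentration `base / within_cow_noise`; reads are then
multinomial draws of `ssu_subsample_size` (default 50,000). This encodes
the trial's structure — communities individual to each cow, stable within
a cow over hours — with the residual temporal drift placed at the family
level, where real classification noise and fine-scale dynamics live.

Calibrated marginals (all fixed from the emulated trial's printed
summaries, not fitted to any test): mean domain shares (25.1, 74.6, 0.3)%;
nine core bacterial families holding ~92.3% of family-assigned bacterial
reads; RNA yields 34.1/69.2/70.0/37.0 ug/g at t0/t1/t3/t5 with log-normal
noise (CV default 0.18, the mean of the printed per-timepoint relative
SDs); VFA fractions (60.4, 21.9, 11.6)% for acetate/propionate/butyrate
peaking at t3; pH a decreasing linear function of total VFA (intercept
8.15, slope -0.0167 fitted once from the packaged reference table, noise SD
0.12 calibrated by simulation so that the 16-sample Pearson correlation
centers near -0.84); CH4/CO2 rates stepping up 1.9/1.5-fold in the first
post-feeding hour and relaxing to baseline by 5 h; H2 a rectangular pulse
confined to the first hour; mRNA reads at 1/25 of total; the four dominant
CAZyme categories at 77.5% of CAZyme reads; mttB at 75% of the
methylamine-methyltransferase (mtMA) pool.

Two generator knobs deserve comment. `within_cow_noise` is not reported
numerically by any trial summary; its default (0.025) was chosen once, by
simulation, so that cow identity explains about 64% of Bray-Curtis
community variation in the default design — the community-stability level
the emulated trial reports — and then frozen. `methylotroph_response`
(default 2) raises the methyl-reducing methanogen genes (mtMA and
Methanosphaera mtaB) at t1/t3 and lowers Methanomassiliicoccales mtaB
inversely, reproducing the electron-acceptor switch observed after feeding;
setting it to 1 gives the constant-relative-activity scenario used to
demonstrate the relative-vs-quantified contrast.

What the generator does **not** emulate: read-level data (no sequences, no
error or chimera models), classification error and database bias,
particle-associated versus fluid communities, absorption/production
kinetics of VFAs, diet shifts, or any between-day variation. Passing tests
on synthetic data therefore demonstrate the pipeline's statistical and
numerical correctness under the trial's declared structure, not the
biological fidelity of upstream classification.

## Statistical methods

* **Relative abundance** at a chosen rank reports taxa unassigned at that
  rank at their deepest assigned higher rank, so per-sample fractions still
  sum to 1.
* **PERMANOVA** (one factor) partitions squared Bray-Curtis distances into
  between/within-group sums of squares (equivalent to the Gower-centered
  partition); the pseudo-F is tested by free permutation with
  \(p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})\), 999 permutations by
  default, or by exhaustive enumeration for small samples
  (`exact = TRUE`). Free permutation is used because a cow-identity test
  has no finer blocking level available.
* **Indicator analysis** scores each taxon by its mean abundance in its
  best group and permutes group labels *within cows*, a deliberate
  strengthening that respects the paired longitudinal design; the
  max-over-groups statistic is recomputed on every permutation, and
  p-values are Sidak-corrected across taxa by default (Benjamini-Hochberg
  by flag). All-zero taxa are skipped with a message.
* **Per-cow z-scoring** (sample SD, n-1) standardizes dimensionally
  heterogeneous metadata within each cow before PCA; zero-variance
  variables map to zeros. PCA operates on the z-scored,
  library-size-normalized matrix; Bray-Curtis operates on non-negative
  relative abundances (z-scores are signed and unsuitable for it). Which
  normalization feeds the PERMANOVA is exposed to the caller; the default
  documented here is relative abundances.
* **Paired tests**: consecutive-timepoint comparisons are two-sided paired
  t tests; zero-variance difference vectors return p = 1 (no evidence of
  change) with a message rather than NaN. Significance stars use 0.05/0.01.
* **Function screen**: the paired differential-expression procedure is
  deliberately simple — trimmed-mean-scaled counts-per-million, a
  low-expression filter (mean CPM >= 5), a paired t test on log2(CPM + 0.5)
  per function, Benjamini-Hochberg adjustment. It is a documented stand-in
  for a negative-binomial GLM analysis, adequate for the package's purpose
  (a calibrated, FDR-controlled screen) but less powerful at n = 4 cows.
* **Correlations**: Spearman by default for transcript-process linkage
  (average-rank ties; exact permutation p for n <= 8 without ties),
  Pearson for pH-VFA.

## Pathway and marker aggregation

CAZyme Pfam accessions map to substrate categories through an editable TSV
catalog; unmatched Pfams are collected under "other" with a message, and
category totals conserve reads. VFA pathway definitions (ordered EC lists
for three acetate routes, the succinate and acrylate propionate routes, and
the butyrate kinase and butyryl-CoA:acetate CoA-transferase routes) also
ship as an editable TSV; pathway activity is the EC sum divided by the
number of steps, ECs shared between routes count in every route containing
them (documented double-counting of "possibly involved" enzymes), and
production-specific steps are flagged so activity can optionally be
restricted to them. Where the route membership of an EC is uncertain the
catalog row carries a `tentative` flag rather than a silent guess — the
shipped catalogs are synthetic reconstructions for the generator and tests,
and users with curated pathway knowledge should edit them. Methanogenesis
markers follow the field's conventions: mcrA for all methanogens, mtMA =
mtmB + mtbB + mttB for the methylamine route, mtrA for the CO2-reduction
route, mtaB for methanol with the Methanosphaera and
Methanomassiliicoccales contributions reported separately.

## Numerical choices and degenerate inputs

All computation is double precision. Permutation p-values include the +1
correction (never exactly zero); the exact enumeration mode includes the
identity permutation in its reference set. Dirichlet draws use the gamma
construction with zero-concentration components pinned at zero;
`within_cow_noise = 0` short-circuits to the cow base composition exactly.
Log-normal noise is parameterized by arithmetic mean and CV so that CV = 0
returns the means bit-exactly. A single top-level seed reaches every output
table through named substreams (a deterministic hash of the stream name),
so adding one output never perturbs another — a tested contract. Validation
errors from table readers name the file, column and line; pipeline stage
failures name the stage.

## Problem sizes

The shipped tests and the acceptance script run on the default design (16
samples, 50,000-read SSU subsamples, 20,000-read mRNA subsamples), with
999-permutation tests, false-positive-rate calibrations of 200 null
simulations, and replicate-averaged synthetic summaries (4-8 replicate
trials) — sizes chosen so the whole suite completes in a few minutes on one
core while leaving the Monte-Carlo standard errors well inside the asserted
tolerances.

## Known limitations

The quantification inherits every upstream bias (extraction efficiency,
amplification, classification database); the absolute scale is only as good
as the total RNA yield measurement and the fixed 1:25 mRNA ratio, and the
average-length model flattens real length variation across taxa and genes.
The generator's independence assumptions (functions multinomial given taxon
weights, acids Dirichlet given totals) are conveniences, not biology. The
PERMANOVA is one-factor; crossed cow x time designs need external tooling.
NMDS ordination is intentionally omitted (PCA plus PERMANOVA cover the
package's inferential surface).
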