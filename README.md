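# rumiquant

Quantitative metatranscriptomics of the rumen microbiome.

## The problem

Relative read counts from a metatranscriptome cannot be linked to process
rates: if the whole community doubles its activity after a cow is fed, every
relative abundance stays flat while methane pours out of the animal.
`rumiquant` converts relative rRNA and mRNA read counts from rumen-fluid
metatranscriptomes into **absolute transcript copies per gram of rumen
fluid** by anchoring them to the total RNA yield per gram, and then carries
those quantified profiles through the downstream analyses of a diurnal
feeding trial: three-domain community profiling, CAZyme (carbohydrate-active
enzyme) category summaries, volatile fatty acid (VFA) production pathway
activities, methanogenesis marker genes, and the statistical linkage of all
of these to process data (VFA concentrations, pH, CH4/CO2/H2 emissions).

It is written for microbiome researchers who have classified/annotated count
tables (from SortMeRNA/BLAST/MEGAN/HMMER-style upstream tools) plus routine
process measurements, and want absolute, process-linkable transcript
concentrations rather than compositions.

## The core quantity

For a transcript *A* in sample *r*:

```
                         xRNA_r         A_r              N_A
  A [copies/g] = RNA * ----------- * ---------- * ----------------
                       xRNA_r+yRNA_r  n_sub,r      M(Nt) * L_A
```

where `RNA` is the total RNA yield (ug per g rumen fluid), the second factor
is the read-class fraction (mRNA or SSU rRNA share of total reads; for mRNA
a fixed 1:25 mRNA:total ratio corrects the polyadenylation enrichment of the
library protocol), `A_r / n_sub,r` is the share of the classified subsample
assigned to *A*, `N_A` is the Avogadro constant, `M(Nt) = 330e6 ug/mol` the
average single-stranded nucleotide mass, and `L_A` the average transcript
length (1,000 nt for mRNA; 1,500/1,900 nt for prokaryotic/eukaryotic SSU
rRNA).

Because the anchor is a per-gram mass, multiplying the community's biomass
by *k* multiplies every quantified abundance by *k* while all relative
abundances are unchanged — exactly the contrast the method exists to expose.

A synthetic feeding-trial generator (`simulate_study()`) emulates the
post-classification tables of a 4-cow x 4-timepoint experiment
(cow-individual but temporally stable communities, a whole-community growth
response after feeding, coupled VFA/pH/gas dynamics), so the entire pipeline
is testable without sequence data. A transcribed VFA/pH reference table
ships with the package (`rumen_vfa_table1()`).

## Worked example

```r
library(rumiquant)

# one transcript: 50 ug RNA/g, 1:25 mRNA fraction, 100 of 10,000
# subsampled reads, 1 kb transcript
quantify_transcript(50, 0.04, 100, 10000, 1000)
#> [1] 3.65e+10        # transcript copies per gram of rumen fluid

# full pipeline on a synthetic feeding trial
res <- run_pipeline(out_dir = "demo_out", config = list(seed = 1, n_perm = 199))
writeLines(res$report)
#> rumiquant pipeline report (seed 1, config 493e15f9)
#>
#> Samples: 16 (4 cows x 4 timepoints)
#> VFA fractions (% of total, mean +- SD): acetate 58.6 +- 4.7, propionate 22.9 +- 4.0, butyrate 12.2 +- 2.3
#> pH vs total VFA: Pearson r = -0.839 (n = 16, p = 5e-05)
#> Feeding response folds: ch4 1.87, co2 1.51
#> Cow identity PERMANOVA: R2 = 0.694, p = 0.005
#> Core nine-family share of family-assigned bacterial reads: 94.4%
#> Four dominant CAZyme categories: 77.1% of CAZyme reads
#> Functions significant at q < 0.05 for t0 -> t1: 0 of 79
```

Reading the report: total VFA and pH anti-correlate strongly (fermentation
acidifies the rumen); CH4 emission roughly doubles in the first hour after
feeding; cow identity — not time — explains most of the community variation
(the microbiota are individual but stable); and almost no single function
changes its *relative* expression after feeding, because the response is a
growth of the whole community, which only the quantified (per-gram) profiles
reveal.

Key entry points: `simulate_study()`, `quantify_table()`,
`relative_abundance()`, `permanova()`, `indicator_analysis()`,
`categorize_cazymes()`, `pathway_activity()`, `methanogenesis_markers()`,
`vfa_fractions()`, `ph_vfa_correlation()`, `feeding_response()`,
`paired_function_screen()`, `run_pipeline()`.

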