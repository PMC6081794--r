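# Shared fixtures, built in code.

toy_design <- function(n_cows = 2) {
  study_design(cows = paste0("cow", seq_len(n_cows)))
}

# minimal two-taxon count table for two samples
toy_taxon_counts <- function() {
  data.frame(
    sample = rep(c("s1", "s2"), each = 2),
    cow = rep(c("cow1", "cow2"), each = 2),
    timepoint = "t0",
    domain = "Bacteria",
    phylum = "Bacteroidetes",
    class = "Bacteroidia",
    family = rep(c("Prevotellaceae", "RF16"), 2),
    genus = NA_character_,
    reads = c(30, 70, 60, 40),
    stringsAsFactors = FALSE)
}

toy_read_class <- function(samples = c("s1", "s2")) {
  data.frame(sample = samples, total_reads = 200000, ssu_reads = 80000,
             lsu_reads = 70000, mrna_reads = 8000,
             ssu_subsample_size = 100, mrna_subsample_size = 1000,
             stringsAsFactors = FALSE)
}

toy_yields <- function(samples = c("s1", "s2"), ug = 50) {
  data.frame(sample = samples, micrograms_per_gram = ug,
             stringsAsFactors = FALSE)
}

# samples x taxa relative-abundance matrix at family level
abundance_matrix_for_test <- function(com, level = "family") {
  rel <- relative_abundance(com, level)
  as.matrix(unclass(stats::xtabs(fraction ~ sample + taxon, data = rel)))
}

# per-(cow, timepoint) series helper
series_df <- function(cows, timepoints, values) {
  data.frame(cow = rep(cows, each = length(timepoints)),
             timepoint = rep(timepoints, length(cows)),
             value = values, stringsAsFactors = FALSE)
}
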