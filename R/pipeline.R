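#' Run the full quantitative metatranscriptomics pipeline
#'
#' Orchestrates the four analysis stages over a dataset — quantification
#' (transcripts per gram of rumen fluid), community profiling (relative
#' abundances, Bray-Curtis, PERMANOVA, indicator analysis), functional
#' aggregation (CAZyme categories, VFA pathways, methanogenesis markers)
#' and process integration (VFA fractions, pH-VFA correlation, feeding
#' response, marker-process correlations, paired tests) — and writes the
#' output tables plus a human-readable report. Deterministic given the
#' seed in `config`.
#'
#' @param data a dataset as returned by [simulate_study()], or a list of
#'   paths (`taxon_counts`, `function_counts`, `read_class`, `rna_yield`,
#'   `vfa`, `gas`) read with [read_table()]. `NULL` simulates a dataset
#'   from `config`.
#' @param out_dir output directory (created if needed). `NULL` skips
#'   writing.
#' @param config list of settings: `seed`, `n_perm`, `fdr_q`,
#'   `correction`, `policy_mode`, plus any [generator_params()] argument
#'   used when `data` is simulated; or the path to a key = value text
#'   file with one setting per line (`#` comments allowed).
#' @return invisibly, a list with every stage result (`quantified_ssu`,
#'   `quantified_mrna`, `relative`, `permanova_cow`, `indicators`,
#'   `cazymes`, `pathway_activities`, `markers`, `vfa_summary`,
#'   `ph_vfa`, `feeding_folds`, `marker_ch4_correlations`,
#'   `paired_yield_tests`, `function_screen`, `report` (character
#'   vector), and `files` when `out_dir` is given).
#' @export
run_pipeline <- function(data = NULL, out_dir = NULL, config = list()) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1
  n_perm <- config$n_perm %||% 999
  fdr_q <- config$fdr_q %||% 0.05
  correction <- config$correction %||% "sidak"
  policy <- class_fraction_policy(config$policy_mode %||% "fixed_ratio")
  digest <- config_digest(config)

  if (is.null(data)) {
    gp_args <- config[intersect(names(config), names(formals(generator_params)))]
    gp_args$seed <- seed
    data <- simulate_study(do.call(generator_params, gp_args))
  } else if (!is.null(data$taxon_counts) && is.character(data$taxon_counts)) {
    data <- list(
      community = read_table(data$taxon_counts, "taxon_counts"),
      function_counts = read_table(data$function_counts, "function_counts"),
      read_class = read_table(data$read_class, "read_class"),
      rna_yield = read_table(data$rna_yield, "rna_yield"),
      vfa = read_table(data$vfa, "vfa"),
      gas = read_table(data$gas, "gas"),
      design = study_design())
  }
  design <- data$design %||% study_design()
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- quantify ------------------------------------------------------------
  q_ssu <- stage("quantify", quantify_table(data$rna_yield, data$read_class,
                                            data$community, policy))
  q_mrna <- stage("quantify", quantify_table(data$rna_yield, data$read_class,
                                             data$function_counts, policy))

  # -- community -----------------------------------------------------------
  rel <- stage("community", relative_abundance(data$community, "family"))
  relmat <- abundance_matrix(rel)
  meta <- design$samples[match(rownames(relmat), design$samples$sample), ]
  bc <- stage("community", bray_curtis(relmat))
  pmv <- stage("community", permanova(bc, meta$cow, n_perm = n_perm,
                                      seed = seed))
  ind <- stage("community", indicator_analysis(relmat, meta$timepoint,
                                               blocks = meta$cow,
                                               n_perm = n_perm, seed = seed,
                                               correction = correction))
  core <- stage("community", core_family_share(rel))

  # -- pathways ------------------------------------------------------------
  caz <- stage("pathways", categorize_cazymes(data$function_counts))
  pw <- stage("pathways", {
    do.call(rbind, lapply(vfa_pathway_catalog(), function(p) {
      pathway_activity(q_mrna, p)
    }))
  })
  mk <- stage("pathways", methanogenesis_markers(q_mrna))

  # -- process -------------------------------------------------------------
  vfa_sub <- data$vfa[!is.na(data$vfa$timepoint), , drop = FALSE]
  vfa_sum <- stage("process", vfa_fractions(data$vfa))
  phv <- stage("process", ph_vfa_correlation(data$vfa))
  folds <- stage("process", feeding_response(data$gas))
  ch4_tp <- stage("process", {
    # mean CH4 rate in the hour around each sampling timepoint, per cow
    do.call(rbind, lapply(seq_len(nrow(design$samples)), function(i) {
      s <- design$samples[i, ]
      g <- data$gas[data$gas$cow == s$cow &
                      data$gas$hour > s$hour - 0.5 &
                      data$gas$hour <= s$hour + 0.5, , drop = FALSE]
      data.frame(cow = s$cow, timepoint = s$timepoint,
                 value = mean(g$ch4), stringsAsFactors = FALSE)
    }))
  })
  mk_meta <- merge(mk, design$samples[, c("sample", "cow", "timepoint")],
                   by = "sample")
  mk_cor <- stage("process", {
    out <- list()
    for (m in unique(mk_meta$marker)) {
      for (t in unique(mk_meta$taxon[mk_meta$marker == m])) {
        series <- mk_meta[mk_meta$marker == m & mk_meta$taxon == t, ]
        series <- data.frame(cow = series$cow, timepoint = series$timepoint,
                             value = series$transcripts_per_gram)
        if (all(series$value == 0)) next
        ct <- correlate_transcripts_process(series, ch4_tp, "spearman")
        out[[length(out) + 1L]] <- data.frame(
          marker = m, taxon = t, rho = ct$coefficient, p_value = ct$p_value,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  yields <- merge(data$rna_yield, design$samples[, c("sample", "timepoint")],
                  by = "sample", suffixes = c("", "_d"))
  yield_tests <- stage("process", paired_timepoint_tests(
    data.frame(cow = yields$cow, timepoint = yields$timepoint,
               value = yields$micrograms_per_gram),
    timepoints = names(design$timepoints)))
  screen <- stage("process", paired_function_screen(
    data$function_counts, design,
    transition = names(design$timepoints)[1:2], fdr_q = fdr_q))

  # -- report --------------------------------------------------------------
  acet <- function(a) {
    s <- vfa_sum$summary
    sprintf("%.1f +- %.1f", s$mean_pct[s$acid == a], s$sd_pct[s$acid == a])
  }
  report <- c(
    sprintf("rumiquant pipeline report (seed %s, config %s)", seed, digest),
    "",
    sprintf("Samples: %d (%d cows x %d timepoints)", nrow(design$samples),
            length(design$cows), length(design$timepoints)),
    sprintf("VFA fractions (%% of total, mean +- SD): acetate %s, propionate %s, butyrate %s",
            acet("acetic"), acet("propionic"), acet("butyric")),
    sprintf("pH vs total VFA: Pearson r = %.3f (n = %d, p = %.2g)",
            phv$coefficient, phv$n, phv$p_value),
    sprintf("Feeding response folds: %s",
            paste(sprintf("%s %.2f", names(folds$mean), folds$mean),
                  collapse = ", ")),
    sprintf("Cow identity PERMANOVA: R2 = %.3f, p = %.3g",
            pmv$r_squared, pmv$p_value),
    sprintf("Core nine-family share of family-assigned bacterial reads: %.1f%%",
            100 * core$mean),
    sprintf("Four dominant CAZyme categories: %.1f%% of CAZyme reads",
            100 * caz$four_category_share),
    sprintf("Functions significant at q < %.2g for %s -> %s: %d of %d",
            fdr_q, names(design$timepoints)[1], names(design$timepoints)[2],
            sum(screen$significant), nrow(screen)))

  result <- list(design = design, quantified_ssu = q_ssu,
                 quantified_mrna = q_mrna, relative = rel,
                 permanova_cow = pmv, indicators = ind, core_families = core,
                 cazymes = caz, pathway_activities = pw, markers = mk,
                 vfa_summary = vfa_sum, ph_vfa = phv, feeding_folds = folds,
                 marker_ch4_correlations = mk_cor,
                 paired_yield_tests = yield_tests, function_screen = screen,
                 report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      write_table(df, file.path(out_dir, name), seed = seed,
                  config_hash = digest)
    }
    files <- c(
      w(q_ssu, "quantified_ssu.tsv"), w(q_mrna, "quantified_mrna.tsv"),
      w(rel, "relative_abundance.tsv"), w(ind, "indicators.tsv"),
      w(caz$table, "cazyme_summary.tsv"), w(pw, "pathway_activity.tsv"),
      w(mk, "methanogen_markers.tsv"),
      w(vfa_sum$summary, "vfa_fraction_summary.tsv"),
      w(yield_tests, "paired_tests.tsv"), w(screen, "function_screen.tsv"))
    writeLines(c(report, "",
                 sprintf("PERMANOVA detail: pseudo-F = %.3f, %d permutations",
                         pmv$pseudo_f, pmv$n_permutations)),
               file.path(out_dir, "report.txt"))
    result$files <- c(files, file.path(out_dir, "report.txt"))
  }
  invisible(result)
}
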