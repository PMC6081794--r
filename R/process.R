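# VFA, pH and gas-emission summaries and their linkage to quantified
# transcript series.

vfa_acid_columns <- function() {
  c("formic", "acetic", "propionic", "iso_butyric", "butyric",
    "iso_valeric", "valeric", "caproic", "heptanoic", "lactic", "succinic")
}

#' Per-sample VFA fractions and their summary
#'
#' Expresses every acid as a percent of the sample's total VFA and
#' summarizes each acid as unweighted mean and sample SD across samples.
#' Invariant to rescaling of the concentration units.
#'
#' @param records VFA table with one column per acid (see
#'   [vfa_acid_columns()]) and a `total` column; typically
#'   [rumen_vfa_table1()] or the `vfa` element of [simulate_study()]
#'   (missing acid columns are treated as absent acids).
#' @return list with `per_sample` (the input plus `<acid>_pct` columns)
#'   and `summary` (data.frame: acid, mean_pct, sd_pct).
#' @export
vfa_fractions <- function(records) {
  assert_columns(records, "total", "records")
  if (any(records$total <= 0)) stop("zero or negative total VFA")
  acids <- intersect(vfa_acid_columns(), names(records))
  if (length(acids) == 0) stop("no acid concentration columns found")
  per <- records
  for (a in acids) {
    if (any(records[[a]] < 0)) stop("negative concentration in ", a)
    per[[paste0(a, "_pct")]] <- 100 * records[[a]] / records$total
  }
  summ <- data.frame(
    acid = acids,
    mean_pct = vapply(acids, function(a) mean(per[[paste0(a, "_pct")]]), numeric(1)),
    sd_pct = vapply(acids, function(a) stats::sd(per[[paste0(a, "_pct")]]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(per_sample = per, summary = summ)
}

#' Pearson correlation between pH and total VFA
#'
#' Product-moment correlation over the records with a measured pH (rows
#' lacking pH are excluded), with `df = n - 2` and a two-sided p-value.
#'
#' @param records VFA table with `total` and `ph` columns.
#' @param subset optional logical or integer index selecting records
#'   before the pH filter (e.g. only the t0..t5 timepoints).
#' @return list (`correlation_result`) with `method`, `coefficient`, `n`,
#'   `df`, `p_value`.
#' @export
ph_vfa_correlation <- function(records, subset = NULL) {
  assert_columns(records, c("total", "ph"), "records")
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  ok <- !is.na(records$ph) & !is.na(records$total)
  records <- records[ok, , drop = FALSE]
  if (nrow(records) < 3) stop("need >= 3 complete (pH, total VFA) pairs")
  if (stats::sd(records$ph) == 0 || stats::sd(records$total) == 0) {
    stop("zero variance in pH or total VFA")
  }
  ct <- stats::cor.test(records$ph, records$total, method = "pearson")
  structure(list(method = "pearson", coefficient = unname(ct$estimate),
                 n = nrow(records), df = unname(ct$parameter),
                 p_value = ct$p.value), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (n = %d, p = %.3g)\n",
              x$method, x$coefficient, x$n, x$p_value))
  invisible(x)
}

#' Post-feeding fold change of gas emission rates
#'
#' Fold = mean rate in the post-feeding window / mean rate in the
#' pre-feeding window, per cow and averaged over cows, for each gas
#' column.
#'
#' @param gas gas series (columns `cow`, `hour` relative to feeding
#'   start, and one column per gas, e.g. `ch4`, `co2`, `h2`).
#' @param pre_window,post_window numeric length-2 half-open intervals
#'   (lo, hi] in hours relative to feeding start; must not overlap and
#'   must each contain at least one observation.
#' @param gases gas column names to evaluate.
#' @return list with `per_cow` (data.frame: cow, gas, fold) and `mean`
#'   (named vector of mean folds across cows).
#' @export
feeding_response <- function(gas, pre_window = c(-1, 0),
                             post_window = c(0, 1),
                             gases = intersect(c("ch4", "co2"),
                                               names(gas))) {
  assert_columns(gas, c("cow", "hour"), "gas")
  if (max(pre_window) > min(post_window)) stop("windows must not overlap")
  in_win <- function(h, w) h > w[1] & h <= w[2]
  rows <- list()
  for (cow in unique(gas$cow)) {
    g <- gas[gas$cow == cow, , drop = FALSE]
    pre <- g[in_win(g$hour, pre_window), , drop = FALSE]
    post <- g[in_win(g$hour, post_window), , drop = FALSE]
    if (nrow(pre) == 0 || nrow(post) == 0) {
      stop("empty observation window for cow ", cow)
    }
    for (gs in gases) {
      mpre <- mean(pre[[gs]])
      if (mpre == 0) stop("zero pre-feeding mean for ", gs, " in cow ", cow)
      rows[[length(rows) + 1L]] <- data.frame(
        cow = cow, gas = gs, fold = mean(post[[gs]]) / mpre,
        stringsAsFactors = FALSE)
    }
  }
  per_cow <- do.call(rbind, rows)
  list(per_cow = per_cow,
       mean = tapply(per_cow$fold, per_cow$gas, mean)[gases])
}

#' Correlate a quantified transcript series with a process series
#'
#' Aligns two per-(cow, timepoint) series and computes a Spearman rank
#' correlation (average-rank tie handling; exact permutation p for
#' n <= 8 without ties, asymptotic otherwise) or a Pearson correlation.
#'
#' @param transcripts data.frame with columns `cow`, `timepoint`,
#'   `value`.
#' @param process data.frame with the same columns.
#' @param method "spearman" (default) or "pearson".
#' @return `correlation_result` list (see [ph_vfa_correlation()]).
#' @export
correlate_transcripts_process <- function(transcripts, process,
                                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  assert_columns(transcripts, c("cow", "timepoint", "value"), "transcripts")
  assert_columns(process, c("cow", "timepoint", "value"), "process")
  key <- function(d) paste(d$cow, d$timepoint, sep = "|")
  m <- merge(transcripts, process, by = c("cow", "timepoint"),
             suffixes = c("_t", "_p"))
  if (nrow(m) < length(unique(key(transcripts))) ||
      nrow(m) < length(unique(key(process)))) {
    stop("transcript and process series are misaligned on (cow, timepoint)")
  }
  if (nrow(m) < 4) stop("need >= 4 aligned pairs")
  exact <- method == "spearman" && nrow(m) <= 8 &&
    !anyDuplicated(m$value_t) && !anyDuplicated(m$value_p)
  ct <- suppressWarnings(stats::cor.test(m$value_t, m$value_p,
                                         method = method, exact = exact))
  structure(list(method = method, coefficient = unname(ct$estimate),
                 n = nrow(m), df = if (method == "pearson") nrow(m) - 2 else NA,
                 p_value = ct$p.value), class = "correlation_result")
}

#' Paired t tests between consecutive timepoints
#'
#' Two-sided paired t test of a per-(cow, timepoint) series for every
#' consecutive timepoint transition, with significance stars at the
#' configurable thresholds. Zero-variance paired differences (no evidence
#' of change) return p = 1 with a message.
#'
#' @param series data.frame with columns `cow`, `timepoint`, `value`;
#'   every cow must be observed at both timepoints of a transition.
#' @param timepoints ordered character vector of timepoint labels.
#' @param thresholds two-element numeric: p cutoffs for "*" and "**".
#' @return data.frame with columns `from`, `to`, `mean_difference`,
#'   `t_statistic`, `df`, `p_value`, `stars`.
#' @export
paired_timepoint_tests <- function(series,
                                   timepoints = c("t0", "t1", "t3", "t5"),
                                   thresholds = c(0.05, 0.01)) {
  assert_columns(series, c("cow", "timepoint", "value"), "series")
  out <- list()
  for (i in seq_len(length(timepoints) - 1)) {
    a <- timepoints[i]; b <- timepoints[i + 1]
    sa <- series[series$timepoint == a, c("cow", "value")]
    sb <- series[series$timepoint == b, c("cow", "value")]
    m <- merge(sa, sb, by = "cow", suffixes = c("_a", "_b"))
    if (nrow(m) < 2) stop("fewer than 2 complete pairs for ", a, " -> ", b)
    diffs <- m$value_b - m$value_a
    if (stats::sd(diffs) == 0) {
      message("zero-variance paired differences for ", a, " -> ", b,
              "; p set to 1")
      res <- list(statistic = NA_real_, parameter = nrow(m) - 1, p.value = 1)
    } else {
      res <- stats::t.test(m$value_b, m$value_a, paired = TRUE)
    }
    p <- res$p.value
    stars <- if (p < thresholds[2]) "**" else if (p < thresholds[1]) "*" else ""
    out[[i]] <- data.frame(from = a, to = b, mean_difference = mean(diffs),
                           t_statistic = unname(res$statistic),
                           df = unname(res$parameter), p_value = p,
                           stars = stars, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Trimmed-mean scaling factor of sample col relative to reference ref
# (log2-ratio trimmed mean over functions expressed in both).
trimmed_mean_factor <- function(col, ref, trim = 0.3) {
  ok <- col > 0 & ref > 0
  if (!any(ok)) return(1)
  lr <- log2((col[ok] / sum(col)) / (ref[ok] / sum(ref)))
  2^mean(lr, trim = trim)
}

#' Screen functions for paired expression changes across a transition
#'
#' A simplified paired differential-expression procedure: counts are
#' normalized to counts-per-million with a trimmed-mean scaling factor per
#' sample (30% trimmed mean of log ratios to a reference sample), lowly
#' expressed functions are filtered, each remaining function is tested
#' with a two-sided paired t test on log2(CPM + 0.5) across cows, and
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param function_counts function count table (columns `sample`, `cow`,
#'   `timepoint`, `function_id`, `reads`).
#' @param design [study_design()] (cows define the pairing).
#' @param transition length-2 character vector, e.g. `c("t0", "t1")`.
#' @param fdr_q BH false-discovery threshold used for the `significant`
#'   flag.
#' @param min_cpm functions whose mean CPM falls below this are filtered
#'   out before testing.
#' @return data.frame with columns `function_id`, `log2_fold_change`,
#'   `t_statistic`, `p_value`, `p_adjusted`, `significant`, sorted by
#'   adjusted p.
#' @export
paired_function_screen <- function(function_counts, design = study_design(),
                                   transition = c("t0", "t1"),
                                   fdr_q = 0.05, min_cpm = 5) {
  assert_columns(function_counts, c("sample", "cow", "timepoint",
                                    "function_id", "reads"),
                 "function_counts")
  if (length(design$cows) < 2) stop("fewer than 2 cows")
  fc <- function_counts[function_counts$timepoint %in% transition, ,
                        drop = FALSE]
  have <- unique(fc[, c("cow", "timepoint")])
  for (cow in design$cows) {
    if (!all(transition %in% have$timepoint[have$cow == cow])) {
      stop("cow ", cow, " lacks counts at both transition timepoints")
    }
  }
  agg <- stats::aggregate(list(reads = fc$reads),
                          by = list(sample = fc$sample, cow = fc$cow,
                                    timepoint = fc$timepoint,
                                    function_id = fc$function_id),
                          FUN = sum)
  mat <- stats::xtabs(reads ~ function_id + sample, data = agg)
  mat <- unclass(mat)
  ref <- which.max(colSums(mat))
  cpm <- sapply(seq_len(ncol(mat)), function(j) {
    f <- trimmed_mean_factor(mat[, j], mat[, ref])
    mat[, j] / (sum(mat[, j]) * f) * 1e6
  })
  colnames(cpm) <- colnames(mat)
  keep <- rowMeans(cpm) >= min_cpm & rowSums(mat) > 0
  cpm <- cpm[keep, , drop = FALSE]
  if (nrow(cpm) == 0) stop("no functions pass the expression filter")
  logcpm <- log2(cpm + 0.5)

  meta <- unique(agg[, c("sample", "cow", "timepoint")])
  s_a <- meta$sample[match(paste(design$cows, transition[1]),
                           paste(meta$cow, meta$timepoint))]
  s_b <- meta$sample[match(paste(design$cows, transition[2]),
                           paste(meta$cow, meta$timepoint))]
  d <- logcpm[, s_b, drop = FALSE] - logcpm[, s_a, drop = FALSE]
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- apply(d, 1, stats::sd)
  tstat <- ifelse(sdd == 0, NA_real_, md / (sdd / sqrt(n)))
  p <- ifelse(sdd == 0, 1, 2 * stats::pt(-abs(tstat), df = n - 1))
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(function_id = rownames(d), log2_fold_change = md,
                    t_statistic = tstat, p_value = p, p_adjusted = p_adj,
                    significant = p_adj < fdr_q, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p_adjusted, out$p_value), , drop = FALSE]
}
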