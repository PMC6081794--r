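#' Summarize CAZyme counts into substrate categories
#'
#' Maps Pfam-annotated mRNA rows onto CAZyme substrate categories
#' (cellulases, hemicellulases, starch-degrading enzymes, oligosaccharide
#' hydrolases, minor categories), preserving the taxonomic attribution of
#' every row. Pfam rows not present in the catalog are collected under
#' "other" (with a message). Also reports the share of all CAZyme reads
#' captured by the four dominant categories.
#'
#' @param function_counts function count table (columns `sample`,
#'   `function_id`, `function_system`, `taxon`, `reads`); only
#'   `function_system == "pfam"` rows are used.
#' @param catalog [cazyme_catalog()] data.frame.
#' @return list with `table` (data.frame: sample, category, taxon, reads),
#'   `category_totals` (reads per category), `four_category_share`
#'   (fraction of CAZyme reads in the four dominant categories) and
#'   `per_sample_share` (the same share per sample).
#' @export
categorize_cazymes <- function(function_counts, catalog = cazyme_catalog()) {
  assert_columns(function_counts, c("sample", "function_id",
                                    "function_system", "taxon", "reads"),
                 "function_counts")
  pf <- function_counts[function_counts$function_system == "pfam", ,
                        drop = FALSE]
  if (nrow(pf) == 0 || nrow(catalog) == 0) {
    return(list(table = data.frame(sample = character(),
                                   category = character(),
                                   taxon = character(), reads = numeric()),
                category_totals = numeric(0),
                four_category_share = NA_real_,
                per_sample_share = numeric(0)))
  }
  category <- catalog$category[match(pf$function_id, catalog$pfam)]
  unmatched <- is.na(category)
  if (any(unmatched)) {
    message(length(unique(pf$function_id[unmatched])),
            " Pfam accession(s) not in the CAZyme catalog -> category 'other'")
    category[unmatched] <- "other"
  }
  tab <- stats::aggregate(
    list(reads = pf$reads),
    by = list(sample = pf$sample, category = category, taxon = pf$taxon),
    FUN = sum)
  totals <- tapply(tab$reads, tab$category, sum)
  dom <- dominant_cazyme_categories()
  per_sample <- sapply(split(tab, tab$sample), function(s) {
    sum(s$reads[s$category %in% dom]) / sum(s$reads)
  })
  list(table = tab,
       category_totals = totals,
       four_category_share = sum(totals[names(totals) %in% dom]) / sum(totals),
       per_sample_share = per_sample)
}

#' Step-normalized VFA pathway activity
#'
#' Sums quantified transcript abundances over the EC numbers of a pathway
#' (optionally restricted to a taxon) and divides by the number of
#' enzymatic steps, giving a per-sample activity in transcripts per gram.
#' ECs shared between pathways contribute to every pathway containing
#' them. With `production_specific_only = TRUE` only the ECs flagged as
#' production-specific enter the sum (n_steps is unchanged: it is a
#' pathway property).
#'
#' @param quantified quantified table from [quantify_table()] (mRNA rows
#'   with EC-number entities, `function_system == "ec"` when present).
#' @param pathway a [pathway_definition()].
#' @param taxon_filter optional character vector of taxa to include.
#' @param production_specific_only restrict to production-specific ECs.
#' @return data.frame with columns `sample`, `pathway`, `product`,
#'   `activity` (transcripts per gram per step).
#' @export
pathway_activity <- function(quantified, pathway, taxon_filter = NULL,
                             production_specific_only = FALSE) {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (pathway$n_steps == 0) stop("n_steps must be >= 1")
  assert_columns(quantified, c("sample", "entity", "taxon",
                               "transcripts_per_gram"), "quantified")
  ecs <- if (production_specific_only) pathway$production_specific
         else pathway$ec_numbers
  q <- quantified
  if ("function_system" %in% names(q)) {
    q <- q[q$function_system == "ec", , drop = FALSE]
  }
  q <- q[q$entity %in% ecs, , drop = FALSE]
  if (!is.null(taxon_filter)) q <- q[q$taxon %in% taxon_filter, , drop = FALSE]
  samples <- unique(quantified$sample)
  act <- vapply(samples, function(s) {
    sum(q$transcripts_per_gram[q$sample == s])
  }, numeric(1)) / pathway$n_steps
  data.frame(sample = samples, pathway = pathway$name,
             product = pathway$product, activity = unname(act),
             stringsAsFactors = FALSE)
}

#' Quantified methanogenesis marker series
#'
#' Aggregates quantified mRNA abundances over methanogenesis marker sets
#' per sample and taxon: mcrA (all methanogens), mtMA (sum of mtmB, mtbB
#' and mttB), mtrA, and mtaB with the Methanomassiliicoccales and
#' Methanosphaera contributions reported separately.
#'
#' @param quantified quantified table from [quantify_table()] (gene-entity
#'   mRNA rows).
#' @param markers named list of marker sets as returned by
#'   [marker_sets()].
#' @return data.frame with columns `sample`, `marker`, `taxon`,
#'   `transcripts_per_gram`; one row per (sample, marker, taxon)
#'   combination, zero-filled for samples without matching rows.
#' @export
methanogenesis_markers <- function(quantified, markers = marker_sets()) {
  assert_columns(quantified, c("sample", "entity", "taxon",
                               "transcripts_per_gram"), "quantified")
  vocabulary <- c("mcrA", "mtmB", "mtbB", "mttB", "mtrA", "mtaB")
  bad <- setdiff(unlist(lapply(markers, `[[`, "genes")), vocabulary)
  if (length(bad) > 0) {
    stop("unknown methanogenesis gene name(s) in marker set: ",
         paste(bad, collapse = ", "))
  }
  samples <- unique(quantified$sample)
  out <- list()
  for (m in names(markers)) {
    genes <- markers[[m]]$genes
    taxa <- markers[[m]]$taxa
    q <- quantified[quantified$entity %in% genes, , drop = FALSE]
    if (length(taxa) > 0) q <- q[q$taxon %in% taxa, , drop = FALSE]
    split_taxa <- if (length(taxa) > 0) taxa else
      (if (nrow(q) > 0) unique(q$taxon) else NA_character_)
    for (t in split_taxa) {
      qt <- if (is.na(t[1])) q else q[q$taxon == t, , drop = FALSE]
      v <- vapply(samples, function(s) {
        sum(qt$transcripts_per_gram[qt$sample == s])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        sample = samples, marker = m,
        taxon = if (is.na(t[1])) "all" else t,
        transcripts_per_gram = unname(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
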