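#' Physical constants for transcript quantification
#'
#' @param avogadro Avogadro constant, molecules per mole.
#' @param m_nt average molecular weight of a single-stranded nucleotide,
#'   in micrograms per mole (330e6 ug/mol).
#' @return object of class `physical_constants`.
#' @export
physical_constants <- function(avogadro = 6.02214076e23, m_nt = 330e6) {
  if (avogadro <= 0 || m_nt <= 0) stop("constants must be strictly positive")
  structure(list(avogadro = avogadro, m_nt = m_nt),
            class = "physical_constants")
}

#' Average transcript length model
#'
#' Average transcript lengths used to convert transcript mass into copy
#' numbers: 1,000 nt for mRNA and 1,500/1,900 nt for prokaryotic/eukaryotic
#' SSU rRNA.
#'
#' @param mrna_nt,ssu_prok_nt,ssu_euk_nt average lengths in nucleotides.
#' @return object of class `length_model`.
#' @export
length_model <- function(mrna_nt = 1000, ssu_prok_nt = 1500,
                         ssu_euk_nt = 1900) {
  if (any(c(mrna_nt, ssu_prok_nt, ssu_euk_nt) < 1)) {
    stop("transcript lengths must be >= 1 nt")
  }
  structure(list(mrna_nt = mrna_nt, ssu_prok_nt = ssu_prok_nt,
                 ssu_euk_nt = ssu_euk_nt), class = "length_model")
}

#' Read-class fraction policy
#'
#' Controls the x/(x+y) read-class term of the quantification formula for
#' mRNA entities. Polyadenylation during cDNA synthesis moderately
#' enriches mRNA, so under the default `fixed_ratio` mode the mRNA share
#' of total RNA is fixed at `mrna_total_ratio` (1:25) rather than taken
#' from the observed (enriched) read counts; `observed` uses
#' `mrna_reads/total_reads` as sequenced. SSU rRNA always uses the
#' observed `ssu_reads/total_reads` share: the fixed ratio corrects the
#' mRNA enrichment specifically.
#'
#' @param mode "fixed_ratio" or "observed".
#' @param mrna_total_ratio mRNA/total RNA read ratio in (0,1).
#' @return object of class `class_fraction_policy`.
#' @export
class_fraction_policy <- function(mode = c("fixed_ratio", "observed"),
                                  mrna_total_ratio = 1 / 25) {
  mode <- match.arg(mode)
  if (mrna_total_ratio <= 0 || mrna_total_ratio >= 1) {
    stop("mrna_total_ratio must lie in (0,1)")
  }
  structure(list(mode = mode, mrna_total_ratio = mrna_total_ratio),
            class = "class_fraction_policy")
}

#' Read-class fraction for one sample and entity kind
#'
#' @param policy [class_fraction_policy()].
#' @param counts one read-class record (a one-row data.frame or list with
#'   `total_reads`, `ssu_reads`, `mrna_reads`).
#' @param entity_kind "mRNA" or "SSU" (SSU-prok / SSU-euk are accepted).
#' @return fraction in [0,1].
#' @export
class_fraction <- function(policy, counts, entity_kind) {
  stopifnot(inherits(policy, "class_fraction_policy"))
  if (is.null(counts$total_reads) || any(counts$total_reads == 0)) {
    stop("total_reads must be positive")
  }
  kind <- if (grepl("^SSU", entity_kind)) "SSU" else entity_kind
  switch(kind,
    mRNA = if (policy$mode == "fixed_ratio") policy$mrna_total_ratio
           else counts$mrna_reads / counts$total_reads,
    SSU = counts$ssu_reads / counts$total_reads,
    stop("unknown entity kind: ", entity_kind))
}

#' Quantify one transcript: copies per gram of rumen fluid
#'
#' Converts a relative read count into an absolute transcript
#' concentration:
#' \deqn{A = \mathrm{RNA} \times \frac{x}{x+y} \times \frac{A_r}{n_{sub}}
#'   \times \frac{N_A}{M(\mathrm{Nt}) \times L_A}}
#' where RNA is the total RNA yield (ug per g rumen fluid), x/(x+y) the
#' read-class fraction, \eqn{A_r/n_{sub}} the share of the classified
#' subsample assigned to the transcript, \eqn{N_A} the Avogadro constant,
#' M(Nt) the nucleotide molecular weight (ug/mol) and \eqn{L_A} the
#' average transcript length (nt). Vectorized over all arguments.
#'
#' @param yield_ug total RNA in micrograms per gram of rumen fluid.
#' @param fraction read-class fraction in [0,1].
#' @param assigned_reads reads assigned to the transcript
#'   (<= subsample_size).
#' @param subsample_size classified subsample size (>= 1).
#' @param length_nt average transcript length in nucleotides.
#' @param constants [physical_constants()].
#' @return transcripts per gram of rumen fluid (double; a concentration,
#'   not rounded to integers).
#' @examples
#' # 50 ug/g, 1:25 mRNA fraction, 100 of 10,000 subsampled reads, 1 kb:
#' quantify_transcript(50, 0.04, 100, 10000, 1000)  # ~3.65e10 per g
#' @export
quantify_transcript <- function(yield_ug, fraction, assigned_reads,
                                subsample_size, length_nt,
                                constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (any(subsample_size < 1)) stop("subsample_size must be >= 1")
  if (any(assigned_reads < 0) || any(yield_ug < 0) || any(fraction < 0) ||
      any(length_nt < 1)) {
    stop("negative inputs are not allowed")
  }
  if (any(assigned_reads > subsample_size)) {
    stop("assigned_reads must not exceed subsample_size")
  }
  yield_ug * fraction * (assigned_reads / subsample_size) *
    constants$avogadro / (constants$m_nt * length_nt)
}

# Resolve deepest assigned taxon label of a hierarchy row set.
deepest_label <- function(tab) {
  ranks <- c("genus", "family", "class", "phylum", "domain")
  out <- rep(NA_character_, nrow(tab))
  for (r in ranks) {
    idx <- is.na(out) & !is.na(tab[[r]])
    out[idx] <- tab[[r]][idx]
  }
  out[is.na(out)] <- "unassigned"
  out
}

#' Quantify a taxon or function count table
#'
#' Applies [quantify_transcript()] row-wise to a taxon (SSU rRNA) or
#' function (mRNA) count table. SSU entities labelled Eukaryota use the
#' eukaryotic SSU length, all other SSU entities the prokaryotic length
#' (rows without a domain assignment fall back to the prokaryotic length
#' and are flagged in `length_defaulted`); mRNA entities use the mRNA
#' length. LSU rRNA is never quantified; LSU reads only contribute to the
#' read totals.
#'
#' @param yields data.frame with columns `sample`,
#'   `micrograms_per_gram`.
#' @param read_class data.frame with per-sample read-class counts
#'   (columns `sample`, `total_reads`, `ssu_reads`, `mrna_reads`,
#'   `ssu_subsample_size`, `mrna_subsample_size`).
#' @param assignments taxon count table (columns `sample`, `domain` ...
#'   `genus`, `reads`) or function count table (columns `sample`,
#'   `function_id`, `function_system`, `taxon`, `reads`).
#' @param policy [class_fraction_policy()].
#' @param lengths [length_model()].
#' @param constants [physical_constants()].
#' @return quantified table: data.frame with columns `sample`, `entity`,
#'   `kind` ("mRNA", "SSU-prok" or "SSU-euk"), `taxon`,
#'   `transcripts_per_gram`, `assigned_reads`, `subsample_size`,
#'   `length_defaulted`, plus `cow`/`timepoint` and the taxon rank columns
#'   when present in the input.
#' @export
quantify_table <- function(yields, read_class, assignments,
                           policy = class_fraction_policy(),
                           lengths = length_model(),
                           constants = physical_constants()) {
  assert_columns(yields, c("sample", "micrograms_per_gram"), "yields")
  assert_columns(read_class, c("sample", "total_reads", "ssu_reads",
                               "mrna_reads", "ssu_subsample_size",
                               "mrna_subsample_size"), "read_class")
  samples <- unique(assignments$sample)
  for (what in list(yields, read_class)) {
    miss <- setdiff(samples, what$sample)
    if (length(miss) > 0) {
      stop("missing per-sample metadata for sample(s): ",
           paste(miss, collapse = ", "))
    }
  }
  is_function_table <- "function_id" %in% names(assignments)
  yi <- match(assignments$sample, yields$sample)
  ri <- match(assignments$sample, read_class$sample)
  yield <- yields$micrograms_per_gram[yi]

  if (is_function_table) {
    kind <- rep("mRNA", nrow(assignments))
    length_nt <- rep(lengths$mrna_nt, nrow(assignments))
    defaulted <- rep(FALSE, nrow(assignments))
    subsample <- read_class$mrna_subsample_size[ri]
    entity <- assignments$function_id
    taxon <- assignments$taxon
  } else {
    assert_columns(assignments, c("domain", "reads"), "taxon assignments")
    euk <- !is.na(assignments$domain) & assignments$domain == "Eukaryota"
    defaulted <- is.na(assignments$domain)
    kind <- ifelse(euk, "SSU-euk", "SSU-prok")
    length_nt <- ifelse(euk, lengths$ssu_euk_nt, lengths$ssu_prok_nt)
    subsample <- read_class$ssu_subsample_size[ri]
    entity <- deepest_label(assignments)
    taxon <- entity
  }
  fraction <- vapply(seq_along(ri), function(i) {
    class_fraction(policy, read_class[ri[i], ], kind[i])
  }, numeric(1))
  tpg <- quantify_transcript(yield, fraction, assignments$reads, subsample,
                             length_nt, constants)
  out <- data.frame(sample = assignments$sample, entity = entity,
                    kind = kind, taxon = taxon, transcripts_per_gram = tpg,
                    assigned_reads = assignments$reads,
                    subsample_size = subsample,
                    length_defaulted = defaulted, stringsAsFactors = FALSE)
  for (col in c("cow", "timepoint", "function_system",
                "domain", "phylum", "class", "family", "genus")) {
    if (col %in% names(assignments)) out[[col]] <- assignments[[col]]
  }
  out
}
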