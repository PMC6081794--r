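# Tab-separated readers/writers with schema validation, and the packaged
# VFA/pH reference table.

table_schemas <- function() {
  list(
    taxon_counts = list(
      required = c("sample", "cow", "timepoint", "domain", "phylum",
                   "class", "family", "genus", "reads"),
      numeric = "reads", non_negative = "reads",
      key = c("sample", "domain", "phylum", "class", "family", "genus")),
    function_counts = list(
      required = c("sample", "function_id", "function_system", "taxon",
                   "reads"),
      numeric = "reads", non_negative = "reads",
      key = c("sample", "function_id", "taxon")),
    read_class = list(
      required = c("sample", "total_reads", "ssu_reads", "lsu_reads",
                   "mrna_reads", "ssu_subsample_size", "mrna_subsample_size"),
      numeric = c("total_reads", "ssu_reads", "lsu_reads", "mrna_reads",
                  "ssu_subsample_size", "mrna_subsample_size"),
      non_negative = c("total_reads", "ssu_reads", "lsu_reads", "mrna_reads"),
      key = "sample"),
    rna_yield = list(
      required = c("sample", "micrograms_per_gram"),
      numeric = "micrograms_per_gram", positive = "micrograms_per_gram",
      key = "sample"),
    vfa = list(
      required = c("cow", "timepoint", vfa_acid_columns(), "total", "ph"),
      numeric = c(vfa_acid_columns(), "total", "ph"),
      non_negative = vfa_acid_columns(), key = NULL),
    gas = list(
      required = c("cow", "hour", "ch4", "co2", "h2"),
      numeric = c("hour", "ch4", "co2", "h2"),
      non_negative = c("ch4", "co2", "h2"), key = NULL),
    quantified = list(
      required = c("sample", "entity", "kind", "taxon",
                   "transcripts_per_gram", "assigned_reads",
                   "subsample_size"),
      numeric = c("transcripts_per_gram", "assigned_reads",
                  "subsample_size"),
      non_negative = c("transcripts_per_gram", "assigned_reads"),
      key = NULL)
  )
}

#' Read and validate a pipeline table
#'
#' Reads a UTF-8, tab-delimited table ("." decimal separator; `#`-prefixed
#' header comments are skipped) and validates it against one of the named
#' pipeline schemas. Validation failures report the offending line number
#' and column.
#'
#' @param path file path.
#' @param schema one of "taxon_counts", "function_counts", "read_class",
#'   "rna_yield", "vfa", "gas", "quantified".
#' @return validated data.frame.
#' @export
read_table <- function(path, schema = c("taxon_counts", "function_counts",
                                        "read_class", "rna_yield", "vfa",
                                        "gas", "quantified")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- table_schemas()[[schema]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  miss <- setdiff(sc$required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  # line numbers in the file: header is line 1 (+ any leading comments)
  n_comment <- 0
  con <- file(path, "r"); on.exit(close(con))
  while (grepl("^#", readLines(con, n = 1))) n_comment <- n_comment + 1
  line_of <- function(i) i + 1 + n_comment
  for (col in sc$numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, col, line_of(bad)))
    }
  }
  for (col in sc$non_negative) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("%s: negative value in column '%s' at line %d",
                   path, col, line_of(bad[1])))
    }
  }
  for (col in sc$positive %||% character()) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("%s: non-positive value in column '%s' at line %d",
                   path, col, line_of(bad[1])))
    }
  }
  if (!is.null(sc$key)) {
    key_cols <- intersect(sc$key, names(df))
    key <- do.call(paste, c(df[key_cols], sep = "\r"))
    if (anyDuplicated(key)) {
      stop(sprintf("%s: duplicate key (%s) at line %d", path,
                   paste(key_cols, collapse = ", "),
                   line_of(which(duplicated(key))[1])))
    }
  }
  df
}

#' Write a pipeline table
#'
#' Writes a tab-delimited table with a header comment carrying the package
#' version, the seed and a configuration digest, so every output file
#' records its provenance. `read_table()` skips these comments, making
#' write/read round trips value-identical.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the header (NA if not applicable).
#' @param config_hash short configuration digest recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, seed = NA, config_hash = "") {
  header <- sprintf("# rumiquant %s | seed=%s | config=%s",
                    as.character(utils::packageVersion("rumiquant")),
                    as.character(seed), config_hash)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Parses a plain `key = value` text file (one setting per line, `#`
#' comments allowed) into the settings list [run_pipeline()] accepts.
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical; everything else stays character.
#'
#' @param path configuration file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  out
}

# Cheap deterministic digest of a configuration list (no external deps).
config_digest <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' The packaged rumen VFA and pH reference table
#'
#' Volatile fatty acid concentrations (nmol per g rumen fluid) and pH of
#' 28 rumen fluid samples from four cows sampled over a feeding day
#' (4 a.m. to 4 p.m.); the four metatranscriptome timepoints t0/t1/t3/t5
#' are labelled and carry pH measurements (16 samples), the remaining
#' clock-time samples do not. Printed row totals differ from the acid sums
#' by at most 0.2 (rounding of the printed concentrations).
#'
#' @return data.frame with columns `cow`, `time`, `timepoint`, one column
#'   per acid, `total`, `ph`.
#' @export
rumen_vfa_table1 <- function() {
  path <- system.file("extdata", "table1_vfa.tsv", package = "rumiquant",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df$cow <- as.character(df$cow)
  df
}
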