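#' Define a feeding-trial study design
#'
#' A study design enumerates the cows and the sampling time points of a
#' diurnal feeding trial and is the blocking structure for all statistics in
#' the package. The default mirrors a 4-cow experiment sampled immediately
#' before the morning feeding (t0) and 1, 3 and 5 hours after feeding
#' started (t1, t3, t5).
#'
#' @param cows character vector of cow identifiers (at least two).
#' @param timepoints named numeric vector of hour offsets relative to
#'   feeding start, strictly increasing; names are the canonical timepoint
#'   labels.
#' @param feeding_start clock hour at which the morning feeding starts
#'   (only used to translate clock times in external tables).
#'
#' @return An object of class `study_design`: a list with elements `cows`,
#'   `timepoints`, `feeding_start` and `samples`, the latter a data.frame
#'   with one row per (cow, timepoint) pair and columns `sample`, `cow`,
#'   `timepoint`, `hour`.
#' @examples
#' d <- study_design()
#' d$samples
#' @export
study_design <- function(cows = paste0("cow", 1:4),
                         timepoints = c(t0 = 0, t1 = 1, t3 = 3, t5 = 5),
                         feeding_start = 7) {
  cows <- as.character(cows)
  if (length(cows) < 2) stop("a study design needs at least two cows")
  if (anyDuplicated(cows)) stop("cow identifiers must be unique")
  if (is.null(names(timepoints)) || any(names(timepoints) == "")) {
    stop("timepoints must be a named numeric vector of hour offsets")
  }
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  samples <- expand.grid(timepoint = names(timepoints), cow = cows,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("cow", "timepoint")]
  samples$hour <- unname(timepoints[samples$timepoint])
  samples$sample <- paste(samples$cow, samples$timepoint, sep = "_")
  samples <- samples[order(samples$cow, samples$hour),
                     c("sample", "cow", "timepoint", "hour")]
  rownames(samples) <- NULL
  structure(list(cows = cows, timepoints = timepoints,
                 feeding_start = feeding_start, samples = samples),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d cows x %d timepoints (%s)\n",
              length(x$cows), length(x$timepoints),
              paste(names(x$timepoints), collapse = ", ")))
  invisible(x)
}

is_study_design <- function(x) inherits(x, "study_design")
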