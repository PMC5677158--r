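#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

abort_bad_arg <- function(msg, ...) abort(msg, class = "cc_invalid_argument", ...)
abort_capacity <- function(msg, ...) abort(msg, class = "cc_capacity_error", ...)
abort_format <- function(msg, ...) abort(msg, class = "cc_format_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "cc_config_error", ...)
abort_io <- function(msg, ...) abort(msg, class = "cc_io_error", ...)

#' Chromosome sizes of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] as returned by [sim_genome()] or
#'   [read_genome()].
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  stats::setNames(Biostrings::width(genome), names(genome))
}

# feature classes recognised throughout the package
feature_classes <- function() {
  c("ACS_CONFIRMED_LIKELY", "ACS_DUBIOUS", "ORC1", "CENTROMERE", "TSS")
}

check_scalar_number <- function(x, name, min = -Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    abort_bad_arg(sprintf("`%s` must be a single number", name))
  }
  if (x < min) abort_bad_arg(sprintf("`%s` must be >= %s", name, min))
  invisible(x)
}

# midpoint convention used for every feature-centred computation
interval_midpoint <- function(start, end) as.integer(floor((start + end) / 2))
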