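#' Reads-per-million signal track
#'
#' The quantitative normalisation: the value at each genomic position is
#' `1e6 * reads at that position / total aligned reads in the library`.
#' Strands at the same position are summed (display tracks are unstranded),
#' so the track always sums to exactly 1e6 when every aligned read belongs
#' to an event.
#'
#' @param events Insertion-set tibble from [call_insertions()] or
#'   [as_insertion_set()].
#' @param total Library denominator; defaults to the set's
#'   `total_aligned_reads` attribute. Must be > 0.
#' @return A track tibble with columns `chrom`, `pos`, `value` and attributes
#'   `mode = "RPM"` and `total`.
#' @export
rpm_track <- function(events, total = total_aligned_reads(events)) {
  if (is.null(total) || !is.finite(total) || total <= 0) {
    abort_bad_arg("`total` aligned reads must be > 0 for RPM normalisation")
  }
  track <- events %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::summarise(value = 1e6 * sum(.data$read_count) / total,
                     .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$pos)
  attr(track, "mode") <- "RPM"
  attr(track, "total") <- total
  track
}

#' Unique-insertion indicator track
#'
#' The positional normalisation: 1 at every genomic position carrying at
#' least one insertion event, regardless of how many reads (or
#' opposite-strand events) support it. Erases inverse-PCR amplification bias
#' entirely, so every peak has the same height.
#'
#' @param events Insertion-set tibble.
#' @return A track tibble with columns `chrom`, `pos`, `value` (all 1) and
#'   attribute `mode = "UNIQUE"`.
#' @export
unique_track <- function(events) {
  track <- events %>%
    dplyr::distinct(.data$chrom, .data$pos) %>%
    dplyr::mutate(value = 1) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  attr(track, "mode") <- "UNIQUE"
  track
}

# ---- bedGraph serialization -------------------------------------------------

write_bedgraph_intervals <- function(df, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header)) lines <- header
  if (nrow(df) > 0) {
    df <- dplyr::arrange(df, .data$chrom, .data$start)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", df$chrom,
                              as.integer(df$start), as.integer(df$end),
                              formatC(df$value, digits = 12, format = "g")))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

read_bedgraph_intervals <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- which(keep)
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = numeric()))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    abort_format(sprintf("malformed bedGraph line %d in %s", rows[bad[1]],
                         path))
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) {
    abort_format(sprintf("malformed bedGraph line %d in %s", rows[bad[1]],
                         path))
  }
  tibble::tibble(chrom = m[, 1], start = start, end = end, value = value)
}

#' Read / write a signal track as bedGraph
#'
#' Tracks are written as 0-based half-open single-base intervals, sorted per
#' chromosome, with the normalisation mode recorded in a `#` header comment.
#' `read_bedgraph(write_bedgraph(t))` reproduces the track to better than
#' 1e-9 relative tolerance.
#'
#' @param track Track tibble from [rpm_track()] or [unique_track()].
#' @param path File path.
#' @return `read_bedgraph()` returns a track tibble with the `mode`
#'   attribute restored; `write_bedgraph()` returns `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write_bedgraph_intervals(
    tibble::tibble(chrom = track$chrom, start = track$pos,
                   end = track$pos + 1L, value = track$value),
    path, header = sprintf("# callingcardr track mode=%s",
                           attr(track, "mode") %||% "RPM"))
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  mode <- if (length(first) && grepl("mode=", first)) {
    sub("^.*mode=", "", first)
  } else NA_character_
  bg <- read_bedgraph_intervals(path)
  if (nrow(bg) > 0 && any(bg$end - bg$start != 1L)) {
    abort_format("signal-track bedGraph must contain single-base intervals")
  }
  track <- tibble::tibble(chrom = bg$chrom, pos = bg$start, value = bg$value)
  attr(track, "mode") <- mode
  track
}
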