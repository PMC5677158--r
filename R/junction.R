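#' Trim the Ty5 junction tag from reads
#'
#' A junction read begins with the fixed Ty5 terminal tag followed by genomic
#' sequence. Reads whose prefix matches the tag within `max_mismatch`
#' Hamming distance are trimmed to their genomic fragment; others are flagged
#' `NO_TAG`. Fragments shorter than `min_frag` are flagged `TOO_SHORT`.
#'
#' @param reads Read tibble with columns `id`, `seq` (and optionally `qual`,
#'   `digest`).
#' @param tag Tag sequence (>= 8 bp).
#' @param max_mismatch Maximum Hamming mismatches allowed in the tag prefix.
#' @param min_frag Minimum genomic-fragment length to keep (default 18).
#' @return The input tibble with added columns `fragment` and `status`
#'   (`OK`, `NO_TAG` or `TOO_SHORT`).
#' @export
trim_junction <- function(reads, tag, max_mismatch = 0L, min_frag = 18L) {
  if (nchar(tag) < 8) abort_bad_arg("`tag` must be at least 8 bp")
  if (nrow(reads) > 0 && any(nchar(reads$seq) == 0)) {
    abort_bad_arg("empty read sequence")
  }
  t_len <- nchar(tag)
  tag_raw <- charToRaw(tag)
  prefix <- substr(reads$seq, 1L, t_len)
  # reads from one library share few distinct prefixes; compare each once
  u <- unique(prefix)
  mm <- vapply(u, function(p) {
    if (nchar(p) < t_len) return(t_len)
    sum(charToRaw(p) != tag_raw)
  }, integer(1))
  ok_tag <- unname(mm[match(prefix, u)] <= max_mismatch)
  fragment <- ifelse(ok_tag, substr(reads$seq, t_len + 1L, nchar(reads$seq)),
                     NA_character_)
  status <- dplyr::case_when(
    !ok_tag ~ "NO_TAG",
    nchar(fragment) < min_frag ~ "TOO_SHORT",
    TRUE ~ "OK")
  fragment[status != "OK"] <- NA_character_
  dplyr::mutate(reads, fragment = fragment, status = status)
}

# exact occurrences of a set of fragments on both strands of the genome;
# returns, per fragment, the total hit count and (if unique) the junction
# coordinate: for a plus-strand hit the match start, for a minus-strand hit
# the plus-strand coordinate of the match's last base (the base adjacent to
# the tag reads outward on the minus strand).
locate_fragments <- function(fragments, genome) {
  sizes <- chrom_sizes(genome)
  rc <- Biostrings::reverseComplement(genome)
  res <- tibble::tibble(fragment = fragments, n_hits = 0L,
                        chrom = NA_character_, pos = NA_integer_,
                        strand = NA_character_)
  valid <- grepl("^[ACGT]+$", fragments)
  by_width <- split(which(valid), nchar(fragments[valid]))
  for (w in names(by_width)) {
    idx <- by_width[[w]]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(res$fragment[idx]))
    for (ch in names(sizes)) {
      L <- sizes[[ch]]
      for (str in c("+", "-")) {
        subject <- if (str == "+") genome[[ch]] else rc[[ch]]
        m <- Biostrings::matchPDict(pd, subject)
        starts <- BiocGenerics::start(m)   # list: 1-based starts per pattern
        hit_n <- lengths(starts)
        has <- which(hit_n > 0L)
        for (j in has) {
          i <- idx[j]
          first <- starts[[j]][1]
          # 1-based start s on plus strand -> junction 0-based s-1;
          # on the reverse complement, rc index s maps to plus 0-based L-s
          p <- if (str == "+") first - 1L else L - first
          if (res$n_hits[i] == 0L) {
            res$chrom[i] <- ch
            res$pos[i] <- as.integer(p)
            res$strand[i] <- str
          }
          res$n_hits[i] <- res$n_hits[i] + hit_n[j]
        }
      }
    }
  }
  res
}

#' Map genomic fragments with an exact both-strand lookup
#'
#' Replaces an external aligner at desk scale: each fragment is located as an
#' exact substring of either strand of the genome. Exactly one occurrence
#' across both strands gives a `UNIQUE` call whose `pos` is the 0-based
#' plus-strand coordinate of the fragment base adjacent to the Ty5 tag (the
#' junction base) and whose `strand` is the matching strand; more than one
#' occurrence gives `MULTI`; none (or a non-ACGT fragment) gives `UNMAPPED`.
#'
#' @param trimmed Tibble from [trim_junction()]; rows whose `status` is not
#'   `OK` pass through unchanged.
#' @param genome A [Biostrings::DNAStringSet].
#' @return The input tibble with `status` updated to
#'   `UNIQUE`/`MULTI`/`UNMAPPED` for mapped rows and columns `chrom`, `pos`,
#'   `strand` filled for `UNIQUE` rows.
#' @export
map_fragments <- function(trimmed, genome) {
  out <- dplyr::mutate(trimmed, chrom = NA_character_, pos = NA_integer_,
                       strand = NA_character_)
  todo <- which(out$status == "OK")
  if (length(todo) == 0) return(out)
  frags <- unique(out$fragment[todo])
  loc <- locate_fragments(frags, genome)
  hit <- loc[match(out$fragment[todo], loc$fragment), ]
  out$status[todo] <- dplyr::case_when(
    hit$n_hits == 1L ~ "UNIQUE",
    hit$n_hits > 1L ~ "MULTI",
    TRUE ~ "UNMAPPED")
  uniq <- hit$n_hits == 1L
  out$chrom[todo[uniq]] <- hit$chrom[uniq]
  out$pos[todo[uniq]] <- hit$pos[uniq]
  out$strand[todo[uniq]] <- hit$strand[uniq]
  out
}

#' Collapse unique mappings into deduplicated insertion events
#'
#' Groups `UNIQUE` mappings by (chrom, position, strand): each group is one
#' Ty5 insertion event whose `read_count` is the number of reads supporting
#' it (inverse-PCR amplification collapses here) and whose `digests` records
#' which restriction digests recovered it. All other mapping statuses are
#' tallied in a QC report and never become events.
#'
#' @param mappings Tibble from [map_fragments()] or [import_sam()].
#' @param construct Construct/strain label for the library.
#' @param merge_strands If `TRUE`, opposite-strand events at the same
#'   position are merged (default `FALSE`: Ty5 integrates directionally and
#'   the two orientations are distinct molecular events).
#' @return An insertion-set tibble with columns `chrom`, `pos`, `strand`,
#'   `read_count`, `digests`, carrying attributes `construct`,
#'   `total_aligned_reads` (number of `UNIQUE` mappings) and `qc` (named
#'   status counts). Use [qc_report()] / [total_aligned_reads()] to read
#'   them.
#' @export
call_insertions <- function(mappings, construct = "construct",
                            merge_strands = FALSE) {
  statuses <- c("UNIQUE", "MULTI", "UNMAPPED", "NO_TAG", "TOO_SHORT")
  qc <- stats::setNames(integer(length(statuses)), statuses)
  tab <- table(factor(mappings$status, levels = statuses))
  qc[names(tab)] <- as.integer(tab)
  uniq <- dplyr::filter(mappings, .data$status == "UNIQUE")
  if (!"digest" %in% names(uniq)) uniq$digest <- NA_character_
  keys <- if (merge_strands) c("chrom", "pos") else c("chrom", "pos", "strand")
  events <- uniq %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      read_count = dplyr::n(),
      digests = paste(sort(unique(stats::na.omit(.data$digest))),
                      collapse = ","),
      .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$pos)
  if (merge_strands) events$strand <- "*"
  events <- dplyr::select(events, "chrom", "pos", "strand", "read_count",
                          "digests")
  attr(events, "construct") <- construct
  attr(events, "total_aligned_reads") <- sum(qc["UNIQUE"])
  attr(events, "qc") <- qc
  events
}

#' Accessors for insertion-set metadata
#'
#' @param x An insertion-set tibble from [call_insertions()].
#' @return `qc_report()` the named status counts; `total_aligned_reads()` the
#'   library denominator (number of uniquely aligned reads);
#'   `construct_label()` the construct label.
#' @export
qc_report <- function(x) attr(x, "qc")

#' @rdname qc_report
#' @export
total_aligned_reads <- function(x) attr(x, "total_aligned_reads")

#' @rdname qc_report
#' @export
construct_label <- function(x) attr(x, "construct")

#' Build an insertion set directly from a simulation truth table
#'
#' Bypasses sequencing: every ground-truth insertion becomes an event with
#' `read_count = n_reads`. Useful for studying the normalisation and
#' meta-analysis stages in isolation from the read model.
#'
#' @param truth Ground-truth tibble from [sim_insertions()].
#' @param construct Construct label.
#' @return An insertion-set tibble (see [call_insertions()]).
#' @export
as_insertion_set <- function(truth, construct = "truth") {
  events <- truth %>%
    dplyr::transmute(chrom = .data$chrom, pos = .data$pos,
                     strand = .data$strand, read_count = .data$n_reads,
                     digests = "") %>%
    dplyr::arrange(.data$chrom, .data$pos)
  attr(events, "construct") <- construct
  attr(events, "total_aligned_reads") <- sum(truth$n_reads)
  attr(events, "qc") <- c(UNIQUE = sum(truth$n_reads), MULTI = 0L,
                          UNMAPPED = 0L, NO_TAG = 0L, TOO_SHORT = 0L)
  events
}

#' Read / write insertion events as TSV
#'
#' @param events Insertion-set tibble.
#' @param path File path.
#' @param construct,total_aligned_reads Metadata recovered on read (stored in
#'   `#`-comment header lines on write).
#' @return `read_insertions()` returns an insertion-set tibble;
#'   `write_insertions()` returns `path` invisibly.
#' @export
write_insertions <- function(events, path) {
  hdr <- c(sprintf("# construct=%s", construct_label(events) %||% ""),
           sprintf("# total_aligned_reads=%d",
                   as.integer(total_aligned_reads(events) %||% 0L)))
  readr::write_lines(hdr, path)
  readr::write_tsv(events, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_insertions
#' @export
read_insertions <- function(path) {
  hdr <- readr::read_lines(path, n_max = 2, progress = FALSE)
  events <- readr::read_tsv(path, comment = "#", col_types = "cicic",
                            progress = FALSE)
  attr(events, "construct") <- sub("^# construct=", "", hdr[1])
  attr(events, "total_aligned_reads") <-
    as.integer(sub("^# total_aligned_reads=", "", hdr[2]))
  events
}

#' Import externally aligned junction reads from SAM/BAM
#'
#' For data aligned outside the package (reads must already be
#' junction-trimmed). Primary mapped records become `UNIQUE` calls: on the
#' plus strand the junction base is the 1-based `POS` converted to 0-based;
#' on the minus strand it is the last aligned base, i.e. the 0-based
#' exclusive alignment end minus one. Secondary/supplementary records are
#' flagged `MULTI`, unmapped records `UNMAPPED`.
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly).
#' @param genome_names Character vector of valid reference names; a record
#'   aligned to any other reference raises a format error.
#' @return A mapping tibble compatible with [call_insertions()].
#' @export
import_sam <- function(path, genome_names = NULL) {
  rlang::check_installed(c("Rsamtools", "GenomicAlignments"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand")))[[1]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  rname <- as.character(b$rname)
  if (!is.null(genome_names)) {
    bad <- which(!unmapped & !is.na(rname) & !(rname %in% genome_names))
    if (length(bad)) {
      abort_format(sprintf("unknown reference '%s' for record '%s'",
                           rname[bad[1]], b$qname[bad[1]]))
    }
  }
  ref_width <- rep(NA_integer_, length(flag))
  has_cigar <- !unmapped & !is.na(b$cigar)
  ref_width[has_cigar] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[has_cigar])
  minus <- as.character(b$strand) == "-"
  pos0 <- ifelse(minus, b$pos - 1L + ref_width - 1L, b$pos - 1L)
  tibble::tibble(
    id = b$qname,
    status = dplyr::case_when(unmapped ~ "UNMAPPED",
                              secondary ~ "MULTI",
                              TRUE ~ "UNIQUE"),
    chrom = ifelse(unmapped | secondary, NA_character_, rname),
    pos = ifelse(unmapped | secondary, NA_integer_, as.integer(pos0)),
    strand = dplyr::case_when(unmapped | secondary ~ NA_character_,
                              minus ~ "-", TRUE ~ "+"),
    digest = NA_character_)
}
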