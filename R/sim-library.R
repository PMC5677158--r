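#' Simulate a junction-read library from ground-truth insertions
#'
#' Models the calling-cards library preparation: genomic DNA is digested in
#' three separate restriction reactions, fragments are circularised and the
#' DNA flanking each Ty5 junction is recovered by inverse PCR, so each read
#' is the fixed Ty5 terminal tag followed by genomic sequence starting at the
#' junction base and running towards the nearest downstream recognition site
#' on the insertion strand. An insertion's `n_reads` amplified reads are
#' split as evenly as possible across the enzyme digests (remainders rotate
#' with insertion index, mirroring pooling of the three reactions). An
#' insertion-digest pair with no downstream recognition site before the
#' chromosome end escapes digestion: its fragment is dropped and counted.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param truth Ground-truth tibble from [sim_insertions()].
#' @param params A `cc_sim_params` object (defaults to the one attached to
#'   `truth`).
#' @return A read tibble with columns `id`, `seq`, `qual`, `digest`, plus
#'   attributes `reads_emitted`, `reads_dropped`, `fragments_dropped` and
#'   `reads_expected` (= sum of `n_reads`).
#' @export
sim_library <- function(genome, truth, params = attr(truth, "params")) {
  stopifnot(inherits(params, "cc_sim_params"))
  sizes <- chrom_sizes(genome)
  if (nrow(truth) > 0 &&
      (any(!truth$chrom %in% names(sizes)) ||
       any(truth$pos < 0 | truth$pos >= sizes[truth$chrom]))) {
    abort_bad_arg("truth insertion outside the genome")
  }
  enzymes <- params$enzymes
  K <- length(enzymes)
  tag <- params$tag
  frag_len <- params$read_length - nchar(tag)

  # recognition-site start positions per chromosome, plus strand and
  # reverse-complement coordinates (search is strand-symmetric via revcomp)
  seq_chr <- stats::setNames(as.character(genome), names(genome))
  rc_chr <- stats::setNames(
    as.character(Biostrings::reverseComplement(genome)), names(genome))
  site_starts <- function(s, pattern) {
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(s))
    BiocGenerics::start(m) - 1L   # 0-based
  }

  rows <- list()
  reads_dropped <- 0L
  fragments_dropped <- 0L
  sites_cache <- list()
  get_sites <- function(chrom, strand, enzyme) {
    key <- paste(chrom, strand, enzyme, sep = "|")
    if (is.null(sites_cache[[key]])) {
      s <- if (strand == "+") seq_chr[[chrom]] else rc_chr[[chrom]]
      sites_cache[[key]] <<- site_starts(s, enzymes[[enzyme]])
    }
    sites_cache[[key]]
  }

  for (i in seq_len(nrow(truth))) {
    chrom <- truth$chrom[i]
    L <- sizes[[chrom]]
    n <- truth$n_reads[i]
    # even split of n reads over K digests, remainder rotated by index
    base <- n %/% K
    alloc <- rep(base, K)
    rem <- n - base * K
    if (rem > 0) {
      extra <- ((i - 1L + seq_len(rem) - 1L) %% K) + 1L
      alloc[extra] <- alloc[extra] + 1L
    }
    # work in insertion-strand coordinates: q is the junction offset on the
    # strand the fragment is read from
    strand <- truth$strand[i]
    q <- if (strand == "+") truth$pos[i] else L - 1L - truth$pos[i]
    s <- if (strand == "+") seq_chr[[chrom]] else rc_chr[[chrom]]
    for (k in seq_len(K)) {
      if (alloc[k] == 0L) next
      st <- get_sites(chrom, strand, names(enzymes)[k])
      nxt <- st[st >= q]
      if (length(nxt) == 0L) {
        fragments_dropped <- fragments_dropped + 1L
        reads_dropped <- reads_dropped + alloc[k]
        next
      }
      # circularisation by sticky-end ligation regenerates the recognition
      # site at the junction, so a read crossing it still matches the
      # reference through the full site: the fragment's mappable prefix
      # runs to the site end, not the cut position
      frag <- substr(s, q + 1L,
                     min(nxt[1] + nchar(enzymes[[k]]), q + frag_len))
      read_seq <- paste0(tag, frag)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("ins%06d:%s:%d", i, names(enzymes)[k],
                     seq_len(alloc[k])),
        seq = read_seq, qual = strrep("I", nchar(read_seq)),
        digest = names(enzymes)[k])
    }
  }
  reads <- dplyr::bind_rows(rows)
  if (nrow(truth) == 0 || nrow(reads) == 0) {
    reads <- tibble::tibble(id = character(), seq = character(),
                            qual = character(), digest = character())
  }
  attr(reads, "reads_expected") <- sum(truth$n_reads)
  attr(reads, "reads_emitted") <- nrow(reads)
  attr(reads, "reads_dropped") <- reads_dropped
  attr(reads, "fragments_dropped") <- fragments_dropped
  reads
}

#' Read / write junction reads as FASTQ
#'
#' Phred+33 with constant quality `I`; the digest label is carried in the
#' read name (`ins000001:HindIII:1`).
#'
#' @param reads Read tibble from [sim_library()].
#' @param path File path.
#' @return `read_fastq()` returns a read tibble (with `digest` recovered from
#'   the read name where present); `write_fastq()` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(0)
  if (nrow(reads) > 0) {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq,
                             "+", reads$qual))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), seq = character(),
                          qual = character(), digest = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort_format(sprintf("truncated FASTQ: %d lines in %s",
                         length(lines), path))
  }
  id <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  id <- sub("\\s.*$", "", id)
  tibble::tibble(
    id = id,
    seq = lines[seq(2, length(lines), by = 4)],
    qual = lines[seq(4, length(lines), by = 4)],
    digest = ifelse(grepl(":", id),
                    vapply(strsplit(id, ":", fixed = TRUE),
                           function(x) if (length(x) >= 2) x[2] else
                             NA_character_, character(1)),
                    NA_character_))
}
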