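#' Simulate a toy genome
#'
#' Draws i.i.d. bases over \{A, C, G, T\} at a target GC content. Chromosomes
#' are named `chr1`, `chr2`, ... The alphabet is strictly ACGT (no ambiguity
#' codes), matching what the downstream exact mapper assumes.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param lengths Integer vector of chromosome lengths in bp, one per
#'   chromosome; each must be >= 1000.
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed reproduces the same genome exactly.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @examples
#' g <- sim_genome(2, c(5000, 8000), gc = 0.38, seed = 1)
#' chrom_sizes(g)
#' @export
sim_genome <- function(n_chrom, lengths, gc = 0.38, seed = 1L) {
  check_scalar_number(n_chrom, "n_chrom", min = 1)
  if (length(lengths) != n_chrom) {
    abort_bad_arg("`lengths` must have one entry per chromosome")
  }
  if (any(!is.finite(lengths)) || any(lengths < 1000)) {
    abort_bad_arg("all chromosome `lengths` must be >= 1000")
  }
  check_scalar_number(gc, "gc")
  if (gc <= 0 || gc >= 1) abort_bad_arg("`gc` must be strictly between 0 and 1")
  lengths <- as.integer(lengths)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    purrr::map_chr(lengths, function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
    })
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(n_chrom))
  out
}

#' Read / write a genome as FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path File path.
#' @return `read_genome()` returns a [Biostrings::DNAStringSet];
#'   `write_genome()` returns `path` invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the name
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
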