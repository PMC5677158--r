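#' Simulate a replication-timing landscape
#'
#' Builds a piecewise-constant replication-timing (T_rep) profile from a set
#' of origin positions: each origin fires at `t0` minutes and forks move
#' outward at `fork_rate` bp/min, so a position p on a chromosome replicates
#' at `t0 + min_o |p - o| / fork_rate`, capped at `t_max`. The result mimics
#' the shape of genome-wide microarray T_rep profiles: valleys at early
#' origins rising linearly into late-replicating termination zones.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param origins Tibble with columns `chrom` and `pos` (0-based origin
#'   positions); every chromosome must carry at least one origin.
#' @param fork_rate Replication-fork speed in bp/min (> 0).
#' @param t0 Firing time of the origins, minutes.
#' @param t_max Cap on T_rep, minutes (default 70).
#' @param resolution Segment width in bp at which the profile is stored
#'   piecewise constant. The default of 1 stores the exact per-base profile
#'   (adjacent equal values are merged).
#' @return A timing tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `t_rep` (minutes), covering every position exactly once.
#' @examples
#' g <- sim_genome(1, 20000, seed = 1)
#' tp <- sim_timing(g, tibble::tibble(chrom = "chr1", pos = 5000),
#'                  fork_rate = 1000, t0 = 10)
#' timing_at(tp, "chr1", c(5000, 6000))
#' @export
sim_timing <- function(genome, origins, fork_rate = 1000, t0 = 10,
                       t_max = 70, resolution = 1L) {
  sizes <- chrom_sizes(genome)
  check_scalar_number(fork_rate, "fork_rate")
  if (fork_rate <= 0) abort_bad_arg("`fork_rate` must be > 0")
  check_scalar_number(t0, "t0", min = 0)
  check_scalar_number(t_max, "t_max", min = 0)
  missing <- setdiff(names(sizes), unique(origins$chrom))
  if (length(missing)) {
    abort_bad_arg(paste0("chromosome with no origin: ", missing[1]))
  }
  purrr::imap(as.list(sizes), function(L, chrom) {
    o <- sort(origins$pos[origins$chrom == chrom])
    if (any(o < 0 | o >= L)) abort_bad_arg("origin outside chromosome")
    starts <- seq.int(0L, L - 1L, by = as.integer(resolution))
    eval_at <- if (resolution == 1L) starts else
      pmin(starts + as.integer(resolution) %/% 2L, L - 1L)
    j <- findInterval(eval_at, o)
    d_left <- ifelse(j >= 1, eval_at - o[pmax(j, 1L)], Inf)
    d_right <- ifelse(j < length(o), o[pmin(j + 1L, length(o))] - eval_at, Inf)
    d <- pmin(d_left, d_right)
    t_rep <- pmin(t0 + d / fork_rate, t_max)
    r <- rle(t_rep)
    seg_end_idx <- cumsum(r$lengths)
    seg_start <- starts[c(1L, seg_end_idx[-length(seg_end_idx)] + 1L)]
    seg_end <- pmin(starts[seg_end_idx] + as.integer(resolution), L)
    tibble::tibble(chrom = chrom, start = seg_start, end = seg_end,
                   t_rep = r$values)
  }) %>% dplyr::bind_rows()
}

#' Look up T_rep at genomic positions
#'
#' @param timing A timing tibble (see [sim_timing()]).
#' @param chrom,pos Equal-length vectors of chromosomes and 0-based positions.
#' @return Numeric vector of T_rep values (minutes); `NA` where a position is
#'   not covered by the profile.
#' @export
timing_at <- function(timing, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  if (length(chrom) != length(pos)) {
    abort_bad_arg("`chrom` and `pos` must have equal length")
  }
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    seg <- timing[timing$chrom == ch, ]
    if (nrow(seg) == 0) next
    i <- which(chrom == ch)
    j <- findInterval(pos[i], seg$start)
    ok <- j >= 1 & pos[i] < seg$end[pmax(j, 1L)]
    out[i[ok]] <- seg$t_rep[j[ok]]
  }
  out
}

#' Read / write a timing profile as bedGraph
#'
#' @param timing Timing tibble.
#' @param path File path.
#' @return `read_timing()` returns a timing tibble; `write_timing()` returns
#'   `path` invisibly.
#' @export
write_timing <- function(timing, path) {
  write_bedgraph_intervals(
    tibble::tibble(chrom = timing$chrom, start = timing$start,
                   end = timing$end, value = timing$t_rep),
    path, header = "# callingcardr timing profile (T_rep, minutes)")
}

#' @rdname write_timing
#' @export
read_timing <- function(path) {
  bg <- read_bedgraph_intervals(path)
  tibble::tibble(chrom = bg$chrom, start = bg$start, end = bg$end,
                 t_rep = bg$value)
}
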