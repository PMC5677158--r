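#' Keep only insertions in early-replicating DNA
#'
#' Restricts an insertion set to events whose genomic position has
#' `T_rep <= t_max` (default: the first 30 minutes of S phase, the filter the
#' origin-centred meta-profiles are computed under). The library denominator
#' (`total_aligned_reads`) is deliberately left unchanged: RPM normalisation
#' is per library, not per subset.
#'
#' @param events Insertion-set tibble.
#' @param timing Timing tibble from [sim_timing()] / [read_timing()].
#' @param t_max Cutoff in minutes (default 30).
#' @return The filtered insertion-set tibble, metadata preserved.
#' @export
filter_by_timing <- function(events, timing, t_max = 30) {
  check_scalar_number(t_max, "t_max", min = 0)
  t_rep <- timing_at(timing, events$chrom, events$pos)
  if (anyNA(t_rep)) {
    abort_config("insertion position not covered by the timing profile")
  }
  out <- events[t_rep <= t_max, , drop = FALSE]
  attr(out, "construct") <- attr(events, "construct")
  attr(out, "total_aligned_reads") <- attr(events, "total_aligned_reads")
  attr(out, "qc") <- attr(events, "qc")
  out
}

#' Signal summarised in replication-timing windows
#'
#' Divides the genome into `width`-minute T_rep windows (left-closed:
#' `[0,5), [5,10), ...`; the last window is open-ended so every position
#' falls in exactly one window) and collects the track signal per window.
#' Two granularities are available:
#'
#' * `bin = NULL` (default): the per-window value list holds the track value
#'   of every *tracked* position in the window, and `mean` is their mean.
#' * `bin = <bp>`: each chromosome is tiled into `bin`-bp genomic bins,
#'   assigned to a window by the T_rep of their midpoint; the value list
#'   holds each bin's per-bp mean signal (zeros included), so `mean` is a
#'   signal *density*. This is the granularity suited to comparing binding
#'   density between constructs.
#'
#' `density` (total signal / genomic bases in the window) is reported in
#' both modes.
#'
#' @param track Track tibble from [rpm_track()] / [unique_track()].
#' @param timing Timing tibble.
#' @param width Window width in minutes (> 0), default 5.
#' @param bin Optional genomic bin width in bp (see above).
#' @param t_max Upper end of the windowed range; defaults to the largest
#'   T_rep in the profile.
#' @return A tibble with one row per window: `window_lo`, `window_hi`, `n`
#'   (length of the value list), `n_bases`, `total`, `mean`, `density` and a
#'   list-column `values`. Empty windows are reported with `n = 0`.
#' @export
window_signal <- function(track, timing, width = 5, bin = NULL,
                          t_max = NULL) {
  if (!is.numeric(width) || width <= 0) {
    abort_bad_arg("window `width` must be > 0")
  }
  t_max <- t_max %||% max(timing$t_rep)
  n_win <- max(1L, ceiling(t_max / width))
  win_of <- function(t) pmin(floor(t / width), n_win - 1L) + 1L
  # genomic bases per window, from the piecewise-constant profile directly
  seg_win <- win_of(timing$t_rep)
  n_bases <- vapply(seq_len(n_win), function(k) {
    sum(as.numeric(timing$end - timing$start)[seg_win == k])
  }, numeric(1))

  if (is.null(bin)) {
    t_pos <- timing_at(timing, track$chrom, track$pos)
    if (anyNA(t_pos)) {
      abort_config("tracked position not covered by the timing profile")
    }
    k <- win_of(t_pos)
    values <- lapply(seq_len(n_win), function(i) track$value[k == i])
  } else {
    check_scalar_number(bin, "bin", min = 1)
    values_by_win <- rep(list(numeric(0)), n_win)
    for (ch in unique(timing$chrom)) {
      L <- max(timing$end[timing$chrom == ch])
      starts <- seq.int(0L, L - 1L, by = as.integer(bin))
      ends <- pmin(starts + as.integer(bin), L)
      mid <- pmin(starts + as.integer(bin) %/% 2L, L - 1L)
      t_mid <- timing_at(timing, rep(ch, length(mid)), mid)
      kb <- win_of(t_mid)
      tr <- track[track$chrom == ch, ]
      sums <- numeric(length(starts))
      if (nrow(tr) > 0) {
        bi <- findInterval(tr$pos, starts)
        agg <- tapply(tr$value, bi, sum)
        sums[as.integer(names(agg))] <- agg
      }
      per_bp <- sums / (ends - starts)
      for (i in seq_len(n_win)) {
        values_by_win[[i]] <- c(values_by_win[[i]], per_bp[kb == i])
      }
    }
    values <- values_by_win
  }

  t_all <- timing_at(timing, track$chrom, track$pos)
  k_all <- win_of(t_all)
  total <- vapply(seq_len(n_win), function(i) sum(track$value[k_all == i]),
                  numeric(1))
  tibble::tibble(
    window_lo = (seq_len(n_win) - 1L) * width,
    window_hi = seq_len(n_win) * width,
    n = lengths(values),
    n_bases = n_bases,
    total = total,
    mean = vapply(values, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    density = ifelse(n_bases > 0, total / n_bases, NA_real_),
    values = values)
}

#' Feature-centred meta-profile
#'
#' Averages a signal track in fixed-width bins of offset relative to feature
#' midpoints (the construction behind origin-, Orc1-, TSS- and
#' centromere-centred profiles). For every site the `[-flank, +flank)`
#' window is tiled into `bin_width`-bp bins; each bin's value is the mean
#' per-position track value over its `bin_width` positions (untracked
#' positions count as 0), and the profile bin is the mean over sites.
#' Offsets are unstranded. Sites whose window would run off a chromosome end
#' are dropped and counted, not zero-padded.
#'
#' @param track Track tibble.
#' @param sites Feature tibble (needs `chrom`, `start`, `end`; midpoint is
#'   `floor((start+end)/2)`). Filter to one class before calling.
#' @param flank Half-window in bp; must be a multiple of `bin_width`.
#' @param bin_width Bin width in bp.
#' @param sizes Named chromosome lengths (from [chrom_sizes()]), used to drop
#'   end-truncated sites.
#' @return A profile tibble with one row per bin: `bin`, `offset_lo`,
#'   `offset_hi` (half-open, relative to midpoint), `offset_mid`, `value`;
#'   attributes `n_sites`, `n_dropped`, `flank`, `bin_width`, `mode`.
#' @export
feature_profile <- function(track, sites, flank = 1000L, bin_width = 100L,
                            sizes = NULL) {
  check_scalar_number(flank, "flank", min = 1)
  check_scalar_number(bin_width, "bin_width", min = 1)
  if (flank %% bin_width != 0) {
    abort_bad_arg("`flank` must be divisible by `bin_width`")
  }
  if (nrow(sites) == 0) abort_bad_arg("`sites` must be non-empty")
  mids <- tibble::tibble(chrom = sites$chrom,
                         mid = interval_midpoint(sites$start, sites$end))
  n_before <- nrow(mids)
  if (!is.null(sizes)) {
    keep <- mids$mid - flank >= 0 & mids$mid + flank <= sizes[mids$chrom]
    mids <- mids[keep, , drop = FALSE]
  }
  n_dropped <- n_before - nrow(mids)
  if (nrow(mids) == 0) {
    abort_bad_arg("no sites remain after dropping end-truncated sites")
  }
  n_bins <- as.integer(2 * flank / bin_width)
  mids$site_id <- seq_len(nrow(mids))
  hits <- dplyr::inner_join(track, mids, by = "chrom",
                            relationship = "many-to-many") %>%
    dplyr::mutate(offset = .data$pos - .data$mid) %>%
    dplyr::filter(.data$offset >= -flank, .data$offset < flank) %>%
    dplyr::mutate(bin = floor((.data$offset + flank) / bin_width) + 1L)
  bin_sums <- numeric(n_bins)
  if (nrow(hits) > 0) {
    agg <- tapply(hits$value, hits$bin, sum)
    bin_sums[as.integer(names(agg))] <- agg
  }
  value <- bin_sums / (bin_width * nrow(mids))
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    offset_lo = -flank + (seq_len(n_bins) - 1L) * bin_width,
    offset_hi = -flank + seq_len(n_bins) * bin_width,
    offset_mid = -flank + (seq_len(n_bins) - 0.5) * bin_width,
    value = value)
  attr(out, "n_sites") <- nrow(mids)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "flank") <- as.integer(flank)
  attr(out, "bin_width") <- as.integer(bin_width)
  attr(out, "mode") <- attr(track, "mode")
  out
}

#' Fold ratio between two meta-profiles over a central region
#'
#' Compares the mean bin value of profile `a` to that of profile `b` over
#' bins lying entirely within `region` (default the central +/- 100 bp, the
#' region where origin-proximal binding concentrates).
#'
#' @param a,b Profile tibbles from [feature_profile()] with identical
#'   binning.
#' @param region Length-2 numeric, offset range in bp.
#' @return A one-row tibble: `ratio`, `mean_a`, `mean_b`, `n_bins`,
#'   `undefined` (`TRUE` when both means are 0, in which case `ratio` is
#'   `NA`).
#' @export
profile_ratio <- function(a, b, region = c(-100, 100)) {
  same <- nrow(a) == nrow(b) &&
    isTRUE(all.equal(a$offset_lo, b$offset_lo)) &&
    isTRUE(all.equal(a$offset_hi, b$offset_hi))
  if (!same) abort_bad_arg("profiles `a` and `b` must share their binning")
  sel <- a$offset_lo >= region[1] & a$offset_hi <= region[2]
  if (!any(sel)) abort_bad_arg("no bins fall inside `region`")
  mean_a <- mean(a$value[sel])
  mean_b <- mean(b$value[sel])
  undefined <- mean_a == 0 && mean_b == 0
  tibble::tibble(ratio = if (undefined) NA_real_ else mean_a / mean_b,
                 mean_a = mean_a, mean_b = mean_b, n_bins = sum(sel),
                 undefined = undefined)
}
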