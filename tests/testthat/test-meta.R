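toy_set <- function(pos, read_count = 1L, strand = "+", total = NULL) {
  df <- tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                       strand = strand,
                       read_count = as.integer(read_count), digests = "")
  attr(df, "construct") <- "toy"
  attr(df, "total_aligned_reads") <- total %||% sum(df$read_count)
  df
}

test_that("timing filter keeps exactly the early events", {
  g <- sim_genome(1, 20000, seed = 1)
  tp <- sim_timing(g, tibble::tibble(chrom = "chr1", pos = 0),
                   fork_rate = 250, t0 = 0, t_max = 80)
  early <- toy_set(c(1000, 2000, 3000))          # T_rep 4, 8, 12
  expect_equal(nrow(filter_by_timing(early, tp, 30)), 3)
  late <- toy_set(c(11000, 12000))               # T_rep 44, 48
  expect_equal(nrow(filter_by_timing(late, tp, 30)), 0)
  mixed <- toy_set(seq(500, 19500, by = 500))
  kept <- filter_by_timing(mixed, tp, 30)
  t_all <- timing_at(tp, mixed$chrom, mixed$pos)
  expect_equal(nrow(kept), sum(t_all <= 30))     # per-event lookup oracle
  # denominator untouched: normalisation stays per library
  expect_equal(total_aligned_reads(kept), total_aligned_reads(mixed))
  off <- toy_set(25000)
  expect_error(filter_by_timing(off, tp, 30), class = "cc_config_error")
})

test_that("uniform track over uniform timing gives equal window means", {
  g <- sim_genome(1, 20000, seed = 2)
  # two segments, 10 and 20 min, equal genomic footprint
  tp <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                       end = c(10000L, 20000L), t_rep = c(2, 7))
  track <- tibble::tibble(chrom = "chr1", pos = seq(0L, 19999L, by = 100L),
                          value = 3.5)
  ws <- window_signal(track, tp, width = 5)
  means <- ws$mean[ws$n > 0]
  expect_lt(max(means) - min(means), 1e-12)
})

test_that("window means match hand-computed values on a 10-position track", {
  tp <- tibble::tibble(chrom = "chr1", start = c(0L, 100L, 200L),
                       end = c(100L, 200L, 300L), t_rep = c(2, 6, 12))
  track <- tibble::tibble(chrom = "chr1",
                          pos = c(10L, 20L, 30L, 110L, 120L, 130L, 140L,
                                  210L, 220L, 230L),
                          value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  ws <- window_signal(track, tp, width = 5)
  # window [0,5): positions at T_rep 2 -> values 1,2,3, mean 2
  # window [5,10): T_rep 6 -> values 4:7, mean 5.5
  # window [10,15): T_rep 12 -> values 8,9,10, mean 9
  expect_equal(ws$mean[1:3], c(2, 5.5, 9))
  expect_equal(ws$n[1:3], c(3L, 4L, 3L))
  expect_equal(ws$total[1:3], c(6, 22, 27))
  expect_equal(ws$n_bases[1:3], c(100, 100, 100))
  # partition: every tracked position contributes to exactly one window
  expect_equal(sum(ws$n), nrow(track))
  expect_error(window_signal(track, tp, width = 0),
               class = "cc_invalid_argument")
})

test_that("binned window values are per-bp densities including zeros", {
  tp <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                       end = c(1000L, 2000L), t_rep = c(2, 8))
  track <- tibble::tibble(chrom = "chr1", pos = c(50L, 150L), value = c(2, 4))
  ws <- window_signal(track, tp, width = 5, bin = 100)
  expect_equal(ws$n, c(10L, 10L))                # 10 bins per window
  v1 <- ws$values[[1]]
  expect_equal(v1[1:2], c(0.02, 0.04))           # bin sums / bin width
  expect_equal(sum(v1 > 0), 2)
  expect_equal(ws$values[[2]], rep(0, 10))
  expect_equal(ws$density, c(6 / 1000, 0))
})

test_that("a delta of signal at each midpoint lands in the central bin", {
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(5000L, 9000L, 13000L),
                          end = c(5000L, 9000L, 13000L) + 11L)
  mids <- floor((sites$start + sites$end) / 2)
  track <- tibble::tibble(chrom = "chr1", pos = mids, value = 1)
  prof <- feature_profile(track, sites, flank = 1000, bin_width = 100,
                          sizes = c(chr1 = 20000L))
  expect_equal(nrow(prof), 20)
  central <- prof$offset_lo == 0
  expect_equal(prof$value[central], 1 / 100)
  expect_true(all(prof$value[!central] == 0))
  expect_equal(attr(prof, "n_sites"), 3L)
})

test_that("uniform insertions give a flat profile within Monte Carlo error", {
  g <- sim_genome(1, 1000000, seed = 31)
  f <- sim_features(g, c(ACS_CONFIRMED_LIKELY = 40), spacing_min = 10000,
                    seed = 32)
  p <- sim_params(n_insertions = 10000, seed = 33)
  truth <- sim_insertions(g, NULL, NULL, p)
  track <- unique_track(as_insertion_set(truth))
  prof <- feature_profile(track, f, flank = 1000, bin_width = 100,
                          sizes = chrom_sizes(g))
  # per-bin counts ~ Binomial(n, bin footprint / L) over n_sites sites
  n_sites <- attr(prof, "n_sites")
  rate <- 10000 / 1e6
  se <- sqrt(rate * 100 * n_sites) / (100 * n_sites)
  expect_true(all(abs(prof$value - rate) < 3 * se + 1e-12))
})

test_that("profiles are equivariant under a constant genomic shift", {
  g_len <- 50000L
  withr::with_seed(41, {
    pos <- sort(sample(5000:30000, 300))
  })
  sites <- tibble::tibble(chrom = "chr1", start = c(9000L, 17000L, 25000L),
                          end = c(9011L, 17011L, 25011L))
  track <- tibble::tibble(chrom = "chr1", pos = pos, value = 1)
  shift <- 4000L
  prof0 <- feature_profile(track, sites, flank = 1000, bin_width = 100,
                           sizes = c(chr1 = g_len))
  prof1 <- feature_profile(
    dplyr::mutate(track, pos = pos + shift),
    dplyr::mutate(sites, start = start + shift, end = end + shift),
    flank = 1000, bin_width = 100, sizes = c(chr1 = g_len + shift))
  expect_equal(prof1$value, prof0$value)
})

test_that("end-truncated sites are dropped and counted, not padded", {
  sites <- tibble::tibble(chrom = "chr1", start = c(100L, 5000L),
                          end = c(111L, 5011L))
  track <- tibble::tibble(chrom = "chr1", pos = 5005L, value = 1)
  prof <- feature_profile(track, sites, flank = 1000, bin_width = 100,
                          sizes = c(chr1 = 10000L))
  expect_equal(attr(prof, "n_sites"), 1L)
  expect_equal(attr(prof, "n_dropped"), 1L)
  all_bad <- tibble::tibble(chrom = "chr1", start = 100L, end = 111L)
  expect_error(feature_profile(track, all_bad, flank = 1000, bin_width = 100,
                               sizes = c(chr1 = 1500L)),
               class = "cc_invalid_argument")
  expect_error(feature_profile(track, sites, flank = 1000, bin_width = 300,
                               sizes = c(chr1 = 10000L)),
               class = "cc_invalid_argument")
})

test_that("profile ratios recover scaling and flag undefined cases", {
  sites <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5011L)
  track <- tibble::tibble(chrom = "chr1",
                          pos = as.integer(seq(4005, 6005, by = 50)),
                          value = 2)
  a <- feature_profile(track, sites, flank = 1000, bin_width = 100,
                       sizes = c(chr1 = 20000L))
  b <- a
  b$value <- b$value / 3
  expect_equal(profile_ratio(a, b)$ratio, 3)
  expect_equal(profile_ratio(a, a)$ratio, 1)
  z <- a
  z$value <- 0
  r <- profile_ratio(z, z)
  expect_true(r$undefined)
  expect_true(is.na(r$ratio))
  mismatched <- feature_profile(track, sites, flank = 1000, bin_width = 200,
                                sizes = c(chr1 = 20000L))
  expect_error(profile_ratio(a, mismatched), class = "cc_invalid_argument")
})

test_that("unique-mode profiles ignore pcr bias while RPM profiles see it", {
  g <- sim_genome(1, 200000, seed = 51)
  f <- sim_features(g, c(ACS_CONFIRMED_LIKELY = 10), spacing_min = 8000,
                    seed = 52)
  p_lo <- sim_params(n_insertions = 2000,
                     feature_enrichment = list(
                       ACS_CONFIRMED_LIKELY = list(fold = 20, lambda = 100)),
                     pcr_meanlog = 1, pcr_sdlog = 0.1, seed = 53)
  p_hi <- sim_params(n_insertions = 2000,
                     feature_enrichment = list(
                       ACS_CONFIRMED_LIKELY = list(fold = 20, lambda = 100)),
                     pcr_meanlog = 3, pcr_sdlog = 1.5, seed = 53)
  t_lo <- sim_insertions(g, f, NULL, p_lo)
  t_hi <- sim_insertions(g, f, NULL, p_hi)
  # same seed, same weights: identical positions, different read counts
  expect_equal(t_lo[c("chrom", "pos", "strand")],
               t_hi[c("chrom", "pos", "strand")], ignore_attr = TRUE)
  sizes <- chrom_sizes(g)
  u_lo <- feature_profile(unique_track(as_insertion_set(t_lo)), f,
                          sizes = sizes)
  u_hi <- feature_profile(unique_track(as_insertion_set(t_hi)), f,
                          sizes = sizes)
  expect_equal(u_lo$value, u_hi$value)           # amplification erased
  r_lo <- feature_profile(rpm_track(as_insertion_set(t_lo)), f,
                          sizes = sizes)
  r_hi <- feature_profile(rpm_track(as_insertion_set(t_hi)), f,
                          sizes = sizes)
  expect_false(isTRUE(all.equal(r_lo$value, r_hi$value)))
})
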