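tag20 <- "TGTTGGAATAGCAAGGCAGT"

test_that("tag trimming handles exact, mismatched and missing prefixes", {
  frag <- "ACGTACGTACGTACGTAC"   # 18 bp
  reads <- tibble::tibble(id = "r1", seq = paste0(tag20, frag))
  out <- trim_junction(reads, tag20, max_mismatch = 0)
  expect_equal(out$status, "OK")
  expect_equal(out$fragment, frag)

  no_tag <- tibble::tibble(id = "r2", seq = paste0(strrep("G", 20), frag))
  expect_equal(trim_junction(no_tag, tag20)$status, "NO_TAG")

  # one mismatch in the tag: accepted at max_mismatch 1, rejected at 0
  tag_mm <- paste0("A", substr(tag20, 2, 20))
  read_mm <- tibble::tibble(id = "r3",
                            seq = paste0(tag_mm, strrep("ACGTAC", 5)))
  expect_equal(trim_junction(read_mm, tag20, max_mismatch = 1)$status, "OK")
  expect_equal(trim_junction(read_mm, tag20, max_mismatch = 0)$status,
               "NO_TAG")

  short <- tibble::tibble(id = "r4", seq = paste0(tag20, "ACGTACGTACGTACGTA"))
  expect_equal(trim_junction(short, tag20)$status, "TOO_SHORT")
  expect_error(trim_junction(tibble::tibble(id = "r5", seq = ""), tag20),
               class = "cc_invalid_argument")
})

test_that("exact mapper agrees with a brute-force both-strand scan", {
  g <- sim_genome(2, c(2000, 1500), seed = 42)
  s1 <- as.character(g[[1]])
  cases <- list(
    substr(s1, 101, 130),                                  # plus-strand hit
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(s1, 501, 530)))),       # minus-strand hit
    strrep("ACGT", 8))                                     # likely absent
  for (frag in cases) {
    expected <- brute_force_status(frag, g)
    got <- map_fragments(tibble::tibble(id = "x", seq = frag,
                                        fragment = frag, status = "OK"), g)
    expect_equal(got$status, expected$status)
    if (expected$status == "UNIQUE") {
      expect_equal(got$chrom, expected$chrom)
      expect_equal(got$pos, expected$pos)
      expect_equal(got$strand, expected$strand)
    }
  }
})

test_that("minus-strand unique mapping reports the junction base", {
  g <- sim_genome(1, 2000, seed = 7)
  s <- as.character(g[[1]])
  # fragment = revcomp of plus [701, 730] (1-based): junction base is the
  # plus-strand coordinate of the match's last base, 0-based 729
  frag <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 701, 730))))
  got <- map_fragments(tibble::tibble(id = "x", seq = frag, fragment = frag,
                                      status = "OK"), g)
  oracle <- brute_force_status(frag, g)
  expect_equal(oracle$status, "UNIQUE")
  expect_equal(got$strand, "-")
  expect_equal(got$pos, 729)
  expect_equal(got$pos, oracle$pos)
})

test_that("whole-chromosome fragments and cross-chromosome repeats", {
  g <- sim_genome(1, 1200, seed = 9)
  whole <- as.character(g[[1]])
  got <- map_fragments(tibble::tibble(id = "w", seq = whole,
                                      fragment = whole, status = "OK"), g)
  expect_equal(got$status, "UNIQUE")
  expect_equal(got$pos, 0)
  expect_equal(got$strand, "+")

  dup <- substr(whole, 1, 40)
  g2 <- Biostrings::DNAStringSet(c(chr1 = whole,
                                   chr2 = paste0(strrep("A", 1000), dup)))
  got2 <- map_fragments(tibble::tibble(id = "d", seq = dup, fragment = dup,
                                       status = "OK"), g2)
  expect_equal(got2$status, "MULTI")
})

test_that("insertion calling collapses by (chrom, pos, strand)", {
  m <- tibble::tibble(
    id = paste0("r", 1:12),
    status = c(rep("UNIQUE", 10), "MULTI", "NO_TAG"),
    chrom = c(rep("chr1", 10), NA, NA),
    pos = c(rep(500L, 10), NA, NA),
    strand = c(rep("+", 7), rep("-", 3), NA, NA),
    digest = c(rep("HindIII", 5), rep("TaqI", 5), NA, NA))
  set <- call_insertions(m, "toy")
  expect_equal(nrow(set), 2)           # strand-keyed events
  expect_equal(sort(set$read_count), c(3L, 7L))
  expect_equal(total_aligned_reads(set), 10L)
  expect_equal(qc_report(set)[["MULTI"]], 1L)
  expect_equal(qc_report(set)[["NO_TAG"]], 1L)
  merged <- call_insertions(m, "toy", merge_strands = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$read_count, 10L)
})

test_that("round-trip recovers truth and read statuses partition reads", {
  pipe <- make_small_pipeline(n = 60, len = 30000, seed = 5)
  expect_setequal(event_key(pipe$events), event_key(pipe$truth))
  qc <- qc_report(pipe$events)
  # every read gets exactly one status; UNIQUE reads all land in events
  expect_equal(sum(qc), nrow(pipe$reads))
  expect_equal(sum(pipe$events$read_count), qc[["UNIQUE"]])
})

test_that("calling a library concatenated with itself doubles read counts", {
  pipe <- make_small_pipeline(n = 30, len = 20000, seed = 6)
  once <- pipe$events
  twice <- call_insertions(dplyr::bind_rows(pipe$mappings, pipe$mappings),
                           "toy")
  expect_setequal(event_key(once), event_key(twice))
  j <- match(event_key(once), event_key(twice))
  expect_equal(twice$read_count[j], 2L * once$read_count)
})

test_that("oracle equivalence: caller matches brute-force scan end to end", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      g <- sim_genome(1, sample(5000:15000, 1), seed = sample(1000, 1))
      p <- sim_params(n_insertions = 25, seed = sample(1000, 1))
      truth <- sim_insertions(g, NULL, NULL, p)
      reads <- sim_library(g, truth, p)
      trimmed <- trim_junction(reads, p$tag)
      fast <- call_insertions(map_fragments(trimmed, g), "x")
      ok <- trimmed[trimmed$status == "OK", ]
      brute <- purrr::map_dfr(seq_len(nrow(ok)), function(i) {
        r <- brute_force_status(ok$fragment[i], g)
        tibble::tibble(status = r$status,
                       chrom = r$chrom %||% NA_character_,
                       pos = r$pos %||% NA_integer_,
                       strand = r$strand %||% NA_character_)
      })
      slow <- brute %>%
        dplyr::filter(status == "UNIQUE") %>%
        dplyr::count(chrom, pos, strand, name = "read_count")
      expect_setequal(event_key(fast), event_key(slow))
      j <- match(event_key(fast), event_key(slow))
      expect_equal(slow$read_count[j], fast$read_count)
    }
  })
})
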