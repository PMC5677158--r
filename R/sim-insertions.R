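#' Simulation parameters for a calling-cards experiment
#'
#' Bundles the knobs of the insertion and read models. Per-base sampling
#' weight at position p is
#' `background_rate * prod_over_classes(1 + (fold - 1) * exp(-d/lambda)) *
#' exp(-T_rep(p)/tau)`,
#' where d is the distance to the nearest feature midpoint of the class.
#' `tau = Inf` switches timing coupling off. Read multiplicity per insertion
#' is log-normal (rounded, floored at 1), a heavy-tailed stand-in for
#' inverse-PCR amplification bias.
#'
#' @param n_insertions Number of insertions to draw (>= 0).
#' @param background_rate Uniform per-base weight (> 0).
#' @param feature_enrichment Named list, one entry per feature class, each a
#'   list/vector with elements `fold` (>= 1) and `lambda` (bp).
#' @param tau Timing-coupling scale in minutes; `Inf` disables.
#' @param pcr_meanlog,pcr_sdlog Log-normal parameters of the per-insertion
#'   read-count distribution.
#' @param read_length Read length in bp (>= 20).
#' @param tag Ty5 terminal tag sequence prefixed to every read.
#' @param enzymes Named character vector of restriction-enzyme recognition
#'   sequences; defaults HindIII (AAGCTT), HpaII (CCGG), TaqI (TCGA).
#' @param seed Integer seed used by [sim_insertions()] and [sim_library()].
#' @return A list of class `cc_sim_params`.
#' @export
sim_params <- function(n_insertions = 1000L,
                       background_rate = 1,
                       feature_enrichment = list(),
                       tau = Inf,
                       pcr_meanlog = 2.3, pcr_sdlog = 0.8,
                       read_length = 50L,
                       tag = "TGTTGGAATAGCAAGGCAGT",
                       enzymes = c(HindIII = "AAGCTT", HpaII = "CCGG",
                                   TaqI = "TCGA"),
                       seed = 1L) {
  check_scalar_number(n_insertions, "n_insertions", min = 0)
  check_scalar_number(background_rate, "background_rate")
  if (background_rate <= 0) abort_bad_arg("`background_rate` must be > 0")
  check_scalar_number(tau, "tau", allow_inf = TRUE)
  if (tau <= 0) abort_bad_arg("`tau` must be > 0 (Inf disables)")
  check_scalar_number(read_length, "read_length", min = 20)
  if (length(enzymes) < 1) abort_bad_arg("`enzymes` must be non-empty")
  if (is.null(names(enzymes)) || any(names(enzymes) == "")) {
    names(enzymes) <- paste0("enzyme", seq_along(enzymes))
  }
  if (nchar(tag) < 8) abort_bad_arg("`tag` must be at least 8 bp")
  bad <- setdiff(names(feature_enrichment), feature_classes())
  if (length(bad)) abort_bad_arg(paste0("unknown feature class: ", bad[1]))
  for (fe in feature_enrichment) {
    fe <- as.list(fe)
    if (fe$fold < 1) abort_bad_arg("enrichment `fold` must be >= 1")
    if (fe$lambda <= 0) abort_bad_arg("enrichment `lambda` must be > 0")
  }
  structure(list(
    n_insertions = as.integer(n_insertions),
    background_rate = background_rate,
    feature_enrichment = lapply(feature_enrichment, as.list),
    tau = tau, pcr_meanlog = pcr_meanlog, pcr_sdlog = pcr_sdlog,
    read_length = as.integer(read_length), tag = toupper(tag),
    enzymes = toupper(enzymes), seed = as.integer(seed)
  ), class = "cc_sim_params")
}

# per-base sampling weights for one chromosome
insertion_weights <- function(L, chrom, features, timing, params) {
  pos <- seq.int(0L, L - 1L)
  w <- rep(params$background_rate, L)
  for (cls in names(params$feature_enrichment)) {
    fe <- params$feature_enrichment[[cls]]
    mids <- sort(features$midpoint[features$class == cls &
                                     features$chrom == chrom])
    if (length(mids) == 0) next
    j <- findInterval(pos, mids)
    d_left <- ifelse(j >= 1, pos - mids[pmax(j, 1L)], Inf)
    d_right <- ifelse(j < length(mids),
                      mids[pmin(j + 1L, length(mids))] - pos, Inf)
    d <- pmin(d_left, d_right)
    w <- w * (1 + (fe$fold - 1) * exp(-d / fe$lambda))
  }
  if (is.finite(params$tau)) {
    if (is.null(timing)) {
      abort_bad_arg("finite `tau` requires a timing profile")
    }
    t_rep <- timing_at(timing, rep(chrom, L), pos)
    if (anyNA(t_rep)) abort_config("timing profile does not cover the genome")
    w <- w * exp(-t_rep / params$tau)
  }
  w
}

#' Draw ground-truth Ty5 insertions
#'
#' Samples `n_insertions` distinct genomic positions without replacement with
#' probability proportional to the per-base weight described in
#' [sim_params()], assigns each a uniform random strand and a log-normal read
#' multiplicity. This is the generative model of a protein that binds
#' preferentially near designated features and in early-replicating DNA.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param features Feature tibble from [sim_features()], or `NULL`.
#' @param timing Timing tibble from [sim_timing()], or `NULL` (required if
#'   `tau` is finite).
#' @param params A `cc_sim_params` object.
#' @return Ground-truth tibble with columns `chrom`, `pos` (0-based), `strand`
#'   (`+`/`-`), `n_fragments`, `n_reads`, carrying `params` as an attribute.
#' @export
sim_insertions <- function(genome, features = NULL, timing = NULL, params) {
  stopifnot(inherits(params, "cc_sim_params"))
  sizes <- chrom_sizes(genome)
  if (params$n_insertions > sum(sizes)) {
    abort_bad_arg("`n_insertions` exceeds genome length")
  }
  if (is.null(features)) {
    features <- tibble::tibble(chrom = character(), start = integer(),
                               end = integer(), class = character(),
                               midpoint = integer())
  }
  truth <- withr::with_seed(params$seed, {
    w <- unlist(purrr::imap(as.list(sizes), function(L, ch) {
      insertion_weights(L, ch, features, timing, params)
    }), use.names = FALSE)
    n <- params$n_insertions
    if (n == 0) {
      tibble::tibble(chrom = character(), pos = integer(),
                     strand = character(), n_fragments = integer(),
                     n_reads = integer())
    } else {
      # Efraimidis-Spirakis exponential-key sampling: equivalent in law to
      # sequential weighted sampling without replacement, but O(N log N)
      idx <- utils::head(order(stats::rexp(length(w)) / w), n)
      offsets <- c(0L, cumsum(as.integer(sizes)))
      ci <- findInterval(idx, offsets + 1L)
      pos <- idx - offsets[ci] - 1L
      n_reads <- pmax(1L, as.integer(round(
        stats::rlnorm(n, params$pcr_meanlog, params$pcr_sdlog))))
      tibble::tibble(
        chrom = names(sizes)[ci], pos = as.integer(pos),
        strand = ifelse(stats::runif(n) < 0.5, "+", "-"),
        n_fragments = pmin(n_reads, length(params$enzymes)),
        n_reads = n_reads
      ) %>% dplyr::arrange(.data$chrom, .data$pos)
    }
  })
  attr(truth, "params") <- params
  truth
}

#' Read / write a ground-truth insertion table as TSV
#'
#' @param truth Ground-truth tibble from [sim_insertions()].
#' @param path File path.
#' @return `read_truth()` returns the tibble; `write_truth()` returns `path`
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = "cicii", progress = FALSE)
}
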