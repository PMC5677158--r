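#' Simulate feature annotations on a genome
#'
#' Places non-overlapping feature intervals of each requested class uniformly
#' at random subject to a minimum start-to-start spacing, emulating the kind
#' of curated site lists (oriDB ARS consensus sites, Orc1 ChIP sites,
#' centromeres, TSS) the analysis is run against. ACS intervals default to
#' the 11-bp consensus width.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param counts Named integer vector or list, names from
#'   `ACS_CONFIRMED_LIKELY, ACS_DUBIOUS, ORC1, CENTROMERE, TSS`, giving how
#'   many sites of each class to place.
#' @param spacing_min Minimum distance in bp between the starts of two sites
#'   of the same class.
#' @param seed Integer seed.
#' @param widths Named vector of interval widths per class; defaults to 11 bp
#'   for both ACS classes, 30 bp for ORC1, 120 bp for CENTROMERE and 1 bp for
#'   TSS.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `class`, `name` and `midpoint`, sorted within class.
#' @examples
#' g <- sim_genome(1, 100000, seed = 1)
#' sim_features(g, c(ACS_CONFIRMED_LIKELY = 20), spacing_min = 2000, seed = 2)
#' @export
sim_features <- function(genome, counts, spacing_min = 1000L, seed = 1L,
                         widths = NULL) {
  sizes <- chrom_sizes(genome)
  default_widths <- c(ACS_CONFIRMED_LIKELY = 11L, ACS_DUBIOUS = 11L,
                      ORC1 = 30L, CENTROMERE = 120L, TSS = 1L)
  widths <- utils::modifyList(as.list(default_widths), as.list(widths %||% list()))
  counts <- unlist(counts)
  bad <- setdiff(names(counts), feature_classes())
  if (length(bad)) abort_bad_arg(paste0("unknown feature class: ", bad[1]))
  check_scalar_number(spacing_min, "spacing_min", min = 1)

  place_class <- function(class, n) {
    w <- as.integer(widths[[class]])
    if (n == 0) return(NULL)
    # capacity: per chromosome, floor((L - w) / spacing_min) + 1 sites fit
    cap <- pmax(0L, (sizes - w) %/% as.integer(spacing_min) + 1L)
    names(cap) <- names(sizes)   # pmax drops names
    if (n > sum(cap)) {
      abort_capacity(sprintf(
        "cannot place %d %s sites with spacing %d on a %d bp genome",
        n, class, as.integer(spacing_min), sum(sizes)))
    }
    # allocate counts to chromosomes proportionally to capacity, bounded by it
    alloc <- floor(n * cap / sum(cap))
    while (sum(alloc) < n) {
      room <- which(alloc < cap)
      i <- room[which.max((cap - alloc)[room])]
      alloc[i] <- alloc[i] + 1L
    }
    purrr::imap(alloc, function(k, chrom) {
      if (k == 0) return(NULL)
      L <- sizes[[chrom]]
      # sorted draws + cumulative spacing give starts with pairwise gaps
      # >= spacing_min while remaining uniform over feasible configurations
      slack <- L - w - (k - 1L) * as.integer(spacing_min)
      u <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
      start <- u + (seq_len(k) - 1L) * as.integer(spacing_min)
      tibble::tibble(chrom = chrom, start = start, end = start + w,
                     class = class)
    }) %>% purrr::compact() %>% dplyr::bind_rows()
  }

  out <- withr::with_seed(seed, {
    purrr::imap(as.list(counts), function(n, cls) place_class(cls, n)) %>%
      purrr::compact() %>% dplyr::bind_rows()
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), class = character())
  }
  out %>%
    dplyr::arrange(.data$class, .data$chrom, .data$start) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(name = paste0(.data$class, "_", dplyr::row_number())) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(midpoint = interval_midpoint(.data$start, .data$end))
}

#' Read / write feature annotations as BED
#'
#' Six-column BED (chrom, start, end, name, score, strand) where the name
#' column carries the feature class.
#'
#' @param features Feature tibble as from [sim_features()].
#' @param path File path.
#' @return `read_features()` returns a feature tibble; `write_features()`
#'   returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  bed <- tibble::tibble(chrom = features$chrom,
                        start = features$start, end = features$end,
                        name = features$class, score = 0L, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  bed %>%
    dplyr::transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
                     class = .data$name) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(name = paste0(.data$class, "_", dplyr::row_number())) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(midpoint = interval_midpoint(.data$start, .data$end))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
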