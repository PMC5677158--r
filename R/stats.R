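#' Wilcoxon rank-sum test with exact small-sample p-values
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test using midranks for ties.
#' When the pooled sample size is at most `exact_max` (default 16, i.e. at
#' most choose(16, 8) = 12870 labelings) the two-sided p-value is computed
#' by full enumeration of all group labelings:
#' `p = P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)` under the permutation
#' null, which is valid in the presence of ties. For larger samples the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max Pooled-size threshold for exact enumeration.
#' @return An object of class `cc_wilcoxon`: a list with `U` (the smaller of
#'   the two one-sided U statistics), `U1` (U of `x`), `n1`, `n2`, `p`,
#'   `method` (`"EXACT"` or `"NORMAL_APPROX"`) and `stars`. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 16L) {
  if (length(x) < 1 || length(y) < 1) {
    abort_bad_arg("both samples must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) abort_bad_arg("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)           # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev <- abs(U1 - mu)
  if (N <= exact_max) {
    method <- "EXACT"
    labelings <- utils::combn(N, n1)
    c1 <- n1 * (n1 + 1) / 2
    devs <- abs(colSums(matrix(r[labelings], nrow = n1)) - c1 - mu)
    p <- mean(devs >= dev - 1e-9)
  } else {
    method <- "NORMAL_APPROX"
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (dev - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  structure(list(U = min(U1, n1 * n2 - U1), U1 = U1, n1 = n1, n2 = n2,
                 p = p, method = method, stars = significance_stars(p)),
            class = "cc_wilcoxon")
}

#' @export
print.cc_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): U = %g, n = (%d, %d), p = %.4g [%s]\n",
              x$method, x$U, x$n1, x$n2, x$p, x$stars))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x A `cc_wilcoxon` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `U`, `n1`, `n2`, `p.value`,
#'   `method`, `stars`.
#' @export
tidy.cc_wilcoxon <- function(x, ...) {
  tibble::tibble(U = x$U, n1 = x$n1, n2 = x$n2, p.value = x$p,
                 method = x$method, stars = x$stars)
}

#' @rdname tidy.cc_wilcoxon
#' @export
glance.cc_wilcoxon <- function(x, ...) tidy.cc_wilcoxon(x)

#' Significance categories for p-values
#'
#' The star banding used throughout the window comparisons:
#' `***` for p < 0.001, `**` for 0.001 <= p < 0.01, `*` for 0.01 <= p <=
#' 0.05, `NS` above 0.05.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector over `{NS, *, **, ***}`.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_bad_arg("p-values must lie in [0, 1]")
  }
  dplyr::case_when(p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p <= 0.05 ~ "*",
                   TRUE ~ "NS")
}

#' Ty5 transposition efficiency from plating counts
#'
#' The efficiency assay: cells carrying a genomic Ty5 integration are His+
#' and have lost the URA3 donor plasmid, so they grow on -His 5-FOA plates;
#' total viable cells are counted on YPD. Efficiency is the ratio of -His
#' FOA colonies to total viable cells, corrected for the dilution at which
#' the FOA plate was seeded.
#'
#' @param foa_colonies Colony count on -His FOA (>= 0).
#' @param total_viable Viable-cell count on YPD (> 0), already corrected to
#'   the master culture.
#' @param dilution_factor Fold dilution of the master applied to the plated
#'   aliquot (default 1 = undiluted).
#' @return A one-row tibble: `foa_colonies`, `total_viable`,
#'   `dilution_factor`, `rate` (events per cell).
#' @examples
#' transposition_efficiency(500, 1e6)  # 5e-4 events/cell
#' @export
transposition_efficiency <- function(foa_colonies, total_viable,
                                     dilution_factor = 1) {
  check_scalar_number(foa_colonies, "foa_colonies", min = 0)
  check_scalar_number(total_viable, "total_viable")
  check_scalar_number(dilution_factor, "dilution_factor")
  if (total_viable <= 0) abort_bad_arg("`total_viable` must be > 0")
  if (dilution_factor <= 0) abort_bad_arg("`dilution_factor` must be > 0")
  rate <- foa_colonies / (total_viable * dilution_factor)
  if (rate > 1) abort_bad_arg("efficiency above 1/cell: check counts")
  tibble::tibble(foa_colonies = foa_colonies, total_viable = total_viable,
                 dilution_factor = dilution_factor, rate = rate)
}

#' Per-window rank-sum comparison of two constructs
#'
#' Runs [wilcoxon_rank_sum()] on the per-window value lists of two
#' [window_signal()] results, window by window, and attaches significance
#' stars. No multiple-testing adjustment is applied (stars are per window);
#' set `adjust = "BH"` for Benjamini-Hochberg-adjusted stars. A window empty
#' in either construct is flagged untestable rather than raising an error.
#'
#' @param a,b Window tibbles from [window_signal()] (same windows).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per window: `window_lo`, `window_hi`, `n1`,
#'   `n2`, `U`, `p`, `method`, `stars`, `testable`.
#' @export
compare_windows <- function(a, b, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$window_lo, b$window_lo))) {
    abort_bad_arg("window summaries must share their windows")
  }
  res <- purrr::map2(a$values, b$values, function(va, vb) {
    if (length(va) == 0 || length(vb) == 0) {
      return(list(n1 = length(va), n2 = length(vb), U = NA_real_,
                  p = NA_real_, method = NA_character_, testable = FALSE))
    }
    w <- wilcoxon_rank_sum(va, vb)
    list(n1 = w$n1, n2 = w$n2, U = w$U, p = w$p, method = w$method,
         testable = TRUE)
  })
  out <- tibble::tibble(
    window_lo = a$window_lo, window_hi = a$window_hi,
    n1 = purrr::map_int(res, ~ as.integer(.x$n1)),
    n2 = purrr::map_int(res, ~ as.integer(.x$n2)),
    U = purrr::map_dbl(res, "U"),
    p = purrr::map_dbl(res, "p"),
    method = purrr::map_chr(res, "method"),
    testable = purrr::map_lgl(res, "testable"))
  p_for_stars <- out$p
  if (adjust == "BH") p_for_stars <- stats::p.adjust(out$p, method = "BH")
  out$stars <- ifelse(out$testable, significance_stars(
    ifelse(is.na(p_for_stars), 1, p_for_stars)), NA_character_)
  out$stars[!out$testable] <- NA_character_
  out
}
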