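#' Plot a feature-centred meta-profile
#'
#' @param profile Profile tibble from [feature_profile()] (or a named list of
#'   them, drawn as one line per construct).
#' @return A ggplot object: mean signal per offset bin relative to the
#'   feature midpoint.
#' @export
plot_profile <- function(profile) {
  df <- if (is.data.frame(profile)) {
    dplyr::mutate(profile, construct = "construct")
  } else {
    dplyr::bind_rows(purrr::imap(profile, function(p, nm) {
      dplyr::mutate(p, construct = nm)
    }))
  }
  mode <- attr(if (is.data.frame(profile)) profile else profile[[1]], "mode")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_mid, y = .data$value,
                                   colour = .data$construct)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from feature midpoint (bp)",
                  y = sprintf("mean %s per bp", mode %||% "signal"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot signal by replication-timing window
#'
#' Boxplots of the per-window value lists of one or more constructs,
#' mirroring the standard presentation of calling-cards signal against
#' T_rep.
#'
#' @param ws Window tibble from [window_signal()], or a named list of them.
#' @return A ggplot object.
#' @export
plot_window_signal <- function(ws) {
  as_long <- function(w, nm) {
    tidyr::unnest(
      dplyr::transmute(w, window = sprintf("[%g,%g)", .data$window_lo,
                                           .data$window_hi),
                       window_lo = .data$window_lo, values = .data$values),
      "values") %>%
      dplyr::mutate(construct = nm)
  }
  df <- if (is.data.frame(ws)) as_long(ws, "construct") else {
    dplyr::bind_rows(purrr::imap(ws, as_long))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$window,
                                                      .data$window_lo),
                                   y = .data$values,
                                   fill = .data$construct)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "replication-timing window (min)", y = "signal",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
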