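#' Plot an angle series
#'
#' Trunk and thigh angle traces over time, faceted by segment.
#'
#' @param ... One or more angle series tibbles; named arguments become the
#'   series labels, otherwise the `source` column is used.
#' @return A ggplot object.
#' @export
plot_angles <- function(...) {
  series <- list(...)
  labels <- names(series) %||% rep("", length(series))
  dfs <- purrr::imap(series, function(df, i) {
    check_series(df, "angle")
    lab <- if (is.character(i) && nzchar(i)) i else df$source[1L] %||% "series"
    dplyr::mutate(df, series = lab)
  })
  long <- dplyr::bind_rows(dfs) |>
    tidyr::pivot_longer(c("theta_trunk_deg", "theta_thigh_deg"),
                        names_to = "segment", values_to = "angle_deg") |>
    dplyr::mutate(segment = ifelse(.data$segment == "theta_trunk_deg",
                                   "trunk (deg from vertical)",
                                   "thigh (deg from horizontal)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$angle_deg,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~segment, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "segment angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trial
#'
#' Overlays the ground-truth angles with the chair-model angles recovered
#' from the virtual laser distances and the marker-based angles, after the
#' standard pre-processing chain.
#'
#' @param object An `sts_trial` from [simulate_trial()].
#' @param filter A [filter_spec()] or `NULL`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sts_trial
#' @export
autoplot.sts_trial <- function(object, filter = filter_spec(), ...) {
  chair <- process_distances(object$distances, object$geom, filter = filter)
  ref <- process_markers(object$markers, filter = filter,
                         fs_out = series_fs(object$distances))
  plot_angles(`ground truth` = object$truth, `chair model` = chair,
              `marker based` = ref) +
    ggplot2::geom_vline(xintercept = c(object$events$peak_s),
                        linetype = "dashed", colour = "grey50")
}

#' Plot per-trial validation metrics
#'
#' Dot plot of the similarity coefficients and excursion errors of one or
#' more validated trials.
#'
#' @param object An `sts_validation`, or a tibble of per-trial metrics
#'   (rows = trials) as consumed by [summarize_validations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sts_validation
#' @export
autoplot.sts_validation <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(size = 3, na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
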