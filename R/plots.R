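#' Bar plot of templated 3'-end positions
#'
#' Mirrors the standard per-reference 3'-end figure: one bar per
#' templated end position (labelled `+nU` for snRNAs with a known Lsm
#' boundary), faceted by sample.
#'
#' @param profile Profile tibble for one reference, possibly with
#'   several `sample_id` values.
#' @param ref Optional one-row reference tibble for `+nU` labelling.
#' @return A ggplot object.
#' @export
plot_end_positions <- function(profile, ref = NULL) {
  by_sample <- profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      d$ref_id <- profile$ref_id[1]
      summarize_profile(d, "endpos", ref = ref)
    }) |>
    dplyr::ungroup()
  by_sample$label <- factor(by_sample$label,
                            levels = unique(by_sample$label[order(by_sample$end_offset)]))
  ggplot2::ggplot(by_sample, ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "templated 3' end position", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Bar plot of tail-class fractions
#'
#' @param profile Profile tibble for one reference, possibly with
#'   several `sample_id` values.
#' @return A ggplot object.
#' @export
plot_tail_classes <- function(profile) {
  by_sample <- profile |>
    dplyr::mutate(category = tail_category(profile)) |>
    dplyr::group_by(.data$sample_id, .data$category) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  ggplot2::ggplot(by_sample,
                  ggplot2::aes(x = .data$category, y = .data$fraction,
                               fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tail class", y = "fraction of reads", fill = "sample") +
    ggplot2::theme_minimal()
}

#' Plot decay time courses with fitted exponentials
#'
#' @param object A `decay_fit` from [fit_decay()].
#' @param series Optional observed series (as passed to [fit_decay()])
#'   to overlay as points, normalized to t = 0 within replicate.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, series = NULL, ...) {
  tmax <- if (!is.null(series)) max(series$time) else
    max(3 * object$half_life[is.finite(object$half_life)], 8)
  curves <- tidy(object) |>
    dplyr::mutate(data = purrr::map(.data$k, function(kk) {
      tibble(time = seq(0, tmax, length.out = 50),
             rel = exp(-kk * seq(0, tmax, length.out = 50)))
    })) |>
    tidyr::unnest("data")
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$rel,
                                            colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$ref_id)) +
    ggplot2::labs(x = "hours after transcription shutoff",
                  y = "abundance relative to t = 0", colour = "condition") +
    ggplot2::theme_minimal()
  if (!is.null(series)) {
    if (!"condition" %in% names(series)) series$condition <- "all"
    pts <- series |>
      dplyr::group_by(.data$ref_id, .data$condition, .data$replicate) |>
      dplyr::mutate(rel = .data$abundance / .data$abundance[.data$time == 0]) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.6)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
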