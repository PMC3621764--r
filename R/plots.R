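# ggplot2 visualisations for linkage, intervals and the triage cascade.

#' Plot per-marker linkage status across individuals
#'
#' A marker-by-individual tile map: linked, recombined and uninformative
#' calls along the chromosome, the visual analogue of a fine-mapping
#' genotype table.
#'
#' @param object An `fs_linkage` tibble from [assign_linkage()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_linkage <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$pos / 1e6, y = .data$individual,
      fill = .data$status
    )
  ) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(
      linked = "#1b7837", recombined = "#d73027", uninformative = "grey80"
    )) +
    ggplot2::labs(
      x = "Position (Mb)", y = NULL, fill = "Status",
      title = "Marker linkage across individuals"
    ) +
    ggplot2::theme_minimal()
}

#' Plot causative intervals per individual
#'
#' Inner (minimum) intervals as thick bars and outer (maximum) intervals as
#' thin whiskers, one row per individual.
#'
#' @param object An `fs_intervals` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_intervals <- function(object, ...) {
  d <- as_tibble(as.data.frame(object))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$individual)) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = dplyr::coalesce(.data$outer_left, .data$inner_left) / 1e6,
        xend = dplyr::coalesce(.data$outer_right, .data$inner_right) / 1e6,
        yend = .data$individual
      ),
      linewidth = 0.4, colour = "grey55"
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$inner_left / 1e6, xend = .data$inner_right / 1e6,
        yend = .data$individual
      ),
      linewidth = 2.4, colour = "#2166ac"
    ) +
    ggplot2::labs(
      x = "Position (Mb)", y = NULL,
      title = "Minimum (thick) and maximum (thin) causative intervals"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the elimination cascade
#'
#' Variant counts by class and verdict, with elimination reasons.
#'
#' @param object An `fs_triage` from [triage_cascade()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_triage <- function(object, ...) {
  d <- object$verdicts |>
    mutate(outcome = dplyr::coalesce(.data$reason, "retained_unique"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vclass, fill = .data$outcome)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = NULL, y = "Variants", fill = "Outcome",
      title = "Variant elimination cascade"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
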