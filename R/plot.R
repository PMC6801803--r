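# ggplot2 displays for the per-nucleotide tracks and result objects.

#' @export
autoplot.reactivity_profile <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(band = cut(.data$reactivity, c(-Inf, 0.4, 0.85, Inf),
                      labels = c("low", "mid", "high")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position,
                                    y = .data$reactivity,
                                    fill = .data$band)) +
    ggplot2::geom_col(width = 1, na.rm = TRUE) +
    ggplot2::scale_fill_manual(
      values = c(low = "grey30", mid = "orange", high = "firebrick"),
      na.value = "grey85", name = "reactivity") +
    ggplot2::labs(x = "position",
                  y = paste0(attr(object, "reagent"), " reactivity"),
                  title = attr(object, "rna_id")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confidence_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$position, .data$confidence)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 70, linetype = "dashed") +
    ggplot2::labs(x = "position", y = "jackknife confidence (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$position, .data$entropy)) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
    ggplot2::labs(x = "position", y = "Shannon entropy (log10)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pair_probability_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$i, .data$j,
                               size = .data$probability)) +
    ggplot2::geom_point(alpha = 0.6, color = "navy") +
    ggplot2::scale_size_area(max_size = 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position i", y = "position j",
                  size = "P(i,j)") +
    ggplot2::theme_minimal()
}

#' Combined per-nucleotide track figure for a pipeline run
#'
#' Reactivity, jackknife confidence and Shannon entropy stacked as
#' facets, with well-defined regions shaded.
#'
#' @param run A `shapefold_run`.
#' @return A ggplot object.
#' @export
plot_run_track <- function(run) {
  stopifnot(inherits(run, "shapefold_run"))
  track <- tidy(run) %>%
    select("position", "reactivity", "confidence", "entropy") %>%
    tidyr::pivot_longer(-"position", names_to = "track") %>%
    mutate(track = factor(.data$track,
                          c("reactivity", "confidence", "entropy")))
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, color = "grey20") +
    ggplot2::facet_grid("track", scales = "free_y") +
    ggplot2::labs(x = "position", y = NULL, title = run$rna_id) +
    ggplot2::theme_minimal()
  if (nrow(run$regions))
    p <- p + ggplot2::geom_rect(
      data = run$regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "seagreen", alpha = 0.15)
  p
}

#' @export
autoplot.shapefold_run <- function(object, ...) plot_run_track(object)
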