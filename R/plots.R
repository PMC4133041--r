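# ggplot2 displays: U-shaped curves with theory overlays, waiting-time
# histograms with both analytic densities.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an analytic rescue curve
#'
#' @param object A [theory_curve()] result.
#' @param components Also draw the wildtype and mutant components.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rescue_theory_curve
#' @export
autoplot.rescue_theory_curve <- function(object, components = TRUE, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "N_wt", "N_mut", "N_total")],
    -"t", names_to = "component", values_to = "N")
  if (!components) long <- dplyr::filter(long, .data$component == "N_total")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$N,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations since environmental change",
                  y = "expected individuals",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot rescue-conditioned ensemble means with theory overlays
#'
#' Draws the mean total population size over rescued runs, with the
#' oversampling-corrected and (optionally) naive analytic curves overlaid --
#' the standard U-curve comparison.
#'
#' @param object A `rescue_ensemble` with recorded curves.
#' @param naive Overlay the naive (unconditioned) curve as well.
#' @param source Theory curve source to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rescue_ensemble
#' @export
autoplot.rescue_ensemble <- function(object, naive = TRUE,
                                     source = c("standing", "new_mutation"),
                                     ...) {
  source <- match.arg(source)
  cm <- conditional_moments(object)
  grid <- cm$t
  over <- theory_curve(object$params, t_grid = grid, source = source)
  layers <- tibble::tibble(t = grid, N = over$N_total,
                           curve = "theory (oversampling)")
  if (naive && source == "standing") {
    nv <- theory_curve(object$params, t_grid = grid, source = "standing",
                       correction = "naive")
    layers <- dplyr::bind_rows(
      layers, tibble::tibble(t = grid, N = nv$N_total,
                             curve = "theory (naive)"))
  }
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = cm, ggplot2::aes(.data$t, .data$mean_total,
                              colour = "simulated conditional mean")) +
    ggplot2::geom_line(
      data = layers, ggplot2::aes(.data$t, .data$N, colour = .data$curve),
      linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations since environmental change",
                  y = "population size (rescued runs)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the waiting-time distribution of successful mutations
#'
#' Histogram of simulated origin times with the geometric and improved
#' analytic densities overlaid.
#'
#' @param ensemble A `rescue_ensemble` with new-mutation rescues.
#' @param breaks Bin width in generations.
#' @return A ggplot.
#' @export
plot_waiting_times <- function(ensemble, breaks = 10) {
  h <- waiting_time_distribution(ensemble, breaks = breaks)
  grid <- seq(0, max(h$bin_hi), length.out = 300)
  dens <- dplyr::bind_rows(
    tibble::tibble(t = grid, form = "geometric",
                   density = waiting_time_density(grid, ensemble$params,
                                                  "geometric")),
    tibble::tibble(t = grid, form = "improved",
                   density = waiting_time_density(grid, ensemble$params,
                                                  "improved"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_col(data = h, ggplot2::aes(.data$mid, .data$density),
                      width = h$bin_hi - h$bin_lo, fill = "grey80") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(.data$t, .data$density,
                                    colour = .data$form)) +
    ggplot2::labs(x = "origin generation of the successful mutation",
                  y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
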