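#' Helical-wheel plot
#'
#' Draws the classic wheel: residues on a circle at their helical angles,
#' coloured by Eisenberg hydrophobicity, with the mean hydrophobic-moment
#' direction as an arrow. Amphipathic masks show their apolar binder-
#' facing arc at a glance.
#'
#' @param wheel A [helical_wheel()] tibble (or a sequence string).
#' @param twist Degrees per residue, used when `wheel` is a string.
#' @return A ggplot object.
#' @export
plot_wheel <- function(wheel, twist = 100) {
  if (is.character(wheel)) wheel <- helical_wheel(wheel, twist)
  theta <- wheel$angle_deg * pi / 180
  d <- mutate(wheel, wx = cos(theta), wy = sin(theta))
  mx <- sum(d$hydrophobicity * d$wx) / nrow(d)
  my <- sum(d$hydrophobicity * d$wy) / nrow(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wx, y = .data$wy)) +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 181)),
                      y = sin(seq(0, 2 * pi, length.out = 181)),
                      colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$hydrophobicity),
                        shape = 21, size = 7) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), size = 3) +
    ggplot2::annotate("segment", x = 0, y = 0, xend = mx, yend = my,
                      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm")),
                      colour = "red") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "orange", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "Eisenberg\nhydrophobicity")
}

#' Plot sensorgrams, optionally with a fitted model overlay
#'
#' @param x A sensorgram tibble (columns `time`, `response`, `conc`) or
#'   an `afm_kinetics_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sensorgrams <- function(x, ...) {
  if (inherits(x, "afm_kinetics_fit")) {
    d <- x$fitted
    ggplot2::ggplot(d, ggplot2::aes(x = .data$time, colour = factor(.data$conc))) +
      ggplot2::geom_point(ggplot2::aes(y = .data$response), size = 0.4, alpha = 0.5) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
      ggplot2::labs(x = "time (s)", y = "response (RU)", colour = "conc (M)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(as_tibble(x),
                    ggplot2::aes(x = .data$time, y = .data$response,
                                 colour = factor(.data$conc))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "response (RU)", colour = "conc (M)") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot afm_kinetics_fit
#' @export
autoplot.afm_kinetics_fit <- function(object, ...) plot_sensorgrams(object, ...)

#' Dose-response plot for a 4PL fit
#'
#' @param object An `afm_4pl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot afm_4pl_fit
#' @export
autoplot.afm_4pl_fit <- function(object, ...) {
  p <- object$params
  grid <- exp(seq(log(min(object$data$conc)), log(max(object$data$conc)),
                  length.out = 200))
  curve <- tibble(
    conc = grid,
    response = p$bottom + (p$top - p$bottom) / (1 + (grid / p$ic50)^p$hill)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = p$ic50, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "response") +
    ggplot2::theme_minimal()
}

#' Triage metric overview plot
#'
#' Coverage against interchain PAE for a batch of evaluated designs,
#' coloured by pass/fail, with the threshold lines drawn.
#'
#' @param records Evaluated design records ([rank_designs()] output).
#' @param thresholds The [triage_thresholds()] used.
#' @return A ggplot object.
#' @export
plot_triage <- function(records, thresholds = triage_thresholds()) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$interchain_pae, y = .data$coverage,
                               colour = .data$passed)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thresholds$min_coverage, linetype = 2) +
    ggplot2::geom_vline(xintercept = thresholds$max_interchain_pae, linetype = 2) +
    ggplot2::labs(x = "interchain PAE (A)", y = "interface coverage") +
    ggplot2::theme_minimal()
}
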