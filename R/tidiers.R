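#' Tidy a 1:1 kinetic fit
#'
#' @param x An `afm_kinetics_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy afm_kinetics_fit
#' @export
tidy.afm_kinetics_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("kon", "koff", "kd", "rmax"),
    estimate = c(p$kon, p$koff, p$kd, p$rmax),
    std.error = c(p$kon_se, p$koff_se, NA_real_, p$rmax_se)
  )
}

#' @rdname tidy.afm_kinetics_fit
#' @method glance afm_kinetics_fit
#' @export
glance.afm_kinetics_fit <- function(x, ...) {
  tibble(
    kd = x$params$kd,
    residual_sd = x$residual_sd,
    n_curves = length(unique(x$data$conc)),
    n_points = nrow(x$data),
    converged = x$converged
  )
}

#' Tidy a 4PL dose-response fit
#'
#' @param x An `afm_4pl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @method tidy afm_4pl_fit
#' @export
tidy.afm_4pl_fit <- function(x, ...) {
  p <- x$params
  tibble(term = c("ic50", "hill", "top", "bottom"),
         estimate = c(p$ic50, p$hill, p$top, p$bottom))
}

#' @rdname tidy.afm_4pl_fit
#' @method glance afm_4pl_fit
#' @export
glance.afm_4pl_fit <- function(x, ...) {
  tibble(ic50 = x$params$ic50, residual_sd = x$residual_sd,
         n_points = nrow(x$data), converged = x$converged)
}
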