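#' 1:1 Langmuir binding parameters
#'
#' @param kon Association rate constant (1/(M s)).
#' @param koff Dissociation rate constant (1/s).
#' @param rmax Maximal response (response units).
#' @return One-row tibble with `kon`, `koff`, `kd = koff/kon` (M) and
#'   `rmax`.
#' @export
kinetics_params <- function(kon, koff, rmax) {
  if (any(c(kon, koff, rmax) <= 0)) abort("kinetic parameters must be positive")
  tibble(kon = kon, koff = koff, kd = koff / kon, rmax = rmax)
}

# Closed-form 1:1 response at analyte concentration `conc`.
langmuir_response <- function(t, kon, koff, rmax, conc, t_assoc) {
  kd <- koff / kon
  kobs <- kon * conc + koff
  req <- rmax * conc / (conc + kd)
  r_assoc <- req * (1 - exp(-kobs * pmin(t, t_assoc)))
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc, r_assoc, r_end * exp(-koff * (t - t_assoc)))
}

#' Simulate a BLI-style 1:1 sensorgram
#'
#' Association follows `R(t) = Rmax C/(C+KD) (1 - exp(-(kon C + koff) t))`
#' and dissociation decays exponentially with `koff` from the association
#' end point. Optional Gaussian noise is seeded explicitly; there is no
#' hidden randomness.
#'
#' @param params [kinetics_params()] row.
#' @param conc Analyte concentration (M).
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param dt Sampling interval (s), smaller than either phase.
#' @param noise_sd Gaussian noise standard deviation (response units);
#'   0 for a noiseless curve.
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @return Tibble of class `afm_sensorgram`: `time`, `response`, `conc`,
#'   `phase` (`"association"`/`"dissociation"`); attribute `t_assoc`.
#' @export
simulate_sensorgram <- function(params, conc, t_assoc, t_dissoc, dt = 0.5,
                                noise_sd = 0, seed = NULL) {
  if (any(c(conc, t_assoc, t_dissoc, dt) <= 0)) abort("inputs must be positive")
  if (dt >= t_assoc || dt >= t_dissoc) abort("dt must be smaller than the phase durations")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed)) abort("noisy simulation requires an explicit seed")
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- langmuir_response(t, params$kon, params$koff, params$rmax, conc, t_assoc)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    r <- r + rnorm(length(r), 0, noise_sd)
  }
  out <- tibble(
    time = t, response = r, conc = conc,
    phase = ifelse(t <= t_assoc, "association", "dissociation")
  )
  class(out) <- c("afm_sensorgram", class(out))
  attr(out, "t_assoc") <- t_assoc
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Global 1:1 kinetic fit across concentrations
#'
#' Fits `kon`, `koff` and `rmax` shared across all curves by
#' Levenberg-Marquardt nonlinear least squares (log-parameterised so the
#' rates stay positive). Starting values come from a linearised
#' observed-rate analysis: for each curve the association phase gives an
#' apparent rate `kobs`, and the regression `kobs = kon * C + koff`
#' initialises the rates. `kd` is reported as `koff/kon` identically.
#'
#' @param sensorgrams A single tibble with columns `time`, `response`,
#'   `conc`, `phase` (stacked curves), or a list of
#'   [simulate_sensorgram()] outputs. At least 3 distinct concentrations
#'   spanning a 10-fold range are required.
#' @param t_assoc Association end time (s); taken from the data's `phase`
#'   column if omitted.
#' @return Object of class `afm_kinetics_fit` with elements `params`
#'   (tibble: `kon`, `koff`, `kd`, `rmax`, standard errors), `data`,
#'   `fitted`, `residual_sd`, `converged`. Has [tidy()] and [glance()]
#'   methods and an [ggplot2::autoplot()].
#' @export
fit_1to1 <- function(sensorgrams, t_assoc = NULL) {
  d <- if (is.data.frame(sensorgrams)) as_tibble(sensorgrams) else bind_rows(sensorgrams)
  need <- c("time", "response", "conc", "phase")
  if (!all(need %in% names(d))) abort("sensorgram data needs columns time, response, conc, phase")
  concs <- sort(unique(d$conc))
  if (length(concs) < 3) abort("need at least 3 distinct analyte concentrations")
  if (max(concs) / min(concs) < 10) abort("concentrations must span at least a 10-fold range")
  if (is.null(t_assoc)) t_assoc <- max(d$time[d$phase == "association"])
  if (all(abs(d$response) < 1e-12)) abort("all-zero response; nothing to fit")

  # --- initialisation: per-curve kobs from a log-linear association fit
  kobs <- map_dbl(concs, function(cc) {
    a <- d[d$conc == cc & d$phase == "association" & d$time > 0, ]
    req <- max(a$response) * 1.02 + 1e-9
    y <- 1 - a$response / req
    ok <- y > 1e-6
    if (sum(ok) < 3) return(NA_real_)
    -unname(coef(lm(log(y[ok]) ~ a$time[ok]))[2])
  })
  ok <- is.finite(kobs) & kobs > 0
  if (sum(ok) >= 2) {
    ab <- coef(lm(kobs[ok] ~ concs[ok]))
    kon0 <- max(ab[2], 1e2)
    koff0 <- max(ab[1], 1e-4)
  } else {
    kon0 <- 1e4; koff0 <- 0.1
  }
  rmax0 <- max(d$response) * (1 + koff0 / (kon0 * max(concs)))

  model_resid <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2]); rmax <- exp(p[3])
    pred <- langmuir_response(d$time, kon, koff, rmax, d$conc, t_assoc)
    d$response - pred
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(kon0, koff0, rmax0)),
    fn = model_resid,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  )
  converged <- fit$info %in% 1:4
  if (!converged) warn(paste0("1:1 fit did not converge: ", fit$message))
  est <- exp(fit$par)
  # delta-method SEs on the natural scale from the log-scale covariance
  se <- tryCatch({
    cv <- tryCatch(vcov(fit), error = function(e) NULL)
    if (is.null(cv)) rep(NA_real_, 3) else sqrt(diag(cv)) * est
  }, error = function(e) rep(NA_real_, 3))
  params <- tibble(
    kon = est[1], koff = est[2], kd = est[2] / est[1], rmax = est[3],
    kon_se = se[1], koff_se = se[2], rmax_se = se[3]
  )
  fitted <- langmuir_response(d$time, est[1], est[2], est[3], d$conc, t_assoc)
  structure(list(
    params = params,
    data = d,
    fitted = mutate(d, fitted = fitted),
    residual_sd = sd(d$response - fitted),
    t_assoc = t_assoc,
    converged = converged
  ), class = "afm_kinetics_fit")
}

#' @export
print.afm_kinetics_fit <- function(x, ...) {
  p <- x$params
  cat("<afm_kinetics_fit> 1:1 Langmuir, global over ",
      length(unique(x$data$conc)), " concentrations\n",
      sprintf("  kon  = %.4g 1/(M s)\n  koff = %.4g 1/s\n  KD   = %.4g M\n  Rmax = %.4g RU\n",
              p$kon, p$koff, p$kd, p$rmax),
      if (!x$converged) "  (fit did not converge)\n", sep = "")
  invisible(x)
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Fits `R(C) = bottom + (top - bottom) / (1 + (C / ic50)^hill)` by
#' Levenberg-Marquardt least squares. `hill > 0` describes a response
#' that falls with concentration (the usual competition-format readout);
#' the sign is free during fitting. Initialisation scans a log-spaced
#' IC50 grid across the measured concentrations. Flat data is rejected as
#' unidentifiable.
#'
#' @param conc Concentrations (M), at least 5 distinct values.
#' @param response Responses, same length.
#' @return Object of class `afm_4pl_fit` with `params` (tibble: `ic50`,
#'   `hill`, `top`, `bottom`), `data`, `fitted`, `residual_sd`,
#'   `converged`. Has [tidy()]/[glance()]/[ggplot2::autoplot()] methods.
#' @export
fit_4pl <- function(conc, response) {
  if (length(conc) != length(response)) abort("conc and response lengths differ")
  if (length(unique(conc)) < 5) abort("need at least 5 distinct concentrations")
  if (any(conc <= 0)) abort("concentrations must be positive")
  if (diff(range(response)) < max(1e-12, 1e-9 * max(abs(response)))) {
    abort("flat response; IC50 unidentifiable")
  }
  ord <- order(conc)
  cc <- conc[ord]; rr <- response[ord]
  top0 <- max(rr); bot0 <- min(rr)
  resid_fn <- function(p) {
    ic50 <- exp(p[1]); hill <- p[2]; top <- p[3]; bottom <- p[4]
    response - (bottom + (top - bottom) / (1 + (conc / ic50)^hill))
  }
  grid <- exp(seq(log(min(cc)), log(max(cc)), length.out = 15))
  best <- NULL
  for (ic0 in grid) {
    for (h0 in c(1, -1)) {
      f <- tryCatch(minpack.lm::nls.lm(
        par = c(log(ic0), h0, top0, bot0), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13, ptol = 1e-13)
      ), error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
    }
  }
  if (is.null(best)) abort("4PL fit failed")
  p <- best$par
  # canonical form: the (hill, top, bottom) -> (-hill, bottom, top)
  # reparameterisation traces the same curve; report hill > 0
  if (p[2] < 0) p <- c(p[1], -p[2], p[4], p[3])
  params <- tibble(ic50 = exp(p[1]), hill = p[2], top = p[3], bottom = p[4])
  fitted <- params$bottom + (params$top - params$bottom) /
    (1 + (conc / params$ic50)^params$hill)
  structure(list(
    params = params,
    data = tibble(conc = conc, response = response),
    fitted = tibble(conc = conc, response = response, fitted = fitted),
    residual_sd = sd(response - fitted),
    converged = best$info %in% 1:4
  ), class = "afm_4pl_fit")
}

#' @export
print.afm_4pl_fit <- function(x, ...) {
  p <- x$params
  cat("<afm_4pl_fit> ",
      sprintf("IC50 = %.4g M, hill = %.3g, top = %.4g, bottom = %.4g\n",
              p$ic50, p$hill, p$top, p$bottom), sep = "")
  invisible(x)
}

#' IC50 fold-shift and masking-efficiency category
#'
#' The masking field reports efficiency as the IC50 ratio of the masked
#' over the unmasked binder, binned as at least 100-fold, 10-100-fold,
#' 2-10-fold, or under 2-fold (lower edges inclusive).
#'
#' @param ic50_masked,ic50_unmasked IC50 values (M), both positive.
#' @return One-row tibble: `ic50_masked`, `ic50_unmasked`, `fold_shift`,
#'   `category`.
#' @export
fold_shift <- function(ic50_masked, ic50_unmasked) {
  if (ic50_masked <= 0 || ic50_unmasked <= 0) abort("IC50 values must be positive")
  fold <- ic50_masked / ic50_unmasked
  category <- if (fold >= 100) ">=100-fold"
  else if (fold >= 10) "10-100-fold"
  else if (fold >= 2) "2-10-fold"
  else "<2-fold"
  tibble(ic50_masked = ic50_masked, ic50_unmasked = ic50_unmasked,
         fold_shift = fold, category = category)
}
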