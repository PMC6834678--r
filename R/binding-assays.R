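# Computational pieces of the binding / functional assays: SPR equilibrium
# and kinetic 1:1 fits, pH-normalized binding, percent target-cell lysis,
# and plasmon-wavelength extraction from gold-nanoparticle absorbance
# spectra.

#' 1:1 Langmuir equilibrium response
#'
#' Steady-state SPR response `Rmax * C / (Kd + C)` of a 1:1 binding model.
#'
#' @param C Analyte concentration(s), nM, `>= 0`.
#' @param Kd Equilibrium dissociation constant, nM, `> 0`.
#' @param Rmax Saturating response, RU.
#' @return Response(s) in RU.
#' @examples
#' langmuir_equilibrium(550, Kd = 550, Rmax = 100) # half saturation
#' @export
langmuir_equilibrium <- function(C, Kd, Rmax) {
  stopifnot(all(C >= 0), Kd > 0)
  Rmax * C / (Kd + C)
}

#' Fit a steady-state 1:1 isotherm
#'
#' Nonlinear least squares of [langmuir_equilibrium()] on untransformed
#' responses with uniform weights. Confidence intervals come from the
#' linearized covariance of the fit. An isotherm with no signal (all
#' responses zero) or a Kd far outside the tested concentration range
#' (100-fold) is returned flagged rather than failing, mirroring
#' "not detectable" entries in affinity tables.
#'
#' @param data Data frame with columns `conc_nM` and `response_RU`; at
#'   least 4 concentrations spanning at least 10-fold.
#' @return An object of class `kd_fit`; `tidy()` gives `Kd_nM` and
#'   `Rmax_RU` with SE and 95% CI, `glance()` the fit quality and flag.
#' @export
fit_kd_steady_state <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("conc_nM", "response_RU") %in% names(data)))
  conc <- data$conc_nM
  resp <- data$response_RU
  stopifnot(all(conc > 0), all(is.finite(resp)))
  if (length(unique(conc)) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  if (max(conc) / min(conc) < 10) {
    stop("concentrations must span at least 10-fold", call. = FALSE)
  }
  if (max(abs(resp)) == 0) {
    return(new_kd_fit(NULL, data, flagged = TRUE, reason = "no binding"))
  }
  half <- max(resp) / 2
  kd0 <- tryCatch(stats::approx(resp, conc, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(response_RU ~ Rmax * conc_nM / (Kd + conc_nM),
                      data = data,
                      start = list(Rmax = 1.05 * max(resp), Kd = kd0),
                      lower = c(Rmax = 0, Kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_kd_fit(NULL, data, flagged = TRUE,
                      reason = "fit did not converge"))
  }
  kd <- stats::coef(fit)[["Kd"]]
  flagged <- kd > 100 * max(conc) || kd < min(conc) / 100
  reason <- if (flagged) "Kd outside 100x the tested range" else NA_character_
  new_kd_fit(fit, data, flagged = flagged, reason = reason)
}

new_kd_fit <- function(fit, data, flagged, reason = NA_character_) {
  est <- if (is.null(fit)) {
    tibble::tibble(term = c("Kd_nM", "Rmax_RU"), estimate = NA_real_,
                   std.error = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_)
  } else {
    cf <- stats::coef(fit)[c("Kd", "Rmax")]
    se <- sqrt(diag(stats::vcov(fit)))[c("Kd", "Rmax")]
    df <- stats::df.residual(fit)
    tq <- stats::qt(0.975, df)
    tibble::tibble(term = c("Kd_nM", "Rmax_RU"),
                   estimate = unname(cf),
                   std.error = unname(se),
                   conf.low = unname(cf - tq * se),
                   conf.high = unname(cf + tq * se))
  }
  structure(list(estimates = est, fit = fit, data = data,
                 flagged = flagged, reason = reason),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<kd_fit> 1:1 steady-state isotherm\n")
  if (x$flagged) cat("  FLAGGED:", x$reason, "\n")
  print(x$estimates)
  invisible(x)
}

#' Tidy a steady-state Kd fit
#'
#' @param x A `kd_fit` from [fit_kd_steady_state()].
#' @param ... Unused.
#' @return Tibble of estimates with standard errors and 95% CI.
#' @method tidy kd_fit
#' @export
tidy.kd_fit <- function(x, ...) x$estimates

#' @rdname tidy.kd_fit
#' @method glance kd_fit
#' @export
glance.kd_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(sigma = NA_real_, r.squared = NA_real_,
                          flagged = x$flagged, reason = x$reason))
  }
  r <- stats::residuals(x$fit)
  y <- x$data$response_RU
  tibble::tibble(
    sigma = sqrt(sum(r^2) / stats::df.residual(x$fit)),
    r.squared = 1 - sum(r^2) / sum((y - mean(y))^2),
    flagged = x$flagged, reason = x$reason
  )
}

#' Isotherm plot with fitted curve
#'
#' @param object A `kd_fit`.
#' @param ... Unused.
#' @return A ggplot of response vs concentration (log axis) with the
#'   fitted 1:1 isotherm when available.
#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$conc_nM, .data$response_RU)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "analyte concentration (nM)", y = "response (RU)")
  if (!is.null(object$fit)) {
    cf <- stats::coef(object$fit)
    grid <- tibble::tibble(
      conc_nM = exp(seq(log(min(object$data$conc_nM)),
                        log(max(object$data$conc_nM)), length.out = 100)))
    grid$response_RU <- langmuir_equilibrium(grid$conc_nM, cf[["Kd"]],
                                             cf[["Rmax"]])
    p <- p + ggplot2::geom_line(data = grid, color = "steelblue")
  }
  p
}

#' 1:1 Langmuir binding kinetics
#'
#' Response trace of the 1:1 kinetic model: during association at analyte
#' concentration `C`, `R(t) = Req (1 - exp(-(ka C + kd_off) t))` with
#' `Req = Rmax C / (Kd + C)` and `Kd = kd_off / ka`; after `t_assoc` the
#' response decays as `exp(-kd_off (t - t_assoc))`. The `t -> Inf`
#' association limit therefore coincides with [langmuir_equilibrium()].
#'
#' @param times Times in seconds.
#' @param C Analyte concentration, nM.
#' @param ka Association rate, 1/(nM s), `>= 0`.
#' @param kd_off Dissociation rate, 1/s, `>= 0`.
#' @param Rmax Saturating response, RU.
#' @param t_assoc End of the association phase in seconds (default `Inf`:
#'   association only).
#' @return A tibble with `time_s` and `response_RU`.
#' @export
kinetic_1to1 <- function(times, C, ka, kd_off, Rmax, t_assoc = Inf) {
  stopifnot(ka >= 0, kd_off >= 0, C >= 0, all(times >= 0))
  req <- if (ka == 0) 0 else Rmax * C / (kd_off / ka + C)
  kobs <- ka * C + kd_off
  assoc <- function(t) req * (1 - exp(-kobs * t))
  r <- ifelse(times <= t_assoc, assoc(times),
              assoc(t_assoc) * exp(-kd_off * (times - t_assoc)))
  tibble::tibble(time_s = times, response_RU = r)
}

#' Fit 1:1 kinetics across concentrations
#'
#' Global nonlinear least squares of association traces at several analyte
#' concentrations to the 1:1 model (shared `ka`, `kd_off`, `Rmax`).
#' Starting values come from curve stripping: per-concentration observed
#' rate constants `k_obs` regressed on concentration give `ka` (slope) and
#' `kd_off` (intercept).
#'
#' @param data Data frame with columns `conc_nM`, `time_s`, `response_RU`
#'   (association phase).
#' @return A tibble with `ka_per_nM_s`, `kd_off_per_s`, `Rmax_RU` and the
#'   implied `Kd_nM = kd_off / ka`.
#' @export
fit_kinetics_1to1 <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("conc_nM", "time_s", "response_RU") %in% names(data)))
  concs <- sort(unique(data$conc_nM))
  if (length(concs) < 2L) {
    stop("kinetic fitting needs traces at >= 2 concentrations",
         call. = FALSE)
  }
  # strip: per-concentration plateau and observed rate
  strip <- purrr::map_dfr(concs, function(cc) {
    tr <- data[data$conc_nM == cc, ]
    req <- max(tr$response_RU)
    ok <- tr$response_RU < 0.99 * req & tr$response_RU > 0 & tr$time_s > 0
    kobs <- if (sum(ok) >= 2) {
      -unname(stats::coef(stats::lm(log(1 - tr$response_RU[ok] / (req * 1.001))
                                    ~ tr$time_s[ok]))[2])
    } else {
      NA_real_
    }
    tibble::tibble(conc_nM = cc, req = req, kobs = kobs)
  })
  strip <- strip[is.finite(strip$kobs) & strip$kobs > 0, ]
  if (nrow(strip) >= 2L) {
    lf <- stats::lm(kobs ~ conc_nM, data = strip)
    ka0 <- max(unname(stats::coef(lf)[2]), 1e-8)
    koff0 <- max(unname(stats::coef(lf)[1]), 1e-8)
  } else {
    ka0 <- 1e-4
    koff0 <- 1e-2
  }
  rmax0 <- max(data$response_RU) * 1.1
  fit <- minpack.lm::nlsLM(
    response_RU ~ exp(lRmax) * conc_nM / (exp(lkoff) / exp(lka) + conc_nM) *
      (1 - exp(-(exp(lka) * conc_nM + exp(lkoff)) * time_s)),
    data = data,
    start = list(lka = log(ka0), lkoff = log(koff0), lRmax = log(rmax0)),
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  )
  cf <- exp(stats::coef(fit))
  tibble::tibble(ka_per_nM_s = cf[["lka"]], kd_off_per_s = cf[["lkoff"]],
                 Rmax_RU = cf[["lRmax"]],
                 Kd_nM = cf[["lkoff"]] / cf[["lka"]])
}

#' Normalized pH-dependent binding
#'
#' Ratio of the SPR response at some pH to the maximal response at pH 6.0
#' (the reference condition of full endosomal binding), clipped below at 0.
#'
#' @param ru Response(s) at the probed pH, RU.
#' @param ru_max_ph6 Maximal response at pH 6.0, RU, `> 0`.
#' @return Normalized binding fraction(s).
#' @export
normalized_ph_binding <- function(ru, ru_max_ph6) {
  if (!is.numeric(ru_max_ph6) || length(ru_max_ph6) != 1L ||
      ru_max_ph6 <= 0) {
    stop("`ru_max_ph6` must be a single positive reference response",
         call. = FALSE)
  }
  pmax(ru / ru_max_ph6, 0)
}

#' Percent target-cell lysis
#'
#' `100 (E - S) / (M - S)` where `E` is the experimental fluorescence, `S`
#' the spontaneous-release (no antibody) control and `M` the
#' maximal-release (detergent) control.
#'
#' @param E,S,M Fluorescence readings (recycled to a common length).
#' @return Percent lysis.
#' @examples
#' percent_lysis(E = 80, S = 20, M = 120) # 60
#' @export
percent_lysis <- function(E, S, M) {
  if (any(M == S)) {
    stop("no dynamic range: maximal and spontaneous release are equal",
         call. = FALSE)
  }
  100 * (E - S) / (M - S)
}

#' Plasmon wavelength of an absorbance spectrum
#'
#' Least-squares quadratic over the window of `half_window` measurements on
#' each side of the absorbance maximum (41 points for the default window of
#' 20, i.e. the ~40 measurements surrounding the peak); the plasmon
#' wavelength is the vertex `-b / 2a` where the fitted first derivative
#' vanishes. Ties in the maximum break toward the lower wavelength; a peak
#' closer than `half_window` points to an edge truncates the window with a
#' warning; a non-concave fit (`a >= 0`) is an error.
#'
#' @param data Data frame with columns `wavelength_nm` (strictly
#'   increasing, equally spaced, e.g. 450-650 in 1 nm steps) and
#'   `absorbance`.
#' @param half_window Points on each side of the maximum (default 20).
#' @return Plasmon wavelength in nm.
#' @export
plasmon_wavelength <- function(data, half_window = 20L) {
  stopifnot(is.data.frame(data),
            all(c("wavelength_nm", "absorbance") %in% names(data)))
  w <- data$wavelength_nm
  a <- data$absorbance
  n <- length(w)
  if (n < 2L * half_window + 1L) {
    stop("spectrum must contain at least ", 2L * half_window + 1L,
         " measurements", call. = FALSE)
  }
  dw <- diff(w)
  if (any(dw <= 0) || diff(range(dw)) > 1e-6 * stats::median(dw)) {
    stop("wavelengths must be strictly increasing and equally spaced",
         call. = FALSE)
  }
  imax <- which.max(a) # first maximum = lower wavelength on ties
  lo <- imax - half_window
  hi <- imax + half_window
  if (lo < 1L || hi > n) {
    warning("absorbance maximum within ", half_window,
            " points of the spectrum edge; window truncated")
    lo <- max(1L, lo)
    hi <- min(n, hi)
  }
  idx <- lo:hi
  fit <- stats::lm(a[idx] ~ w[idx] + I(w[idx]^2))
  cf <- stats::coef(fit)
  if (!is.finite(cf[3]) || cf[3] >= 0) {
    stop("no concave peak: quadratic coefficient is non-negative",
         call. = FALSE)
  }
  unname(-cf[2] / (2 * cf[3]))
}

#' Plasmon shift between a test and a control spectrum
#'
#' Difference of [plasmon_wavelength()] of the test sample and of the
#' no-antibody control; self-association red-shifts the gold-nanoparticle
#' plasmon peak.
#'
#' @param test,control Spectra as in [plasmon_wavelength()].
#' @inheritParams plasmon_wavelength
#' @return Shift in nm (positive = red shift).
#' @export
plasmon_shift <- function(test, control, half_window = 20L) {
  plasmon_wavelength(test, half_window) -
    plasmon_wavelength(control, half_window)
}
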