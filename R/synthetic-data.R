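# Seeded generators for every input the analysis consumes: serum
# concentration-time curves under i.v. bolus dosing with multiplicative
# assay noise and LLOQ censoring, packaged half-life / PK / affinity
# reference tables, SPR isotherms and absorbance spectra.

#' Design of a simulated mouse PK study
#'
#' Captures the study conditions: 2 mg/kg i.v. bolus on day 0, tail-vein
#' sampling at fixed times, per-animal multiplicative log-normal assay
#' noise and lower-limit-of-quantification censoring. The true
#' concentration curve per variant comes either from a
#' [trafficking_params()] object (bolus into the central compartment,
#' `C_c(0) = dose / plasma volume`) or from a biexponential parameter table.
#'
#' @param truth Either a [trafficking_params()] object whose variants are
#'   simulated, or a data frame with columns `variant`, `A_ug_ml`,
#'   `alpha_per_day`, `B_ug_ml`, `beta_per_day`.
#' @param dose_mg_kg Intravenous bolus dose (default 2 mg/kg).
#' @param times_h Sampling times in hours; default 1 h, 6 h, then days 1,
#'   2, 4, 7, 10, 14, 21, 28 (>= 6 terminal points for the NCA window).
#' @param n_animals Animals per variant (default 6).
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   assay noise (default 0.1).
#' @param lloq_ug_ml Lower limit of quantification; simulated values below
#'   it are flagged censored (default 0.05 ug/mL).
#' @param central_volume_ml_kg Plasma (central) volume used to convert the
#'   dose to an initial concentration when `truth` is a trafficking model
#'   (default 50 mL/kg, a typical mouse plasma volume).
#' @param seed Integer seed; the generator is a pure function of
#'   (design, seed).
#' @return An object of class `study_design`.
#' @export
study_design <- function(truth, dose_mg_kg = 2,
                         times_h = c(1, 6, 24, 48, 96, 168, 240, 336,
                                     504, 672),
                         n_animals = 6L, cv = 0.1, lloq_ug_ml = 0.05,
                         central_volume_ml_kg = 50, seed = 1L) {
  stopifnot(dose_mg_kg > 0, n_animals >= 1L, cv >= 0, lloq_ug_ml >= 0,
            central_volume_ml_kg > 0)
  if (any(diff(times_h) <= 0) || any(times_h < 0)) {
    stop("`times_h` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (inherits(truth, "trafficking_params")) {
    kind <- "trafficking"
    variants <- variant_names(truth) %||% "default"
  } else if (is.data.frame(truth)) {
    stopifnot(all(c("variant", "A_ug_ml", "alpha_per_day", "B_ug_ml",
                    "beta_per_day") %in% names(truth)))
    kind <- "biexponential"
    variants <- truth$variant
  } else {
    stop("`truth` must be trafficking parameters or a biexponential table",
         call. = FALSE)
  }
  structure(
    list(truth = truth, kind = kind, variants = variants,
         dose_mg_kg = dose_mg_kg, times_h = times_h,
         n_animals = as.integer(n_animals), cv = cv,
         lloq_ug_ml = lloq_ug_ml,
         central_volume_ml_kg = central_volume_ml_kg,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

design_prediction <- function(design, variant) {
  if (design$kind == "trafficking") {
    c0 <- design$dose_mg_kg * 1000 / design$central_volume_ml_kg
    v <- if (identical(variant, "default")) NULL else variant
    propagate(c(c0, 0, 0), design$truth, design$times_h, variant = v)$C_c
  } else {
    row <- design$truth[design$truth$variant == variant, ]
    td <- design$times_h / 24
    row$A_ug_ml * exp(-row$alpha_per_day * td) +
      row$B_ug_ml * exp(-row$beta_per_day * td)
  }
}

#' Simulate a serum PK study
#'
#' Per animal, the model-predicted central concentration at each sampling
#' time is multiplied by log-normal noise `exp(eps)`,
#' `eps ~ Normal(0, sigma)` with `sigma = sqrt(ln(1 + CV^2))` (so the
#' multiplicative CV equals the design CV), and flagged censored when below
#' the LLOQ. Identical designs (including seed) reproduce identical
#' datasets.
#'
#' @param design A [study_design()] object.
#' @return A tibble with columns `subject_id`, `variant`, `time_h`,
#'   `conc_ug_ml`, `censored` (0/1), `dose_mg_kg`.
#' @export
simulate_pk_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  sigma <- sqrt(log(1 + design$cv^2))
  out <- purrr::map_dfr(design$variants, function(v) {
    pred <- design_prediction(design, v)
    purrr::map_dfr(seq_len(design$n_animals), function(a) {
      eps <- if (sigma > 0) stats::rnorm(length(pred), 0, sigma) else
        rep(0, length(pred))
      conc <- pred * exp(eps)
      tibble::tibble(
        subject_id = sprintf("%s_%02d", v, a),
        variant = v,
        time_h = design$times_h,
        conc_ug_ml = conc,
        censored = as.integer(conc < design$lloq_ug_ml),
        dose_mg_kg = design$dose_mg_kg
      )
    })
  })
  tibble::as_tibble(out)
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "fcrnpk", mustWork = TRUE)
}

#' Packaged beta-phase half-life observations
#'
#' Reference beta-phase serum half-lives (mean +/- SD, hours) of
#' trastuzumab formatted with wt, DHS, YTE or LS Fc domains after a 2 mg/kg
#' i.v. bolus, measured in two human-FcRn mouse models: the hemizygous
#' Tg276 transgenic strain (n = 11) and the Scarlett knock-in strain
#' (hFcRn, hbeta2m, hFcgammaR, hIgG1/kappa; n = 6). These are the
#' likelihood data for [fit_trafficking()]; the standard error column is
#' `sd_h / sqrt(n)`.
#'
#' @param strain `"Tg276"` or `"Scarlett"`.
#' @return A tibble with `strain`, `variant`, `mean_h`, `sd_h`, `n`, `se_h`.
#' @export
half_life_observations <- function(strain = c("Tg276", "Scarlett")) {
  strain <- match.arg(strain)
  tab <- readr::read_csv(extdata_path("half_lives.csv"),
                         show_col_types = FALSE)
  tab <- tab[tab$strain == strain, ]
  tab$se_h <- tab$sd_h / sqrt(tab$n)
  tab
}

#' Packaged FcRn affinity table
#'
#' Equilibrium dissociation constants of the Fc variants for the
#' hFcRn:hbeta2m dimer at endosomal pH 5.8 and, where detectable, at
#' physiological pH 7.4 at three immobilization densities (~500 / 2000 /
#' 4000 RU). `NA` marks "not detectable"; `ph74_detectable` summarizes
#' whether any density showed binding at pH 7.4. The ordering of the pH 5.8
#' and pH 7.4 columns drives the prior order constraints in
#' [build_priors()]. The EDHY and EDHS screening isolates are included for
#' affinity fold-change arithmetic only.
#'
#' @return A tibble with `variant`, `kd_ph58_nM`, `kd_ph58_sd_nM`,
#'   `kd_ph74_low_nM`, `kd_ph74_medium_nM`, `kd_ph74_high_nM`,
#'   `ph74_detectable`.
#' @export
fcrn_affinities <- function() {
  readr::read_csv(extdata_path("fcrn_affinities.csv"),
                  show_col_types = FALSE)
}

#' Packaged per-variant PK parameter tables
#'
#' Reference noncompartmental PK parameters (mean +/- SD) per Fc variant in
#' the Tg276 and Scarlett strains: AUC to infinity (ug day/mL), clearance
#' (per day; whether per animal or per kilogram is ambiguous for these
#' measurements, so only ratio structure should be compared), beta-phase
#' half-life (h), steady-state volume of distribution (mL/kg) and, for
#' Scarlett, C_max in ug/mL (the only unit consistent with 2 mg/kg
#' dosing). These tables feed [fold_changes()].
#'
#' @inheritParams half_life_observations
#' @return A tibble with `variant` and `<param>` / `<param>_sd` columns.
#' @export
pk_reference_table <- function(strain = c("Tg276", "Scarlett")) {
  strain <- match.arg(strain)
  tab <- readr::read_csv(extdata_path("pk_reference.csv"),
                         show_col_types = FALSE)
  tab <- tab[tab$strain == strain, ]
  tab$strain <- NULL
  if (all(is.na(tab$cmax_ug_ml))) {
    tab$cmax_ug_ml <- NULL
    tab$cmax_sd <- NULL
  }
  tab
}

#' Two-fold SPR concentration ladder
#'
#' The analyte dilution series used for steady-state isotherms: serial
#' two-fold dilutions from `top` with the final step clamped at `bottom`
#' (default 1000, 500, 250, 125, 62.5, 40 nM).
#'
#' @param top,bottom Highest and lowest concentrations (nM).
#' @param fold Dilution factor (default 2).
#' @return Decreasing numeric vector of concentrations (nM).
#' @export
spr_concentration_ladder <- function(top = 1000, bottom = 40, fold = 2) {
  stopifnot(top > bottom, bottom > 0, fold > 1)
  out <- top
  while (out[length(out)] > bottom) {
    out <- c(out, max(out[length(out)] / fold, bottom))
  }
  out
}

#' Simulate a steady-state SPR isotherm
#'
#' 1:1 Langmuir equilibrium responses at a concentration series with
#' optional multiplicative log-normal noise.
#'
#' @param Kd_nM,Rmax_RU True equilibrium constant and saturating response.
#' @param conc_nM Concentration series (default the two-fold 1000-40 nM
#'   ladder, [spr_concentration_ladder()]).
#' @param cv Multiplicative noise CV (default 0: exact model values).
#' @param seed Optional integer seed.
#' @return A tibble with `conc_nM`, `response_RU`.
#' @export
simulate_isotherm <- function(Kd_nM, Rmax_RU,
                              conc_nM = spr_concentration_ladder(),
                              cv = 0, seed = NULL) {
  stopifnot(Kd_nM > 0, Rmax_RU > 0, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  resp <- langmuir_equilibrium(conc_nM, Kd_nM, Rmax_RU)
  if (cv > 0) {
    sigma <- sqrt(log(1 + cv^2))
    resp <- resp * exp(stats::rnorm(length(resp), 0, sigma))
  }
  tibble::tibble(conc_nM = conc_nM, response_RU = resp)
}

#' Simulate a nanoparticle absorbance spectrum
#'
#' Gaussian plasmon peak on the 450-650 nm grid in 1 nm increments, with
#' optional additive Gaussian noise.
#'
#' @param center_nm,width_nm,amplitude Peak position, Gaussian SD width and
#'   height.
#' @param baseline Constant absorbance offset.
#' @param noise_sd Additive noise SD (default 0).
#' @param wavelengths_nm Wavelength grid (default `450:650`).
#' @param seed Optional integer seed.
#' @return A tibble with `wavelength_nm`, `absorbance`.
#' @export
simulate_spectrum <- function(center_nm = 535, width_nm = 30,
                              amplitude = 1, baseline = 0.02,
                              noise_sd = 0, wavelengths_nm = 450:650,
                              seed = NULL) {
  stopifnot(width_nm > 0, amplitude > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  a <- baseline + amplitude *
    exp(-(wavelengths_nm - center_nm)^2 / (2 * width_nm^2))
  if (noise_sd > 0) {
    a <- a + stats::rnorm(length(a), 0, noise_sd)
  }
  tibble::tibble(wavelength_nm = as.numeric(wavelengths_nm), absorbance = a)
}
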