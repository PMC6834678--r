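# Noncompartmental and two-compartment PK estimation from serum
# concentration-time data. AUC uses the linear-up/log-down trapezoid;
# the terminal window is the last n >= min_points measurable points with n
# chosen to maximize adjusted R^2; tables are in the field's mixed units
# (times sampled in hours, AUC/clearance per day).

# Per-interval trapezoid contributions. Linear rule when the concentration
# is non-decreasing or an endpoint is zero; logarithmic rule on strictly
# decreasing intervals with positive endpoints. Times in days.
auc_segments <- function(time, conc) {
  n <- length(time)
  t1 <- time[-n]; t2 <- time[-1]
  c1 <- conc[-n]; c2 <- conc[-1]
  dt <- t2 - t1
  log_ok <- c1 > 0 & c2 > 0 & c2 < c1
  k <- ifelse(log_ok, log(c1 / c2) / dt, NA_real_)
  auc <- ifelse(log_ok, (c1 - c2) / k, dt * (c1 + c2) / 2)
  aumc <- ifelse(log_ok,
                 (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2,
                 dt * (t1 * c1 + t2 * c2) / 2)
  list(auc = auc, aumc = aumc)
}

check_series <- function(time, conc, min_points = 2L) {
  if (length(time) != length(conc)) {
    stop("`time` and `conc` must have equal length", call. = FALSE)
  }
  if (length(time) < min_points) {
    stop("at least ", min_points, " uncensored points are required",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  invisible(NULL)
}

#' Log-linear trapezoidal AUC and AUMC to the last observation
#'
#' Area under the concentration-time curve by the linear-up/log-down
#' convention: linear trapezoid on non-decreasing intervals or intervals
#' touching zero, logarithmic trapezoid `(C1 - C2) dt / ln(C1/C2)` on
#' strictly decreasing positive intervals. `aumc_loglinear()` returns the
#' first-moment area under the same per-interval rules.
#'
#' @param time Times, strictly increasing. Use days for areas in
#'   ug day/mL.
#' @param conc Concentrations (ug/mL), aligned with `time`, all `>= 0`.
#' @return Scalar area (concentration x time units).
#' @examples
#' auc_loglinear(c(0, 1), c(100, 50)) # log rule: 50 / ln 2
#' @export
auc_loglinear <- function(time, conc) {
  check_series(time, conc)
  sum(auc_segments(time, conc)$auc)
}

#' @rdname auc_loglinear
#' @export
aumc_loglinear <- function(time, conc) {
  check_series(time, conc)
  sum(auc_segments(time, conc)$aumc)
}

#' Terminal-phase log-linear regression
#'
#' Ordinary least squares of `ln(conc)` on `time` over the terminal window:
#' the last `n` measurable points, `n` running from `min_points` up to all
#' points, selecting the window that maximizes adjusted R^2 (smallest window
#' on ties). The slope magnitude is the terminal rate constant `lambda_z`.
#'
#' @inheritParams auc_loglinear
#' @param min_points Minimum number of terminal points (default 6).
#' @return A list with `lambda_z` (1/time unit), `intercept` (log
#'   concentration at time 0), `n_points`, and `adj_r2`.
#' @export
terminal_phase_fit <- function(time, conc, min_points = 6L) {
  check_series(time, conc, min_points = min_points)
  if (any(conc <= 0)) {
    stop("terminal regression requires positive concentrations", call. = FALSE)
  }
  n <- length(time)
  best <- NULL
  for (k in seq(min_points, n)) {
    idx <- seq(n - k + 1L, n)
    y <- log(conc[idx])
    fit <- stats::lm(y ~ time[idx])
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 0
    adj_r2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj_r2 > best$adj_r2 + 1e-12) {
      best <- list(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   n_points = k, adj_r2 = adj_r2)
    }
  }
  if (best$slope >= 0) {
    stop("no terminal decay: fitted terminal slope is non-negative",
         call. = FALSE)
  }
  list(lambda_z = -best$slope, intercept = best$intercept,
       n_points = best$n_points, adj_r2 = best$adj_r2)
}

#' Extrapolate AUC and AUMC to infinite time
#'
#' `AUC_inf = AUC_last + C_last / lambda_z` and
#' `AUMC_inf = AUMC_last + t_last C_last / lambda_z + C_last / lambda_z^2`.
#'
#' @param auc_last,aumc_last Areas to the last observation.
#' @param t_last,c_last Time and concentration of the last observation.
#' @param lambda_z Terminal rate constant (> 0), per same time unit.
#' @return A list with `auc_inf` and `aumc_inf`.
#' @export
auc_to_inf <- function(auc_last, aumc_last, t_last, c_last, lambda_z) {
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("`lambda_z` must be positive", call. = FALSE)
  }
  list(auc_inf = auc_last + c_last / lambda_z,
       aumc_inf = aumc_last + t_last * c_last / lambda_z +
         c_last / lambda_z^2)
}

#' Clearance and steady-state volume of distribution
#'
#' `clearance()` computes `CL = dose / AUC_inf` (mL/day/kg for a dose in
#' ug/kg and AUC in ug day/mL). `vss()` computes
#' `V_ss = dose x AUMC_inf / AUC_inf^2` (mL/kg).
#'
#' @param dose Dose (ug/kg body weight), positive.
#' @param auc_inf Area under the curve to infinity (ug day/mL), positive.
#' @param aumc_inf First-moment area to infinity (ug day^2/mL), positive.
#' @return Scalar clearance (mL/day/kg) or volume (mL/kg).
#' @export
clearance <- function(dose, auc_inf) {
  if (!is.numeric(dose) || dose <= 0) stop("`dose` must be positive",
                                           call. = FALSE)
  if (!is.numeric(auc_inf) || auc_inf <= 0) {
    stop("`auc_inf` must be positive", call. = FALSE)
  }
  dose / auc_inf
}

#' @rdname clearance
#' @export
vss <- function(dose, aumc_inf, auc_inf) {
  if (!is.numeric(dose) || dose <= 0) stop("`dose` must be positive",
                                           call. = FALSE)
  if (!is.numeric(aumc_inf) || aumc_inf <= 0) {
    stop("`aumc_inf` must be positive", call. = FALSE)
  }
  if (!is.numeric(auc_inf) || auc_inf <= 0) {
    stop("`auc_inf` must be positive", call. = FALSE)
  }
  dose * aumc_inf / auc_inf^2
}

#' Noncompartmental PK analysis of serum concentration curves
#'
#' Per-subject NCA: maximum observed concentration, linear-up/log-down AUC
#' and AUMC to the last measurable point, terminal log-linear regression
#' over at least `min_terminal_points` points ([terminal_phase_fit()]),
#' extrapolation to infinity, and -- when the dose is available -- clearance
#' and steady-state volume of distribution. Censored (below-LLOQ) points are
#' excluded before any computation.
#'
#' @param data A data frame with columns `time_h` and `conc_ug_ml`;
#'   optionally `censored` (0/1 or logical), `dose_mg_kg`, `subject_id` and
#'   `variant`. With several subjects, results are computed per subject.
#' @param dose_ug_kg Dose in ug per kg body weight; overrides any
#'   `dose_mg_kg` column (which is taken as mg/kg and converted).
#' @param min_terminal_points Minimum terminal window size (default 6).
#' @return A tibble, one row per subject, with `c_max_ug_ml`,
#'   `auc_last`, `auc_inf_ug_day_ml`, `aumc_inf_ug_day2_ml`,
#'   `lambda_z_per_day`, `t_half_beta_h`, `n_terminal_points`,
#'   `cl_ml_day_kg` and `vss_ml_kg` (the last two `NA` without a dose).
#' @examples
#' tc <- tibble::tibble(time_h = c(1, 6, 24, 48, 96, 168, 240, 336),
#'                      conc_ug_ml = 40 * exp(-0.1 * (time_h / 24)))
#' nca(tc, dose_ug_kg = 2000)
#' @export
nca <- function(data, dose_ug_kg = NULL, min_terminal_points = 6L) {
  stopifnot(is.data.frame(data))
  if (!all(c("time_h", "conc_ug_ml") %in% names(data))) {
    stop("`data` needs columns `time_h` and `conc_ug_ml`", call. = FALSE)
  }
  if ("subject_id" %in% names(data) &&
      dplyr::n_distinct(data$subject_id) > 1L) {
    out <- data |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_map(~ {
        res <- nca(.x, dose_ug_kg = dose_ug_kg,
                   min_terminal_points = min_terminal_points)
        dplyr::bind_cols(.y, res)
      }) |>
      dplyr::bind_rows()
    return(out)
  }
  keep_cols <- intersect(c("variant"), names(data))
  meta <- if (length(keep_cols)) {
    dplyr::distinct(data[, keep_cols, drop = FALSE])
  } else {
    NULL
  }
  if ("censored" %in% names(data)) {
    data <- data[!as.logical(data$censored), , drop = FALSE]
  }
  check_series(data$time_h, data$conc_ug_ml)
  if (is.null(dose_ug_kg) && "dose_mg_kg" %in% names(data)) {
    dose_ug_kg <- unique(data$dose_mg_kg) * 1000
    stopifnot(length(dose_ug_kg) == 1L)
  }
  td <- data$time_h / 24
  conc <- data$conc_ug_ml
  seg <- auc_segments(td, conc)
  auc_last <- sum(seg$auc)
  aumc_last <- sum(seg$aumc)
  term <- terminal_phase_fit(td, conc, min_points = min_terminal_points)
  ext <- auc_to_inf(auc_last, aumc_last, td[length(td)], conc[length(conc)],
                    term$lambda_z)
  res <- tibble::tibble(
    n_obs = length(td),
    c_max_ug_ml = max(conc),
    auc_last = auc_last,
    auc_inf_ug_day_ml = ext$auc_inf,
    aumc_inf_ug_day2_ml = ext$aumc_inf,
    lambda_z_per_day = term$lambda_z,
    t_half_beta_h = 24 * log(2) / term$lambda_z,
    n_terminal_points = term$n_points,
    cl_ml_day_kg = if (is.null(dose_ug_kg)) NA_real_ else
      clearance(dose_ug_kg, ext$auc_inf),
    vss_ml_kg = if (is.null(dose_ug_kg)) NA_real_ else
      vss(dose_ug_kg, ext$aumc_inf, ext$auc_inf)
  )
  if (!is.null(meta) && nrow(meta) == 1L) res <- dplyr::bind_cols(meta, res)
  res
}

#' Biexponential (two-compartment) fit of a concentration curve
#'
#' Nonlinear least squares on log concentrations of
#' `A exp(-alpha t) + B exp(-beta t)` with `alpha > beta` enforced by
#' parameterization (`alpha = beta + exp(log-gap)`). Initial values come
#' from curve stripping: a terminal log-linear fit gives `(B, beta)`, a
#' log-linear fit of the positive early-time residuals gives `(A, alpha)`.
#' Mono-exponential data (no distribution phase) raise a degeneracy error.
#'
#' @inheritParams nca
#' @param min_points Minimum number of uncensored points (default 5).
#' @return An object of class `biexp_fit`; see [tidy.biexp_fit()] for the
#'   coefficient table (`A`, `B` in ug/mL; `alpha`, `beta` per day;
#'   `t_half_beta_h = 24 ln 2 / beta`).
#' @export
fit_biexponential <- function(data, min_points = 5L) {
  stopifnot(is.data.frame(data),
            all(c("time_h", "conc_ug_ml") %in% names(data)))
  if ("censored" %in% names(data)) {
    data <- data[!as.logical(data$censored), , drop = FALSE]
  }
  td <- data$time_h / 24
  conc <- data$conc_ug_ml
  check_series(td, conc, min_points = min_points)
  if (any(conc <= 0)) {
    stop("biexponential fitting requires positive concentrations",
         call. = FALSE)
  }
  n <- length(td)
  # strip: terminal fit over the later half (at least 3 points)
  k <- max(3L, floor(n / 2))
  idx <- seq(n - k + 1L, n)
  tfit <- stats::lm(log(conc[idx]) ~ td[idx])
  beta0 <- -unname(stats::coef(tfit)[2])
  B0 <- exp(unname(stats::coef(tfit)[1]))
  if (beta0 <= 0) {
    stop("no terminal decay in the data", call. = FALSE)
  }
  resid <- conc - B0 * exp(-beta0 * td)
  early <- which(resid > 1e-8 * max(conc) & seq_len(n) <= n - k)
  if (length(early) < 2L) {
    stop("degenerate fit: data appear mono-exponential; ",
         "use a one-compartment (terminal) fit instead", call. = FALSE)
  }
  afit <- stats::lm(log(resid[early]) ~ td[early])
  alpha0 <- -unname(stats::coef(afit)[2])
  A0 <- exp(unname(stats::coef(afit)[1]))
  if (!is.finite(alpha0) || alpha0 <= beta0 * 1.01) {
    stop("degenerate fit: distribution and terminal rates are ",
         "indistinguishable; use a mono-exponential fit instead",
         call. = FALSE)
  }
  start <- list(lA = log(A0), lB = log(B0), lbeta = log(beta0),
                lgap = log(alpha0 - beta0))
  df <- data.frame(td = td, lc = log(conc))
  fit <- minpack.lm::nlsLM(
    lc ~ log(exp(lA - (exp(lbeta) + exp(lgap)) * td) +
               exp(lB - exp(lbeta) * td)),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  beta <- exp(cf[["lbeta"]])
  alpha <- beta + exp(cf[["lgap"]])
  if (alpha / beta < 1.05) {
    stop("degenerate fit: alpha approximately equals beta; ",
         "use a mono-exponential fit instead", call. = FALSE)
  }
  structure(
    list(
      coef = tibble::tibble(
        A_ug_ml = exp(cf[["lA"]]), alpha_per_day = alpha,
        B_ug_ml = exp(cf[["lB"]]), beta_per_day = beta,
        t_half_beta_h = 24 * log(2) / beta
      ),
      fit = fit, data = df, n = n
    ),
    class = "biexp_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit> A e^(-alpha t) + B e^(-beta t), t in days\n")
  print(x$coef)
  invisible(x)
}

#' Tidy a biexponential fit
#'
#' @param x A `biexp_fit` from [fit_biexponential()].
#' @param ... Unused.
#' @return One-row tibble of the natural-scale parameters.
#' @method tidy biexp_fit
#' @export
tidy.biexp_fit <- function(x, ...) x$coef

#' @rdname tidy.biexp_fit
#' @method glance biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(
    sigma_log = sqrt(sum(stats::residuals(x$fit)^2) / (x$n - 4)),
    n = x$n,
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}

#' Pairwise fold changes of PK parameters between variants
#'
#' Ratios of every numeric column between ordered pairs of variants,
#' rounded to the stated precision for comparison against printed
#' fold-change statements.
#'
#' @param pk_table A data frame with a `variant` column and numeric
#'   parameter columns (e.g. per-variant mean PK parameters).
#' @param parameters Optional character vector restricting the columns.
#' @param digits Decimal places for `ratio_rounded` (default 1).
#' @return A tibble with `parameter`, `numerator`, `denominator`, `ratio`
#'   and `ratio_rounded`.
#' @examples
#' tab <- tibble::tibble(variant = c("a", "b"), t_half = c(290.9, 148.4))
#' fold_changes(tab)
#' @export
fold_changes <- function(pk_table, parameters = NULL, digits = 1L) {
  stopifnot(is.data.frame(pk_table), "variant" %in% names(pk_table))
  if (dplyr::n_distinct(pk_table$variant) < 2L) {
    stop("at least two variants are required", call. = FALSE)
  }
  num_cols <- names(pk_table)[vapply(pk_table, is.numeric, logical(1))]
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, num_cols)
    if (length(missing)) {
      stop("unknown parameter column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    num_cols <- parameters
  }
  long <- tidyr::pivot_longer(pk_table[, c("variant", num_cols)],
                              -"variant", names_to = "parameter",
                              values_to = "value")
  pairs <- tidyr::expand_grid(numerator = unique(pk_table$variant),
                              denominator = unique(pk_table$variant)) |>
    dplyr::filter(.data$numerator != .data$denominator)
  out <- pairs |>
    dplyr::inner_join(long, by = c(numerator = "variant"),
                      relationship = "many-to-many") |>
    dplyr::rename(value_num = "value") |>
    dplyr::inner_join(long, by = c(denominator = "variant",
                                   parameter = "parameter")) |>
    dplyr::rename(value_den = "value") |>
    dplyr::mutate(ratio = .data$value_num / .data$value_den,
                  ratio_rounded = round(.data$ratio, digits)) |>
    dplyr::select("parameter", "numerator", "denominator", "ratio",
                  "ratio_rounded") |>
    dplyr::arrange(.data$parameter, .data$numerator, .data$denominator)
  tibble::as_tibble(out)
}

#' Look up one fold change
#'
#' Convenience accessor over [fold_changes()] for a single parameter and
#' variant pair.
#'
#' @inheritParams fold_changes
#' @param parameter Column name of the PK parameter.
#' @param numerator,denominator Variant labels.
#' @return The unrounded ratio (numeric scalar).
#' @export
fold_change <- function(pk_table, parameter, numerator, denominator) {
  fc <- fold_changes(pk_table, parameters = parameter)
  row <- fc[fc$numerator == numerator & fc$denominator == denominator, ]
  if (nrow(row) != 1L) {
    stop("variant pair not found in the table", call. = FALSE)
  }
  row$ratio
}
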