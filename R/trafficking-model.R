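# Three-compartment exogenous-IgG trafficking model.
#
# Concentrations (ug/mL) in a central extracellular, peripheral
# extracellular and endosomal space; the central volume is the unit of
# volume, flows are in central-volumes per hour. FcRn biology enters
# through two per-variant fractions: f_sort (endosomal IgG recycled rather
# than degraded) and f_release (surface-presented IgG released rather than
# re-endocytosed); 1 - f_release is the surface recapture fraction.

#' Trafficking model parameters
#'
#' Bundles the volumes, flows and per-variant sorting/release fractions of
#' the linear three-compartment IgG trafficking model. The central volume is
#' fixed at 1 so `V_p` and `V_e` are relative volumes; `Q` and `Q_u` are in
#' central-volumes per hour. `f_sort` and `f_release` may be named vectors
#' (one entry per antibody variant) or unnamed scalars for a single-variant
#' model.
#'
#' @param V_p Peripheral volume relative to the central compartment (> 0).
#' @param V_e Endosomal volume relative to the central compartment (> 0).
#' @param Q Central-peripheral exchange rate, central-volumes per hour (> 0).
#' @param Q_u Cellular uptake rate, central-volumes per hour (>= 0).
#' @param f_sort Fraction of endosomal IgG sorted to recycling, in [0, 1].
#'   Named vector for multiple variants.
#' @param f_release Fraction of surface-presented IgG released to the
#'   extracellular space, in [0, 1]. Must carry the same names as `f_sort`.
#'
#' @return An object of class `trafficking_params`.
#' @examples
#' trafficking_params(V_p = 1, V_e = 0.2, Q = 0.5, Q_u = 1,
#'                    f_sort = c(wt = 0.5, DHS = 0.9),
#'                    f_release = c(wt = 1, DHS = 1))
#' @export
trafficking_params <- function(V_p, V_e, Q, Q_u, f_sort, f_release) {
  check_positive_scalar(V_p, "V_p")
  check_positive_scalar(V_e, "V_e")
  check_positive_scalar(Q, "Q")
  check_nonnegative_scalar(Q_u, "Q_u")
  f_sort <- check_fraction_vector(f_sort, "f_sort")
  f_release <- check_fraction_vector(f_release, "f_release")
  if (length(f_sort) != length(f_release)) {
    stop("`f_sort` and `f_release` must have the same length", call. = FALSE)
  }
  ns <- names(f_sort)
  nr <- names(f_release)
  if (is.null(ns) != is.null(nr) ||
      (!is.null(ns) && !setequal(ns, nr))) {
    stop("`f_sort` and `f_release` must carry identical variant names",
         call. = FALSE)
  }
  if (!is.null(ns)) f_release <- f_release[ns]
  structure(
    list(V_p = V_p, V_e = V_e, Q = Q, Q_u = Q_u,
         f_sort = f_sort, f_release = f_release),
    class = "trafficking_params"
  )
}

#' @export
print.trafficking_params <- function(x, ...) {
  cat("<trafficking_params>\n")
  cat(sprintf("  V_p = %.4g, V_e = %.4g (relative volumes)\n", x$V_p, x$V_e))
  cat(sprintf("  Q = %.4g, Q_u = %.4g (central-volumes / h)\n", x$Q, x$Q_u))
  vars <- variant_names(x)
  if (is.null(vars)) {
    cat(sprintf("  f_sort = %.4g, f_release = %.4g\n",
                x$f_sort, x$f_release))
  } else {
    for (v in vars) {
      cat(sprintf("  %s: f_sort = %.4g, f_release = %.4g (recapture %.3g)\n",
                  v, x$f_sort[[v]], x$f_release[[v]], 1 - x$f_release[[v]]))
    }
  }
  invisible(x)
}

variant_names <- function(params) names(params$f_sort)

# Resolve the (f_sort, f_release) pair for one variant.
variant_fractions <- function(params, variant = NULL) {
  vars <- variant_names(params)
  if (is.null(vars)) {
    if (!is.null(variant)) {
      stop("parameters carry no variant names; leave `variant` NULL",
           call. = FALSE)
    }
    return(list(f_sort = unname(params$f_sort),
                f_release = unname(params$f_release)))
  }
  if (is.null(variant)) {
    if (length(vars) == 1L) {
      variant <- vars
    } else {
      stop("`variant` must be one of: ", paste(vars, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!variant %in% vars) {
    stop("unknown variant '", variant, "'; available: ",
         paste(vars, collapse = ", "), call. = FALSE)
  }
  list(f_sort = unname(params$f_sort[[variant]]),
       f_release = unname(params$f_release[[variant]]))
}

#' Rate matrix of the trafficking ODE system
#'
#' Builds the 3x3 matrix `M` (units 1/h) such that
#' `d(C_c, C_p, C_e)/dt = M %*% c(C_c, C_p, C_e)`:
#' central exchange `dC_c/dt = Q (C_p - C_c)`; peripheral balance
#' `V_p dC_p/dt = Q C_c - Q C_p - Q_u C_p + Q_u C_e f_sort f_release`;
#' endosomal balance
#' `V_e dC_e/dt = Q_u (C_p + C_e ((1 - f_release) f_sort - 1))`.
#' Off-diagonal entries are non-negative and, when `f_sort = f_release = 1`,
#' the system is closed (one zero eigenvalue, total mass conserved).
#'
#' @param params A [trafficking_params()] object.
#' @param variant Variant name selecting the sorting/release fractions;
#'   may be omitted for single-variant parameters.
#' @return A 3x3 numeric matrix with rows/columns `C_c`, `C_p`, `C_e`.
#' @export
rate_matrix <- function(params, variant = NULL) {
  stopifnot(inherits(params, "trafficking_params"))
  fr <- variant_fractions(params, variant)
  fs <- fr$f_sort
  fe <- fr$f_release
  with(params, {
    m <- matrix(c(
      -Q,        Q,                  0,
      Q / V_p,  -(Q + Q_u) / V_p,    Q_u * fs * fe / V_p,
      0,         Q_u / V_e,          Q_u * ((1 - fe) * fs - 1) / V_e
    ), nrow = 3, byrow = TRUE,
    dimnames = list(c("C_c", "C_p", "C_e"), c("C_c", "C_p", "C_e")))
    m
  })
}

as_state_vector <- function(state) {
  if (is.data.frame(state)) {
    stopifnot(all(c("C_c", "C_p", "C_e") %in% names(state)),
              nrow(state) == 1L)
    state <- c(state$C_c, state$C_p, state$C_e)
  }
  state <- as.numeric(state)
  if (length(state) != 3L) {
    stop("a compartment state has exactly three concentrations", call. = FALSE)
  }
  if (any(state < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  state
}

#' Propagate the trafficking model by matrix exponential
#'
#' Advances an initial compartment state to the requested times with
#' `exp(t M)` applied to the initial concentration vector, the exact
#' solution of the linear system.
#'
#' @param state0 Initial state: numeric `c(C_c, C_p, C_e)` in ug/mL, or a
#'   one-row data frame with those columns.
#' @param params A [trafficking_params()] object.
#' @param t Time(s) in hours, all `>= 0`.
#' @inheritParams rate_matrix
#' @return A tibble with columns `t_h`, `C_c`, `C_p`, `C_e`.
#' @examples
#' p <- trafficking_params(1, 0.2, 0.5, 1, f_sort = 0.8, f_release = 0.6)
#' propagate(c(40, 0, 0), p, t = c(0, 24, 168))
#' @export
propagate <- function(state0, params, t, variant = NULL) {
  state0 <- as_state_vector(state0)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  m <- rate_matrix(params, variant)
  states <- vapply(t, function(ti) {
    if (ti == 0) return(state0)
    as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(m * ti))) %*% state0)
  }, numeric(3))
  tibble::tibble(t_h = t, C_c = states[1, ], C_p = states[2, ],
                 C_e = states[3, ])
}

#' Total IgG amount across compartments
#'
#' Amount per central volume: `C_c + C_p V_p + C_e V_e`. Along any model
#' trajectory its time derivative equals `Q_u C_e (f_sort - 1) <= 0`:
#' lysosomal degradation of the unsorted endosomal fraction is the only
#' elimination pathway.
#'
#' @param state Numeric `c(C_c, C_p, C_e)` or a data frame with columns
#'   `C_c`, `C_p`, `C_e` (e.g. the output of [propagate()]).
#' @param params A [trafficking_params()] object.
#' @return Numeric vector of amounts (ug per central volume).
#' @export
total_mass <- function(state, params) {
  stopifnot(inherits(params, "trafficking_params"))
  if (is.data.frame(state)) {
    return(state$C_c + state$C_p * params$V_p + state$C_e * params$V_e)
  }
  state <- as.numeric(state)
  stopifnot(length(state) == 3L)
  state[1] + state[2] * params$V_p + state[3] * params$V_e
}

# Slowest eigenvalue (largest real part) of the rate matrix, computed from
# the characteristic cubic; cheap enough for the MCMC hot path. Returns 0
# for a closed system (within tolerance of the matrix scale).
slow_eigenvalue <- function(V_p, V_e, Q, Q_u, f_sort, f_release) {
  a11 <- -Q
  a12 <- Q
  a21 <- Q / V_p
  a22 <- -(Q + Q_u) / V_p
  a23 <- Q_u * f_sort * f_release / V_p
  a32 <- Q_u / V_e
  a33 <- Q_u * ((1 - f_release) * f_sort - 1) / V_e
  tr <- a11 + a22 + a33
  m2 <- a11 * a22 - a12 * a21 + a11 * a33 + a22 * a33 - a23 * a32
  dt <- a11 * (a22 * a33 - a23 * a32) - a12 * a21 * a33
  # det(lambda I - M) = lambda^3 - tr lambda^2 + m2 lambda - dt
  roots <- polyroot(c(-dt, m2, -tr, 1))
  slow <- max(Re(roots))
  scale <- max(abs(c(a11, a22, a33)), 1)
  if (slow >= -1e-12 * scale) 0 else slow
}

#' Terminal (beta-phase) half-life of the trafficking model
#'
#' `ln(2) / |lambda_slow|` where `lambda_slow` is the rate-matrix eigenvalue
#' of smallest magnitude; this is the asymptotic slope of the log serum
#' concentration, the quantity matched to observed beta-phase half-lives.
#' A closed system (`f_sort = f_release = 1`) has no elimination pathway and
#' returns `Inf` rather than throwing.
#'
#' @inheritParams rate_matrix
#' @return Half-life in hours (possibly `Inf`).
#' @seealso [time_to_half()] for the alternative definition (first time the
#'   central concentration halves).
#' @export
terminal_half_life <- function(params, variant = NULL) {
  stopifnot(inherits(params, "trafficking_params"))
  fr <- variant_fractions(params, variant)
  lam <- slow_eigenvalue(params$V_p, params$V_e, params$Q, params$Q_u,
                         fr$f_sort, fr$f_release)
  if (lam == 0) Inf else log(2) / abs(lam)
}

#' Time for the central concentration to halve
#'
#' Smallest `t > 0` with `C_c(t) = C_c(0) / 2`, found by Newton iteration
#' (derivative `(M exp(tM) c0)[1]`) safeguarded by bisection on a bracket
#' located by doubling. For an effectively mono-exponential decay this
#' coincides with [terminal_half_life()]; during a pronounced distribution
#' (alpha) phase it is shorter.
#'
#' @inheritParams propagate
#' @param rtol Relative convergence tolerance on `t`.
#' @param max_iter Maximum Newton iterations before falling back to pure
#'   bisection within the bracket.
#' @return Time in hours.
#' @export
time_to_half <- function(state0, params, variant = NULL,
                         rtol = 1e-10, max_iter = 100L) {
  state0 <- as_state_vector(state0)
  if (state0[1] <= 0) {
    stop("central concentration must be positive at t = 0", call. = FALSE)
  }
  m <- rate_matrix(params, variant)
  target <- state0[1] / 2
  cc <- function(t) {
    as.numeric((as.matrix(Matrix::expm(Matrix::Matrix(m * t))) %*% state0)[1])
  }
  dcc <- function(t) {
    as.numeric((m %*% (as.matrix(Matrix::expm(Matrix::Matrix(m * t))) %*%
                         state0))[1])
  }
  # bracket [lo, hi] with cc(lo) > target > cc(hi)
  lo <- 0
  hi <- 1
  n_double <- 0L
  while (cc(hi) > target) {
    lo <- hi
    hi <- hi * 2
    n_double <- n_double + 1L
    if (n_double > 60L) {
      stop("central concentration never falls to half its initial value; ",
           "bracket searched up to t = ", hi, " h", call. = FALSE)
    }
  }
  t <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    f <- cc(t) - target
    if (f > 0) lo <- t else hi <- t
    d <- dcc(t)
    t_new <- if (d < 0) t - f / d else NA_real_
    if (!is.finite(t_new) || t_new <= lo || t_new >= hi) {
      t_new <- (lo + hi) / 2
    }
    if (abs(t_new - t) <= rtol * max(t, 1e-300)) {
      return(t_new)
    }
    t <- t_new
  }
  if ((hi - lo) / max(t, 1) < 1e-6) return(t)
  stop("time_to_half did not converge; last bracket [", lo, ", ", hi, "] h",
       call. = FALSE)
}

#' Surface recapture fraction of a variant
#'
#' The fraction of IgG presented at the cell surface that is re-endocytosed
#' instead of released, `1 - f_release`. Residual FcRn binding at
#' extracellular pH manifests as recapture and shortens circulation
#' half-life.
#'
#' @inheritParams rate_matrix
#' @return Numeric recapture fraction in [0, 1].
#' @export
recapture_fraction <- function(params, variant = NULL) {
  stopifnot(inherits(params, "trafficking_params"))
  1 - variant_fractions(params, variant)$f_release
}

#' Write / read trafficking parameters as JSON
#'
#' Serializes a [trafficking_params()] object to a small JSON document with
#' keys `volumes` (`V_p`, `V_e`), `flows` (`Q`, `Q_u`) and `variants`
#' (per-variant `f_sort`, `f_release`). Unnamed single-variant parameters
#' are stored under the key `"default"`.
#'
#' @param params A [trafficking_params()] object.
#' @param path File path.
#' @return `write_trafficking_params()` returns `path` invisibly;
#'   `read_trafficking_params()` returns a [trafficking_params()] object.
#' @export
write_trafficking_params <- function(params, path) {
  stopifnot(inherits(params, "trafficking_params"))
  vars <- variant_names(params)
  if (is.null(vars)) vars <- "default"
  variants <- stats::setNames(lapply(seq_along(vars), function(i) {
    list(f_sort = unname(params$f_sort[[i]]),
         f_release = unname(params$f_release[[i]]))
  }), vars)
  doc <- list(volumes = list(V_p = params$V_p, V_e = params$V_e),
              flows = list(Q = params$Q, Q_u = params$Q_u),
              variants = variants)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trafficking_params
#' @export
read_trafficking_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("volumes", "flows", "variants")) {
    if (is.null(doc[[key]])) {
      stop("parameter file is missing the '", key, "' block", call. = FALSE)
    }
  }
  vars <- names(doc$variants)
  fs <- vapply(doc$variants, function(v) as.numeric(v$f_sort), numeric(1))
  fr <- vapply(doc$variants, function(v) as.numeric(v$f_release), numeric(1))
  names(fs) <- names(fr) <- vars
  if (identical(vars, "default")) {
    fs <- unname(fs)
    fr <- unname(fr)
  }
  trafficking_params(V_p = as.numeric(doc$volumes$V_p),
                     V_e = as.numeric(doc$volumes$V_e),
                     Q = as.numeric(doc$flows$Q),
                     Q_u = as.numeric(doc$flows$Q_u),
                     f_sort = fs, f_release = fr)
}

# ---- validation helpers ----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

check_nonnegative_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("`", name, "` must be a single non-negative number", call. = FALSE)
  }
  invisible(x)
}

check_fraction_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
      any(x < 0) || any(x > 1)) {
    stop("`", name, "` must be numeric in [0, 1]", call. = FALSE)
  }
  x
}
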