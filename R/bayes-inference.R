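# Bayesian inference of trafficking parameters from beta-phase half-life
# observations. Priors: lognormal on the shared volumes/flows; flat,
# affinity-ordered chained-uniform priors on the per-variant sorting and
# release fractions (a variant with stronger endosomal binding cannot have
# a smaller sorting fraction than a weaker binder; variants with no
# measurable surface binding at extracellular pH have f_release fixed at 1).
# Sampling: parallel-tempered adaptive Metropolis in an unconstrained
# reparameterization that enforces every constraint by construction; the
# posterior needs tempering because a narrow data-fitting basin coexists
# with a broad prior-dominated one.

#' Build prior specification from an FcRn affinity table
#'
#' Shared parameters get lognormal priors: `V_p`, `V_e` and `Q` with
#' log-scale location 1 and scale 1, `Q_u` with log-scale location 0.1 and
#' scale 0.5 (the study's prior statements are read as lognormal
#' location/scale pairs, the `Q_u` location being quoted as a power of e;
#' see the methods vignette for the alternative readings and `lognormal`
#' below to override). Sorting fractions get flat priors chained in the
#' order of
#' endosomal (pH 5.8) affinity: the strongest binder has `f_sort ~ U(0, 1)`
#' and each weaker binder is uniform on `(0, f_sort)` of the next stronger
#' one. Release fractions are fixed at 1 for variants with no detectable
#' binding at pH 7.4; the remaining variants are chained the same way in
#' order of *weakening* pH 7.4 affinity (the strongest surface binder gets
#' the smallest release fraction, i.e. the most recapture).
#'
#' @param affinities A data frame like [fcrn_affinities()]: columns
#'   `variant`, `kd_ph58_nM`, `ph74_detectable` (logical) and
#'   `kd_ph74_high_nM` (`NA` when not detectable).
#' @param variants Variants to model (default the four Fc variants).
#' @param lognormal Optional replacement for the lognormal prior table: a
#'   data frame with columns `parameter` (`"V_p"`, `"V_e"`, `"Q"`, `"Q_u"`),
#'   `meanlog` and `sdlog`.
#' @return An object of class `prior_spec`.
#' @export
build_priors <- function(affinities,
                         variants = c("wt", "DHS", "YTE", "LS"),
                         lognormal = NULL) {
  stopifnot(is.data.frame(affinities),
            all(c("variant", "kd_ph58_nM", "ph74_detectable") %in%
                  names(affinities)))
  missing <- setdiff(variants, affinities$variant)
  if (length(missing)) {
    stop("no affinity data for variant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  aff <- affinities[match(variants, affinities$variant), ]
  if (anyNA(aff$kd_ph58_nM)) {
    stop("pH 5.8 Kd required for every fitted variant", call. = FALSE)
  }
  f_sort_order <- aff$variant[order(aff$kd_ph58_nM)]
  fixed <- aff$variant[!aff$ph74_detectable]
  free <- aff[aff$ph74_detectable, ]
  if (nrow(free) > 1L) {
    if (anyNA(free$kd_ph74_high_nM)) {
      stop("pH 7.4 Kd needed to order release fractions of variants with ",
           "detectable surface binding", call. = FALSE)
    }
    f_release_order <- free$variant[order(free$kd_ph74_high_nM,
                                          decreasing = TRUE)]
  } else {
    f_release_order <- free$variant
  }
  if (is.null(lognormal)) {
    lognormal <- tibble::tibble(
      parameter = c("V_p", "V_e", "Q", "Q_u"),
      meanlog = c(1, 1, 1, 0.1),
      sdlog = c(1, 1, 1, 0.5)
    )
  } else {
    lognormal <- tibble::as_tibble(lognormal)
    stopifnot(setequal(lognormal$parameter, c("V_p", "V_e", "Q", "Q_u")),
              all(lognormal$sdlog > 0))
    lognormal <- lognormal[match(c("V_p", "V_e", "Q", "Q_u"),
                                 lognormal$parameter), ]
  }
  structure(
    list(
      lognormal = lognormal,
      f_sort_order = f_sort_order,
      f_release_fixed = fixed,
      f_release_order = f_release_order,
      variants = variants
    ),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n  lognormal priors:\n")
  for (i in seq_len(nrow(x$lognormal))) {
    cat(sprintf("    %s ~ lognormal(meanlog = %.3g, sdlog = %.3g)\n",
                x$lognormal$parameter[i], x$lognormal$meanlog[i],
                x$lognormal$sdlog[i]))
  }
  cat("  f_sort chained-uniform order (strongest pH 5.8 binder first): ",
      paste(x$f_sort_order, collapse = " >= "), "\n", sep = "")
  if (length(x$f_release_fixed)) {
    cat("  f_release fixed at 1: ",
        paste(x$f_release_fixed, collapse = ", "), "\n", sep = "")
  }
  if (length(x$f_release_order)) {
    cat("  f_release chained-uniform order (weakest pH 7.4 binder first): ",
        paste(x$f_release_order, collapse = " >= "), "\n", sep = "")
  }
  invisible(x)
}

# Parameter bookkeeping: unconstrained vector u maps to the model
# parameters. u[1:4] are log(V_p), log(V_e), log(Q), log(Q_u); subsequent
# entries are the chained-fraction links s_i = plogis(u_i),
# f_1 = s_1, f_k = f_{k-1} s_k. Under the chained-uniform prior the
# implied density of each link u_i is exactly standard logistic.
param_map <- function(priors) {
  stopifnot(inherits(priors, "prior_spec"))
  fs <- priors$f_sort_order
  fr <- priors$f_release_order
  list(
    d = 4L + length(fs) + length(fr),
    fs_order = fs,
    fr_order = fr,
    fr_fixed = priors$f_release_fixed,
    meanlog = priors$lognormal$meanlog,
    sdlog = priors$lognormal$sdlog,
    names = c("V_p", "V_e", "Q", "Q_u",
              paste0("f_sort_", fs), paste0("f_release_", fr))
  )
}

chain_fractions <- function(u_links) {
  cumprod(stats::plogis(u_links))
}

u_to_theta <- function(u, map) {
  nfs <- length(map$fs_order)
  nfr <- length(map$fr_order)
  fs <- chain_fractions(u[4L + seq_len(nfs)])
  names(fs) <- map$fs_order
  fr <- if (nfr) chain_fractions(u[4L + nfs + seq_len(nfr)]) else numeric(0)
  names(fr) <- map$fr_order
  fr_all <- c(fr, stats::setNames(rep(1, length(map$fr_fixed)),
                                  map$fr_fixed))
  list(V_p = exp(u[1]), V_e = exp(u[2]), Q = exp(u[3]), Q_u = exp(u[4]),
       f_sort = fs, f_release = fr_all)
}

theta_to_params <- function(theta) {
  vars <- names(theta$f_sort)
  trafficking_params(V_p = theta$V_p, V_e = theta$V_e, Q = theta$Q,
                     Q_u = theta$Q_u,
                     f_sort = theta$f_sort[vars],
                     f_release = theta$f_release[vars])
}

hl_type_code <- function(half_life) {
  half_life <- match.arg(half_life, c("time_to_half", "terminal"))
  if (half_life == "terminal") 0L else 1L
}

obs_dispersion <- function(obs, likelihood_scale) {
  likelihood_scale <- match.arg(likelihood_scale, c("sd", "se"))
  if (likelihood_scale == "se") obs$sd_h / sqrt(obs$n) else obs$sd_h
}

# log prior density in u-space (prior + transform Jacobian collapse to
# normal densities on u[1:4] and standard-logistic densities on the links)
make_log_prior <- function(map) {
  function(u) {
    lp <- sum(stats::dnorm(u[1:4], map$meanlog, map$sdlog, log = TRUE))
    links <- u[-(1:4)]
    if (length(links)) {
      lp <- lp + sum(stats::plogis(links, log.p = TRUE) +
                       stats::plogis(-links, log.p = TRUE))
    }
    lp
  }
}

# log likelihood in u-space through the compiled half-life kernel;
# the zero function when there are no observations (prior-only run)
make_log_lik <- function(map, obs, half_life = "time_to_half",
                         likelihood_scale = "se") {
  if (nrow(obs) == 0L) return(function(u) 0)
  type <- hl_type_code(half_life)
  nfs <- length(map$fs_order)
  nfr <- length(map$fr_order)
  obs_mean <- obs$mean_h
  obs_disp <- obs_dispersion(obs, likelihood_scale)
  fs_idx <- match(obs$variant, map$fs_order)
  fr_idx <- match(obs$variant, map$fr_order)
  function(u) {
    fs_chain <- cumprod(stats::plogis(u[4L + seq_len(nfs)]))
    fr_chain <- if (nfr) cumprod(stats::plogis(u[4L + nfs + seq_len(nfr)]))
                else numeric(0)
    fr_obs <- ifelse(is.na(fr_idx), 1, fr_chain[fr_idx])
    .cpp_loglik(exp(u[1]), exp(u[2]), exp(u[3]), exp(u[4]),
                fs_chain[fs_idx], fr_obs, obs_mean, obs_disp, type)
  }
}

make_log_post <- function(map, obs, half_life = "time_to_half",
                          likelihood_scale = "se") {
  lprior <- make_log_prior(map)
  llik <- make_log_lik(map, obs, half_life, likelihood_scale)
  function(u) {
    lp <- lprior(u)
    if (!is.finite(lp)) return(-Inf)
    lp + llik(u)
  }
}

#' Log likelihood of half-life observations
#'
#' Sum over variants of the normal log density
#' `Normal(mean = observed mean, sd = dispersion)` evaluated at the model's
#' half-life for that variant. The half-life is the time for the central
#' concentration to halve after a bolus ([time_to_half()], the default) or
#' the terminal eigenvalue definition ([terminal_half_life()]); the
#' dispersion is the standard error `sd / sqrt(n)` (default) or the
#' tabulated SD. A model half-life that is infinite (or undefined) gives
#' `-Inf` (a sampler rejection), not an error.
#'
#' @param params A [trafficking_params()] object covering every observed
#'   variant.
#' @param observations Data frame with columns `variant`, `mean_h`, `sd_h`,
#'   `n` (e.g. [half_life_observations()]).
#' @param half_life `"time_to_half"` (default) or `"terminal"`.
#' @param likelihood_scale `"se"` (default) or `"sd"`.
#' @return Scalar log density.
#' @export
log_likelihood <- function(params, observations,
                           half_life = c("time_to_half", "terminal"),
                           likelihood_scale = c("se", "sd")) {
  stopifnot(inherits(params, "trafficking_params"),
            is.data.frame(observations))
  half_life <- match.arg(half_life)
  disp <- obs_dispersion(observations, match.arg(likelihood_scale))
  unnamed <- is.null(variant_names(params))
  ll <- 0
  for (i in seq_len(nrow(observations))) {
    v <- if (unnamed) NULL else observations$variant[i]
    hl <- if (half_life == "terminal") {
      terminal_half_life(params, v)
    } else {
      tryCatch(time_to_half(c(1, 0, 0), params, v),
               error = function(e) Inf)
    }
    if (!is.finite(hl)) return(-Inf)
    ll <- ll + stats::dnorm(hl, observations$mean_h[i], disp[i], log = TRUE)
  }
  ll
}

#' Draw from the prior
#'
#' Exact draws from the prior specification (lognormal shared parameters,
#' chained-uniform ordered fractions). Useful for prior-predictive checks
#' and for verifying that the ordering constraints hold by construction.
#'
#' @param priors A [build_priors()] object.
#' @param n Number of draws.
#' @return A tibble, one row per draw, columns as in the posterior draws.
#' @export
sample_prior <- function(priors, n) {
  map <- param_map(priors)
  u <- matrix(c(stats::rnorm(4 * n, rep(map$meanlog, each = n),
                             rep(map$sdlog, each = n)),
                stats::rlogis(n * (map$d - 4L))),
              nrow = n)
  draws <- t(apply(u, 1, function(ui) {
    th <- u_to_theta(ui, map)
    c(th$V_p, th$V_e, th$Q, th$Q_u, th$f_sort, th$f_release[map$fr_order])
  }))
  colnames(draws) <- map$names
  tibble::as_tibble(draws)
}

#' Fit the trafficking model to half-life data by MCMC
#'
#' Parallel-tempered adaptive Metropolis targeting the posterior over the
#' shared volumes/flows and the per-variant sorting/release fractions.
#' Sampling is in an unconstrained space (logs of the positive parameters;
#' a logistic-chain transform of the ordered fractions) so every draw
#' satisfies the box and ordering constraints by construction. Each chain
#' runs a ladder of power posteriors (`prior x likelihood^beta`, beta from
#' 0 to 1) with adaptive random-walk moves per rung (empirical-covariance
#' proposals, Robbins-Monro scale tuning during warmup, frozen afterwards)
#' and replica swaps between adjacent rungs; tempering lets chains cross
#' between posterior basins, which this posterior needs (a well-fitting
#' basin coexists with a diffuse prior-dominated one). Chains are
#' preconditioned at the posterior mode found by multi-start optimization.
#' Runs are deterministic given `seed`.
#'
#' @inheritParams log_likelihood
#' @param priors A [build_priors()] object; must cover every observed
#'   variant. Observations may be empty (zero rows) for a prior-only run.
#' @param seed Integer seed controlling all randomness of the fit.
#' @param n_chains Number of chains (default 4).
#' @param n_warmup,n_samples Warmup (adaptation, discarded) and retained
#'   iterations per chain (defaults 2000 each).
#' @param n_temps Number of tempering rungs per chain (default 10; a
#'   prior-only run uses a single untempered replica).
#' @inheritParams log_likelihood
#' @return An object of class `trafficking_fit` with elements `draws`
#'   (tibble: `chain`, `iteration`, parameters, `lp`), `accept_rate`,
#'   `priors`, `observations`, `seed`, `n_warmup`, `n_samples`,
#'   `half_life`, `likelihood_scale`.
#' @seealso [mcmc_diagnostics()], [recapture_summary()],
#'   [tidy.trafficking_fit()], [posterior_mean_params()]
#' @export
fit_trafficking <- function(observations, priors, seed = 1L,
                            n_chains = 4L, n_warmup = 2000L,
                            n_samples = 2000L,
                            half_life = c("time_to_half", "terminal"),
                            likelihood_scale = c("se", "sd"),
                            n_temps = 10L) {
  stopifnot(inherits(priors, "prior_spec"), is.data.frame(observations))
  half_life <- match.arg(half_life)
  likelihood_scale <- match.arg(likelihood_scale)
  if (nrow(observations)) {
    stopifnot(all(c("variant", "mean_h", "sd_h", "n") %in%
                    names(observations)))
    extra <- setdiff(observations$variant, priors$variants)
    if (length(extra)) {
      stop("observations for variant(s) without priors: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  map <- param_map(priors)
  lprior <- make_log_prior(map)
  llik <- make_log_lik(map, observations, half_life = half_life,
                       likelihood_scale = likelihood_scale)
  log_post <- function(u) {
    lp <- lprior(u)
    if (!is.finite(lp)) return(-Inf)
    lp + llik(u)
  }
  d <- map$d
  set.seed(seed)
  # deterministic preconditioning: multi-start search for the posterior
  # mode (the posterior can be multimodal: a well-fitting basin and a
  # diffuse prior-dominated one), then local curvature as proposal seed
  prior_draw <- function() {
    c(stats::rnorm(4, map$meanlog, map$sdlog), stats::rlogis(d - 4L))
  }
  has_obs <- nrow(observations) > 0L
  n_starts <- if (has_obs) 60L else 5L
  best <- NULL
  any_finite <- FALSE
  for (i in seq_len(n_starts)) {
    u0 <- prior_draw()
    if (!is.finite(log_post(u0))) next
    any_finite <- TRUE
    o <- stats::optim(u0, log_post, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000))
    if (is.null(best) || o$value > best$value) best <- o
  }
  if (!any_finite) {
    stop("could not find a finite-posterior starting point; ",
         "check priors against the observations", call. = FALSE)
  }
  opt <- stats::optim(best$par, log_post, method = "BFGS",
                      control = list(fnscale = -1, maxit = 500),
                      hessian = TRUE)
  if (opt$value < best$value) opt <- c(best, list(hessian = diag(1, d)))
  sigma0 <- tryCatch({
    s <- solve(-opt$hessian)
    if (!all(is.finite(s)) || any(diag(s) <= 0)) stop("bad hessian")
    chol(s) # fails unless positive definite
    s
  }, error = function(e) diag(0.1, d))
  # tempering ladder: beta = 0 samples the prior alone, so replicas can
  # cross between posterior basins via the ladder
  betas <- if (has_obs) seq(0, 1, length.out = n_temps)^2 else 1
  n_t <- length(betas)
  all_draws <- vector("list", n_chains)
  accept <- numeric(n_chains)
  swap_rate <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    # per-temperature states: cold replica starts near the mode, hot ones
    # from the prior
    U <- vector("list", n_t)
    LPr <- numeric(n_t)
    LLk <- numeric(n_t)
    for (k in seq_len(n_t)) {
      u <- NULL
      for (try in 1:200) {
        cand <- if (betas[k] > 0.5) {
          opt$par + drop(stats::rnorm(d) %*% chol(sigma0)) * 0.5
        } else {
          prior_draw()
        }
        if (is.finite(lprior(cand)) &&
            (betas[k] == 0 || is.finite(llik(cand)))) {
          u <- cand
          break
        }
      }
      if (is.null(u)) u <- opt$par
      U[[k]] <- u
      LPr[k] <- lprior(u)
      LLk[k] <- llik(u)
    }
    # per-temperature adaptation state
    mu <- U
    cov_acc <- rep(list(sigma0), n_t)
    log_scale <- rep(log(2.38 / sqrt(d)), n_t)
    chol_prop <- lapply(seq_len(n_t), function(k) {
      chol(exp(2 * log_scale[k]) * sigma0)
    })
    n_iter <- n_warmup + n_samples
    chain_u <- matrix(NA_real_, n_samples, d)
    chain_lp <- numeric(n_samples)
    n_acc <- 0L
    n_swap <- 0L
    n_swap_try <- 0L
    for (it in seq_len(n_iter)) {
      for (k in seq_len(n_t)) {
        prop <- U[[k]] + drop(stats::rnorm(d) %*% chol_prop[[k]])
        lpr_p <- lprior(prop)
        a_prob <- 0
        if (is.finite(lpr_p)) {
          llk_p <- llik(prop)
          num <- lpr_p + if (betas[k] == 0) 0 else betas[k] * llk_p
          den <- LPr[k] + if (betas[k] == 0) 0 else betas[k] * LLk[k]
          if (is.finite(num)) a_prob <- min(1, exp(num - den))
        }
        if (a_prob > 0 && stats::runif(1) < a_prob) {
          U[[k]] <- prop
          LPr[k] <- lpr_p
          LLk[k] <- llk_p
          if (k == n_t && it > n_warmup) n_acc <- n_acc + 1L
        }
        if (it <= n_warmup) {
          w <- 1 / (it + 10)
          delta <- U[[k]] - mu[[k]]
          mu[[k]] <- mu[[k]] + w * delta
          cov_acc[[k]] <- (1 - w) * cov_acc[[k]] + w * tcrossprod(delta)
          log_scale[k] <- log_scale[k] + it^-0.6 * (a_prob - 0.234)
          if (it >= 50L && it %% 20L == 0L) {
            chol_prop[[k]] <- tryCatch(
              chol(exp(2 * log_scale[k]) * cov_acc[[k]] + diag(1e-12, d)),
              error = function(e) chol_prop[[k]])
          }
        }
      }
      # replica swaps between adjacent temperatures
      if (n_t > 1L) {
        for (k in seq_len(n_t - 1L)) {
          if (!is.finite(LLk[k]) || !is.finite(LLk[k + 1])) next
          log_r <- (betas[k + 1] - betas[k]) * (LLk[k] - LLk[k + 1])
          if (k == n_t - 1L) n_swap_try <- n_swap_try + 1L
          if (log(stats::runif(1)) < log_r) {
            tmp <- U[[k]]; U[[k]] <- U[[k + 1]]; U[[k + 1]] <- tmp
            tmp <- LPr[k]; LPr[k] <- LPr[k + 1]; LPr[k + 1] <- tmp
            tmp <- LLk[k]; LLk[k] <- LLk[k + 1]; LLk[k + 1] <- tmp
            if (k == n_t - 1L) n_swap <- n_swap + 1L
          }
        }
      }
      if (it > n_warmup) {
        chain_u[it - n_warmup, ] <- U[[n_t]]
        chain_lp[it - n_warmup] <- LPr[n_t] + LLk[n_t]
      }
    }
    accept[ch] <- n_acc / n_samples
    swap_rate[ch] <- if (n_swap_try > 0) n_swap / n_swap_try else NA_real_
    theta <- t(apply(chain_u, 1, function(ui) {
      th <- u_to_theta(ui, map)
      c(th$V_p, th$V_e, th$Q, th$Q_u, th$f_sort,
        th$f_release[map$fr_order])
    }))
    colnames(theta) <- map$names
    all_draws[[ch]] <- dplyr::bind_cols(
      tibble::tibble(chain = ch, iteration = seq_len(n_samples)),
      tibble::as_tibble(theta),
      tibble::tibble(lp = chain_lp)
    )
  }
  structure(
    list(draws = dplyr::bind_rows(all_draws),
         accept_rate = accept,
         swap_rate = swap_rate,
         priors = priors,
         observations = observations,
         half_life = half_life,
         likelihood_scale = likelihood_scale,
         seed = seed, n_chains = n_chains,
         n_warmup = n_warmup, n_samples = n_samples),
    class = "trafficking_fit"
  )
}

fit_param_names <- function(fit) {
  setdiff(names(fit$draws), c("chain", "iteration", "lp"))
}

#' @export
print.trafficking_fit <- function(x, ...) {
  cat(sprintf("<trafficking_fit> %d chains x %d draws (warmup %d), seed %d\n",
              x$n_chains, x$n_samples, x$n_warmup, x$seed))
  cat(sprintf("  mean acceptance rate %.2f\n", mean(x$accept_rate)))
  print(tidy(x))
  invisible(x)
}

#' Posterior summaries of a trafficking fit
#'
#' `tidy()` returns per-parameter posterior mean, SD and central 95%
#' interval; `glance()` returns one row of fit-level information.
#'
#' @param x A `trafficking_fit` from [fit_trafficking()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trafficking_fit
#' @export
tidy.trafficking_fit <- function(x, ...) {
  x$draws |>
    tidyr::pivot_longer(dplyr::all_of(fit_param_names(x)),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      q2.5 = stats::quantile(.data$value, 0.025),
      q97.5 = stats::quantile(.data$value, 0.975),
      .groups = "drop"
    )
}

#' @rdname tidy.trafficking_fit
#' @method glance trafficking_fit
#' @export
glance.trafficking_fit <- function(x, ...) {
  diag <- mcmc_diagnostics(x)
  tibble::tibble(
    n_chains = x$n_chains,
    n_draws = nrow(x$draws),
    accept_rate = mean(x$accept_rate),
    max_abs_geweke = max(abs(diag$geweke_z)),
    max_iat = max(diag$iat),
    seed = x$seed
  )
}

#' Posterior-mean trafficking parameters
#'
#' Collapses the posterior draws to their means and returns them as a
#' [trafficking_params()] object (release fractions fixed by the prior are
#' restored at 1).
#'
#' @param fit A `trafficking_fit`.
#' @return A [trafficking_params()] object.
#' @export
posterior_mean_params <- function(fit) {
  stopifnot(inherits(fit, "trafficking_fit"))
  m <- colMeans(fit$draws[fit_param_names(fit)])
  map <- param_map(fit$priors)
  fs <- m[paste0("f_sort_", map$fs_order)]
  names(fs) <- map$fs_order
  fr <- stats::setNames(rep(1, length(map$fs_order)), map$fs_order)
  if (length(map$fr_order)) {
    fr[map$fr_order] <- m[paste0("f_release_", map$fr_order)]
  }
  trafficking_params(V_p = m[["V_p"]], V_e = m[["V_e"]], Q = m[["Q"]],
                     Q_u = m[["Q_u"]], f_sort = fs,
                     f_release = fr[names(fs)])
}

#' Posterior summary of surface recapture
#'
#' Posterior mean, SD and central 95% interval of the recapture fraction
#' `1 - f_release` for each variant whose release fraction is free; variants
#' with `f_release` fixed at 1 are reported with recapture 0.
#'
#' @param fit A `trafficking_fit`.
#' @return A tibble with columns `variant`, `recapture_mean`,
#'   `recapture_sd`, `q2.5`, `q97.5`, `fixed`.
#' @export
recapture_summary <- function(fit) {
  stopifnot(inherits(fit, "trafficking_fit"))
  map <- param_map(fit$priors)
  free <- purrr::map_dfr(map$fr_order, function(v) {
    rec <- 1 - fit$draws[[paste0("f_release_", v)]]
    tibble::tibble(variant = v,
                   recapture_mean = mean(rec),
                   recapture_sd = stats::sd(rec),
                   q2.5 = stats::quantile(rec, 0.025),
                   q97.5 = stats::quantile(rec, 0.975),
                   fixed = FALSE)
  })
  fixed <- tibble::tibble(variant = map$fr_fixed, recapture_mean = 0,
                          recapture_sd = 0, q2.5 = 0, q97.5 = 0,
                          fixed = TRUE)
  dplyr::bind_rows(free, fixed)
}

# ---- convergence diagnostics ----------------------------------------------

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  ord_max <- min(length(x) - 1L, floor(10 * log10(length(x))))
  fit <- stats::ar(x, aic = TRUE, order.max = ord_max)
  if (fit$order == 0L) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardized by spectral-density-at-zero variance
#' estimates of the two segments. Values within about +/- 2 are consistent
#' with a stationary chain.
#'
#' @param x Numeric vector: one chain of one parameter.
#' @param frac1,frac2 Leading and trailing fractions (defaults 0.1, 0.5).
#' @return Scalar z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  stopifnot(n >= 20, frac1 + frac2 <= 1)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq(n - floor(frac2 * n) + 1L, n)]
  denom <- sqrt(spectrum0_ar(a) / length(a) + spectrum0_ar(b) / length(b))
  if (denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}

#' Integrated autocorrelation time
#'
#' `1 + 2 * sum(rho_k)` with the sum truncated by Geyer's initial positive
#' sequence (pairs of successive autocorrelations are summed while their
#' sum stays positive). Equals ~1 for white noise; the effective sample
#' size of a chain of length `n` is `n / iat`.
#'
#' @param x Numeric vector: one chain of one parameter.
#' @return Scalar autocorrelation time, clipped below at 1.
#' @export
integrated_autocorr_time <- function(x) {
  n <- length(x)
  stopifnot(n >= 10)
  if (stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  # Geyer initial positive sequence on pairs (rho_0 + rho_1), ...
  m <- length(rho)
  if (m %% 2L == 1L) rho <- c(rho, 0)
  g <- rho[seq(1, length(rho), by = 2)] + rho[seq(2, length(rho), by = 2)]
  cut <- which(g <= 0)
  keep <- if (length(cut)) seq_len(cut[1] - 1L) else seq_along(g)
  max(1, -1 + 2 * sum(g[keep]))
}

#' MCMC convergence diagnostics
#'
#' Per parameter and chain: the Geweke z-score (first 10% vs last 50%) and
#' the integrated autocorrelation time, with a pass flag `|z| < 2`.
#'
#' @param fit A `trafficking_fit` (or any object with a `draws` tibble
#'   containing `chain`, `iteration` and parameter columns).
#' @return A tibble with columns `parameter`, `chain`, `geweke_z`,
#'   `geweke_pass`, `iat`, `ess`.
#' @export
mcmc_diagnostics <- function(fit) {
  draws <- if (inherits(fit, "trafficking_fit")) fit$draws else fit
  stopifnot(is.data.frame(draws), all(c("chain", "iteration") %in%
                                        names(draws)))
  chains <- unique(draws$chain)
  if (length(chains) < 2L) {
    stop("diagnostics require at least 2 chains", call. = FALSE)
  }
  n_per <- min(table(draws$chain))
  if (n_per < 100L) {
    stop("diagnostics require at least 100 draws per chain", call. = FALSE)
  }
  params <- setdiff(names(draws), c("chain", "iteration", "lp"))
  grid <- tidyr::expand_grid(parameter = params, chain = chains)
  purrr::map2_dfr(grid$parameter, grid$chain, function(p, ch) {
    x <- draws[[p]][draws$chain == ch]
    z <- geweke_z(x)
    iat <- integrated_autocorr_time(x)
    tibble::tibble(parameter = p, chain = ch,
                   geweke_z = z, geweke_pass = abs(z) < 2,
                   iat = iat, ess = length(x) / iat)
  })
}

# ---- sensitivity analysis --------------------------------------------------

#' Elasticities of the model half-life
#'
#' Central finite-difference sensitivities of `ln(T1/2)` at a parameter
#' point: with respect to `ln(theta)` for the positive parameters `V_p`,
#' `V_e`, `Q`, `Q_u` (dimensionless elasticities), and for the sorting
#' fractions with respect to the log complementary loss fraction by
#' default (`fraction_scale = "loss"`): `d ln(T1/2) / d ln(1 - f_sort)`
#' (the lysosomally degraded share) and `d ln(T1/2) / d ln(1 - f_release)`
#' (the surface-recaptured share). The loss scale is the meaningful one
#' near the upper boundary, where the half-life diverges as `f -> 1` and a
#' raw per-unit-fraction derivative grows without bound for any
#' well-recycled variant; `fraction_scale = "fraction"` reports that raw
#' derivative `d ln(T1/2) / d f` instead. A fraction within one step of 0
#' or 1 is differenced one-sidedly and flagged `boundary`.
#'
#' @inheritParams terminal_half_life
#' @param rel_step Relative step for the log-parameter differences
#'   (default 1e-3); fractions use an absolute step of `rel_step / 10`.
#' @param fixed Character vector of parameters to omit from the table
#'   (e.g. `"f_release"` for a variant whose release fraction is fixed by
#'   the prior).
#' @param half_life Half-life definition to differentiate:
#'   `"time_to_half"` (default, matching the fitting default) or
#'   `"terminal"`.
#' @param fraction_scale `"loss"` (default) or `"fraction"`; see above.
#' @return A tibble ranked by `abs_elasticity` (rank 1 = most influential):
#'   columns `parameter`, `value`, `elasticity`, `abs_elasticity`, `scale`,
#'   `boundary`, `rank`.
#' @export
sensitivity_analysis <- function(params, variant = NULL, rel_step = 1e-3,
                                 fixed = character(),
                                 half_life = c("time_to_half",
                                               "terminal"),
                                 fraction_scale = c("loss", "fraction")) {
  stopifnot(inherits(params, "trafficking_params"))
  type <- hl_type_code(match.arg(half_life))
  fraction_scale <- match.arg(fraction_scale)
  fr <- variant_fractions(params, variant)
  base <- list(V_p = params$V_p, V_e = params$V_e, Q = params$Q,
               Q_u = params$Q_u, f_sort = fr$f_sort,
               f_release = fr$f_release)
  hl_at <- function(repl) {
    th <- utils::modifyList(base, repl)
    .cpp_half_life(th$V_p, th$V_e, th$Q, th$Q_u, th$f_sort, th$f_release,
                   type)
  }
  hl0 <- hl_at(list())
  if (!is.finite(hl0)) {
    stop("half-life is infinite at these parameters; sensitivity is ",
         "undefined", call. = FALSE)
  }
  rows <- list()
  for (p in setdiff(c("V_p", "V_e", "Q", "Q_u"), fixed)) {
    h <- rel_step
    up <- hl_at(stats::setNames(list(base[[p]] * exp(h)), p))
    dn <- hl_at(stats::setNames(list(base[[p]] * exp(-h)), p))
    rows[[p]] <- tibble::tibble(
      parameter = p, value = base[[p]],
      elasticity = (log(up) - log(dn)) / (2 * h),
      scale = "log", boundary = FALSE)
  }
  h <- rel_step / 10
  for (p in setdiff(c("f_sort", "f_release"), fixed)) {
    f <- base[[p]]
    lo <- f - h >= 0
    hi <- f + h <= 1 && is.finite(hl_at(stats::setNames(list(f + h), p)))
    if (lo && hi) {
      el <- (log(hl_at(stats::setNames(list(f + h), p))) -
               log(hl_at(stats::setNames(list(f - h), p)))) / (2 * h)
      bnd <- FALSE
    } else if (lo) {
      el <- (log(hl0) - log(hl_at(stats::setNames(list(f - h), p)))) / h
      bnd <- TRUE
    } else {
      el <- (log(hl_at(stats::setNames(list(f + h), p))) - log(hl0)) / h
      bnd <- TRUE
    }
    if (fraction_scale == "loss") {
      # chain rule onto the log complementary (loss) fraction
      el <- -el * (1 - f)
    }
    rows[[p]] <- tibble::tibble(parameter = p, value = f, elasticity = el,
                                scale = if (fraction_scale == "loss")
                                  "loss-log" else "fraction",
                                boundary = bnd)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(abs_elasticity = abs(.data$elasticity)) |>
    dplyr::arrange(dplyr::desc(.data$abs_elasticity)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("parameter", "value", "elasticity", "abs_elasticity",
                  "scale", "boundary", "rank")
  out
}

#' Trace and density plots for a trafficking fit
#'
#' @param object A `trafficking_fit`.
#' @param type `"trace"` or `"density"`.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object faceted by parameter, colored by chain.
#' @method autoplot trafficking_fit
#' @export
autoplot.trafficking_fit <- function(object, type = c("trace", "density"),
                                     parameters = NULL, ...) {
  type <- match.arg(type)
  params <- parameters %||% fit_param_names(object)
  long <- object$draws |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value") |>
    dplyr::mutate(chain = factor(.data$chain))
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                       color = .data$chain)) +
      ggplot2::geom_line(linewidth = 0.2, alpha = 0.8) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$value, color = .data$chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  }
}
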