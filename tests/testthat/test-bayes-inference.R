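test_that("priors encode the affinity-dictated structure", {
  priors <- build_priors(fcrn_affinities())
  expect_equal(priors$f_sort_order, c("YTE", "LS", "DHS", "wt"))
  expect_setequal(priors$f_release_fixed, c("wt", "DHS"))
  expect_equal(priors$f_release_order, c("YTE", "LS"))
  expect_equal(priors$lognormal$sdlog, c(1, 1, 1, 0.5))
  expect_error(build_priors(fcrn_affinities(), variants = c("wt", "zz")),
               "zz")
})

test_that("prior draws always satisfy ordering and box constraints", {
  priors <- build_priors(fcrn_affinities())
  set.seed(43)
  draws <- sample_prior(priors, 1e5)
  expect_true(all(draws$f_sort_YTE >= draws$f_sort_LS))
  expect_true(all(draws$f_sort_LS >= draws$f_sort_DHS))
  expect_true(all(draws$f_sort_DHS >= draws$f_sort_wt))
  expect_true(all(draws$f_release_YTE >= draws$f_release_LS))
  frac <- dplyr::select(draws, dplyr::starts_with("f_"))
  expect_true(all(frac >= 0 & frac <= 1))
  expect_true(all(dplyr::select(draws, V_p, V_e, Q, Q_u) > 0))
  # chained-uniform construction: top of each chain is uniform on (0, 1)
  expect_equal(mean(draws$f_sort_YTE), 0.5, tolerance = 0.01)
})

test_that("log likelihood matches the normal density by hand", {
  p <- trafficking_params(1.2, 0.3, 0.8, 0.9, f_sort = 0.85,
                          f_release = 0.55)
  h0 <- time_to_half(c(1, 0, 0), p)
  obs <- tibble::tibble(variant = "v", mean_h = h0 + 10, sd_h = 10, n = 1)
  expect_equal(log_likelihood(p, obs),
               -0.5 - log(10 * sqrt(2 * pi)))
  # the likelihood peaks when the model half-life equals the observed mean
  obs0 <- tibble::tibble(variant = "v", mean_h = h0, sd_h = 10, n = 1)
  expect_gt(log_likelihood(p, obs0), log_likelihood(p, obs))
  # a closed system has no terminal elimination: likelihood vanishes
  p_closed <- trafficking_params(1.2, 0.3, 0.8, 0.9, f_sort = 1,
                                 f_release = 1)
  expect_identical(
    log_likelihood(p_closed, obs0, half_life = "terminal"), -Inf)
})

test_that("MCMC draws are reproducible and respect all constraints", {
  priors <- build_priors(fcrn_affinities())
  obs <- half_life_observations("Tg276")
  fit1 <- fit_trafficking(obs, priors, seed = 99, n_chains = 2,
                          n_warmup = 300, n_samples = 300, n_temps = 5)
  fit2 <- fit_trafficking(obs, priors, seed = 99, n_chains = 2,
                          n_warmup = 300, n_samples = 300, n_temps = 5)
  expect_identical(fit1$draws, fit2$draws)
  d <- fit1$draws
  expect_true(all(d$f_sort_YTE >= d$f_sort_LS & d$f_sort_LS >= d$f_sort_DHS &
                    d$f_sort_DHS >= d$f_sort_wt))
  expect_true(all(d$f_release_YTE >= d$f_release_LS))
  expect_true(all(d$f_release_YTE <= 1 & d$f_release_LS >= 0))
  expect_true(all(d$V_p > 0 & d$V_e > 0 & d$Q > 0 & d$Q_u > 0))
  expect_error(
    fit_trafficking(tibble::tibble(variant = "zz", mean_h = 10, sd_h = 1,
                                   n = 3), priors),
    "zz")
})

test_that("prior-only run reproduces the closed-form lognormal mean", {
  priors <- build_priors(fcrn_affinities())
  fit <- fit_trafficking(tibble::tibble(variant = character(),
                                        mean_h = numeric(),
                                        sd_h = numeric(), n = integer()),
                         priors, seed = 5, n_chains = 2,
                         n_warmup = 1000, n_samples = 3000)
  qu <- fit$draws$Q_u
  iat <- mean(vapply(unique(fit$draws$chain), function(ch) {
    integrated_autocorr_time(qu[fit$draws$chain == ch])
  }, numeric(1)))
  mcse <- stats::sd(qu) * sqrt(iat / length(qu))
  expect_lt(abs(mean(qu) - exp(0.1 + 0.5^2 / 2)), 3 * mcse)
})

test_that("prior-predictive half-lives are finite when sorting mass is
           below one", {
  priors <- build_priors(fcrn_affinities())
  set.seed(47)
  draws <- sample_prior(priors, 200)
  hls <- vapply(seq_len(200), function(i) {
    fcrnpk:::.cpp_half_life(draws$V_p[i], draws$V_e[i], draws$Q[i],
                            draws$Q_u[i], draws$f_sort_wt[i], 1, 0L)
  }, numeric(1))
  expect_true(all(is.finite(hls)))
})

test_that("fitting synthetic half-lives recovers the recapture ranking", {
  # three synthetic variants with known release fractions 1.0 / 0.8 / 0.5
  aff <- tibble::tibble(
    variant = c("A", "B", "C"),
    kd_ph58_nM = c(100, 50, 20),
    ph74_detectable = c(FALSE, TRUE, TRUE),
    kd_ph74_high_nM = c(NA, 2000, 500)
  )
  priors <- build_priors(aff, variants = c("A", "B", "C"))
  truth <- trafficking_params(0.3, 0.2, 2.5, 0.5,
                              f_sort = c(A = 0.90, B = 0.92, C = 0.94),
                              f_release = c(A = 1, B = 0.8, C = 0.5))
  true_fr <- c(B = 0.8, C = 0.5)
  hl <- vapply(c("A", "B", "C"), function(v) {
    time_to_half(c(1, 0, 0), truth, v)
  }, numeric(1))
  n_rep <- 6
  rank_ok <- 0
  cover <- c(B = 0, C = 0)
  for (r in seq_len(n_rep)) {
    set.seed(600 + r)
    obs <- tibble::tibble(
      variant = c("A", "B", "C"),
      mean_h = hl * exp(stats::rnorm(3, 0, 0.02)),
      sd_h = 0.05 * hl, n = 4
    )
    fit <- fit_trafficking(obs, priors, seed = 700 + r, n_chains = 2,
                           n_warmup = 800, n_samples = 800, n_temps = 6)
    rs <- recapture_summary(fit)
    rec <- stats::setNames(rs$recapture_mean, rs$variant)
    if (rec[["C"]] > rec[["B"]] && rec[["B"]] > rec[["A"]] - 1e-9) {
      rank_ok <- rank_ok + 1
    }
    for (v in c("B", "C")) {
      row <- rs[rs$variant == v, ]
      if (1 - true_fr[[v]] >= row$q2.5 && 1 - true_fr[[v]] <= row$q97.5) {
        cover[v] <- cover[v] + 1
      }
    }
  }
  expect_gte(rank_ok, n_rep - 1)
  expect_gte(cover[["B"]], n_rep - 1)
  expect_gte(cover[["C"]], n_rep - 1)
})

test_that("diagnostics behave on constructed chains", {
  set.seed(53)
  n <- 400
  iid <- tibble::tibble(
    chain = rep(1:2, each = n), iteration = rep(seq_len(n), 2),
    theta = stats::rnorm(2 * n)
  )
  d <- mcmc_diagnostics(iid)
  expect_true(all(abs(d$geweke_z) < 3))
  expect_true(all(d$iat < 1.6))
  # strong linear drift trips the Geweke flag
  drift <- iid
  drift$theta <- drift$theta + drift$iteration / 50
  dd <- mcmc_diagnostics(drift)
  expect_true(any(!dd$geweke_pass))
  # duplicated chains give identical per-chain statistics
  dup <- iid
  dup$theta[dup$chain == 2] <- dup$theta[dup$chain == 1]
  ddup <- mcmc_diagnostics(dup)
  expect_equal(ddup$geweke_z[1], ddup$geweke_z[2])
  expect_equal(ddup$iat[1], ddup$iat[2])
  expect_error(mcmc_diagnostics(iid[iid$chain == 1, ]), "2 chains")
  expect_error(mcmc_diagnostics(iid[iid$iteration <= 50, ]), "100 draws")
})

test_that("iid chains pass diagnostics in most trials", {
  set.seed(59)
  n_trial <- 40
  pass <- 0
  for (i in seq_len(n_trial)) {
    x <- stats::rnorm(1000)
    z <- geweke_z(x)
    if (abs(z) < 2 && integrated_autocorr_time(x) < 2) pass <- pass + 1
  }
  expect_gte(pass, round(0.9 * n_trial))
})

test_that("sensitivity elasticities obey the time-rescaling identity", {
  p <- trafficking_params(1.2, 0.3, 0.8, 0.9, f_sort = 0.85,
                          f_release = 0.55)
  for (hl in c("time_to_half", "terminal")) {
    s <- sensitivity_analysis(p, half_life = hl)
    expect_equal(sum(s$elasticity[s$parameter %in% c("Q", "Q_u")]), -1,
                 tolerance = 1e-4)
  }
  # excluding a fixed release fraction drops it from the table
  s_wt <- sensitivity_analysis(p, fixed = "f_release")
  expect_false("f_release" %in% s_wt$parameter)
  expect_true("f_sort" %in% s_wt$parameter)
  p_closed <- trafficking_params(1, 0.2, 0.5, 1, f_sort = 1, f_release = 1)
  expect_error(sensitivity_analysis(p_closed, half_life = "terminal"),
               "infinite")
})

test_that("fraction sensitivities: loss scale vs raw derivative", {
  p <- trafficking_params(1.2, 0.3, 0.8, 0.9, f_sort = 0.85,
                          f_release = 0.55)
  s_loss <- sensitivity_analysis(p)
  s_raw <- sensitivity_analysis(p, fraction_scale = "fraction")
  raw_fs <- s_raw$elasticity[s_raw$parameter == "f_sort"]
  loss_fs <- s_loss$elasticity[s_loss$parameter == "f_sort"]
  expect_equal(loss_fs, -raw_fs * (1 - 0.85), tolerance = 1e-8)
  # raising either loss fraction shortens the half-life
  expect_lt(loss_fs, 0)
  expect_lt(s_loss$elasticity[s_loss$parameter == "f_release"], 0
            + 1e-12)
})

test_that("posterior summaries are coherent", {
  fit <- fit_trafficking(half_life_observations("Tg276"),
                         build_priors(fcrn_affinities()), seed = 77,
                         n_chains = 2, n_warmup = 400, n_samples = 400,
                         n_temps = 5)
  td <- tidy(fit)
  expect_true(all(td$q2.5 <= td$mean & td$mean <= td$q97.5))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 800L)
  pm <- posterior_mean_params(fit)
  expect_s3_class(pm, "trafficking_params")
  expect_equal(unname(pm$f_release[c("wt", "DHS")]), c(1, 1))
  rs <- recapture_summary(fit)
  expect_setequal(rs$variant, c("wt", "DHS", "YTE", "LS"))
  expect_true(all(rs$recapture_mean[rs$fixed] == 0))
  plt <- autoplot(fit, parameters = c("Q_u", "f_release_YTE"))
  expect_s3_class(plt, "ggplot")
})
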