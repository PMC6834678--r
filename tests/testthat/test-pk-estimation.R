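test_that("trapezoid rules: rectangle, log-interval, analytic exponential", {
  expect_equal(auc_loglinear(c(0, 2), c(10, 10)), 20)
  # strictly decreasing pair uses the logarithmic rule
  expect_equal(auc_loglinear(c(0, 1), c(100, 50)), 50 / log(2))
  t <- seq(0, 20, by = 0.05)
  conc <- 100 * exp(-0.5 * t)
  expect_equal(auc_loglinear(t, conc), 200 * (1 - exp(-10)),
               tolerance = 1e-3)
  expect_error(auc_loglinear(1, 5), "at least 2")
  expect_error(auc_loglinear(c(0, 0), c(1, 1)), "strictly increasing")
})

test_that("AUC is additive over interior split points and log <= linear", {
  set.seed(31)
  for (i in 1:10) {
    t <- sort(stats::runif(9, 0, 10))
    conc <- stats::rlnorm(9, 2, 0.6)
    k <- sample(2:8, 1)
    expect_equal(auc_loglinear(t, conc),
                 auc_loglinear(t[1:k], conc[1:k]) +
                   auc_loglinear(t[k:9], conc[k:9]),
                 tolerance = 1e-12)
  }
  # convexity: on a decreasing interval the log trapezoid sits below
  t <- c(0, 1); conc <- c(80, 20)
  lin <- diff(t) * mean(conc)
  expect_lt(auc_loglinear(t, conc), lin)
})

test_that("leading zeros use the linear rule", {
  # zero endpoint forces the linear trapezoid (log rule undefined)
  expect_equal(auc_loglinear(c(0, 1, 2), c(0, 10, 10)), 5 + 10)
})

test_that("terminal regression recovers exact and late-window slopes", {
  t <- seq(0, 14, by = 1)
  fit <- terminal_phase_fit(t, 50 * exp(-0.3 * t))
  expect_equal(fit$lambda_z, 0.3, tolerance = 1e-12)
  # biexponential sampled late relative to the fast phase
  t2 <- seq(3, 30, by = 1.5)
  conc2 <- 20 * exp(-2 * t2) + 10 * exp(-0.1 * t2)
  fit2 <- terminal_phase_fit(t2, conc2)
  expect_equal(fit2$lambda_z, 0.1, tolerance = 0.01)
  expect_error(terminal_phase_fit(t[1:5], 50 * exp(-0.3 * t[1:5])),
               "at least 6")
  expect_error(terminal_phase_fit(t[1:8], 50 * exp(0.2 * t[1:8])),
               "terminal")
})

test_that("extrapolation tails match hand evaluation", {
  ext <- auc_to_inf(auc_last = 0, aumc_last = 0, t_last = 10, c_last = 1,
                    lambda_z = 0.5)
  expect_equal(ext$auc_inf, 2)
  expect_equal(ext$aumc_inf, 10 / 0.5 + 1 / 0.25)
  expect_error(auc_to_inf(1, 1, 1, 1, 0), "positive")
})

test_that("clearance and Vss formulas and preconditions", {
  expect_equal(clearance(100, 50), 2)
  expect_equal(clearance(2000, 157.9), 2000 / 157.9)
  expect_equal(vss(100, 200, 10), 200)
  expect_error(clearance(100, 0), "positive")
  expect_error(vss(100, 200, 0), "positive")
})

test_that("NCA on dense mono-exponential data matches closed forms", {
  lambda <- 0.5 # per day
  c0 <- 100
  t_d <- seq(0, 24, by = 0.05)
  data <- tibble::tibble(time_h = t_d * 24, conc_ug_ml = c0 * exp(-lambda * t_d))
  dose <- 2000
  res <- nca(data, dose_ug_kg = dose)
  expect_equal(res$auc_inf_ug_day_ml, c0 / lambda, tolerance = 0.005)
  expect_equal(res$cl_ml_day_kg, dose * lambda / c0, tolerance = 0.005)
  expect_equal(res$vss_ml_kg, dose / c0, tolerance = 0.01)
  expect_equal(res$t_half_beta_h, 24 * log(2) / lambda, tolerance = 0.005)
  expect_equal(res$c_max_ug_ml, c0)
})

test_that("NCA excludes censored points and handles multiple subjects", {
  t_h <- c(1, 6, 24, 48, 96, 168, 240, 336)
  mk <- function(id) tibble::tibble(
    subject_id = id, variant = "x", time_h = t_h,
    conc_ug_ml = 40 * exp(-0.004 * t_h),
    censored = c(0, 0, 0, 0, 0, 0, 0, 0), dose_mg_kg = 2)
  two <- dplyr::bind_rows(mk("a"), mk("b"))
  res <- nca(two)
  expect_equal(nrow(res), 2L)
  expect_equal(res$subject_id, c("a", "b"))
  one <- mk("a")
  one$censored[8] <- 1
  res1 <- nca(one, min_terminal_points = 6)
  expect_equal(res1$n_obs, 7L)
})

test_that("biexponential fit recovers generating parameters", {
  t_d <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
           10, 14, 18, 22, 28)
  truth <- c(A = 20, alpha = 2, B = 10, beta = 0.1)
  conc <- truth["A"] * exp(-truth["alpha"] * t_d) +
    truth["B"] * exp(-truth["beta"] * t_d)
  fit <- fit_biexponential(tibble::tibble(time_h = t_d * 24,
                                          conc_ug_ml = conc))
  est <- tidy(fit)
  expect_equal(est$A_ug_ml, 20, tolerance = 1e-6)
  expect_equal(est$alpha_per_day, 2, tolerance = 1e-6)
  expect_equal(est$B_ug_ml, 10, tolerance = 1e-6)
  expect_equal(est$beta_per_day, 0.1, tolerance = 1e-6)
  expect_equal(est$t_half_beta_h, 24 * log(2) / 0.1, tolerance = 1e-6)
})

test_that("biexponential fit rejects mono-exponential input and recovers
           beta under noise", {
  t_d <- seq(0.1, 20, length.out = 15)
  expect_error(
    fit_biexponential(tibble::tibble(time_h = t_d * 24,
                                     conc_ug_ml = 30 * exp(-0.2 * t_d))),
    "mono-exponential")
  set.seed(37)
  t_d2 <- exp(seq(log(0.02), log(28), length.out = 40))
  mu <- 20 * exp(-2 * t_d2) + 10 * exp(-0.1 * t_d2)
  conc <- mu * exp(stats::rnorm(40, 0, sqrt(log(1 + 0.1^2))))
  fit <- fit_biexponential(tibble::tibble(time_h = t_d2 * 24,
                                          conc_ug_ml = conc))
  expect_equal(tidy(fit)$beta_per_day, 0.1, tolerance = 0.1)
})

test_that("fold changes: identity, rounding and lookup", {
  tab <- tibble::tibble(variant = c("a", "b"),
                        t_half = c(290.9, 148.4), auc = c(157.9, 96.9))
  fc <- fold_changes(tab)
  expect_equal(nrow(fc), 4L) # 2 parameters x 2 ordered pairs
  expect_equal(fc$ratio_rounded[fc$parameter == "t_half" &
                                  fc$numerator == "a"], 2.0)
  expect_equal(fold_change(tab, "auc", "a", "b"), 157.9 / 96.9)
  same <- tibble::tibble(variant = c("x", "y"), v = c(3, 3))
  expect_equal(fold_changes(same)$ratio_rounded, c(1, 1))
  expect_error(fold_changes(tab, parameters = "nope"), "unknown parameter")
  expect_error(fold_change(tab, "auc", "a", "zz"), "not found")
})
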