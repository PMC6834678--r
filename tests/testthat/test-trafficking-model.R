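test_that("rate matrix matches the stated mass balances", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_trafficking_params()
    m <- rate_matrix(p)
    conc <- stats::runif(3, 0, 50)
    expect_equal(drop(m %*% conc),
                 trafficking_rhs(conc, p, p$f_sort, p$f_release),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # off-diagonal rates are non-negative (compartmental structure)
    expect_true(all(m[upper.tri(m) | lower.tri(m)] >= 0))
  }
})

test_that("closed system has a zero eigenvalue, no uptake decouples", {
  p <- trafficking_params(2, 0.5, 0.7, 1.3, f_sort = 1, f_release = 1)
  ev <- eigen(rate_matrix(p), only.values = TRUE)$values
  expect_lt(min(abs(Re(ev))), 1e-12)
  p0 <- trafficking_params(2, 0.5, 0.7, 0, f_sort = 0.5, f_release = 0.5)
  m <- rate_matrix(p0)
  expect_equal(unname(m[3, ]), c(0, 0, 0))
  expect_equal(unname(m[, 3]), c(0, 0, 0))
})

test_that("parameter validation names the offending field", {
  expect_error(trafficking_params(-1, 0.5, 1, 1, 0.5, 0.5), "V_p")
  expect_error(trafficking_params(1, 0, 1, 1, 0.5, 0.5), "V_e")
  expect_error(trafficking_params(1, 0.5, 1, -0.1, 0.5, 0.5), "Q_u")
  expect_error(trafficking_params(1, 0.5, 1, 1, 1.2, 0.5), "f_sort")
  expect_error(trafficking_params(1, 0.5, 1, 1, c(a = 0.5), c(b = 0.5)),
               "names")
})

test_that("propagation: identity at t = 0 and mass conservation when closed", {
  p <- trafficking_params(1.4, 0.3, 0.8, 1.1, f_sort = 1, f_release = 1)
  s0 <- c(40, 2, 1)
  tr <- propagate(s0, p, c(0, 5, 50, 500))
  expect_equal(unlist(tr[1, c("C_c", "C_p", "C_e")]), s0,
               ignore_attr = TRUE)
  m0 <- total_mass(s0, p)
  expect_equal(total_mass(tr, p), rep(m0, 4), tolerance = 1e-10)
  expect_error(propagate(s0, p, -1), "non-negative")
})

test_that("matrix-exponential propagation matches an ODE-integrator oracle", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:25) {
    p <- random_trafficking_params()
    s0 <- c(stats::runif(1, 10, 50), 0, 0)
    times <- c(0, 1, 10, 100, 1000)
    got <- propagate(s0, p, times)
    rhs <- function(t, y, parms) list(trafficking_rhs(y, p, p$f_sort,
                                                      p$f_release))
    ref <- deSolve::lsoda(s0, times, rhs, NULL, rtol = 1e-13, atol = 1e-16)
    for (j in 2:4) {
      x <- got[[c("C_c", "C_p", "C_e")[j - 1]]]
      y <- unname(ref[, j])
      # relative agreement; concentrations below 1e-6 of the dose are
      # beneath the integrator's certified accuracy and floor the ratio
      expect_lt(max(abs(x - y) / pmax(abs(y), 1e-6 * s0[1])), 1e-8)
    }
  }
})

test_that("total mass obeys the degradation identity", {
  expect_equal(total_mass(c(1, 1, 1),
                          trafficking_params(1, 1, 1, 1, 0.5, 0.5)), 3)
  set.seed(11)
  for (i in 1:10) {
    p <- random_trafficking_params()
    s0 <- c(30, 0, 0)
    t0 <- stats::runif(1, 1, 30)
    h <- 1e-4
    tr <- propagate(s0, p, c(t0 - h, t0, t0 + h))
    dm_dt <- (total_mass(tr[3, ], p) - total_mass(tr[1, ], p)) / (2 * h)
    expected <- p$Q_u * tr$C_e[2] * (p$f_sort - 1)
    expect_equal(dm_dt, expected, tolerance = 1e-6)
    expect_lte(expected, 0)
  }
  # strictly decreasing mass while endosomal content is positive
  p <- trafficking_params(1, 0.2, 0.5, 1, f_sort = 0.9, f_release = 1)
  tr <- propagate(c(40, 0, 0), p, seq(1, 200, by = 5))
  expect_true(all(diff(total_mass(tr, p)) < 0))
})

test_that("trajectories stay non-negative and scale linearly", {
  set.seed(13)
  for (i in 1:10) {
    p <- random_trafficking_params()
    s0 <- stats::runif(3, 0, 20)
    tr <- propagate(s0, p, c(2, 20, 200))
    expect_true(all(tr$C_c >= 0 & tr$C_p >= 0 & tr$C_e >= 0))
    tr2 <- propagate(3 * s0, p, c(2, 20, 200))
    expect_equal(3 * tr$C_c, tr2$C_c, tolerance = 1e-10)
    expect_equal(3 * tr$C_e, tr2$C_e, tolerance = 1e-10)
  }
})

test_that("terminal half-life: closed limit, slope oracle, rate scaling", {
  p_closed <- trafficking_params(1, 0.2, 0.5, 1, f_sort = 1, f_release = 1)
  expect_identical(terminal_half_life(p_closed), Inf)
  set.seed(17)
  for (i in 1:8) {
    p <- random_trafficking_params()
    hl <- terminal_half_life(p)
    tr <- propagate(c(10, 0, 0), p, c(500, 1000))
    if (tr$C_c[2] < 1e-280) next # decayed past double precision
    slope <- (log(tr$C_c[1]) - log(tr$C_c[2])) / 500
    expect_equal(hl, log(2) / slope, tolerance = 0.01)
    # speeding up both flows by c divides the half-life by c
    p2 <- trafficking_params(p$V_p, p$V_e, 2 * p$Q, 2 * p$Q_u,
                             f_sort = p$f_sort, f_release = p$f_release)
    expect_equal(terminal_half_life(p2), hl / 2, tolerance = 1e-10)
  }
})

test_that("terminal half-life is non-decreasing in f_sort and f_release", {
  grid <- seq(0.05, 0.95, by = 0.15)
  for (fr in c(0.3, 0.7)) {
    hls <- vapply(grid, function(fs) {
      terminal_half_life(trafficking_params(1.2, 0.3, 0.6, 0.9,
                                            f_sort = fs, f_release = fr))
    }, numeric(1))
    expect_true(all(diff(hls) >= -1e-10))
  }
  for (fs in c(0.3, 0.7)) {
    hls <- vapply(grid, function(fr) {
      terminal_half_life(trafficking_params(1.2, 0.3, 0.6, 0.9,
                                            f_sort = fs, f_release = fr))
    }, numeric(1))
    expect_true(all(diff(hls) >= -1e-10))
  }
})

test_that("time_to_half agrees with a bisection oracle and the
           single-mode limit", {
  # uptake-dominated, nothing recycled: effectively one-compartment decay
  p <- trafficking_params(0.5, 0.2, 0.4, 5, f_sort = 0, f_release = 1)
  s0 <- c(20, 0, 0)
  tth <- time_to_half(s0, p)
  cc <- function(t) propagate(s0, p, t)$C_c
  lo <- 0; hi <- 64
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (cc(mid) > 10) lo <- mid else hi <- mid
  }
  expect_equal(tth, (lo + hi) / 2, tolerance = 1e-8)
  # started on the slow eigenvector the decay is mono-exponential and the
  # two half-life definitions coincide
  p2 <- trafficking_params(1.3, 0.4, 0.7, 1.1, f_sort = 0.8,
                           f_release = 0.6)
  e <- eigen(rate_matrix(p2))
  slow <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, slow]))
  expect_equal(time_to_half(v, p2), terminal_half_life(p2),
               tolerance = 1e-6)
  expect_error(time_to_half(c(0, 1, 1), p2), "positive")
})

test_that("compiled half-life kernels agree with the R implementations", {
  set.seed(23)
  for (i in 1:50) {
    p <- random_trafficking_params()
    expect_equal(fcrnpk:::.cpp_half_life(p$V_p, p$V_e, p$Q, p$Q_u,
                                         p$f_sort, p$f_release, 0L),
                 terminal_half_life(p), tolerance = 1e-8)
    expect_equal(fcrnpk:::.cpp_half_life(p$V_p, p$V_e, p$Q, p$Q_u,
                                         p$f_sort, p$f_release, 1L),
                 time_to_half(c(1, 0, 0), p), tolerance = 1e-6)
  }
})

test_that("recapture fraction and variant lookup", {
  p <- trafficking_params(1, 0.2, 0.5, 1,
                          f_sort = c(a = 0.9, b = 0.8),
                          f_release = c(a = 1, b = 0.5))
  expect_equal(recapture_fraction(p, "a"), 0)
  expect_equal(recapture_fraction(p, "b"), 0.5)
  expect_error(recapture_fraction(p, "c"), "unknown variant")
  expect_error(rate_matrix(p), "variant")
})

test_that("parameters round-trip through JSON", {
  p <- trafficking_params(1.7, 0.23, 0.55, 1.2,
                          f_sort = c(wt = 0.4, DHS = 0.9),
                          f_release = c(wt = 1, DHS = 0.7))
  path <- withr::local_tempfile(fileext = ".json")
  write_trafficking_params(p, path)
  p2 <- read_trafficking_params(path)
  expect_equal(p2, p)
  # unnamed single-variant parameters survive under the default key
  p3 <- trafficking_params(1, 0.2, 0.5, 1, 0.5, 0.5)
  write_trafficking_params(p3, path)
  expect_equal(read_trafficking_params(path), p3)
})
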