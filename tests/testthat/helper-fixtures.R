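# Shared test helpers: random well-behaved parameter draws and a cached
# Tg276 posterior fit reused by the model-based acceptance checks.

random_trafficking_params <- function(f_sort = NULL, f_release = NULL) {
  trafficking_params(
    V_p = stats::rlnorm(1, 0, 0.5),
    V_e = stats::rlnorm(1, 0, 0.5),
    Q = stats::rlnorm(1, 0, 0.5),
    Q_u = stats::rlnorm(1, 0, 0.5),
    f_sort = f_sort %||% stats::runif(1, 0.05, 0.95),
    f_release = f_release %||% stats::runif(1, 0.05, 0.95)
  )
}

# right-hand sides of the trafficking mass balances, written directly from
# the stated equations (independent of the rate-matrix construction)
trafficking_rhs <- function(conc, params, f_sort, f_release) {
  with(params, {
    c_c <- conc[1]; c_p <- conc[2]; c_e <- conc[3]
    dcc <- Q * (c_p - c_c)
    dcp <- (Q * c_c - Q * c_p - Q_u * c_p +
              Q_u * c_e * f_sort * f_release) / V_p
    dce <- Q_u * (c_p + c_e * ((1 - f_release) * f_sort - 1)) / V_e
    c(dcc, dcp, dce)
  })
}

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(strain, seed) {
  key <- strain
  if (is.null(.fit_cache[[key]])) {
    priors <- build_priors(fcrn_affinities())
    .fit_cache[[key]] <- fit_trafficking(
      half_life_observations(strain), priors, seed = seed,
      n_chains = 4L, n_warmup = 2000L, n_samples = 2000L
    )
  }
  .fit_cache[[key]]
}
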