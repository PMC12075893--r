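# Posterior inference for the EXNEX mixture and independent models.
# Oracle values are brute-force quadrature results (helper-oracle.R),
# frozen here after computation at fine grid resolution.

test_that("NEX prior parameters follow the plausible-rate formulas", {
  pr <- nex_prior_params(0.5)
  expect_equal(pr$m, 0)
  expect_equal(pr$v2, 4)

  pr <- nex_prior_params(0.3)
  expect_equal(pr$m, log(3 / 7))
  expect_equal(pr$v2, 1 / 0.3 + 1 / 0.7)

  pr <- nex_prior_params(c(0.2, 0.8))
  expect_equal(pr$m, c(log(0.25), log(4)))
  expect_equal(pr$v2, c(6.25, 6.25))

  expect_error(nex_prior_params(0), "0, 1")
  expect_error(nex_prior_params(c(0.3, 1)), "0, 1")
})

test_that("exceedance counts draws strictly above the null rate", {
  expect_equal(exceedance(matrix(0.5, 100, 2), 0.2), c(1, 1))
  expect_equal(exceedance(matrix(0.2, 100, 1), 0.2), 0)  # ties excluded
  expect_equal(exceedance(cbind(c(0.1, 0.3, 0.5, 0.15)), 0.2), 0.5)
  expect_error(exceedance(matrix(numeric(0), 0, 2), 0.2), "empty")
})

test_that("independent model matches the 1-D quadrature oracle", {
  cfg <- exnex_config()
  ms <- mcmc_settings(n_chains = 4, n_warmup = 1000, n_samples = 25000,
                      seed = 101)

  fit <- fit_independent(basket_data(24, 24), cfg, ms)
  expect_gt(fit$exceed_prob, 0.999)

  # oracle_exceed_indep(7, 24, 0.2, logit(0.2), 10) = 0.8399340
  fit <- fit_independent(basket_data(7, 24), cfg, ms)
  expect_equal(unname(fit$exceed_prob), 0.8399340, tolerance = 0.005)

  # oracle_exceed_indep(0, 24, ...) = 8.41e-05
  fit <- fit_independent(basket_data(0, 24), cfg, ms)
  expect_lt(fit$exceed_prob, 0.01)
})

test_that("EXNEX posterior matches the nested quadrature oracle (K = 2)", {
  cfg <- exnex_config()
  fit <- fit_exnex(basket_data(c(3, 4), c(10, 10)), cfg, ms_precise(7))
  # oracle_exceed_exnex(c(3, 4), c(10, 10), exnex_config()) at fine grids
  expect_equal(unname(fit$exceed_prob), c(0.7746713, 0.9178414),
               tolerance = 0.01)
})

test_that("pi = 0 degenerates to independent fits with the NEX prior", {
  dat <- basket_data(c(5, 2), c(14, 10))
  nex <- nex_prior_params(0.3)
  cfg_nex <- exnex_config(pi = 0, rho = 0.3)
  cfg_ind <- exnex_config(indep_prior_mean = nex$m,
                          indep_prior_sd = sqrt(nex$v2))
  ms <- mcmc_settings(n_chains = 4, n_warmup = 1000, n_samples = 25000,
                      seed = 11)
  f_mix <- fit_exnex(dat, cfg_nex, ms)
  ms$seed <- 12
  f_ind <- fit_independent(dat, cfg_ind, ms)
  # both routes must agree with the 1-D quadrature posterior:
  # oracle_exceed_indep under the NEX prior N(logit(0.3), 1/.3 + 1/.7)
  oracle <- c(0.9051153, 0.4833041)
  expect_lt(max(abs(unname(f_mix$exceed_prob) - oracle)), 0.01)
  expect_lt(max(abs(unname(f_ind$exceed_prob) - oracle)), 0.01)
  expect_true(all(f_mix$delta_draws == 0))
})

test_that("exceedance agrees with an independent JAGS fit of the same
           mixture", {
  model <- "
  model {
    for (k in 1:K) {
      y[k] ~ dbin(p[k], n[k])
      logit(p[k]) <- theta[k]
      theta[k] <- delta[k] * M1[k] + (1 - delta[k]) * M2[k]
      M1[k] ~ dnorm(mu, 1 / (sigma * sigma))
      M2[k] ~ dnorm(m[k], 1 / v2[k])
      delta[k] ~ dbern(0.5)
    }
    mu ~ dnorm(mu0, 0.01)
    sigma ~ dnorm(0, 1) T(0,)
  }"
  nex <- nex_prior_params(0.3)
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(y = c(3, 4), n = c(10, 10), K = 2,
                m = rep(nex$m, 2), v2 = rep(nex$v2, 2),
                mu0 = stats::qlogis(0.2)),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 61))
  update(jm, 2000, progress.bar = "none")
  p <- as.matrix(rjags::coda.samples(jm, "p", 20000,
                                     progress.bar = "none"))
  jags_exceed <- unname(colMeans(p > 0.2))

  ours <- fit_exnex(basket_data(c(3, 4), c(10, 10)), exnex_config(),
                    ms_precise(62))
  expect_lt(max(abs(unname(ours$exceed_prob) - jags_exceed)), 0.015)
})

test_that("pi = 1 degenerates to a hierarchical model with all-EX draws", {
  dat <- basket_data(c(9, 10, 11), c(24, 24, 24))
  fit <- fit_exnex(dat, exnex_config(pi = 1), ms_fast(21))
  expect_true(all(fit$delta_draws == 1))
})

test_that("borrowing raises a small homogeneous basket's exceedance", {
  dat <- basket_data(c(10, 10, 10, 10, 6), c(24, 24, 24, 24, 14))
  cfg <- exnex_config()
  f_ex <- fit_exnex(dat, cfg, ms_precise(31))
  f_in <- fit_independent(dat, cfg, ms_precise(32))
  expect_gt(f_ex$exceed_prob[5], f_in$exceed_prob[5])
})

test_that("identical settings and seed give bit-identical draws", {
  dat <- basket_data(c(3, 7), c(14, 24))
  cfg <- exnex_config()
  ms <- mcmc_settings(n_chains = 2, n_warmup = 200, n_samples = 500,
                      seed = 99)
  f1 <- fit_exnex(dat, cfg, ms)
  f2 <- fit_exnex(dat, cfg, ms)
  expect_identical(f1$theta_draws, f2$theta_draws)
  expect_identical(f1$delta_draws, f2$delta_draws)
  expect_identical(f1$sigma_draws, f2$sigma_draws)
  g1 <- fit_independent(dat, cfg, ms)
  g2 <- fit_independent(dat, cfg, ms)
  expect_identical(g1$theta_draws, g2$theta_draws)
})

test_that("exceedance is monotone non-decreasing in the response count", {
  cfg <- exnex_config()
  ms <- mcmc_settings(n_chains = 1, n_warmup = 500, n_samples = 4000,
                      diagnostics = FALSE)
  prev <- -Inf
  for (y1 in 0:10) {
    ms$seed <- 500 + y1
    fit <- fit_exnex(basket_data(c(y1, 3), c(10, 10)), cfg, ms)
    expect_gte(fit$exceed_prob[1], prev - 0.01)
    prev <- fit$exceed_prob[1]
  }
})

test_that("full exchangeability shrinks posterior sd under homogeneity", {
  dat <- basket_data(c(8, 9, 10, 9), c(24, 24, 24, 24))
  f_ex <- fit_exnex(dat, exnex_config(pi = 1), ms_precise(41))
  f_in <- fit_independent(dat, exnex_config(), ms_precise(42))
  expect_true(all(f_ex$post_sd <= f_in$post_sd + 0.005))
})

test_that("posterior result satisfies its structural invariants", {
  dat <- basket_data(c(3, 0, 14), c(24, 10, 14))
  fit <- fit_exnex(dat, exnex_config(), ms_fast(51))
  expect_true(all(fit$exceed_prob >= 0 & fit$exceed_prob <= 1))
  expect_equal(unname(fit$exceed_prob),
               unname(colMeans(fit$p_draws > 0.2)))
  expect_true(all(fit$p_draws > 0 & fit$p_draws < 1))
  expect_true(all(fit$delta_draws %in% 0:1))
  expect_named(fit$diagnostics, c("rhat", "ess", "accept_theta",
                                  "accept_sigma", "warnings"))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(basket_data(c(3, 4), 10), "equal")
  expect_error(basket_data(11, 10), "0 <= y")
  expect_error(basket_data(-1, 10), "0 <= y")
  expect_error(exnex_config(q0 = 0.3, q1 = 0.2), "q0")
  expect_error(exnex_config(pi = 1.2), "0, 1")
})
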