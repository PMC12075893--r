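# Cut-off calibration: global-null, robust (multi-scenario weighted),
# and the UNPL sample-size-matching rule.

test_that("generate_trial draws independent binomial counts", {
  set.seed(1)
  d <- generate_trial(scenario(rep(0, 3), c(10, 10, 5)))
  expect_equal(d$y, c(0L, 0L, 0L))
  d <- generate_trial(scenario(rep(1, 3), c(10, 10, 5)))
  expect_equal(d$y, d$n)

  set.seed(2)
  ys <- replicate(10000, generate_trial(scenario(0.2, 24))$y)
  se <- sqrt(0.2 * 0.8 / 24 / 10000)
  expect_lt(abs(mean(ys) / 24 - 0.2), 3 * se)
})

test_that("cut-off matching picks the closest existing sample size", {
  expect_equal(match_cutoff_by_sample_size(c(0.86, 0.87, 0.88),
                                           c(24, 24, 24), 14), 0.86)
  expect_equal(match_cutoff_by_sample_size(c(0.85, 0.87, 0.90),
                                           c(10, 20, 30), 22), 0.87)
  # tie between |10-20| and |30-20|: smallest index wins
  expect_equal(match_cutoff_by_sample_size(c(0.85, 0.90), c(10, 30), 20),
               0.85)
  expect_error(match_cutoff_by_sample_size(numeric(), integer(), 10),
               "empty")
})

tiny <- make_fixture("tiny")

test_that("robust calibration with one all-null scenario is the classical
           global-null calibration", {
  gn <- scenario(rep(0.2, 3), c(8, 8, 6), name = "gn")
  sp1 <- calibration_spec(list(gn), R = 60, alpha = 0.1, q0 = 0.2,
                          model = "exnex", seed = 5)
  c_rcap <- rcap_calibrate(sp1, tiny$config, ms_fast())
  c_gn <- calibrate_global_null(sp1, tiny$config, ms_fast())
  expect_identical(c_rcap$delta_existing, c_gn$delta_existing)
})

test_that("integer weights equal literal scenario replication", {
  s1 <- scenario(c(0.2, 0.2, 0.2), c(8, 8, 6), weight = 2, name = "s1")
  s2 <- scenario(c(0.4, 0.2, 0.2), c(8, 8, 6), weight = 1, name = "s2")
  sp_w <- calibration_spec(list(s1, s2), R = 40, alpha = 0.1,
                           model = "exnex", seed = 9)
  s1a <- scenario(s1$p, s1$n, weight = 1, name = "s1a")
  s1b <- scenario(s1$p, s1$n, weight = 1, name = "s1b")
  sp_r <- calibration_spec(list(s1a, s1b, s2), R = 40, alpha = 0.1,
                           model = "exnex", seed = 9)
  cw <- rcap_calibrate(sp_w, tiny$config, ms_fast())
  cr <- rcap_calibrate(sp_r, tiny$config, ms_fast())
  expect_identical(cw$delta_existing, cr$delta_existing)
})

test_that("baskets with equal sample sizes get identical cut-offs", {
  sp <- calibration_spec(tiny$rcap_scenarios, R = 40, alpha = 0.1,
                         model = "exnex", seed = 3)
  cs <- rcap_calibrate(sp, tiny$config, ms_fast(), tiny$structure)
  expect_identical(cs$delta_existing[1], cs$delta_existing[2])
})

test_that("the cut-off is the ceiling order statistic of the pooled,
           weighted null store", {
  # independent reconstruction of the store: replay the substreams and
  # fits directly, then compare the resulting quantile with the
  # calibration output
  scens <- list(scenario(c(0.2, 0.2), c(8, 8), weight = 2, name = "a"),
                scenario(c(0.4, 0.2), c(8, 8), weight = 1, name = "b"))
  R <- 30
  seed <- 13
  sp <- calibration_spec(scens, R = R, alpha = 0.5, model = "exnex",
                         seed = seed)
  cs <- rcap_calibrate(sp, tiny$config, ms_fast())

  pool <- c()
  for (scen in scens) {
    h <- basketadd:::scenario_hash(scen)
    nulls <- which(scen$p == 0.2)
    for (r in seq_len(R)) {
      set.seed(basketadd:::substream_seed(seed, h, r))
      fit <- fit_exnex(generate_trial(scen), tiny$config, ms_fast())
      pool <- c(pool, rep(fit$exceed_prob[nulls], scen$weight))
    }
  }
  expected <- sort(pool)[ceiling(0.5 * length(pool))]
  expect_equal(unname(cs$delta_existing[1]), unname(expected))
})

test_that("scenarios without null baskets are skipped, never silently
           absorbed", {
  s_eff <- scenario(c(0.4, 0.4, 0.4), c(8, 8, 6), name = "all effective")
  s_null <- scenario(c(0.2, 0.2, 0.2), c(8, 8, 6), name = "gn")
  sp <- calibration_spec(list(s_eff, s_null), R = 20, model = "exnex",
                         seed = 2)
  expect_message(cs <- rcap_calibrate(sp, tiny$config, ms_fast()),
                 "contributes nothing")
  sp_only_eff <- calibration_spec(list(s_eff), R = 20, model = "exnex",
                                  seed = 2)
  expect_error(
    suppressMessages(rcap_calibrate(sp_only_eff, tiny$config, ms_fast())),
    "null rate")
})

test_that("a sample-size class no scenario nulls raises a named error", {
  # basket 3 (n = 6) is effective in every scenario
  s <- scenario(c(0.2, 0.2, 0.4), c(8, 8, 6), name = "s")
  sp <- calibration_spec(list(s), R = 20, model = "exnex", seed = 2)
  expect_error(rcap_calibrate(sp, tiny$config, ms_fast()),
               "sample size 6")
})

test_that("per-approach calibration wires the models of each approach", {
  ms <- ms_fast()
  R <- 40
  # IND and PL2a share the existing-basket calibration model and seed
  c_ind <- calibrate_approach("IND", tiny$structure, tiny$scenarios,
                              R = R, config = tiny$config, mcmc = ms,
                              method = "global_null", seed = 21)
  c_pl2 <- calibrate_approach("PL2a", tiny$structure, tiny$scenarios,
                              R = R, config = tiny$config, mcmc = ms,
                              method = "global_null", seed = 21)
  expect_identical(c_ind$delta_existing, c_pl2$delta_existing)

  # PL1a and PL2a share the all-basket calibration of the new cut-off
  c_pl1 <- calibrate_approach("PL1a", tiny$structure, tiny$scenarios,
                              R = R, config = tiny$config, mcmc = ms,
                              method = "global_null", seed = 21)
  expect_identical(c_pl1$delta_new, c_pl2$delta_new)

  # UNPL inherits the existing cut-off by sample-size matching
  c_unpl <- calibrate_approach("UNPL", tiny$structure,
                               tiny$unpl_scenarios, R = R,
                               config = tiny$config, mcmc = ms,
                               method = "rcap", seed = 21)
  expect_identical(unname(c_unpl$delta_new),
                   unname(c_unpl$delta_existing[1]))
})

test_that("up-weighting effective-heavy scenarios never lowers the new
           basket's cut-off (matched seeds)", {
  base_w <- c(1L, 1L, 1L)
  up_w <- c(1L, 1L, 3L)  # tiny3 has the most effective baskets
  mk <- function(w) lapply(seq_along(tiny$rcap_scenarios), function(i) {
    s <- tiny$rcap_scenarios[[i]]
    scenario(s$p, s$n, weight = w[i], name = s$name)
  })
  cs_b <- rcap_calibrate(
    calibration_spec(mk(base_w), R = 50, model = "exnex", seed = 33),
    tiny$config, ms_fast(), tiny$structure)
  cs_u <- rcap_calibrate(
    calibration_spec(mk(up_w), R = 50, model = "exnex", seed = 33),
    tiny$config, ms_fast(), tiny$structure)
  expect_gte(cs_u$delta_new, cs_b$delta_new)
})
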