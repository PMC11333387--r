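test_that("multiplicative combination matches direct arithmetic", {
  expect_equal(combine_smd(-0.289), -0.289, tolerance = 1e-12)
  expect_equal(combine_smd(c(-0.147, -0.289)), 1 - 1.147 * 1.289,
               tolerance = 1e-12)
  expect_equal(combine_smd(c(-0.209, -0.366)), -0.651494, tolerance = 1e-9)
  expect_equal(combine_smd(numeric(0)), 0)
  # permutation invariance
  set.seed(1)
  for (i in 1:20) {
    x <- stats::runif(5, -0.5, 0.3)
    expect_equal(combine_smd(x), combine_smd(sample(x)), tolerance = 1e-12)
  }
})

test_that("treatment removal and re-application round-trip", {
  expect_equal(remove_treatment(40, 0, 10), 40)
  expect_equal(remove_treatment(40, -0.478483, 10), 35.21517, tolerance = 1e-9)
  expect_error(remove_treatment(40, -0.3, 0), class = "lbp_validation_error")
  set.seed(2)
  sf <- stats::runif(50, 20, 80)
  smd <- stats::runif(50, -0.6, 0.2)
  back <- remove_treatment(sf, smd, 12) - smd * 12
  expect_equal(back, sf, tolerance = 1e-12)
})

test_that("FUOT applies the optimal class and surgery mixture weights", {
  pooled <- exact_pooled(c(usual_care = 0, psych_physical = -0.460,
                           surgery = -0.366), n_draws = 5L)
  expect_equal(apply_fuot(35.215, pooled, FALSE, 10), 39.815, tolerance = 1e-9)
  # leg pain: 42.9% surgery, 57.1% optimal, as population weights
  got <- apply_fuot(35.215, pooled, TRUE, 10)
  expect_equal(got, 0.429 * (35.215 + 3.66) + 0.571 * (35.215 + 4.60),
               tolerance = 1e-9)
  # zero effect leaves the no-treatment score unchanged
  p0 <- exact_pooled(c(usual_care = 0, psych_physical = 0, surgery = 0),
                     n_draws = 5L)
  expect_equal(apply_fuot(35.215, p0, c(TRUE, FALSE), 10),
               c(35.215, 35.215))
  # missing class is an error
  p_no <- exact_pooled(c(usual_care = 0, physical = -0.289), n_draws = 5L)
  expect_error(apply_fuot(35, p_no, FALSE, 10), class = "lbp_validation_error")
})

test_that("scenario_scores orders scenarios for beneficial effects", {
  cfg <- small_config(seed = 33L)
  r <- gen_respondents(cfg)
  r <- r[r$lbp == 1L, ]
  sc <- scenario_scores(r, lbp_class_smds(), cfg$sigma_sf12)
  expect_true(all(sc$sf12_notreatment <= sc$sf12_observed + 1e-12))
  expect_true(all(sc$sf12_fuot >= sc$sf12_notreatment))
  expect_equal(sc$smd_overall, r$true_smd_overall, tolerance = 1e-12)
})

test_that("scenario summaries recover the analytic truth with exact inputs", {
  cfg <- sim_config(seed = 37L, n_respondents = 60000L)
  r <- gen_respondents(cfg)
  pooled <- exact_pooled(n_draws = 20L)
  cw <- exact_crosswalk(n_draws = 20L)
  cm <- fit_condition_model(r, cw, n_draws = 20L, seed = 4L)
  s <- summarize_scenarios(r, pooled, cw, cm, sigma = cfg$sigma_sf12,
                           n_draws = 20L)
  truth <- sim_truth(cfg)$scenario_dw
  for (i in seq_len(nrow(truth))) {
    got <- s$summary$dw[s$summary$stratum == truth$stratum[i] &
                          s$summary$scenario == truth$scenario[i]]
    expect_lt(abs(got - truth$dw[i]), 0.003)
  }
  # per-draw scenario ordering: fuot <= observed <= no-treatment
  expect_true(all(s$draws[, "fuot", ] <= s$draws[, "observed", ] + 1e-9))
  expect_true(all(s$draws[, "observed", ] <= s$draws[, "no_treatment", ] + 1e-9))
})

test_that("zero coverage makes the observed and no-treatment scenarios identical", {
  cov0 <- lbp_class_coverage()
  cov0$leg_pain <- 0
  cov0$no_leg_pain <- 0
  cfg <- sim_config(seed = 41L, n_respondents = 3000L, coverage = cov0)
  r <- gen_respondents(cfg)
  pooled <- exact_pooled(n_draws = 10L)
  cw <- exact_crosswalk(n_draws = 10L)
  cm <- fit_condition_model(r, cw, n_draws = 10L, seed = 5L)
  s <- summarize_scenarios(r, pooled, cw, cm, sigma = cfg$sigma_sf12,
                           n_draws = 10L)
  expect_equal(s$draws[, "observed", ], s$draws[, "no_treatment", ],
               tolerance = 1e-12)
})

test_that("stratum means are invariant to uniform weight scaling", {
  cfg <- small_config(seed = 43L)
  r <- gen_respondents(cfg)
  pooled <- exact_pooled(n_draws = 5L)
  cw <- exact_crosswalk(n_draws = 5L)
  cm <- fit_condition_model(r, cw, n_draws = 5L, seed = 6L)
  s1 <- summarize_scenarios(r, pooled, cw, cm, sigma = 10, n_draws = 5L)
  r2 <- r
  r2$weight <- r2$weight * 2
  cm2 <- fit_condition_model(r2, cw, n_draws = 5L, seed = 6L)
  s2 <- summarize_scenarios(r2, pooled, cw, cm2, sigma = 10, n_draws = 5L)
  expect_equal(s1$draws, s2$draws, tolerance = 1e-9)
})

test_that("anchor combination weights strata by the leg-pain fraction", {
  cfg <- small_config(seed = 47L)
  r <- gen_respondents(cfg)
  pooled <- exact_pooled(n_draws = 5L)
  cw <- exact_crosswalk(n_draws = 5L)
  cm <- fit_condition_model(r, cw, n_draws = 5L, seed = 7L)
  s <- summarize_scenarios(r, pooled, cw, cm, sigma = 10, n_draws = 5L)
  a <- build_anchors(s, legpain_fraction = 0.3, haq_anchor = 83.6)
  expect_equal(a$dw_observed,
               0.7 * s$draws["no_leg_pain", "observed", ] +
                 0.3 * s$draws["leg_pain", "observed", ],
               tolerance = 1e-12)
  expect_equal(a$haq_anchor, 83.6)
})
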