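test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 7L)
  expect_identical(gen_trials(cfg), gen_trials(cfg))
  expect_identical(gen_respondents(cfg), gen_respondents(cfg))
  expect_identical(gen_crosswalk_pairs(cfg), gen_crosswalk_pairs(cfg))
  expect_identical(gen_haq_prevalence(cfg), gen_haq_prevalence(cfg))
})

test_that("noise-free trials with huge arms recover the true SMD", {
  cfg <- sim_config(seed = 3L, n_trials = 40L, between_trial_sd = 0,
                    trial_size_range = c(200000L, 200001L))
  tr <- gen_trials(cfg)
  eff <- compute_smd(tr)
  truth <- lbp_class_smds()[eff$class_a] - lbp_class_smds()[eff$class_b]
  expect_true(all(abs(eff$smd - truth) < 0.02))
})

test_that("respondent generation honours configured marginals", {
  cfg <- sim_config(seed = 11L, n_respondents = 100000L)
  r <- gen_respondents(cfg)
  lb <- r[r$lbp == 1L, ]

  # leg-pain fraction and treatment coverage within 3 binomial SEs
  f <- mean(lb$leg_pain)
  se_f <- sqrt(0.3 * 0.7 / nrow(lb))
  expect_lt(abs(f - 0.3), 3 * se_f)

  cov <- lbp_class_coverage()
  for (s in 0:1) {
    sub <- lb[lb$leg_pain == s, ]
    p_true <- if (s == 1) cov$leg_pain else cov$no_leg_pain
    for (k in seq_along(cov$class)) {
      p_hat <- weighted_mean(sub[[paste0("trt_", cov$class[k])]], sub$weight)
      se <- sqrt(max(p_true[k] * (1 - p_true[k]), 1e-6) / nrow(sub)) *
        sqrt(nrow(sub) / effective_n(sub$weight))
      expect_lt(abs(p_hat - p_true[k]), 3 * se + 1e-3)
    }
  }

  # survey weights positive, mean ~ 1
  expect_true(all(r$weight > 0))
  expect_lt(abs(mean(r$weight) - 1), 0.02)
})

test_that("treatment removal recovers the untreated score exactly", {
  cfg <- small_config(seed = 5L)
  r <- gen_respondents(cfg)
  nt <- remove_treatment(r$sf12, r$true_smd_overall, cfg$sigma_sf12)
  expect_equal(nt, r$true_sf12_untreated, tolerance = 1e-12)
})

test_that("degenerate coverage and leg-pain settings behave as stated", {
  cov0 <- lbp_class_coverage()
  cov0$leg_pain <- 0
  cov0$no_leg_pain <- 0
  cfg <- sim_config(seed = 2L, n_respondents = 2000L, coverage = cov0,
                    legpain_fraction = 1)
  r <- gen_respondents(cfg)
  expect_true(all(r[r$lbp == 1L, "leg_pain"] == 1L))
  expect_true(all(as.matrix(r[, grep("^trt_", names(r))]) == 0L))
  expect_true(all(r$true_smd_overall == 0))
})

test_that("crosswalk pairs follow the configured logit line", {
  cfg <- small_config()
  pairs <- gen_crosswalk_pairs(cfg, n_states = 62L, noise_sd = 0)
  expect_equal(pairs$dw, inv_logit(2 - 0.08 * pairs$sf12), tolerance = 1e-12)
  expect_true(all(pairs$dw > 0 & pairs$dw < 1))
  expect_error(gen_crosswalk_pairs(cfg, n_states = 1L),
               class = "lbp_config_error")
  expect_error(gen_crosswalk_pairs(cfg, noise_sd = -0.1),
               class = "lbp_config_error")
})

test_that("invalid configurations are rejected", {
  cov <- lbp_class_coverage()
  cov$leg_pain[1] <- 1.2
  expect_error(sim_config(coverage = cov), class = "lbp_config_error")
  cov2 <- lbp_class_coverage()
  cov2$class[1] <- "mystery_therapy"
  expect_error(sim_config(coverage = cov2), class = "lbp_config_error")
  expect_error(sim_config(sf12_sd = 0), class = "lbp_config_error")
  bad <- default_ctry <- sim_config()$countries
  bad$haq[1] <- 101
  expect_error(sim_config(countries = bad), class = "lbp_validation_error")
  expect_error(sim_config(countries = default_ctry[0, ]),
               class = "lbp_validation_error")
})

test_that("calibration makes the analytic observed DW equal the targets", {
  cfg <- small_config()
  tr <- sim_truth(cfg)
  obs <- tr$scenario_dw[tr$scenario_dw$scenario == "observed", ]
  expect_equal(obs$dw[obs$stratum == "no_leg_pain"], 0.103, tolerance = 1e-6)
  expect_equal(obs$dw[obs$stratum == "leg_pain"], 0.169, tolerance = 1e-6)
  # scenario ordering in the analytic truth
  wide <- reshape(tr$scenario_dw, idvar = "stratum", timevar = "scenario",
                  direction = "wide")
  expect_true(all(wide$dw.fuot < wide$dw.observed))
  expect_true(all(wide$dw.observed < wide$dw.no_treatment))
})

test_that("written inputs round-trip through the validated readers", {
  cfg <- sim_config(seed = 9L, n_trials = 20L, n_respondents = 500L)
  dir <- withr::local_tempdir()
  paths <- write_sim_inputs(cfg, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_input_table(paths[["trials"]], "trials")
  expect_equal(nrow(tr), 20L)
  r <- read_input_table(paths[["respondents"]], "respondents")
  r0 <- gen_respondents(cfg)
  expect_equal(r$sf12, r0$sf12, tolerance = 1e-12)
  expect_equal(names(r), names(r0))
})
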