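make_trial <- function(n_a = 50, n_b = 50, mean_a = 10, mean_b = 12,
                       sd_a = 4, sd_b = 4, class_a = "physical",
                       class_b = "usual_care", followup_months = 6,
                       trial_id = "T0001") {
  data.frame(trial_id = trial_id, review_id = "R01", class_a = class_a,
             class_b = class_b, n_a = n_a, n_b = n_b, mean_a = mean_a,
             mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
             followup_months = followup_months, scale_name = "RMDQ",
             stringsAsFactors = FALSE)
}

test_that("Hedges g matches the hand-computed worked example", {
  eff <- compute_smd(make_trial())
  # d = -0.5; J = 1 - 3/391 = 0.992327; g = J*d = -0.4961637;
  # var = 100/2500 + g^2/200; se = 0.2030539
  expect_equal(eff$smd, -0.5 * (1 - 3 / 391), tolerance = 1e-12)
  expect_equal(eff$smd, -0.49617, tolerance = 1e-4)
  g <- -0.5 * (1 - 3 / 391)
  expect_equal(eff$se, sqrt(100 / 2500 + g^2 / 200), tolerance = 1e-12)
  expect_equal(eff$se, 0.20306, tolerance = 1e-4)
})

test_that("SMD is zero for identical arms and antisymmetric in arm order", {
  same <- compute_smd(make_trial(mean_a = 10, mean_b = 10))
  expect_equal(same$smd, 0)
  fwd <- compute_smd(make_trial())
  rev <- compute_smd(make_trial(mean_a = 12, mean_b = 10, sd_a = 4, sd_b = 4,
                                class_a = "usual_care", class_b = "physical"))
  expect_equal(rev$smd, -fwd$smd, tolerance = 1e-12)
  expect_equal(rev$se, fwd$se, tolerance = 1e-12)
})

test_that("degenerate trial records are rejected", {
  expect_error(compute_smd(make_trial(sd_a = 0, sd_b = 0)),
               class = "lbp_validation_error")
  bad <- make_trial()
  bad$sd_a <- bad$sd_b <- 1
  bad$n_a <- 1
  expect_error(compute_smd(bad), class = "lbp_validation_error")
  bad2 <- make_trial(class_a = "physical", class_b = "physical")
  expect_error(compute_smd(bad2), class = "lbp_validation_error")
})

test_that("follow-up window is inclusive and class rule drops small classes", {
  trials <- rbind(
    make_trial(followup_months = 2.9, trial_id = "T0001"),
    make_trial(followup_months = 3.0, trial_id = "T0002"),
    make_trial(followup_months = 12.0, trial_id = "T0003"),
    make_trial(followup_months = 12.1, trial_id = "T0004"))
  kept <- filter_trials(trials, min_trials_per_class = 1L)
  expect_setequal(kept$trial_id, c("T0002", "T0003"))
  excl <- attr(kept, "exclusions")
  expect_setequal(excl$trial_id, c("T0001", "T0004"))
  expect_true(all(excl$reason == "followup_window"))

  # 9 trials of one class, 12 of another: the 9-trial class is excluded
  many <- do.call(rbind, c(
    lapply(1:9, function(i) make_trial(class_a = "surgery",
                                       trial_id = sprintf("S%02d", i))),
    lapply(1:12, function(i) make_trial(trial_id = sprintf("P%02d", i)))))
  kept2 <- filter_trials(many)
  expect_equal(attr(kept2, "excluded_classes"), "surgery")
  expect_true(all(grepl("^P", kept2$trial_id)))
  expect_true(all(attr(kept2, "exclusions")$reason == "class_min_trials"))

  # all eligible: identity
  all_ok <- do.call(rbind, lapply(1:12, function(i)
    make_trial(trial_id = sprintf("P%02d", i))))
  kept3 <- filter_trials(all_ok)
  expect_equal(nrow(kept3), 12L)
  expect_equal(nrow(attr(kept3, "exclusions")), 0L)
})

test_that("single-trial pooling with tau = 0 returns the trial SMD and FE SE", {
  eff <- compute_smd(make_trial())
  pooled <- pool_network(eff, n_draws = 10L, seed = 1L, tau = 0)
  expect_equal(unname(pooled$mean[["physical"]]), eff$smd, tolerance = 1e-12)
  expect_equal(unname(pooled$se[["physical"]]), eff$se, tolerance = 1e-12)
  expect_true(all(pooled$draws[, "usual_care"] == 0))
})

test_that("pooling flags disconnected networks and empty inputs", {
  eff <- compute_smd(rbind(
    make_trial(),
    make_trial(class_a = "education", class_b = "bed_rest", trial_id = "T0002")))
  expect_error(pool_network(eff), class = "lbp_disconnected_network")
  expect_error(pool_network(compute_smd(make_trial())[0, ]),
               class = "lbp_validation_error")
})

test_that("pooling is invariant to flipping a trial's arm order", {
  cfg <- small_config(seed = 21L)
  trials <- filter_trials(gen_trials(cfg), min_trials_per_class = 1L)
  eff <- compute_smd(trials)
  flip <- eff
  flip$smd[1:10] <- -flip$smd[1:10]
  tmp <- flip$class_a[1:10]
  flip$class_a[1:10] <- flip$class_b[1:10]
  flip$class_b[1:10] <- tmp
  p1 <- pool_network(eff, n_draws = 5L, seed = 1L)
  p2 <- pool_network(flip, n_draws = 5L, seed = 1L)
  expect_equal(p1$mean, p2$mean[names(p1$mean)], tolerance = 1e-10)
  expect_equal(p1$tau, p2$tau, tolerance = 1e-10)
})

test_that("network pooling recovers simulated truth with small bias", {
  cfg <- sim_config(seed = 31L, n_trials = 200L)
  truth <- lbp_class_smds()
  ests <- ses <- NULL
  for (s in 1:20) {
    cfg_s <- sim_config(seed = 1000L + s, n_trials = 200L)
    eff <- compute_smd(filter_trials(gen_trials(cfg_s)))
    p <- pool_network(eff, n_draws = 2L, seed = s)
    ests <- rbind(ests, p$mean[names(truth)])
    ses <- rbind(ses, p$se[names(truth)])
  }
  bias <- colMeans(ests) - truth
  expect_true(all(abs(bias[names(bias) != "usual_care"]) < 0.02 +
                    2 * colMeans(ses)[names(bias) != "usual_care"] / sqrt(20)))
})

test_that("coverage estimation matches configured probabilities and flags empty strata", {
  cfg <- sim_config(seed = 13L, n_respondents = 100000L)
  r <- gen_respondents(cfg)
  cov <- estimate_coverage(r, n_draws = 200L, seed = 1L)
  phys <- cov[cov$class == "physical" & cov$leg_pain == 1L, ]
  n_strat <- sum(r$lbp == 1L & r$leg_pain == 1L)
  se <- sqrt(0.306 * (1 - 0.306) / n_strat) * 1.2  # weight design effect
  expect_lt(abs(phys$coverage - 0.306), 3 * se)
  expect_true(phys$lower < phys$coverage & phys$coverage < phys$upper)

  # all respondents report one class -> proportion 1
  one <- data.frame(weight = rep(1, 50), lbp = 1L, leg_pain = 0L,
                    trt_physical = 1L)
  cov1 <- estimate_coverage(one, n_draws = 50L)
  expect_equal(cov1$coverage[cov1$leg_pain == 0L], 1)

  # empty stratum flagged, not zero
  expect_true(all(cov1$empty[cov1$leg_pain == 1L]))
  expect_true(all(is.na(cov1$coverage[cov1$leg_pain == 1L])))
})
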