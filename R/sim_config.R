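# Configuration of the synthetic world.
#
# The generator states a world whose parameters are the published point values:
# true class effects and coverage proportions from the intervention-class
# table, the logit-linear SF-12 crosswalk, observed low-back-pain disability
# weights of 0.103 (without leg pain) and 0.169 (with leg pain), and a
# country set spanning the published Health Access and Quality Index range.
# Everything downstream is then a recovery exercise against known truth.

#' Published intervention-class effect sizes used as simulation truth
#'
#' Point estimates of the pooled standardised mean difference (SMD) versus
#' usual care for the ten intervention classes; negative values mean less
#' functional disability. These are the default true effects of the
#' synthetic-trial generator, so that network meta-analysis recovery tests are
#' interpretable on the published scale.
#'
#' @return Named numeric vector of SMDs, reference class `usual_care = 0`.
#' @export
lbp_class_smds <- function() {
  c(usual_care          =  0,
    bed_rest            =  0.141,
    education           = -0.109,
    epidural_steroids   = -0.178,
    nonopioid_analgesics = -0.147,
    opioid_analgesics   = -0.209,
    physical            = -0.289,
    psych_physical      = -0.460,
    psychological       = -0.255,
    surgery             = -0.366)
}

#' Published treatment coverage proportions used as simulation truth
#'
#' Proportion of low back pain patients using each intervention class, by
#' leg-pain status. Classes that the survey did not capture (bed rest,
#' education) have coverage 0. Values below the survey's reporting threshold
#' ("<0.1%") are set to 0.001.
#'
#' @return data.frame with columns `class`, `leg_pain`, `no_leg_pain`.
#' @export
lbp_class_coverage <- function() {
  data.frame(
    class = c("bed_rest", "education", "epidural_steroids",
              "nonopioid_analgesics", "opioid_analgesics", "physical",
              "psych_physical", "psychological", "surgery"),
    leg_pain    = c(0, 0, 0.001, 0.332, 0.250, 0.306, 0.001, 0.010, 0.101),
    no_leg_pain = c(0, 0, 0.001, 0.307, 0.124, 0.206, 0.001, 0.003, 0.020),
    stringsAsFactors = FALSE
  )
}

default_countries <- function() {
  data.frame(
    country = c("Nordica", "Richland", "Anchorland", "Eastgate",
                "Midland", "Southvale", "Sahelia", "Centralia"),
    haq = c(97.0, 90.7, 83.6, 67.1, 55.6, 47.9, 31.8, 28.3),
    prevalence = c(3.2e4, 2.4e6, 3.6e6, 1.1e6, 5.3e6, 9.5e5, 2.1e6, 1.4e6),
    region = c("Nordic", "Oceania West", "Northern", "Eastern",
               "Central", "Southern", "Sahel", "Sahel"),
    super_region = c("High Income", "High Income", "High Income", "Transition",
                     "Transition", "Transition", "Low Income", "Low Income"),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic-data generator
#'
#' Builds a validated configuration object with known ground truth for every
#' pipeline input: trial arm summaries, survey respondents, crosswalk
#' calibration pairs, and country HAQ/prevalence tables.
#'
#' Respondents are generated directly in the observed (treated) state:
#' `SF12 = sf12_healthy - sum(condition decrements) - lbp decrement + noise`,
#' with decrements constant on the SF-12 scale so that the logit disability
#' weight is exactly linear in the condition indicators (the model the
#' attribution stage fits). The low back pain decrements are calibrated at
#' configuration time (by root finding over the enumerated comorbidity
#' distribution and a quadrature over the SF-12 noise) so that the population
#' mean *observed attributable* disability weight in each stratum equals
#' `lbp_dw` exactly; those targets default to the published 0.103 / 0.169.
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_trials Number of two-arm trials to simulate.
#' @param true_smd_by_class Named vector of true class SMDs versus the
#'   reference; default [lbp_class_smds()].
#' @param reference_class Name of the usual-care reference class.
#' @param trial_size_range Integer range for per-arm sample sizes.
#' @param between_trial_sd Between-trial heterogeneity SD of the true contrast
#'   (tau); default 0.1, a typical value for SMDs in this literature.
#' @param followup_window Eligible follow-up window in months (inclusive).
#' @param followup_in_window_prob Probability a simulated trial's follow-up
#'   falls inside the window.
#' @param prob_vs_reference Probability a trial compares a class directly
#'   against the reference (the rest compare two random classes), keeping the
#'   network connected.
#' @param scale_mean,scale_sd Mean and SD of the nominal symptom scale.
#' @param n_respondents Number of survey respondents.
#' @param lbp_fraction Fraction of respondents with low back pain.
#' @param legpain_fraction Fraction of low back pain respondents whose pain
#'   involves the leg; also used downstream to combine stratum anchors.
#' @param coverage Coverage proportions by class and leg-pain status;
#'   default [lbp_class_coverage()].
#' @param crosswalk_coeffs Named vector `c(intercept, slope)` of the true
#'   logit(DW) ~ SF-12 crosswalk.
#' @param sf12_healthy SF-12 score of a respondent with no recorded condition.
#' @param condition_dw_map Named vector: disability-weight increment each
#'   comorbid condition adds to an otherwise healthy respondent.
#' @param condition_prev Named vector of condition prevalences.
#' @param lbp_dw Target observed attributable disability weight for low back
#'   pain, `c(no_leg_pain, leg_pain)`.
#' @param sf12_sd Residual SD of the SF-12 score (measurement noise), in
#'   SF-12 points.
#' @param weight_sdlog SD (log scale) of the log-normal survey weights
#'   (mean 1).
#' @param surgery_eligible_fraction Fraction of leg-pain cases eligible for
#'   surgery under full optimal treatment (the complement of the published
#'   57.1% spontaneous disc regression).
#' @param haq_anchor HAQ index of the observed-treatment anchor setting.
#' @param countries data.frame with columns `country`, `haq`, `prevalence`,
#'   `region`, `super_region`.
#' @param year Calendar year attached to the HAQ table.
#' @return Object of class `lbp_sim_config` with derived fields:
#'   `delta_conditions` (SF-12 decrement per condition), `delta_lbp`
#'   (calibrated stratum decrements), and `sigma_sf12` (the analytic
#'   population SD of observed SF-12 among low back pain respondents, the
#'   quantity the pipeline estimates for equation-based treatment removal).
#' @export
sim_config <- function(seed = 1L,
                       n_trials = 200L,
                       true_smd_by_class = lbp_class_smds(),
                       reference_class = "usual_care",
                       trial_size_range = c(30L, 200L),
                       between_trial_sd = 0.1,
                       followup_window = c(3, 12),
                       followup_in_window_prob = 0.85,
                       prob_vs_reference = 0.7,
                       scale_mean = 50,
                       scale_sd = 10,
                       n_respondents = 20000L,
                       lbp_fraction = 0.25,
                       legpain_fraction = 0.30,
                       coverage = lbp_class_coverage(),
                       crosswalk_coeffs = c(intercept = 2, slope = -0.08),
                       sf12_healthy = 80,
                       condition_dw_map = c(arthritis = 0.05,
                                            depression = 0.145,
                                            diabetes = 0.03),
                       condition_prev = c(arthritis = 0.20,
                                          depression = 0.10,
                                          diabetes = 0.10),
                       lbp_dw = c(no_leg_pain = 0.103, leg_pain = 0.169),
                       sf12_sd = 3,
                       weight_sdlog = 0.5,
                       surgery_eligible_fraction = 0.429,
                       haq_anchor = 83.6,
                       countries = default_countries(),
                       year = 2020L) {
  cfg <- list(
    seed = as.integer(seed), n_trials = as.integer(n_trials),
    true_smd_by_class = true_smd_by_class, reference_class = reference_class,
    trial_size_range = trial_size_range, between_trial_sd = between_trial_sd,
    followup_window = followup_window,
    followup_in_window_prob = followup_in_window_prob,
    prob_vs_reference = prob_vs_reference,
    scale_mean = scale_mean, scale_sd = scale_sd,
    n_respondents = as.integer(n_respondents),
    lbp_fraction = lbp_fraction, legpain_fraction = legpain_fraction,
    coverage = coverage, crosswalk_coeffs = crosswalk_coeffs,
    sf12_healthy = sf12_healthy, condition_dw_map = condition_dw_map,
    condition_prev = condition_prev, lbp_dw = lbp_dw, sf12_sd = sf12_sd,
    weight_sdlog = weight_sdlog,
    surgery_eligible_fraction = surgery_eligible_fraction,
    haq_anchor = haq_anchor, countries = countries, year = as.integer(year)
  )
  validate_sim_config(cfg)

  a <- cfg$crosswalk_coeffs[["intercept"]]
  b <- cfg$crosswalk_coeffs[["slope"]]
  dw0 <- inv_logit(a + b * cfg$sf12_healthy)
  # SF-12 decrement that adds dw_c to the healthy disability weight
  cfg$delta_conditions <- vapply(cfg$condition_dw_map, function(dwc) {
    (logit(dw0 + dwc) - logit(dw0)) / (-b)
  }, numeric(1))
  cfg$delta_lbp <- c(
    no_leg_pain = calibrate_lbp_delta(cfg, cfg$lbp_dw[["no_leg_pain"]]),
    leg_pain    = calibrate_lbp_delta(cfg, cfg$lbp_dw[["leg_pain"]])
  )
  p <- cfg$condition_prev
  f <- cfg$legpain_fraction
  cfg$sigma_sf12 <- sqrt(
    sum(cfg$delta_conditions^2 * p * (1 - p)) +
      f * (1 - f) * diff(cfg$delta_lbp[c("no_leg_pain", "leg_pain")])^2 +
      cfg$sf12_sd^2
  )
  structure(cfg, class = "lbp_sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$lbp_fraction, cfg$legpain_fraction,
             cfg$followup_in_window_prob, cfg$prob_vs_reference,
             cfg$surgery_eligible_fraction,
             cfg$coverage$leg_pain, cfg$coverage$no_leg_pain,
             cfg$condition_prev)
  if (any(probs < 0 | probs > 1)) {
    lbp_config_error("all probabilities must lie in [0, 1]")
  }
  if (cfg$sf12_sd <= 0) lbp_config_error("sf12_sd must be > 0")
  if (cfg$between_trial_sd < 0) lbp_config_error("between_trial_sd must be >= 0")
  if (!cfg$reference_class %in% names(cfg$true_smd_by_class)) {
    lbp_config_error("reference_class missing from true_smd_by_class")
  }
  if (cfg$true_smd_by_class[[cfg$reference_class]] != 0) {
    lbp_config_error("reference class true SMD must be 0")
  }
  unknown <- setdiff(cfg$coverage$class, names(cfg$true_smd_by_class))
  if (length(unknown)) {
    lbp_config_error(paste0("coverage refers to unknown class(es): ",
                            paste(unknown, collapse = ", ")))
  }
  if (any(cfg$condition_dw_map <= 0 | cfg$condition_dw_map >= 1) ||
      any(cfg$lbp_dw <= 0 | cfg$lbp_dw >= 1)) {
    lbp_config_error("disability weights must lie strictly in (0, 1)")
  }
  if (!setequal(names(cfg$condition_prev), names(cfg$condition_dw_map))) {
    lbp_config_error("condition_prev and condition_dw_map must name the same conditions")
  }
  if (cfg$crosswalk_coeffs[["slope"]] >= 0) {
    lbp_config_error("crosswalk slope must be negative (higher SF-12 = better health)")
  }
  if (nrow(cfg$countries) < 1L) lbp_validation_error("country list must be non-empty")
  if (any(cfg$countries$haq < 0 | cfg$countries$haq > 100)) {
    lbp_validation_error("HAQ index values must lie in [0, 100]")
  }
  if (any(cfg$countries$prevalence <= 0)) {
    lbp_validation_error("prevalence must be positive")
  }
  if (cfg$n_trials < 1L) lbp_config_error("n_trials must be >= 1")
  if (cfg$n_respondents < 1L) lbp_config_error("n_respondents must be >= 1")
  invisible(TRUE)
}

# Enumerate the comorbidity distribution: probability and total SF-12
# decrement of each of the 2^K condition combinations.
comorbidity_combos <- function(cfg) {
  k <- length(cfg$delta_conditions)
  if (k == 0L) return(data.frame(prob = 1, decrement = 0))
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  p <- cfg$condition_prev[names(cfg$delta_conditions)]
  prob <- apply(grid, 1L, function(g) prod(ifelse(g == 1, p, 1 - p)))
  data.frame(prob = prob, decrement = as.numeric(grid %*% cfg$delta_conditions))
}

# Equal-probability quantile grid approximating the N(0, sf12_sd) noise.
noise_grid <- function(cfg, n = 200L) {
  stats::qnorm((seq_len(n) - 0.5) / n) * cfg$sf12_sd
}

# Population mean observed attributable DW in one stratum, as a function of
# the stratum's SF-12 decrement. Matches the estimand of the attribution
# stage: E[ DW_obs * (1 - DW_cf / DW_full) ] with DW_obs including the SF-12
# noise and the predictions excluding it.
mean_attributable <- function(cfg, delta_s) {
  a <- cfg$crosswalk_coeffs[["intercept"]]
  b <- cfg$crosswalk_coeffs[["slope"]]
  combos <- comorbidity_combos(cfg)
  eps <- noise_grid(cfg)
  l_cf <- a + b * (cfg$sf12_healthy - combos$decrement)
  l_full <- l_cf - b * delta_s
  # E over noise of the observed DW, per combo
  e_dw_obs <- vapply(l_full, function(l) mean(inv_logit(l + b * eps)), numeric(1))
  share <- 1 - inv_logit(l_cf) / inv_logit(l_full)
  sum(combos$prob * e_dw_obs * share)
}

calibrate_lbp_delta <- function(cfg, target) {
  stats::uniroot(function(d) mean_attributable(cfg, d) - target,
                 lower = 1e-6, upper = 500, tol = 1e-12)$root
}

#' @export
print.lbp_sim_config <- function(x, ...) {
  cat("<lbp_sim_config>\n")
  cat(sprintf("  seed %d | %d trials | %d respondents (%.0f%% LBP, %.0f%% leg pain)\n",
              x$seed, x$n_trials, x$n_respondents, 100 * x$lbp_fraction,
              100 * x$legpain_fraction))
  cat(sprintf("  crosswalk logit(DW) = %.3g + %.3g * SF12 | sigma_SF12 = %.3f\n",
              x$crosswalk_coeffs[["intercept"]], x$crosswalk_coeffs[["slope"]],
              x$sigma_sf12))
  cat(sprintf("  observed attributable DW targets: %.3f (no leg pain), %.3f (leg pain)\n",
              x$lbp_dw[["no_leg_pain"]], x$lbp_dw[["leg_pain"]]))
  cat(sprintf("  %d countries, HAQ %.1f-%.1f, anchor %.1f\n",
              nrow(x$countries), min(x$countries$haq), max(x$countries$haq),
              x$haq_anchor))
  invisible(x)
}
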