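# Generators for every pipeline input, with ground-truth columns and analytic
# expectations so downstream stages can be tested as recovery exercises.

#' Simulate trial arm summaries
#'
#' Generates two-arm trials comparing intervention classes on a nominal
#' symptom scale. The true contrast of a trial comparing classes a and b is
#' `smd_a - smd_b` plus N(0, between_trial_sd) heterogeneity; observed arm
#' means carry sampling error `sd / sqrt(n)` and observed SDs are drawn from
#' the scaled chi-square sampling distribution, so the computed standardised
#' mean differences have the textbook standard errors.
#'
#' @param config An [sim_config()] object.
#' @return data.frame with one row per trial: `trial_id`, `review_id`,
#'   `class_a`, `class_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `followup_months`, `scale_name`, plus the hidden truth column
#'   `true_contrast`.
#' @export
gen_trials <- function(config) {
  stopifnot(inherits(config, "lbp_sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_trials
  classes <- names(config$true_smd_by_class)
  ref <- config$reference_class
  others <- setdiff(classes, ref)

  vs_ref <- stats::runif(n) < config$prob_vs_reference
  class_a <- character(n)
  class_b <- character(n)
  class_a[vs_ref] <- sample(others, sum(vs_ref), replace = TRUE)
  class_b[vs_ref] <- ref
  for (i in which(!vs_ref)) {
    pair <- sample(classes, 2L)
    class_a[i] <- pair[1L]
    class_b[i] <- pair[2L]
  }

  truth <- config$true_smd_by_class[class_a] - config$true_smd_by_class[class_b] +
    stats::rnorm(n, 0, config$between_trial_sd)

  n_a <- sample(seq(config$trial_size_range[1L], config$trial_size_range[2L]),
                n, replace = TRUE)
  n_b <- sample(seq(config$trial_size_range[1L], config$trial_size_range[2L]),
                n, replace = TRUE)
  mu_b <- config$scale_mean
  mu_a <- mu_b + truth * config$scale_sd
  mean_a <- stats::rnorm(n, mu_a, config$scale_sd / sqrt(n_a))
  mean_b <- stats::rnorm(n, mu_b, config$scale_sd / sqrt(n_b))
  sd_a <- config$scale_sd * sqrt(stats::rchisq(n, n_a - 1) / (n_a - 1))
  sd_b <- config$scale_sd * sqrt(stats::rchisq(n, n_b - 1) / (n_b - 1))

  in_window <- stats::runif(n) < config$followup_in_window_prob
  fu <- numeric(n)
  fu[in_window] <- stats::runif(sum(in_window), config$followup_window[1L],
                                config$followup_window[2L])
  low <- stats::runif(n) < 0.5
  out <- !in_window
  fu[out & low] <- stats::runif(sum(out & low), 0.5,
                                config$followup_window[1L] - 1e-3)
  fu[out & !low] <- stats::runif(sum(out & !low),
                                 config$followup_window[2L] + 1e-3, 24)

  data.frame(
    trial_id = sprintf("T%04d", seq_len(n)),
    review_id = sprintf("R%02d", sample.int(36L, n, replace = TRUE)),
    class_a = class_a, class_b = class_b,
    n_a = n_a, n_b = n_b,
    mean_a = mean_a, mean_b = mean_b,
    sd_a = sd_a, sd_b = sd_b,
    followup_months = fu,
    scale_name = sample(c("RMDQ", "ODI"), n, replace = TRUE),
    true_contrast = as.numeric(truth),
    stringsAsFactors = FALSE
  )
}

#' Simulate survey respondents
#'
#' Respondents are generated in the observed (treated) state. The observed
#' SF-12 score is `sf12_healthy` minus constant decrements for each comorbid
#' condition and for low back pain (by leg-pain stratum) plus N(0, sf12_sd)
#' noise, so logit disability weight is exactly linear in the condition
#' indicators. Treatment indicators are drawn independently per class from the
#' configured coverage probabilities; the truth column `true_sf12_untreated`
#' is the observed score with the respondent's own combined treatment effect
#' added back on (the exact inverse of the treatment-removal equation), using
#' the analytic population SD `config$sigma_sf12`.
#'
#' @param config An [sim_config()] object.
#' @return data.frame with columns `id`, `weight`, `lbp`, `leg_pain`,
#'   `cond_*` indicators, `trt_*` indicators, `sf12`, and truth columns
#'   `true_smd_overall`, `true_sf12_untreated`, `true_dw_obs`,
#'   `true_attributable`.
#' @export
gen_respondents <- function(config) {
  stopifnot(inherits(config, "lbp_sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_respondents
  a <- config$crosswalk_coeffs[["intercept"]]
  b <- config$crosswalk_coeffs[["slope"]]

  weight <- stats::rlnorm(n, -0.5 * config$weight_sdlog^2, config$weight_sdlog)
  lbp <- stats::rbinom(n, 1L, config$lbp_fraction)
  leg_pain <- integer(n)
  leg_pain[lbp == 1L] <- stats::rbinom(sum(lbp), 1L, config$legpain_fraction)

  conds <- vapply(names(config$condition_prev), function(cn) {
    stats::rbinom(n, 1L, config$condition_prev[[cn]])
  }, integer(n))
  cond_dec <- as.numeric(conds %*% config$delta_conditions[colnames(conds)])

  cov <- config$coverage
  trt <- vapply(cov$class, function(cl) {
    p <- ifelse(leg_pain == 1L, cov$leg_pain[cov$class == cl],
                cov$no_leg_pain[cov$class == cl])
    as.integer(stats::rbinom(n, 1L, p) * lbp)
  }, integer(n))

  lbp_dec <- ifelse(lbp == 1L,
                    ifelse(leg_pain == 1L, config$delta_lbp[["leg_pain"]],
                           config$delta_lbp[["no_leg_pain"]]),
                    0)
  eps <- stats::rnorm(n, 0, config$sf12_sd)
  sf12 <- config$sf12_healthy - cond_dec - lbp_dec + eps

  smds <- config$true_smd_by_class[cov$class]
  true_smd_overall <- 1 - exp(as.numeric(trt %*% log1p(-smds)))
  true_sf12_untreated <- sf12 + config$sigma_sf12 * true_smd_overall

  l_cf <- a + b * (config$sf12_healthy - cond_dec)
  l_full <- l_cf - b * lbp_dec
  true_dw_obs <- inv_logit(a + b * sf12)
  true_attributable <- ifelse(
    lbp == 1L, true_dw_obs * (1 - inv_logit(l_cf) / inv_logit(l_full)), 0)

  out <- data.frame(id = seq_len(n), weight = weight, lbp = lbp,
                    leg_pain = leg_pain, stringsAsFactors = FALSE)
  out <- cbind(out, stats::setNames(as.data.frame(conds),
                                    paste0("cond_", colnames(conds))))
  out <- cbind(out, stats::setNames(as.data.frame(trt),
                                    paste0("trt_", colnames(trt))))
  out$sf12 <- sf12
  out$true_smd_overall <- true_smd_overall
  out$true_sf12_untreated <- true_sf12_untreated
  out$true_dw_obs <- true_dw_obs
  out$true_attributable <- true_attributable
  out
}

#' Simulate crosswalk calibration pairs
#'
#' Health states with disability weights generated from the true logit-linear
#' crosswalk: `logit(DW) = intercept + slope * SF12 + N(0, noise_sd)`. The
#' default of 62 states mirrors the size of the calibration sample available
#' for mapping SF-12 summary scores onto the disability-weight scale.
#'
#' @param config An [sim_config()] object.
#' @param n_states Number of calibration health states (>= 2).
#' @param noise_sd SD of the logit-scale noise (>= 0).
#' @return data.frame with columns `health_state`, `sf12`, `dw`.
#' @export
gen_crosswalk_pairs <- function(config, n_states = 62L, noise_sd = 0.3) {
  stopifnot(inherits(config, "lbp_sim_config"))
  if (n_states < 2L) lbp_config_error("n_states must be >= 2")
  if (noise_sd < 0) lbp_config_error("noise_sd must be >= 0")
  set.seed(config$seed + 3L)
  a <- config$crosswalk_coeffs[["intercept"]]
  b <- config$crosswalk_coeffs[["slope"]]
  sf12 <- seq(15, 90, length.out = n_states)
  dw <- inv_logit(a + b * sf12 + stats::rnorm(n_states, 0, noise_sd))
  data.frame(health_state = sprintf("HS%03d", seq_len(n_states)),
             sf12 = sf12, dw = dw, stringsAsFactors = FALSE)
}

#' Build the country HAQ and prevalence tables
#'
#' @param config An [sim_config()] object.
#' @return list with `haq` (`country`, `year`, `haq`) and `prevalence`
#'   (`country`, `prevalence`, `region`, `super_region`).
#' @export
gen_haq_prevalence <- function(config) {
  stopifnot(inherits(config, "lbp_sim_config"))
  ctry <- config$countries
  if (nrow(ctry) < 1L) lbp_validation_error("country list must be non-empty")
  if (any(ctry$haq < 0 | ctry$haq > 100)) {
    lbp_validation_error("HAQ index values must lie in [0, 100]")
  }
  list(
    haq = data.frame(country = ctry$country, year = config$year,
                     haq = ctry$haq, stringsAsFactors = FALSE),
    prevalence = ctry[, c("country", "prevalence", "region", "super_region")]
  )
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Emits the five delimited input tables (`trials.csv`, `respondents.csv`,
#' `crosswalk_pairs.csv`, `haq.csv`, `prevalence.csv`) plus the generator
#' configuration as JSON.
#'
#' @param config An [sim_config()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_sim_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hp <- gen_haq_prevalence(config)
  tabs <- list(trials = gen_trials(config),
               respondents = gen_respondents(config),
               crosswalk_pairs = gen_crosswalk_pairs(config),
               haq = hp$haq, prevalence = hp$prevalence)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(tabs[[nm]], p)
    p
  }, character(1))
  cfg_path <- file.path(dir, "sim_config.json")
  keep <- !vapply(unclass(config), is.data.frame, logical(1))
  cfg <- unclass(config)[keep]
  cfg$countries <- config$countries
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, config = cfg_path))
}

#' Analytic ground truth of the synthetic world
#'
#' Computes, by exact enumeration over comorbidity and treatment combinations
#' and quadrature over the SF-12 noise, the population values that the
#' pipeline estimates: the stratum mean attributable disability weight under
#' the observed, no-treatment, and full-use-of-optimal-treatment scenarios,
#' the mean combined SMD per stratum, the combined (leg-pain-weighted)
#' anchors, and the implied true country disability weights and burden shares.
#'
#' @param config An [sim_config()] object.
#' @param optimal_class,surgery_class Class labels used by the optimal
#'   treatment scenario.
#' @return list with elements `scenario_dw` (data.frame stratum x scenario),
#'   `mean_smd_overall` (per stratum), `anchors` (combined dw_observed,
#'   dw_notreatment, dw_fuot), `country_dw`, and `global_shares` (averted,
#'   avoidable_brc, avoidable_fuot, unavoidable, as % of untreated burden).
#' @export
sim_truth <- function(config, optimal_class = "psych_physical",
                      surgery_class = "surgery") {
  a <- config$crosswalk_coeffs[["intercept"]]
  b <- config$crosswalk_coeffs[["slope"]]
  sig <- config$sigma_sf12
  combos <- comorbidity_combos(config)
  eps <- noise_grid(config)
  smds <- config$true_smd_by_class[config$coverage$class]
  smd_opt <- config$true_smd_by_class[[optimal_class]]
  smd_surg <- config$true_smd_by_class[[surgery_class]]
  elig <- config$surgery_eligible_fraction

  strat <- function(stratum) {
    delta_s <- config$delta_lbp[[stratum]]
    covp <- if (stratum == "leg_pain") config$coverage$leg_pain else
      config$coverage$no_leg_pain
    # enumerate treatment combinations among classes with non-zero coverage
    use <- which(covp > 0)
    tgrid <- if (length(use)) as.matrix(expand.grid(rep(list(0:1), length(use))))
    else matrix(0, 1, 0)
    tprob <- apply(tgrid, 1L, function(g) {
      prod(ifelse(g == 1, covp[use], 1 - covp[use]))
    })
    smd_ov <- 1 - exp(as.numeric(tgrid %*% log1p(-smds[use])))

    l_cf <- a + b * (config$sf12_healthy - combos$decrement)
    l_full <- l_cf - b * delta_s
    share <- 1 - inv_logit(l_cf) / inv_logit(l_full)

    # E over noise of expit(l + b*sigma*shift + b*eps) for every combo pair
    e_dw <- function(shift) {
      m <- outer(l_full, b * sig * shift, `+`)          # combos x tcombos
      em <- matrix(0, nrow(m), ncol(m))
      for (j in seq_len(ncol(m))) {
        em[, j] <- vapply(m[, j], function(l) mean(inv_logit(l + b * eps)),
                          numeric(1))
      }
      em
    }
    w2 <- outer(combos$prob, tprob)
    dw_obs_mat <- e_dw(rep(0, length(smd_ov)))
    attr_obs <- sum(w2 * dw_obs_mat * share)
    dw_nt_mat <- e_dw(smd_ov)                            # untreated: + smd*sigma
    attr_nt <- sum(w2 * (dw_nt_mat - dw_obs_mat * (1 - share)))
    fuot_shift <- function(s_fuot) {
      dw_f <- e_dw(smd_ov - s_fuot)                      # nt score minus fuot effect
      sum(w2 * (dw_f - dw_obs_mat * (1 - share)))
    }
    attr_fuot <- if (stratum == "leg_pain") {
      elig * fuot_shift(smd_surg) + (1 - elig) * fuot_shift(smd_opt)
    } else fuot_shift(smd_opt)
    list(observed = attr_obs, no_treatment = attr_nt, fuot = attr_fuot,
         mean_smd = sum(tprob * smd_ov))
  }

  s_nl <- strat("no_leg_pain")
  s_l <- strat("leg_pain")
  f <- config$legpain_fraction
  comb <- function(field) (1 - f) * s_nl[[field]] + f * s_l[[field]]
  anchors <- c(dw_observed = comb("observed"),
               dw_notreatment = comb("no_treatment"),
               dw_fuot = comb("fuot"))

  haq <- config$countries$haq
  dw_ctry <- pmax(anchors[["dw_notreatment"]] +
                    (anchors[["dw_observed"]] - anchors[["dw_notreatment"]]) *
                    haq / config$haq_anchor,
                  anchors[["dw_fuot"]])
  prev <- config$countries$prevalence
  yld_cur <- prev * dw_ctry
  yld_nt <- prev * anchors[["dw_notreatment"]]
  yld_brc <- prev * dw_ctry[which.max(haq)]
  yld_fuot <- prev * anchors[["dw_fuot"]]
  tot_nt <- sum(yld_nt)
  shares <- 100 * c(averted = sum(yld_nt - yld_cur),
                    avoidable_brc = sum(yld_cur - yld_brc),
                    avoidable_fuot = sum(yld_brc - yld_fuot),
                    unavoidable = sum(yld_fuot)) / tot_nt

  list(
    scenario_dw = data.frame(
      stratum = rep(c("no_leg_pain", "leg_pain"), each = 3L),
      scenario = rep(c("observed", "no_treatment", "fuot"), 2L),
      dw = c(s_nl$observed, s_nl$no_treatment, s_nl$fuot,
             s_l$observed, s_l$no_treatment, s_l$fuot),
      stringsAsFactors = FALSE),
    mean_smd_overall = c(no_leg_pain = s_nl$mean_smd, leg_pain = s_l$mean_smd),
    anchors = anchors,
    country_dw = data.frame(country = config$countries$country, haq = haq,
                            dw = dw_ctry, stringsAsFactors = FALSE),
    global_shares = shares
  )
}
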