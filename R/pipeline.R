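# End-to-end pipeline orchestration: read validated inputs, run every stage,
# and write the report bundle with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param input_dir Directory holding the five input tables (`trials.csv`,
#'   `respondents.csv`, `crosswalk_pairs.csv`, `haq.csv`, `prevalence.csv`),
#'   e.g. as written by [write_sim_inputs()]. Individual paths can be
#'   overridden through `paths`.
#' @param out_dir Directory for the report bundle.
#' @param paths Optional named list overriding individual table paths.
#' @param reference_class Usual-care reference class.
#' @param n_draws Number of uncertainty draws (>= 2, default 1000).
#' @param seed Integer seed controlling every stochastic stage.
#' @param legpain_fraction Leg-pain fraction used to combine stratum anchors.
#' @param haq_anchor HAQ index of the observed-treatment anchor setting.
#' @param gbd_dw Treatment-invariant reference disability weight for the
#'   gradient report.
#' @param followup_window Trial follow-up window in months.
#' @param min_trials_per_class Minimum retained trials per class.
#' @param optimal_class,surgery_class,surgery_eligible_fraction Optimal
#'   treatment settings (see [apply_fuot()]).
#' @return Object of class `lbp_pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir = NULL, paths = list(),
                            reference_class = "usual_care",
                            n_draws = 1000L, seed = 1L,
                            legpain_fraction = 0.30, haq_anchor = 83.6,
                            gbd_dw = 0.096, followup_window = c(3, 12),
                            min_trials_per_class = 10L,
                            optimal_class = "psych_physical",
                            surgery_class = "surgery",
                            surgery_eligible_fraction = 0.429) {
  if (n_draws < 2L) lbp_validation_error("n_draws must be >= 2")
  if (is.null(seed)) lbp_validation_error("seed must be set")
  tabs <- c("trials", "respondents", "crosswalk_pairs", "haq", "prevalence")
  p <- stats::setNames(file.path(input_dir, paste0(tabs, ".csv")), tabs)
  for (nm in names(paths)) p[[nm]] <- paths[[nm]]
  missing <- p[!file.exists(p)]
  if (length(missing)) {
    lbp_validation_error(paste0("input table(s) not found: ",
                                paste(missing, collapse = ", ")))
  }
  structure(list(paths = as.list(p), out_dir = out_dir,
                 reference_class = reference_class,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 legpain_fraction = legpain_fraction, haq_anchor = haq_anchor,
                 gbd_dw = gbd_dw, followup_window = followup_window,
                 min_trials_per_class = as.integer(min_trials_per_class),
                 optimal_class = optimal_class, surgery_class = surgery_class,
                 surgery_eligible_fraction = surgery_eligible_fraction),
            class = "lbp_pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Executes effects pooling, crosswalk and attribution, counterfactual
#' scenarios, and the gradient/burden decomposition, writing (if `out_dir` is
#' set) the intervention-class report, pooled-effect draws, crosswalk
#' coefficients, scenario summary, gradient report, burden shares, and a run
#' manifest. Deterministic for a fixed configuration and seed.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list with all fitted objects and reports: `effects`,
#'   `pooled`, `coverage`, `crosswalk`, `condition_model`, `scenarios`,
#'   `anchors`, `country_dw`, `burden`, `table1`, `table2`, `shares`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lbp_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, lbp_error = function(e) {
      lbp_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                class = class(e)[1L])
    })
  }

  trials <- stage("read", read_input_table(config$paths$trials, "trials"))
  respondents <- stage("read",
                       read_input_table(config$paths$respondents, "respondents"))
  pairs <- stage("read",
                 read_input_table(config$paths$crosswalk_pairs, "crosswalk_pairs"))
  haq <- stage("read", read_input_table(config$paths$haq, "haq"))
  prevalence <- stage("read",
                      read_input_table(config$paths$prevalence, "prevalence"))

  kept <- stage("effects", filter_trials(
    trials, followup_window = config$followup_window,
    min_trials_per_class = config$min_trials_per_class,
    reference = config$reference_class))
  effects <- stage("effects", compute_smd(kept))
  pooled <- stage("effects", pool_network(
    effects, reference = config$reference_class, n_draws = config$n_draws,
    seed = config$seed + 11L,
    excluded_classes = attr(kept, "excluded_classes")))
  coverage <- stage("effects", estimate_coverage(
    respondents, classes = setdiff(pooled$included_classes,
                                   config$reference_class),
    n_draws = config$n_draws, seed = config$seed + 12L))

  crosswalk <- stage("crosswalk", fit_crosswalk(
    pairs, n_draws = config$n_draws, seed = config$seed + 13L))
  condition_model <- stage("crosswalk", fit_condition_model(
    respondents, crosswalk, n_draws = config$n_draws,
    seed = config$seed + 14L))

  scenarios <- stage("counterfactual", summarize_scenarios(
    respondents, pooled, crosswalk, condition_model,
    n_draws = config$n_draws, optimal_class = config$optimal_class,
    surgery_class = config$surgery_class,
    surgery_eligible_fraction = config$surgery_eligible_fraction))
  anchors <- stage("counterfactual", build_anchors(
    scenarios, legpain_fraction = config$legpain_fraction,
    haq_anchor = config$haq_anchor))

  country_dw <- stage("burden", build_country_year_dw(anchors, haq))
  burden <- stage("burden", compute_burden(country_dw, prevalence, anchors))
  burden_all <- if ("region" %in% names(prevalence)) {
    stage("burden", aggregate_burden(burden))
  } else burden

  table1 <- build_table1(pooled, coverage)
  table2 <- table2_report(country_dw, gbd_dw = config$gbd_dw)
  shares <- shares_report(burden_all)

  manifest <- list(
    package = "lbpburden",
    version = as.character(utils::packageVersion("lbpburden")),
    seed = config$seed, n_draws = config$n_draws,
    legpain_fraction = config$legpain_fraction,
    haq_anchor = config$haq_anchor,
    sigma_sf12 = scenarios$sigma,
    excluded_classes = pooled$excluded_classes,
    tau = pooled$tau,
    config_hash = config_hash(jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")], auto_unbox = TRUE)),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  result <- list(effects = effects, pooled = pooled, coverage = coverage,
                 crosswalk = crosswalk, condition_model = condition_model,
                 scenarios = scenarios, anchors = anchors,
                 country_dw = country_dw, burden = burden_all,
                 table1 = table1, table2 = table2, shares = shares,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    write_output_table(table1, file.path(od, "table1_effects_coverage.csv"))
    dr <- as.data.frame(pooled$draws)
    dr$draw <- seq_len(nrow(dr))
    write_output_table(dr, file.path(od, "pooled_draws.csv"))
    write_output_table(
      data.frame(draw = seq_len(nrow(crosswalk$draws)),
                 intercept = crosswalk$draws[, "intercept"],
                 slope = crosswalk$draws[, "slope"]),
      file.path(od, "crosswalk_draws.csv"))
    write_output_table(scenarios$summary, file.path(od, "scenario_summary.csv"))
    write_output_table(table2, file.path(od, "table2_gradient.csv"))
    write_output_table(shares, file.path(od, "burden_shares.csv"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

# Intervention-class report: pooled SMD with UI plus coverage by stratum.
build_table1 <- function(pooled, coverage) {
  classes <- names(pooled$mean)
  rows <- lapply(classes, function(cl) {
    u <- ui(pooled$draws[, cl], n_draws = pooled$n_draws)
    cov_l <- coverage[coverage$class == cl & coverage$leg_pain == 1L, ]
    cov_n <- coverage[coverage$class == cl & coverage$leg_pain == 0L, ]
    pick <- function(df, col) if (nrow(df)) df[[col]][1L] else NA_real_
    data.frame(class = cl,
               smd = u[["mean"]], smd_lower = u[["lower"]],
               smd_upper = u[["upper"]],
               coverage_leg_pain = pick(cov_l, "coverage"),
               coverage_leg_pain_lower = pick(cov_l, "lower"),
               coverage_leg_pain_upper = pick(cov_l, "upper"),
               coverage_no_leg_pain = pick(cov_n, "coverage"),
               coverage_no_leg_pain_lower = pick(cov_n, "lower"),
               coverage_no_leg_pain_upper = pick(cov_n, "upper"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
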