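# Respondent-level counterfactual severity: treatment removal, full use of
# optimal treatment, and scenario summaries.

#' Combine class effect sizes multiplicatively
#'
#' `SMD_overall = 1 - prod(1 - SMD_i)` over the classes a respondent reports;
#' the empty product gives 0 (untreated). The formula is sign-agnostic, so a
#' harmful class (positive SMD, e.g. bed rest) is handled symmetrically.
#'
#' @param class_smds Numeric vector of class SMDs (possibly empty).
#' @return Single combined SMD.
#' @export
combine_smd <- function(class_smds) {
  stopifnot(is.numeric(class_smds))
  1 - prod(1 - class_smds)
}

#' Remove reported treatment effects from an SF-12 score
#'
#' `SF12_notreatment = SF12 + SMD_overall * sigma`: beneficial treatments have
#' negative combined SMDs, so removal lowers the score (worse health).
#'
#' @param sf12 Observed SF-12 score(s).
#' @param smd_overall Combined SMD(s) from [combine_smd()].
#' @param sigma SF-12 standard deviation used to scale effect sizes (> 0).
#' @return No-treatment SF-12 score(s).
#' @export
remove_treatment <- function(sf12, smd_overall, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    lbp_validation_error("sigma must be a single positive number")
  }
  sf12 + smd_overall * sigma
}

#' Full-use-of-optimal-treatment SF-12 score
#'
#' Applies the optimal class effect to the no-treatment score:
#' `SF12_FUOT = SF12_notreatment - SMD_FUOT * sigma`. Respondents without leg
#' pain receive the combined psychological and physical intervention class.
#' For leg-pain respondents a fixed eligible fraction (default 42.9%, the
#' complement of the 57.1% spontaneous disc regression) receives the surgery
#' effect and the remainder the optimal class; the fraction is applied as a
#' population weight on the returned score, not sampled per individual.
#'
#' @param sf12_notreatment No-treatment SF-12 score(s).
#' @param pooled An [pool_network()] object (must contain the optimal class,
#'   and the surgery class if any `leg_pain` is TRUE).
#' @param leg_pain Logical/0-1 vector (recycled) of leg-pain status.
#' @param sigma SF-12 standard deviation (> 0).
#' @param draw Optional draw index into the pooled draws; `NULL` uses means.
#' @param optimal_class,surgery_class Class labels.
#' @param surgery_eligible_fraction Eligible fraction among leg-pain cases.
#' @return FUOT SF-12 score(s).
#' @export
apply_fuot <- function(sf12_notreatment, pooled, leg_pain, sigma, draw = NULL,
                       optimal_class = "psych_physical",
                       surgery_class = "surgery",
                       surgery_eligible_fraction = 0.429) {
  if (sigma <= 0) lbp_validation_error("sigma must be positive")
  n <- max(length(sf12_notreatment), length(leg_pain))
  sf12_notreatment <- rep_len(sf12_notreatment, n)
  leg_pain <- rep_len(as.logical(leg_pain), n)
  smd <- pooled_class_smds(pooled, draw)
  if (!optimal_class %in% names(smd)) {
    lbp_validation_error(paste0("pooled effects lack the optimal class '",
                                optimal_class, "'"))
  }
  out <- sf12_notreatment - smd[[optimal_class]] * sigma
  if (any(leg_pain)) {
    if (!surgery_class %in% names(smd)) {
      lbp_validation_error(paste0("pooled effects lack the surgery class '",
                                  surgery_class, "'"))
    }
    surg <- sf12_notreatment - smd[[surgery_class]] * sigma
    out[leg_pain] <- surgery_eligible_fraction * surg[leg_pain] +
      (1 - surgery_eligible_fraction) * out[leg_pain]
  }
  out
}

pooled_class_smds <- function(pooled, draw = NULL) {
  stopifnot(inherits(pooled, "lbp_pooled_effects"))
  if (is.null(draw)) return(pooled$mean)
  if (draw < 1L || draw > pooled$n_draws) {
    lbp_validation_error("draw index out of range")
  }
  pooled$draws[draw, ]
}

#' Per-respondent counterfactual scores (point version)
#'
#' Convenience wrapper building, for each low back pain respondent, the
#' combined SMD of the treatments reported, the no-treatment score, and the
#' FUOT score from a named vector of class SMDs.
#'
#' @param respondents Respondent table with `sf12`, `leg_pain` and `trt_*`
#'   columns.
#' @param class_smds Named vector of class SMDs; classes without a pooled
#'   effect (excluded upstream) contribute 0.
#' @param sigma SF-12 standard deviation (> 0).
#' @param optimal_class,surgery_class,surgery_eligible_fraction As in
#'   [apply_fuot()].
#' @return data.frame with `sf12_observed`, `smd_overall`, `sf12_notreatment`,
#'   `sf12_fuot`, `surgery_eligible`.
#' @export
scenario_scores <- function(respondents, class_smds, sigma,
                            optimal_class = "psych_physical",
                            surgery_class = "surgery",
                            surgery_eligible_fraction = 0.429) {
  smd_overall <- respondent_smd_overall(respondents, class_smds)
  nt <- remove_treatment(respondents$sf12, smd_overall, sigma)
  leg <- respondents$leg_pain == 1L
  opt <- nt - class_smds[[optimal_class]] * sigma
  fuot <- opt
  if (any(leg)) {
    surg <- nt - class_smds[[surgery_class]] * sigma
    fuot[leg] <- surgery_eligible_fraction * surg[leg] +
      (1 - surgery_eligible_fraction) * opt[leg]
  }
  data.frame(sf12_observed = respondents$sf12, smd_overall = smd_overall,
             sf12_notreatment = nt, sf12_fuot = fuot,
             surgery_eligible = leg)
}

# Vectorised multiplicative combination over the trt_* indicator columns.
respondent_smd_overall <- function(respondents, class_smds) {
  trt_cols <- grep("^trt_", names(respondents), value = TRUE)
  if (!length(trt_cols)) return(rep(0, nrow(respondents)))
  cls <- sub("^trt_", "", trt_cols)
  smd <- ifelse(cls %in% names(class_smds), class_smds[cls], 0)
  tmat <- as.matrix(respondents[, trt_cols, drop = FALSE])
  1 - exp(drop(tmat %*% log1p(-smd)))
}

#' Scenario mean attributable disability weights with draws
#'
#' For every draw, maps each low back pain respondent's observed,
#' no-treatment, and FUOT SF-12 scores through that draw's crosswalk
#' coefficients, removes the comorbidity share implied by that draw's
#' condition model, and returns survey-weighted stratum means. The comorbidity
#' component `DW_observed * DW_cf / DW_full` is held fixed across scenarios:
#' the scenarios move the low back pain severity, not the comorbid burden.
#' The surgery-eligible fraction enters as a population weight on the two
#' FUOT disability weights for the leg-pain stratum.
#'
#' @param respondents Respondent table.
#' @param pooled An [pool_network()] object.
#' @param crosswalk An [fit_crosswalk()] object.
#' @param condition_model An [fit_condition_model()] object.
#' @param sigma SF-12 SD used to scale effect sizes; default: survey-weighted
#'   SD of observed SF-12 among low back pain respondents.
#' @param n_draws Number of draws (default: the pooled draw count; the
#'   crosswalk and condition model must have at least as many).
#' @param optimal_class,surgery_class,surgery_eligible_fraction As in
#'   [apply_fuot()].
#' @return Object of class `lbp_scenario_summary`: data.frame `summary`
#'   (stratum x scenario with mean DW and 95% UI), `draws` (stratum x
#'   scenario x draw array), `mean_smd_overall` (per stratum, per draw),
#'   `sigma`, `empty_strata`.
#' @export
summarize_scenarios <- function(respondents, pooled, crosswalk,
                                condition_model, sigma = NULL,
                                n_draws = pooled$n_draws,
                                optimal_class = "psych_physical",
                                surgery_class = "surgery",
                                surgery_eligible_fraction = 0.429) {
  r <- respondents[respondents$lbp == 1L, , drop = FALSE]
  if (!nrow(r)) lbp_validation_error("no low back pain respondents")
  need <- optimal_class
  if (any(r$leg_pain == 1L)) need <- c(need, surgery_class)
  lack <- setdiff(need, colnames(pooled$draws))
  if (length(lack)) {
    lbp_validation_error(paste0(
      "pooled effects lack required class(es) for the optimal scenario: ",
      paste(lack, collapse = ", "),
      " (excluded upstream or never trialled)"))
  }
  if (is.null(sigma)) sigma <- weighted_sd(r$sf12, r$weight)
  if (n_draws > pooled$n_draws || n_draws > nrow(crosswalk$draws) ||
      n_draws > condition_model$n_draws) {
    lbp_validation_error("n_draws exceeds the draws available in a fitted input")
  }

  strata <- c(no_leg_pain = 0L, leg_pain = 1L)
  scen <- c("observed", "no_treatment", "fuot")
  empty <- vapply(strata, function(s) !any(r$leg_pain == s), logical(1))

  x <- condition_design(r)
  x_cf <- x
  x_cf[, condition_model$lbp_terms] <- 0
  trt_cols <- grep("^trt_", names(r), value = TRUE)
  cls <- sub("^trt_", "", trt_cols)
  tmat <- as.matrix(r[, trt_cols, drop = FALSE])
  leg <- r$leg_pain == 1L
  w <- r$weight

  dr <- array(NA_real_, dim = c(2L, 3L, n_draws),
              dimnames = list(names(strata), scen, NULL))
  smd_dr <- matrix(NA_real_, 2L, n_draws,
                   dimnames = list(names(strata), NULL))
  all_smd <- pooled$draws
  for (d in seq_len(n_draws)) {
    smd_d <- stats::setNames(rep(0, length(cls)), cls)
    hit <- cls %in% colnames(all_smd)
    smd_d[cls[hit]] <- all_smd[d, cls[hit]]
    smd_ov <- 1 - exp(drop(tmat %*% log1p(-smd_d)))
    sf_nt <- r$sf12 + smd_ov * sigma

    cw <- crosswalk$draws[d, ]
    dwf <- function(sf) inv_logit(cw[1L] + cw[2L] * sf)
    beta <- condition_model$draws[d, ]
    ratio <- inv_logit(beta[1L] + drop(x_cf %*% beta[-1L])) /
      inv_logit(beta[1L] + drop(x %*% beta[-1L]))
    dw_obs <- dwf(r$sf12)
    como <- dw_obs * ratio

    attr_obs <- dw_obs - como
    attr_nt <- dwf(sf_nt) - como
    dw_opt <- dwf(sf_nt - all_smd[d, optimal_class] * sigma)
    attr_fuot <- dw_opt - como
    if (any(leg)) {
      dw_surg <- dwf(sf_nt - all_smd[d, surgery_class] * sigma)
      attr_fuot[leg] <- surgery_eligible_fraction * (dw_surg[leg] - como[leg]) +
        (1 - surgery_eligible_fraction) * (dw_opt[leg] - como[leg])
    }
    for (s in names(strata)) {
      if (empty[[s]]) next
      i <- r$leg_pain == strata[[s]]
      dr[s, "observed", d] <- weighted_mean(attr_obs[i], w[i])
      dr[s, "no_treatment", d] <- weighted_mean(attr_nt[i], w[i])
      dr[s, "fuot", d] <- weighted_mean(attr_fuot[i], w[i])
      smd_dr[s, d] <- weighted_mean(smd_ov[i], w[i])
    }
  }

  summ <- do.call(rbind, lapply(names(strata), function(s) {
    do.call(rbind, lapply(scen, function(sc) {
      if (empty[[s]]) {
        data.frame(stratum = s, scenario = sc, dw = NA_real_,
                   lower = NA_real_, upper = NA_real_, stringsAsFactors = FALSE)
      } else {
        u <- ui(dr[s, sc, ], n_draws = n_draws)
        data.frame(stratum = s, scenario = sc, dw = u[["mean"]],
                   lower = u[["lower"]], upper = u[["upper"]],
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  structure(list(summary = summ, draws = dr, mean_smd_overall = smd_dr,
                 sigma = sigma, empty_strata = names(strata)[empty],
                 n_draws = as.integer(n_draws)),
            class = "lbp_scenario_summary")
}

#' @export
print.lbp_scenario_summary <- function(x, ...) {
  cat(sprintf("<lbp_scenario_summary> sigma_SF12 = %.3f, %d draws\n",
              x$sigma, x$n_draws))
  s <- x$summary
  s$dw <- round(s$dw, 4); s$lower <- round(s$lower, 4); s$upper <- round(s$upper, 4)
  print(s, row.names = FALSE)
  if (length(x$empty_strata)) {
    cat("empty strata:", paste(x$empty_strata, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Combine stratum scenario draws into severity anchors
#'
#' Weighted combination of the leg-pain and no-leg-pain scenario means using a
#' leg-pain prevalence fraction, producing the anchors of the
#' access-quality gradient: the no-treatment disability weight (applies at
#' HAQ 0), the observed disability weight (applies at the anchor HAQ), and
#' the FUOT disability weight (the floor).
#'
#' @param scenarios An [summarize_scenarios()] object.
#' @param legpain_fraction Fraction of low back pain cases with leg pain.
#' @param haq_anchor HAQ index of the observed-treatment setting.
#' @return An [severity_anchors()] object.
#' @export
build_anchors <- function(scenarios, legpain_fraction, haq_anchor) {
  stopifnot(inherits(scenarios, "lbp_scenario_summary"))
  if (length(scenarios$empty_strata)) {
    lbp_validation_error(paste0("cannot combine anchors: empty stratum ",
                                paste(scenarios$empty_strata, collapse = ", ")))
  }
  f <- legpain_fraction
  comb <- function(sc) {
    (1 - f) * scenarios$draws["no_leg_pain", sc, ] +
      f * scenarios$draws["leg_pain", sc, ]
  }
  severity_anchors(dw_notreatment = comb("no_treatment"),
                   dw_observed = comb("observed"),
                   dw_fuot = comb("fuot"),
                   haq_anchor = haq_anchor,
                   legpain_fraction = f)
}
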