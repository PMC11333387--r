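# SF-12 to disability-weight crosswalk and comorbidity-corrected attribution
# of disability to low back pain.

#' Fit the SF-12 to disability-weight crosswalk
#'
#' Linear regression of logit disability weight on the SF-12 summary score,
#' with coefficient uncertainty propagated as parametric draws from the
#' multivariate normal sampling distribution. Calibration states at the
#' boundaries of (0, 1) must be pre-clamped with [clamp_dw()].
#'
#' @param pairs data.frame with columns `dw` (strictly in (0,1)) and `sf12`.
#' @param n_draws Number of coefficient draws (default 1000).
#' @param seed Optional seed for the draws.
#' @return Object of class `lbp_crosswalk_fit`: `intercept`, `slope`,
#'   `residual_sd`, `draws` (n_draws x 2), `n`.
#' @export
fit_crosswalk <- function(pairs, n_draws = 1000L, seed = NULL) {
  if (!all(c("dw", "sf12") %in% names(pairs))) {
    lbp_validation_error("crosswalk pairs need 'dw' and 'sf12' columns")
  }
  if (any(pairs$dw <= 0 | pairs$dw >= 1)) {
    lbp_validation_error(
      "disability weights must lie strictly in (0, 1); pre-clamp with clamp_dw()")
  }
  if (length(unique(pairs$sf12)) < 2L) {
    lbp_abort("degenerate design: SF-12 column is constant",
              class = "lbp_degenerate_design")
  }
  fit <- stats::lm(logit(dw) ~ sf12, data = pairs)
  co <- stats::coef(fit)
  sigma <- stats::sigma(fit)
  # a saturated/noise-free fit has a zero (or undefined) residual variance;
  # suppressWarnings avoids summary.lm's "essentially perfect fit" chatter
  vc <- if (is.finite(sigma) && sigma > 1e-10) {
    suppressWarnings(stats::vcov(fit))
  } else matrix(0, 2L, 2L)
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_mvnorm(n_draws, c(intercept = unname(co[1L]),
                                  slope = unname(co[2L])), vc)
  structure(list(intercept = unname(co[1L]), slope = unname(co[2L]),
                 residual_sd = if (is.finite(sigma)) sigma else 0,
                 draws = draws, n = nrow(pairs)),
            class = "lbp_crosswalk_fit")
}

#' @export
print.lbp_crosswalk_fit <- function(x, ...) {
  cat(sprintf(
    "<lbp_crosswalk_fit> logit(DW) = %.4f %+.4f * SF12 (n = %d, residual SD %.3f)\n",
    x$intercept, x$slope, x$n, x$residual_sd))
  invisible(x)
}

#' Predict a disability weight from an SF-12 score
#'
#' `plogis(intercept + slope * sf12)` using either the point coefficients
#' (`draw = NULL`) or an indexed coefficient draw. Strictly inside (0, 1) and
#' monotone decreasing in `sf12` for a fitted (negative) slope.
#'
#' @param fit An [fit_crosswalk()] object.
#' @param sf12 Numeric vector of SF-12 scores.
#' @param draw Optional draw index.
#' @return Numeric vector of disability weights.
#' @export
predict_dw <- function(fit, sf12, draw = NULL) {
  stopifnot(inherits(fit, "lbp_crosswalk_fit"))
  co <- crosswalk_coefs(fit, draw)
  inv_logit(co[1L] + co[2L] * sf12)
}

crosswalk_coefs <- function(fit, draw = NULL) {
  if (is.null(draw)) c(fit$intercept, fit$slope) else {
    if (draw < 1L || draw > nrow(fit$draws)) {
      lbp_validation_error("draw index out of range")
    }
    fit$draws[draw, ]
  }
}

#' Fit the comorbidity condition model
#'
#' Survey-weighted regression of the logit cumulative disability weight
#' (each respondent's SF-12 score mapped through the crosswalk) on all
#' condition indicators: low back pain split by leg-pain status
#' (`lbp_no_leg_pain`, `lbp_leg_pain`) plus every `cond_*` column.
#'
#' Because the crosswalk is linear on the logit scale, the outcome is an
#' affine function of SF-12; the model is therefore fitted once as a weighted
#' regression of SF-12 on the indicators and mapped through the crosswalk
#' coefficients. Coefficient draws combine the regression's sampling
#' distribution with the crosswalk's coefficient draws, index-aligned so that
#' downstream stages propagate both sources of uncertainty coherently.
#'
#' @param respondents Respondent table with `weight`, `lbp`, `leg_pain`,
#'   `sf12` and `cond_*` columns.
#' @param fit An [fit_crosswalk()] object.
#' @param n_draws Number of draws; defaults to the crosswalk's draw count.
#' @param seed Optional seed.
#' @return Object of class `lbp_condition_model`: `coef` (point coefficients
#'   on the logit-DW scale), `draws` (n_draws x terms), `terms`, `lbp_terms`,
#'   and the crosswalk fit used.
#' @export
fit_condition_model <- function(respondents, fit, n_draws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "lbp_crosswalk_fit"))
  needed <- c("weight", "lbp", "leg_pain", "sf12")
  missing <- setdiff(needed, names(respondents))
  if (length(missing)) {
    lbp_validation_error(paste0("respondent table missing column(s): ",
                                paste(missing, collapse = ", ")))
  }
  if (is.null(n_draws)) n_draws <- nrow(fit$draws)
  x <- condition_design(respondents)
  w <- respondents$weight
  check_weights(w, nrow(x))
  gfit <- stats::lm.wfit(cbind(`(Intercept)` = 1, x), respondents$sf12, w)
  if (any(is.na(gfit$coefficients))) {
    bad <- names(gfit$coefficients)[is.na(gfit$coefficients)]
    lbp_abort(paste0("collinear/degenerate condition design: ",
                     paste(bad, collapse = ", ")),
              class = "lbp_degenerate_design")
  }
  gamma <- gfit$coefficients
  # classical WLS covariance of gamma
  rdf <- length(gfit$residuals) - length(gamma)
  s2 <- sum(w * gfit$residuals^2) / rdf
  xtwx <- crossprod(cbind(1, x) * sqrt(w))
  vg <- s2 * solve(xtwx)

  if (!is.null(seed)) set.seed(seed)
  gdraws <- draw_mvnorm(n_draws, gamma, vg)
  cw <- fit$draws
  if (nrow(cw) < n_draws) {
    lbp_validation_error("crosswalk fit has fewer draws than requested")
  }
  # beta = a * e_intercept + b * gamma, per aligned draw
  draws <- cw[seq_len(n_draws), "slope"] * gdraws
  draws[, 1L] <- draws[, 1L] + cw[seq_len(n_draws), "intercept"]
  beta <- fit$slope * gamma
  beta[1L] <- beta[1L] + fit$intercept
  colnames(draws) <- names(beta) <- names(gamma)

  structure(list(coef = beta, draws = draws,
                 terms = colnames(x),
                 lbp_terms = c("lbp_no_leg_pain", "lbp_leg_pain"),
                 crosswalk = fit, n_draws = as.integer(n_draws)),
            class = "lbp_condition_model")
}

condition_design <- function(respondents) {
  cond_cols <- grep("^cond_", names(respondents), value = TRUE)
  x <- cbind(
    lbp_no_leg_pain = as.numeric(respondents$lbp == 1L & respondents$leg_pain == 0L),
    lbp_leg_pain = as.numeric(respondents$lbp == 1L & respondents$leg_pain == 1L)
  )
  if (length(cond_cols)) {
    x <- cbind(x, as.matrix(respondents[, cond_cols, drop = FALSE]))
  }
  x
}

#' @export
print.lbp_condition_model <- function(x, ...) {
  cat(sprintf("<lbp_condition_model> %d terms, %d draws\n",
              length(x$coef), x$n_draws))
  print(round(x$coef, 4))
  invisible(x)
}

#' Disability weight attributable to low back pain
#'
#' Multiplicative-share attribution: with `DW_full` the model prediction using
#' all conditions and `DW_cf` the prediction with the low back pain terms
#' dropped, each respondent's attributable disability weight is
#' `DW_observed * (1 - DW_cf / DW_full)`, bounded in `[0, DW_observed]`.
#' Respondents without low back pain get 0.
#'
#' @param model An [fit_condition_model()] object.
#' @param respondents Respondent table (same columns as used for the fit).
#' @param draw Optional draw index; `NULL` uses point coefficients.
#' @return Numeric vector of attributable disability weights.
#' @export
attribute_lbp <- function(model, respondents, draw = NULL) {
  stopifnot(inherits(model, "lbp_condition_model"))
  x <- condition_design(respondents)
  beta <- if (is.null(draw)) model$coef else {
    if (draw < 1L || draw > nrow(model$draws)) {
      lbp_validation_error("draw index out of range")
    }
    model$draws[draw, ]
  }
  l_full <- beta[1L] + drop(x %*% beta[-1L])
  x_cf <- x
  x_cf[, model$lbp_terms] <- 0
  l_cf <- beta[1L] + drop(x_cf %*% beta[-1L])
  dw_obs <- predict_dw(model$crosswalk, respondents$sf12, draw)
  out <- dw_obs * (1 - inv_logit(l_cf) / inv_logit(l_full))
  out[respondents$lbp != 1L] <- 0
  out
}
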