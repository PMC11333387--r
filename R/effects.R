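# Trial-level standardised mean differences and random-effects network
# meta-analysis versus a usual-care reference.

#' Compute Hedges-g standardised mean differences from arm summaries
#'
#' For each trial the bias-corrected standardised mean difference is
#' `g = J * (mean_a - mean_b) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4 * (n_a + n_b - 2) - 1)` and sampling variance
#' `(n_a + n_b) / (n_a * n_b) + g^2 / (2 * (n_a + n_b))`. Negative values mean
#' the intervention arm (`class_a`) has less functional disability.
#'
#' @param trials data.frame of trial records with columns `class_a`,
#'   `class_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b` (and
#'   optionally `trial_id`).
#' @return data.frame with `trial_id`, `class_a`, `class_b`, `smd`, `se`.
#' @export
compute_smd <- function(trials) {
  validate_trial_records(trials)
  n_a <- as.numeric(trials$n_a); n_b <- as.numeric(trials$n_b)
  sp <- sqrt(((n_a - 1) * trials$sd_a^2 + (n_b - 1) * trials$sd_b^2) /
               (n_a + n_b - 2))
  if (any(sp <= 0)) {
    lbp_abort(paste0("undefined effect: zero pooled SD in trial(s) ",
                     paste(which(sp <= 0), collapse = ", ")),
              class = "lbp_undefined_effect")
  }
  d <- (trials$mean_a - trials$mean_b) / sp
  j <- 1 - 3 / (4 * (n_a + n_b - 2) - 1)
  g <- j * d
  v <- (n_a + n_b) / (n_a * n_b) + g^2 / (2 * (n_a + n_b))
  data.frame(
    trial_id = if ("trial_id" %in% names(trials)) trials$trial_id
    else sprintf("T%04d", seq_len(nrow(trials))),
    class_a = trials$class_a, class_b = trials$class_b,
    smd = g, se = sqrt(v), stringsAsFactors = FALSE
  )
}

validate_trial_records <- function(trials) {
  needed <- c("class_a", "class_b", "n_a", "n_b", "mean_a", "mean_b",
              "sd_a", "sd_b")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    lbp_validation_error(paste0("trial table missing column(s): ",
                                paste(missing, collapse = ", ")))
  }
  if (any(trials$n_a < 2 | trials$n_b < 2)) {
    lbp_validation_error("arm sample sizes must be >= 2")
  }
  if (any(trials$sd_a <= 0 | trials$sd_b <= 0)) {
    lbp_validation_error("arm SDs must be > 0")
  }
  if (any(trials$class_a == trials$class_b)) {
    lbp_validation_error("class_a and class_b must differ")
  }
  invisible(TRUE)
}

#' Filter trials by follow-up window and minimum class size
#'
#' Retains trials whose follow-up lies in the window (inclusive at both ends),
#' then iteratively drops non-reference classes appearing in fewer than
#' `min_trials_per_class` retained trials, together with the trials that
#' involve them. Exclusions are reported in the `exclusions` attribute (one
#' row per dropped trial with a reason) and dropped classes in the
#' `excluded_classes` attribute.
#'
#' @param trials data.frame of trial records with `followup_months`.
#' @param followup_window Numeric length-2 inclusive window in months.
#' @param min_trials_per_class Minimum number of retained trials per
#'   non-reference class (default 10).
#' @param reference Reference class label, exempt from the class rule.
#' @return The filtered data.frame (possibly empty) with attributes
#'   `exclusions` and `excluded_classes`.
#' @export
filter_trials <- function(trials, followup_window = c(3, 12),
                          min_trials_per_class = 10L,
                          reference = "usual_care") {
  if (!"followup_months" %in% names(trials)) {
    lbp_validation_error("trial table missing column(s): followup_months")
  }
  out_fu <- trials$followup_months < followup_window[1L] |
    trials$followup_months > followup_window[2L]
  excl <- data.frame(trial_id = trials$trial_id[out_fu],
                     reason = rep("followup_window", sum(out_fu)),
                     stringsAsFactors = FALSE)
  kept <- trials[!out_fu, , drop = FALSE]
  dropped_classes <- character(0)
  repeat {
    counts <- table(c(kept$class_a, kept$class_b))
    small <- setdiff(names(counts)[counts < min_trials_per_class], reference)
    if (!length(small)) break
    hit <- kept$class_a %in% small | kept$class_b %in% small
    excl <- rbind(excl, data.frame(trial_id = kept$trial_id[hit],
                                   reason = rep("class_min_trials", sum(hit)),
                                   stringsAsFactors = FALSE))
    dropped_classes <- union(dropped_classes, small)
    kept <- kept[!hit, , drop = FALSE]
  }
  if (!nrow(kept)) message("filter_trials: no trials remain after filtering")
  attr(kept, "exclusions") <- excl
  attr(kept, "excluded_classes") <- dropped_classes
  kept
}

#' Pool effects by random-effects network meta-analysis
#'
#' Contrast-based network meta-analysis assuming consistency: trial effects
#' `y_i` with variances `v_i` are modelled as `y_i = d_{a(i)} - d_{b(i)}`
#' with the reference class fixed at 0 and a common additive heterogeneity
#' variance tau^2 across contrasts. tau^2 is estimated by the generalised
#' DerSimonian-Laird (multivariate method-of-moments) estimator; per-class
#' effects are the weighted least-squares solution with weights
#' `1 / (v_i + tau^2)`, and uncertainty is propagated as parametric draws from
#' the multivariate normal sampling distribution of the coefficients.
#'
#' @param effects data.frame from [compute_smd()].
#' @param reference Reference class label.
#' @param n_draws Number of posterior-style draws (default 1000).
#' @param seed Optional integer seed for the draws.
#' @param tau Optional fixed heterogeneity SD; `NULL` (default) estimates it.
#' @param excluded_classes Optional character vector of classes dropped
#'   upstream (carried into the result for reporting; they contribute zero
#'   effect downstream).
#' @return Object of class `lbp_pooled_effects` with elements `mean`, `se`
#'   (named per class, reference = 0), `tau`, `draws` (n_draws x classes,
#'   reference column identically 0), `included_classes`, `excluded_classes`,
#'   `reference`, `n_draws`.
#' @export
pool_network <- function(effects, reference = "usual_care", n_draws = 1000L,
                         seed = NULL, tau = NULL, excluded_classes = character(0)) {
  if (!nrow(effects)) lbp_validation_error("no effect estimates to pool")
  if (any(!is.finite(effects$se) | effects$se <= 0)) {
    lbp_validation_error("all standard errors must be finite and positive")
  }
  classes <- union(reference, unique(c(effects$class_a, effects$class_b)))
  edges <- cbind(effects$class_a, effects$class_b)
  reachable <- connected_to(edges, reference)
  dis <- setdiff(classes, reachable)
  if (length(dis)) {
    lbp_abort(paste0("network disconnected from reference: ",
                     paste(sort(dis), collapse = ", ")),
              class = "lbp_disconnected_network")
  }
  others <- setdiff(classes, reference)
  x <- matrix(0, nrow(effects), length(others),
              dimnames = list(NULL, others))
  for (k in seq_along(others)) {
    x[, k] <- (effects$class_a == others[k]) - (effects$class_b == others[k])
  }
  y <- effects$smd
  v <- effects$se^2
  if (nrow(x) < ncol(x)) {
    lbp_validation_error("fewer contrasts than classes to estimate")
  }

  wls <- function(w) {
    xtwx <- crossprod(x, x * w)
    beta <- solve(xtwx, crossprod(x, y * w))
    list(beta = drop(beta), vcov = solve(xtwx))
  }

  fe <- wls(1 / v)
  if (is.null(tau)) {
    resid <- y - drop(x %*% fe$beta)
    q <- sum(resid^2 / v)
    df <- nrow(x) - ncol(x)
    w <- 1 / v
    denom <- sum(w) - sum(diag(fe$vcov %*% crossprod(x, x * w^2)))
    tau2 <- max(0, (q - df) / denom)
  } else {
    if (tau < 0) lbp_validation_error("tau must be >= 0")
    tau2 <- tau^2
  }
  re <- wls(1 / (v + tau2))

  if (!is.null(seed)) set.seed(seed)
  draws <- draw_mvnorm(n_draws, re$beta, re$vcov)
  draws <- cbind(matrix(0, n_draws, 1L, dimnames = list(NULL, reference)),
                 draws)
  mean_v <- c(stats::setNames(0, reference), re$beta)
  se_v <- c(stats::setNames(0, reference), sqrt(diag(re$vcov)))
  structure(list(mean = mean_v, se = se_v, tau = sqrt(tau2), draws = draws,
                 included_classes = classes,
                 excluded_classes = excluded_classes,
                 reference = reference, n_draws = as.integer(n_draws)),
            class = "lbp_pooled_effects")
}

#' @export
print.lbp_pooled_effects <- function(x, ...) {
  cat(sprintf("<lbp_pooled_effects> %d classes vs '%s', tau = %.3f, %d draws\n",
              length(x$included_classes), x$reference, x$tau, x$n_draws))
  tab <- data.frame(class = names(x$mean), smd = round(x$mean, 3),
                    se = round(x$se, 3), row.names = NULL)
  print(tab)
  if (length(x$excluded_classes)) {
    cat("excluded:", paste(x$excluded_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Survey-weighted treatment coverage by leg-pain status
#'
#' Estimates, among low back pain respondents, the weighted proportion using
#' each intervention class, stratified by leg-pain status, with draw-based
#' uncertainty from a Beta distribution matched to the Kish effective sample
#' size (Jeffreys-style 0.5 pseudo-counts).
#'
#' @param respondents Respondent table with `weight`, `lbp`, `leg_pain` and
#'   `trt_*` indicator columns.
#' @param classes Optional class labels to report; defaults to the `trt_*`
#'   columns present. Classes without a column are reported as `NA`
#'   (not surveyed).
#' @param n_draws Number of uncertainty draws (default 1000).
#' @param seed Optional seed for the draws.
#' @return data.frame with `class`, `leg_pain`, `coverage`, `lower`, `upper`,
#'   `n_eff`, `empty`; the draw array is attached as attribute `draws`
#'   (class x stratum x draw).
#' @export
estimate_coverage <- function(respondents, classes = NULL, n_draws = 1000L,
                              seed = NULL) {
  if (!all(c("weight", "leg_pain") %in% names(respondents))) {
    lbp_validation_error("respondent table needs 'weight' and 'leg_pain' columns")
  }
  r <- respondents
  if ("lbp" %in% names(r)) r <- r[r$lbp == 1L, , drop = FALSE]
  trt_cols <- grep("^trt_", names(r), value = TRUE)
  have <- sub("^trt_", "", trt_cols)
  if (is.null(classes)) classes <- have
  if (!is.null(seed)) set.seed(seed)

  res <- list()
  dr <- array(NA_real_, dim = c(length(classes), 2L, n_draws),
              dimnames = list(classes, c("no_leg_pain", "leg_pain"), NULL))
  for (s in 0:1) {
    sub <- r[r$leg_pain == s, , drop = FALSE]
    empty <- nrow(sub) == 0L
    if (!empty) check_weights(sub$weight, nrow(sub))
    for (cl in classes) {
      if (empty || !cl %in% have) {
        res[[length(res) + 1L]] <- data.frame(
          class = cl, leg_pain = s, coverage = NA_real_, lower = NA_real_,
          upper = NA_real_, n_eff = if (empty) 0 else effective_n(sub$weight),
          empty = empty, stringsAsFactors = FALSE)
        next
      }
      p <- weighted_mean(sub[[paste0("trt_", cl)]], sub$weight)
      neff <- effective_n(sub$weight)
      d <- stats::rbeta(n_draws, p * neff + 0.5, (1 - p) * neff + 0.5)
      dr[cl, s + 1L, ] <- d
      u <- ui(d, n_draws = n_draws)
      res[[length(res) + 1L]] <- data.frame(
        class = cl, leg_pain = s, coverage = p, lower = u[["lower"]],
        upper = u[["upper"]], n_eff = neff, empty = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "draws") <- dr
  out
}
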