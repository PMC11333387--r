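# Disability-weight gradient along the Health Access and Quality Index and
# decomposition of the burden into averted, avoidable, and unavoidable parts.

#' Severity anchors for the access-quality gradient
#'
#' Holds draw-indexed combined disability weights: the no-treatment level
#' (assumed to apply at HAQ index 0), the observed level (applies at the
#' anchor HAQ, the observed-treatment setting), and the full-use-of-optimal
#' -treatment level used as a floor when extrapolating beyond the anchor.
#'
#' @param dw_notreatment,dw_observed,dw_fuot Numeric draw vectors of equal
#'   length, each strictly in (0, 1).
#' @param haq_anchor HAQ value of the observed-treatment setting, in (0, 100].
#' @param legpain_fraction Leg-pain fraction used for combining (metadata).
#' @return Object of class `lbp_severity_anchors`.
#' @export
severity_anchors <- function(dw_notreatment, dw_observed, dw_fuot, haq_anchor,
                             legpain_fraction = NA_real_) {
  n <- length(dw_notreatment)
  if (length(dw_observed) != n || length(dw_fuot) != n) {
    lbp_validation_error("anchor draw vectors must have equal length")
  }
  if (any(c(dw_notreatment, dw_observed, dw_fuot) <= 0) ||
      any(c(dw_notreatment, dw_observed, dw_fuot) >= 1)) {
    lbp_validation_error("anchor disability weights must lie strictly in (0, 1)")
  }
  if (haq_anchor <= 0 || haq_anchor > 100) {
    lbp_validation_error("haq_anchor must lie in (0, 100]")
  }
  viol <- mean(dw_fuot > dw_observed | dw_observed > dw_notreatment)
  if (viol > 0) {
    warning(sprintf(
      "anchor ordering dw_fuot <= dw_observed <= dw_notreatment violated in %.1f%% of draws",
      100 * viol))
  }
  structure(list(dw_notreatment = dw_notreatment, dw_observed = dw_observed,
                 dw_fuot = dw_fuot, haq_anchor = haq_anchor,
                 legpain_fraction = legpain_fraction, n_draws = n),
            class = "lbp_severity_anchors")
}

#' @export
print.lbp_severity_anchors <- function(x, ...) {
  cat(sprintf(
    "<lbp_severity_anchors> %d draws | no-treatment %.4f @ HAQ 0, observed %.4f @ HAQ %.1f, FUOT floor %.4f\n",
    x$n_draws, mean(x$dw_notreatment), mean(x$dw_observed), x$haq_anchor,
    mean(x$dw_fuot)))
  invisible(x)
}

#' Interpolate a disability weight along the HAQ index
#'
#' Linear interpolation in disability-weight space between the no-treatment
#' anchor at HAQ 0 and the observed anchor at `haq_anchor`:
#' `DW(haq) = dw_notreatment + (dw_observed - dw_notreatment) * haq / haq_anchor`.
#' Beyond the anchor the line is extrapolated and floored at the FUOT
#' disability weight (no country can do better than full optimal treatment).
#'
#' @param anchors An [severity_anchors()] object.
#' @param haq HAQ index value(s), >= 0.
#' @param draw Optional draw index; `NULL` returns a matrix of all draws
#'   (length(haq) x n_draws).
#' @return Numeric vector (one draw) or matrix (all draws).
#' @export
interpolate_dw <- function(anchors, haq, draw = NULL) {
  stopifnot(inherits(anchors, "lbp_severity_anchors"))
  if (any(haq < 0)) lbp_validation_error("HAQ index must be >= 0")
  frac <- haq / anchors$haq_anchor
  if (!is.null(draw)) {
    nt <- anchors$dw_notreatment[draw]
    ob <- anchors$dw_observed[draw]
    fu <- anchors$dw_fuot[draw]
    return(pmax(nt + (ob - nt) * frac, fu))
  }
  nt <- anchors$dw_notreatment
  ob <- anchors$dw_observed
  out <- outer(frac, ob - nt) + matrix(nt, length(frac), anchors$n_draws,
                                       byrow = TRUE)
  pmax(out, matrix(anchors$dw_fuot, length(frac), anchors$n_draws, byrow = TRUE))
}

#' Country-year disability weights along the gradient
#'
#' @param anchors An [severity_anchors()] object.
#' @param haq_table data.frame with `country`, `year`, `haq`.
#' @return Object of class `lbp_country_dw`: `summary` data.frame (`country`,
#'   `year`, `haq`, `dw`, `lower`, `upper`) and `draws` matrix
#'   (country-year x draws).
#' @export
build_country_year_dw <- function(anchors, haq_table) {
  needed <- c("country", "year", "haq")
  missing <- setdiff(needed, names(haq_table))
  if (length(missing)) {
    lbp_validation_error(paste0("HAQ table missing column(s): ",
                                paste(missing, collapse = ", ")))
  }
  key <- paste(haq_table$country, haq_table$year)
  if (anyDuplicated(key)) {
    lbp_validation_error(paste0("duplicate country-year in HAQ table: ",
                                key[duplicated(key)][1L]))
  }
  if (any(haq_table$haq < 0 | haq_table$haq > 100)) {
    lbp_validation_error("HAQ index values must lie in [0, 100]")
  }
  draws <- interpolate_dw(anchors, haq_table$haq)
  rownames(draws) <- key
  us <- t(apply(draws, 1L, ui, n_draws = anchors$n_draws))
  structure(list(
    summary = data.frame(country = haq_table$country, year = haq_table$year,
                         haq = haq_table$haq, dw = us[, "mean"],
                         lower = us[, "lower"], upper = us[, "upper"],
                         row.names = NULL, stringsAsFactors = FALSE),
    draws = draws, anchors = anchors), class = "lbp_country_dw")
}

#' Decompose the burden into averted, avoidable, and unavoidable parts
#'
#' Per country and draw, with `prev` the low back pain prevalence:
#' * `yld_notreatment = prev * dw_notreatment` (the untreated burden),
#' * `yld_current = prev * DW-hat(country)` (or the supplied current YLDs),
#' * `yld_brc = prev * DW-hat(highest-HAQ country)` (best routine care),
#' * `yld_fuot = prev * dw_fuot`,
#' * `averted = yld_notreatment - yld_current`,
#' * `avoidable_brc = yld_current - yld_brc`,
#' * `avoidable_fuot = yld_brc - yld_fuot`,
#' * `unavoidable = yld_fuot`,
#' and shares express each component as a percentage of the untreated burden.
#' The four components sum to the untreated burden identically per draw.
#'
#' @param dws An [build_country_year_dw()] object.
#' @param prevalence data.frame with `country`, `prevalence` (> 0), optional
#'   `yld_current`, and optional `region` / `super_region` labels.
#' @param anchors The [severity_anchors()] object used for `dws`.
#' @return Object of class `lbp_burden_table`: `summary` data.frame of means
#'   and 95% UIs per location, and `draws`, a named list of component
#'   matrices (location x draw).
#' @export
compute_burden <- function(dws, prevalence, anchors) {
  stopifnot(inherits(dws, "lbp_country_dw"),
            inherits(anchors, "lbp_severity_anchors"))
  if (!all(c("country", "prevalence") %in% names(prevalence))) {
    lbp_validation_error("prevalence table needs 'country' and 'prevalence'")
  }
  if (any(prevalence$prevalence < 0)) {
    lbp_validation_error("prevalence must be non-negative")
  }
  miss <- setdiff(prevalence$country, dws$summary$country)
  if (length(miss)) {
    lbp_validation_error(paste0("no disability-weight record for: ",
                                paste(miss, collapse = ", ")))
  }
  idx <- match(prevalence$country, dws$summary$country)
  prev <- prevalence$prevalence
  n_draws <- anchors$n_draws
  dw_cur <- dws$draws[idx, , drop = FALSE]
  best <- which.max(dws$summary$haq)
  dw_brc <- dws$draws[best, ]

  yld_current <- if ("yld_current" %in% names(prevalence) &&
                     !all(is.na(prevalence$yld_current))) {
    matrix(prevalence$yld_current, length(prev), n_draws)
  } else prev * dw_cur
  yld_nt <- outer(prev, anchors$dw_notreatment)
  yld_brc <- outer(prev, dw_brc)
  yld_fuot <- outer(prev, anchors$dw_fuot)

  comp <- list(
    yld_current = yld_current, yld_notreatment = yld_nt, yld_brc = yld_brc,
    yld_fuot = yld_fuot,
    averted = yld_nt - yld_current,
    avoidable_brc = yld_current - yld_brc,
    avoidable_fuot = yld_brc - yld_fuot,
    unavoidable = yld_fuot
  )
  comp <- lapply(comp, function(m) {
    rownames(m) <- prevalence$country
    m
  })
  meta <- data.frame(location = prevalence$country, level = "country",
                     prevalence = prev, stringsAsFactors = FALSE)
  if ("region" %in% names(prevalence)) meta$region <- prevalence$region
  if ("super_region" %in% names(prevalence)) {
    meta$super_region <- prevalence$super_region
  }
  new_burden_table(comp, meta, n_draws)
}

new_burden_table <- function(comp, meta, n_draws) {
  shares <- c("averted", "avoidable_brc", "avoidable_fuot", "unavoidable")
  summ <- meta
  for (nm in names(comp)) {
    u <- t(apply(comp[[nm]], 1L, ui, n_draws = n_draws))
    summ[[nm]] <- u[, "mean"]
    summ[[paste0(nm, "_lower")]] <- u[, "lower"]
    summ[[paste0(nm, "_upper")]] <- u[, "upper"]
  }
  for (nm in shares) {
    sh <- 100 * comp[[nm]] / comp$yld_notreatment
    u <- t(apply(sh, 1L, ui, n_draws = n_draws))
    summ[[paste0("share_", nm)]] <- u[, "mean"]
    summ[[paste0("share_", nm, "_lower")]] <- u[, "lower"]
    summ[[paste0("share_", nm, "_upper")]] <- u[, "upper"]
  }
  structure(list(summary = summ, draws = comp, n_draws = n_draws),
            class = "lbp_burden_table")
}

#' @export
print.lbp_burden_table <- function(x, ...) {
  cat(sprintf("<lbp_burden_table> %d locations, %d draws\n",
              nrow(x$summary), x$n_draws))
  cols <- c("location", "level", "share_averted", "share_avoidable_brc",
            "share_avoidable_fuot", "share_unavoidable")
  s <- x$summary[, intersect(cols, names(x$summary))]
  for (cc in setdiff(names(s), c("location", "level"))) s[[cc]] <- round(s[[cc]], 1)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Aggregate a burden table over a location hierarchy
#'
#' Sums the YLD components per draw over regions, super-regions, and globally
#' (levels present in the table's metadata), recomputing shares from the
#' aggregated components, and returns a burden table containing all levels.
#'
#' @param burden An [compute_burden()] object whose metadata includes
#'   `region` / `super_region` columns.
#' @return An `lbp_burden_table` with rows at every aggregation level.
#' @export
aggregate_burden <- function(burden) {
  stopifnot(inherits(burden, "lbp_burden_table"))
  meta <- burden$summary[burden$summary$level == "country",
                         intersect(c("location", "level", "prevalence",
                                     "region", "super_region"),
                                   names(burden$summary))]
  if (!"region" %in% names(meta)) {
    lbp_validation_error("burden table has no hierarchy metadata to aggregate")
  }
  if (any(is.na(meta$region)) ||
      ("super_region" %in% names(meta) && any(is.na(meta$super_region)))) {
    lbp_validation_error("unmapped country in hierarchy")
  }
  levels <- list(country = meta$location, region = meta$region)
  if ("super_region" %in% names(meta)) levels$super_region <- meta$super_region
  levels$global <- rep("Global", nrow(meta))

  comp_all <- list()
  meta_rows <- list()
  for (lv in names(levels)) {
    groups <- levels[[lv]]
    for (g in unique(groups)) {
      i <- which(groups == g)
      comp_all[[length(comp_all) + 1L]] <- lapply(burden$draws, function(m) {
        colSums(m[i, , drop = FALSE])
      })
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        location = g, level = lv, prevalence = sum(meta$prevalence[i]),
        stringsAsFactors = FALSE)
    }
  }
  comp <- lapply(names(burden$draws), function(nm) {
    do.call(rbind, lapply(comp_all, `[[`, nm))
  })
  names(comp) <- names(burden$draws)
  meta_out <- do.call(rbind, meta_rows)
  comp <- lapply(comp, function(m) {
    rownames(m) <- meta_out$location
    m
  })
  new_burden_table(comp, meta_out, burden$n_draws)
}

#' Mean and 95% uncertainty interval from ranked draws
#'
#' The lower and upper bounds are the `ceiling(0.025 n)`-th and
#' `floor(0.975 n)`-th order statistics of the draws; with the canonical
#' 1000 draws these are the 25th and 975th ranked values.
#'
#' @param draws Numeric vector of draws.
#' @param n_draws Expected draw count (default 1000); a mismatch is an error.
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
ui <- function(draws, n_draws = 1000L) {
  if (length(draws) != n_draws) {
    lbp_validation_error(sprintf("expected %d draws, got %d", n_draws,
                                 length(draws)))
  }
  s <- sort(draws)
  lo <- max(1L, ceiling(0.025 * n_draws))
  hi <- min(n_draws, floor(0.975 * n_draws))
  c(mean = mean(draws), lower = s[lo], upper = s[hi])
}

#' Percent change, rounded half to even
#'
#' `100 * (new - old) / old`, rounded with [round_half_even()]; used for the
#' disability-weight change column of the gradient report.
#'
#' @param new,old Numeric vectors.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
percent_change <- function(new, old, digits = 1L) {
  round_half_even(100 * (new - old) / old, digits)
}

#' Gradient report: old versus new disability weights per location
#'
#' A report in the style of the published region table: location, HAQ, the
#' treatment-invariant reference disability weight, the new
#' gradient disability weight (rounded to 3 decimals), and the percent change
#' (1 decimal, half-even) computed from the rounded new value.
#'
#' @param dws An [build_country_year_dw()] object.
#' @param gbd_dw Reference (treatment-invariant) disability weight,
#'   default 0.096.
#' @return data.frame with `location`, `year`, `haq`, `gbd_dw`, `new_dw`,
#'   `new_dw_lower`, `new_dw_upper`, `pct_change`.
#' @export
table2_report <- function(dws, gbd_dw = 0.096) {
  stopifnot(inherits(dws, "lbp_country_dw"))
  s <- dws$summary
  new_dw <- round_half_even(s$dw, 3L)
  data.frame(location = s$country, year = s$year, haq = s$haq,
             gbd_dw = gbd_dw, new_dw = new_dw,
             new_dw_lower = round_half_even(s$lower, 3L),
             new_dw_upper = round_half_even(s$upper, 3L),
             pct_change = percent_change(new_dw, gbd_dw),
             stringsAsFactors = FALSE)
}

#' Burden-shares report
#'
#' Shares of the untreated burden (averted, avoidable with best routine care,
#' avoidable with full optimal treatment, unavoidable) per location, each with
#' a 95% uncertainty interval, rounded to 1 decimal (half-even).
#'
#' @param burden An `lbp_burden_table` (typically from [aggregate_burden()]).
#' @return data.frame, one row per location.
#' @export
shares_report <- function(burden) {
  stopifnot(inherits(burden, "lbp_burden_table"))
  s <- burden$summary
  cols <- grep("^share_", names(s), value = TRUE)
  out <- s[, c("location", "level")]
  for (cc in cols) out[[cc]] <- round_half_even(s[[cc]], 1L)
  out
}
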