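# Small numeric and error helpers shared across the package.

#' Logit and inverse logit
#'
#' Thin wrappers around [stats::qlogis()] and [stats::plogis()] used throughout
#' the crosswalk and attribution code.
#'
#' @param p Probabilities / disability weights strictly in (0, 1).
#' @param x Values on the logit scale.
#' @return Numeric vector.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Clamp disability weights away from the logit boundaries
#'
#' Disability weights of exactly 0 (full health) or 1 are undefined on the
#' logit scale; calibration health states at the boundaries are moved a small
#' distance inside the unit interval before transformation.
#'
#' @param dw Numeric vector of disability weights in \[0, 1\].
#' @param eps Boundary offset; defaults to 1e-6.
#' @return Numeric vector strictly inside (0, 1).
#' @export
clamp_dw <- function(dw, eps = 1e-6) {
  pmin(pmax(dw, eps), 1 - eps)
}

#' Round half to even, robust to binary-representation noise
#'
#' Report columns are rounded half-to-even (banker's rounding, as in base
#' `round()`). Quantities such as `0.006 / 0.096 * 100` are exactly 6.25 in
#' decimal but carry an O(1e-15) binary artifact that would flip the rounded
#' digit; values are therefore snapped to `digits + 8` decimals first.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_even <- function(x, digits = 1L) {
  round(round(x, digits + 8L), digits)
}

#' Survey-weighted mean and spread
#'
#' @param x Numeric vector.
#' @param w Positive weights (need not sum to one).
#' @return `weighted_mean()` the weighted mean; `weighted_sd()` the weighted
#'   population standard deviation `sqrt(sum(w * (x - m)^2) / sum(w))`;
#'   `effective_n()` the Kish effective sample size `sum(w)^2 / sum(w^2)`.
#' @export
weighted_mean <- function(x, w) {
  check_weights(w, length(x))
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' @rdname weighted_mean
#' @export
effective_n <- function(w) {
  sum(w)^2 / sum(w^2)
}

check_weights <- function(w, n) {
  if (length(w) != n) {
    lbp_abort("weights must have the same length as the data")
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    lbp_abort("weights must be finite and strictly positive")
  }
  if (sum(w) <= 0) lbp_abort("total weight must be positive")
  invisible(TRUE)
}

# Multivariate normal draws via a Cholesky factor; falls back to the mean when
# the covariance is numerically zero (e.g. a saturated two-point fit).
draw_mvnorm <- function(n, mu, sigma) {
  p <- length(mu)
  sigma <- as.matrix(sigma)
  if (!all(is.finite(sigma)) || max(abs(sigma)) == 0) {
    return(matrix(mu, nrow = n, ncol = p, byrow = TRUE,
                  dimnames = list(NULL, names(mu))))
  }
  ch <- tryCatch(chol(sigma), error = function(e) {
    chol(sigma + diag(1e-12 * max(diag(sigma)), p))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  out <- sweep(z %*% ch, 2L, mu, `+`)
  colnames(out) <- names(mu)
  out
}

# Breadth-first search connectivity on an undirected class graph given a
# two-column edge matrix of labels.
connected_to <- function(edges, start) {
  nodes <- unique(c(edges))
  reached <- start
  frontier <- start
  while (length(frontier)) {
    hit <- edges[, 1L] %in% frontier | edges[, 2L] %in% frontier
    nxt <- setdiff(unique(c(edges[hit, , drop = FALSE])), reached)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  reached
}

# Error conditions ------------------------------------------------------------

lbp_abort <- function(msg, class = "lbp_error", call. = FALSE) {
  stop(structure(
    class = c(class, "lbp_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1L))
  ))
}

lbp_validation_error <- function(msg) lbp_abort(msg, class = "lbp_validation_error")
lbp_config_error <- function(msg) lbp_abort(msg, class = "lbp_config_error")

# Polynomial rolling hash of a character scalar; used for run manifests so
# that reports can be tied to the exact configuration without a digest
# dependency (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
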