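const_anchors <- function(nt = 0.132, obs = 0.103, fuot = 0.0776,
                          haq_anchor = 83.6, n = 10L) {
  severity_anchors(rep(nt, n), rep(obs, n), rep(fuot, n), haq_anchor)
}

test_that("interpolation hits both anchors and the worked midpoint", {
  a <- const_anchors()
  expect_equal(interpolate_dw(a, 0, draw = 1L), 0.132, tolerance = 1e-15)
  expect_equal(interpolate_dw(a, 83.6, draw = 1L), 0.103, tolerance = 1e-12)
  expect_equal(interpolate_dw(a, 41.8, draw = 1L), 0.1175, tolerance = 1e-9)
  expect_error(interpolate_dw(a, -1), class = "lbp_validation_error")
})

test_that("interpolation is linear, monotone, and floored at the FUOT weight", {
  a <- const_anchors()
  haq <- seq(0, 100, by = 2.5)
  dw <- interpolate_dw(a, haq, draw = 1L)
  expect_true(all(diff(dw) < 0))
  # pre-floor linearity to 1e-12 over the unfloored range
  lin <- 0.132 + (0.103 - 0.132) * haq / 83.6
  unfloored <- lin >= a$dw_fuot[1L]
  expect_equal(dw[unfloored], lin[unfloored], tolerance = 1e-12)
  # far beyond the anchor the floor binds
  steep <- const_anchors(nt = 0.2, obs = 0.1, fuot = 0.095, haq_anchor = 50)
  expect_equal(interpolate_dw(steep, 100, draw = 1L), 0.095)
})

test_that("country-year table is monotone in HAQ and rejects duplicates", {
  a <- const_anchors()
  haq <- data.frame(country = c("A", "B"), year = 2020L, haq = c(28.3, 85.8))
  dws <- build_country_year_dw(a, haq)
  expect_true(all(dws$draws["A 2020", ] > dws$draws["B 2020", ]))
  dup <- rbind(haq, haq[1L, ])
  expect_error(build_country_year_dw(a, dup), class = "lbp_validation_error")
})

test_that("burden components satisfy the worked Eq-4 example and conservation", {
  a <- const_anchors(nt = 0.2, obs = 0.092, fuot = 0.05, haq_anchor = 100,
                     n = 4L)
  haq <- data.frame(country = c("X", "Best"), year = 2020L, haq = c(50, 100))
  dws <- build_country_year_dw(a, haq)
  prev <- data.frame(country = c("X", "Best"), prevalence = c(1000, 500),
                     yld_current = c(100, 46))
  b <- compute_burden(dws, prev, a)
  # avoidable_brc = yld_current - prev * DW-hat(highest HAQ) = 100 - 92
  expect_equal(unname(b$draws$avoidable_brc["X", 1L]), 8, tolerance = 1e-9)
  expect_equal(unname(b$draws$avoidable_brc["Best", 1L]), 0, tolerance = 1e-9)
  # averted share arithmetic: untreated 121, current 100 -> 21/121
  expect_equal(unname(100 * (121 - 100) / 121), 17.35537, tolerance = 1e-4)
  # conservation per draw
  tot <- b$draws$averted + b$draws$avoidable_brc + b$draws$avoidable_fuot +
    b$draws$unavoidable
  expect_equal(tot, b$draws$yld_notreatment, tolerance = 1e-12)
  expect_error(
    compute_burden(dws, data.frame(country = "X", prevalence = -1), a),
    class = "lbp_validation_error")
  expect_error(
    compute_burden(dws, data.frame(country = "Z", prevalence = 10), a),
    class = "lbp_validation_error")
})

test_that("aggregation sums components per draw and shares close to 100", {
  a <- const_anchors(n = 6L)
  haq <- data.frame(country = c("A", "B", "C"), year = 2020L,
                    haq = c(30, 60, 90))
  dws <- build_country_year_dw(a, haq)
  prev <- data.frame(country = c("A", "B", "C"),
                     prevalence = c(1000, 2000, 1000),
                     region = c("R1", "R1", "R2"),
                     super_region = c("S1", "S1", "S2"))
  b <- aggregate_burden(compute_burden(dws, prev, a))
  s <- b$summary
  # single-country region equals the country row
  expect_equal(s[s$location == "R2", "averted"],
               s[s$location == "C", "averted"], tolerance = 1e-12)
  # region = sum of members
  expect_equal(s[s$location == "R1", "yld_current"],
               s[s$location == "A", "yld_current"] +
                 s[s$location == "B", "yld_current"], tolerance = 1e-9)
  # shares sum to 100 at every level, per draw
  for (lv in unique(s$level)) {
    rows <- which(b$summary$level == lv)
    tot <- (b$draws$averted[rows, , drop = FALSE] +
              b$draws$avoidable_brc[rows, , drop = FALSE] +
              b$draws$avoidable_fuot[rows, , drop = FALSE] +
              b$draws$unavoidable[rows, , drop = FALSE]) /
      b$draws$yld_notreatment[rows, , drop = FALSE]
    expect_equal(unname(tot), matrix(1, length(rows), b$n_draws),
                 tolerance = 1e-12)
  }
  # two equal countries double the components
  prev2 <- data.frame(country = c("A", "B"), prevalence = c(1000, 1000),
                      region = "R", super_region = "S")
  haq2 <- data.frame(country = c("A", "B"), year = 2020L, haq = c(50, 50))
  b2 <- aggregate_burden(compute_burden(build_country_year_dw(a, haq2),
                                        prev2, a))
  s2 <- b2$summary
  expect_equal(s2[s2$location == "R", "yld_notreatment"],
               2 * s2[s2$location == "A", "yld_notreatment"],
               tolerance = 1e-12)
})

test_that("ui returns the 25th/975th ranked values and validates draw count", {
  expect_equal(ui(1:1000), c(mean = 500.5, lower = 25, upper = 975))
  expect_equal(ui(rep(3.2, 1000)), c(mean = 3.2, lower = 3.2, upper = 3.2))
  expect_error(ui(1:999), class = "lbp_validation_error")
  set.seed(99)
  z <- stats::rnorm(1000)
  u <- ui(z)
  expect_lt(abs(u[["lower"]] - stats::qnorm(0.025)), 0.15)
  expect_lt(abs(u[["upper"]] - stats::qnorm(0.975)), 0.15)
})

test_that("gradient report rounds half-even and computes percent change", {
  expect_equal(percent_change(0.112, 0.096), 16.7)
  expect_equal(percent_change(0.102, 0.096), 6.2)
  a <- const_anchors()
  haq <- data.frame(country = c("Low", "High"), year = 2020L,
                    haq = c(28.3, 85.8))
  rep2 <- table2_report(build_country_year_dw(a, haq), gbd_dw = 0.096)
  expect_equal(rep2$new_dw,
               round(0.132 + (0.103 - 0.132) * c(28.3, 85.8) / 83.6, 3))
  expect_equal(rep2$pct_change, percent_change(rep2$new_dw, 0.096))
})
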