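test_that("default gates recover the true class counts exactly", {
  for (s in c(1, 17, 99)) {
    ev <- generate_events(event_spec(seed = s))
    g <- gate_events(ev$events)
    expect_equal(g$cell_count, sum(ev$truth$class == "cell"))
    expect_equal(g$bead_count, sum(ev$truth$class == "bead"))
  }
})

test_that("gate edge cases", {
  ev <- generate_events(event_spec(seed = 2))
  everything <- gate_spec(cells = list(fl1 = c(-10, 10), ssc = c(-10, 10)),
                          beads = list(fsc = c(-10, 10), ssc = c(-10, 10)))
  g <- gate_events(ev$events, everything)
  expect_equal(g$cell_count, nrow(ev$events))
  expect_equal(g$bead_count, nrow(ev$events))
  nothing <- gate_spec(cells = list(fl1 = c(9, 10), ssc = c(9, 10)),
                       beads = list(fsc = c(9, 10), ssc = c(9, 10)))
  w <- capture_warnings(g0 <- gate_events(ev$events, nothing))
  expect_match(w, "no events", all = TRUE)
  expect_length(w, 2L)  # one per empty gate
  expect_equal(g0$cell_count, 0L)
  expect_error(gate_events(data.frame(FSC = numeric(0), SSC = numeric(0),
                                      FL1 = numeric(0))), "empty")
})

test_that("absolute concentration follows the bead-referenced arithmetic", {
  r <- absolute_concentration(30000, 10000, beads_total_in_tube = 20000,
                              tube_volume_ul = 400, sample_aliquot_ul = 380)
  expect_equal(r$analyzed_volume_ml, 0.2)           # half the beads seen
  expect_equal(r$conc_tube_per_ml, 1.5e5)
  expect_equal(r$conc_suspension_per_ml, 1.5e5 * 400 / 380)
  expect_equal(r$rel_se, sqrt(1 / 30000 + 1 / 10000))
  # dilution factor and OD normalization
  r2 <- absolute_concentration(30000, 10000, 20000, dilution_factor = 500,
                               od = 0.5)
  expect_equal(r2$conc_culture_per_ml, r$conc_suspension_per_ml * 500)
  expect_equal(r2$od_specific_conc, r2$conc_culture_per_ml / 0.5)
  # aliquot correction is ~5% and optional
  r3 <- absolute_concentration(30000, 10000, 20000, aliquot_correction = FALSE)
  expect_equal(r3$conc_suspension_per_ml, 1.5e5)
  # degenerate inputs
  r0 <- absolute_concentration(0, 10000, 20000)
  expect_equal(r0$conc_culture_per_ml, 0)
  expect_true(is.na(r0$rel_se))
  expect_error(absolute_concentration(100, 0, 20000), "bead_count")
  expect_error(absolute_concentration(100, 30, 20), "beads_total_in_tube")
})

test_that("full counting pipeline recovers known concentrations", {
  # analyzed volume <= tube volume always; estimator is scale-equivariant
  n_seeds <- 60
  hits <- 0
  for (s in seq_len(n_seeds)) {
    spec <- event_spec(true_cell_conc_per_ml = 1e6, beads_total = 20000,
                       analyzed_volume_ul = 30, seed = 1000 + s)
    ev <- generate_events(spec)
    g <- gate_events(ev$events)
    r <- absolute_concentration(g$cell_count, g$bead_count,
                                beads_total_in_tube = spec$beads_total,
                                aliquot_correction = FALSE)
    expect_lte(r$analyzed_volume_ml, spec$tube_volume_ul * 1e-3)
    err <- abs(r$conc_tube_per_ml - 1e6) / 1e6
    if (err <= 3 * r$rel_se) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("doubling the true concentration doubles the estimate", {
  est <- function(conc, s) {
    ev <- generate_events(event_spec(true_cell_conc_per_ml = conc,
                                     seed = s))
    g <- gate_events(ev$events)
    absolute_concentration(g$cell_count, g$bead_count, 20000,
                           aliquot_correction = FALSE)$conc_tube_per_ml
  }
  e1 <- mean(vapply(1:10, function(s) est(5e5, s), numeric(1)))
  e2 <- mean(vapply(1:10, function(s) est(1e6, s), numeric(1)))
  expect_equal(e2 / e1, 2, tolerance = 0.05)
})

test_that("scatter-to-volume calibration recovers exact and noisy lines", {
  s <- c(100, 200, 300, 400, 500)
  v <- 0.01 * s + 0.5
  m <- calibrate_scatter_to_volume(s, v, "FSC")
  expect_equal(m$slope, 0.01, tolerance = 1e-10)
  expect_equal(m$intercept, 0.5, tolerance = 1e-8)
  expect_equal(m$r_squared, 1)
  p <- predict_volume_from_scatter(m, 300)
  expect_equal(p$volume_fl, v[3], tolerance = 1e-8)
  expect_warning(predict_volume_from_scatter(m, 1000), "extrapolat")

  # noisy slope recovery, modest simulation
  slopes <- vapply(1:50, function(sd) {
    set.seed(sd)
    sc <- runif(20, 100, 600)
    vol <- 0.01 * sc + 0.5 + rnorm(20, 0, 0.3)
    calibrate_scatter_to_volume(sc, vol, "SSC")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.01) / 0.01, 0.05)
})

test_that("exclusions drop flagged points and match a manual fit", {
  set.seed(7)
  sc <- seq(100, 600, length.out = 12)
  vol <- 0.01 * sc + rnorm(12, 0, 0.2)
  vol[11:12] <- vol[11:12] + 5  # stationary-like FSC outliers
  excl <- c(rep(FALSE, 10), TRUE, TRUE)
  m <- calibrate_scatter_to_volume(sc, vol, "FSC", exclude = excl)
  manual <- lm(vol[1:10] ~ sc[1:10])
  expect_equal(m$slope, unname(coef(manual)[2]))
  expect_equal(m$excluded, c(11L, 12L))
  expect_error(calibrate_scatter_to_volume(sc[1:4], vol[1:4],
                                           exclude = c(TRUE, TRUE, FALSE, FALSE)),
               "at least 3")
  expect_error(calibrate_scatter_to_volume(rep(5, 5), vol[1:5]), "variance")
})

test_that("prediction intervals achieve near-nominal coverage", {
  covered <- vapply(1:100, function(s) {
    set.seed(s)
    sc <- runif(15, 100, 600)
    vol <- 0.01 * sc + 0.5 + rnorm(15, 0, 0.3)
    m <- calibrate_scatter_to_volume(sc, vol, "FSC")
    new_s <- 350
    truth <- 0.01 * new_s + 0.5 + rnorm(1, 0, 0.3)
    p <- predict_volume_from_scatter(m, new_s)
    truth >= p$lwr && truth <= p$upr
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("replicate days with 10% CV keep the measured CV near 10%", {
  # day-to-day multiplicative noise on the true concentration
  set.seed(99)
  day_conc <- 1e6 * exp(rnorm(12, 0, sqrt(log(1 + 0.1^2))))
  est <- vapply(seq_along(day_conc), function(i) {
    ev <- generate_events(event_spec(true_cell_conc_per_ml = day_conc[i],
                                     seed = 2000 + i))
    g <- gate_events(ev$events)
    absolute_concentration(g$cell_count, g$bead_count, 20000,
                           aliquot_correction = FALSE)$conc_tube_per_ml
  }, numeric(1))
  expect_lte(sd(est) / mean(est), 0.12)
})
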