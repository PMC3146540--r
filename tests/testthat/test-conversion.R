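test_that("copies-per-cell and molar conversions match hand arithmetic", {
  rec <- omics_records("x", 1e-9)
  copies <- to_copies_per_cell(rec, REF_N_GLUCOSE)
  expect_equal(copies, 1e-9 * 6.02214076e23 / 1.11e9)
  expect_equal(copies, 5.43e5, tolerance = 0.01)
  molar <- to_molar(rec, REF_VTOT_GLUCOSE)
  expect_equal(molar, 1e-9 / 3.6e-6)
  expect_equal(molar, 2.78e-4, tolerance = 0.01)
  # zero amount, exact-inverse construction, scaling law
  expect_equal(to_copies_per_cell(omics_records("z", 0), 1e9), 0)
  inv <- omics_records("one", REF_N_GLUCOSE / od_constants()$avogadro)
  expect_equal(to_copies_per_cell(inv, REF_N_GLUCOSE), 1)
  expect_equal(to_molar(rec, 2 * REF_VTOT_GLUCOSE), molar / 2)
  # linearity in amount
  amounts <- c(0, 1e-12, 5e-10, 1e-9)
  recs <- omics_records(letters[1:4], amounts)
  expect_equal(to_copies_per_cell(recs, REF_N_GLUCOSE),
               amounts * 6.02214076e23 / REF_N_GLUCOSE)
})

test_that("unit tagging is enforced", {
  bad <- data.frame(analyte_id = "x", amount_per_ml_od = 1e-9,
                    unit = "nmol_per_mgDW")
  expect_error(to_copies_per_cell(bad, 1e9), "unit")
  expect_error(to_molar(data.frame(analyte_id = "x",
                                   amount_per_ml_od = 1e-9), 3.6), "unit")
})

test_that("convert_table reproduces generator ground truth", {
  g <- generate_omics_table(10, "glucose", seed = 5)
  res <- convert_table(g$omics, condition = "glucose", uncertainty = "none")
  expect_equal(nrow(res), 10L)
  expect_lt(max(abs(res$copies_per_cell / g$truth$copies_per_cell - 1)), 1e-3)
  expect_lt(max(abs(res$conc_molar / g$truth$conc_molar - 1)), 1e-3)
  empty <- convert_table(omics_records(character(0), numeric(0)),
                         condition = "glucose", uncertainty = "none")
  expect_equal(nrow(empty), 0L)
  expect_error(convert_table(g$omics, condition = "unobtainium"),
               "unknown condition")
  expect_error(convert_table(g$omics), "exactly one")
})

test_that("round-trip consistency with product-consistent factors", {
  tab <- load_reference_table()
  for (id in tab$condition_id) {
    rec <- get_condition(id)
    res <- convert_table(omics_records("x", 1e-9), condition = id,
                         vtot_source = "product", uncertainty = "none")
    v_cell_l <- rec$volume_fl * 1e-15
    implied_molar <- res$copies_per_cell /
      (v_cell_l * od_constants()$avogadro)
    expect_lt(abs(implied_molar / res$conc_molar - 1), 0.01, label = id)
  }
})

test_that("Monte Carlo uncertainty is seeded and agrees with delta method", {
  om <- omics_records("x", 1e-9)
  mc1 <- convert_table(om, condition = "glucose", uncertainty = "mc",
                       mc_samples = 20000, seed = 11)
  mc2 <- convert_table(om, condition = "glucose", uncertainty = "mc",
                       mc_samples = 20000, seed = 11)
  expect_identical(mc1$copies_sd, mc2$copies_sd)
  de <- convert_table(om, condition = "glucose", uncertainty = "delta")
  expect_lt(abs(mc1$copies_sd / de$copies_sd - 1), 0.15)
  expect_lt(abs(mc1$molar_sd / de$molar_sd - 1), 0.15)
  expect_warning(convert_table(om, condition = "glucose",
                               mc_samples = 50, seed = 1), "unreliable")
})

test_that("doubling the dominant input SD doubles the output SD", {
  # amount SD dominates when it is much larger than the factor CVs (~0.4)
  om1 <- omics_records("x", 1e-9, amount_sd = 5e-9)
  om2 <- omics_records("x", 1e-9, amount_sd = 1e-8)
  d1 <- convert_table(om1, condition = "glucose", uncertainty = "delta")
  d2 <- convert_table(om2, condition = "glucose", uncertainty = "delta")
  ratio <- d2$molar_sd / d1$molar_sd
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("model-route conversion works for arbitrary growth rates", {
  om <- omics_records("x", 1e-9)
  res <- convert_table(om, mu = 0.6, uncertainty = "delta")
  fac <- attr(res, "factors")
  expect_equal(fac$source, "model")
  # factors should be near the glucose row (mu = 0.60)
  expect_lt(abs(fac$n_cells_per_ml_od / REF_N_GLUCOSE - 1), 0.35)
})

test_that("OD calibration is monotone, identity-exact and truth-recovering", {
  od <- 10^seq(-3, 1, length.out = 10)
  ident <- calibrate_od(data.frame(od_device = od, od_reference = od))
  expect_lt(max(abs(ident(od) - od)), 1e-6)
  expect_lt(abs(ident(0.3) - 0.3), 1e-6)

  pairs <- generate_od_pairs(20, device_model = list(type = "saturating",
                                                     od_sat = 2,
                                                     noise_cv = 0.005),
                             seed = 3)
  cal <- calibrate_od(data.frame(od_device = pairs$od_device,
                                 od_reference = pairs$od_true))
  dev_new <- 2 * 0.8 / (2 + 0.8)  # noiseless device reading at true OD 0.8
  expect_lt(abs(cal(dev_new) / 0.8 - 1), 0.03)  # within the noise scale

  expect_error(calibrate_od(data.frame(od_device = od[1:3],
                                       od_reference = od[1:3])), "at least 4")
  expect_error(calibrate_od(data.frame(od_device = c(1, 2, 3, 4),
                                       od_reference = c(1, 3, 2, 4))),
               "monotone")
  expect_warning(ident(20), "clamped")
})
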