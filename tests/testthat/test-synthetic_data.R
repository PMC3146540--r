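test_that("generators are pure functions of their spec (seed included)", {
  s <- image_spec(n_cells = 3L, shape = c(128L, 128L), seed = 9)
  a <- render_cells(s); b <- render_cells(s)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  ev1 <- generate_events(event_spec(seed = 4))
  ev2 <- generate_events(event_spec(seed = 4))
  expect_identical(ev1$events, ev2$events)
  om1 <- generate_omics_table(5, "glucose", seed = 8)
  om2 <- generate_omics_table(5, "glucose", seed = 8)
  expect_identical(om1, om2)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(render_cells(s)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a rendered rod's unblurred mask has the requested pixel extents", {
  out <- render_cells(single_rod_spec(3.0, 1.26, seed = 5))
  idx <- which(out$mask == 1L, arr.ind = TRUE)
  ax <- odcell:::axis_extents(idx[, 1], idx[, 2])
  expect_lt(abs(ax[1] - 3.0 / 0.092), 1.5)   # ~33 px long
  expect_lt(abs(ax[2] - 1.26 / 0.092), 1.5)  # ~14 px wide
})

test_that("empty and degenerate image specs behave", {
  blank <- render_cells(image_spec(n_cells = 0L, shape = c(64L, 64L), seed = 1))
  expect_equal(nrow(blank$truth), 0L)
  expect_true(all(blank$mask == 0L))
  expect_true(all(abs(as.numeric(blank$image) - 800) < 800))  # noise only
  # over-dense placement fails with a clear error
  expect_error(
    render_cells(image_spec(n_cells = 200L, shape = c(64L, 64L), seed = 1)),
    "density")
  # sub-resolution beads warn
  expect_warning(
    render_beads(image_spec(n_cells = 1L, shape = c(64L, 64L),
                            bead_diameter_um = 0.1, seed = 1)),
    "resolvable")
})

test_that("bead renderer produces the requested number of disks", {
  out <- render_beads(image_spec(n_cells = 15L, shape = c(800L, 800L),
                                 bead_diameter_um = 7, seed = 3))
  expect_equal(nrow(out$truth), 15L)
  expect_true(all(out$truth$diameter_um == 7))
  expect_equal(length(unique(out$mask[out$mask > 0])), 15L)
})

test_that("event counts are Poisson in the analyzed volume", {
  # ~30000 cells at the protocol's working concentration and draw volume
  ev <- generate_events(event_spec(true_cell_conc_per_ml = 1e6,
                                   analyzed_volume_ul = 30, seed = 10))
  n_cells <- sum(ev$truth$class == "cell")
  expect_lt(abs(n_cells - 30000) / 30000, 0.05)
  # variance/mean over 100 seeds at a small count (cheap, same law)
  counts <- vapply(1:100, function(s) {
    sum(generate_events(event_spec(true_cell_conc_per_ml = 2e4,
                                   analyzed_volume_ul = 10,
                                   seed = s))$truth$class == "cell")
  }, numeric(1))
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("event table edge cases", {
  ev0 <- generate_events(event_spec(true_cell_conc_per_ml = 0, seed = 1))
  expect_equal(sum(ev0$truth$class == "cell"), 0L)
  expect_error(generate_events(event_spec(true_cell_conc_per_ml = 1e12)),
               "1e7")
  expect_error(event_spec(analyzed_volume_ul = 500, tube_volume_ul = 400))
})

test_that("OD pair generator is monotone and honors its preconditions", {
  id <- generate_od_pairs(10, device_model = list(type = "identity",
                                                  noise_cv = 0), seed = 1)
  expect_equal(id$od_device, id$od_true)
  sat <- generate_od_pairs(20, seed = 2)
  expect_true(all(diff(sat$od_device) >= 0))
  expect_true(all(diff(sat$od_true) > 0))
  # saturating model compresses the upper decade
  high <- sat$od_true > 1
  expect_true(all(sat$od_device[high] < sat$od_true[high]))
  expect_error(generate_od_pairs(2), "at least 3")
  expect_error(
    generate_od_pairs(10, device_model = list(fn = function(x) -x)),
    "monotone")
})

test_that("omics generator truth follows from the printed factors", {
  out <- generate_omics_table(1, "glucose", amount_range = c(1e-9, 1e-9),
                              seed = 1)
  expect_equal(out$omics$amount_per_ml_od, 1e-9)
  expect_equal(out$truth$copies_per_cell,
               1e-9 * od_constants()$avogadro / REF_N_GLUCOSE,
               tolerance = 1e-12)
  expect_equal(out$truth$copies_per_cell, 5.43e5, tolerance = 0.01)
  expect_equal(out$truth$conc_molar, 1e-9 / (REF_VTOT_GLUCOSE * 1e-6))
  empty <- generate_omics_table(0, "glucose")
  expect_equal(nrow(empty$omics), 0L)
  expect_error(generate_omics_table(3, "maltose"), "unknown condition")
})
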