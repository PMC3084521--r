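test_that("intensity images integrate decay gates and subtract background", {
  z <- time_gated_stack(array(0, c(7, 3, 3)), test_schedule())
  expect_equal(intensity_image(z), matrix(0, 3, 3))
  one <- time_gated_stack(array(1, c(1, 3, 3)),
                          gate_schedule(0, 100, Inf))
  expect_equal(intensity_image(one), matrix(1, 3, 3))
  ## matches the direct gate-sum oracle, offset gate removed
  st <- quick_stack(2400, photons = 400, dims = c(6, 6), seed = 21, Z = 3)
  di <- which(st$schedule$roles == "decay")
  oi <- which(st$schedule$roles == "offset")
  oracle <- apply(st$counts[di, , ], c(2, 3), sum) -
    length(di) * st$counts[oi, , ]
  expect_equal(intensity_image(st), pmax(oracle, 0))
})

test_that("threshold masks use a strict comparison", {
  img <- matrix(c(50, 100, 150, 99, 101, 100, 200, 0, 100), 3, 3)
  expect_equal(sum(threshold_mask(img, 100)), 3)
  expect_true(all(threshold_mask(img + 1, 0)))
  expect_false(any(threshold_mask(img, Inf)))
})

test_that("prescan selects fields in order and flags shortfalls", {
  fields <- lapply(c(0.1, 0.3, 0.5), function(f) {
    m <- matrix(0, 10, 10); m[seq_len(100 * f)] <- 10; m
  })
  r <- prescan_select(fields, threshold = 5, min_fraction = 0.25,
                      n_required = 1)
  expect_equal(r$selected, 2L)
  expect_true(r$sufficient)
  r2 <- prescan_select(fields, 5, 0.25, 5)
  expect_equal(r2$selected, c(2L, 3L))
  expect_false(r2$sufficient)
  r3 <- prescan_select(fields, 5, 0, 2)
  expect_equal(r3$selected, c(1L, 2L))
  ## n_required = Inf returns exactly the qualifying subset
  r4 <- prescan_select(fields, 5, 0.25, Inf)
  expect_equal(r4$selected, c(2L, 3L))
  expect_true(r4$sufficient)
})

test_that("motion check is zero for duplicated frames and detects shifts", {
  st <- quick_stack(2500, photons = 600, dims = c(16, 16), seed = 22)
  mi <- which(st$schedule$roles == "motion_check")
  pi <- which(st$schedule$roles == "decay" &
                abs(st$schedule$delays - st$schedule$delays[mi]) < 1e-9)
  ## duplicated frame
  st$counts[mi, , ] <- st$counts[pi, , ]
  expect_equal(motion_check(st)$metric, 0)
  expect_true(motion_check(st)$pass)
  ## frame shifted by 5 px
  st2 <- st
  st2$counts[mi, , ] <- st$counts[pi, c(6:16, 1:5), ]
  expect_gt(motion_check(st2)$metric, 0)
  ## independent Poisson re-realisation stays near the shot-noise floor
  st3 <- quick_stack(2500, photons = 600, dims = c(16, 16), seed = 23)
  st$counts[mi, , ] <- st3$counts[pi, , ]
  mc <- motion_check(st, rel_tolerance = 0.2)
  expect_true(mc$pass)
  expect_gt(mc$metric, 0)
  ## error without a motion-check gate
  plain <- time_gated_stack(array(1, c(1, 2, 2)), gate_schedule(0, 100, Inf))
  expect_error(motion_check(plain), "motion_check")
})

test_that("well aggregation pools pixels without field weighting", {
  c1 <- matrix(2500, 4, 4)
  s <- aggregate_well(list(c1), "A1")
  expect_equal(s$mean_tau, 2500); expect_equal(s$sd_tau, 0)
  expect_equal(s$n_pixels, 16L)
  expect_equal(sum(s$histogram$counts), s$n_pixels)
  s2 <- aggregate_well(list(matrix(2000, 4, 4), matrix(3000, 4, 4)), "A2")
  expect_equal(s2$mean_tau, 2500)
  ## pooled equals concatenate-then-summarise
  set.seed(24)
  f1 <- matrix(stats::rnorm(16, 2500, 50), 4)
  f2 <- matrix(stats::rnorm(8, 2600, 50), 2)
  s3 <- aggregate_well(list(f1, f2), "A3")
  expect_equal(s3$mean_tau, mean(c(f1, f2)))
  expect_equal(s3$sd_tau, stats::sd(c(f1, f2)))
  ## all-NA input marks the well empty
  expect_true(aggregate_well(list(matrix(NA_real_, 2, 2)), "A4")$empty)
})

test_that("plate maps carry missing wells and ignore input order", {
  lay <- plate_layout(2, 2)
  ss <- list(aggregate_well(list(matrix(2000, 2, 2)), "A1"),
             aggregate_well(list(matrix(2500, 2, 2)), "A2"),
             aggregate_well(list(matrix(3000, 2, 2)), "B2"))
  m <- plate_map(lay, ss)
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["B", "1"]))
  expect_equal(m["A", "1"], 2000)
  m2 <- plate_map(lay, rev(ss))
  expect_equal(m, m2)
  bad <- list(aggregate_well(list(matrix(1, 2, 2)), "Z9"))
  expect_error(plate_map(lay, bad), "unknown well")
})

test_that("per-ROI analysis conserves photons over a partition", {
  st <- quick_stack(2400, photons = 500, dims = c(10, 10), seed = 25)
  labels <- matrix(rep(1:4, each = 25), 10, 10)
  tab <- per_roi_analysis(st, labels, opts = fit_options(min_photons = 0))
  di <- which(st$schedule$roles == "decay")
  expect_equal(sum(tab$n_photons), sum(st$counts[di, , ]))
  ## a single label covering the image equals the whole-image binned fit
  whole <- per_roi_analysis(st, matrix(1L, 10, 10),
                            opts = fit_options(min_photons = 0))
  f <- fit_binned_roi(st, matrix(TRUE, 10, 10), 1, irf_delta(),
                      fit_options(min_photons = 0))
  expect_equal(whole$tau, mean_lifetime(f$model), tolerance = 1e-9)
  expect_error(per_roi_analysis(st, matrix(0L, 10, 10)), "label")
})

test_that("membrane ROIs report shorter lifetimes than cytosol ROIs", {
  fld <- make_fret_cell_field(n_cells = 4, dims = c(48, 48),
                              photons = 400, seed = 26)
  o <- fit_options(min_photons = 0)
  mem <- per_roi_analysis(fld$stack, fld$membrane_mask, opts = o)
  cyt <- per_roi_analysis(fld$stack, fld$cytosol_mask, opts = o)
  expect_lt(mean(mem$tau), mean(cyt$tau))
})

test_that("plate layout round-trips through CSV and JSON", {
  d <- withr::local_tempdir()
  lay <- plate_layout(8, 12, conditions = rep(c("a", "b"), each = 48),
                      fields_per_well = 3)
  write_plate_layout(lay, file.path(d, "layout.csv"))
  l2 <- read_plate_layout(file.path(d, "layout.csv"), fields_per_well = 3)
  expect_equal(l2$well_conditions, lay$well_conditions)
  expect_equal(l2$rows, 8L); expect_equal(l2$cols, 12L)
  write_plate_layout(lay, file.path(d, "layout.json"))
  l3 <- read_plate_layout(file.path(d, "layout.json"))
  expect_equal(l3$well_conditions, lay$well_conditions)
  expect_equal(l3$fields_per_well, 3L)
})
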