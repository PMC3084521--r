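opts0 <- fit_options(min_photons = 0)

test_that("noiseless mono-exponential data are inverted exactly", {
  sch <- test_schedule()
  for (irf in list(irf_delta(), irf_gaussian(150, t0 = 50))) {
    y <- forward_counts(decay_model(2500, 1, I0 = 100, Z = 5), sch, irf)
    f <- fit_mono_pixel(y, sch, irf, opts0)
    expect_equal(coef(f)[["tau1"]], 2500, tolerance = 1e-6)
    expect_equal(coef(f)[["I0"]], 100, tolerance = 1e-6)
    expect_equal(coef(f)[["Z"]], 5, tolerance = 1e-6)
    expect_true(f$converged)
  }
})

test_that("lifetimes much shorter than the gate width are recovered", {
  sch <- test_schedule()
  y <- forward_counts(decay_model(600, 1, I0 = 300, Z = 1), sch,
                      irf_delta())
  f <- fit_mono_pixel(y, sch, irf_delta(), opts0)
  expect_equal(coef(f)[["tau1"]], 600, tolerance = 1e-6)
})

test_that("mono fits at the 300-photon budget are accurate in the median", {
  st <- quick_stack(2500, photons = 300, dims = c(32, 32), seed = 11)
  im <- fit_image_per_pixel(st, opts = fit_options(min_photons = 1))
  expect_equal(stats::median(im$tau, na.rm = TRUE), 2500,
               tolerance = 0.02)
})

test_that("two fixed lifetimes reduce to an exact linear solve", {
  sch <- test_schedule()
  y <- forward_counts(decay_model(c(3000, 1000), c(0.7, 0.3), I0 = 50,
                                  Z = 2), sch, irf_delta())
  o <- fit_options(min_photons = 0, fixed_taus = c("1" = 3000, "2" = 1000))
  f <- fit_multi_pixel(y, sch, irf_delta(), 2, o)
  expect_equal(f$model$alphas, c(0.7, 0.3), tolerance = 1e-9)
  expect_equal(f$model$I0, 50, tolerance = 1e-9)
  expect_true(all(f$tau_fixed))
})

test_that("free double-exponential fits invert noiseless mixtures", {
  sch <- test_schedule()
  y <- forward_counts(decay_model(c(2516, 1068), c(0.53, 0.47), I0 = 500,
                                  Z = 2), sch, irf_gaussian(150))
  f <- fit_multi_pixel(y, sch, irf_gaussian(150), 2, opts0)
  expect_equal(f$model$taus, c(2516, 1068), tolerance = 1e-4)
  expect_equal(f$model$alphas, c(0.53, 0.47), tolerance = 1e-4)
})

test_that("a vanishing second component is not invented", {
  sch <- test_schedule()
  o <- fit_options(min_photons = 0, fixed_taus = c("1" = 2516, "2" = 1068))
  a2 <- replicate(200, {
    y <- forward_counts(decay_model(2516, 1, I0 = 1, Z = 0), sch,
                        irf_delta())
    yc <- y / sum(y[1:5]) * 1e4
    f <- fit_multi_pixel(stats::rpois(length(yc), yc), sch, irf_delta(),
                         2, o)
    if (f$model$n_components == 2L) f$model$alphas[2L] else 0
  })
  expect_lte(mean(a2), 0.02)
})

test_that("solve_linear_amplitudes matches dense linear algebra", {
  ## orthogonal toy = normal-equation hand solve
  B <- cbind(c(2, 0), c(0, 3))
  s <- solve_linear_amplitudes(B, c(4, 9), c(1, 1))
  expect_equal(s$coef, c(2, 3))
  ## random 7x3 against pseudo-inverse (positive solutions)
  set.seed(3)
  for (i in 1:20) {
    B <- matrix(stats::runif(21, 0.1, 2), 7, 3)
    xt <- stats::runif(3, 0.5, 2)
    y <- drop(B %*% xt) + stats::rnorm(7, 0, 1e-3)
    w <- stats::runif(7, 0.5, 2)
    s <- solve_linear_amplitudes(B, y, w)
    expect_equal(s$coef, dense_wls(B, y, w), tolerance = 1e-10)
    expect_equal(s$chi2, sum(w * (y - drop(B %*% s$coef))^2),
                 tolerance = 1e-12)
  }
  ## negative unconstrained optimum is clipped to the boundary
  B <- cbind(c(1, 1), c(1, 1.01))
  s <- solve_linear_amplitudes(B, c(1, -2), c(1, 1))
  expect_true(all(s$coef >= 0))
  ## duplicate lifetimes give a degenerate basis
  expect_error(solve_linear_amplitudes(cbind(1:3, 1:3), c(1, 2, 3),
                                       rep(1, 3)), "degenerate")
})

test_that("per-pixel image fits resolve spatial lifetime structure", {
  tau_map <- cbind(matrix(2000, 24, 12), matrix(2600, 24, 12))
  sc <- sim_scenario(taus = list(tau_map), alphas = 1,
                     photons_per_pixel = 1000, seed = 4)
  im <- fit_image_per_pixel(simulate_stack(sc)$stack,
                            opts = fit_options(min_photons = 1))
  expect_equal(mean(im$tau[, 1:12]), 2000, tolerance = 0.02)
  expect_equal(mean(im$tau[, 13:24]), 2600, tolerance = 0.02)
  ## all-zero stack is fully masked
  z <- time_gated_stack(array(0, c(7, 4, 4)), test_schedule())
  expect_warning(imz <- fit_image_per_pixel(z), "masked")
  expect_true(all(is.na(imz$tau)))
  expect_false(any(imz$mask))
})

test_that("reported chi2 is recomputable from the returned parameters", {
  sch <- test_schedule()
  st <- quick_stack(c(2516, 1068), c(0.6, 0.4), dims = c(6, 6),
                    photons = 2000, seed = 5)
  y <- st$counts[, 2, 3]
  f <- fit_multi_pixel(y, sch, irf_delta(), 2, opts0)
  mu <- fitted(f)[f$rows]
  expect_equal(f$chi2, sum(f$weights * (y[f$rows] - mu)^2),
               tolerance = 1e-9)
})

test_that("global fit equals the single-pixel fit on one pixel", {
  sch <- test_schedule()
  st <- quick_stack(c(2516, 1068), c(0.6, 0.4), dims = c(1, 1),
                    photons = 5000, seed = 6)
  o <- fit_options(min_photons = 0, fixed_taus = c("1" = 2516))
  g <- varpro_global_fit(st, 2, irf_delta(), o)
  f <- fit_multi_pixel(st$counts[, 1, 1], sch, irf_delta(), 2, o)
  expect_equal(g$taus, f$model$taus, tolerance = 1e-4)
  expect_equal(g$chi2_global, f$chi2, tolerance = 1e-6)
})

test_that("variable projection attains the full simultaneous optimum", {
  sch <- test_schedule()
  st <- quick_stack(c(2700, 900), c(0.55, 0.45), dims = c(8, 8),
                    photons = 10000, seed = 7, Z = 20)
  o <- fit_options(min_photons = 0, n_reweight = 0)
  g <- varpro_global_fit(st, 2, irf_delta(), o)
  ## solution is strictly interior, so the unconstrained oracle is comparable
  expect_true(all(g$Z_maps[[1]] > 0) && all(g$alpha_maps[[1]] > 0))
  Y <- matrix(st$counts, nrow = 7)[flimgate:::fit_rows(sch, o), ]
  W <- 1 / pmax(Y, 1)
  bf <- brute_force_global(Y, W, sch, irf_delta(),
                           start_taus = c(2700, 900))
  expect_equal(g$chi2_global, bf$chi2, tolerance = 1e-6)
  expect_lt(max(abs(g$taus - bf$taus)), 0.1)
})

test_that("global results are invariant to pixel order", {
  sch <- test_schedule()
  st <- quick_stack(c(2516, 1068), c(0.7, 0.3), dims = c(6, 6),
                    photons = 800, seed = 8)
  o <- fit_options(min_photons = 0, fixed_taus = c("1" = 2516))
  g1 <- varpro_global_fit(st, 2, irf_delta(), o)
  set.seed(9); perm <- sample(36)
  m <- matrix(st$counts, nrow = 7)[, perm]
  st2 <- time_gated_stack(array(m, c(7, 6, 6)), sch)
  g2 <- varpro_global_fit(st2, 2, irf_delta(), o)
  expect_equal(g1$taus, g2$taus, tolerance = 1e-9)
  expect_equal(g1$chi2_global, g2$chi2_global, tolerance = 1e-9)
})

test_that("binned ROI fits sum the masked decay", {
  st <- quick_stack(2300, photons = 500, dims = c(5, 5), seed = 10)
  mask1 <- matrix(FALSE, 5, 5); mask1[2, 3] <- TRUE
  f1 <- fit_binned_roi(st, mask1, 1, irf_delta(), opts0)
  fp <- fit_mono_pixel(st$counts[, 2, 3], st$schedule, irf_delta(), opts0)
  expect_equal(coef(f1), coef(fp), tolerance = 1e-9)
  ## additivity of the binned decays over disjoint masks
  maskA <- matrix(FALSE, 5, 5); maskA[1:2, ] <- TRUE
  maskB <- matrix(FALSE, 5, 5); maskB[4:5, ] <- TRUE
  yA <- rowSums(matrix(st$counts, nrow = 7)[, as.vector(maskA)])
  yB <- rowSums(matrix(st$counts, nrow = 7)[, as.vector(maskB)])
  yAB <- rowSums(matrix(st$counts, nrow = 7)[, as.vector(maskA | maskB)])
  expect_identical(yA + yB, yAB)
  expect_error(fit_binned_roi(st, matrix(FALSE, 5, 5)), "empty")
})

test_that("lifetime-linked series fits share lifetimes but not fractions", {
  base <- sim_scenario(taus = c(3139, 588), alphas = c(0.8, 0.2),
                       dims = c(16, 16), photons_per_pixel = 500, seed = 12)
  ser <- make_series(base, c(0.2, 0.5, 0.8))
  f <- linked_series_fit(ser$stacks, "linked_lifetimes",
                         opts = fit_options(min_photons = 0))
  expect_equal(f$taus, c(3139, 588), tolerance = 0.05)
  a2 <- vapply(f$per_timepoint, function(p) p$mean_alpha2, 0)
  expect_true(all(diff(a2) > 0))
  expect_equal(a2, c(0.2, 0.5, 0.8), tolerance = 0.1)
})

test_that("identical timepoints give identical per-timepoint results", {
  st <- quick_stack(c(3139, 588), c(0.6, 0.4), dims = c(8, 8),
                    photons = 800, seed = 13)
  f <- linked_series_fit(list(st, st), "linked_lifetimes",
                         opts = fit_options(min_photons = 0))
  expect_equal(f$per_timepoint[[1L]]$mean_alpha2,
               f$per_timepoint[[2L]]$mean_alpha2, tolerance = 1e-9)
  expect_equal(f$per_timepoint[[1L]]$chi2, f$per_timepoint[[2L]]$chi2,
               tolerance = 1e-6)
})

test_that("ratio-linked fits match unlinked fits on ratio-constant truth", {
  base <- sim_scenario(taus = c(3139, 588), alphas = c(0.6, 0.4),
                       dims = c(12, 12), photons_per_pixel = 800, seed = 14)
  ser <- make_series(base, c(0.4, 0.4, 0.4))
  o <- fit_options(min_photons = 0)
  fr <- linked_series_fit(ser$stacks, "linked_ratio", opts = o)
  expect_equal(fr$alphas[2L], 0.4, tolerance = 0.05)
  ## unlinked comparator: the same model with the ratio free per timepoint
  ## (fitting each timepoint paired with itself shares the ratio trivially)
  chi_unlinked <- sum(vapply(ser$stacks, function(s)
    linked_series_fit(list(s, s), "linked_ratio", opts = o)$chi2_total / 2,
    0))
  expect_lt(abs(fr$chi2_total - chi_unlinked) / chi_unlinked, 0.01)
})

test_that("fit preconditions are enforced", {
  sch3 <- gate_schedule(c(0, 1000, 3000), width = 1500, rep_period = Inf)
  y <- forward_counts(decay_model(2000, 1, I0 = 100), sch3, irf_delta())
  expect_silent(fit_mono_pixel(y, sch3, irf_delta(), opts0))
  expect_error(fit_multi_pixel(y, sch3, irf_delta(), 2, opts0),
               "decay gates")
  expect_error(fit_mono_pixel(c(1, 1, 1), sch3, irf_delta(),
                              fit_options(min_photons = 300)),
               "min_photons")
  expect_error(fit_multi_pixel(rep(100, 7), test_schedule(), irf_delta(), 2,
                               fit_options(fixed_taus = c("3" = 100))),
               "out of range")
})
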