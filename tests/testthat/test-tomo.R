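disc_plane <- function(n = 48, frac = 0.3) {
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - ctr, n, n)
  list(img = ifelse(xs^2 + ys^2 <= (frac * n)^2, 1, 0),
       r2 = xs^2 + ys^2, n = n)
}

test_that("forward projection respects Radon geometry", {
  d <- disc_plane()
  ang <- seq(0, 350, by = 10)
  sino <- forward_project(d$img, ang)
  ## centred disc: angle-independent sinogram (up to pixelisation jaggies)
  expect_lt(max(apply(sino, 2, stats::sd)) / max(sino), 0.03)
  expect_lt(stats::sd(rowSums(sino)) / mean(rowSums(sino)), 1e-3)
  ## zero plane maps to zero sinogram
  expect_equal(forward_project(matrix(0, 16, 16), ang),
               matrix(0, length(ang), 16))
  ## a single off-centre point traces a sinusoid across the detector
  n <- 33; pt <- matrix(0, n, n); pt[17 + 8, 17] <- 1
  ang2 <- seq(0, 359, by = 1)
  s2 <- forward_project(pt, ang2)
  peak <- apply(s2, 1, which.max)
  th <- ang2 * pi / 180
  expected <- 17 + 8 * sin(th)
  expect_lt(max(abs(peak - expected)), 1.6)
  ## parallel-beam symmetry: theta + 180 mirrors the detector axis
  expect_equal(s2[1, ], rev(s2[181, ]), tolerance = 1e-9)
  expect_error(forward_project(matrix(0, 3, 4), ang), "square")
})

test_that("filtered back-projection inverts the projection", {
  d <- disc_plane(n = 64)
  ang <- seq(0, 359, by = 1)
  rec <- fbp_reconstruct(forward_project(d$img, ang), ang)
  interior <- d$r2 <= (0.3 * d$n - 2)^2
  expect_lt(sqrt(mean((rec[interior] - 1)^2)), 0.05)
  ## linearity
  set.seed(51)
  a <- matrix(stats::runif(64^2), 64); b <- matrix(stats::runif(64^2), 64)
  sa <- forward_project(a, ang[1:40]); sb <- forward_project(b, ang[1:40])
  expect_equal(fbp_reconstruct(sa + sb, ang[1:40]),
               fbp_reconstruct(sa, ang[1:40]) +
                 fbp_reconstruct(sb, ang[1:40]), tolerance = 1e-9)
  expect_error(fbp_reconstruct(sa, ang), "angles")
})

test_that("round-trip fidelity improves with the number of angles", {
  d <- disc_plane(n = 48)
  interior <- d$r2 <= (0.3 * d$n - 2)^2
  err <- vapply(c(30, 90, 360), function(k) {
    ang <- seq(0, 360 - 360 / k, by = 360 / k)
    rec <- fbp_reconstruct(forward_project(d$img, ang), ang)
    sqrt(mean((rec[interior] - 1)^2))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("unfiltered back-projection blurs but keeps the peak location", {
  n <- 33; pt <- matrix(0, n, n); pt[21, 13] <- 1
  ang <- seq(0, 359, by = 3)
  rec <- fbp_reconstruct(forward_project(pt, ang), ang, filter = "none")
  expect_equal(which(rec == max(rec), arr.ind = TRUE)[1, ],
               c(row = 21, col = 13))
  ## energy spreads: peak far below a filtered reconstruction's
  recf <- fbp_reconstruct(forward_project(pt, ang), ang)
  expect_lt(max(rec) / sum(rec), max(recf) / sum(abs(recf)))
})

test_that("two-well phantoms reconstruct their lifetime contrast", {
  ph <- make_well_phantom(tau_a = 2550, tau_b = 2000, n = 48, nz = 1,
                          angles = seq(0, 358, by = 2), photons = 300,
                          seed = 52)
  v <- tomo_flim(ph$series)
  ## interior well means (eroding the partial-volume rim)
  shrink <- function(mask) {
    m <- mask
    m[c(1, nrow(m)), ] <- FALSE; m[, c(1, ncol(m))] <- FALSE
    er <- m
    for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1))
      er[i, j] <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])
    er
  }
  ta <- mean(v$tau[, , 1][shrink(ph$truth$well_a)], na.rm = TRUE)
  tb <- mean(v$tau[, , 1][shrink(ph$truth$well_b)], na.rm = TRUE)
  expect_equal(ta - tb, 550, tolerance = 0.1 * 550 / 550)
  expect_equal((ta - tb) / 550, 1, tolerance = 0.1)
  ## equal-lifetime wells give no contrast
  ph0 <- make_well_phantom(tau_a = 2200, tau_b = 2200, n = 48, nz = 1,
                           angles = seq(0, 358, by = 2), photons = 300,
                           seed = 53)
  v0 <- tomo_flim(ph0$series)
  t0a <- mean(v0$tau[, , 1][shrink(ph0$truth$well_a)], na.rm = TRUE)
  t0b <- mean(v0$tau[, , 1][shrink(ph0$truth$well_b)], na.rm = TRUE)
  expect_lt(abs(t0a - t0b), 0.03 * 2200)
  ## background voxels are masked
  expect_false(any(v$mask[!ph$truth$intensity_map > 0]))
  ## zero photon budget propagates to an all-zero series
  phz <- make_well_phantom(photons = 0, n = 32, nz = 1,
                           angles = seq(0, 350, by = 10))
  expect_true(all(phz$series$data == 0))
})

test_that("lifetimes are invariant to projection intensity scaling", {
  ph <- make_well_phantom(n = 40, nz = 1, angles = seq(0, 355, by = 5),
                          photons = 100, noise = FALSE)
  v1 <- tomo_flim(ph$series)
  sc <- ph$series; sc$data <- sc$data * 7.3
  v2 <- tomo_flim(sc)
  expect_equal(v1$tau, v2$tau, tolerance = 1e-6)
})

test_that("homogeneous phantoms reconstruct their lifetime to 2%", {
  ph <- make_well_phantom(tau_a = 2400, tau_b = 2400, slab_tau = 2400,
                          slab_intensity = 1, n = 40, nz = 1,
                          angles = seq(0, 357, by = 3), photons = 500,
                          seed = 54)
  v <- tomo_flim(ph$series)
  inside <- ph$truth$intensity_map > 0 & v$mask[, , 1]
  expect_equal(mean(v$tau[, , 1][inside], na.rm = TRUE), 2400,
               tolerance = 0.02)
})
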