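test_that("delta-IRF gate integrals match the analytic boxcar integral", {
  sch1 <- gate_schedule(0, width = 2000, rep_period = Inf)
  expect_equal(decay_basis(2000, sch1, irf_delta()),
               2000 * (1 - exp(-1)), tolerance = 1e-9)
  sch2 <- gate_schedule(2000, width = 2000, rep_period = Inf)
  expect_equal(decay_basis(2000, sch2, irf_delta()),
               exp(-1) * 2000 * (1 - exp(-1)), tolerance = 1e-9)
  ## general positions and lifetimes
  for (tau in c(350, 1068, 2516, 9000)) {
    sch <- gate_schedule(c(0, 700, 1800, 4100), width = 1300,
                         rep_period = Inf)
    a <- c(0, 700, 1800, 4100)
    expect_equal(decay_basis(tau, sch),
                 tau * (exp(-a / tau) - exp(-(a + 1300) / tau)),
                 tolerance = 1e-9)
  }
})

test_that("gaussian-IRF gate integrals match brute-force quadrature", {
  sch <- gate_schedule(seq(0, 6000, by = 1000), width = 2000,
                       rep_period = Inf)
  b <- decay_basis(2500, sch, irf_gaussian(200))
  oracle <- vapply(seq(0, 6000, by = 1000), function(d)
    quad_gate_gaussian(2500, d, d + 2000, fwhm = 200), 0)
  expect_equal(b, oracle, tolerance = 1e-6)
})

test_that("measured-IRF response is the weighted sum of shifted responses", {
  tt <- c(-100, 0, 100, 200); wt <- c(0.1, 0.4, 0.3, 0.2)
  irf <- irf_measured(tt, wt)
  sch <- gate_schedule(c(500, 2500), width = 2000, rep_period = Inf)
  manual <- rowSums(vapply(seq_along(tt), function(j)
    wt[j] * decay_basis(1800, sch, irf_delta(t0 = tt[j])),
    numeric(2)))
  expect_equal(decay_basis(1800, sch, irf), manual, tolerance = 1e-12)
})

test_that("steady-state incomplete-decay factor has its closed form", {
  expect_equal(steady_state_factor(3000, 16666.7),
               1 / (1 - exp(-16666.7 / 3000)), tolerance = 1e-12)
  expect_equal(round(steady_state_factor(3000, 16666.7), 5), 1.00388)
  expect_equal(steady_state_factor(1, 16666.7), 1.0, tolerance = 1e-9)
  expect_equal(steady_state_factor(16666.7, 16666.7),
               1 / (1 - exp(-1)), tolerance = 1e-12)
  expect_error(steady_state_factor(-1, 100), "positive")
})

test_that("periodic gating conserves emitted photons over one period", {
  T <- 1e6 / 60
  for (tau in c(700, 3000, 12000)) {
    edges <- seq(0, T, length.out = 9)
    sch <- gate_schedule(edges[-9], width = diff(edges)[1],
                         rep_period = T)
    expect_equal(sum(decay_basis(tau, sch)), tau, tolerance = 1e-9)
  }
})

test_that("gates wrapping past the repetition period pick up the next pulse", {
  T <- 16666.7; tau <- 3000
  sch <- gate_schedule(15500, width = 2000, rep_period = T)
  s <- steady_state_factor(tau, T)
  manual <- s * tau * ((exp(-15500 / tau) - exp(-T / tau)) +
                       (1 - exp(-(17500 - T) / tau)))
  expect_equal(decay_basis(tau, sch), manual, tolerance = 1e-9)
})

test_that("basis values decrease strictly with gate delay", {
  sch <- test_schedule()
  for (irf in list(irf_delta(), irf_gaussian(250, t0 = 100)))
    expect_true(all(diff(decay_basis(2300, sch, irf)) < 0))
})

test_that("forward_counts is linear and respects gate roles", {
  sch <- test_schedule()
  irf <- irf_gaussian(150)
  m1 <- decay_model(2516, 1, I0 = 7, Z = 0.5)
  m2 <- decay_model(1068, 1, I0 = 3, Z = 1.1)
  mix <- decay_model(c(2516, 1068), c(0.7, 0.3), I0 = 10, Z = 1.6)
  f1 <- forward_counts(m1, sch, irf); f2 <- forward_counts(m2, sch, irf)
  expect_equal(forward_counts(mix, sch, irf), f1 + f2, tolerance = 1e-9)
  ## offset gate carries Z only; motion gate duplicates its partner
  oi <- which(sch$roles == "offset"); mi <- which(sch$roles == "motion_check")
  expect_equal(f1[oi], 0.5)
  expect_equal(f1[mi], f1[which(sch$roles == "decay" &
                                  abs(sch$delays - sch$delays[mi]) < 1e-9)])
  ## two equal-lifetime components collapse to one
  ma <- decay_model(2000, 1, I0 = 5)
  suppressWarnings(
    mb <- decay_model(c(2000, 2000 + 1e-12), c(0.5, 0.5), I0 = 5))
  expect_equal(forward_counts(mb, sch, irf), forward_counts(ma, sch, irf),
               tolerance = 1e-9)
})

test_that("two-component forward counts are the amplitude-weighted bases", {
  sch <- test_schedule(); irf <- irf_delta()
  fc <- forward_counts(decay_model(c(2516, 1068), c(0.53, 0.47)), sch, irf)
  di <- which(sch$roles == "decay")
  expect_equal(fc[di],
               0.53 * decay_basis(2516, sch, irf) +
                 0.47 * decay_basis(1068, sch, irf), tolerance = 1e-12)
})

test_that("mean lifetime conventions", {
  expect_equal(mean_lifetime(decay_model(2516, 1)), 2516)
  expect_equal(mean_lifetime(decay_model(c(3000, 1000), c(0.5, 0.5))), 2000)
  expect_equal(mean_lifetime(decay_model(c(2516, 1068), c(0.90, 0.10))),
               2371.2)
  expect_equal(mean_lifetime(decay_model(c(3000, 1000), c(0.5, 0.5)),
                             "intensity"),
               (0.5 * 3000^2 + 0.5 * 1000^2) / 2000)
})

test_that("decay model enforces its invariants and canonical order", {
  m <- decay_model(c(1068, 2516), c(0.47, 0.53))
  expect_equal(m$taus, c(2516, 1068))
  expect_equal(m$alphas, c(0.53, 0.47))
  expect_error(decay_model(c(2000, -1), c(0.5, 0.5)), "positive")
  expect_error(decay_model(c(2000, 1000), c(0.8, 0.4)), "sum to 1")
  expect_error(decay_model(2000, 1.5), "sum to 1|\\[0, 1\\]")
})

test_that("gate schedule validation", {
  expect_error(gate_schedule(c(0, 0), width = 100, rep_period = Inf),
               "distinct")
  expect_error(gate_schedule(c(0, 100), width = 100,
                             roles = c("offset", "offset")),
               "offset")
  expect_error(gate_schedule(0, width = 100, roles = "offset"),
               "decay gate")
  expect_error(gate_schedule(c(0, 100, 50), width = 100,
                             roles = c("decay", "decay", "motion_check")),
               "duplicate")
  expect_error(decay_basis(-5, test_schedule()), "positive")
  ## measured IRF sampled too coarsely for the gate width
  irf <- irf_measured(c(0, 400), c(0.5, 0.5))
  expect_error(decay_basis(2000, gate_schedule(0, width = 2000,
                                               rep_period = Inf), irf),
               "coarser")
})

test_that("schedule and IRF serialise through JSON and CSV", {
  d <- withr::local_tempdir()
  sch <- test_schedule()
  write_gate_schedule(sch, file.path(d, "sch.json"))
  sch2 <- read_gate_schedule(file.path(d, "sch.json"))
  expect_equal(sch2$delays, sch$delays)
  expect_equal(sch2$roles, sch$roles)
  expect_equal(sch2$rep_period, sch$rep_period)

  irf <- irf_gaussian(180, t0 = 40)
  write_irf(irf, file.path(d, "irf.json"))
  expect_equal(read_irf(file.path(d, "irf.json")), irf)

  mi <- irf_measured(c(-50, 0, 50), c(1, 2, 1))
  write_irf(mi, file.path(d, "irf.csv"))
  mi2 <- read_irf(file.path(d, "irf.csv"))
  expect_equal(mi2$time, mi$time)
  expect_equal(mi2$weight, mi$weight, tolerance = 1e-12)
})
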