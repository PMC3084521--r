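## Independent oracles used across the test suite.  These deliberately avoid
## the package's own closed forms: quadrature instead of antiderivatives,
## dense linear algebra instead of partitioned solves, all-parameter
## optimisation instead of variable projection.

## brute-force midpoint quadrature of the gated, IRF-convolved decay:
## c(t) = int_0^inf g(t - x) exp(-x/tau) dx, gate value = int_a^b c(t) dt
quad_gate_gaussian <- function(tau, a, b, fwhm, t0 = 0, dt = 1) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  x <- seq(dt / 2, 12 * tau, by = dt)
  tm <- seq(a + dt / 2, b - dt / 2, by = dt)
  vapply(tm, function(t)
    sum(stats::dnorm(t - x, t0, sig) * exp(-x / tau)) * dt, 0) |> sum() * dt
}

## dense weighted least squares via pseudo-inverse (no constraints)
dense_wls <- function(B, y, w) {
  sw <- sqrt(w)
  A <- B * sw
  as.numeric(solve(t(A) %*% A, t(A) %*% (y * sw)))
}

## all-parameter simultaneous NLLS on a small image: the lifetimes and every
## pixel's amplitudes/offset are optimised together (no projection step)
brute_force_global <- function(Y, W, schedule, irf, start_taus,
                               start_amps = NULL) {
  G <- nrow(Y); P <- ncol(Y)
  k <- length(start_taus)
  rows_decay <- seq_len(length(flimgate:::decay_gate_idx(schedule)))
  if (is.null(start_amps)) {
    B0 <- flimgate:::make_design(start_taus, schedule, irf,
                                 flimgate:::fit_rows(schedule, fit_options()))
    start_amps <- vapply(seq_len(P), function(p)
      dense_wls(B0, Y[, p], W[, p]), numeric(k + 1L))
  }
  par0 <- c(log(start_taus), as.vector(start_amps))
  sw <- sqrt(W)
  resid_fn <- function(par) {
    taus <- exp(par[seq_len(k)])
    X <- matrix(par[-seq_len(k)], k + 1L, P)
    B <- flimgate:::make_design(taus, schedule, irf,
                                flimgate:::fit_rows(schedule, fit_options()))
    as.vector((Y - B %*% X) * sw)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400, ftol = 1e-12, ptol = 1e-12))
  taus <- exp(fit$par[seq_len(k)])
  o <- order(-taus)
  list(taus = taus[o], chi2 = sum(resid_fn(fit$par)^2), info = fit$info)
}

## seven-gate schedule used widely in tests
test_schedule <- function(rep_period = 1e6 / 60)
  default_gate_schedule(rep_period = rep_period)

## quick uniform-truth stack
quick_stack <- function(taus, alphas = NULL, dims = c(16, 16),
                        photons = 300, seed = 1,
                        schedule = test_schedule(), irf = irf_delta(),
                        Z = 0) {
  simulate_stack(sim_scenario(taus = taus, alphas = alphas, dims = dims,
                              schedule = schedule, irf = irf,
                              photons_per_pixel = photons, Z = Z,
                              seed = seed))$stack
}
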