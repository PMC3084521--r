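#' Incomplete-decay steady-state factor
#'
#' At high pulse repetition rates a fluorophore whose lifetime is not short
#' compared with the repetition period \eqn{T} has not fully decayed when the
#' next excitation pulse arrives.  In the periodic steady state the observed
#' signal within one period is the single-pulse decay scaled by the geometric
#' pile-up factor
#' \deqn{s(\tau, T) = \frac{1}{1 - e^{-T/\tau}} \ge 1.}
#'
#' @param tau lifetime (ps), positive.
#' @param rep_period repetition period T (ps), positive (may be `Inf`).
#' @return The scalar factor (vectorised over `tau`).
#' @examples
#' steady_state_factor(3000, 1e6 / 60)   # ~1.00388
#' steady_state_factor(16666.7, 16666.7) # 1/(1 - exp(-1)) ~ 1.5820
#' @export
steady_state_factor <- function(tau, rep_period) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(rep_period <= 0)) stop("rep_period must be positive")
  1 / (1 - exp(-rep_period / tau))
}

## ---- closed-form single-pulse gated response -------------------------------
##
## c1(t) is the convolution of the IRF with a unit-amplitude one-sided
## exponential exp(-t/tau); C1(t) its antiderivative.  Gate values are
## differences of C1 at the gate edges, summed over excitation pulses
## k*T (exact periodic steady state; reproduces the geometric factor
## steady_state_factor() for gates inside one period and additionally
## handles gates that wrap past the period).

## antiderivative of exp(-(t-t0)/tau) * H(t-t0); vectorised over t or tau
C1_delta <- function(t, tau, t0) {
  tau * (1 - exp(-pmax(t - t0, 0) / tau))
}

## EMG: exp(sig^2/(2 tau^2) - x/tau) * Phi(x/sig - sig/tau), log-stable
c1_gauss <- function(t, tau, t0, sigma) {
  x <- t - t0
  exp(sigma^2 / (2 * tau^2) - x / tau +
      stats::pnorm(x / sigma - sigma / tau, log.p = TRUE))
}

C1_gauss <- function(t, tau, t0, sigma) {
  x <- t - t0
  tau * (stats::pnorm(x / sigma) - c1_gauss(t, tau, t0, sigma))
}

C1_irf <- function(t, tau, irf) {
  switch(irf$kind,
         delta = C1_delta(t, tau, irf$t0),
         gaussian = C1_gauss(t, tau, irf$t0, irf_sigma(irf)),
         measured = {
           v <- 0
           for (j in seq_along(irf$time))
             v <- v + irf$weight[j] * C1_delta(t, tau, irf$t0 + irf$time[j])
           v
         })
}

## earliest time at which c1 is non-negligible
irf_tmin <- function(irf) {
  switch(irf$kind,
         delta = irf$t0,
         gaussian = irf$t0 - 8 * irf_sigma(irf),
         measured = irf$t0 + min(irf$time))
}

## asymptotic (far past the IRF) antiderivative difference of c1 over [a, b]:
## exact once a is well beyond the IRF support
E_tail <- function(a, b, tau, irf) {
  switch(irf$kind,
         delta = {
           x <- a - irf$t0
           tau * exp(-x / tau) * (1 - exp(-(b - a) / tau))
         },
         gaussian = {
           s <- irf_sigma(irf)
           x <- a - irf$t0
           tau * exp(s^2 / (2 * tau^2) - x / tau) *
             (1 - exp(-(b - a) / tau))
         },
         measured = {
           v <- 0
           for (j in seq_along(irf$time)) {
             x <- a - irf$t0 - irf$time[j]
             v <- v + irf$weight[j] * tau * exp(-x / tau)
           }
           v * (1 - exp(-(b - a) / tau))
         })
}

## latest time of IRF support (beyond which c1 is purely exponential)
irf_tmax <- function(irf) {
  switch(irf$kind,
         delta = irf$t0,
         gaussian = irf$t0 + 8 * irf_sigma(irf),
         measured = irf$t0 + max(irf$time))
}

## gate integral of the periodic steady-state signal over [a, b];
## scalar gate edges, vectorised over tau.  The k = 0 pulse is evaluated
## from the closed-form antiderivative; earlier pulses (k >= 1) form an
## exact geometric tail once the shifted gate lies beyond the IRF support;
## later pulses (k < 0) arise only for gates wrapping past the period.
gate_integral_periodic <- function(tau, a, b, rep_period, irf) {
  v <- C1_irf(b, tau, irf) - C1_irf(a, tau, irf)
  if (is.infinite(rep_period)) return(v)
  tmax <- irf_tmax(irf)
  if (a + rep_period >= tmax + 1e-9) {
    ## all k >= 1 shifted gates are in the pure-exponential regime
    geo <- exp(-rep_period / tau) / (1 - exp(-rep_period / tau))
    v <- v + geo * E_tail(a, b, tau, irf)
  } else {
    kmax <- max(1, ceiling(32 * max(tau) / rep_period))
    for (k in seq_len(kmax)) {
      sh <- k * rep_period
      v <- v + (C1_irf(b + sh, tau, irf) - C1_irf(a + sh, tau, irf))
    }
  }
  ## wrapped gates: signal excited by the next pulse(s)
  tmin <- irf_tmin(irf)
  k <- -1L
  while (b + k * rep_period > tmin) {
    sh <- k * rep_period
    v <- v + (C1_irf(b + sh, tau, irf) - C1_irf(a + sh, tau, irf))
    k <- k - 1L
  }
  v
}

#' Per-gate response of a unit-amplitude exponential decay
#'
#' Computes, for every decay gate in the schedule, the boxcar integral over
#' the gate window of the IRF-convolved exponential \eqn{e^{-t/\tau}} in the
#' periodic steady state of the excitation source (which accounts exactly for
#' incomplete decays at the arrival of the next pulse).  Offset and
#' motion-check gates are excluded.  This is the column of the linear design
#' used by all fitting routines: the expected decay-gate signal of a full
#' model is \eqn{I_0 \sum_i \alpha_i} times these basis vectors plus Z.
#'
#' @param tau lifetime (ps), positive.
#' @param schedule a [gate_schedule()].
#' @param irf an IRF (see [irf_delta()]).
#' @return Numeric vector with one entry per decay gate (units ps, i.e.
#'   photons per unit I0).
#' @examples
#' sch <- gate_schedule(0, width = 2000, rep_period = Inf)
#' decay_basis(2000, sch, irf_delta())  # 2000 * (1 - exp(-1))
#' @export
decay_basis <- function(tau, schedule, irf = irf_delta()) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive lifetime")
  res <- irf_resolution(irf)
  if (res > schedule$width / 10)
    stop("measured IRF sampling (", res,
         " ps) is coarser than a tenth of the gate width")
  i <- decay_gate_idx(schedule)
  a <- schedule$delays[i]
  vapply(seq_along(a), function(g)
    gate_integral_periodic(tau, a[g], a[g] + schedule$width,
                           schedule$rep_period, irf), 0)
}

#' Expected per-gate counts of a decay model
#'
#' Evaluates the forward model for every gate in the schedule: decay gates
#' receive \eqn{I_0 \sum_i \alpha_i B_g(\tau_i) + Z}, the offset gate receives
#' the background \eqn{Z} alone, and a motion-check gate duplicates the
#' expectation of the decay gate whose delay it shares.  The result is exactly
#' linear in \eqn{(I_0\alpha_1, \dots, I_0\alpha_n, Z)}.
#'
#' @param model a [decay_model()].
#' @param schedule a [gate_schedule()].
#' @param irf an IRF.
#' @return Numeric vector of expected counts, one per gate.
#' @export
forward_counts <- function(model, schedule, irf = irf_delta()) {
  di <- decay_gate_idx(schedule)
  decay <- rep(0, length(di))
  for (i in seq_len(model$n_components))
    decay <- decay + model$alphas[i] * decay_basis(model$taus[i], schedule, irf)
  out <- numeric(n_gates(schedule))
  out[di] <- model$I0 * decay + model$Z
  oi <- offset_gate_idx(schedule)
  if (length(oi)) out[oi] <- model$Z
  for (mi in motion_gate_idx(schedule))
    out[mi] <- out[motion_partner_idx(schedule, mi)]
  out
}

#' Time-gated image stack
#'
#' The universal input container: a 3-D array of per-gate photon counts
#' (`[gate, row, col]`) together with its gate schedule.
#'
#' @param counts numeric 3-D array `[gate, row, col]`, finite and
#'   non-negative, first dimension matching the schedule.
#' @param schedule a [gate_schedule()].
#' @param pixel_size optional pixel pitch (micrometres).
#' @param meta free-form provenance list.
#' @return An object of class `time_gated_stack`.
#' @export
time_gated_stack <- function(counts, schedule, pixel_size = NULL,
                             meta = list()) {
  counts <- as.array(counts)
  if (length(dim(counts)) == 2L)
    dim(counts) <- c(dim(counts), 1L)
  stopifnot(length(dim(counts)) == 3L)
  if (dim(counts)[1L] != n_gates(schedule))
    stop("first dimension of counts (", dim(counts)[1L],
         ") must equal the number of gates (", n_gates(schedule), ")")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  structure(list(counts = counts, schedule = schedule,
                 pixel_size = pixel_size, meta = meta),
            class = "time_gated_stack")
}

#' @export
print.time_gated_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Time-gated stack: %d gates, %d x %d pixels, %s photons total\n",
              d[1L], d[2L], d[3L], format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$counts)[2:3]

## counts as gates x pixels matrix (column-major pixel order)
stack_matrix <- function(stack) {
  d <- dim(stack$counts)
  matrix(stack$counts, nrow = d[1L])
}
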