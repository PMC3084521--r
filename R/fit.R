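#' Options controlling decay fitting
#'
#' @param weighting `"poisson"` (variance = expected counts, appropriate for
#'   photon-counting statistics) or `"uniform"`.  Poisson weights start from
#'   the observed counts (\eqn{1/\max(y,1)}) and are then re-estimated from
#'   the fitted expectations (`n_reweight` rounds), which removes the
#'   low-count bias of purely observation-based weights.
#' @param max_iter maximum outer (lifetime) iterations.
#' @param tol relative chi-square convergence threshold.
#' @param tau_bounds lifetime search bounds (ps); default spans a tenth of
#'   the gate width to the repetition period.
#' @param tau_init optional numeric vector of starting lifetimes for the free
#'   components; default is a log-spaced multi-start grid over `tau_bounds`.
#' @param fixed_taus named numeric vector mapping component index to a fixed
#'   lifetime in ps, e.g. `c("1" = 2516)`; unnamed components are fitted.
#' @param n_reweight rounds of model-based weight re-estimation for Poisson
#'   weighting.
#' @param min_photons minimum total decay-gate counts for a pixel to be
#'   fitted.  Default 300, the photon budget at which a mono-exponential fit
#'   is considered reliable.
#' @param use_offset_gate include the offset gate as an observation
#'   constraining the background Z?
#' @param pin_offset fix Z to the offset-gate counts instead of fitting it.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(weighting = c("poisson", "uniform"),
                        max_iter = 100L, tol = 1e-8,
                        tau_bounds = NULL, tau_init = NULL,
                        fixed_taus = NULL, n_reweight = 2L,
                        min_photons = 300L,
                        use_offset_gate = TRUE, pin_offset = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(tol > 0, max_iter >= 1L, min_photons >= 0, n_reweight >= 0L)
  if (!is.null(tau_bounds))
    stopifnot(length(tau_bounds) == 2L, all(tau_bounds > 0),
              tau_bounds[1L] < tau_bounds[2L])
  structure(list(weighting = weighting, max_iter = as.integer(max_iter),
                 tol = tol, tau_bounds = tau_bounds, tau_init = tau_init,
                 fixed_taus = fixed_taus, n_reweight = as.integer(n_reweight),
                 min_photons = min_photons,
                 use_offset_gate = use_offset_gate, pin_offset = pin_offset),
            class = "fit_options")
}

default_tau_bounds <- function(schedule) {
  lb <- max(schedule$width / 10, 1)
  span <- max(schedule$delays) + schedule$width
  ub <- if (is.finite(schedule$rep_period)) schedule$rep_period
        else 10 * span
  c(lb, max(ub, 2 * lb))
}

## gate indices entering the residual: decay gates, then the offset gate
fit_rows <- function(schedule, opts) {
  r <- decay_gate_idx(schedule)
  oi <- offset_gate_idx(schedule)
  if (length(oi) && opts$use_offset_gate && !opts$pin_offset) r <- c(r, oi)
  r
}

## design matrix over `rows`: one basis column per component, then Z
make_design <- function(taus, schedule, irf, rows) {
  nd <- length(decay_gate_idx(schedule))
  B <- matrix(0, length(rows), length(taus) + 1L)
  for (i in seq_along(taus))
    B[seq_len(nd), i] <- decay_basis(taus[i], schedule, irf)
  B[, length(taus) + 1L] <- 1
  B
}

weights_for <- function(y, weighting) {
  if (weighting == "poisson") 1 / pmax(y, 1) else rep(1, length(y))
}

parse_fixed_taus <- function(fixed_taus, n) {
  out <- rep(NA_real_, n)
  if (is.null(fixed_taus) || !length(fixed_taus)) return(out)
  fixed_taus <- unlist(fixed_taus)
  idx <- as.integer(names(fixed_taus))
  if (any(is.na(idx)))
    stop("fixed_taus must be named by component index, e.g. c('1' = 2516)")
  if (any(idx < 1L | idx > n))
    stop("fixed_taus component index out of range 1..", n)
  if (any(fixed_taus <= 0)) stop("fixed lifetimes must be positive")
  out[idx] <- as.numeric(fixed_taus)
  out
}

normalise_model_config <- function(model_config) {
  if (is.numeric(model_config))
    model_config <- list(n_components = as.integer(model_config))
  if (is.null(model_config$n_components)) model_config$n_components <- 1L
  if (is.null(model_config$fixed_taus)) model_config$fixed_taus <- NULL
  model_config
}

## default multi-start candidates for nf free lifetimes
tau_start_sets <- function(nf, bounds, tau_init) {
  if (!is.null(tau_init)) {
    ti <- if (is.list(tau_init)) tau_init else list(as.numeric(tau_init))
    ti <- lapply(ti, function(v) sort(v, decreasing = TRUE))
    if (any(lengths(ti) != nf))
      stop("tau_init must supply ", nf, " free lifetimes per start")
    return(ti)
  }
  grid <- exp(seq(log(bounds[1L] * 1.02), log(bounds[2L] * 0.98),
                  length.out = max(6L, 3L + nf)))
  if (nf == 1L) return(as.list(grid))
  cmb <- utils::combn(rev(grid), nf)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

## ---- single-decay fitting core ---------------------------------------------
##
## y_full: counts over all gates of `schedule`.  Fits n_components lifetimes
## (some possibly fixed) plus non-negative amplitudes and offset Z by
## variable projection: the lifetimes are the only nonlinear parameters, the
## amplitudes are eliminated by a weighted linear solve at every iterate.
fit_pixel_core <- function(y_full, schedule, irf, n_components, opts,
                           fit_type) {
  stopifnot(length(y_full) == n_gates(schedule))
  nd <- length(decay_gate_idx(schedule))
  need <- 2L * n_components + 1L
  if (nd < need)
    stop("need at least ", need, " decay gates for a ", n_components,
         "-component fit with background; schedule has ", nd)
  rows <- fit_rows(schedule, opts)
  y <- y_full[rows]
  n_photons <- sum(y_full[decay_gate_idx(schedule)])
  if (n_photons < opts$min_photons)
    stop("pixel has ", n_photons, " decay-gate photons, below min_photons = ",
         opts$min_photons)
  pin_z <- opts$pin_offset && length(offset_gate_idx(schedule)) > 0L
  z_pin <- if (pin_z) mean(y_full[offset_gate_idx(schedule)]) else 0
  if (pin_z) y <- y - z_pin
  w <- weights_for(y_full[rows], opts$weighting)
  bounds <- opts$tau_bounds
  if (is.null(bounds)) bounds <- default_tau_bounds(schedule)

  fixed <- parse_fixed_taus(opts$fixed_taus, n_components)
  free_i <- which(is.na(fixed))
  nf <- length(free_i)
  if (nf > nd - 1L)
    stop("free lifetimes (", nf, ") must not exceed decay gates - 1")

  taus_of <- function(th_free) {
    taus <- fixed; taus[free_i] <- th_free; taus
  }
  solve_at <- function(taus, w) {
    B <- make_design(taus, schedule, irf, rows)
    if (pin_z) B <- B[, -ncol(B), drop = FALSE]
    if (length(taus) > 1L && min(diff(sort(taus))) < 1e-9)
      return(list(chi2 = Inf, coef = rep(0, ncol(B)), B = B))
    sw <- sqrt(w)
    x <- tryCatch(qr.coef(qr(B * sw), y * sw), error = function(e) NULL)
    if (is.null(x) || anyNA(x) || any(x < 0))
      x <- pracma::lsqnonneg(B * sw, y * sw)$x
    r <- (y - drop(B %*% x)) * sw
    list(chi2 = sum(r^2), coef = as.numeric(x), B = B)
  }

  run_at <- function(w) {
    converged <- TRUE; niter <- 0L
    if (nf == 0L) {
      taus <- fixed
    } else if (nf == 1L) {
      obj <- function(lt) solve_at(taus_of(exp(lt)), w)$chi2
      lg <- seq(log(bounds[1L]), log(bounds[2L]), length.out = 40L)
      cg <- vapply(lg, obj, 0)
      j <- which.min(cg)
      lo <- lg[max(1L, j - 1L)]; hi <- lg[min(length(lg), j + 1L)]
      op <- stats::optimize(obj, c(lo, hi), tol = 1e-9)
      taus <- taus_of(exp(op$minimum))
      niter <- length(lg) + 40L
    } else {
      starts <- tau_start_sets(nf, bounds, opts$tau_init)
      sc <- vapply(starts, function(s) solve_at(taus_of(s), w)$chi2, 0)
      best <- starts[[which.min(sc)]]
      resid_fn <- function(lt) {
        s <- solve_at(taus_of(exp(lt)), w)
        if (!is.finite(s$chi2)) return(rep(1e6, length(y)))
        (y - drop(s$B %*% s$coef)) * sqrt(w)
      }
      fit <- minpack.lm::nls.lm(
        par = log(best), fn = resid_fn,
        lower = rep(log(bounds[1L]), nf), upper = rep(log(bounds[2L]), nf),
        control = minpack.lm::nls.lm.control(
          maxiter = opts$max_iter, ftol = opts$tol, ptol = 1e-12))
      taus <- taus_of(exp(fit$par))
      converged <- fit$info %in% 1:4
      niter <- fit$niter
    }
    list(taus = taus, converged = converged, niter = niter)
  }

  r0 <- run_at(w)
  if (opts$weighting == "poisson" && opts$n_reweight > 0L) {
    for (rw in seq_len(opts$n_reweight)) {
      s <- solve_at(r0$taus, w)
      mu <- drop(s$B %*% s$coef) + if (pin_z) z_pin else 0
      w <- 1 / pmax(mu, 1)
      r0 <- run_at(w)
    }
  }
  taus <- r0$taus; converged <- r0$converged; niter <- r0$niter
  s <- solve_at(taus, w)
  amps <- s$coef[seq_len(n_components)]
  Z <- if (pin_z) z_pin else s$coef[n_components + 1L]
  I0 <- sum(amps)
  alphas <- if (I0 > 0) amps / I0 else rep(1 / n_components, n_components)
  model <- decay_model(taus, alphas, I0 = I0, Z = Z)
  tau_fixed <- !is.na(fixed)
  ## track fixed flags through the canonical (descending) reordering
  o <- order(-taus, -alphas)
  if (nf > 0L || n_components > 1L)
    model <- merge_close_components(model, tol = 1)
  structure(list(model = model, chi2 = s$chi2, n_photons = n_photons,
                 converged = converged, niter = niter,
                 tau_fixed = tau_fixed[o][seq_len(model$n_components)],
                 fit_type = fit_type, schedule = schedule, irf = irf,
                 counts = y_full, rows = rows, weights = w, opts = opts,
                 df = length(y) - (nf + n_components + !pin_z)),
            class = "flim_fit")
}

#' Fit a mono-exponential decay to one pixel's gated counts
#'
#' Weighted nonlinear least squares for the lifetime with the amplitude and
#' background eliminated by a linear solve at every candidate lifetime
#' (single-pixel variable projection).  Requires at least three decay gates
#' (lifetime, amplitude and background are three unknowns).
#'
#' @param counts per-gate counts (length = number of gates in `schedule`).
#' @param schedule a [gate_schedule()].
#' @param irf an IRF.
#' @param opts a [fit_options()] list.
#' @return A `flim_fit` object; see [coef.flim_fit()], [fitted.flim_fit()].
#' @export
fit_mono_pixel <- function(counts, schedule, irf = irf_delta(),
                           opts = fit_options()) {
  opts$fixed_taus <- NULL
  fit_pixel_core(counts, schedule, irf, 1L, opts, "mono_pixel")
}

#' Fit a multiexponential decay to one pixel's gated counts
#'
#' As [fit_mono_pixel()] with `n_components` lifetimes; any subset may be
#' fixed through `opts$fixed_taus` (with both lifetimes of a two-component
#' model fixed the problem is purely linear).  Requires at least
#' `2 * n_components + 1` decay gates.
#'
#' @inheritParams fit_mono_pixel
#' @param n_components number of exponential components (>= 1).
#' @return A `flim_fit` object.
#' @export
fit_multi_pixel <- function(counts, schedule, irf = irf_delta(),
                            n_components = 2L, opts = fit_options()) {
  fit_pixel_core(counts, schedule, irf, as.integer(n_components), opts,
                 if (n_components == 1L) "mono_pixel" else "multi_pixel")
}

#' Fit the binned decay of a region of interest
#'
#' Sums the gated counts over all masked pixels ("global binning") and fits
#' the composite decay as a single profile, under the assumption that the
#' lifetimes are invariant across the region.
#'
#' @param stack a [time_gated_stack()].
#' @param mask logical matrix selecting the ROI pixels (same spatial
#'   dimensions as the stack).
#' @param model_config number of components, or a list
#'   `list(n_components =, fixed_taus =)`.
#' @param irf an IRF.
#' @param opts a [fit_options()] list.
#' @return A `flim_fit` object (`n_photons` is the ROI total).
#' @export
fit_binned_roi <- function(stack, mask, model_config = 1L,
                           irf = irf_delta(), opts = fit_options()) {
  mc <- normalise_model_config(model_config)
  stopifnot(is.logical(mask), all(dim(mask) == stack_dim(stack)))
  if (!any(mask)) stop("empty ROI mask")
  Y <- stack_matrix(stack)[, as.vector(mask), drop = FALSE]
  y <- rowSums(Y)
  opts$fixed_taus <- mc$fixed_taus
  fit_pixel_core(y, stack$schedule, irf, mc$n_components, opts, "binned_roi")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
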