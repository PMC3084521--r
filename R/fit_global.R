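#' Global image fitting with shared lifetimes by variable projection
#'
#' Fits one or more time-gated image stacks jointly to a multiexponential
#' decay model in which the lifetimes are shared by every pixel while each
#' pixel keeps its own non-negative amplitudes and background.  The global
#' chi-square is minimised by variable projection: for any candidate set of
#' lifetimes the amplitudes of each pixel depend only on that pixel's counts,
#' so they are eliminated through independent small weighted linear solves
#' and the outer nonlinear search runs over the lifetimes alone
#' (Levenberg-Marquardt on the reduced residuals).  Memory use scales
#' linearly with the number of pixels: only the per-pixel solutions and the
#' reduced residuals are held.
#'
#' Any subset of lifetimes can be fixed via `opts$fixed_taus` (e.g. a donor
#' lifetime calibrated from donor-only wells); with all lifetimes fixed the
#' fit reduces to a single linear pass.
#'
#' @param stacks a [time_gated_stack()] or list of stacks sharing one gate
#'   schedule.
#' @param n_components number of shared exponential components.
#' @param irf an IRF.
#' @param opts a [fit_options()] list; pixels below `min_photons` decay-gate
#'   counts are excluded.
#' @param masks optional logical matrix (or list, one per stack) restricting
#'   the fitted pixels.
#' @return An object of class `flim_global_fit` with shared `taus` (and
#'   `tau_fixed` flags), per-stack amplitude-fraction maps `alpha_maps`
#'   (row x col x component arrays), `I0_maps`, `Z_maps`, `chi2_maps`, the
#'   scalar `chi2_global`, `n_pixels_fit` and convergence diagnostics.
#' @export
varpro_global_fit <- function(stacks, n_components = 2L, irf = irf_delta(),
                              opts = fit_options(), masks = NULL) {
  if (inherits(stacks, "time_gated_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1L)
  sch <- stacks[[1L]]$schedule
  for (s in stacks[-1L]) check_same_schedule(sch, s$schedule)
  if (!is.null(masks) && is.matrix(masks)) masks <- list(masks)
  n_components <- as.integer(n_components)

  nd <- length(decay_gate_idx(sch))
  rows <- fit_rows(sch, opts)
  fixed <- parse_fixed_taus(opts$fixed_taus, n_components)
  free_i <- which(is.na(fixed)); nf <- length(free_i)
  if (nf > nd - 1L)
    stop("free lifetimes (", nf, ") must not exceed decay gates - 1")
  bounds <- opts$tau_bounds %||% default_tau_bounds(sch)

  ## assemble fitted pixels across stacks
  Ys <- lapply(stacks, stack_matrix)
  di <- decay_gate_idx(sch)
  sel <- vector("list", length(stacks))
  for (s in seq_along(stacks)) {
    ok <- colSums(Ys[[s]][di, , drop = FALSE]) >= opts$min_photons
    if (!is.null(masks)) ok <- ok & as.vector(masks[[s]])
    sel[[s]] <- ok
  }
  P_s <- vapply(sel, sum, 0L)
  if (sum(P_s) < 1L) stop("no unmasked pixel reaches min_photons")
  Y <- do.call(cbind, lapply(seq_along(stacks),
                             function(s) Ys[[s]][rows, sel[[s]], drop = FALSE]))
  W <- apply(Y, 2L, weights_for, weighting = opts$weighting)
  if (!is.matrix(W)) W <- matrix(W, nrow = length(rows))

  solve_at <- function(taus, W) {
    if (length(taus) > 1L && min(diff(sort(taus))) < 1e-9)
      return(NULL)
    B <- make_design(taus, sch, irf, rows)
    batched_wls(B, Y, W)
  }
  taus_of <- function(th) { t0 <- fixed; t0[free_i] <- th; t0 }

  run_at <- function(W) {
    chi2_at <- function(taus) {
      s <- solve_at(taus, W)
      if (is.null(s)) Inf else sum(s$chi2)
    }
    converged <- TRUE; niter <- 0L
    if (nf == 0L) {
      taus <- fixed
    } else if (nf == 1L) {
      obj <- function(lt) chi2_at(taus_of(exp(lt)))
      lg <- seq(log(bounds[1L]), log(bounds[2L]), length.out = 30L)
      cg <- vapply(lg, obj, 0)
      j <- which.min(cg)
      op <- stats::optimize(obj, c(lg[max(1L, j - 1L)],
                                   lg[min(length(lg), j + 1L)]), tol = 1e-9)
      taus <- taus_of(exp(op$minimum)); niter <- 30L + 40L
    } else {
      starts <- tau_start_sets(nf, bounds, opts$tau_init)
      sc <- vapply(starts, function(s) chi2_at(taus_of(s)), 0)
      best <- starts[[which.min(sc)]]
      resid_fn <- function(lt) {
        s <- solve_at(taus_of(exp(lt)), W)
        if (is.null(s)) return(rep(1e6, length(Y)))
        as.vector(s$residuals)
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

  r0 <- run_at(W)
  if (opts$weighting == "poisson" && opts$n_reweight > 0L) {
    for (rw in seq_len(opts$n_reweight)) {
      s <- solve_at(r0$taus, W)
      MU <- make_design(r0$taus, sch, irf, rows) %*% s$coef
      W <- 1 / pmax(MU, 1)
      r0 <- run_at(W)
    }
  }
  taus <- r0$taus; converged <- r0$converged; niter <- r0$niter
  fin <- solve_at(taus, W)
  if (is.null(fin)) stop("degenerate lifetimes at solution")
  ## canonical ordering: lifetimes descending
  o <- order(-taus)
  taus <- taus[o]; tau_fixed <- (!is.na(fixed))[o]
  A <- fin$coef[o, , drop = FALSE]                   # components x P
  Zrow <- fin$coef[n_components + 1L, ]
  I0 <- colSums(A)
  AL <- sweep(A, 2L, ifelse(I0 > 0, I0, 1), "/")
  AL[, I0 <= 0] <- 1 / n_components

  ## scatter back into per-stack maps
  alpha_maps <- I0_maps <- Z_maps <- chi2_maps <- fitted_masks <-
    vector("list", length(stacks))
  off <- 0L
  for (s in seq_along(stacks)) {
    d <- stack_dim(stacks[[s]])
    idx <- off + seq_len(P_s[s]); off <- off + P_s[s]
    am <- array(NA_real_, c(d, n_components))
    for (i in seq_len(n_components)) {
      m <- matrix(NA_real_, d[1L], d[2L]); m[sel[[s]]] <- AL[i, idx]
      am[, , i] <- m
    }
    mk <- function(v) { m <- matrix(NA_real_, d[1L], d[2L]); m[sel[[s]]] <- v; m }
    alpha_maps[[s]] <- am
    I0_maps[[s]] <- mk(I0[idx])
    Z_maps[[s]] <- mk(Zrow[idx])
    chi2_maps[[s]] <- mk(fin$chi2[idx])
    fitted_masks[[s]] <- matrix(sel[[s]], d[1L], d[2L])
  }
  structure(list(taus = taus, tau_fixed = tau_fixed,
                 n_components = n_components,
                 alpha_maps = alpha_maps, I0_maps = I0_maps,
                 Z_maps = Z_maps, chi2_maps = chi2_maps,
                 fitted_masks = fitted_masks,
                 chi2_global = sum(fin$chi2), n_pixels_fit = sum(P_s),
                 converged = converged, niter = niter,
                 schedule = sch, irf = irf, opts = opts),
            class = "flim_global_fit")
}

check_same_schedule <- function(a, b) {
  same <- isTRUE(all.equal(a$delays, b$delays)) &&
    isTRUE(all.equal(a$width, b$width)) &&
    identical(a$roles, b$roles) &&
    (identical(a$rep_period, b$rep_period) ||
       isTRUE(all.equal(a$rep_period, b$rep_period)))
  if (!same) stop("gate schedules differ across stacks")
  invisible(TRUE)
}

#' @export
print.flim_global_fit <- function(x, ...) {
  cat(sprintf("Global variable-projection fit: %d component(s), %d pixels%s\n",
              x$n_components, x$n_pixels_fit,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (i in seq_len(x$n_components))
    cat(sprintf("  tau%d = %.1f ps%s  (mean alpha = %.3f)\n", i, x$taus[i],
                if (x$tau_fixed[i]) " (fixed)" else " (fitted)",
                mean(unlist(lapply(x$alpha_maps, function(a) a[, , i])),
                     na.rm = TRUE)))
  cat(sprintf("  global chi2 = %.6g\n", x$chi2_global))
  invisible(x)
}

#' @export
coef.flim_global_fit <- function(object, ...) {
  stats::setNames(object$taus,
                  paste0("tau", seq_len(object$n_components)))
}

#' @export
summary.flim_global_fit <- function(object, ...) {
  am <- vapply(seq_len(object$n_components), function(i)
    mean(unlist(lapply(object$alpha_maps, function(a) a[, , i])),
         na.rm = TRUE), 0)
  out <- list(taus = object$taus, tau_fixed = object$tau_fixed,
              mean_alphas = am, chi2_global = object$chi2_global,
              n_pixels_fit = object$n_pixels_fit,
              converged = object$converged)
  class(out) <- "summary.flim_global_fit"
  out
}

#' @export
print.summary.flim_global_fit <- function(x, ...) {
  cat("Shared lifetimes (ps):",
      paste(sprintf("%.1f%s", x$taus,
                    ifelse(x$tau_fixed, " (fixed)", "")), collapse = ", "),
      "\n")
  cat("Mean amplitude fractions:",
      paste(sprintf("%.3f", x$mean_alphas), collapse = ", "), "\n")
  cat(sprintf("Global chi2 %.6g over %d pixels\n",
              x$chi2_global, x$n_pixels_fit))
  invisible(x)
}

#' Global fitting of a FLIM time series with linked parameters
#'
#' Two linkage modes for an ordered series of stacks (e.g. a calcium-dye
#' time course):
#'
#' * `linked_lifetimes` — the component lifetimes are shared across the
#'   whole series (a variable-projection fit over the concatenated data);
#'   each pixel at each timepoint keeps its own amplitudes, so the
#'   bound/unbound fractions may evolve.
#' * `linked_ratio` — the amplitude ratio \eqn{\alpha_1/\alpha_2} is shared
#'   across the series while the two lifetimes are shared within each
#'   timepoint but free to differ between timepoints; per-pixel scale and
#'   background remain free.
#'
#' @param series list of [time_gated_stack()] (>= 2, consistent schedules).
#' @param mode `"linked_lifetimes"` or `"linked_ratio"`.
#' @param n_components shared components (linked_ratio requires 2).
#' @param irf an IRF.
#' @param opts a [fit_options()] list.
#' @return An object of class `flim_series_fit`: per-timepoint lifetime and
#'   amplitude summaries, `chi2_total`, and the full per-timepoint maps.
#' @export
linked_series_fit <- function(series,
                              mode = c("linked_lifetimes", "linked_ratio"),
                              n_components = 2L, irf = irf_delta(),
                              opts = fit_options()) {
  mode <- match.arg(mode)
  stopifnot(length(series) >= 2L)
  sch <- series[[1L]]$schedule
  for (s in series[-1L]) check_same_schedule(sch, s$schedule)

  if (mode == "linked_lifetimes") {
    g <- varpro_global_fit(series, n_components, irf, opts)
    per_t <- lapply(seq_along(series), function(t) {
      a2 <- if (n_components >= 2L) mean(g$alpha_maps[[t]][, , 2L],
                                         na.rm = TRUE) else NA_real_
      mt <- 0
      for (i in seq_len(n_components))
        mt <- mt + g$taus[i] * g$alpha_maps[[t]][, , i]
      list(alpha_map = g$alpha_maps[[t]], I0_map = g$I0_maps[[t]],
           Z_map = g$Z_maps[[t]], mean_alpha2 = a2,
           mean_tau = mean(mt, na.rm = TRUE),
           chi2 = sum(g$chi2_maps[[t]], na.rm = TRUE))
    })
    return(structure(list(mode = mode, taus = g$taus,
                          tau_fixed = g$tau_fixed,
                          per_timepoint = per_t,
                          chi2_total = g$chi2_global,
                          converged = g$converged,
                          global_fit = g, schedule = sch, irf = irf),
                     class = "flim_series_fit"))
  }

  ## linked_ratio: shared alpha ratio, per-timepoint lifetime pairs
  if (n_components != 2L)
    stop("linked_ratio mode is defined for two components")
  nt <- length(series)
  rows <- fit_rows(sch, opts)
  di <- decay_gate_idx(sch)
  Ys <- lapply(series, stack_matrix)
  sel <- lapply(Ys, function(Y)
    colSums(Y[di, , drop = FALSE]) >= opts$min_photons)
  Yl <- lapply(seq_len(nt), function(t) Ys[[t]][rows, sel[[t]], drop = FALSE])
  Wl <- lapply(Yl, function(Y) {
    W <- apply(Y, 2L, weights_for, weighting = opts$weighting)
    if (!is.matrix(W)) W <- matrix(W, nrow = length(rows)); W
  })
  if (any(vapply(Yl, ncol, 0L) < 1L))
    stop("a timepoint has no pixel reaching min_photons")
  bounds <- opts$tau_bounds %||% default_tau_bounds(sch)

  ## start from a lifetimes-linked fit
  g0 <- varpro_global_fit(series, 2L, irf, opts)
  a2bar <- mean(unlist(lapply(g0$alpha_maps, function(a) a[, , 2L])),
                na.rm = TRUE)
  a2bar <- min(max(a2bar, 0.02), 0.98)
  par0 <- c(rep(log(g0$taus), nt), log((1 - a2bar) / a2bar))

  nd <- length(di)
  resid_fn <- function(par) {
    q <- par[2L * nt + 1L]
    a1 <- exp(q) / (1 + exp(q)); a2 <- 1 - a1
    out <- vector("list", nt)
    for (t in seq_len(nt)) {
      tt <- exp(par[c(2L * t - 1L, 2L * t)])
      if (abs(tt[1L] - tt[2L]) < 1e-9)
        return(rep(1e6, sum(vapply(Yl, length, 0L))))
      bcomb <- a1 * decay_basis(tt[1L], sch, irf) +
        a2 * decay_basis(tt[2L], sch, irf)
      B <- matrix(0, length(rows), 2L)
      B[seq_len(nd), 1L] <- bcomb; B[, 2L] <- 1
      out[[t]] <- as.vector(batched_wls(B, Yl[[t]], Wl[[t]])$residuals)
    }
    unlist(out)
  }
  run_lm <- function(par0) minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = c(rep(log(bounds[1L]), 2L * nt), -8),
    upper = c(rep(log(bounds[2L]), 2L * nt), 8),
    control = minpack.lm::nls.lm.control(
      maxiter = opts$max_iter, ftol = opts$tol, ptol = 1e-12))
  fit <- run_lm(par0)
  if (opts$weighting == "poisson" && opts$n_reweight > 0L) {
    for (rw in seq_len(opts$n_reweight)) {
      ## re-estimate weights from the fitted expectations
      q <- fit$par[2L * nt + 1L]
      a1 <- exp(q) / (1 + exp(q))
      for (t in seq_len(nt)) {
        tt <- exp(fit$par[c(2L * t - 1L, 2L * t)])
        bcomb <- a1 * decay_basis(tt[1L], sch, irf) +
          (1 - a1) * decay_basis(tt[2L], sch, irf)
        B <- matrix(0, length(rows), 2L)
        B[seq_len(nd), 1L] <- bcomb; B[, 2L] <- 1
        X <- batched_wls(B, Yl[[t]], Wl[[t]])$coef
        Wl[[t]] <- 1 / pmax(B %*% X, 1)
      }
      fit <- run_lm(fit$par)
    }
  }
  q <- fit$par[2L * nt + 1L]
  a1 <- exp(q) / (1 + exp(q))
  taus_t <- matrix(exp(fit$par[seq_len(2L * nt)]), nrow = 2L)
  ## canonical: tau1 >= tau2 within each timepoint (ratio follows component 1)
  per_t <- lapply(seq_len(nt), function(t) {
    tt <- taus_t[, t]
    list(taus = sort(tt, decreasing = TRUE),
         mean_tau = a1 * max(tt) + (1 - a1) * min(tt))
  })
  structure(list(mode = mode,
                 alphas = c(a1, 1 - a1),
                 per_timepoint = per_t,
                 chi2_total = sum(resid_fn(fit$par)^2),
                 converged = fit$info %in% 1:4,
                 niter = fit$niter, schedule = sch, irf = irf),
            class = "flim_series_fit")
}

#' @export
print.flim_series_fit <- function(x, ...) {
  cat("Linked series fit (", x$mode, "), ",
      length(x$per_timepoint), " timepoints\n", sep = "")
  if (x$mode == "linked_lifetimes") {
    cat("  shared lifetimes (ps):",
        paste(sprintf("%.1f", x$taus), collapse = ", "), "\n")
    a2 <- vapply(x$per_timepoint, function(p) p$mean_alpha2, 0)
    if (!anyNA(a2))
      cat("  mean alpha2 by timepoint:",
          paste(sprintf("%.3f", a2), collapse = ", "), "\n")
  } else {
    cat(sprintf("  shared amplitude fractions: %.3f / %.3f\n",
                x$alphas[1L], x$alphas[2L]))
    for (t in seq_along(x$per_timepoint))
      cat(sprintf("  t%d: tau = %.1f / %.1f ps\n", t,
                  x$per_timepoint[[t]]$taus[1L],
                  x$per_timepoint[[t]]$taus[2L]))
  }
  cat(sprintf("  total chi2 = %.6g\n", x$chi2_total))
  invisible(x)
}
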