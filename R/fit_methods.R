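#' Methods for single-decay fit objects
#'
#' A `flim_fit` holds the fitted [decay_model()], the weighted residual sum
#' of squares (chi-square), the photon budget and convergence diagnostics of
#' a per-pixel or binned-ROI fit.
#'
#' @param x,object a `flim_fit`.
#' @param ... unused.
#' @name flim_fit-methods
NULL

#' @rdname flim_fit-methods
#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf("Gated-decay fit (%s): %d photons, chi2 = %.4g%s\n",
              x$fit_type, round(x$n_photons), x$chi2,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$model)
  invisible(x)
}

#' @rdname flim_fit-methods
#' @export
summary.flim_fit <- function(object, ...) {
  m <- object$model
  tab <- data.frame(gate = object$rows,
                    delay = object$schedule$delays[object$rows],
                    role = object$schedule$roles[object$rows],
                    observed = object$counts[object$rows],
                    fitted = fitted(object)[object$rows])
  out <- list(fit = object, gates = tab,
              mean_tau = mean_lifetime(m),
              chi2_reduced = object$chi2 / max(object$df, 1))
  class(out) <- "summary.flim_fit"
  out
}

#' @export
print.summary.flim_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Amplitude-weighted mean lifetime: %.1f ps\n", x$mean_tau))
  cat(sprintf("Reduced chi2: %.4g on %d d.o.f.\n",
              x$chi2_reduced, x$fit$df))
  print(x$gates, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @rdname flim_fit-methods
#' @export
coef.flim_fit <- function(object, ...) {
  m <- object$model
  k <- m$n_components
  stats::setNames(c(m$taus, m$alphas, m$I0, m$Z),
                  c(paste0("tau", seq_len(k)), paste0("alpha", seq_len(k)),
                    "I0", "Z"))
}

#' @rdname flim_fit-methods
#' @export
fitted.flim_fit <- function(object, ...) {
  forward_counts(object$model, object$schedule, object$irf)
}

#' @rdname flim_fit-methods
#' @param type `"weighted"` (default, \eqn{\sqrt w (y-\hat y)}) or `"raw"`.
#' @export
residuals.flim_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- (object$counts - fitted(object))[object$rows]
  if (type == "weighted") r * sqrt(object$weights) else r
}

#' @rdname flim_fit-methods
#' @param schedule,irf optionally predict expected counts under a different
#'   acquisition timebase or IRF.
#' @export
predict.flim_fit <- function(object, schedule = object$schedule,
                             irf = object$irf, ...) {
  forward_counts(object$model, schedule, irf)
}

#' @rdname flim_fit-methods
#' @param nsim,seed number of Poisson realisations and optional RNG seed.
#' @export
simulate.flim_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  replicate(nsim, stats::rpois(length(mu), mu), simplify = FALSE)
}
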