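#' Calibrate the donor-only lifetime
#'
#' Determines the unquenched donor lifetime from donor-only fields, either
#' by a global single-exponential variable-projection fit across all fields
#' (default, matching the plate-reader workflow of fixing the non-FRETing
#' donor lifetime from donor-only wells) or as the mean of per-pixel
#' mono-exponential fits.
#'
#' @param stacks a [time_gated_stack()] or list of donor-only stacks.
#' @param method `"global_fit"` or `"per_pixel_mean"`.
#' @param irf an IRF.
#' @param opts a [fit_options()] list.
#' @return An object of class `donor_calibration`: `tau_D` (ps), `source`,
#'   `n_fields`.
#' @export
calibrate_donor <- function(stacks, method = c("global_fit",
                                               "per_pixel_mean"),
                            irf = irf_delta(), opts = fit_options()) {
  method <- match.arg(method)
  if (inherits(stacks, "time_gated_stack")) stacks <- list(stacks)
  if (!length(stacks)) stop("no donor-only data supplied")
  if (method == "global_fit") {
    g <- varpro_global_fit(stacks, n_components = 1L, irf = irf, opts = opts)
    tau_D <- g$taus[1L]
  } else {
    taus <- unlist(lapply(stacks, function(s) {
      im <- fit_image_per_pixel(s, 1L, irf, opts)
      im$tau[!is.na(im$tau)]
    }))
    if (!length(taus)) stop("no pixel reached min_photons")
    tau_D <- mean(taus)
  }
  structure(list(tau_D = tau_D, source = method,
                 n_fields = length(stacks)), class = "donor_calibration")
}

#' @export
print.donor_calibration <- function(x, ...) {
  cat(sprintf("Donor calibration: tau_D = %.1f ps (%s over %d field(s))\n",
              x$tau_D, x$source, x$n_fields))
  invisible(x)
}

#' FRET efficiency from donor lifetime quenching
#'
#' The standard donor-quenching relation \eqn{E = 1 - \tau_{DA}/\tau_D}.
#' An apparent \eqn{\tau_{DA} > \tau_D} yields a negative value, which is
#' returned with a warning rather than clipped, so that artefacts (e.g.
#' refractive-index or homo-FRET effects) remain visible.
#'
#' @param tau_D donor-only lifetime (ps).
#' @param tau_DA donor lifetime in the presence of acceptor (ps).
#' @return Efficiency (dimensionless, vectorised).
#' @examples
#' fret_efficiency(2516, 1068)  # 0.5755
#' @export
fret_efficiency <- function(tau_D, tau_DA) {
  stopifnot(all(tau_D > 0), all(tau_DA > 0))
  E <- 1 - tau_DA / tau_D
  if (any(E < 0)) warning("tau_DA exceeds tau_D: negative apparent FRET")
  E
}

#' FRETing donor fraction map
#'
#' Extracts the second-component amplitude-fraction image from a
#' two-component global fit in which component 1 is the (typically fixed)
#' non-FRETing donor and component 2 the FRETing donor.
#'
#' @param global_result a two-component `flim_global_fit`.
#' @param which_stack stack index when the fit spanned several fields.
#' @return A list: `alpha2_map` (matrix), `mean_alpha2` over unmasked
#'   pixels, `tau2` (the FRETing-donor lifetime, ps).
#' @export
fretting_fraction_map <- function(global_result, which_stack = 1L) {
  if (global_result$n_components != 2L)
    stop("fretting fraction requires a two-component global fit")
  a2 <- global_result$alpha_maps[[which_stack]][, , 2L]
  list(alpha2_map = a2, mean_alpha2 = mean(a2, na.rm = TRUE),
       tau2 = global_result$taus[2L])
}

#' Effective FRET efficiency map
#'
#' The effective efficiency is the product of the actual FRET efficiency of
#' the FRETing population and the fraction of donors engaged in FRET:
#' \eqn{E_{eff} = \alpha_2 (1 - \tau_2/\tau_D)} per pixel.  An
#' intensity-weighted variant, which weights the FRETing fraction by the
#' photon contribution of each component, is also returned.
#'
#' @param global_result a two-component `flim_global_fit`.
#' @param tau_D donor-only lifetime (ps; e.g. from [calibrate_donor()]).
#' @param which_stack stack index.
#' @return A list: `E_eff_map` (amplitude-weighted, matrix), `E_fret`
#'   (scalar efficiency of the FRETing population), and
#'   `E_eff_map_intensity` (intensity-weighted variant).
#' @export
effective_efficiency_map <- function(global_result, tau_D,
                                     which_stack = 1L) {
  ff <- fretting_fraction_map(global_result, which_stack)
  E <- fret_efficiency(tau_D, ff$tau2)
  a2 <- ff$alpha2_map
  t1 <- global_result$taus[1L]; t2 <- global_result$taus[2L]
  w2 <- a2 * t2 / ((1 - a2) * t1 + a2 * t2)
  list(E_eff_map = a2 * E, E_fret = E, E_eff_map_intensity = w2 * E)
}

#' Compare lifetime summaries between conditions
#'
#' Pairwise mean-lifetime differences between experimental conditions (e.g.
#' donor-only vs donor+acceptor wells) with pooled standard deviations,
#' Welch standard errors and the standardised effect size.  No p-value
#' machinery: the intended readout is the lifetime contrast and its
#' uncertainty.
#'
#' @param by_condition named list of numeric vectors of lifetimes (per ROI,
#'   per well or per pixel), one entry per condition.
#' @return data.frame with one row per ordered pair: `condition_a`,
#'   `condition_b`, `mean_a`, `mean_b`, `delta_tau` (a - b), `pooled_sd`,
#'   `se_welch`, `cohens_d`, `n_a`, `n_b`; conditions with fewer than two
#'   observations are flagged in `sd_defined`.
#' @export
compare_conditions <- function(by_condition) {
  stopifnot(is.list(by_condition), length(by_condition) >= 2L,
            !is.null(names(by_condition)))
  nm <- names(by_condition)
  out <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) next
    a <- by_condition[[i]]; b <- by_condition[[j]]
    na <- length(a); nb <- length(b)
    va <- if (na >= 2L) stats::var(a) else NA_real_
    vb <- if (nb >= 2L) stats::var(b) else NA_real_
    sd_ok <- na >= 2L && nb >= 2L
    pooled <- if (sd_ok)
      sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)) else NA_real_
    se <- if (sd_ok) sqrt(va / na + vb / nb) else NA_real_
    d <- mean(a) - mean(b)
    out[[length(out) + 1L]] <- data.frame(
      condition_a = nm[i], condition_b = nm[j],
      mean_a = mean(a), mean_b = mean(b), delta_tau = d,
      pooled_sd = pooled, se_welch = se,
      cohens_d = if (sd_ok && pooled > 0) d / pooled else NA_real_,
      n_a = na, n_b = nb, sd_defined = sd_ok)
  }
  do.call(rbind, out)
}
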