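## run code with a private, reproducible RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Gaussian stand-in for a measured IRF
#'
#' Real instruments record the IRF with a sub-150-ps-lifetime dye; for
#' simulation a normalised Gaussian of the same width is a convenient
#' stand-in.  With `sampled = TRUE` the Gaussian is tabulated as a measured
#' IRF (useful to exercise the measured-IRF code path); otherwise the exact
#' parametric form is returned.
#'
#' @param fwhm full width at half maximum (ps).
#' @param t0 centre (ps).
#' @param sampled tabulate on a grid instead of the parametric form?
#' @param dt grid step for the sampled form (ps).
#' @return An `irf` object.
#' @export
make_gaussian_irf <- function(fwhm, t0 = 0, sampled = FALSE, dt = NULL) {
  stopifnot(fwhm > 0)
  if (!sampled) return(irf_gaussian(fwhm, t0))
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(dt)) dt <- max(sig / 10, 0.25)
  tt <- seq(-5 * sig, 5 * sig, by = dt)
  irf_measured(tt, stats::dnorm(tt, 0, sig), t0 = t0)
}

#' Define a simulation scenario
#'
#' Ground-truth description of a synthetic time-gated acquisition: per-pixel
#' lifetime and amplitude-fraction maps (scalars are recycled over the
#' image), a relative intensity map, background, gate schedule, IRF, target
#' photon budget and RNG seed.  The intensity map is rescaled so that the
#' mean total expected decay-gate signal per pixel (background excluded)
#' equals `photons_per_pixel`.
#'
#' @param taus lifetimes (ps): numeric vector (uniform image) or list of
#'   matrices, one per component.
#' @param alphas amplitude fractions summing to 1 per pixel: numeric vector
#'   or list of matrices.
#' @param dims image dimensions `c(rows, cols)` (ignored when maps are
#'   given).
#' @param schedule a [gate_schedule()].
#' @param irf an IRF.
#' @param photons_per_pixel target mean decay-gate photons per pixel.
#' @param Z background offset (counts per gate), scalar or matrix.
#' @param I0_rel relative intensity map (matrix) or scalar.
#' @param seed integer seed; identical seeds give identical stacks.
#' @param name scenario label.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(taus, alphas = NULL, dims = c(32L, 32L),
                         schedule = default_gate_schedule(),
                         irf = irf_delta(), photons_per_pixel = 300,
                         Z = 0, I0_rel = 1, seed = 1L,
                         name = "scenario") {
  k <- length(taus)
  if (is.null(alphas)) alphas <- rep(1 / k, k)
  ## image dimensions come from whichever argument supplies a map
  if (is.list(taus)) dims <- dim(taus[[1L]])
  else if (is.list(alphas)) dims <- dim(alphas[[1L]])
  else if (is.matrix(I0_rel)) dims <- dim(I0_rel)
  as_maps <- function(x, k) {
    if (is.list(x)) {
      lapply(x, function(m) { stopifnot(all(dim(m) == dims)); m })
    } else {
      lapply(seq_len(k), function(i) matrix(x[i], dims[1L], dims[2L]))
    }
  }
  tau_maps <- as_maps(taus, k)
  alpha_maps <- as_maps(alphas, k)
  if (!is.matrix(Z)) Z <- matrix(Z, dims[1L], dims[2L])
  if (!is.matrix(I0_rel)) I0_rel <- matrix(I0_rel, dims[1L], dims[2L])
  structure(list(name = name, n_components = k, tau_maps = tau_maps,
                 alpha_maps = alpha_maps, Z = Z, I0_rel = I0_rel,
                 dims = dims, schedule = schedule, irf = irf,
                 photons_per_pixel = photons_per_pixel,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

## expected per-gate counts (gates x pixels) and the calibrated I0 map
scenario_expectation <- function(sc) {
  sch <- sc$schedule
  di <- decay_gate_idx(sch)
  nd <- length(di)
  P <- prod(sc$dims)
  a_edge <- sch$delays[di]; b_edge <- a_edge + sch$width
  MU <- matrix(0, nd, P)
  for (i in seq_len(sc$n_components)) {
    tv <- as.vector(sc$tau_maps[[i]]); av <- as.vector(sc$alpha_maps[[i]])
    for (g in seq_len(nd))
      MU[g, ] <- MU[g, ] + av * gate_integral_periodic(
        tv, a_edge[g], b_edge[g], sch$rep_period, sc$irf)
  }
  MU <- MU * rep(as.vector(sc$I0_rel), each = nd)
  tot <- mean(colSums(MU))
  scale <- if (tot > 0 && sc$photons_per_pixel > 0)
    sc$photons_per_pixel / tot else 0
  MU <- MU * scale
  full <- matrix(0, n_gates(sch), P)
  full[di, ] <- MU + rep(as.vector(sc$Z), each = nd)
  oi <- offset_gate_idx(sch)
  if (length(oi)) full[oi, ] <- rep(as.vector(sc$Z), each = length(oi))
  for (mi in motion_gate_idx(sch))
    full[mi, ] <- full[motion_partner_idx(sch, mi), ]
  list(mu = full, I0_map = matrix(scale * as.vector(sc$I0_rel), sc$dims[1L]))
}

#' Simulate a Poisson-noise time-gated stack from a scenario
#'
#' Draws independent Poisson counts around the forward-model expectation of
#' every gate (offset and motion-check gates included).  Deterministic under
#' the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return A list: `stack` (a [time_gated_stack()]), `truth` (the scenario
#'   plus the calibrated `I0_map` and expectation).
#' @export
simulate_stack <- function(scenario) {
  ex <- scenario_expectation(scenario)
  counts <- with_seed(scenario$seed,
                      stats::rpois(length(ex$mu), as.vector(ex$mu)))
  arr <- array(as.numeric(counts),
               c(n_gates(scenario$schedule), scenario$dims))
  list(stack = time_gated_stack(arr, scenario$schedule,
                                meta = list(scenario = scenario$name,
                                            seed = scenario$seed)),
       truth = c(scenario, list(I0_map = ex$I0_map, mu = ex$mu)))
}

#' Synthetic dye-mixture multiwell plate
#'
#' Emulates a two-dye plate in which wells contain amplitude mixtures of a
#' short- and a long-lifetime fluorophore at the stated ratios (e.g. the
#' classic 100:0 / 80:20 / ... / 0:100 dilution series).  Wells are assigned
#' to ratios in contiguous blocks; each well holds `fields_per_well`
#' independently simulated fields.  The default lifetime pair (1500 ps /
#' 3900 ps) is an invented stand-in for a rhodamine-like pair and carries no
#' calibration weight — recovery is always judged against the returned
#' truth.
#'
#' @param ratios amplitude fraction of the short-lifetime dye per condition,
#'   in `[0, 1]`.
#' @param tau_pair lifetimes (ps) of the short and long dye.
#' @param layout a [plate_layout()]; default 8 x 12 with equal blocks per
#'   ratio.
#' @param field_dim pixel dimensions of each field of view.
#' @param fields_per_well fields imaged per well.
#' @param photons mean decay-gate photons per pixel.
#' @param schedule gate schedule; default six contiguous 2000-ps gates.
#' @param irf an IRF.
#' @param seed master seed; field seeds are derived deterministically.
#' @return A list: `layout`, `wells` (named list per well of `fields`, each
#'   a stack, and the well's `ratio`), `truth` (lifetime pair, per-well
#'   ratios), `schedule`, `irf`.
#' @export
make_mixture_plate <- function(ratios = c(1, 0.8, 0.6, 0.4, 0.2, 0),
                               tau_pair = c(1500, 3900),
                               layout = NULL,
                               field_dim = c(16L, 16L),
                               fields_per_well = 1L,
                               photons = 300,
                               schedule = gate_schedule(
                                 seq(0, by = 2000, length.out = 6),
                                 width = 2000, rep_period = 1e6 / 60),
                               irf = irf_delta(), seed = 1L) {
  stopifnot(all(ratios >= 0 & ratios <= 1), length(tau_pair) == 2L)
  if (is.null(layout)) {
    n_per <- floor(96 / length(ratios))
    cond <- rep(paste0("ratio_", round(100 * ratios)),
                each = n_per)[seq_len(96)]
    layout <- plate_layout(8L, 12L, conditions = cond,
                           fields_per_well = fields_per_well)
  }
  well_ratio <- stats::setNames(
    ratios[match(layout$well_conditions,
                 paste0("ratio_", round(100 * ratios)))],
    names(layout$well_conditions))
  wells <- vector("list", length(well_ratio))
  names(wells) <- names(well_ratio)
  i <- 0L
  for (w in names(well_ratio)) {
    i <- i + 1L
    r <- well_ratio[[w]]
    if (is.na(r)) { wells[[w]] <- NULL; next }
    fields <- lapply(seq_len(fields_per_well), function(f) {
      sc <- sim_scenario(taus = tau_pair, alphas = c(r, 1 - r),
                         dims = field_dim, schedule = schedule, irf = irf,
                         photons_per_pixel = photons,
                         seed = (seed * 10007L + i * 131L + f) %%
                           .Machine$integer.max,
                         name = paste0(w, "_f", f))
      simulate_stack(sc)$stack
    })
    wells[[w]] <- list(ratio = r, fields = fields)
  }
  list(layout = layout, wells = wells,
       truth = list(tau_pair = tau_pair, well_ratio = well_ratio),
       schedule = schedule, irf = irf, seed = seed)
}

#' Synthetic FRET cell field with membrane geometry
#'
#' Emulates a field of cells expressing a membrane-targeted FRET pair: each
#' cell is an ellipse whose rim ("membrane", a ring of `membrane_width`
#' pixels) carries an elevated FRETing-donor fraction and brighter signal,
#' while the interior ("cytosol") is donor-dominated.  Default lifetimes
#' follow a CFP-like donor (2580 ps unquenched, 1586 ps FRETing).
#'
#' @param n_cells number of cells (>= 1).
#' @param dims field dimensions (pixels).
#' @param donor_tau,fret_tau non-FRETing and FRETing donor lifetimes (ps).
#' @param alpha2_membrane,alpha2_cytosol FRETing fraction on the membrane
#'   and in the cytosol.
#' @param membrane_boost relative membrane brightness.
#' @param membrane_width rim thickness (pixels).
#' @param photons mean decay-gate photons per pixel over the field.
#' @param schedule,irf acquisition timebase and IRF.
#' @param seed RNG seed (cell geometry and noise).
#' @return A list: `stack`, integer label images `membrane_mask` and
#'   `cytosol_mask` (0 = background, i = cell i), and `truth`.
#' @export
make_fret_cell_field <- function(n_cells = 5L, dims = c(64L, 64L),
                                 donor_tau = 2580, fret_tau = 1586,
                                 alpha2_membrane = 0.6,
                                 alpha2_cytosol = 0,
                                 membrane_boost = 2,
                                 membrane_width = 2L,
                                 photons = 300,
                                 schedule = default_gate_schedule(),
                                 irf = irf_delta(), seed = 1L) {
  stopifnot(n_cells >= 1L)
  geom <- with_seed(seed * 7L + 3L, {
    data.frame(cy = stats::runif(n_cells, 0.15, 0.85) * dims[1L],
               cx = stats::runif(n_cells, 0.15, 0.85) * dims[2L],
               ry = stats::runif(n_cells, 0.08, 0.14) * dims[1L],
               rx = stats::runif(n_cells, 0.08, 0.14) * dims[2L])
  })
  membrane <- cytosol <- matrix(0L, dims[1L], dims[2L])
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  for (i in seq_len(n_cells)) {
    d2 <- ((rr - geom$cy[i]) / geom$ry[i])^2 +
      ((cc - geom$cx[i]) / geom$rx[i])^2
    ## ring thickness expressed on the normalised radius
    shrink <- 1 - membrane_width / mean(c(geom$ry[i], geom$rx[i]))
    inside <- d2 <= 1
    inner <- d2 <= shrink^2
    free <- membrane == 0L & cytosol == 0L   # first cell claims overlaps
    membrane[inside & !inner & free] <- i
    cytosol[inner & free] <- i
  }
  alpha2 <- matrix(0, dims[1L], dims[2L])
  alpha2[cytosol > 0L] <- alpha2_cytosol
  alpha2[membrane > 0L] <- alpha2_membrane
  I0_rel <- matrix(0, dims[1L], dims[2L])
  I0_rel[cytosol > 0L] <- 1
  I0_rel[membrane > 0L] <- membrane_boost
  sc <- sim_scenario(taus = c(donor_tau, fret_tau),
                     alphas = list(1 - alpha2, alpha2),
                     schedule = schedule, irf = irf,
                     photons_per_pixel = photons, I0_rel = I0_rel,
                     seed = seed, name = "fret_cell_field")
  sim <- simulate_stack(sc)
  list(stack = sim$stack, membrane_mask = membrane, cytosol_mask = cytosol,
       truth = c(sim$truth, list(alpha2_map = alpha2,
                                 donor_tau = donor_tau,
                                 fret_tau = fret_tau)))
}

#' Synthetic FLIM time series with a varying FRETing fraction
#'
#' Generates one stack per timepoint sharing the base scenario's lifetimes
#' while the second-component amplitude fraction follows
#' `alpha2_trajectory` (e.g. a calcium-binding time course).  Per-timepoint
#' seeds are derived from the scenario seed, so timepoints are independent
#' but the whole series is reproducible.
#'
#' @param base a [sim_scenario()] with two components.
#' @param alpha2_trajectory numeric vector (length >= 2) of per-timepoint
#'   second-component fractions in `[0, 1]`.
#' @return A list: `stacks` (list of [time_gated_stack()]), `truth`.
#' @export
make_series <- function(base, alpha2_trajectory) {
  stopifnot(inherits(base, "sim_scenario"), base$n_components == 2L,
            length(alpha2_trajectory) >= 2L,
            all(alpha2_trajectory >= 0 & alpha2_trajectory <= 1))
  stacks <- lapply(seq_along(alpha2_trajectory), function(t) {
    a2 <- alpha2_trajectory[t]
    sc <- base
    sc$alpha_maps <- list(matrix(1 - a2, base$dims[1L], base$dims[2L]),
                          matrix(a2, base$dims[1L], base$dims[2L]))
    sc$seed <- (base$seed * 2654435L + t * 97L) %% .Machine$integer.max
    simulate_stack(sc)$stack
  })
  list(stacks = stacks,
       truth = list(taus = vapply(base$tau_maps, function(m) m[1L], 0),
                    alpha2 = alpha2_trajectory, base_seed = base$seed))
}
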