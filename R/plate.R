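#' Multiwell-plate layout
#'
#' @param rows,cols plate geometry (8 x 12 for a 96-well plate).
#' @param conditions character vector of condition labels, one per well in
#'   row-major order (A1, A2, ...), or a named vector keyed by well id.
#' @param fields_per_well fields of view imaged per well.
#' @return An object of class `plate_layout` with unique well ids of the
#'   form `A1 .. H12`.
#' @export
plate_layout <- function(rows = 8L, cols = 12L, conditions = NULL,
                         fields_per_well = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, fields_per_well >= 1L)
  ids <- as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
  if (is.null(conditions)) conditions <- rep("default", rows * cols)
  if (is.null(names(conditions))) {
    stopifnot(length(conditions) == rows * cols)
    conditions <- stats::setNames(conditions, ids)
  } else if (!all(names(conditions) %in% ids)) {
    stop("unknown well id in conditions")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 well_ids = ids,
                 well_conditions = as.list(conditions[ids]),
                 fields_per_well = as.integer(fields_per_well)),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("Plate layout: %d x %d (%d wells), %d field(s)/well, %d condition(s)\n",
              x$rows, x$cols, length(x$well_ids), x$fields_per_well,
              length(unique(unlist(x$well_conditions)))))
  invisible(x)
}

#' Read / write a plate layout as CSV
#'
#' Columns `well,row,col,condition`; JSON (`.json`) is also accepted.
#'
#' @param layout a [plate_layout()].
#' @param path file path.
#' @return `read_plate_layout` returns a [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  rowi <- match(substr(layout$well_ids, 1L, 1L), LETTERS)
  coli <- as.integer(substring(layout$well_ids, 2L))
  utils::write.csv(data.frame(well = layout$well_ids, row = rowi,
                              col = coli,
                              condition = unlist(layout$well_conditions)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_layout
#' @param fields_per_well fields per well (not stored in the CSV form).
#' @export
read_plate_layout <- function(path, fields_per_well = 1L) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(plate_layout(x$rows, x$cols,
                        stats::setNames(unlist(x$well_conditions),
                                        names(x$well_conditions)),
                        x$fields_per_well))
  }
  d <- utils::read.csv(path)
  plate_layout(max(d$row), max(d$col),
               stats::setNames(as.character(d$condition), d$well),
               fields_per_well)
}

#' Integrated fluorescence intensity image
#'
#' Sums the decay-gate counts per pixel (integration under the sampled decay
#' curve) and subtracts the background estimated from the offset gate, if
#' one exists, times the number of decay gates; clipped at zero.
#'
#' @param stack a [time_gated_stack()].
#' @return Numeric matrix of background-corrected intensities.
#' @export
intensity_image <- function(stack) {
  di <- decay_gate_idx(stack$schedule)
  img <- apply(stack$counts[di, , , drop = FALSE], c(2L, 3L), sum)
  oi <- offset_gate_idx(stack$schedule)
  if (length(oi)) {
    z <- apply(stack$counts[oi, , , drop = FALSE], c(2L, 3L), mean)
    img <- img - length(di) * z
  }
  pmax(img, 0)
}

#' Threshold an intensity image
#'
#' @param image numeric matrix.
#' @param threshold strict lower cut: pixels with `image > threshold` are
#'   selected.
#' @return Logical mask.
#' @export
threshold_mask <- function(image, threshold) {
  stopifnot(threshold >= 0)
  image > threshold
}

#' Prescan field selection
#'
#' Reproduces the plate reader's seek logic: fields of view are scanned in
#' acquisition order and a field qualifies when the fraction of its pixels
#' above the intensity threshold reaches `min_fraction`; scanning stops once
#' `n_required` fields qualify.  If fewer qualify the well is flagged as
#' having insufficient cells.
#'
#' @param fields list of intensity images (matrices).
#' @param threshold intensity threshold.
#' @param min_fraction required above-threshold pixel fraction in `[0, 1]`.
#' @param n_required number of fields sought (`Inf` returns every
#'   qualifying field).
#' @return A list: `selected` (indices, order preserved), `sufficient`
#'   (logical), `fractions` (per scanned field).
#' @export
prescan_select <- function(fields, threshold, min_fraction, n_required) {
  stopifnot(min_fraction >= 0, min_fraction <= 1, n_required >= 1)
  sel <- integer(0)
  fr <- numeric(0)
  for (i in seq_along(fields)) {
    f <- mean(fields[[i]] > threshold)
    fr[i] <- f
    if (f >= min_fraction) sel <- c(sel, i)
    if (length(sel) >= n_required) break
  }
  list(selected = sel,
       sufficient = is.infinite(n_required) || length(sel) >= n_required,
       fractions = fr)
}

#' Sample-motion check
#'
#' Compares the motion-check gate image with its partner decay gate acquired
#' at the same delay.  Both frames are normalised to unit total counts and
#' the metric is the mean absolute pixel difference relative to the mean
#' pixel level (equivalently the L1 distance of the normalised frames); it
#' is zero for identical frames and sits at the shot-noise floor for a
#' static sample.
#'
#' @param stack a [time_gated_stack()] whose schedule has a motion-check
#'   gate.
#' @param rel_tolerance pass threshold on the metric.
#' @return A list: `metric`, `pass`.
#' @export
motion_check <- function(stack, rel_tolerance = 0.2) {
  mi <- motion_gate_idx(stack$schedule)
  if (!length(mi)) stop("schedule has no motion_check gate")
  mi <- mi[1L]
  pi <- motion_partner_idx(stack$schedule, mi)
  f1 <- stack$counts[pi, , ]; f2 <- stack$counts[mi, , ]
  s1 <- sum(f1); s2 <- sum(f2)
  if (s1 <= 0 || s2 <= 0)
    return(list(metric = Inf, pass = FALSE))
  metric <- sum(abs(f1 / s1 - f2 / s2))
  list(metric = metric, pass = metric <= rel_tolerance)
}

#' Aggregate fitted lifetimes over a well
#'
#' Pools the unmasked pixel lifetimes of all fields of a well (each pixel
#' counts once; fields are not reweighted) and summarises them as mean,
#' standard deviation and a histogram with 10-ps bins.
#'
#' @param images list of `flim_image` results (or lifetime matrices), one
#'   per field.
#' @param well_id well label.
#' @param mask optional logical matrix (or list per field) restricting the
#'   pooled pixels.
#' @param bin_width histogram bin width (ps).
#' @return An object of class `well_summary`: `well_id`, `mean_tau`,
#'   `sd_tau`, `n_pixels`, `n_fields`, `histogram` (list of `breaks`,
#'   `counts`), `empty` flag.
#' @export
aggregate_well <- function(images, well_id = "well", mask = NULL,
                           bin_width = 10) {
  if (!is.list(images) || inherits(images, "flim_image"))
    images <- list(images)
  taus <- c()
  for (i in seq_along(images)) {
    im <- images[[i]]
    tau <- if (inherits(im, "flim_image")) im$tau else im
    if (!is.null(mask)) {
      m <- if (is.list(mask)) mask[[i]] else mask
      tau[!m] <- NA
    }
    taus <- c(taus, tau[!is.na(tau)])
  }
  if (!length(taus)) {
    return(structure(list(well_id = well_id, mean_tau = NA_real_,
                          sd_tau = NA_real_, n_pixels = 0L,
                          n_fields = length(images), histogram = NULL,
                          empty = TRUE), class = "well_summary"))
  }
  lo <- floor(min(taus) / bin_width) * bin_width
  hi <- ceiling(max(taus) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(taus, breaks = breaks, plot = FALSE)
  structure(list(well_id = well_id, mean_tau = mean(taus),
                 sd_tau = stats::sd(taus),
                 n_pixels = length(taus), n_fields = length(images),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 empty = FALSE), class = "well_summary")
}

#' @export
print.well_summary <- function(x, ...) {
  if (x$empty) {
    cat("Well", x$well_id, "- empty (no fitted pixels)\n")
  } else {
    cat(sprintf("Well %s: mean tau %.1f +/- %.1f ps over %d pixels (%d fields)\n",
                x$well_id, x$mean_tau, x$sd_tau, x$n_pixels, x$n_fields))
  }
  invisible(x)
}

#' Per-well mean-lifetime plate map
#'
#' @param layout a [plate_layout()].
#' @param summaries list of [aggregate_well()] results keyed (or named) by
#'   well id.
#' @return Numeric matrix in plate geometry (rows x cols, dimnames by row
#'   letter / column number); wells without data, or flagged empty, are
#'   `NA`.
#' @export
plate_map <- function(layout, summaries) {
  if (is.null(names(summaries)))
    names(summaries) <- vapply(summaries, function(s) s$well_id, "")
  unknown <- setdiff(names(summaries), layout$well_ids)
  if (length(unknown))
    stop("unknown well id(s): ", paste(unknown, collapse = ", "))
  m <- matrix(NA_real_, layout$rows, layout$cols,
              dimnames = list(LETTERS[seq_len(layout$rows)],
                              seq_len(layout$cols)))
  for (w in names(summaries)) {
    s <- summaries[[w]]
    if (!isTRUE(s$empty))
      m[substr(w, 1L, 1L), substring(w, 2L)] <- s$mean_tau
  }
  m
}

#' Per-ROI binned lifetime analysis
#'
#' For every nonzero label of a segmentation image, bins the gated counts of
#' the region into a composite decay ([fit_binned_roi()]) and fits a
#' mono-exponential (or the supplied model).  This is the classic per-ROI
#' readout: one lifetime per cell or membrane region.
#'
#' @param stack a [time_gated_stack()].
#' @param labels integer label image (0 = background).
#' @param model_config passed to [fit_binned_roi()].
#' @param irf an IRF.
#' @param opts a [fit_options()] list.
#' @return data.frame with one row per label: `label`, `tau` (amplitude-
#'   weighted mean lifetime, ps), `n_photons`, `chi2`, `n_pixels`,
#'   `converged`.
#' @export
per_roi_analysis <- function(stack, labels, model_config = 1L,
                             irf = irf_delta(), opts = fit_options()) {
  stopifnot(all(dim(labels) == stack_dim(stack)))
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) stop("no nonzero label in segmentation image")
  out <- lapply(labs, function(l) {
    f <- fit_binned_roi(stack, labels == l, model_config, irf, opts)
    data.frame(label = l, tau = mean_lifetime(f$model),
               n_photons = f$n_photons, chi2 = f$chi2,
               n_pixels = sum(labels == l), converged = f$converged)
  })
  do.call(rbind, out)
}
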