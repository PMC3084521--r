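#' Instrument response functions
#'
#' The temporal instrument response function (IRF) of a gated imaging system
#' is the response to an instantaneous emitter; on real instruments it is
#' measured with very short-lifetime dyes (DASPI, erythrosin B, lifetimes
#' below 150 ps).  Three representations are supported:
#'
#' * `irf_delta(t0)` — an ideal impulse at time `t0`;
#' * `irf_gaussian(fwhm, t0)` — a normalised Gaussian of full width at half
#'   maximum `fwhm` centred at `t0`;
#' * `irf_measured(time, weight, t0)` — a sampled IRF given as
#'   (time, weight) pairs; weights must be non-negative and are normalised
#'   to unit sum.
#'
#' All times are picoseconds; `t0` absorbs any trigger offset between the
#' nominal excitation time and the true arrival of the pulse.
#'
#' @param t0 temporal offset (ps).
#' @param fwhm full width at half maximum (ps), Gaussian only.
#' @param time,weight sample positions (ps) and non-negative weights,
#'   measured IRF only.
#' @return An object of class `irf`.
#' @seealso [make_gaussian_irf()], [decay_basis()]
#' @export
irf_delta <- function(t0 = 0) {
  structure(list(kind = "delta", t0 = as.numeric(t0)), class = "irf")
}

#' @rdname irf_delta
#' @export
irf_gaussian <- function(fwhm, t0 = 0) {
  stopifnot(is.finite(fwhm), fwhm > 0)
  structure(list(kind = "gaussian", t0 = as.numeric(t0),
                 fwhm = as.numeric(fwhm)), class = "irf")
}

#' @rdname irf_delta
#' @export
irf_measured <- function(time, weight, t0 = 0) {
  time <- as.numeric(time); weight <- as.numeric(weight)
  stopifnot(length(time) == length(weight), length(time) >= 1L,
            all(is.finite(time)), all(is.finite(weight)))
  if (any(weight < 0)) stop("measured IRF weights must be >= 0")
  s <- sum(weight)
  if (s <= 0) stop("measured IRF weights must have positive sum")
  o <- order(time)
  structure(list(kind = "measured", t0 = as.numeric(t0),
                 time = time[o], weight = weight[o] / s), class = "irf")
}

#' @export
print.irf <- function(x, ...) {
  cat("IRF:", x$kind,
      switch(x$kind,
             delta = sprintf("(t0 = %g ps)", x$t0),
             gaussian = sprintf("(fwhm = %g ps, t0 = %g ps)", x$fwhm, x$t0),
             measured = sprintf("(%d samples, t0 = %g ps)",
                                length(x$time), x$t0)),
      "\n")
  invisible(x)
}

irf_sigma <- function(irf) irf$fwhm / (2 * sqrt(2 * log(2)))

## coarsest spacing of a measured IRF; used for the resolution check
irf_resolution <- function(irf) {
  if (irf$kind != "measured" || length(irf$time) < 2L) return(0)
  max(diff(irf$time))
}

#' Serialise / deserialise an IRF
#'
#' JSON carries any IRF kind; a measured IRF can alternatively be written as
#' a two-column CSV (`time_ps`, `weight`).
#'
#' @param irf an [irf_delta()], [irf_gaussian()] or [irf_measured()] object.
#' @param path file path; `.csv` selects the CSV form (measured IRFs only).
#' @return `read_irf` returns an `irf`; `write_irf` returns `path` invisibly.
#' @export
write_irf <- function(irf, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (irf$kind != "measured")
      stop("CSV form is only defined for measured IRFs")
    utils::write.csv(data.frame(time_ps = irf$time, weight = irf$weight),
                     path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(irf), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_irf
#' @export
read_irf <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
    return(irf_measured(d$time_ps, d$weight))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(x$kind,
         delta = irf_delta(x$t0),
         gaussian = irf_gaussian(x$fwhm, x$t0),
         measured = irf_measured(x$time, x$weight, x$t0),
         stop("unknown IRF kind: ", x$kind))
}
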