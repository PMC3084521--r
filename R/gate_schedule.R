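#' Gate schedule for time-gated FLIM acquisition
#'
#' A gate schedule describes the acquisition timebase of a gated optical
#' intensifier (GOI) system: the start time of each gate relative to the
#' nominal excitation pulse, the (common) gate width, the excitation
#' repetition period, and the role of each gate.  A typical plate-reader
#' schedule uses seven gates: five sampling the decay, one offset gate
#' measuring the background with the intensifier gated away from the decay,
#' and one motion-check gate duplicating the delay of a decay gate so that
#' sample movement during the acquisition can be detected.
#'
#' @param delays numeric vector of gate start times in picoseconds, relative
#'   to the nominal excitation pulse.
#' @param width single positive gate duration in picoseconds (all gates share
#'   one width).
#' @param rep_period excitation repetition period T in picoseconds
#'   (e.g. 1e6/60 ps for a 60 MHz source).  `Inf` disables incomplete-decay
#'   handling.
#' @param roles character vector, one per gate, each one of `"decay"`,
#'   `"offset"` or `"motion_check"`.  Defaults to all `"decay"`.
#'
#' @return An object of class `gate_schedule`.
#' @details Gates may extend past the repetition period (they then integrate
#'   signal excited by the next pulse); at most one offset gate is allowed and
#'   every motion-check gate must duplicate the delay of some decay gate.
#'   Decay-gate delays must be distinct.
#' @seealso [default_gate_schedule()], [decay_basis()], [forward_counts()]
#' @export
gate_schedule <- function(delays, width, rep_period = Inf,
                          roles = rep("decay", length(delays))) {
  delays <- as.numeric(delays)
  stopifnot(length(width) == 1L, is.finite(width), width > 0,
            length(rep_period) == 1L, rep_period > 0,
            length(roles) == length(delays))
  roles <- match.arg(roles, c("decay", "offset", "motion_check"),
                     several.ok = TRUE)
  if (sum(roles == "offset") > 1L)
    stop("at most one offset gate is allowed")
  if (!any(roles == "decay"))
    stop("schedule must contain at least one decay gate")
  ddel <- delays[roles == "decay"]
  if (anyDuplicated(ddel))
    stop("decay-gate delays must be distinct")
  for (d in delays[roles == "motion_check"])
    if (!any(abs(ddel - d) < 1e-9))
      stop("motion_check gate must duplicate the delay of a decay gate")
  structure(list(delays = delays, width = width,
                 rep_period = rep_period, roles = roles),
            class = "gate_schedule")
}

#' Default seven-gate plate-reader schedule
#'
#' Seven gates of width 2000 ps: decay gates at delays 0, 1000, 2500, 4500
#' and 7000 ps, one offset gate and one motion-check gate duplicating the
#' first delay, with a repetition period of 1e6/60 ps (60 MHz excitation).
#'
#' @param width gate width (ps).
#' @param delays decay-gate delays (ps).
#' @param rep_period repetition period (ps).
#' @param offset include an offset gate?
#' @param motion_check include a motion-check gate (duplicate of the first
#'   decay delay)?
#' @return A [gate_schedule()].
#' @export
default_gate_schedule <- function(width = 2000,
                                  delays = c(0, 1000, 2500, 4500, 7000),
                                  rep_period = 1e6 / 60,
                                  offset = TRUE, motion_check = TRUE) {
  d <- delays; r <- rep("decay", length(delays))
  if (offset) { d <- c(d, max(delays) + 2 * width); r <- c(r, "offset") }
  if (motion_check) { d <- c(d, delays[1L]); r <- c(r, "motion_check") }
  gate_schedule(d, width = width, rep_period = rep_period, roles = r)
}

#' @export
print.gate_schedule <- function(x, ...) {
  cat("Gate schedule:", length(x$delays), "gates, width", x$width, "ps,",
      "rep. period", format(x$rep_period), "ps\n")
  cat(sprintf("  %-13s %s\n", "delay (ps)", "role"))
  for (i in seq_along(x$delays))
    cat(sprintf("  %-13g %s\n", x$delays[i], x$roles[i]))
  invisible(x)
}

n_gates <- function(schedule) length(schedule$delays)

decay_gate_idx <- function(schedule) which(schedule$roles == "decay")
offset_gate_idx <- function(schedule) which(schedule$roles == "offset")
motion_gate_idx <- function(schedule) which(schedule$roles == "motion_check")

## index (into delays) of the decay gate a motion-check gate duplicates
motion_partner_idx <- function(schedule, mc_idx) {
  d <- decay_gate_idx(schedule)
  d[which(abs(schedule$delays[d] - schedule$delays[mc_idx]) < 1e-9)[1L]]
}

#' Serialise / deserialise a gate schedule as JSON
#'
#' @param schedule a [gate_schedule()].
#' @param path file path.
#' @return `read_gate_schedule` returns a [gate_schedule()];
#'   `write_gate_schedule` returns `path` invisibly.
#' @export
write_gate_schedule <- function(schedule, path) {
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gate_schedule
#' @export
read_gate_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rp <- x$rep_period
  if (is.character(rp)) rp <- as.numeric(rp)  # "Inf" round-trip
  gate_schedule(x$delays, x$width, rp, x$roles)
}
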