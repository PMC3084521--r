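#' Write / read a time-gated stack as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per gate (32-bit float samples; counts are divided by a
#' power-of-two scale recorded in the sidecar, so integer photon counts
#' below 2^24 round-trip losslessly) and a JSON sidecar (`<path>.json`)
#' carrying the gate schedule, the scale, pixel size and provenance.
#'
#' @param stack a [time_gated_stack()].
#' @param path TIFF file path (the sidecar is written next to it).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   [time_gated_stack()].
#' @export
write_stack <- function(stack, path) {
  maxv <- max(stack$counts)
  integer_data <- all(stack$counts == round(stack$counts))
  if (integer_data) {
    bits <- if (maxv <= 65535) 16L else 32L
    scale <- 2^bits - 1          # integer counts map onto exact sample codes
  } else {
    bits <- 32L
    scale <- max(maxv, 1)
  }
  pages <- lapply(seq_len(dim(stack$counts)[1L]),
                  function(g) stack$counts[g, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  sidecar <- list(format = "flimgate-stack", scale = scale,
                  integer_data = integer_data,
                  n_gates = n_gates(stack$schedule),
                  schedule = unclass(stack$schedule),
                  pixel_size = stack$pixel_size, meta = stack$meta)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar '", sp, "': every stack TIFF needs a JSON ",
         "sidecar with its gate schedule (see write_stack)")
  sc <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                 error = function(e)
                   stop("corrupt sidecar '", sp, "': ",
                        conditionMessage(e)))
  if (is.null(sc$schedule) || is.null(sc$scale))
    stop("corrupt sidecar '", sp, "': missing schedule or scale")
  rp <- sc$schedule$rep_period
  if (is.character(rp)) rp <- as.numeric(rp)
  schedule <- gate_schedule(sc$schedule$delays, sc$schedule$width,
                            rp, sc$schedule$roles)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_gates(schedule))
    stop("format error: TIFF has ", length(pages),
         " pages but the schedule lists ", n_gates(schedule), " gates")
  counts <- array(0, c(length(pages), dim(pages[[1L]])[1:2]))
  for (g in seq_along(pages)) {
    pg <- pages[[g]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    counts[g, , ] <- pg * sc$scale
  }
  if (isTRUE(sc$integer_data)) counts <- round(counts)
  time_gated_stack(counts, schedule,
                   pixel_size = sc$pixel_size,
                   meta = if (is.null(sc$meta)) list() else sc$meta)
}

#' Write analysis results with a hash manifest
#'
#' Tables go to CSV, image maps to 32-bit-float TIFF (power-of-two scaled,
#' scale in the manifest), and a JSON manifest lists every artifact with its
#' MD5 hash in deterministic (sorted) order.
#'
#' @param tables named list of data.frames.
#' @param maps named list of numeric matrices (NA allowed; stored as -1).
#' @param outdir output directory (created if needed).
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
write_results <- function(tables = list(), maps = list(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (nm in sort(names(tables))) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    entries[[length(entries) + 1L]] <-
      list(name = nm, file = basename(f), kind = "table",
           md5 = unname(tools::md5sum(f)))
  }
  for (nm in sort(names(maps))) {
    m <- maps[[nm]]
    m[is.na(m)] <- -1           # NA marker, recovered via the offset
    offset <- min(m, 0)
    scale <- 2^max(0, ceiling(log2(max(m) - offset + 1)))
    f <- file.path(outdir, paste0(nm, ".tif"))
    tiff::writeTIFF((m - offset) / scale, f, bits.per.sample = 32L,
                    compression = "none")
    entries[[length(entries) + 1L]] <-
      list(name = nm, file = basename(f), kind = "map", scale = scale,
           offset = offset, md5 = unname(tools::md5sum(f)))
  }
  manifest <- list(artifacts = entries)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a false-colour lifetime image
#'
#' The conventional FLIM display: hue encodes the lifetime (clipped to
#' `tau_range`, blue = long to red = short) and brightness encodes the
#' integrated intensity; masked (`NA`) or zero-intensity pixels are black.
#'
#' @param tau_map lifetime image (ps).
#' @param intensity_map intensity image, same dimensions.
#' @param tau_range lifetime limits (ps) mapped to the colour-scale ends.
#' @return RGB array (rows x cols x 3) in `[0, 1]`.
#' @export
render_lifetime_image <- function(tau_map, intensity_map,
                                  tau_range = range(tau_map, na.rm = TRUE)) {
  stopifnot(all(dim(tau_map) == dim(intensity_map)),
            length(tau_range) == 2L, tau_range[1L] < tau_range[2L])
  tr <- pmin(pmax(tau_map, tau_range[1L]), tau_range[2L])
  frac <- (tr - tau_range[1L]) / diff(tau_range)
  v <- intensity_map / max(intensity_map, na.rm = TRUE)
  v[!is.finite(v) | v < 0] <- 0
  bad <- is.na(tau_map) | is.na(intensity_map)
  frac[bad] <- 0; v[bad] <- 0
  col <- grDevices::hsv(h = 0.7 * frac, s = 1, v = v)
  rgb <- grDevices::col2rgb(col) / 255
  out <- array(0, c(dim(tau_map), 3L))
  out[, , 1L] <- matrix(rgb[1L, ], nrow(tau_map))
  out[, , 2L] <- matrix(rgb[2L, ], nrow(tau_map))
  out[, , 3L] <- matrix(rgb[3L, ], nrow(tau_map))
  out
}
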