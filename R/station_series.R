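#' Digitized body-outline station series
#'
#' A `station_series` holds the dorsal/ventral/lateral extrema of a body
#' outline digitized at successive anteroposterior stations, together with an
#' anatomical region label for every inter-station interval.  It is the raw
#' geometric input from which frustum chains and all mass properties are
#' derived.
#'
#' Coordinate convention: `x` is measured in metres from the tip of the
#' rostrum (`x = 0`), `y` from the ventral-most point of the trunk
#' (`y = 0`, typically the pubic foot), and `z = 0` is the midline;
#' `z_half` is the half-width, so the body is assumed bilaterally
#' symmetrical.
#'
#' @param x Numeric vector of station positions (m), strictly increasing.
#' @param y_dorsal,y_ventral Dorsal and ventral outline heights (m) at each
#'   station; `y_dorsal >= y_ventral` everywhere.
#' @param z_half Half-widths (m) from the midline, non-negative.
#' @param region Character vector of region labels, one per inter-station
#'   interval (length `length(x) - 1`), drawn from contiguous blocks such as
#'   `"head"`, `"neck"`, `"trunk"`, `"tail"`.  A vector of length `length(x)`
#'   is also accepted (per-station labels, as stored on file); the label of
#'   the anterior station is then used for each interval.
#' @param scale_reference Optional femur length (m) recording the scale bar
#'   used when digitizing.
#' @param warn_segments If `TRUE`, warn when the series has fewer than 60
#'   intervals (digitizations of full bodies are expected to use 60 or more
#'   segments; fewer is legal but coarse).
#'
#' @return An object of class `station_series`: a list with elements
#'   `stations` (data frame `x`, `y_dorsal`, `y_ventral`, `z_half`),
#'   `region` (per-interval labels) and `scale_reference`.
#' @seealso [read_station_series()], [slice_to_frusta()],
#'   [apply_tail_modifiers()]
#' @export
station_series <- function(x, y_dorsal, y_ventral, z_half, region,
                           scale_reference = NULL, warn_segments = FALSE) {
  n <- length(x)
  if (n < 2L)
    stop("a station series needs at least 2 stations", call. = FALSE)
  lens <- c(length(y_dorsal), length(y_ventral), length(z_half))
  if (any(lens != n))
    stop("x, y_dorsal, y_ventral and z_half must have equal length",
         call. = FALSE)
  if (length(region) == n) region <- region[-n]
  if (length(region) != n - 1L)
    stop("region must have one label per inter-station interval (",
         n - 1L, "), got ", length(region), call. = FALSE)

  bad <- which(diff(x) <= 0)
  if (length(bad))
    stop("station x positions must be strictly increasing; violation at ",
         "station ", bad[1L] + 1L, " (x = ", x[bad[1L] + 1L], ")",
         call. = FALSE)
  bad <- which(y_dorsal < y_ventral)
  if (length(bad))
    stop("y_dorsal < y_ventral at station ", bad[1L], call. = FALSE)
  if (any(z_half < 0))
    stop("z_half must be non-negative (station ",
         which(z_half < 0)[1L], ")", call. = FALSE)

  region <- as.character(region)
  blocks <- rle(region)$values
  if (anyDuplicated(blocks))
    stop("region labels must form contiguous blocks; '",
         blocks[anyDuplicated(blocks)], "' appears in two separate blocks",
         call. = FALSE)
  if (warn_segments && (n - 1L) < 60L)
    warning("station series has only ", n - 1L,
            " intervals; digitizations usually use 60+ segments",
            call. = FALSE)

  structure(
    list(stations = data.frame(x = as.numeric(x),
                               y_dorsal = as.numeric(y_dorsal),
                               y_ventral = as.numeric(y_ventral),
                               z_half = as.numeric(z_half)),
         region = region,
         scale_reference = scale_reference),
    class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  st <- x$stations
  cat("Station series: ", nrow(st), " stations, ", nrow(st) - 1L,
      " intervals\n", sep = "")
  cat("  extent: ", format(min(st$x)), " - ", format(max(st$x)), " m\n",
      sep = "")
  tab <- table(factor(x$region, levels = unique(x$region)))
  cat("  regions: ",
      paste(names(tab), " (", as.integer(tab), ")", sep = "",
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$scale_reference))
    cat("  scale reference (femur length): ", x$scale_reference, " m\n",
        sep = "")
  invisible(x)
}

#' Straightened hind-leg station series
#'
#' Stations along the proximo-distal axis of a straightened leg.  The
#' mediolateral semi-axis `r_lm` is held constant along the whole leg (the
#' muscled leg is modelled with a uniform mediolateral semi-minor axis);
#' anteroposterior radii `r_ap` vary by station.
#'
#' @param s Strictly increasing station positions (m) from the proximal end.
#' @param r_ap Anteroposterior radii (m) at each station, non-negative.
#' @param r_lm Mediolateral radius (m): either a single value or a constant
#'   vector.
#' @param z_offset Lateral distance (m) from the body midline to the leg
#'   axis.
#' @param hip_x Optional anteroposterior position (m, from the rostrum) of
#'   the leg axis, used when composing body and swing-leg inertia.
#'
#' @return An object of class `leg_series`.
#' @export
leg_series <- function(s, r_ap, r_lm, z_offset = 0, hip_x = NA_real_) {
  if (length(s) < 2L)
    stop("a leg series needs at least 2 stations", call. = FALSE)
  if (length(r_ap) != length(s))
    stop("r_ap must match s in length", call. = FALSE)
  if (length(r_lm) == 1L) r_lm <- rep(r_lm, length(s))
  if (length(r_lm) != length(s))
    stop("r_lm must be scalar or match s in length", call. = FALSE)
  if (max(r_lm) - min(r_lm) > 1e-12 * max(r_lm, 1))
    stop("r_lm must be constant along the leg", call. = FALSE)
  bad <- which(diff(s) <= 0)
  if (length(bad))
    stop("leg station s positions must be strictly increasing; violation ",
         "at station ", bad[1L] + 1L, call. = FALSE)
  if (any(r_ap < 0) || any(r_lm < 0))
    stop("leg radii must be non-negative", call. = FALSE)
  structure(
    list(stations = data.frame(s = as.numeric(s), r_ap = as.numeric(r_ap),
                               r_lm = as.numeric(r_lm)),
         z_offset = z_offset, hip_x = hip_x),
    class = "leg_series")
}

#' @export
print.leg_series <- function(x, ...) {
  cat("Leg series: ", nrow(x$stations), " stations, length ",
      format(max(x$stations$s) - min(x$stations$s)), " m, z offset ",
      x$z_offset, " m\n", sep = "")
  invisible(x)
}

#' Read a digitized station table
#'
#' Reads a comma-separated station table with columns `x_m`, `y_dorsal_m`,
#' `y_ventral_m`, `z_half_m` and `region` (one row per station; an
#' interval takes the region label of its anterior station).  If both
#' `femur_length` and `femur_digitized` are supplied, all coordinates are
#' rescaled by `femur_length / femur_digitized` so that the digitization
#' matches the specimen's femur length.
#'
#' @param path Path to the CSV file.
#' @param femur_length True femur length of the specimen (m), optional.
#' @param femur_digitized Femur length as measured in the digitization (m),
#'   optional.
#' @param warn_segments Warn when fewer than 60 intervals are present
#'   (default `TRUE` for files, which are expected to be full digitizations).
#' @return A [station_series()].
#' @export
read_station_series <- function(path, femur_length = NULL,
                                femur_digitized = NULL,
                                warn_segments = TRUE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_m", "y_dorsal_m", "y_ventral_m", "z_half_m", "region")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("station table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in need[1:4]) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column ", col, " of ", path, call. = FALSE)
    tab[[col]] <- v
  }
  scl <- 1
  scale_ref <- NULL
  if (!is.null(femur_length) && !is.null(femur_digitized)) {
    if (femur_length <= 0 || femur_digitized <= 0)
      stop("femur lengths must be positive", call. = FALSE)
    scl <- femur_length / femur_digitized
    scale_ref <- femur_length
  }
  station_series(tab$x_m * scl, tab$y_dorsal_m * scl, tab$y_ventral_m * scl,
                 tab$z_half_m * scl, tab$region,
                 scale_reference = scale_ref, warn_segments = warn_segments)
}

#' Write a station series to a CSV station table
#'
#' Inverse of [read_station_series()]: emits the documented `x_m`,
#' `y_dorsal_m`, `y_ventral_m`, `z_half_m`, `region` header.  The last
#' station repeats the final interval's region label.
#'
#' @param body A [station_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_station_series <- function(body, path) {
  stopifnot(inherits(body, "station_series"))
  st <- body$stations
  reg <- c(body$region, body$region[length(body$region)])
  out <- data.frame(x_m = st$x, y_dorsal_m = st$y_dorsal,
                    y_ventral_m = st$y_ventral, z_half_m = st$z_half,
                    region = reg)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply tail width and depth modifiers
#'
#' Rescales the tail region of a body outline: half-widths (`z_half`) are
#' multiplied by `width_factor`, and the dorsoventral extent is scaled about
#' its midline by `depth_factor`.  A `width_factor` of 1.4 reproduces the
#' upper-bound tail cross-sections measured on adult *Alligator*; depth
#' factors of 0.9/1.1 probe the sensitivity of mass properties to
#' chevron-to-caudal-rib articulation.
#'
#' The modifier applies to every station that bounds a tail interval,
#' including the station shared with the preceding region, so that a tail of
#' constant cross-section changes volume by exactly `width_factor`.  The
#' posterior face of the last pre-tail frustum therefore also widens; all
#' other regions are untouched (see the methods vignette for the boundary
#' convention).
#'
#' @param body A [station_series()].
#' @param width_factor Multiplier (> 0) on tail half-widths.
#' @param depth_factor Multiplier (> 0) on tail dorsoventral extents.
#' @param tail_region Label of the tail region (default `"tail"`).
#' @return A modified [station_series()].
#' @export
apply_tail_modifiers <- function(body, width_factor = 1.4,
                                 depth_factor = 1, tail_region = "tail") {
  stopifnot(inherits(body, "station_series"))
  if (width_factor <= 0 || depth_factor <= 0)
    stop("tail modifiers must be positive", call. = FALSE)
  st <- body$stations
  n <- nrow(st)
  is_tail_int <- body$region == tail_region
  ## a station is modified when any adjacent interval belongs to the tail
  touch <- c(is_tail_int, FALSE) | c(FALSE, is_tail_int)
  if (any(touch)) {
    st$z_half[touch] <- st$z_half[touch] * width_factor
    mid <- (st$y_dorsal[touch] + st$y_ventral[touch]) / 2
    half <- (st$y_dorsal[touch] - st$y_ventral[touch]) / 2
    st$y_dorsal[touch] <- mid + half * depth_factor
    st$y_ventral[touch] <- mid - half * depth_factor
  }
  station_series(st$x, st$y_dorsal, st$y_ventral, st$z_half, body$region,
                 scale_reference = body$scale_reference)
}
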