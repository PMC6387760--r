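#' Default regional body densities
#'
#' Densities (kg/m^3) applied to the anatomical regions of a sliced body:
#' an averaged head density of 990 accounting for cranial air spaces, a
#' pneumatized neck at 930, a lung- and air-sac-bearing trunk at 740, and
#' tail and legs at muscle density, 1,060.
#'
#' @return Named numeric vector of densities.
#' @export
default_densities <- function() {
  c(head = 990, neck = 930, trunk = 740, tail = 1060, leg = 1060)
}

#' Slice a body outline into a chain of superelliptical frusta
#'
#' Converts each inter-station interval of a digitized outline into a
#' frustum whose anterior and posterior faces are superellipses with
#' dorsoventral semi-axis `(y_dorsal - y_ventral) / 2` and mediolateral
#' semi-axis `z_half` at the bounding stations.  Face areas are
#' `C(k) * (2 r_DV) * (2 r_LM)` with `C` from [superellipse_constant()].
#'
#' @param body A [station_series()].
#' @param k Superellipse exponent shared by all cross-sections
#'   (default 2.3, the best-estimate exponent for terrestrial vertebrates).
#' @param densities Named vector mapping every region present in `body` to a
#'   density in kg/m^3; see [default_densities()].
#' @param constant_method Source for the area constant,
#'   passed to [superellipse_constant()].
#' @return An object of class `frustum_chain`: a data frame with one row per
#'   frustum (`x_ant`, `x_post`, `l`, face semi-axes `r_ant_dv`, `r_ant_lm`,
#'   `r_post_dv`, `r_post_lm`, face heights `y_ant_dorsal`, `y_ant_ventral`,
#'   `y_post_dorsal`, `y_post_ventral`, `rho`, `region`) carrying attributes
#'   `k` and `C`.
#' @export
slice_to_frusta <- function(body, k = 2.3, densities = default_densities(),
                            constant_method = c("closed_form", "table")) {
  stopifnot(inherits(body, "station_series"))
  constant_method <- match.arg(constant_method)
  st <- body$stations
  n <- nrow(st)
  reg <- body$region
  miss <- setdiff(unique(reg), names(densities))
  if (length(miss))
    stop("no density supplied for region(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rho <- unname(densities[reg])
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("densities must be positive and finite", call. = FALSE)

  a <- seq_len(n - 1L)
  p <- a + 1L
  chain <- data.frame(
    x_ant = st$x[a], x_post = st$x[p], l = st$x[p] - st$x[a],
    r_ant_dv = (st$y_dorsal[a] - st$y_ventral[a]) / 2,
    r_ant_lm = st$z_half[a],
    r_post_dv = (st$y_dorsal[p] - st$y_ventral[p]) / 2,
    r_post_lm = st$z_half[p],
    y_ant_dorsal = st$y_dorsal[a], y_ant_ventral = st$y_ventral[a],
    y_post_dorsal = st$y_dorsal[p], y_post_ventral = st$y_ventral[p],
    rho = rho, region = reg,
    stringsAsFactors = FALSE)
  structure(chain, k = k,
            C = superellipse_constant(k, constant_method),
            class = c("frustum_chain", "data.frame"))
}

#' Slice a straightened leg into frusta
#'
#' Legs rotate about their own (vertical) long axis in the en-pointe
#' scenario, so the leg chain keeps anteroposterior and mediolateral radii
#' distinct.  The dorsoventral slots of the chain hold the anteroposterior
#' radii; lengths run along the proximo-distal axis `s`.
#'
#' @param leg A [leg_series()].
#' @param k Superellipse exponent (default 2.3).
#' @param density Leg density in kg/m^3 (default muscle, 1,060).
#' @inheritParams slice_to_frusta
#' @return A `frustum_chain` (region `"leg"`), with attributes `z_offset`
#'   and `hip_x` copied from the leg series.
#' @export
slice_leg_to_frusta <- function(leg, k = 2.3,
                                density = default_densities()[["leg"]],
                                constant_method = c("closed_form", "table")) {
  stopifnot(inherits(leg, "leg_series"))
  constant_method <- match.arg(constant_method)
  st <- leg$stations
  n <- nrow(st)
  a <- seq_len(n - 1L)
  p <- a + 1L
  chain <- data.frame(
    x_ant = st$s[a], x_post = st$s[p], l = st$s[p] - st$s[a],
    r_ant_dv = st$r_ap[a], r_ant_lm = st$r_lm[a],
    r_post_dv = st$r_ap[p], r_post_lm = st$r_lm[p],
    y_ant_dorsal = st$r_ap[a], y_ant_ventral = -st$r_ap[a],
    y_post_dorsal = st$r_ap[p], y_post_ventral = -st$r_ap[p],
    rho = density, region = "leg",
    stringsAsFactors = FALSE)
  structure(chain, k = k,
            C = superellipse_constant(k, constant_method),
            z_offset = leg$z_offset, hip_x = leg$hip_x,
            class = c("frustum_chain", "data.frame"))
}

#' @export
print.frustum_chain <- function(x, ...) {
  cat("Frustum chain: ", nrow(x), " frusta, k = ", attr(x, "k"),
      " (C = ", format(attr(x, "C"), digits = 6), ")\n", sep = "")
  cat("  extent ", format(min(x$x_ant)), " - ", format(max(x$x_post)),
      " m; regions: ", paste(unique(x$region), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## superellipse face areas (m^2) of a chain; side = "ant" or "post"
face_area <- function(chain, side = c("ant", "post")) {
  side <- match.arg(side)
  C <- attr(chain, "C")
  if (side == "ant") C * (2 * chain$r_ant_dv) * (2 * chain$r_ant_lm)
  else C * (2 * chain$r_post_dv) * (2 * chain$r_post_lm)
}
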