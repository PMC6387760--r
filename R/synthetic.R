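#' Analytic solids with closed-form mass properties
#'
#' Builds a station series sampling an elliptical cylinder, a circular cone
#' (base anterior, apex posterior), or a triaxial spheroid, together with
#' the exact mass, centre of mass, and yaw inertia of the solid.  These
#' pairs are the oracles against which the frustum slicing, centroid, and
#' parallel-axis machinery is verified: the sliced estimates must converge
#' to the closed forms as `n_slices` grows.  All closed forms assume
#' elliptical cross-sections, so chains built from these bodies should be
#' sliced with exponent `k = 2`.
#'
#' @param shape `"elliptical_cylinder"`, `"cone"`, or `"spheroid"`.
#' @param dims Named list/vector of dimensions (m): cylinder `r_dv`, `r_lm`,
#'   `l`; cone `r`, `l`; spheroid semi-axes `a` (anteroposterior), `b`
#'   (dorsoventral), `c` (mediolateral).
#' @param density Uniform density (kg/m^3), default 1000.
#' @param n_slices Number of inter-station intervals, at least 2.
#' @param region Region label for the whole body (default `"trunk"`).
#' @return List with `body` (a [station_series()]) and `closed_form` (a
#'   `mass_properties` object: exact mass, COM, and `I_y` about the vertical
#'   axis through the COM).
#' @export
make_analytic_solid <- function(shape = c("elliptical_cylinder", "cone",
                                          "spheroid"),
                                dims, density = 1000, n_slices = 200,
                                region = "trunk") {
  shape <- match.arg(shape)
  if (n_slices < 2L) stop("n_slices must be at least 2", call. = FALSE)
  dims <- as.list(dims)
  if (any(unlist(dims) <= 0)) stop("dims must be positive", call. = FALSE)

  if (shape == "elliptical_cylinder") {
    l <- dims$l; rdv <- dims$r_dv; rlm <- dims$r_lm
    x <- seq(0, l, length.out = n_slices + 1L)
    rdvx <- rep(rdv, length(x)); rlmx <- rep(rlm, length(x))
    mass <- density * pi * rdv * rlm * l
    cf <- list(mass = mass, com_x = l / 2, com_y = rdv, com_z = 0,
               I_y = mass * (rlm^2 / 4 + l^2 / 12), pivot_x = l / 2)
  } else if (shape == "cone") {
    l <- dims$l; r <- dims$r
    x <- seq(0, l, length.out = n_slices + 1L)
    rdvx <- r * (1 - x / l); rlmx <- rdvx
    mass <- density * pi * r^2 * l / 3
    ## transverse inertia about the centroid (at l/4 from the base)
    cf <- list(mass = mass, com_x = l / 4, com_y = r, com_z = 0,
               I_y = mass * (3 * r^2 / 20 + 3 * l^2 / 80),
               pivot_x = l / 4)
  } else {
    a <- dims$a; b <- dims$b; cc <- dims$c
    x <- seq(0, 2 * a, length.out = n_slices + 1L)
    u <- (x - a) / a
    f <- sqrt(pmax(0, 1 - u^2))
    rdvx <- b * f; rlmx <- cc * f
    mass <- density * 4 / 3 * pi * a * b * cc
    cf <- list(mass = mass, com_x = a, com_y = b, com_z = 0,
               I_y = mass * (a^2 + cc^2) / 5, pivot_x = a)
  }
  mid <- if (shape == "cone") dims$r else
    if (shape == "spheroid") dims$b else dims$r_dv
  body <- station_series(x, mid + rdvx, mid - rdvx, rlmx,
                         rep(region, length(x) - 1L))
  list(body = body,
       closed_form = structure(cf, class = "mass_properties"))
}

## smooth per-region depth/width profiles of the parametric body
.region_profile <- function(u, region) {
  switch(region,
         head = 0.25 + 0.75 * sin(pi * pmin(u * 1.15, 1) / 2)^0.9,
         neck = 0.95 + 0.05 * cos(pi * u),
         trunk = 0.85 + 0.15 * pmax(0, sin(pi * u))^1.2,
         tail = pmax(0, 1 - u)^0.95)
}

#' Parametric theropod-like body generator
#'
#' Builds a smooth, bilaterally symmetrical bipedal body — tapering head,
#' narrow neck, deep trunk, long tapering tail — as a station series with
#' 60+ stations, together with a straightened hind leg and a synthetic
#' lateral ilium area defined as a fixed fraction of the trunk's lateral
#' (depth-by-length) area, so that geometric scaling laws hold exactly
#' across scaled copies.  Default dimensions give a large-bodied theropod of
#' roughly 10 m and a few tonnes with the tail near a fifth of total mass.
#' The generator is deterministic; a positive `jitter` adds reproducible
#' (seeded) station-level noise to emulate digitization scatter.
#'
#' @param head_length,neck_length,trunk_length,tail_length Region lengths
#'   (m).
#' @param head_depth,neck_depth,trunk_depth,tail_depth Maximum dorsoventral
#'   extents per region (m).
#' @param head_width,neck_width,trunk_width,tail_width Maximum full widths
#'   per region (m).
#' @param leg_length Leg length (m); `leg_r_ap` proximal anteroposterior
#'   radius (m), tapering distally; `leg_r_lm` constant mediolateral radius
#'   (m); `leg_offset` lateral distance of the leg axis from the midline
#'   (m).
#' @param ilium_fraction Synthetic ilium area as a fraction of trunk lateral
#'   area.
#' @param n_stations Approximate total number of stations (>= 61 so at
#'   least 60 intervals).
#' @param jitter Relative station noise amplitude (default 0: none).
#' @param seed Seed for the jitter (ignored when `jitter = 0`).
#' @return List with `body` (a [station_series()]), `leg` (a
#'   [leg_series()] with `hip_x` at the rear of the trunk),
#'   `ilium_area_cm2`, and `params` (the arguments used).
#' @export
make_theropod_body <- function(head_length = 1.6, neck_length = 1.25,
                               trunk_length = 3.7, tail_length = 4.7,
                               head_depth = 1.25, neck_depth = 0.95,
                               trunk_depth = 2.1, tail_depth = 1.05,
                               head_width = 0.75, neck_width = 0.65,
                               trunk_width = 1.5, tail_width = 0.68,
                               leg_length = 3.1, leg_r_ap = 0.56,
                               leg_r_lm = 0.29, leg_offset = 0.45,
                               ilium_fraction = 0.08,
                               n_stations = 97, jitter = 0, seed = NULL) {
  params <- as.list(environment())
  lens <- c(head = head_length, neck = neck_length, trunk = trunk_length,
            tail = tail_length)
  depths <- c(head = head_depth, neck = neck_depth, trunk = trunk_depth,
              tail = tail_depth)
  widths <- c(head = head_width, neck = neck_width, trunk = trunk_width,
              tail = tail_width)
  if (any(c(lens, depths, widths, leg_length, leg_r_ap, leg_r_lm) <= 0))
    stop("all body dimensions must be positive", call. = FALSE)
  if (n_stations < 61L)
    stop("n_stations must be at least 61 (60 intervals)", call. = FALSE)
  total <- sum(lens)

  ## stations allocated proportionally to region length
  n_int <- pmax(2L, round((n_stations - 1L) * lens / total))
  bounds <- cumsum(c(0, lens))
  x <- numeric(0); region <- character(0)
  depth_x <- numeric(0); width_x <- numeric(0)
  for (i in seq_along(lens)) {
    reg <- names(lens)[i]
    xs <- seq(bounds[i], bounds[i + 1L], length.out = n_int[i] + 1L)
    u <- (xs - bounds[i]) / lens[i]
    prof <- .region_profile(u, reg)
    keep <- if (i == 1L) seq_along(xs) else -1L  # drop shared boundary
    x <- c(x, xs[keep])
    depth_x <- c(depth_x, (depths[i] * prof)[keep])
    width_x <- c(width_x, (widths[i] * prof)[keep])
    region <- c(region, rep(reg, n_int[i]))
  }
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    fac <- function(n) 1 + stats::runif(n, -jitter, jitter)
    depth_x <- depth_x * fac(length(depth_x))
    width_x <- width_x * fac(length(width_x))
  }
  ## centreline height (from the ventral-most trunk point) as a smooth
  ## fraction of trunk depth: raised head/neck, low-slung trunk, tail
  ## carried near horizontal
  knots_x <- cumsum(c(0, head_length, neck_length, trunk_length / 2,
                      trunk_length / 2, tail_length))
  knots_f <- c(0.85, 0.8, 0.62, 0.5, 0.58, 0.75)
  mid <- stats::approx(knots_x, knots_f * trunk_depth, xout = x,
                       rule = 2)$y
  body <- station_series(x, mid + depth_x / 2, mid - depth_x / 2,
                         width_x / 2, region)

  s <- seq(0, leg_length, length.out = 25L)
  r_ap <- leg_r_ap * (0.22 + 0.78 * (1 - s / leg_length)^1.1)
  leg <- leg_series(s, r_ap, leg_r_lm, z_offset = leg_offset,
                    hip_x = unname(bounds[3L]) + 0.6 * trunk_length)

  trunk_lateral_m2 <- sum((depth_x[-1] + depth_x[-length(depth_x)]) / 2 *
                            diff(x) * (region == "trunk"))
  list(body = body, leg = leg,
       ilium_area_cm2 = ilium_fraction * trunk_lateral_m2 * 1e4,
       params = params)
}

#' Geometric scaling series of one body plan
#'
#' Produces geometrically scaled copies of a parametric body (every linear
#' dimension multiplied by a factor `s`), runs the full mass-property and
#' agility pipeline on each, and returns one specimen row per factor.
#' Under pure geometric scaling mass grows as `s^3`, ilium area as `s^2`,
#' and yaw inertia as `s^5`, so `log10(Agility_force)` against
#' `log10(mass)` has slope exactly -1 and `log10(Agility_moment)` slope
#' exactly -2/3.
#'
#' @param factors Positive scale factors, one specimen per factor.
#' @param k Superellipse exponent used when slicing.
#' @param base Named list of overrides for [make_theropod_body()]
#'   arguments (the unscaled plan).
#' @param densities Regional densities, see [default_densities()].
#' @return Specimen table (see [build_specimen_table()]) with a leading
#'   `scale_factor` column.
#' @export
make_scaling_series <- function(factors = c(1, 2, 4), k = 2.3,
                                base = list(),
                                densities = default_densities()) {
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  linear <- c("head_length", "neck_length", "trunk_length", "tail_length",
              "head_depth", "neck_depth", "trunk_depth", "tail_depth",
              "head_width", "neck_width", "trunk_width", "tail_width",
              "leg_length", "leg_r_ap", "leg_r_lm", "leg_offset")
  rows <- lapply(factors, function(s) {
    args <- base
    defaults <- formals(make_theropod_body)
    for (nm in linear) {
      v <- if (!is.null(base[[nm]])) base[[nm]] else eval(defaults[[nm]])
      args[[nm]] <- v * s
    }
    spec <- do.call(make_theropod_body, args)
    chain <- slice_to_frusta(spec$body, k = k, densities = densities)
    leg_chain <- slice_leg_to_frusta(spec$leg, k = k,
                                     density = densities[["leg"]])
    mp <- body_mass_properties(chain)
    lp <- leg_mass_properties(leg_chain)
    data.frame(scale_factor = s, taxon = paste0("synthetic_x", s),
               ilium_area_cm2 = spec$ilium_area_cm2,
               mass_kg = mp$mass + 2 * lp$mass,
               iy_body = mp$I_y, iy_leg = lp$I_y,
               iy_body_leg = iy_body_plus_leg(mp, lp),
               stringsAsFactors = FALSE)
  })
  build_specimen_table(do.call(rbind, rows))
}

#' Simulate a time-scaled pure-birth tree
#'
#' Pure-birth (Yule) tree with unit speciation rate, rescaled to a given
#' root depth; a simple source of realistic ultrametric topologies for
#' calibration and parameter-recovery experiments.
#'
#' @param n_tips Number of tips.
#' @param depth Root depth after rescaling (default 100, in Myr).
#' @param seed Optional RNG seed.
#' @return A `phylo` tree.
#' @export
simulate_bm_tree <- function(n_tips, depth = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length *
    (depth / max(ape::node.depth.edgelength(tree)))
  tree
}

#' Simulate regression traits with known phylogenetic signal and grades
#'
#' Draws `y = intercept + slope * x + noise (+ grade offset)` on a tree,
#' where the noise is multivariate normal with covariance `rate * V(lambda)`
#' (the lambda-transformed Brownian-motion structure), and `x` is either
#' supplied or itself simulated as plain Brownian motion with rate
#' `x_rate`.  With `rate = 0` the relation is exactly linear.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param lambda Signal of the residual noise, in \[0, 1\].
#' @param slope,intercept Regression parameters.
#' @param rate Residual Brownian rate (variance per unit branch length).
#'   The default, 1e-5, yields tip-level residual scatter of about 0.03
#'   log10 units on a 100-Myr-deep tree, matching the residual standard
#'   errors typical of log-log agility regressions.
#' @param grade_offsets Optional named vector of intercept offsets per
#'   group.
#' @param groups Optional named group assignment per tip (required when
#'   `grade_offsets` is given).
#' @param x Optional named covariate; simulated if `NULL`.
#' @param x_rate Brownian rate of the simulated covariate; the default
#'   spreads log10 body mass over roughly two thirds of a decade on a
#'   100-Myr tree.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `tip`, `x`, `y`, `group`.
#' @export
simulate_traits <- function(tree, lambda = 1, slope = -1, intercept = 3,
                            rate = 1e-5, grade_offsets = NULL,
                            groups = NULL, x = NULL, x_rate = 0.005,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)
  V <- ape::vcv(tree)
  if (is.null(x)) {
    Rx <- chol(x_rate * V)
    x <- drop(t(Rx) %*% stats::rnorm(n))
    names(x) <- tips
  } else x <- x[tips]
  y <- intercept + slope * x
  if (rate > 0) {
    Vl <- bm_covariance(tree, lambda)
    Rl <- chol(rate * Vl)
    y <- y + drop(t(Rl) %*% stats::rnorm(n))
  }
  grp <- rep(NA_character_, n)
  if (!is.null(groups)) grp <- as.character(groups[tips])
  if (!is.null(grade_offsets)) {
    if (is.null(groups))
      stop("grade_offsets requires groups", call. = FALSE)
    off <- grade_offsets[grp]
    off[is.na(off)] <- 0
    y <- y + off
  }
  data.frame(tip = tips, x = as.numeric(x), y = as.numeric(y),
             group = grp, stringsAsFactors = FALSE)
}
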