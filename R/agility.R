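#' Force-based agility index
#'
#' `Agility_force = A_ilium / I_y`: muscle-force proxy (lateral ilium area,
#' cm^2) divided by the yaw rotational inertia the muscles must overcome
#' (kg m^2).  A comparative index of turning ability, not an absolute
#' biomechanical quantity.  With `I_y` of the axial body about its own COM
#' it scores the planted-feet scenario; with the body-plus-swing-leg inertia
#' it scores pivoting en pointe over the stance foot.
#'
#' @param a_ilium Lateral ilium area (cm^2), non-negative.
#' @param i_y Yaw rotational inertia (kg m^2), positive.
#' @return The agility index (vectorized).
#' @export
agility_force <- function(a_ilium, i_y) {
  if (any(i_y <= 0))
    stop("I_y must be positive", call. = FALSE)
  if (any(a_ilium < 0))
    stop("ilium area must be non-negative", call. = FALSE)
  a_ilium / i_y
}

#' Relative torque index
#'
#' `tau_relative = (m^{1/3} / divisor) * A_ilium * specific_tension`, with
#' mass in kg and ilium area in cm^2.  `m^{1/3}` stands in for isometrically
#' scaling muscle moment arms; the default specific tension is a sub-maximal
#' concentric 20 N/cm^2 and the divisor of 100 is an arbitrary linear
#' adjustment that brings relative moment arms into an intuitive range —
#' neither constant affects between-taxon ratios.  The result is an index,
#' not a physical torque.
#'
#' @param mass Body mass (kg), positive.
#' @param a_ilium Lateral ilium area (cm^2).
#' @param specific_tension Muscle specific tension (N/cm^2), default 20.
#' @param divisor Linear scaling divisor, default 100.
#' @return The relative torque index (vectorized).
#' @export
tau_relative <- function(mass, a_ilium, specific_tension = 20,
                         divisor = 100) {
  if (any(mass <= 0))
    stop("mass must be positive", call. = FALSE)
  if (specific_tension <= 0 || divisor <= 0)
    stop("specific tension and divisor must be positive", call. = FALSE)
  (mass^(1 / 3) / divisor) * a_ilium * specific_tension
}

#' Moment-based agility index
#'
#' `Agility_moment = tau_relative / I_y`, an index of relative angular
#' acceleration.
#'
#' @param tau Relative torque index from [tau_relative()].
#' @param i_y Yaw rotational inertia (kg m^2), positive.
#' @return The agility index (vectorized).
#' @export
agility_moment <- function(tau, i_y) {
  if (any(i_y <= 0))
    stop("I_y must be positive", call. = FALSE)
  tau / i_y
}

#' Assemble a specimen agility table
#'
#' Populates the four agility columns (force/moment under the planted and
#' en-pointe scenarios) from each specimen's ilium area, total mass, and
#' yaw inertias, producing one row per specimen in the shape of the
#' published per-taxon summary tables.
#'
#' @param records Data frame with at least `taxon`, `ilium_area_cm2`,
#'   `mass_kg`, `iy_body`, and `iy_body_leg` columns; an optional `group`
#'   column (e.g. `"tyrannosaurid_adult"`, `"tyrannosaurid_juvenile"`,
#'   `"other"`) and `iy_leg` and `cfl_area_cm2` columns are carried through.
#' @param specific_tension,divisor Constants for [tau_relative()].
#' @return The input data frame with columns `log10_mass`,
#'   `agility_force_planted`, `agility_moment_planted`,
#'   `agility_force_pointe`, `agility_moment_pointe` appended.
#' @export
build_specimen_table <- function(records, specific_tension = 20,
                                 divisor = 100) {
  need <- c("taxon", "ilium_area_cm2", "mass_kg", "iy_body", "iy_body_leg")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("specimen records are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- records
  tau <- tau_relative(out$mass_kg, out$ilium_area_cm2,
                      specific_tension, divisor)
  out$log10_mass <- log10(out$mass_kg)
  out$agility_force_planted <- agility_force(out$ilium_area_cm2, out$iy_body)
  out$agility_moment_planted <- agility_moment(tau, out$iy_body)
  out$agility_force_pointe <- agility_force(out$ilium_area_cm2,
                                            out$iy_body_leg)
  out$agility_moment_pointe <- agility_moment(tau, out$iy_body_leg)
  out
}

#' Validate a specimen agility table against its own printed values
#'
#' Recomputes the agility indices of every row from the row's own mass,
#' ilium area, and inertia columns and flags cells whose printed values
#' (columns suffixed `_printed`, when present) disagree beyond rounding at
#' the printed precision.  Also flags physically impossible rows where
#' `iy_body_leg < iy_body` (parallel-axis composition only ever adds
#' non-negative terms) and non-positive masses, areas, or inertias.
#'
#' A printed cell is considered consistent when it differs from the
#' recomputed value by at most 1.5 units in its last printed decimal place
#' (half a unit of rounding in the cell itself plus headroom for the
#' rounding already present in the printed inputs it was derived from).
#'
#' @param table Data frame as returned by [build_specimen_table()],
#'   optionally with printed columns `agility_force_planted_printed`,
#'   `agility_moment_planted_printed`, `agility_force_pointe_printed`,
#'   `agility_moment_pointe_printed`, `log10_mass_printed` (numeric, or
#'   character preserving trailing zeros).
#' @param tol_units Allowed discrepancy in units of the last printed decimal
#'   (default 1.5).
#' @return Data frame of flags with columns `taxon`, `row`, `column`,
#'   `printed`, `recomputed`, `flag` (one of `"mismatch"`,
#'   `"inertia_inconsistent"`, `"nonpositive"`); zero rows when the table is
#'   fully consistent.
#' @export
validate_specimen_table <- function(table, tol_units = 1.5) {
  flags <- list()
  add <- function(taxon, row, column, printed, recomputed, flag)
    flags[[length(flags) + 1L]] <<- data.frame(
      taxon = taxon, row = row, column = column,
      printed = printed, recomputed = recomputed, flag = flag,
      stringsAsFactors = FALSE)

  for (col in c("mass_kg", "ilium_area_cm2", "iy_body", "iy_body_leg")) {
    if (!col %in% names(table)) next
    bad <- which(!is.finite(table[[col]]) | table[[col]] <= 0)
    for (i in bad)
      add(table$taxon[i], i, col, NA_real_, table[[col]][i], "nonpositive")
  }
  bad <- which(table$iy_body_leg < table$iy_body)
  for (i in bad)
    add(table$taxon[i], i, "iy_body_leg", table$iy_body_leg[i],
        table$iy_body[i], "inertia_inconsistent")

  recomputed <- build_specimen_table(table)
  cols <- c("agility_force_planted", "agility_moment_planted",
            "agility_force_pointe", "agility_moment_pointe", "log10_mass")
  for (col in cols) {
    pcol <- paste0(col, "_printed")
    if (!pcol %in% names(table)) next
    printed_chr <- as.character(table[[pcol]])
    printed <- suppressWarnings(as.numeric(printed_chr))
    dp <- decimal_places(printed_chr)
    tol <- tol_units * 10^(-dp)
    bad <- which(is.finite(printed) &
                   abs(printed - recomputed[[col]]) > tol)
    for (i in bad)
      add(table$taxon[i], i, col, printed[i], recomputed[[col]][i],
          "mismatch")
  }
  if (length(flags)) do.call(rbind, flags)
  else data.frame(taxon = character(), row = integer(),
                  column = character(), printed = numeric(),
                  recomputed = numeric(), flag = character(),
                  stringsAsFactors = FALSE)
}

## number of decimal places in the printed representation of a value
decimal_places <- function(x) {
  x <- as.character(x)
  out <- integer(length(x))
  has_dot <- grepl(".", x, fixed = TRUE)
  out[has_dot] <- nchar(sub("^[^.]*\\.", "", x[has_dot]))
  out
}

#' Published per-specimen agility fixture
#'
#' Loads the packaged table of 20 theropod specimens (ilium areas, masses,
#' yaw inertias, and the published agility indices as printed), which serves
#' as input for recomputation, validation, and the statistical stages.
#' Printed agility and log-mass cells are kept as character columns
#' (suffix `_printed`) so their printed precision is preserved; the known
#' internal inconsistencies of a handful of printed cells are deliberately
#' retained and are surfaced by [validate_specimen_table()].
#'
#' @return Data frame with one row per specimen: `taxon`, `specimen`,
#'   `group`, `ilium_area_cm2`, `mass_kg`, `iy_body`, `iy_leg`,
#'   `iy_body_leg`, and `_printed` character columns.
#' @export
theropod_agility_fixture <- function() {
  path <- system.file("extdata", "theropod_agility_table.csv",
                      package = "theroturn")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           taxon = "character", specimen = "character",
                           group = "character",
                           ilium_area_cm2 = "numeric", mass_kg = "numeric",
                           iy_body = "numeric", iy_leg = "numeric",
                           iy_body_leg = "numeric",
                           log10_mass_printed = "character",
                           agility_force_planted_printed = "character",
                           agility_moment_planted_printed = "character",
                           agility_force_pointe_printed = "character",
                           agility_moment_pointe_printed = "character"))
  tab
}
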