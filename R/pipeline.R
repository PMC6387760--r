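#' Run the full agility-comparison pipeline
#'
#' Orchestrates an end-to-end run: body outlines are sliced into frustum
#' chains; mass, COM, and yaw inertias are computed for the planted and
#' en-pointe scenarios; muscle-force proxies and the four agility indices
#' are assembled into a specimen table; a tail-width sensitivity table
#' (baseline versus widened tail) is produced; and, when a tree is
#' supplied, Pagel's lambda, PGLS regressions, and grade-wise phylogenetic
#' ANCOVA reports are computed for each agility index.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{`specimens`}{List of per-specimen lists with `taxon`, optional
#'       `group`, `body` (a [station_series()] or CSV path), `leg` (a
#'       [leg_series()]), and either `ilium_area_cm2` (scalar) or
#'       `ilium_outline` (polygon for [ilium_area()]); optionally `cfl`
#'       (list with `depth`, and optional `centrum_area`, `width_factor`).}
#'     \item{`k`}{Superellipse exponent (default 2.3).}
#'     \item{`constant_method`}{`"closed_form"` (default) or `"table"`.}
#'     \item{`densities`}{Region densities (default [default_densities()]).}
#'     \item{`tail_width_factor`}{Widened-tail factor for the sensitivity
#'       table (default 1.4).}
#'     \item{`specific_tension`, `divisor`}{Torque-index constants
#'       (defaults 20 N/cm^2 and 100).}
#'     \item{`stats`}{Optional list with `tree` (`phylo` or Newick path),
#'       optional `occurrences` (data frame or CSV path for
#'       [calibrate_tree()]), `lambda` (`"ml"` or fixed), `grade_model`,
#'       `comparisons`.}
#'     \item{`out_dir`}{Optional directory; the tables are written there as
#'       CSV files.}
#'   }
#' @return A list (invisibly if `out_dir` is set) with `specimen_table`,
#'   `com_table`, `sensitivity_table`, `flags`, and (when requested)
#'   `stats` containing `lambda`, `pgls`, and `ancova` per agility index.
#' @export
run_agility_pipeline <- function(config) {
  if (is.null(config$specimens) || !length(config$specimens))
    stop("config$specimens must list at least one specimen", call. = FALSE)
  k <- config$k %||% 2.3
  cmeth <- config$constant_method %||% "closed_form"
  densities <- config$densities %||% default_densities()
  wf <- config$tail_width_factor %||% 1.4
  st <- config$specific_tension %||% 20
  dv <- config$divisor %||% 100

  rows <- list(); coms <- list(); sens <- list()
  for (spec in config$specimens) {
    taxon <- spec$taxon %||% stop("specimen without taxon", call. = FALSE)
    body <- spec$body
    if (is.character(body)) body <- read_station_series(body)
    leg <- spec$leg
    chain <- slice_to_frusta(body, k = k, densities = densities,
                             constant_method = cmeth)
    mp <- body_mass_properties(chain)
    if (!is.null(leg)) {
      leg_chain <- slice_leg_to_frusta(leg, k = k,
                                       density = densities[["leg"]],
                                       constant_method = cmeth)
      lp <- leg_mass_properties(leg_chain)
    } else {
      lp <- structure(list(mass = 0, com_x = mp$com_x, com_y = NA_real_,
                           com_z = 0, I_y = 0, pivot_x = NA_real_),
                      class = "mass_properties")
    }
    a_il <- spec$ilium_area_cm2 %||%
      (if (!is.null(spec$ilium_outline))
         ilium_area(spec$ilium_outline, spec$ilium_scale %||% 1)
       else stop("specimen '", taxon, "' has neither ilium_area_cm2 nor ",
                 "ilium_outline", call. = FALSE))
    cfl <- if (!is.null(spec$cfl))
      cfl_cross_section(spec$cfl$depth, spec$cfl$centrum_area %||% 0,
                        spec$cfl$width_factor %||% 1)
    else NA_real_

    iy_bl <- if (lp$mass > 0) iy_body_plus_leg(mp, lp) else mp$I_y
    cc <- if (lp$mass > 0) combined_com(mp, lp)
          else list(com_x = mp$com_x, com_z = 0)
    rows[[taxon]] <- data.frame(
      taxon = taxon, group = spec$group %||% NA_character_,
      ilium_area_cm2 = a_il, cfl_area_cm2 = cfl,
      mass_kg = mp$mass + 2 * lp$mass,
      iy_body = mp$I_y, iy_leg = lp$I_y, iy_body_leg = iy_bl,
      stringsAsFactors = FALSE)
    coms[[taxon]] <- data.frame(
      taxon = taxon, com_x = mp$com_x, com_y = mp$com_y, com_z = 0,
      leg_com_z = lp$com_z, combined_com_x = cc$com_x,
      combined_com_z = cc$com_z, stringsAsFactors = FALSE)

    wide <- apply_tail_modifiers(body, width_factor = wf)
    wchain <- slice_to_frusta(wide, k = k, densities = densities,
                              constant_method = cmeth)
    wmp <- body_mass_properties(wchain)
    sens[[taxon]] <- data.frame(
      taxon = taxon, mass_initial = mp$mass, mass_wide = wmp$mass,
      com_x_initial = mp$com_x, com_x_wide = wmp$com_x,
      iy_initial = mp$I_y, iy_wide = wmp$I_y,
      mass_pct_initial = 100 * wmp$mass / mp$mass,
      com_pct_initial = 100 * wmp$com_x / mp$com_x,
      iy_pct_initial = 100 * wmp$I_y / mp$I_y,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  specimen_table <- build_specimen_table(records, specific_tension = st,
                                         divisor = dv)
  out <- list(specimen_table = specimen_table,
              com_table = do.call(rbind, coms),
              sensitivity_table = do.call(rbind, sens),
              flags = validate_specimen_table(specimen_table))

  if (!is.null(config$stats)) {
    sc <- config$stats
    tree <- sc$tree
    occ <- sc$occurrences
    if (is.character(occ)) occ <- utils::read.csv(occ,
                                                  stringsAsFactors = FALSE)
    tree <- calibrate_tree(tree, occ)
    x <- stats::setNames(specimen_table$log10_mass, specimen_table$taxon)
    groups <- stats::setNames(specimen_table$group, specimen_table$taxon)
    traits <- c("agility_force_planted", "agility_moment_planted",
                "agility_force_pointe", "agility_moment_pointe")
    lam <- list(); pgls <- list(); ancova <- list()
    for (tr in traits) {
      y <- stats::setNames(log10(specimen_table[[tr]]),
                           specimen_table$taxon)
      lam[[tr]] <- estimate_lambda(y, tree)
      pgls[[tr]] <- pgls_fit(y, x, tree, lambda = sc$lambda %||% "ml")
      ancova[[tr]] <- phyl_ancova(y, x, tree, groups,
                                  comparisons = sc$comparisons,
                                  lambda = sc$lambda %||% "ml",
                                  grade_model = sc$grade_model %||%
                                    "intercept")
    }
    out$stats <- list(tree = tree, lambda = lam, pgls = pgls,
                      ancova = ancova)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$specimen_table,
                     file.path(config$out_dir, "specimen_table.csv"),
                     row.names = FALSE)
    utils::write.csv(out$com_table,
                     file.path(config$out_dir, "com_table.csv"),
                     row.names = FALSE)
    utils::write.csv(out$sensitivity_table,
                     file.path(config$out_dir, "sensitivity_table.csv"),
                     row.names = FALSE)
    utils::write.csv(out$flags,
                     file.path(config$out_dir, "validation_flags.csv"),
                     row.names = FALSE)
    if (!is.null(out$stats)) {
      anc <- do.call(rbind, lapply(names(out$stats$ancova), function(tr) {
        cbind(trait = tr, out$stats$ancova[[tr]])
      }))
      utils::write.csv(anc, file.path(config$out_dir, "ancova_report.csv"),
                       row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}
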