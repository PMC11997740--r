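#' @keywords internal
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " table is missing columns: ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Validate a woody-plant inventory table
#'
#' Schema and invariant checks with row-level diagnostics: positive
#' heights, DBH >= 5 cm for adult trees, per-agent loss fractions in
#' \[0, 1\] summing below 1, positive subplot areas.
#'
#' @param inventory inventory data.frame.
#' @return The table, invisibly; errors on violation.
#' @export
validate_inventory <- function(inventory) {
  require_columns(inventory,
                  c("plot_id", "species", "growth_form", "height_m",
                    "crown_d1_m", "crown_d2_m", "dbh_cm",
                    paste0("loss_", LOSS_AGENTS), "subplot_area_m2"),
                  "inventory")
  if (nrow(inventory) == 0) return(invisible(inventory))
  match_growth_form(inventory$growth_form)
  bad <- which(!(inventory$height_m > 0))
  if (length(bad)) stop("non-positive height in inventory rows: ",
                        paste(utils::head(bad), collapse = ", "))
  adult <- inventory$growth_form == "adult_tree"
  bad <- which(adult & (is.na(inventory$dbh_cm) | inventory$dbh_cm < 5))
  if (length(bad)) {
    stop("adult trees require DBH >= 5 cm; offending rows: ",
         paste(utils::head(bad), collapse = ", "))
  }
  losses <- as.matrix(inventory[, paste0("loss_", LOSS_AGENTS)])
  bad <- which(losses < 0 | losses > 1, arr.ind = TRUE)
  if (nrow(bad)) stop("loss fractions outside [0, 1] in rows: ",
                      paste(utils::head(unique(bad[, 1])), collapse = ", "))
  bad <- which(rowSums(losses) >= 1)
  if (length(bad)) stop("loss fractions sum to >= 1 in rows: ",
                        paste(utils::head(bad), collapse = ", "))
  bad <- which(!(inventory$subplot_area_m2 > 0))
  if (length(bad)) stop("non-positive subplot area in rows: ",
                        paste(utils::head(bad), collapse = ", "))
  invisible(inventory)
}

#' Validate a species trait table
#'
#' @param species data.frame with `species`, `swd` (g/cm3, in (0.1, 1.5))
#'   and `carbon_fraction` (in (0.3, 0.6)).
#' @return The table, invisibly.
#' @export
validate_species <- function(species) {
  require_columns(species, c("species", "swd", "carbon_fraction"), "species")
  if (any(duplicated(species$species))) stop("duplicated species in trait table")
  if (any(species$swd <= 0.1 | species$swd >= 1.5)) {
    stop("specific wood density outside (0.1, 1.5) g/cm3")
  }
  if (any(species$carbon_fraction <= 0.3 | species$carbon_fraction >= 0.6)) {
    stop("carbon fraction outside (0.3, 0.6)")
  }
  invisible(species)
}

#' Validate a soil-core table
#'
#' @param soil long-format soil table (`plot_id`, `patch_type`,
#'   `depth_class`, `conc_g_kg`, `bulk_density_g_cm3`, `max_depth_cm`).
#' @return The table, invisibly.
#' @export
validate_soil <- function(soil) {
  require_columns(soil, c("plot_id", "patch_type", "depth_class",
                          "conc_g_kg", "bulk_density_g_cm3",
                          "max_depth_cm"), "soil")
  if (nrow(soil) == 0) return(invisible(soil))
  if (any(!(soil$patch_type %in% PATCH_TYPES))) {
    stop("unknown patch type; expected: ", paste(PATCH_TYPES, collapse = ", "))
  }
  if (any(!(soil$depth_class %in% depth_classes()$depth_class))) {
    stop("unknown depth class")
  }
  bad <- which(soil$conc_g_kg < 0)
  if (length(bad)) stop("negative carbon concentration in rows: ",
                        paste(utils::head(bad), collapse = ", "))
  bad <- which(soil$bulk_density_g_cm3 <= 0.8 | soil$bulk_density_g_cm3 >= 2)
  if (length(bad)) stop("bulk density outside (0.8, 2.0) g/cm3 in rows: ",
                        paste(utils::head(bad), collapse = ", "))
  if (any(!(soil$max_depth_cm %in% c(50, 100)))) {
    stop("max_depth_cm must be 50 (hand auger) or 100")
  }
  invisible(soil)
}

#' Validate a plot table
#'
#' @param plots plot data.frame (design metadata, disturbance scores,
#'   patch covers).
#' @return The table, invisibly.
#' @export
validate_plots <- function(plots) {
  require_columns(plots, c("plot_id", "vegetation_type", "landuse",
                           "plot_area_m2", "browsing_over", "browsing_under",
                           "fire_intensity", "woodcut_intensity",
                           "cover_under_tree", "cover_between_trees",
                           "cover_bare"), "plots")
  if (nrow(plots) == 0) return(invisible(plots))
  if (any(duplicated(plots$plot_id))) stop("duplicated plot ids")
  if (any(plots$plot_area_m2 <= 0)) stop("non-positive plot area")
  covers <- plots$cover_under_tree + plots$cover_between_trees +
    plots$cover_bare
  bad <- which(abs(covers - 1) > 1e-6)
  if (length(bad)) stop("patch covers do not sum to 1 for plots: ",
                        paste(utils::head(plots$plot_id[bad]), collapse = ", "))
  check_rating_grid(plots$browsing_over, max = 10)
  check_rating_grid(plots$browsing_under, max = 10)
  check_rating_grid(plots$fire_intensity, max = 20)
  check_rating_grid(plots$woodcut_intensity, max = 20)
  invisible(plots)
}
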