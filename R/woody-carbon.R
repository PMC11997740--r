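#' @keywords internal
LOSS_AGENTS <- c("elephant", "other_browser", "woodcutting", "fire", "other")

#' @keywords internal
GROWTH_FORMS <- c("adult_tree", "subadult", "gulliver", "shrub")

#' Total disturbance-loss fraction of an individual
#'
#' Sums the per-agent fractions of pre-disturbance aboveground biomass lost
#' to the five disturbance agents (elephant browsing, other browsers,
#' woodcutting, wildfire, other). Sums above 1 violate the simplex and are
#' rejected; valid sums are capped at 0.99 so the pre-disturbance
#' extrapolation stays finite.
#'
#' @param losses numeric matrix or data.frame with one column per agent, or
#'   a numeric vector for a single individual.
#' @return Numeric vector of total loss fractions in \[0, 0.99\].
#' @export
total_loss_fraction <- function(losses) {
  m <- as.matrix(losses)
  if (is.vector(losses) && is.numeric(losses)) m <- matrix(losses, nrow = 1)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("per-agent loss fractions must lie in [0, 1]")
  }
  s <- rowSums(m)
  if (any(s > 1 + 1e-9)) {
    stop("per-agent loss fractions sum above 1 (simplex violation)")
  }
  pmin(s, 0.99)
}

#' Extrapolate pre-disturbance aboveground carbon
#'
#' Inverts the loss correction: with losses expressed as fractions of the
#' pre-disturbance stock, `agc_pre = agc_actual / (1 - total_loss)`.
#'
#' @param agc_actual post-disturbance AGC, kg C, `>= 0`.
#' @param total_loss total loss fraction in \[0, 0.99\].
#' @return Pre-disturbance AGC, kg C.
#' @examples
#' pre_disturbance_agc(7, 0.3) # 10
#' @export
pre_disturbance_agc <- function(agc_actual, total_loss) {
  if (any(agc_actual < 0)) stop("agc_actual must be non-negative")
  if (any(total_loss < 0) || any(total_loss > 0.99)) {
    stop("total_loss must lie in [0, 0.99]")
  }
  agc_actual / (1 - total_loss)
}

#' Root-to-shoot ratio
#'
#' Adult trees get a size-dependent ratio decreasing with the largest stem's
#' DBH, \eqn{RS = 1.89208 \times DBH^{-0.43491}}; shrub-like growth forms
#' (shrub, gulliver, subadult) get the fixed savanna shrub ratio 2.16.
#'
#' @param growth_form character vector over
#'   `c("adult_tree", "subadult", "gulliver", "shrub")`.
#' @param dbh DBH (cm) of the largest stem; required (positive) for adult
#'   trees, ignored otherwise.
#' @return Unitless root:shoot ratios.
#' @examples
#' rs_ratio("shrub")          # 2.16
#' rs_ratio("adult_tree", 20)
#' @export
rs_ratio <- function(growth_form, dbh = NULL) {
  growth_form <- match_growth_form(growth_form)
  out <- rep(2.16, length(growth_form))
  adult <- growth_form == "adult_tree"
  if (any(adult)) {
    if (is.null(dbh)) stop("dbh is required for adult trees")
    dbh <- rep_len(dbh, length(growth_form))
    if (anyNA(dbh[adult]) || any(dbh[adult] <= 0)) {
      stop("adult trees need a positive dbh")
    }
    out[adult] <- 1.89208 * dbh[adult]^(-0.43491)
  }
  out
}

#' @keywords internal
match_growth_form <- function(growth_form) {
  growth_form <- as.character(growth_form)
  bad <- !(growth_form %in% GROWTH_FORMS)
  if (any(bad)) {
    stop("unknown growth form: ", paste(unique(growth_form[bad]), collapse = ", "))
  }
  growth_form
}

#' Belowground carbon of an individual
#'
#' Undamaged and slightly damaged individuals (total AGC loss <= 30%) carry
#' root carbon proportional to their pre-disturbance AGC, `rs * agc_pre`.
#' Heavily disturbed gullivers (loss > 30%) get the mean of that maximum and
#' the post-disturbance minimum `rs * agc_actual`, approximating partial
#' root dieback. The function is continuous in its inputs except for the
#' documented jump at the 30% threshold.
#'
#' @param agc_actual post-disturbance AGC, kg C.
#' @param agc_pre pre-disturbance AGC, kg C, `>= agc_actual`.
#' @param total_loss total loss fraction in \[0, 1).
#' @param rs root:shoot ratio.
#' @param threshold loss fraction separating the two branches (default 0.30,
#'   assigned to the slightly-damaged branch).
#' @return BGC in kg C (vectorized).
#' @examples
#' individual_bgc(5, 10, 0.5, 0.5) # (0.5*10 + 0.5*5)/2 = 3.75
#' @export
individual_bgc <- function(agc_actual, agc_pre, total_loss, rs,
                           threshold = 0.30) {
  if (any(agc_actual < 0) || any(agc_pre < 0)) stop("carbon must be non-negative")
  if (any(agc_pre < agc_actual - 1e-9)) {
    stop("agc_pre must be at least agc_actual")
  }
  ifelse(total_loss <= threshold,
         rs * agc_pre,
         (rs * agc_pre + rs * agc_actual) / 2)
}

#' Compartment assignment of a woody individual
#'
#' Adult trees contribute to the tree AGC/BGC compartments; shrubs,
#' gullivers and subadults to the shrub compartments.
#'
#' @param growth_form character vector of growth forms.
#' @return Character vector `"tree"` / `"shrub"`.
#' @export
assign_compartment <- function(growth_form) {
  growth_form <- match_growth_form(growth_form)
  ifelse(growth_form == "adult_tree", "tree", "shrub")
}

#' Scale individual carbon to per-hectare stocks
#'
#' Each individual recorded on a subplot of `subplot_area` m2 contributes
#' `(kg C / 1000) * (10000 / subplot_area)` t C/ha; contributions are summed
#' per plot and compartment.
#'
#' @param plot_id plot identifier (vector).
#' @param kg_c carbon per individual, kg.
#' @param compartment compartment label per individual (e.g. `"tree_agc"`).
#' @param subplot_area sampling area per individual, m2, `> 0`.
#' @return data.frame with one row per plot and one column per compartment
#'   (t C/ha); plots with no individual in a compartment get 0.
#' @export
scale_to_hectare <- function(plot_id, kg_c, compartment, subplot_area) {
  if (any(subplot_area <= 0)) stop("subplot_area must be positive")
  if (any(kg_c < 0)) stop("carbon must be non-negative")
  t_ha <- (kg_c / 1000) * (10000 / subplot_area)
  tab <- tapply(t_ha, list(as.character(plot_id), as.character(compartment)),
                sum, default = 0)
  out <- data.frame(plot_id = rownames(tab), as.data.frame(unclass(tab)),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Flag methuselah trees
#'
#' TRUE when any adult tree on the plot has a largest-stem DBH strictly
#' greater than the threshold (default 60 cm) — rare old-growth trees that
#' have outgrown the fire, browser and woodcutting traps.
#'
#' @param dbh DBH values (cm), `NA` for non-adults.
#' @param growth_form growth forms matching `dbh`.
#' @param threshold DBH threshold in cm (strict inequality).
#' @return Single logical.
#' @export
flag_methuselah <- function(dbh, growth_form, threshold = 60) {
  if (length(dbh) == 0) return(FALSE)
  adult <- match_growth_form(growth_form) == "adult_tree"
  any(adult & !is.na(dbh) & dbh > threshold)
}

#' Per-plot woody carbon compartments from an inventory
#'
#' Runs the full individual-level chain — allometric AGB, carbon-fraction
#' conversion, loss-corrected pre-disturbance AGC, damage-adjusted
#' root:shoot BGC — and aggregates to the four woody compartments
#' (tree AGC, tree BGC, shrub AGC, shrub BGC) in t C/ha per plot.
#'
#' Adult trees use the tree model on DBH, height and species wood density;
#' all other growth forms use the crown-area model. The allometric estimate
#' is the actual (post-disturbance) aboveground stock; the recorded per-agent
#' loss fractions drive pre-disturbance extrapolation and the BGC rule.
#'
#' @param inventory data.frame with columns `plot_id`, `species`,
#'   `growth_form`, `height_m`, `crown_d1_m`, `crown_d2_m`, `dbh_cm`,
#'   `loss_elephant`, `loss_other_browser`, `loss_woodcutting`, `loss_fire`,
#'   `loss_other`, `subplot_area_m2`.
#' @param species data.frame with columns `species`, `swd`,
#'   `carbon_fraction`.
#' @param cfg an [allometry_config()].
#' @param gulliver_threshold loss fraction separating the BGC branches.
#' @param methuselah_dbh DBH threshold (cm) flagging old-growth trees.
#' @param all_plots optional vector of plot ids that must appear in the
#'   output even when empty (stocks 0).
#' @return data.frame: `plot_id`, `tree_agc`, `tree_bgc`, `shrub_agc`,
#'   `shrub_bgc` (t C/ha), `methuselah` (logical).
#' @export
compute_woody_carbon <- function(inventory, species, cfg = allometry_config(),
                                 gulliver_threshold = 0.30,
                                 methuselah_dbh = 60, all_plots = NULL) {
  validate_inventory(inventory)
  validate_species(species)
  inv <- merge(inventory, species[, c("species", "swd", "carbon_fraction")],
               by = "species", sort = FALSE)
  if (nrow(inv) < nrow(inventory)) {
    stop("inventory contains species missing from the trait table")
  }
  empty <- data.frame(plot_id = character(), tree_agc = numeric(),
                      tree_bgc = numeric(), shrub_agc = numeric(),
                      shrub_bgc = numeric(), methuselah = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(inv) == 0) {
    out <- empty
  } else {
    adult <- inv$growth_form == "adult_tree"
    agb <- numeric(nrow(inv))
    if (any(adult)) {
      agb[adult] <- tree_agb(inv$dbh_cm[adult], inv$height_m[adult],
                             inv$swd[adult], cfg)
    }
    if (any(!adult)) {
      agb[!adult] <- shrub_agb(inv$crown_d1_m[!adult], inv$crown_d2_m[!adult],
                               inv$height_m[!adult], cfg)
    }
    agc <- agb_to_agc(agb, inv$carbon_fraction)
    loss <- total_loss_fraction(inv[, paste0("loss_", LOSS_AGENTS)])
    agc_pre <- pre_disturbance_agc(agc, loss)
    rs <- rs_ratio(inv$growth_form, inv$dbh_cm)
    bgc <- individual_bgc(agc, agc_pre, loss, rs,
                          threshold = gulliver_threshold)
    pool <- assign_compartment(inv$growth_form)
    stocks_ag <- scale_to_hectare(inv$plot_id, agc, paste0(pool, "_agc"),
                                  inv$subplot_area_m2)
    stocks_bg <- scale_to_hectare(inv$plot_id, bgc, paste0(pool, "_bgc"),
                                  inv$subplot_area_m2)
    out <- merge(stocks_ag, stocks_bg, by = "plot_id", all = TRUE)
    for (comp in c("tree_agc", "tree_bgc", "shrub_agc", "shrub_bgc")) {
      if (is.null(out[[comp]])) out[[comp]] <- 0
      out[[comp]][is.na(out[[comp]])] <- 0
    }
    meth <- tapply(seq_len(nrow(inv)), as.character(inv$plot_id), function(i) {
      flag_methuselah(inv$dbh_cm[i], inv$growth_form[i], methuselah_dbh)
    })
    out$methuselah <- as.logical(meth[out$plot_id])
    out <- out[, c("plot_id", "tree_agc", "tree_bgc", "shrub_agc",
                   "shrub_bgc", "methuselah")]
  }
  if (!is.null(all_plots)) {
    missing <- setdiff(as.character(all_plots), out$plot_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(plot_id = missing, tree_agc = 0,
                                   tree_bgc = 0, shrub_agc = 0, shrub_bgc = 0,
                                   methuselah = FALSE,
                                   stringsAsFactors = FALSE))
    }
    out <- out[match(as.character(all_plots), out$plot_id), ]
    rownames(out) <- NULL
  }
  out
}

#' Assemble the six-compartment carbon table
#'
#' Joins woody and soil compartment tables and derives the pools:
#' AGC = tree + shrub AGC, BGC = tree + shrub BGC, SOC = topsoil + subsoil,
#' and whole-ecosystem `c_total` = AGC + BGC + SOC.
#'
#' @param woody output of [compute_woody_carbon()].
#' @param soil per-plot data.frame with `plot_id`, `topsoil_soc`,
#'   `subsoil_soc` (t C/ha).
#' @param plots optional plot table whose metadata columns are carried along.
#' @return data.frame of class `carbon_compartments`.
#' @export
carbon_compartments <- function(woody, soil, plots = NULL) {
  out <- merge(woody, soil, by = "plot_id", all = TRUE)
  stock_cols <- c("tree_agc", "tree_bgc", "shrub_agc", "shrub_bgc",
                  "topsoil_soc", "subsoil_soc")
  for (cc in stock_cols) {
    if (anyNA(out[[cc]])) stop("missing compartment value for some plots: ", cc)
    if (any(out[[cc]] < 0)) stop("negative carbon stock in ", cc)
  }
  out$agc <- out$tree_agc + out$shrub_agc
  out$bgc <- out$tree_bgc + out$shrub_bgc
  out$soc <- out$topsoil_soc + out$subsoil_soc
  out$c_total <- out$agc + out$bgc + out$soc
  if (!is.null(plots)) {
    keep <- setdiff(names(plots), names(out))
    out <- merge(plots[, c("plot_id", keep)], out, by = "plot_id")
  }
  class(out) <- c("carbon_compartments", "data.frame")
  out
}

#' @export
print.carbon_compartments <- function(x, ...) {
  cat(sprintf("Carbon compartments: %d plots\n", nrow(x)))
  cat(sprintf("  mean AGC %.2f, BGC %.2f, SOC %.2f, C_total %.2f t C/ha\n",
              mean(x$agc), mean(x$bgc), mean(x$soc), mean(x$c_total)))
  NextMethod()
}
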