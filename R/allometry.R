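#' Allometric model configuration
#'
#' Bundles the coefficient sets of the two allometric models used to convert
#' woody-plant size measurements to aboveground biomass (AGB):
#'
#' * adult trees: a pantropical power-law model
#'   \eqn{AGB = a (\rho D^2 H)^b} with wood density \eqn{\rho} in g/cm3,
#'   diameter at breast height \eqn{D} in cm and height \eqn{H} in m,
#'   yielding kg dry mass;
#' * shrub-like growth forms (shrubs, subadults, gullivers): a power-law
#'   crown-area x height model \eqn{AGB = c\,CA^d H^e} with elliptical crown
#'   area \eqn{CA} in m2 and height in m, yielding kg.
#'
#' The tree defaults are the widely used pantropical coefficients
#' (a = 0.0673, b = 0.976). The shrub defaults are package defaults for a
#' generic semi-arid shrub and should be replaced with a locally calibrated
#' coefficient set for real inventories; the functional form, not the
#' default values, is the contract.
#'
#' @param tree named numeric vector `c(a=, b=)`, both positive.
#' @param shrub named numeric vector `c(c=, d=, e=)`, all positive.
#' @return An object of class `allometry_config`.
#' @examples
#' cfg <- allometry_config()
#' tree_agb(dbh = 10, height = 8, swd = 0.6, cfg = cfg)
#' @export
allometry_config <- function(tree = c(a = 0.0673, b = 0.976),
                             shrub = c(c = 2.5, d = 1.2, e = 0.9)) {
  tree <- tree[c("a", "b")]
  shrub <- shrub[c("c", "d", "e")]
  if (anyNA(tree) || anyNA(shrub)) {
    stop("allometry coefficients must be named: tree c(a, b), shrub c(c, d, e)")
  }
  if (any(tree <= 0) || any(shrub <= 0)) {
    stop("allometry coefficients must be positive")
  }
  structure(
    list(tree = tree, shrub = shrub,
         units = c(dbh = "cm", height = "m", crown_diameter = "m",
                   swd = "g/cm3", agb = "kg")),
    class = "allometry_config"
  )
}

#' @export
print.allometry_config <- function(x, ...) {
  cat("Allometry configuration\n")
  cat(sprintf("  tree : AGB = %.4g * (swd * dbh^2 * height)^%.4g  [kg]\n",
              x$tree["a"], x$tree["b"]))
  cat(sprintf("  shrub: AGB = %.4g * crown_area^%.4g * height^%.4g  [kg]\n",
              x$shrub["c"], x$shrub["d"], x$shrub["e"]))
  invisible(x)
}

#' Specific wood density
#'
#' Oven-dry mass per fresh volume (g/cm3), the wood trait entering the tree
#' allometry. Vectorized; species means are arithmetic means of per-sample
#' densities.
#'
#' @param dry_mass oven-dry mass in g, `>= 0`.
#' @param fresh_volume fresh volume in cm3, `> 0`.
#' @return Numeric vector of densities (g/cm3).
#' @examples
#' specific_wood_density(6, 10) # 0.6
#' @export
specific_wood_density <- function(dry_mass, fresh_volume) {
  if (any(!is.finite(fresh_volume)) || any(fresh_volume <= 0)) {
    stop("fresh_volume must be positive")
  }
  if (any(!is.finite(dry_mass)) || any(dry_mass < 0)) {
    stop("dry_mass must be non-negative")
  }
  dry_mass / fresh_volume
}

#' Elliptical crown area from two perpendicular crown diameters
#'
#' @param d1,d2 crown diameters in m.
#' @return Crown area in m2.
#' @export
crown_area <- function(d1, d2) {
  if (any(!is.finite(d1)) || any(!is.finite(d2)) || any(d1 < 0) || any(d2 < 0)) {
    stop("crown diameters must be non-negative")
  }
  pi * (d1 / 2) * (d2 / 2)
}

#' Aboveground biomass of adult trees
#'
#' Pantropical power-law model \eqn{AGB = a (\rho D^2 H)^b}. Strictly
#' increasing in wood density, diameter and height.
#'
#' @param dbh diameter at breast height of the largest stem, cm.
#' @param height tree height, m.
#' @param swd specific wood density, g/cm3.
#' @param cfg an [allometry_config()].
#' @return AGB in kg (vectorized).
#' @export
tree_agb <- function(dbh, height, swd, cfg = allometry_config()) {
  if (anyNA(dbh)) stop("dbh is required for adult trees")
  if (any(dbh < 0) || any(height <= 0) || any(swd <= 0)) {
    stop("dbh must be >= 0 and height, swd positive")
  }
  a <- cfg$tree[["a"]]
  b <- cfg$tree[["b"]]
  a * (swd * dbh^2 * height)^b
}

#' Aboveground biomass of shrub-like growth forms
#'
#' Crown-area x height power law \eqn{AGB = c\,CA^d H^e}, with crown area
#' taken as the ellipse spanned by two perpendicular crown diameters.
#' Applied to shrubs, gullivers and (by default) subadult individuals.
#'
#' @param crown_d1,crown_d2 perpendicular crown diameters, m.
#' @param height plant height, m.
#' @param cfg an [allometry_config()].
#' @return AGB in kg (vectorized).
#' @export
shrub_agb <- function(crown_d1, crown_d2, height, cfg = allometry_config()) {
  if (anyNA(crown_d1) || anyNA(crown_d2)) {
    stop("both crown diameters are required for shrub-like growth forms")
  }
  if (any(height <= 0)) stop("height must be positive")
  ca <- crown_area(crown_d1, crown_d2)
  cfg$shrub[["c"]] * ca^cfg$shrub[["d"]] * height^cfg$shrub[["e"]]
}

#' Convert aboveground biomass to aboveground carbon
#'
#' Multiplies AGB by a species-specific wood carbon fraction.
#'
#' @param agb aboveground biomass, kg, `>= 0`.
#' @param carbon_fraction unitless fraction in (0, 1).
#' @return Aboveground carbon in kg C.
#' @examples
#' agb_to_agc(100, 0.47) # 47
#' @export
agb_to_agc <- function(agb, carbon_fraction) {
  if (any(agb < 0)) stop("agb must be non-negative")
  if (any(carbon_fraction <= 0) || any(carbon_fraction >= 1)) {
    stop("carbon_fraction must lie in (0, 1)")
  }
  agb * carbon_fraction
}
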