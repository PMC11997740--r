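#' Soil depth classes
#'
#' The six sampling depth classes of the soil cores, with upper and lower
#' bounds and thicknesses in cm. Topsoil is 0-30 cm (three 10 cm classes),
#' subsoil 30-100 cm (20, 20 and 30 cm classes).
#'
#' @return data.frame with `depth_class`, `top`, `bottom`, `thickness`,
#'   `horizon` (`"topsoil"`/`"subsoil"`).
#' @export
depth_classes <- function() {
  data.frame(
    depth_class = c("0-10", "10-20", "20-30", "30-50", "50-70", "70-100"),
    top = c(0, 10, 20, 30, 50, 70),
    bottom = c(10, 20, 30, 50, 70, 100),
    thickness = c(10, 10, 10, 20, 20, 30),
    horizon = rep(c("topsoil", "subsoil"), each = 3),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
PATCH_TYPES <- c("under_tree", "between_trees", "bare")

#' SOC stock of one depth layer
#'
#' \eqn{SOC\ [t/ha] = C\ [g/kg] \times \rho_b\ [g/cm^3] \times d\ [cm] / 10}.
#'
#' @param conc carbon concentration, g/kg.
#' @param bd dry bulk density, g/cm3.
#' @param thickness layer thickness, cm.
#' @return SOC stock in t C/ha (vectorized).
#' @examples
#' soc_stock_layer(5, 1.5, 10) # 7.5
#' @export
soc_stock_layer <- function(conc, bd, thickness) {
  if (any(conc < 0) || any(bd < 0) || any(thickness < 0)) {
    stop("concentration, bulk density and thickness must be non-negative")
  }
  conc * bd * thickness / 10
}

#' Aggregate one soil core to topsoil and subsoil stocks
#'
#' Sums layer stocks over 0-10/10-20/20-30 cm (topsoil) and
#' 30-50/50-70/70-100 cm (subsoil). All six classes must be present, either
#' measured or imputed (see [impute_subsoil()]).
#'
#' @param core data.frame for one core with columns `depth_class`,
#'   `conc_g_kg`, `bulk_density_g_cm3`.
#' @return Named numeric `c(topsoil_soc=, subsoil_soc=)` in t C/ha.
#' @export
aggregate_core <- function(core) {
  dc <- depth_classes()
  idx <- match(dc$depth_class, core$depth_class)
  if (anyNA(idx)) {
    stop("core is missing depth classes: ",
         paste(dc$depth_class[is.na(idx)], collapse = ", "))
  }
  stocks <- soc_stock_layer(core$conc_g_kg[idx],
                            core$bulk_density_g_cm3[idx],
                            dc$thickness)
  c(topsoil_soc = sum(stocks[dc$horizon == "topsoil"]),
    subsoil_soc = sum(stocks[dc$horizon == "subsoil"]))
}

#' Impute missing deep layers of hand-augered cores
#'
#' Cores sampled with a hand auger stop at 50 cm and lack the 50-70 and
#' 70-100 cm classes. Their layer stocks are imputed as the arithmetic mean
#' of the corresponding measured layer stocks in neighbouring cores, i.e.
#' all full-depth cores from plots sharing land-use and vegetation type
#' (cores of the same patch type are used when any exist). Since the
#' imputation works on layer stocks (t/ha), the imputed rows carry the mean
#' stock in `conc_g_kg` with bulk density 10/thickness, so that
#' [soc_stock_layer()] returns exactly the imputed stock.
#'
#' @param soil long-format soil-core table with columns `plot_id`,
#'   `patch_type`, `depth_class`, `conc_g_kg`, `bulk_density_g_cm3`,
#'   `max_depth_cm`.
#' @param plots plot table with `plot_id`, `landuse`, `vegetation_type`.
#' @return The soil table with imputed rows appended and a logical column
#'   `imputed`.
#' @export
impute_subsoil <- function(soil, plots) {
  dc <- depth_classes()
  soil$imputed <- if (is.null(soil$imputed)) FALSE else soil$imputed
  soil <- merge(soil, plots[, c("plot_id", "landuse", "vegetation_type")],
                by = "plot_id", sort = FALSE)
  deep <- c("50-70", "70-100")
  core_key <- interaction(soil$plot_id, soil$patch_type, drop = TRUE)
  new_rows <- list()
  for (key in levels(core_key)) {
    rows <- soil[core_key == key, ]
    if (rows$max_depth_cm[1] >= 100) next
    missing <- setdiff(deep, rows$depth_class)
    if (!length(missing)) next
    nb <- soil[soil$landuse == rows$landuse[1] &
               soil$vegetation_type == rows$vegetation_type[1] &
               soil$plot_id != rows$plot_id[1] &
               soil$max_depth_cm >= 100 &
               soil$depth_class %in% missing & !soil$imputed, ]
    if (!nrow(nb)) {
      stop("no full-depth neighbour core (same land-use and vegetation type) ",
           "to impute plot ", rows$plot_id[1], " patch ", rows$patch_type[1])
    }
    same_patch <- nb[nb$patch_type == rows$patch_type[1], ]
    if (nrow(same_patch)) nb <- same_patch
    for (d in missing) {
      nbd <- nb[nb$depth_class == d, ]
      thick <- dc$thickness[dc$depth_class == d]
      mean_stock <- mean(soc_stock_layer(nbd$conc_g_kg,
                                         nbd$bulk_density_g_cm3, thick))
      new_rows[[length(new_rows) + 1]] <- data.frame(
        plot_id = rows$plot_id[1], patch_type = rows$patch_type[1],
        depth_class = d, conc_g_kg = mean_stock,
        bulk_density_g_cm3 = 10 / thick, max_depth_cm = rows$max_depth_cm[1],
        imputed = TRUE, landuse = rows$landuse[1],
        vegetation_type = rows$vegetation_type[1],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(new_rows)) soil <- rbind(soil, do.call(rbind, new_rows))
  soil$landuse <- NULL
  soil$vegetation_type <- NULL
  soil
}

#' Weight per-patch values by relative patch cover
#'
#' Plot value = sum of cover-weighted patch values. Covers are renormalized
#' over the sampled patch types, so a patch type absent from the plot
#' carries zero weight.
#'
#' @param values numeric vector of per-patch values (one per sampled patch).
#' @param covers cover fractions for the same patches, `>= 0`.
#' @return Weighted plot-level value.
#' @examples
#' weight_by_patch(c(10, 20), c(0.5, 0.5)) # 15
#' @export
weight_by_patch <- function(values, covers) {
  if (length(values) != length(covers)) stop("values and covers differ in length")
  if (any(covers < 0)) stop("covers must be non-negative")
  total <- sum(covers)
  if (total <= 0) stop("covers sum to zero over sampled patches")
  w <- covers / total
  if (abs(sum(w) - 1) > 1e-8) stop("covers do not renormalize to 1")
  sum(w * values)
}

#' Per-plot soil organic carbon from the core table
#'
#' Imputes missing deep layers, aggregates each core to topsoil/subsoil
#' stocks, and cover-weights the patch-type cores to plot-level stocks.
#'
#' @param soil long-format soil-core table (see [impute_subsoil()]).
#' @param plots plot table with `plot_id`, `landuse`, `vegetation_type` and
#'   patch covers `cover_under_tree`, `cover_between_trees`, `cover_bare`.
#' @return data.frame `plot_id`, `topsoil_soc`, `subsoil_soc`, `imputed`
#'   (TRUE when any core of the plot used imputation).
#' @export
compute_soil_carbon <- function(soil, plots) {
  validate_soil(soil)
  soil <- impute_subsoil(soil, plots)
  plot_ids <- unique(as.character(soil$plot_id))
  out <- lapply(plot_ids, function(pid) {
    sub <- soil[soil$plot_id == pid, ]
    patches <- unique(sub$patch_type)
    agg <- vapply(patches, function(pt) {
      aggregate_core(sub[sub$patch_type == pt, ])
    }, numeric(2))
    pr <- plots[as.character(plots$plot_id) == pid, ]
    covers <- vapply(patches, function(pt) pr[[paste0("cover_", pt)]],
                     numeric(1))
    data.frame(plot_id = pid,
               topsoil_soc = weight_by_patch(agg["topsoil_soc", ], covers),
               subsoil_soc = weight_by_patch(agg["subsoil_soc", ], covers),
               imputed = any(sub$imputed), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
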