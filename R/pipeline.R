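#' Pipeline run configuration
#'
#' Collects everything a reproducible end-to-end run needs: either a
#' simulation seed (tables are generated) or pre-loaded input tables, the
#' allometry coefficients, and the accounting thresholds (gulliver loss
#' 0.30, methuselah DBH 60 cm, Spearman 0.75).
#'
#' @param seed integer seed for simulation and model fitting.
#' @param design a [savanna_design()] (ignored when `tables` is given).
#' @param mix an [agent_mix()].
#' @param tables optional pre-built `savanna_dataset`-like list with
#'   `plots`, `inventory`, `species`, `soil`.
#' @param allometry an [allometry_config()].
#' @param gulliver_threshold loss fraction separating the BGC branches.
#' @param methuselah_dbh DBH threshold (cm).
#' @param spearman_threshold collinearity threshold for the GAMM predictor
#'   set.
#' @param fit_models fit the AGC and C_total GAMMs (set `FALSE` for a
#'   stocks-only run).
#' @param out_dir optional directory; when given, result tables and a run
#'   manifest are written there as delimited text.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, design = savanna_design(), mix = agent_mix(),
                       tables = NULL, allometry = allometry_config(),
                       gulliver_threshold = 0.30, methuselah_dbh = 60,
                       spearman_threshold = 0.75, fit_models = TRUE,
                       out_dir = NULL) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(gulliver_threshold > 0, methuselah_dbh > 0,
            spearman_threshold > 0)
  structure(list(seed = as.integer(seed), design = design, mix = mix,
                 tables = tables, allometry = allometry,
                 gulliver_threshold = gulliver_threshold,
                 methuselah_dbh = methuselah_dbh,
                 spearman_threshold = spearman_threshold,
                 fit_models = fit_models, out_dir = out_dir),
            class = "run_config")
}

#' Run the whole-ecosystem carbon pipeline
#'
#' Orchestrates simulate (or load) -> woody carbon -> soil carbon ->
#' disturbance summaries -> statistics. The result bundle contains the
#' per-plot six-compartment table with derived pools, per-land-use damage
#' shares, Games-Howell comparisons of AGC and C_total between land-use
#' types within each vegetation type, the two GAMM fits, and a manifest
#' (seed, thresholds, config hash) that makes every output traceable.
#' Re-running with the same config yields identical results.
#'
#' @param config a [run_config()].
#' @return List of class `savanna_run` with elements `compartments`,
#'   `damage_shares`, `group_tests`, `gamm_agc`, `gamm_ctotal`, `dataset`
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$tables)) {
    ds <- generate_dataset(config$design, config$mix, seed = config$seed)
  } else {
    ds <- config$tables
  }
  validate_plots(ds$plots)
  validate_inventory(ds$inventory)
  validate_species(ds$species)
  validate_soil(ds$soil)

  woody <- compute_woody_carbon(ds$inventory, ds$species, config$allometry,
                                gulliver_threshold = config$gulliver_threshold,
                                methuselah_dbh = config$methuselah_dbh,
                                all_plots = ds$plots$plot_id)
  soil <- compute_soil_carbon(ds$soil, ds$plots)
  comp <- carbon_compartments(woody, soil[, c("plot_id", "topsoil_soc",
                                              "subsoil_soc")],
                              plots = ds$plots)
  comp$bg_ag_ratio <- below_above_ratio(comp)
  shares <- damage_share_per_agent(ds$inventory, ds$plots)

  group_tests <- list()
  for (resp in c("agc", "c_total")) {
    for (veg in unique(comp$vegetation_type)) {
      sub <- comp[comp$vegetation_type == veg, ]
      if (length(unique(sub$landuse)) < 2) next
      key <- paste(resp, veg, sep = ".")
      group_tests[[key]] <- games_howell(sub[[resp]], sub$landuse)
    }
  }

  gamm_agc <- gamm_ctotal <- NULL
  if (isTRUE(config$fit_models)) {
    set.seed(config$seed)
    gamm_agc <- fit_gamm(comp, response = "agc",
                         spearman_threshold = config$spearman_threshold)
    gamm_ctotal <- fit_gamm(comp, response = "c_total",
                            spearman_threshold = config$spearman_threshold)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("savcarbon")),
    seed = config$seed,
    n_plots = nrow(comp),
    thresholds = c(gulliver = config$gulliver_threshold,
                   methuselah_dbh = config$methuselah_dbh,
                   spearman = config$spearman_threshold),
    allometry = unlist(config$allometry[c("tree", "shrub")]),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  run <- structure(list(compartments = comp, damage_shares = shares,
                        group_tests = group_tests, gamm_agc = gamm_agc,
                        gamm_ctotal = gamm_ctotal, dataset = ds,
                        manifest = manifest),
                   class = "savanna_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @keywords internal deterministic config fingerprint (no external deps)
config_hash <- function(config) {
  fields <- config[c("seed", "gulliver_threshold", "methuselah_dbh",
                     "spearman_threshold")]
  fields$allometry <- unlist(config$allometry[c("tree", "shrub")])
  fields$design <- unlist(config$design[c("n_plots", "plot_area",
                                          "replicates")])
  txt <- paste(deparse(fields), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)))
}

#' @keywords internal
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(run$compartments),
                   file.path(dir, "carbon_compartments.csv"),
                   row.names = FALSE)
  utils::write.csv(run$damage_shares, file.path(dir, "damage_shares.csv"),
                   row.names = FALSE)
  for (key in names(run$group_tests)) {
    utils::write.csv(run$group_tests[[key]],
                     file.path(dir, paste0("games_howell_", key, ".csv")),
                     row.names = FALSE)
  }
  manifest <- run$manifest
  writeLines(paste(names(manifest),
                   vapply(manifest, function(x) paste(format(x), collapse = " "),
                          character(1)), sep = ": "),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.savanna_run <- function(x, ...) {
  cat("Savanna carbon pipeline run\n")
  cat(sprintf("  %d plots; mean C_total %.1f t C/ha (AGC %.1f, BGC %.1f, SOC %.1f)\n",
              nrow(x$compartments), mean(x$compartments$c_total),
              mean(x$compartments$agc), mean(x$compartments$bgc),
              mean(x$compartments$soc)))
  if (!is.null(x$gamm_agc)) {
    cat(sprintf("  AGC GAMM deviance explained: %.1f%%\n",
                x$gamm_agc$deviance_explained))
  }
  cat(sprintf("  manifest hash: %s (seed %d)\n", x$manifest$config_hash,
              x$manifest$seed))
  invisible(x)
}

#' Per-land-use mean stocks
#'
#' Convenience summary: mean of a stock column per vegetation type and
#' land-use type, plus the pooled (plot-count weighted) land-use mean.
#'
#' @param compartments a [carbon_compartments()] table.
#' @param column stock column to summarize.
#' @return List with `by_veg` (data.frame) and `pooled` (named vector).
#' @export
landuse_means <- function(compartments, column = "agc") {
  by_veg <- stats::aggregate(compartments[[column]],
                             by = list(vegetation_type = compartments$vegetation_type,
                                       landuse = compartments$landuse),
                             FUN = mean)
  names(by_veg)[3] <- column
  pooled <- tapply(compartments[[column]], compartments$landuse, mean)
  list(by_veg = by_veg, pooled = pooled)
}
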