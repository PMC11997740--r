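#' Herbivore guild membership
#'
#' Lookup table mapping the herbivore species scored on plots (dung, tracks
#' and trampling indices, 0-10 per species) to the four guilds used in the
#' analysis: 13 wild grazers/mixed feeders, 3 domestic grazers/mixed
#' feeders, 1 mega-browser (elephant) and 2 other browsers.
#'
#' @return data.frame with columns `species` and `guild`.
#' @export
herbivore_guilds <- function() {
  data.frame(
    species = c("buffalo", "plains_zebra", "impala", "blue_wildebeest",
                "tsessebe", "waterbuck", "reedbuck", "red_lechwe", "roan",
                "sable", "eland", "warthog", "hippopotamus",
                "cattle", "goat", "sheep",
                "elephant",
                "kudu", "steenbok"),
    guild = c(rep("wild_grazer", 13), rep("domestic_grazer", 3),
              "mega_browser", rep("other_browser", 2)),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
check_rating_grid <- function(rating, max = 5) {
  if (any(!is.finite(rating)) || any(rating < 0) || any(rating > max) ||
      any(abs(rating * 2 - round(rating * 2)) > 1e-9)) {
    stop("ratings must lie on the 0.5-step grid in [0, ", max, "]")
  }
  invisible(rating)
}

#' Plot-level disturbance intensity for one agent
#'
#' Sums the four component ratings of an agent (overstorey/understorey x
#' old/recent events, each 0-5 in 0.5 steps) into an ordinal intensity
#' score from 0 to 20. Used for fire and woodcutting; browsing is kept
#' separate by layer (see [browsing_by_layer()]).
#'
#' @param ratings numeric vector of four component ratings.
#' @return Intensity score in \[0, 20\].
#' @export
agent_intensity <- function(ratings) {
  if (length(ratings) != 4) {
    stop("agent_intensity expects four component ratings (2 layers x 2 recency)")
  }
  check_rating_grid(ratings)
  sum(ratings)
}

#' Layer-wise browsing intensity
#'
#' Browsing ratings are summed over recency within each vegetation layer
#' and kept separate: the overstorey score (> 3 m, predominantly reachable
#' by elephants) and the understorey score (<= 3 m, all browsers), each
#' ranging 0-10 in 0.5 steps.
#'
#' @param over_old,over_recent overstorey ratings (old / recent events).
#' @param under_old,under_recent understorey ratings.
#' @return Named numeric `c(overstorey=, understorey=)`.
#' @export
browsing_by_layer <- function(over_old, over_recent, under_old, under_recent) {
  check_rating_grid(c(over_old, over_recent, under_old, under_recent))
  c(overstorey = over_old + over_recent,
    understorey = under_old + under_recent)
}

#' Herbivore-guild density scores
#'
#' Sums per-species abundance indices (0 = missing to 10 = very high
#' density) within guilds.
#'
#' @param indices data.frame with columns `species` and `index`
#'   (integers 0-10).
#' @param guilds guild lookup, defaults to [herbivore_guilds()].
#' @return Named numeric vector of per-guild totals (all guilds present,
#'   zero-filled).
#' @export
guild_density <- function(indices, guilds = herbivore_guilds()) {
  if (any(!(indices$index %in% 0:10))) {
    stop("herbivore indices must be integers in 0..10")
  }
  g <- guilds$guild[match(indices$species, guilds$species)]
  if (anyNA(g)) {
    stop("species with unknown guild: ",
         paste(unique(indices$species[is.na(g)]), collapse = ", "))
  }
  out <- tapply(indices$index, factor(g, levels = unique(guilds$guild)),
                sum, default = 0)
  stats::setNames(as.numeric(out), names(out))
}

#' Per-land-use damage shares of the five disturbance agents
#'
#' From the living-plant inventory, the share of each agent in the total
#' recorded biomass loss per land-use class:
#' share(agent) = sum(agent losses) / sum(all losses). Land-use classes
#' with zero total recorded damage get `NA` shares.
#'
#' @param inventory inventory table with the five `loss_*` columns and
#'   `plot_id`.
#' @param plots plot table with `plot_id` and `landuse`.
#' @return data.frame with `landuse`, `agent`, `share`.
#' @export
damage_share_per_agent <- function(inventory, plots) {
  lu <- plots$landuse[match(as.character(inventory$plot_id),
                            as.character(plots$plot_id))]
  if (anyNA(lu)) stop("inventory rows reference plots missing from plot table")
  loss_cols <- paste0("loss_", LOSS_AGENTS)
  out <- lapply(split(seq_len(nrow(inventory)), lu), function(i) {
    tot <- colSums(inventory[i, loss_cols, drop = FALSE])
    s <- sum(tot)
    share <- if (s > 0) tot / s else rep(NA_real_, length(tot))
    data.frame(landuse = lu[i[1]], agent = LOSS_AGENTS,
               share = as.numeric(share), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
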