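# Small in-code fixtures shared across test files.

tiny_species <- function() {
  data.frame(
    species = c("sp_tree", "sp_shrub"),
    swd = c(0.60, 0.55),
    carbon_fraction = c(0.47, 0.46),
    stringsAsFactors = FALSE
  )
}

# one adult tree and one shrub on a 1000 m2 plot
tiny_inventory <- function(loss_elephant = 0, loss_fire = 0) {
  data.frame(
    plot_id = "P1",
    species = c("sp_tree", "sp_shrub"),
    growth_form = c("adult_tree", "shrub"),
    height_m = c(8, 2),
    crown_d1_m = c(3, 2),
    crown_d2_m = c(3, 2),
    basal_diameter_cm = c(12, 3),
    dbh_cm = c(10, NA),
    loss_elephant = loss_elephant,
    loss_other_browser = 0,
    loss_woodcutting = 0,
    loss_fire = loss_fire,
    loss_other = 0,
    subplot_area_m2 = c(1000, 100),
    stringsAsFactors = FALSE
  )
}

# a full-depth soil core in long format
tiny_core <- function(plot_id = "P1", patch_type = "under_tree",
                      conc = rep(5, 6), bd = rep(1.5, 6), max_depth = 100) {
  dc <- depth_classes()
  n <- sum(dc$bottom <= max_depth)
  data.frame(
    plot_id = plot_id, patch_type = patch_type,
    depth_class = dc$depth_class[seq_len(n)],
    conc_g_kg = conc[seq_len(n)], bulk_density_g_cm3 = bd[seq_len(n)],
    max_depth_cm = max_depth, stringsAsFactors = FALSE
  )
}

tiny_plots <- function(plot_id = "P1", landuse = "L", veg = "scrub",
                       covers = c(0.4, 0.4, 0.2)) {
  data.frame(
    plot_id = plot_id, vegetation_type = veg, landuse = landuse,
    plot_area_m2 = 1000,
    browsing_over = 2, browsing_under = 2, fire_intensity = 8,
    woodcut_intensity = 1,
    cover_under_tree = covers[1], cover_between_trees = covers[2],
    cover_bare = covers[3], stringsAsFactors = FALSE
  )
}
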