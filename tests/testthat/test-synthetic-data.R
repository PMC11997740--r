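test_that("the default design generates the 84-plot study layout", {
  ds <- generate_dataset(seed = 2)
  expect_equal(nrow(ds$plots), 84)
  expect_equal(as.integer(table(ds$plots$vegetation_type)), c(42L, 42L))
  counts <- table(ds$plots$landuse, ds$plots$vegetation_type)
  expect_equal(as.integer(counts[c("L", "M", "H", "R", "A"), "scrub"]),
               c(10L, 10L, 10L, 6L, 6L))
  expect_true(all(ds$plots$plot_area_m2[ds$plots$landuse != "A"] == 1000))
  expect_true(all(ds$plots$plot_area_m2[ds$plots$landuse == "A"] > 1000))
})

test_that("generation is deterministic under a fixed seed and requires one", {
  a <- generate_dataset(seed = 33)
  b <- generate_dataset(seed = 33)
  expect_identical(a$plots, b$plots)
  expect_identical(a$inventory, b$inventory)
  expect_identical(a$soil, b$soil)
  expect_identical(a$truth$plot, b$truth$plot)
  c <- generate_dataset(seed = 34)
  expect_false(identical(a$plots, c$plots))
  expect_error(generate_dataset(), "seed")
})

test_that("an empty design yields empty tables without error", {
  design <- savanna_design(n_plots = c(L = 0, M = 0, H = 0, R = 0, A = 0))
  ds <- generate_dataset(design, seed = 1)
  expect_equal(nrow(ds$plots), 0)
  expect_equal(nrow(ds$inventory), 0)
  expect_equal(nrow(ds$soil), 0)
  expect_error(savanna_design(n_plots = c(L = -1, M = 0, H = 0, R = 0, A = 0)),
               "non-negative")
})

test_that("generated tables satisfy the downstream invariants", {
  ds <- generate_dataset(seed = 5)
  expect_silent(validate_plots(ds$plots))
  expect_silent(validate_inventory(ds$inventory))
  expect_silent(validate_species(ds$species))
  expect_silent(validate_soil(ds$soil))
  losses <- as.matrix(ds$inventory[, paste0("loss_", c("elephant",
    "other_browser", "woodcutting", "fire", "other"))])
  expect_true(all(losses >= 0 & losses <= 1))
  expect_true(all(rowSums(losses) < 1))
  covers <- ds$plots$cover_under_tree + ds$plots$cover_between_trees +
    ds$plots$cover_bare
  expect_equal(covers, rep(1, nrow(ds$plots)))
  # woodland plots carry more tree carbon than scrub plots at equal land use
  woody <- compute_woody_carbon(ds$inventory, ds$species,
                                all_plots = ds$plots$plot_id)
  agc <- woody$tree_agc + woody$shrub_agc
  lu <- ds$plots$landuse
  veg <- ds$plots$vegetation_type
  expect_gt(mean(agc[veg == "woodland" & lu == "L"]),
            mean(agc[veg == "scrub" & lu == "L"]))
})

test_that("soil cores decline in carbon with depth and match the reported bulk densities", {
  ds <- generate_dataset(seed = 8)
  top <- ds$soil[ds$soil$depth_class == "0-10", ]
  deep <- ds$soil[ds$soil$depth_class == "70-100", ]
  conc_top <- tapply(top$conc_g_kg, top$plot_id, mean)
  conc_deep <- tapply(deep$conc_g_kg, deep$plot_id, mean)
  shared <- intersect(names(conc_top), names(conc_deep))
  expect_gt(mean(conc_top[shared] > conc_deep[shared]), 0.95)
  dc <- depth_classes()
  topsoil <- ds$soil$depth_class %in% dc$depth_class[dc$horizon == "topsoil"]
  expect_equal(mean(ds$soil$bulk_density_g_cm3[topsoil]), 1.45,
               tolerance = 0.02)
  expect_equal(mean(ds$soil$bulk_density_g_cm3[!topsoil]), 1.74,
               tolerance = 0.02)
  # rangeland/agriculture carry a positive SOC offset over the reference
  lu <- ds$plots$landuse[match(top$plot_id, ds$plots$plot_id)]
  expect_gt(mean(top$conc_g_kg[lu %in% c("R", "A")]),
            mean(top$conc_g_kg[lu == "L"]))
  expect_equal(mean(ds$plots$sand_pct), 93, tolerance = 0.03)
})

test_that("per-land-use damage shares converge to the configured agent mix", {
  # a large design so inventory-level shares stabilize
  ds <- generate_dataset(savanna_design(replicates = 4), seed = 9)
  shares <- damage_share_per_agent(ds$inventory, ds$plots)
  mix <- unclass(ds$truth$agent_mix)
  for (l in c("L", "H", "A")) {
    for (agent in c("elephant", "woodcutting", "fire")) {
      got <- shares$share[shares$landuse == l & shares$agent == agent]
      n_l <- sum(ds$plots$landuse[match(ds$inventory$plot_id,
                                        ds$plots$plot_id)] == l)
      se <- sqrt(mix[l, agent] * (1 - mix[l, agent]) / n_l) +
        0.2 / sqrt(n_l)
      expect_lt(abs(got - mix[l, agent]), max(3 * se, 0.04))
    }
  }
})

test_that("the unimodal response kernel peaks where programmed and is symmetric", {
  expect_equal(generate_unimodal_response(4, peak = 4, amplitude = 3), 3)
  expect_equal(generate_unimodal_response(2.5, 4, 3),
               generate_unimodal_response(5.5, 4, 3))
  x <- seq(0, 10, 0.1)
  y <- generate_unimodal_response(x, 4, 3)
  expect_equal(x[which.max(y)], 4)
  expect_error(generate_unimodal_response(1, 4, -1), "amplitude")
  expect_error(generate_unimodal_response(1, 4, 1, noise_sd = -1), "noise_sd")
})

test_that("Monte-Carlo mean of the noisy kernel matches the closed form", {
  set.seed(99)
  x <- 2.5
  draws <- generate_unimodal_response(rep(x, 1e4), peak = 4, amplitude = 3,
                                      noise_sd = 0.8)
  closed <- 3 * exp(-(x - 4)^2 / (2 * 2^2))
  se <- 0.8 / sqrt(1e4)
  expect_lt(abs(mean(draws) - closed), 3 * se)
})

test_that("dataset round trip through delimited text preserves the tables", {
  ds <- generate_dataset(savanna_design(n_plots = c(L = 2, M = 0, H = 0,
                                                    R = 0, A = 1)), seed = 4)
  dir <- tempfile("savds")
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  plots2 <- read.csv(paths[["plots"]], stringsAsFactors = FALSE)
  expect_equal(plots2$plot_id, ds$plots$plot_id)
  expect_equal(plots2$cover_bare, ds$plots$cover_bare, tolerance = 1e-12)
  inv2 <- read.csv(paths[["inventory"]], stringsAsFactors = FALSE)
  expect_equal(nrow(inv2), nrow(ds$inventory))
  unlink(dir, recursive = TRUE)
})
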