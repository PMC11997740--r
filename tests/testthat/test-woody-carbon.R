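test_that("total loss sums agents, rejects simplex violations, caps at 0.99", {
  expect_equal(total_loss_fraction(c(0, 0, 0, 0, 0)), 0)
  expect_equal(total_loss_fraction(c(0.2, 0, 0, 0.1, 0)), 0.3)
  expect_error(total_loss_fraction(c(0.5, 0.55, 0, 0, 0)), "simplex")
  expect_error(total_loss_fraction(c(-0.1, 0, 0, 0, 0)), "\\[0, 1\\]")
  expect_equal(total_loss_fraction(c(0.995, 0, 0, 0.005, 0)), 0.99)
})

test_that("pre-disturbance extrapolation inverts the loss correction", {
  expect_equal(pre_disturbance_agc(7, 0), 7)
  expect_equal(pre_disturbance_agc(7, 0.3), 10)
  expect_equal(pre_disturbance_agc(5, 0.5), 10)
  expect_error(pre_disturbance_agc(5, 1), "0.99")
  # algebraic round trip: agc_pre * (1 - loss) recovers agc_actual
  set.seed(7)
  loss <- runif(100, 0, 0.95)
  agc <- runif(100, 0, 500)
  expect_equal(pre_disturbance_agc(agc, loss) * (1 - loss), agc)
})

test_that("root:shoot ratio is fixed for shrub forms and size-dependent for trees", {
  expect_equal(rs_ratio("shrub"), 2.16)
  expect_equal(rs_ratio("gulliver"), 2.16)
  expect_equal(rs_ratio("subadult", dbh = 40), 2.16)
  expect_equal(rs_ratio("adult_tree", 1), 1.89208)
  expect_equal(rs_ratio("adult_tree", 20), 0.514172138361405, tolerance = 1e-12)
  expect_error(rs_ratio("adult_tree"), "dbh")
  expect_error(rs_ratio("sapling"), "unknown growth form")
})

test_that("tree RS ratio decreases in DBH and crosses the shrub ratio exactly once", {
  d <- seq(0.5, 100, by = 0.1)
  rs <- rs_ratio(rep("adult_tree", length(d)), d)
  expect_true(all(diff(rs) < 0))
  # sign changes of rs - 2.16
  expect_equal(sum(diff(sign(rs - 2.16)) != 0), 1)
})

test_that("individual BGC follows the gulliver min/max averaging rule", {
  expect_equal(individual_bgc(10, 10, 0, 0.5), 5)
  expect_equal(individual_bgc(5, 10, 0.5, 0.5), 3.75)
  # boundary at exactly 30% loss stays on the slightly-damaged branch
  expect_equal(individual_bgc(7, 10, 0.30, 1), 10)
  expect_equal(individual_bgc(6.9, 10, 0.31, 1), (10 + 6.9) / 2)
  expect_error(individual_bgc(-1, 1, 0, 1), "non-negative")
  expect_error(individual_bgc(10, 5, 0.5, 1), "at least")
})

test_that("gulliver BGC is bounded by the pre and post stocks", {
  set.seed(42)
  n <- 1000
  loss <- runif(n, 0, 0.95)
  agc_pre <- runif(n, 1, 100)
  agc <- agc_pre * (1 - loss)
  rs <- runif(n, 0.3, 2.5)
  bgc <- individual_bgc(agc, agc_pre, loss, rs)
  expect_true(all(bgc >= rs * agc - 1e-12))
  expect_true(all(bgc <= rs * agc_pre + 1e-12))
})

test_that("compartment assignment splits trees from shrub-like forms", {
  expect_equal(assign_compartment("adult_tree"), "tree")
  expect_equal(assign_compartment(c("gulliver", "shrub", "subadult")),
               rep("shrub", 3))
  expect_error(assign_compartment("liana"), "unknown growth form")
})

test_that("per-hectare scaling matches brute-force per-individual expansion", {
  expect_equal(scale_to_hectare("P1", 1, "tree_agc", 100)$tree_agc, 0.1)
  two <- scale_to_hectare(c("P1", "P1"), c(1, 1), c("tree_agc", "tree_agc"),
                          c(100, 100))
  expect_equal(two$tree_agc, 0.2)
  # mixed subplot sizes vs brute-force oracle
  set.seed(5)
  n <- 200
  pid <- sample(c("A", "B", "C"), n, replace = TRUE)
  kg <- runif(n, 0, 50)
  comp <- sample(c("tree_agc", "shrub_agc"), n, replace = TRUE)
  area <- sample(c(100, 250, 1000), n, replace = TRUE)
  got <- scale_to_hectare(pid, kg, comp, area)
  for (p in c("A", "B", "C")) {
    for (cc in c("tree_agc", "shrub_agc")) {
      i <- pid == p & comp == cc
      oracle <- sum(kg[i] / 1000 * 10000 / area[i])
      expect_equal(got[[cc]][got$plot_id == p], oracle)
    }
  }
  expect_error(scale_to_hectare("P1", 1, "tree_agc", 0), "positive")
})

test_that("methuselah flag uses a strict 60 cm threshold on adult trees", {
  expect_false(flag_methuselah(60, "adult_tree"))
  expect_true(flag_methuselah(61, "adult_tree"))
  expect_false(flag_methuselah(numeric(0), character(0)))
  # a 70 cm basal diameter on a shrub-form individual does not count
  expect_false(flag_methuselah(c(NA, 70), c("adult_tree", "gulliver")))
})

test_that("plot-level stocks equal a brute-force individual-level computation", {
  inv <- tiny_inventory(loss_elephant = 0.2, loss_fire = 0.25)
  sp <- tiny_species()
  got <- compute_woody_carbon(inv, sp)
  cfg <- allometry_config()
  # independent brute force for both individuals
  agb1 <- 0.0673 * (0.60 * 10^2 * 8)^0.976
  agc1 <- agb1 * 0.47
  pre1 <- agc1 / (1 - 0.45)
  rs1 <- 1.89208 * 10^(-0.43491)
  bgc1 <- (rs1 * pre1 + rs1 * agc1) / 2  # loss 0.45 > 0.30
  agb2 <- 2.5 * (pi * 1 * 1)^1.2 * 2^0.9
  agc2 <- agb2 * 0.46
  pre2 <- agc2 / (1 - 0.45)
  bgc2 <- (2.16 * pre2 + 2.16 * agc2) / 2
  expect_equal(got$tree_agc, agc1 / 1000 * 10)
  expect_equal(got$tree_bgc, bgc1 / 1000 * 10)
  expect_equal(got$shrub_agc, agc2 / 1000 * 100)
  expect_equal(got$shrub_bgc, bgc2 / 1000 * 100)
  expect_false(got$methuselah)
})

test_that("zero losses reduce the pipeline to uncorrected allometry", {
  inv0 <- tiny_inventory()
  inv1 <- tiny_inventory(loss_elephant = 0.2)
  sp <- tiny_species()
  got0 <- compute_woody_carbon(inv0, sp)
  got1 <- compute_woody_carbon(inv1, sp)
  # actual AGC is unaffected by the recorded losses
  expect_equal(got0$tree_agc, got1$tree_agc)
  # with zero loss, BGC is exactly rs * agc
  agc1 <- 0.0673 * (0.60 * 10^2 * 8)^0.976 * 0.47
  rs1 <- 1.89208 * 10^(-0.43491)
  expect_equal(got0$tree_bgc, rs1 * agc1 / 1000 * 10)
})

test_that("compartment table derives pools and enforces identities", {
  woody <- data.frame(plot_id = "P1", tree_agc = 4, tree_bgc = 3,
                      shrub_agc = 2, shrub_bgc = 1, methuselah = FALSE)
  soil <- data.frame(plot_id = "P1", topsoil_soc = 12, subsoil_soc = 18)
  comp <- carbon_compartments(woody, soil)
  expect_equal(comp$agc, 6)
  expect_equal(comp$bgc, 4)
  expect_equal(comp$soc, 30)
  expect_equal(comp$c_total, 40)
  soil_bad <- data.frame(plot_id = "P1", topsoil_soc = -1, subsoil_soc = 18)
  expect_error(carbon_compartments(woody, soil_bad), "negative")
})

test_that("inventory validation enforces the data invariants", {
  inv <- tiny_inventory()
  expect_silent(validate_inventory(inv))
  bad <- inv; bad$dbh_cm[1] <- 4
  expect_error(validate_inventory(bad), "DBH >= 5")
  bad <- inv; bad$loss_elephant <- c(0.6, 0.6); bad$loss_fire <- c(0.5, 0.5)
  expect_error(validate_inventory(bad), "sum")
  bad <- inv; bad$height_m[2] <- 0
  expect_error(validate_inventory(bad), "height")
})
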