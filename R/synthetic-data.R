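#' Study design specification
#'
#' The sampling design the generator emulates: two savanna vegetation types
#' (short scrub, tall woodland), five land-use types along the composite
#' disturbance gradient — low-disturbance reference (L), medium (M) and
#' high (H) elephant density, rangeland (R) and agricultural fields (A) —
#' with 10/10/10/6/6 plots per vegetation type (84 plots in total) and a
#' plot size of 1000 m2 (agricultural plots take the field's area and are
#' drawn larger).
#'
#' @param n_plots named integer vector of plots per land-use type (per
#'   vegetation type).
#' @param vegetation_types character vector of vegetation types.
#' @param plot_area plot area in m2.
#' @param replicates integer; replicate the whole design this many times
#'   (used for larger simulation studies, e.g. `replicates = 5` gives 420
#'   plots).
#' @return Object of class `savanna_design`.
#' @export
savanna_design <- function(n_plots = c(L = 10, M = 10, H = 10, R = 6, A = 6),
                           vegetation_types = c("scrub", "woodland"),
                           plot_area = 1000, replicates = 1) {
  if (any(n_plots < 0) || any(n_plots != round(n_plots))) {
    stop("plot counts must be non-negative integers")
  }
  if (plot_area <= 0) stop("plot_area must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(n_plots = n_plots, vegetation_types = vegetation_types,
                 plot_area = plot_area, replicates = as.integer(replicates)),
            class = "savanna_design")
}

#' Land-use disturbance-agent mix
#'
#' Mean share of total recorded biomass damage attributed to each of the
#' five disturbance agents, per land-use type. The defaults are anchored to
#' the observed archive percentages: the elephant share rises from 31% on
#' low-density (L) plots to 78% on high-density (H) plots and falls to 7%
#' on agricultural (A) plots; the woodcutting share rises from 2% (L) to
#' 58% (A); the fire share is maximal on L plots (61%) and drops to 14% on
#' H plots. Rows are simplexes (non-negative, summing to 1).
#'
#' @param mix numeric matrix, land-use types in rows, agents
#'   (`elephant`, `other_browser`, `woodcutting`, `fire`, `other`) in
#'   columns.
#' @return The validated matrix (class `agent_mix`).
#' @export
agent_mix <- function(mix = default_agent_mix_matrix()) {
  mix <- as.matrix(mix)
  if (any(mix < 0) || any(mix > 1)) stop("agent shares must lie in [0, 1]")
  if (any(abs(rowSums(mix) - 1) > 1e-8)) {
    stop("agent shares must sum to 1 per land-use type")
  }
  if (!identical(colnames(mix), LOSS_AGENTS)) {
    stop("agent columns must be: ", paste(LOSS_AGENTS, collapse = ", "))
  }
  structure(mix, class = c("agent_mix", "matrix"))
}

#' @keywords internal
default_agent_mix_matrix <- function() {
  m <- rbind(
    L = c(0.31, 0.04, 0.02, 0.61, 0.02),
    M = c(0.55, 0.05, 0.03, 0.35, 0.02),
    H = c(0.78, 0.04, 0.02, 0.14, 0.02),
    R = c(0.15, 0.12, 0.35, 0.30, 0.08),
    A = c(0.07, 0.09, 0.58, 0.20, 0.06)
  )
  colnames(m) <- LOSS_AGENTS
  m
}

#' Unimodal disturbance-carbon response kernel
#'
#' Gaussian bump used to program hump-shaped ("intermediate disturbance")
#' carbon responses in the generator: expected response is maximal
#' (`amplitude`) at `x = peak`, declines symmetrically with width `width`,
#' plus optional Gaussian noise.
#'
#' @param x disturbance score(s).
#' @param peak score at which the response peaks.
#' @param amplitude response maximum, t C/ha, `>= 0`.
#' @param noise_sd Gaussian noise standard deviation, t C/ha, `>= 0`.
#' @param width kernel standard deviation on the score scale.
#' @return Numeric vector of responses.
#' @export
generate_unimodal_response <- function(x, peak, amplitude, noise_sd = 0,
                                       width = 2) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (width <= 0) stop("width must be positive")
  mu <- amplitude * exp(-(x - peak)^2 / (2 * width^2))
  if (noise_sd > 0) mu <- mu + stats::rnorm(length(x), 0, noise_sd)
  mu
}

# ---- fixed generator conditions -------------------------------------------

#' @keywords internal
#' Land-use means of the plot-level drivers (the generated study
#' conditions); scores on their ordinal scales, soil N in %, CEC in
#' cmol/kg, soc_base in g C/kg (plot-mean topsoil-class concentration
#' scale).
lu_conditions <- function() {
  data.frame(
    landuse = c("L", "M", "H", "R", "A"),
    browse_over = c(1.5, 4.0, 7.5, 1.0, 0.5),
    browse_under = c(2.0, 3.0, 3.5, 6.0, 3.0),
    woodcut = c(0.5, 1.0, 1.0, 6.0, 14.0),
    fire = c(10.0, 9.0, 8.0, 9.0, 8.0),
    wild_graz = c(10, 18, 14, 5, 3),
    dom_graz = c(0.5, 0.5, 0.5, 12, 8),
    soil_n = c(0.020, 0.020, 0.022, 0.030, 0.035),
    cec = c(2.5, 2.5, 3.0, 4.5, 5.0),
    soc_base = c(2.0, 2.0, 2.2, 2.5, 2.7),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
#' Programmed partial-effect functions of expected actual AGC (t C/ha).
#' The overstorey-browsing effect is unimodal (bump minus linear decline),
#' understorey browsing is linearly negative, woodcutting is a depletion
#' curve, wild grazer density is a pure bump, fire and domestic grazers
#' are programmed nulls.
agc_effects <- function() {
  list(
    baseline = c(scrub = 6.0, woodland = 9.8),
    browsing_over = function(x) {
      generate_unimodal_response(x, peak = 3, amplitude = 2.5, width = 2.2) -
        0.25 * x
    },
    browsing_under = function(x) -0.25 * x,
    woodcut_intensity = function(x) -8 * (1 - exp(-x / 6)),
    fire_intensity = function(x) 0 * x,
    wild_grazer = function(x) {
      generate_unimodal_response(x, peak = 14, amplitude = 1.2, width = 6)
    },
    domestic_grazer = function(x) 0 * x,
    soil_n = function(x) 25 * (x - 0.025),
    cec = function(x) -0.22 * (x - 3.5),
    methuselah_bonus = 8,
    noise_sd = 1.0,
    floor = 0.2
  )
}

#' @keywords internal
#' Species trait table (specific wood density g/cm3, wood carbon fraction)
#' for the tree and shrub pools of the two vegetation types.
species_pool <- function() {
  data.frame(
    species = c("Terminalia_sericea", "Vachellia_erioloba",
                "Combretum_collinum", "Philenoptera_nelsii",
                "Baikiaea_plurijuga", "Burkea_africana",
                "Erythrophleum_africanum", "Senegalia_nigrescens",
                "Baphia_massaiensis", "Dichrostachys_cinerea"),
    swd = c(0.61, 0.82, 0.60, 0.55, 0.78, 0.63, 0.72, 0.75, 0.58, 0.76),
    carbon_fraction = c(0.47, 0.48, 0.46, 0.46, 0.48, 0.47, 0.48, 0.47,
                        0.46, 0.47),
    habit = c("both", "tree", "tree", "tree", "tree", "tree", "tree",
              "tree", "shrub", "shrub"),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
tree_species_for <- function(veg) {
  if (veg == "scrub") {
    c("Terminalia_sericea", "Vachellia_erioloba", "Combretum_collinum",
      "Philenoptera_nelsii")
  } else {
    c("Baikiaea_plurijuga", "Burkea_africana", "Erythrophleum_africanum",
      "Senegalia_nigrescens", "Vachellia_erioloba")
  }
}

#' @keywords internal
shrub_species_for <- function(veg) {
  c("Baphia_massaiensis", "Dichrostachys_cinerea", "Terminalia_sericea")
}

#' @keywords internal snap to the 0.5 rating grid, clamped to [0, max]
snap_rating <- function(x, max = 5) {
  pmin(max, pmax(0, round(x * 2) / 2))
}

#' @keywords internal Dirichlet draw via gamma normalization
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

# ---- generator -------------------------------------------------------------

#' Generate a synthetic savanna carbon dataset
#'
#' Produces the four input tables of the carbon-accounting pipeline —
#' woody-plant inventory, species traits, soil cores, plot table — plus a
#' ground-truth record, for the full study design. The generated data carry
#' the study's statistical structure: woodland plots have a higher tree
#' carbon baseline than scrub plots; per-agent biomass-loss fractions are
#' Beta-distributed totals split across agents by a Dirichlet whose
#' land-use means follow the agent mix (elephant damage rising L to H,
#' woodcutting rising L to A, fire maximal at L); expected actual AGC is an
#' additive function of the plot's disturbance scores with programmed
#' unimodal overstorey-browsing and wild-grazer effects and programmed
#' null fire and domestic-grazer effects; soil carbon concentrations
#' decline with depth, carry a positive offset on rangeland/agricultural
#' plots, and sit on bulk densities near 1.45 g/cm3 in topsoil and 1.74
#' g/cm3 in subsoil; sand contents are near 93 +/- 4 %.
#'
#' Plot realization fills each plot with individuals (adult trees first,
#' then understorey shrubs/subadults/gullivers) until the plot's programmed
#' actual AGC is reached, so re-running the accounting pipeline on the
#' inventory recovers the programmed plot stocks up to one small
#' individual's carbon.
#'
#' The ground truth is never consumed by the pipeline itself; it exists so
#' parameter-recovery tests can compare estimates against the programmed
#' values.
#'
#' @param design a [savanna_design()].
#' @param mix an [agent_mix()].
#' @param seed integer seed; required (reproducibility contract). One RNG
#'   substream is derived per table, so adding a table does not perturb the
#'   others.
#' @return List of class `savanna_dataset` with elements `plots`,
#'   `inventory`, `species`, `soil`, `herbivores` and `truth`.
#' @export
generate_dataset <- function(design = savanna_design(), mix = agent_mix(),
                             seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("an integer seed is required")
  }
  stopifnot(inherits(design, "savanna_design"))
  mix <- agent_mix(unclass(mix))
  set.seed(as.integer(seed))
  substream <- sample.int(.Machine$integer.max - 1, 3)

  species <- species_pool()[, c("species", "swd", "carbon_fraction")]
  plots <- generate_plot_table(design, substream[1])
  inventory <- generate_inventory(plots, mix, substream[2])
  soil <- generate_soil_cores(plots, substream[3])
  herb <- attr(plots, "herbivores")
  attr(plots, "herbivores") <- NULL

  eff <- agc_effects()
  lu <- lu_conditions()
  expected <- expected_landuse_means(design)
  truth <- structure(list(
    plot = plots[, c("plot_id", "vegetation_type", "landuse",
                     "expected_agc", "target_agc", "methuselah_truth")],
    effects = eff,
    peak_overstorey = optimize_peak(eff$browsing_over, c(0, 10)),
    expected_landuse_means = expected,
    agent_mix = mix,
    conditions = lu,
    seed = as.integer(seed)
  ), class = "savanna_truth")
  plots$expected_agc <- NULL
  plots$target_agc <- NULL
  plots$methuselah_truth <- NULL

  structure(list(plots = plots, inventory = inventory, species = species,
                 soil = soil, herbivores = herb, truth = truth),
            class = "savanna_dataset")
}

#' @keywords internal numeric argmax of an effect function on an interval
optimize_peak <- function(f, range) {
  stats::optimize(f, interval = range, maximum = TRUE)$maximum
}

#' Expected land-use means of actual AGC under the generated conditions
#'
#' Deterministic part of the programmed plot AGC evaluated at the land-use
#' mean driver values (methuselah bonus entering with its occurrence
#' probability), per vegetation type.
#'
#' @param design a [savanna_design()].
#' @param p_methuselah plot-level methuselah probability used by the
#'   generator.
#' @return data.frame `vegetation_type`, `landuse`, `n_plots`,
#'   `expected_agc`.
#' @export
expected_landuse_means <- function(design = savanna_design(),
                                   p_methuselah = 0.05) {
  eff <- agc_effects()
  lu <- lu_conditions()
  out <- expand.grid(vegetation_type = design$vegetation_types,
                     landuse = lu$landuse, stringsAsFactors = FALSE)
  i <- match(out$landuse, lu$landuse)
  out$n_plots <- as.integer(design$n_plots[out$landuse] * design$replicates)
  out$expected_agc <- eff$baseline[out$vegetation_type] +
    eff$browsing_over(lu$browse_over[i]) +
    eff$browsing_under(lu$browse_under[i]) +
    eff$woodcut_intensity(lu$woodcut[i]) +
    eff$wild_grazer(lu$wild_graz[i]) +
    eff$soil_n(lu$soil_n[i]) +
    eff$cec(lu$cec[i]) +
    p_methuselah * eff$methuselah_bonus
  out$expected_agc <- pmax(out$expected_agc, eff$floor)
  rownames(out) <- NULL
  out
}

#' @keywords internal
generate_plot_table <- function(design, stream_seed, p_methuselah = 0.05) {
  set.seed(stream_seed)
  lu <- lu_conditions()
  eff <- agc_effects()
  guilds <- herbivore_guilds()
  rows <- list()
  herb_rows <- list()
  counter <- 0
  for (rep_i in seq_len(design$replicates)) {
    for (veg in design$vegetation_types) {
      for (l in names(design$n_plots)) {
        n <- design$n_plots[[l]]
        if (n == 0) next
        cond <- lu[lu$landuse == l, ]
        for (p in seq_len(n)) {
          counter <- counter + 1
          pid <- sprintf("P%03d_%s_%s", counter, substr(veg, 1, 1), l)
          area <- if (l == "A") round(stats::runif(1, 2000, 8000)) else
            design$plot_area

          # component disturbance ratings on the 0.5 grid
          b_over <- snap_rating(stats::rnorm(2, cond$browse_over / 2,
                                             0.35 + cond$browse_over / 8))
          b_under <- snap_rating(stats::rnorm(2, cond$browse_under / 2,
                                              0.35 + cond$browse_under / 8))
          f_comp <- snap_rating(stats::rnorm(4, cond$fire / 4,
                                             0.3 + cond$fire / 12))
          w_comp <- snap_rating(stats::rnorm(4, cond$woodcut / 4,
                                             0.3 + cond$woodcut / 12))
          browse <- browsing_by_layer(b_over[1], b_over[2],
                                      b_under[1], b_under[2])
          fire <- agent_intensity(f_comp)
          woodcut <- agent_intensity(w_comp)

          # herbivore indices per species, summed to guild densities
          idx <- integer(nrow(guilds))
          wild_i <- guilds$guild == "wild_grazer"
          dom_i <- guilds$guild == "domestic_grazer"
          ob_i <- guilds$guild == "other_browser"
          herd_factor <- stats::rgamma(1, shape = 4, rate = 4)
          idx[wild_i] <- pmin(10, stats::rpois(sum(wild_i),
                                               herd_factor * cond$wild_graz /
                                                 sum(wild_i) * 1.3))
          idx[dom_i] <- pmin(10, stats::rpois(sum(dom_i),
                                              stats::rgamma(1, 4, 4) *
                                                cond$dom_graz / sum(dom_i)))
          idx[guilds$guild == "mega_browser"] <-
            pmin(10, round(browse[["overstorey"]] +
                             stats::rnorm(1, 0, 0.7)))
          idx[ob_i] <- pmin(10, stats::rpois(sum(ob_i), 1 +
                                               cond$browse_under / 4))
          idx <- pmax(0L, as.integer(idx))
          gd <- guild_density(data.frame(species = guilds$species,
                                         index = idx))
          herb_rows[[counter]] <- data.frame(plot_id = pid,
                                             species = guilds$species,
                                             index = idx,
                                             stringsAsFactors = FALSE)

          soil_n <- min(0.06, max(0.01, stats::rnorm(1, cond$soil_n, 0.004)))
          cec <- min(8, max(0.5, stats::rnorm(1, cond$cec, 0.5)))
          sand <- min(99, max(80, stats::rnorm(1, 93, 4)))
          meth <- stats::runif(1) < p_methuselah

          expected <- unname(eff$baseline[veg]) +
            eff$browsing_over(browse[["overstorey"]]) +
            eff$browsing_under(browse[["understorey"]]) +
            eff$woodcut_intensity(woodcut) +
            eff$fire_intensity(fire) +
            eff$wild_grazer(gd[["wild_grazer"]]) +
            eff$domestic_grazer(gd[["domestic_grazer"]]) +
            eff$soil_n(soil_n) +
            eff$cec(cec) +
            if (meth) eff$methuselah_bonus else 0
          target <- max(eff$floor, expected + stats::rnorm(1, 0, eff$noise_sd))

          covers <- if (l == "A") rdirichlet1(c(3, 6, 11)) else
            rdirichlet1(c(7, 9, 4))

          rows[[counter]] <- data.frame(
            plot_id = pid, vegetation_type = veg, landuse = l,
            plot_area_m2 = area,
            browsing_over = browse[["overstorey"]],
            browsing_under = browse[["understorey"]],
            fire_intensity = fire, woodcut_intensity = woodcut,
            wild_grazer = gd[["wild_grazer"]],
            domestic_grazer = gd[["domestic_grazer"]],
            mega_browser = gd[["mega_browser"]],
            other_browser = gd[["other_browser"]],
            soil_n = soil_n, cec = cec, sand_pct = sand,
            dist_river_km = exp(stats::rnorm(1,
              log(c(L = 12, M = 5, H = 2, R = 8, A = 7)[[l]]), 0.35)),
            dist_school_km = exp(stats::rnorm(1,
              log(c(L = 18, M = 20, H = 15, R = 4, A = 2)[[l]]), 0.35)),
            cover_under_tree = covers[1], cover_between_trees = covers[2],
            cover_bare = covers[3],
            expected_agc = expected, target_agc = target,
            methuselah_truth = meth,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_plot_table()
  }
  attr(out, "herbivores") <-
    if (length(herb_rows)) do.call(rbind, herb_rows) else
      data.frame(plot_id = character(), species = character(),
                 index = integer(), stringsAsFactors = FALSE)
  out
}

#' @keywords internal
empty_plot_table <- function() {
  cols <- c("plot_id", "vegetation_type", "landuse", "plot_area_m2",
            "browsing_over", "browsing_under", "fire_intensity",
            "woodcut_intensity", "wild_grazer", "domestic_grazer",
            "mega_browser", "other_browser", "soil_n", "cec", "sand_pct",
            "dist_river_km", "dist_school_km", "cover_under_tree",
            "cover_between_trees", "cover_bare", "expected_agc",
            "target_agc", "methuselah_truth")
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                       cols))
  out$plot_id <- character(0)
  out$vegetation_type <- character(0)
  out$landuse <- character(0)
  out$methuselah_truth <- logical(0)
  out
}

#' @keywords internal
#' Mean total-loss fraction of an individual given the plot's disturbance
#' scores; precision of the Beta draw is fixed at 4.
plot_loss_mean <- function(browse_over, browse_under, woodcut, fire) {
  raw <- 0.05 + 0.85 * (0.45 * browse_over / 10 + 0.15 * browse_under / 10 +
                          0.25 * woodcut / 20 + 0.15 * fire / 20)
  min(0.75, max(0.03, raw))
}

#' @keywords internal draw per-agent losses for n individuals of one plot
draw_losses <- function(n, mu_total, mix_row, dirichlet_conc = 6) {
  phi <- 4
  total <- stats::rbeta(n, mu_total * phi, (1 - mu_total) * phi)
  total <- pmin(total, 0.95)
  split <- t(vapply(seq_len(n),
                    function(i) rdirichlet1(dirichlet_conc * mix_row),
                    numeric(length(mix_row))))
  losses <- split * total
  colnames(losses) <- paste0("loss_", LOSS_AGENTS)
  losses
}

#' @keywords internal
generate_inventory <- function(plots, mix, stream_seed,
                               tree_share = c(scrub = 0.60, woodland = 0.85)) {
  set.seed(stream_seed)
  cfg <- allometry_config()
  traits <- species_pool()
  out <- vector("list", nrow(plots))
  for (r in seq_len(nrow(plots))) {
    pl <- plots[r, ]
    veg <- pl$vegetation_type
    mix_row <- unclass(mix)[pl$landuse, ]
    mu_loss <- plot_loss_mean(pl$browsing_over, pl$browsing_under,
                              pl$woodcut_intensity, pl$fire_intensity)
    target <- pl$target_agc

    # --- adult tree candidates -------------------------------------------
    n_cand <- 120
    tsp <- sample(tree_species_for(veg), n_cand, replace = TRUE)
    dbh <- exp(stats::rnorm(n_cand,
                            log(if (veg == "scrub") 12 else 18),
                            if (veg == "scrub") 0.40 else 0.50))
    dbh <- pmin(pmax(dbh, 5), 58)
    height <- (if (veg == "scrub") 1.3 else 1.6) * dbh^0.6 *
      exp(stats::rnorm(n_cand, 0, 0.12))
    height <- pmin(pmax(height, 2), 20)
    if (pl$methuselah_truth) {
      tsp[1] <- "Vachellia_erioloba"
      dbh[1] <- stats::runif(1, 62, 70)
      height[1] <- stats::runif(1, 11, 13)
    }
    swd <- traits$swd[match(tsp, traits$species)]
    cf <- traits$carbon_fraction[match(tsp, traits$species)]
    agc_tree <- agb_to_agc(tree_agb(dbh, height, swd, cfg), cf)
    contrib_tree <- agc_tree / 1000 * 10000 / pl$plot_area_m2
    loss_tree <- draw_losses(n_cand, mu_loss, mix_row)

    tree_target <- tree_share[[veg]] * target
    if (pl$methuselah_truth) {
      n_tree <- max(1, sum(cumsum(contrib_tree) <= max(tree_target,
                                                       contrib_tree[1])))
    } else {
      n_tree <- sum(cumsum(contrib_tree) <= tree_target)
    }
    tree_idx <- seq_len(n_tree)

    # --- understorey candidates (growth form and subplot area decided
    # up front so the filling loop uses the true per-ha contributions) ----
    n_uc <- 400
    ssp <- sample(shrub_species_for(veg), n_uc, replace = TRUE)
    h_u <- pmin(pmax(exp(stats::rnorm(n_uc, log(1.5), 0.35)), 0.3), 3)
    d1 <- pmin(pmax(exp(stats::rnorm(n_uc, log(1.1), 0.40)), 0.2), 5)
    d2 <- d1 * stats::runif(n_uc, 0.7, 1.0)
    cf_u <- traits$carbon_fraction[match(ssp, traits$species)]
    agc_u <- agb_to_agc(shrub_agb(d1, d2, h_u, cfg), cf_u)
    loss_u <- draw_losses(n_uc, mu_loss, mix_row)
    tot_u <- rowSums(loss_u)
    gf_under <- ifelse(tot_u > 0.3, "gulliver",
                       ifelse(stats::runif(n_uc) < 0.6, "shrub", "subadult"))
    sub_area_u <- ifelse(gf_under == "shrub", 100, 250)
    contrib_u <- agc_u / 1000 * 10000 / sub_area_u

    remaining <- target - sum(contrib_tree[tree_idx])
    cum_u <- cumsum(contrib_u)
    # stop before crossing the target; small recruits close the gap below
    n_under <- if (remaining <= 0) 0L else sum(cum_u <= remaining)
    under_idx <- seq_len(n_under)

    # --- small recruits: fine-grained gap filling ------------------------
    gap <- target - sum(contrib_tree[tree_idx]) - sum(contrib_u[under_idx])
    n_rc <- 120
    h_r <- pmin(pmax(exp(stats::rnorm(n_rc, log(0.55), 0.25)), 0.3), 1.2)
    d1_r <- pmin(pmax(exp(stats::rnorm(n_rc, log(0.35), 0.25)), 0.15), 1)
    d2_r <- d1_r * stats::runif(n_rc, 0.7, 1.0)
    rsp <- sample(shrub_species_for(veg), n_rc, replace = TRUE)
    cf_r <- traits$carbon_fraction[match(rsp, traits$species)]
    agc_r <- agb_to_agc(shrub_agb(d1_r, d2_r, h_r, cfg), cf_r)
    contrib_r <- agc_r / 1000 * 10000 / 100
    n_rec <- max(3L, if (gap > 0) sum(cumsum(contrib_r) <= gap) else 0L)
    rec_idx <- seq_len(min(n_rec, n_rc))
    loss_r <- draw_losses(length(rec_idx), mu_loss, mix_row)
    gf_r <- ifelse(rowSums(loss_r) > 0.3, "gulliver", "shrub")

    n_ind <- n_tree + n_under + length(rec_idx)
    if (n_ind == 0) next
    df <- data.frame(
      plot_id = pl$plot_id,
      species = c(tsp[tree_idx], ssp[under_idx], rsp[rec_idx]),
      growth_form = c(rep("adult_tree", n_tree), gf_under[under_idx],
                      gf_r),
      height_m = c(height[tree_idx], h_u[under_idx], h_r[rec_idx]),
      crown_d1_m = c(pmax(0.5, dbh[tree_idx] / 8), d1[under_idx],
                     d1_r[rec_idx]),
      crown_d2_m = c(pmax(0.5, dbh[tree_idx] / 9), d2[under_idx],
                     d2_r[rec_idx]),
      basal_diameter_cm = c(dbh[tree_idx] * 1.15,
                            pmax(0.5, d1[under_idx] * 1.5),
                            pmax(0.5, d1_r[rec_idx] * 1.5)),
      dbh_cm = c(dbh[tree_idx], rep(NA_real_, n_under + length(rec_idx))),
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(rbind(loss_tree[tree_idx, , drop = FALSE],
                                        loss_u[under_idx, , drop = FALSE],
                                        loss_r)))
    df$subplot_area_m2 <- c(rep(pl$plot_area_m2, n_tree),
                            sub_area_u[under_idx],
                            rep(100, length(rec_idx)))
    out[[r]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(cbind(
      data.frame(plot_id = character(), species = character(),
                 growth_form = character(), height_m = numeric(),
                 crown_d1_m = numeric(), crown_d2_m = numeric(),
                 basal_diameter_cm = numeric(), dbh_cm = numeric(),
                 stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(matrix(numeric(0), 0, 5)),
                      paste0("loss_", LOSS_AGENTS)),
      data.frame(subplot_area_m2 = numeric())
    ))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$individual_id <- sprintf("I%05d", seq_len(nrow(res)))
  res[, c("plot_id", "individual_id",
          setdiff(names(res), c("plot_id", "individual_id")))]
}

#' @keywords internal
generate_soil_cores <- function(plots, stream_seed, p_hand_auger = 0.2) {
  set.seed(stream_seed)
  dc <- depth_classes()
  profile <- c(1.6, 1.2, 1.0, 0.8, 0.65, 0.55)
  patch_mult <- c(under_tree = 1.3, between_trees = 1.0, bare = 0.75)
  lu <- lu_conditions()
  rows <- list()
  k <- 0
  first_in_stratum <- !duplicated(paste(plots$landuse,
                                        plots$vegetation_type))
  for (r in seq_len(nrow(plots))) {
    pl <- plots[r, ]
    base <- lu$soc_base[lu$landuse == pl$landuse] *
      (if (pl$vegetation_type == "woodland") 0.95 else 1.0) *
      exp(stats::rnorm(1, 0, 0.15))
    covers <- c(under_tree = pl$cover_under_tree,
                between_trees = pl$cover_between_trees,
                bare = pl$cover_bare)
    sampled <- names(covers)[covers > 0.02]
    if (!length(sampled)) sampled <- names(which.max(covers))
    for (pt in sampled) {
      # hand-auger cores stop at 50 cm; force the first plot of each
      # land-use x vegetation stratum to full depth so imputation always
      # has a neighbour
      hand <- !first_in_stratum[r] && stats::runif(1) < p_hand_auger
      max_depth <- if (hand) 50 else 100
      classes <- dc$depth_class[dc$bottom <= max_depth]
      n_cl <- length(classes)
      conc <- base * patch_mult[[pt]] * profile[seq_len(n_cl)] *
        exp(stats::rnorm(n_cl, 0, 0.08))
      topsoil <- dc$horizon[seq_len(n_cl)] == "topsoil"
      bd <- ifelse(topsoil, stats::rnorm(n_cl, 1.45, 0.05),
                   stats::rnorm(n_cl, 1.74, 0.06))
      bd <- pmin(pmax(bd, 0.9), 1.95)
      k <- k + 1
      rows[[k]] <- data.frame(
        plot_id = pl$plot_id, patch_type = pt, depth_class = classes,
        conc_g_kg = conc, bulk_density_g_cm3 = bd,
        max_depth_cm = max_depth, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(plot_id = character(), patch_type = character(),
                      depth_class = character(), conc_g_kg = numeric(),
                      bulk_density_g_cm3 = numeric(),
                      max_depth_cm = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a generated dataset as delimited text
#'
#' One UTF-8 CSV per table plus the plot-level ground truth; effect
#' functions are not serialized.
#'
#' @param ds a `savanna_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "savanna_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    plots = file.path(dir, "plots.csv"),
    inventory = file.path(dir, "inventory.csv"),
    species = file.path(dir, "species.csv"),
    soil = file.path(dir, "soil_cores.csv"),
    herbivores = file.path(dir, "herbivore_indices.csv"),
    truth = file.path(dir, "truth_plots.csv")
  )
  utils::write.csv(ds$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(ds$inventory, paths["inventory"], row.names = FALSE)
  utils::write.csv(ds$species, paths["species"], row.names = FALSE)
  utils::write.csv(ds$soil, paths["soil"], row.names = FALSE)
  utils::write.csv(ds$herbivores, paths["herbivores"], row.names = FALSE)
  utils::write.csv(ds$truth$plot, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' @export
print.savanna_dataset <- function(x, ...) {
  cat(sprintf("Synthetic savanna dataset: %d plots, %d individuals, %d soil rows\n",
              nrow(x$plots), nrow(x$inventory), nrow(x$soil)))
  invisible(x)
}
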