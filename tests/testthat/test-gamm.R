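# small simulated model frames for the GAMM contract tests

sim_frame <- function(n, seed, effect = c("none", "linear", "hump")) {
  effect <- match.arg(effect)
  set.seed(seed)
  d <- data.frame(
    browsing_under = runif(n, 0, 10),
    browsing_over = runif(n, 0, 10),
    woodcut_intensity = runif(n, 0, 20),
    fire_intensity = runif(n, 0, 20),
    wild_grazer = runif(n, 0, 30),
    domestic_grazer = runif(n, 0, 20),
    soil_n = runif(n, 0.01, 0.06),
    cec = runif(n, 1, 6),
    vegetation_type = sample(c("scrub", "woodland"), n, TRUE),
    methuselah = FALSE
  )
  mu <- switch(effect,
               none = 0,
               linear = -0.5 * d$browsing_under,
               hump = generate_unimodal_response(d$browsing_over, peak = 4,
                                                 amplitude = 4, width = 2))
  d$agc <- 5 + mu + rnorm(n, 0, 1)
  d
}

test_that("a pure-noise response yields near-zero smooth edf and deviance", {
  d <- sim_frame(300, seed = 61, effect = "none")
  fit <- fit_gamm(d, response = "agc")
  smooth_edf <- fit$edf[grepl("^s\\(", names(fit$edf)) &
                          !grepl("vegetation", names(fit$edf))]
  expect_lt(max(smooth_edf), 0.5)
  expect_lt(fit$deviance_explained, 10)
})

test_that("a programmed linear effect is recovered with the right sign", {
  d <- sim_frame(300, seed = 67, effect = "linear")
  fit <- fit_gamm(d, response = "agc")
  expect_gt(fit$edf[["s(browsing_under)"]], 0.5)
  pe <- partial_effect(fit, "browsing_under")
  slope <- coef(lm(effect ~ x, data = pe))[["x"]]
  expect_equal(slope, -0.5, tolerance = 0.15)
  # near-linear: the smooth does not spend many degrees of freedom
  expect_lt(fit$edf[["s(browsing_under)"]], 2.5)
})

test_that("a programmed hump is recovered at its peak location", {
  d <- sim_frame(400, seed = 71, effect = "hump")
  fit <- fit_gamm(d, response = "agc")
  expect_equal(peak_location(fit, "browsing_over"), 4, tolerance = 0.25)
  # partial effects are centred: mean over the data is ~0
  pe <- partial_effect(fit, "browsing_over")
  expect_lt(abs(mean(predict(fit$model, type = "terms")[, "s(browsing_over)"])),
            1e-6)
})

test_that("the fit surfaces its contract violations", {
  d <- sim_frame(30, seed = 73)
  d$agc[1] <- NA
  expect_error(fit_gamm(d, response = "agc"), "missing values")
  d2 <- sim_frame(100, seed = 74)
  d2$dup <- d2$browsing_over + rnorm(100, 0, 0.01)
  expect_warning(fit_gamm(d2, response = "agc",
                          predictors = c("browsing_over", "dup",
                                         "browsing_under"),
                          interactions = NULL),
                 "Spearman")
})

test_that("savanna_gamm methods expose the fitted model", {
  d <- sim_frame(150, seed = 79, effect = "linear")
  fit <- fit_gamm(d, response = "agc", interactions = NULL)
  expect_s3_class(fit, "savanna_gamm")
  expect_output(print(fit), "deviance explained")
  expect_length(residuals(fit), 150)
  expect_equal(unname(predict(fit)[1]),
               unname(predict(fit$model)[1]))
})

test_that("deviance partition matches an independent permutation-enumeration oracle", {
  set.seed(83)
  n <- 150
  d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  d$y <- 2 * d$x1 + sin(2 * pi * d$x2) + rnorm(n, 0, 0.5)
  preds <- c("x1", "x2", "x3")
  got <- deviance_partition(d, "y", preds, k = 5)

  # oracle: average marginal contribution over the 3! orderings, with
  # subset deviances computed by direct mgcv calls
  dev_of <- function(vars) {
    if (!length(vars)) return(0)
    fml <- as.formula(paste("y ~",
                            paste(sprintf("s(%s, bs = 'tp', k = 5)", vars),
                                  collapse = " + ")))
    m <- mgcv::gam(fml, data = d, method = "REML", select = TRUE)
    (m$null.deviance - m$deviance) / m$null.deviance
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  oracle <- setNames(numeric(3), preds)
  for (perm in perms) {
    for (pos in seq_along(perm)) {
      before <- preds[perm[seq_len(pos - 1)]]
      i <- preds[perm[pos]]
      oracle[i] <- oracle[i] + (dev_of(c(before, i)) - dev_of(before)) / 6
    }
  }
  expect_equal(got$share, unname(100 * oracle), tolerance = 1e-6)
  # shares sum to the full model's explained deviance within 1 point
  expect_lt(abs(sum(got$share) - attr(got, "total")), 1)
})

test_that("a single-predictor partition returns the total explained deviance", {
  set.seed(89)
  d <- data.frame(x1 = runif(100))
  d$y <- 3 * d$x1 + rnorm(100, 0, 0.3)
  got <- deviance_partition(d, "y", "x1", k = 5)
  expect_equal(got$share, attr(got, "total"))
  expect_gt(got$share, 50)
})

test_that("orthogonal equally informative predictors share the deviance evenly", {
  # shares fluctuate with the realized sample; average a few replicates
  shares <- sapply(c(97, 98, 99), function(s) {
    set.seed(s)
    n <- 400
    d <- data.frame(x1 = runif(n), x2 = runif(n))
    d$y <- d$x1 + d$x2 + rnorm(n, 0, 0.3)
    deviance_partition(d, "y", c("x1", "x2"), k = 5)$share
  })
  expect_lt(abs(mean(shares[1, ]) - mean(shares[2, ])), 8)
})
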