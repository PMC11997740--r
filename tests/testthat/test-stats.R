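test_that("the Spearman filter removes collinear predictors greedily", {
  set.seed(31)
  n <- 200
  x <- rnorm(n)
  df <- data.frame(a = x, b = x + rnorm(n, 0, 1e-8), c = rnorm(n))
  got <- spearman_filter(df)
  expect_length(got$dropped, 1)
  expect_true(got$dropped %in% c("a", "b"))
  expect_true("c" %in% got$retained)
  # independent noise columns are all retained
  noise <- as.data.frame(matrix(rnorm(200 * 5), 200))
  expect_length(spearman_filter(noise)$dropped, 0)
  expect_error(spearman_filter(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("the filtered set passes an exhaustive pairwise check", {
  set.seed(37)
  n <- 120
  z <- rnorm(n)
  df <- data.frame(a = z + rnorm(n, 0, 0.1), b = z + rnorm(n, 0, 0.1),
                   c = z + rnorm(n, 0, 2), d = rnorm(n), e = -z + rnorm(n, 0, 0.2))
  got <- spearman_filter(df, threshold = 0.75)
  rho <- cor(df[got$retained], method = "spearman")
  diag(rho) <- 0
  expect_lt(max(abs(rho)), 0.75)
})

test_that("PCA variance shares equal the correlation-matrix eigenvalues", {
  set.seed(41)
  x <- matrix(rnorm(300), 100, 3)
  x[, 2] <- x[, 1] * 0.5 + x[, 2]
  got <- pca_overview(x)
  ev <- eigen(cor(x))$values
  expect_equal(got$variance_share, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(got$variance_share), 1)
  # two perfectly correlated variables load entirely on PC1
  y <- cbind(a = 1:50, b = (1:50) * 2)
  expect_equal(pca_overview(y)$variance_share[1], 1)
  expect_error(pca_overview(x[1:2, ]), "three rows")
})

test_that("Bartlett's statistic matches the textbook formula on a hand-computed triple", {
  g1 <- c(2.1, 2.5, 3.0, 2.8)
  g2 <- c(1.0, 4.0, 2.0, 6.0, 3.0)
  g3 <- c(5.0, 5.5, 4.5)
  values <- c(g1, g2, g3)
  groups <- rep(c("a", "b", "c"), c(4, 5, 3))
  got <- bartlett_variance_test(values, groups)
  # textbook formula computed independently
  ns <- c(4, 5, 3); k <- 3; N <- sum(ns)
  vars <- c(var(g1), var(g2), var(g3))
  sp2 <- sum((ns - 1) * vars) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ns - 1) * log(vars))) /
    (1 + (sum(1 / (ns - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(got$statistic, stat, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p.value, pchisq(stat, 2, lower.tail = FALSE))
  expect_error(bartlett_variance_test(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "zero-variance")
})

test_that("Games-Howell reduces to Welch's t under two groups", {
  set.seed(43)
  g1 <- rnorm(12, 0, 1)
  g2 <- rnorm(20, 0.5, 3)
  got <- games_howell(c(g1, g2), rep(c("a", "b"), c(12, 20)))
  wt <- t.test(g2, g1, var.equal = FALSE)
  expect_equal(got$diff, unname(diff(rev(wt$estimate))), tolerance = 1e-10)
  expect_equal(got$df, unname(wt$parameter), tolerance = 1e-10)
  # with k = 2 the studentized-range p equals the two-sided Welch p
  expect_equal(got$p.adj, wt$p.value, tolerance = 1e-8)
})

test_that("Games-Howell handles identical groups and degenerate inputs", {
  g <- c(1, 2, 3, 4)
  got <- games_howell(c(g, g), rep(c("a", "b"), each = 4))
  expect_equal(got$diff, 0)
  expect_equal(got$p.adj, 1)
  expect_error(games_howell(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
  # five groups give all ten ordered pairs
  set.seed(44)
  v <- rnorm(50)
  g5 <- rep(letters[1:5], each = 10)
  expect_equal(nrow(games_howell(v, g5)), 10)
})

test_that("one-way ANOVA matches a brute-force sums-of-squares decomposition", {
  set.seed(47)
  values <- c(rnorm(10, 0), rnorm(12, 1), rnorm(8, 3))
  groups <- rep(c("a", "b", "c"), c(10, 12, 8))
  got <- anova_tukey(values, groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((values - means[groups])^2)
  f <- (ss_between / 2) / (ss_within / (length(values) - 3))
  expect_equal(got$anova$statistic, f, tolerance = 1e-10)
})

test_that("the compact letter display separates shifted groups and pools identical ones", {
  set.seed(53)
  same <- rnorm(30)
  got_same <- anova_tukey(rep(same, 2), rep(c("a", "b"), each = 30))
  expect_equal(unname(got_same$letters["a"]), unname(got_same$letters["b"]))
  shifted <- c(rnorm(15, 0, 1), rnorm(15, 0, 1), rnorm(15, 10, 1))
  got <- anova_tukey(shifted, rep(c("a", "b", "c"), each = 15))
  expect_equal(unname(got$letters["a"]), unname(got$letters["b"]))
  expect_false(unname(got$letters["c"]) == unname(got$letters["a"]))
  expect_error(anova_tukey(rnorm(5), rep("a", 5)), "two groups")
})

test_that("percent change and pooled means reproduce the printed worked values", {
  expect_equal(percent_change(9, 6.3), -30)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 20), 100)
  expect_error(percent_change(0, 5), "positive")
  expect_equal(pooled_mean(c(7.1, 10.9), c(10, 10)), 9)
  expect_equal(pooled_mean(c(2, 4), c(1, 3)), 3.5)
})

test_that("the belowground:aboveground ratio is scale invariant", {
  comp <- data.frame(agc = c(10, 0), bgc = c(10, 5), soc = c(30, 5))
  got <- below_above_ratio(comp)
  expect_equal(got[1], 4)
  expect_true(is.na(got[2]))
  comp2 <- data.frame(agc = 20, bgc = 20, soc = 60)
  expect_equal(below_above_ratio(comp2), 4)
})
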