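#' Greedy Spearman collinearity filter
#'
#' Repeatedly finds the worst-correlated predictor pair (Spearman rank
#' correlation) and drops the member with the higher mean absolute
#' correlation against all remaining candidates, until every pairwise
#' |rho| is below the threshold.
#'
#' @param x data.frame or matrix of numeric candidate predictors (complete
#'   cases, no constant columns).
#' @param threshold pairwise |rho| cut-off (default 0.75; strict).
#' @return List with `retained` (column names), `dropped` (in removal
#'   order) and `cor` (the Spearman matrix of the retained set).
#' @export
spearman_filter <- function(x, threshold = 0.75) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least two candidate predictors")
  if (anyNA(x)) stop("complete cases required")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant columns cannot be rank-correlated: ",
         paste(names(x)[sds == 0], collapse = ", "))
  }
  keep <- names(x)
  dropped <- character()
  repeat {
    rho <- stats::cor(x[keep], method = "spearman")
    diag(rho) <- 0
    worst <- max(abs(rho))
    if (worst < threshold || length(keep) == 1) break
    idx <- which(abs(rho) == worst, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    mean_abs <- rowMeans(abs(rho))[pair]
    drop <- pair[which.max(mean_abs)]
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, dropped = dropped,
       cor = stats::cor(x[keep], method = "spearman"))
}

#' Standardized principal component overview
#'
#' PCA on unit-variance, zero-centred predictors, used descriptively to
#' inspect how environmental drivers covary. Variance shares are the
#' correlation-matrix eigenvalues over their sum.
#'
#' @param x numeric data.frame/matrix, complete cases, at least 3 rows.
#' @return List with `variance_share` (sums to 1), `loadings` and `scores`.
#' @export
pca_overview <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least three rows for a PCA overview")
  if (anyNA(x)) stop("complete cases required")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  shares <- p$sdev^2 / sum(p$sdev^2)
  list(variance_share = shares, loadings = p$rotation, scores = p$x)
}

#' Bartlett's test of variance homogeneity
#'
#' Standard Bartlett statistic against chi-square(k-1), with a guard
#' against degenerate zero-variance groups.
#'
#' @param values numeric response vector.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
bartlett_variance_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  vars <- tapply(values, groups, stats::var)
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(vars == 0)) stop("zero-variance group: Bartlett statistic undefined")
  bt <- stats::bartlett.test(values, groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p.value = bt$p.value)
}

#' Games-Howell post hoc comparisons
#'
#' All pairwise group comparisons for unequal sample sizes and unequal
#' variances. For groups i, j: standard error
#' \eqn{\sqrt{s_i^2/n_i + s_j^2/n_j}}, degrees of freedom by
#' Welch-Satterthwaite, and the adjusted p-value from the studentized-range
#' distribution with k groups at that df
#' (\eqn{p = P(q_{k,df} > |\bar x_i - \bar x_j| \sqrt 2 / SE)}).
#'
#' @param values numeric response vector.
#' @param groups grouping factor (each group n >= 2).
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean difference group2 - group1), `se`, `df`, `q` (studentized-range
#'   statistic) and `p.adj`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("each group needs n >= 2")
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  vn <- vars / ns
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]
  j <- pairs[2, ]
  diff <- means[j] - means[i]
  se <- sqrt(vn[i] + vn[j])
  df <- (vn[i] + vn[j])^2 / (vn[i]^2 / (ns[i] - 1) + vn[j]^2 / (ns[j] - 1))
  q <- abs(diff) / se * sqrt(2)
  p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  data.frame(group1 = levels(groups)[i], group2 = levels(groups)[j],
             diff = as.numeric(diff), se = as.numeric(se),
             df = as.numeric(df), q = as.numeric(q),
             p.adj = pmin(1, as.numeric(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical equal-variance group comparison used for the damage-share
#' panels: one-way ANOVA, Tukey honest significant differences, and a
#' compact letter display in which groups sharing a letter do not differ
#' at `alpha`.
#'
#' @param values numeric response vector.
#' @param groups grouping factor with >= 2 levels.
#' @param alpha significance level for the letter display.
#' @return List with `anova` (F statistic, df, p), `tukey` (pairwise
#'   table) and `letters` (named character vector per group).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  fit <- stats::aov(values ~ groups)
  at <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$groups
  letters <- compact_letters(rownames(tk), tk[, "p adj"],
                             levels(groups), alpha)
  list(anova = list(statistic = at[["F value"]][1],
                    df = at[["Df"]], p.value = at[["Pr(>F)"]][1]),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p.adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE),
       letters = letters)
}

#' @keywords internal
#' Insert-and-absorb compact letter display from pairwise p-values.
compact_letters <- function(pair_names, p_adj, groups, alpha = 0.05) {
  sig <- p_adj < alpha
  parts <- strsplit(pair_names, "-", fixed = TRUE)
  # start with one column (letter) containing all groups; split on each
  # significant pair that shares a column
  cols <- list(groups)
  for (idx in which(sig)) {
    a <- parts[[idx]][1]
    b <- parts[[idx]][2]
    for (ci in seq_along(cols)) {
      if (a %in% cols[[ci]] && b %in% cols[[ci]]) {
        cols[[length(cols) + 1]] <- setdiff(cols[[ci]], a)
        cols[[ci]] <- setdiff(cols[[ci]], b)
      }
    }
    # absorb duplicated/contained columns
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) {
      for (cj in seq_along(cols)) {
        if (ci != cj && keep[ci] && keep[cj] &&
            all(cols[[ci]] %in% cols[[cj]])) {
          keep[ci] <- FALSE
        }
      }
    }
    cols <- cols[keep]
  }
  out <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(cc) g %in% cc, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

#' Percent change between a reference and an endpoint mean
#'
#' `100 * (end - ref) / ref`; negative values are losses.
#'
#' @param ref_mean reference mean (t C/ha), `> 0`.
#' @param end_mean endpoint mean (t C/ha).
#' @return Percent change.
#' @examples
#' percent_change(9, 6.3) # -30
#' @export
percent_change <- function(ref_mean, end_mean) {
  if (any(ref_mean <= 0)) stop("reference mean must be positive")
  100 * (end_mean - ref_mean) / ref_mean
}

#' Pooled mean across strata
#'
#' Plot-count weighted mean of per-stratum means, e.g. pooling the two
#' vegetation types' land-use means into one land-use mean.
#'
#' @param means per-stratum means.
#' @param n per-stratum plot counts (defaults to equal weights).
#' @return Pooled mean.
#' @export
pooled_mean <- function(means, n = rep(1, length(means))) {
  if (any(n <= 0)) stop("counts must be positive")
  sum(means * n) / sum(n)
}

#' Belowground-to-aboveground carbon ratio
#'
#' `(BGC + SOC) / AGC` per plot; plots without aboveground carbon get `NA`.
#'
#' @param compartments a [carbon_compartments()] table (or any data.frame
#'   with `agc`, `bgc`, `soc` columns).
#' @return Numeric vector of ratios.
#' @export
below_above_ratio <- function(compartments) {
  ifelse(compartments$agc > 0,
         (compartments$bgc + compartments$soc) / compartments$agc,
         NA_real_)
}
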