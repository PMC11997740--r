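#' Fit the disturbance-carbon generalized additive mixed model
#'
#' Fits a Gaussian identity-link GAMM of a per-plot carbon stock on the
#' plot-level drivers: thin-plate regression spline smooths for the
#' continuous predictors, two tensor-product interaction smooths
#' (fire x overstorey browsing, fire x understorey browsing) that separate
#' joint effects from the marginal smooths, vegetation type both as a
#' parametric fixed effect and as a random intercept, and methuselah
#' presence as a binary parametric term. Smoothness is selected by REML
#' with an additional null-space penalty on every smooth (the
#' double-penalty approach), so uninformative predictors can be shrunk to
#' effectively zero degrees of freedom and drop out of the model.
#'
#' The engine is \pkg{mgcv}; the fitted object keeps the data and term
#' structure so partial effects, peak locations and deviance partitions can
#' be computed downstream.
#'
#' @param data data.frame with the response column, the smooth predictors,
#'   `vegetation_type` (factor/character, 2 levels) and `methuselah`
#'   (logical).
#' @param response name of the response column (e.g. `"agc"` or
#'   `"c_total"`, t C/ha).
#' @param predictors character vector of smooth predictor columns. The
#'   default is the eight-driver set: understorey and overstorey browsing,
#'   woodcutting and fire intensity, wild and domestic grazer density, soil
#'   nitrogen and CEC.
#' @param interactions list of length-2 character vectors naming tensor
#'   interaction pairs; `NULL` for none.
#' @param k basis dimension of the marginal smooths.
#' @param k_ti marginal basis dimension of the tensor interactions.
#' @param select enable the double penalty (null-space shrinkage).
#' @param gamma smoothness-selection inflation factor passed to
#'   [mgcv::gam()]. The default `max(1.5, log(n)/2)` gives BIC-like
#'   selection, which makes the double penalty exclude uninformative
#'   predictors consistently rather than leaving them small spurious
#'   wiggles.
#' @param spearman_threshold the collinearity contract on the predictor
#'   set; a warning is issued when any pairwise Spearman |rho| reaches it.
#' @return Object of class `savanna_gamm`.
#' @export
fit_gamm <- function(data, response = "agc",
                     predictors = c("browsing_under", "browsing_over",
                                    "woodcut_intensity", "fire_intensity",
                                    "wild_grazer", "domestic_grazer",
                                    "soil_n", "cec"),
                     interactions = list(
                       c("fire_intensity", "browsing_over"),
                       c("fire_intensity", "browsing_under")),
                     k = 6, k_ti = 4, select = TRUE,
                     gamma = max(1.5, log(nrow(data)) / 2),
                     spearman_threshold = 0.75) {
  stopifnot(is.data.frame(data), response %in% names(data))
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred)) {
    stop("predictors missing from data: ", paste(missing_pred, collapse = ", "))
  }
  if (anyNA(data[, c(response, predictors)])) stop("missing values in model frame")
  if (nrow(data) < length(predictors)) stop("fewer rows than predictors")
  rho <- stats::cor(data[predictors], method = "spearman")
  diag(rho) <- 0
  if (max(abs(rho)) >= spearman_threshold) {
    warning(sprintf("predictor pair exceeds Spearman |rho| < %.2f: %s",
                    spearman_threshold,
                    paste(rownames(which(abs(rho) == max(abs(rho)),
                                         arr.ind = TRUE))[1], collapse = " ")))
  }
  data$vegetation_type <- factor(data$vegetation_type)
  data$methuselah <- as.logical(data$methuselah)

  terms <- c("vegetation_type", "methuselah",
             sprintf("s(%s, bs = 'tp', k = %d)", predictors, k))
  if (!is.null(interactions)) {
    terms <- c(terms, vapply(interactions, function(pr) {
      sprintf("ti(%s, %s, k = c(%d, %d))", pr[1], pr[2], k_ti, k_ti)
    }, character(1)))
  }
  terms <- c(terms, "s(vegetation_type, bs = 're')")
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  model <- mgcv::gam(fml, data = data, family = stats::gaussian(),
                     method = "REML", select = select, gamma = gamma)
  if (!model$converged) {
    stop("GAMM fit did not converge; inspect predictors and basis dimensions")
  }
  sm <- summary(model)
  structure(list(
    model = model,
    response = response,
    predictors = predictors,
    interactions = interactions,
    data = data,
    edf = stats::setNames(sm$s.table[, "edf"], rownames(sm$s.table)),
    s_table = sm$s.table,
    p_table = sm$p.table,
    deviance_explained = 100 * sm$dev.expl,
    r_squared = sm$r.sq
  ), class = "savanna_gamm")
}

#' @export
print.savanna_gamm <- function(x, ...) {
  cat("Savanna carbon GAMM (thin-plate smooths, double penalty, REML)\n")
  cat(sprintf("  response: %s   n = %d plots\n", x$response, nrow(x$data)))
  cat(sprintf("  deviance explained: %.1f%%   adjusted R2: %.3f\n",
              x$deviance_explained, x$r_squared))
  cat("  smooth edf:\n")
  for (nm in names(x$edf)) cat(sprintf("    %-38s %6.2f\n", nm, x$edf[nm]))
  invisible(x)
}

#' @export
summary.savanna_gamm <- function(object, ...) summary(object$model, ...)

#' @export
predict.savanna_gamm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  stats::predict(object$model, newdata = newdata, ...)
}

#' @export
residuals.savanna_gamm <- function(object, ...) stats::residuals(object$model, ...)

#' @export
coef.savanna_gamm <- function(object, ...) stats::coef(object$model)

#' Centered partial effect of one smooth predictor
#'
#' Evaluates the fitted marginal smooth of `predictor` on a grid spanning
#' its observed range, holding everything else fixed. The curve is the
#' model-centred contribution (zero mean over the data), i.e. deviations
#' around the model mean.
#'
#' @param object a `savanna_gamm`.
#' @param predictor one of the fitted smooth predictors.
#' @param n grid size.
#' @return data.frame with columns `x` and `effect`.
#' @export
partial_effect <- function(object, predictor, n = 200) {
  stopifnot(inherits(object, "savanna_gamm"),
            predictor %in% object$predictors)
  rng <- range(object$data[[predictor]])
  grid <- object$data[rep(1, n), , drop = FALSE]
  for (p in object$predictors) grid[[p]] <- stats::median(object$data[[p]])
  grid[[predictor]] <- seq(rng[1], rng[2], length.out = n)
  term <- sprintf("s(%s)", predictor)
  tm <- stats::predict(object$model, newdata = grid, type = "terms",
                       terms = term)
  data.frame(x = grid[[predictor]], effect = as.numeric(tm[, 1]))
}

#' Location of a partial-effect maximum
#'
#' Argmax of the centred partial effect over the observed predictor range,
#' used to locate unimodal (intermediate-disturbance) optima.
#'
#' @inheritParams partial_effect
#' @return The predictor value at which the partial effect peaks.
#' @export
peak_location <- function(object, predictor, n = 400) {
  pe <- partial_effect(object, predictor, n = n)
  pe$x[which.max(pe$effect)]
}

#' @export
plot.savanna_gamm <- function(x, predictors = x$predictors, ...) {
  np <- length(predictors)
  nc <- ceiling(sqrt(np))
  nr <- ceiling(np / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in predictors) {
    pe <- partial_effect(x, p)
    graphics::plot(pe$x, pe$effect, type = "l", xlab = p,
                   ylab = sprintf("partial effect on %s", x$response), ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Hierarchical partitioning of explained deviance
#'
#' Attributes the model's total explained deviance to individual smooth
#' predictors by averaging each predictor's marginal contribution over all
#' orderings of the predictor set (exhaustive over the 2^p subset lattice
#' for p <= `max_exhaustive`; random orderings beyond that). Negative
#' average contributions are floored at zero with a warning. Shares are in
#' percent and sum to the full model's explained deviance (up to the
#' flooring).
#'
#' @param data model frame.
#' @param response response column name.
#' @param predictors smooth predictors to partition over.
#' @param base optional character vector of terms (formula fragments)
#'   included in every submodel, e.g. `"vegetation_type"`.
#' @param k basis dimension for the subset refits.
#' @param select double penalty in the refits.
#' @param max_exhaustive largest p for exhaustive subset enumeration.
#' @param n_orderings number of sampled orderings when p is larger.
#' @return data.frame with `predictor`, `share` (% deviance explained) and
#'   attribute `total` (% deviance explained of the full model relative to
#'   the base model).
#' @export
deviance_partition <- function(data, response, predictors, base = NULL,
                               k = 6, select = TRUE, max_exhaustive = 10,
                               n_orderings = 200) {
  p <- length(predictors)
  stopifnot(p >= 1)
  cache <- new.env(parent = emptyenv())
  dev_expl <- function(subset_idx) {
    key <- paste0("s", paste(sort(subset_idx), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    rhs <- c(base,
             sprintf("s(%s, bs = 'tp', k = %d)", predictors[subset_idx], k))
    if (!length(rhs)) rhs <- "1"
    fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
    m <- mgcv::gam(fml, data = data, family = stats::gaussian(),
                   method = "REML", select = select)
    d <- (m$null.deviance - m$deviance) / m$null.deviance
    cache[[key]] <- d
    d
  }
  shares <- stats::setNames(numeric(p), predictors)
  if (p <= max_exhaustive) {
    others <- function(i) setdiff(seq_len(p), i)
    for (i in seq_len(p)) {
      contrib <- 0
      rest <- others(i)
      n_rest <- length(rest)
      for (mask in 0:(2^n_rest - 1)) {
        s_idx <- rest[bitwAnd(mask, 2^(seq_len(n_rest) - 1)) > 0]
        s <- length(s_idx)
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        contrib <- contrib + w * (dev_expl(c(s_idx, i)) - dev_expl(s_idx))
      }
      shares[i] <- contrib
    }
  } else {
    for (ord in seq_len(n_orderings)) {
      perm <- sample.int(p)
      for (pos in seq_len(p)) {
        before <- perm[seq_len(pos - 1)]
        i <- perm[pos]
        shares[i] <- shares[i] +
          (dev_expl(c(before, i)) - dev_expl(before)) / n_orderings
      }
    }
  }
  if (any(shares < 0)) {
    warning("negative average contributions floored at 0")
    shares[shares < 0] <- 0
  }
  total <- dev_expl(seq_len(p)) - dev_expl(integer(0))
  out <- data.frame(predictor = predictors, share = 100 * as.numeric(shares),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- 100 * total
  out
}
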