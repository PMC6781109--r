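# The statistical layer: group comparisons, rank correlations, centred and
# scaled ANCOVA with Type II sums of squares, all-subsets BIC model
# averaging, vif screening, greedy log-transform selection, and
# principal-component regression.

#' Two-sided Mann-Whitney U test
#'
#' Exact distribution for small untied samples, tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with \code{U} (statistic for \code{x}) and two-sided
#'   \code{p}.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted P values, monotone and capped at 1.
#'
#' @param pvalues Raw P values in [0,1].
#' @return Adjusted P values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("P values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Spearman rank-order correlation test
#'
#' Pearson correlation of mid-ranks with the t-distribution approximation
#' for the P value.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return List with \code{rho} and \code{p}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need equal lengths >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Centre and scale model variables
#'
#' Every listed column is centred to mean 0 and scaled to sample sd 1 --
#' binary indicators identically to continuous variables.
#'
#' @param data Data.frame.
#' @param columns Columns to standardize (default: all numeric columns).
#' @return \code{data} with the columns standardized.
#' @export
standardize <- function(data, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  for (cl in columns) {
    v <- data[[cl]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cl)
    data[[cl]] <- (v - mean(v)) / s
  }
  data
}

#' Greedy log-transform selection
#'
#' Walks the candidate predictors once, in their declared order; each is
#' log-transformed iff doing so increases the R-squared of the full additive
#' model (other predictors at their current state). Variables with
#' non-positive values fall back to log(x + 1), which is recorded. Binary
#' (two-valued) predictors and protected variables are never transformed;
#' when the response is the stochastic expression F*, the mean expression
#' level is automatically protected to avoid re-introducing a mean
#' correlation through the transform.
#'
#' @param data Data.frame holding response and predictors (untransformed).
#' @param response Response column name.
#' @param predictors Candidate predictor column names, in search order.
#' @param protect Predictors never to transform.
#' @param response_is_fstar Set when the response is F*.
#' @param mean_expression Column name of the mean expression level.
#' @return List: \code{transforms} (named vector over predictors with values
#'   "identity", "log" or "log1p") and \code{data} with transforms applied.
#' @export
choose_transforms <- function(data, response, predictors,
                              protect = character(),
                              response_is_fstar = FALSE,
                              mean_expression = "mu") {
  if (response %in% predictors) stop("response cannot be a predictor")
  if (response_is_fstar) protect <- union(protect, mean_expression)
  transforms <- setNames(rep("identity", length(predictors)), predictors)
  cur <- data
  r2 <- function(d) {
    f <- stats::reformulate(predictors, response)
    summary(stats::lm(f, data = d))$r.squared
  }
  base_r2 <- r2(cur)
  for (v in predictors) {
    if (v %in% protect) next
    vals <- cur[[v]]
    if (length(unique(vals)) <= 2) next
    if (min(vals) <= -1) next  # no admissible log transform
    kind <- if (all(vals > 0)) "log" else "log1p"
    trial <- cur
    trial[[v]] <- if (kind == "log") log(vals) else log1p(vals)
    trial_r2 <- r2(trial)
    if (trial_r2 > base_r2) {
      transforms[v] <- kind
      cur <- trial
      base_r2 <- trial_r2
    }
  }
  list(transforms = transforms, data = cur)
}

#' Variance inflation factors
#'
#' vif_j = 1 / (1 - R2_j) from regressing predictor j on the remaining
#' predictors. Callers enforcing the collinearity rule should drop
#' predictors with sqrt(vif) >= 2 (vif >= 4).
#'
#' @param design Numeric matrix or data.frame of predictors (>= 2 columns),
#'   full column rank.
#' @return Named vector of vifs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("need >= 2 predictors")
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("rank-deficient design")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}

# BIC convention used throughout: n*log(RSS/n) + (p+1)*log(n) with p the
# number of predictors (intercept included in the count, error variance
# not). Differences between models -- the only quantity used -- agree with
# stats::BIC at fixed n.
bic_from_rss <- function(rss, n, n_pred) {
  n * log(rss / n) + (n_pred + 1) * log(n)
}

#' Fit a (centred/scaled) ANCOVA model
#'
#' Ordinary least squares with per-term Type II sums of squares and F tests,
#' R-squared, BIC and vifs.
#'
#' @param data Data.frame with response and predictors (already standardized
#'   by the caller when emulating the published procedure).
#' @param response Response column name.
#' @param predictors Predictor column names.
#' @return A \code{model_fit}: coefficient table, per-term ANOVA table,
#'   \code{r2}, \code{bic}, \code{vif}, and the underlying \code{lm}.
#' @export
fit_ancova <- function(data, response, predictors) {
  n <- nrow(data)
  if (n <= length(predictors) + 1) stop("need n > p + 1")
  f <- stats::reformulate(predictors, response)
  fit <- stats::lm(f, data = data)
  if (any(is.na(stats::coef(fit)))) stop("singular design")
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  # Type II SS for an additive model of numeric terms: the drop-one increase
  # in residual sum of squares (robust to an exactly saturated fit)
  X <- stats::model.matrix(fit)
  y <- data[[response]]
  df_res <- nrow(X) - ncol(X)
  anova_tab <- do.call(rbind, lapply(predictors, function(v) {
    red <- stats::lm.fit(X[, colnames(X) != v, drop = FALSE], y)
    ss <- sum(red$residuals^2) - rss
    fv <- if (rss <= 0) Inf else (ss / 1) / (rss / df_res)
    data.frame(term = v, sum_sq = ss, f_value = fv,
               p_value = stats::pf(fv, 1, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  vifs <- if (length(predictors) >= 2) {
    vif(stats::model.matrix(fit)[, -1, drop = FALSE])
  } else setNames(1, predictors)
  structure(list(response = response, predictors = predictors,
                 coefficients = stats::coef(fit),
                 coef_p = sm$coefficients[, "Pr(>|t|)"],
                 anova = anova_tab, r2 = sm$r.squared,
                 bic = bic_from_rss(rss, n, length(predictors)),
                 vif = vifs, lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit:", x$response, "~", paste(x$predictors, collapse = " + "),
      "\n  R2 =", signif(x$r2, 4), " BIC =", signif(x$bic, 6), "\n")
  print(x$anova)
  invisible(x)
}

#' All-subsets BIC model averaging
#'
#' Fits every subset of the candidate predictors (always including the
#' intercept and any \code{always_keep} predictors), weights models by
#' exp(-0.5 * deltaBIC), and reports full-average coefficients (a predictor
#' absent from a model contributes 0), per-predictor relative importance
#' (sum of weights of models containing it) and the minimum-BIC best model.
#'
#' @param data Data.frame (standardized by the caller).
#' @param response Response column name.
#' @param predictors Candidate predictors (at most 20).
#' @param always_keep Predictors forced into every model.
#' @return An \code{averaged_model}: \code{coefficients}, \code{importance},
#'   \code{best} (predictor names), \code{best_bic}, \code{weights_total}.
#' @export
bic_model_average <- function(data, response, predictors,
                              always_keep = character()) {
  p <- length(predictors)
  if (p > 20) stop("too many predictors for all-subsets enumeration")
  stopifnot(all(always_keep %in% predictors))
  y <- data[[response]]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  n <- length(y)
  G <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  free <- setdiff(predictors, always_keep)
  q <- length(free)
  keep_idx <- match(always_keep, predictors) + 1L
  n_models <- 2^q
  bics <- numeric(n_models)
  coefs <- vector("list", n_models)
  subsets <- vector("list", n_models)
  for (m in seq_len(n_models) - 1L) {
    in_free <- as.logical(bitwAnd(m, 2^(seq_len(q) - 1L)))
    idx <- sort(c(1L, keep_idx, match(free[in_free], predictors) + 1L))
    b <- solve(G[idx, idx, drop = FALSE], Xty[idx])
    rss <- yty - sum(b * Xty[idx])
    rss <- max(rss, 1e-12)
    bics[m + 1] <- bic_from_rss(rss, n, length(idx) - 1L)
    coefs[[m + 1]] <- setNames(as.vector(b), colnames(X)[idx])
    subsets[[m + 1]] <- colnames(X)[idx][-1]
  }
  w <- exp(-0.5 * (bics - min(bics)))
  w <- w / sum(w)
  avg <- setNames(numeric(p + 1), colnames(X))
  imp <- setNames(numeric(p), predictors)
  for (m in seq_len(n_models)) {
    avg[names(coefs[[m]])] <- avg[names(coefs[[m]])] + w[m] * coefs[[m]]
    imp[subsets[[m]]] <- imp[subsets[[m]]] + w[m]
  }
  best <- which.min(bics)
  structure(list(coefficients = avg, importance = imp,
                 best = subsets[[best]], best_bic = bics[best],
                 weights = w, n_models = n_models),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("averaged_model over", x$n_models, "models\n  best (BIC",
      signif(x$best_bic, 6), "):",
      if (length(x$best)) paste(x$best, collapse = " + ") else "(intercept only)",
      "\n  importance:\n")
  print(round(sort(x$importance, decreasing = TRUE), 3))
  invisible(x)
}

#' Principal-component regression on the gbM term
#'
#' Replaces the (standardized) non-gbM features by their principal
#' components -- orthogonal by construction, removing multicollinearity --
#' and regresses the response on gbM plus all component scores.
#'
#' @param features Standardized numeric matrix/data.frame of non-gbM
#'   features.
#' @param gbm 0/1 gbM indicator.
#' @param response Numeric response.
#' @return List: \code{gbm_coef}, \code{gbm_p}, \code{n_components},
#'   \code{lm}.
#' @export
pcr_fit <- function(features, gbm, response) {
  X <- as.matrix(features)
  if (any(apply(X, 2, sd) == 0)) stop("zero-variance feature")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  d <- data.frame(.y = response, gbM = gbm, pc$x)
  fit <- stats::lm(.y ~ ., data = d)
  sm <- summary(fit)$coefficients
  list(gbm_coef = sm["gbM", "Estimate"], gbm_p = sm["gbM", "Pr(>|t|)"],
       n_components = ncol(pc$x), lm = fit)
}

#' Which genomic features predict gbM?
#'
#' Ordinary least-squares regression of the 0/1 gbM indicator on the
#' candidate features: predictors violating sqrt(vif) < 2 are dropped first
#' (worst offender iteratively), then all-subsets BIC model averaging is run
#' on the survivors.
#'
#' @param data Standardized data.frame containing the gbM indicator and
#'   candidate features.
#' @param predictors Candidate feature columns.
#' @param gbm_col Name of the gbM response column.
#' @param vif_threshold Drop predictors with vif at or above this (default 4,
#'   i.e. sqrt(vif) >= 2).
#' @return List: \code{dropped} (vif violators) and \code{model} (the
#'   \code{averaged_model}).
#' @export
predict_gbm_model <- function(data, predictors, gbm_col = "gbM",
                              vif_threshold = 4) {
  kept <- predictors
  dropped <- character()
  repeat {
    if (length(kept) < 2) break
    # a duplicated/collinear column defeats vif itself; detect and drop first
    Xk <- as.matrix(data[kept])
    if (qr(cbind(1, Xk))$rank < ncol(Xk) + 1) {
      qq <- qr(cbind(1, Xk))
      dep <- qq$pivot[-seq_len(qq$rank)]
      dep <- dep[dep > 1] - 1L
      drop_j <- kept[dep[1]]
      dropped <- c(dropped, drop_j)
      kept <- setdiff(kept, drop_j)
      next
    }
    v <- vif(Xk)
    if (max(v) < vif_threshold) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    kept <- setdiff(kept, worst)
  }
  list(dropped = dropped,
       model = bic_model_average(data, gbm_col, kept))
}

#' Group-difference table for gbM vs unmethylated genes
#'
#' For each feature, the per-group median (proportion for binary features),
#' the two-sided Mann-Whitney P value, and its Benjamini-Hochberg
#' adjustment across all features.
#'
#' @param data Data.frame with a \code{class} column ("gbM"/"unmethylated")
#'   and feature columns.
#' @param features Feature column names to compare.
#' @return Data.frame: feature, gbM, unmethylated, p, p_adj.
#' @export
group_comparison_table <- function(data, features) {
  a <- data[data$class == "gbM", , drop = FALSE]
  b <- data[data$class == "unmethylated", , drop = FALSE]
  rows <- lapply(features, function(f) {
    binary <- length(unique(data[[f]])) <= 2
    stat <- if (binary) function(v) mean(v) else function(v) median(v)
    p <- mann_whitney(a[[f]], b[[f]])$p
    data.frame(feature = f, gbM = stat(a[[f]]), unmethylated = stat(b[[f]]),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
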