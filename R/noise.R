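# Single-cell expression noise: the expression filter, the polynomial
# mean-variance decorrelation yielding stochastic expression F*, the
# coefficient-of-variation noise F', and expression consistency.

#' Filter genes by the single-cell expression threshold
#'
#' Keeps genes whose maximum over cells of log(FPKM + 1) exceeds the
#' threshold in at least one cell.
#'
#' @param mat Genes-by-cells FPKM matrix.
#' @param threshold Filter threshold on the log scale (default 1.5).
#' @param log_base Logarithm base (default 2).
#' @return The filtered matrix (rows subset).
#' @export
filter_expressed <- function(mat, threshold = 1.5, log_base = 2) {
  stopifnot(is.matrix(mat), nrow(mat) > 0)
  if (!is.numeric(log_base) || log_base <= 0 || log_base == 1) {
    stop("invalid log base")
  }
  keep <- apply(log(mat + 1, base = log_base), 1, max) > threshold
  mat[keep, , drop = FALSE]
}

#' Per-gene mean and sample variance over cells
#'
#' Zeros count as observations; variance uses the n - 1 denominator.
#'
#' @param mat Genes-by-cells FPKM matrix (>= 2 cells).
#' @return Data.frame \code{gene_id}, \code{mu}, \code{s2}.
#' @export
mean_variance <- function(mat) {
  if (ncol(mat) < 2) stop("need >= 2 cells for a variance")
  mu <- rowMeans(mat)
  s2 <- rowSums((mat - mu)^2) / (ncol(mat) - 1)
  data.frame(gene_id = rownames(mat), mu = mu, s2 = s2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the polynomial mean-variance trend
#'
#' Least-squares fit of log(s2) on powers of log(mu) up to \code{degree}
#' (natural logs). Genes with mu <= 0 or s2 <= 0 are excluded from the fit
#' and flagged. The expected variance at a mean is exp of the fitted value.
#'
#' @param mu,s2 Per-gene means and variances.
#' @param degree Polynomial degree (>= 1).
#' @return A \code{variance_model}: coefficients, degree, logical
#'   \code{fitted_genes}, fitted log-variance for those genes, plus (filled
#'   by \code{\link{select_degree}}) the F*-vs-mu decorrelation test.
#' @export
fit_variance_trend <- function(mu, s2, degree) {
  if (degree < 1) stop("degree must be >= 1")
  use <- mu > 0 & s2 > 0
  if (sum(use) < degree + 2) stop("fewer usable genes than degree + 2")
  x <- log(mu[use]); y <- log(s2[use])
  X <- outer(x, 0:degree, `^`)
  cf <- qr.coef(qr(X), y)
  structure(list(degree = degree, coefficients = unname(cf),
                 fitted_genes = use, fitted_log_s2 = drop(X %*% cf),
                 tau = NA_real_, tau_p = NA_real_, warning = FALSE),
            class = "variance_model")
}

#' Predict expected variance from a fitted trend
#' @param model A \code{variance_model}.
#' @param mu Means at which to predict (> 0).
#' @return Expected variances exp(fitted log s2).
#' @export
predict_variance <- function(model, mu) {
  stopifnot(inherits(model, "variance_model"), all(mu > 0))
  x <- log(mu)
  exp(drop(outer(x, 0:model$degree, `^`) %*% model$coefficients))
}

#' Stochastic expression F*
#'
#' The ratio of observed to trend-expected variance.
#'
#' @param s2 Observed variances.
#' @param s2_expected Trend-expected variances (> 0).
#' @return F* values.
#' @export
compute_Fstar <- function(s2, s2_expected) {
  if (any(s2_expected <= 0)) stop("expected variance must be positive")
  s2 / s2_expected
}

#' Select the lowest decorrelating polynomial degree
#'
#' Searches forward from degree 1 and returns the smallest degree whose F*
#' is uncorrelated with the mean (Kendall rank correlation P >= alpha) on
#' the fitted genes. If no degree up to \code{max_degree} decorrelates, the
#' max-degree model is returned with its \code{warning} flag set.
#'
#' @param mu,s2 Per-gene means and variances.
#' @param max_degree Largest degree to try (default 6).
#' @param alpha Significance level of the decorrelation test (default 0.05).
#' @return A \code{variance_model} with \code{tau} and \code{tau_p} recorded.
#' @export
select_degree <- function(mu, s2, max_degree = 6, alpha = 0.05) {
  if (max_degree < 1) stop("max_degree must be >= 1")
  use <- mu > 0 & s2 > 0
  if (sum(use) < max_degree + 2) stop("fewer genes than max_degree + 2")
  model <- NULL
  for (d in seq_len(max_degree)) {
    model <- fit_variance_trend(mu, s2, d)
    fstar <- compute_Fstar(s2[model$fitted_genes],
                           exp(model$fitted_log_s2))
    kt <- kendall_tau(fstar, mu[model$fitted_genes])
    model$tau <- kt$tau; model$tau_p <- kt$p
    if (kt$p >= alpha) return(model)
  }
  model$warning <- TRUE
  model
}

#' @export
print.variance_model <- function(x, ...) {
  cat("variance_model: degree", x$degree, "on", sum(x$fitted_genes),
      "genes; Kendall tau(F*, mu) =", signif(x$tau, 3),
      "(P =", signif(x$tau_p, 3), ")",
      if (x$warning) "[decorrelation not reached]" else "", "\n")
  invisible(x)
}

#' Transcriptional noise F' (coefficient of variation)
#'
#' Sample standard deviation divided by mean, per gene over all cells.
#'
#' @param mat Genes-by-cells FPKM matrix; every gene mean must be positive.
#' @return Named vector of F' values.
#' @export
compute_Fprime <- function(mat) {
  mu <- rowMeans(mat)
  if (any(mu == 0)) stop("F' undefined for genes with zero mean")
  sdv <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1))
  setNames(sdv / mu, rownames(mat))
}

#' Expression consistency
#'
#' The number of single cells in which a gene is detected as expressed
#' (FPKM strictly greater than 0).
#'
#' @param mat Genes-by-cells FPKM matrix.
#' @return Named integer vector in 0..n_cells.
#' @export
expression_consistency <- function(mat) {
  setNames(as.integer(rowSums(mat > 0)), rownames(mat))
}

#' Kendall rank correlation test
#'
#' Tie-corrected tau-b; the P value uses exact enumeration for small
#' untied samples and the normal approximation otherwise.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return List with \code{tau} and \code{p}.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need length >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("tau undefined for a constant vector")
  }
  exact <- length(x) <= 8 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = exact))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Assemble the per-gene noise table
#'
#' Runs the expression filter, degree selection and all per-gene noise
#' measures in one pass.
#'
#' @param mat Genes-by-cells FPKM matrix (unfiltered).
#' @param threshold,log_base Expression-filter parameters.
#' @param max_degree,alpha Degree-selection parameters.
#' @return List with \code{table} (gene_id, mu, s2, fstar, fprime,
#'   consistency) and \code{model} (the selected \code{variance_model}).
#'   Genes excluded from the trend fit (s2 = 0) carry \code{NA} F*.
#' @export
noise_table <- function(mat, threshold = 1.5, log_base = 2, max_degree = 6,
                        alpha = 0.05) {
  kept <- filter_expressed(mat, threshold, log_base)
  mv <- mean_variance(kept)
  model <- select_degree(mv$mu, mv$s2, max_degree, alpha)
  fstar <- rep(NA_real_, nrow(mv))
  fstar[model$fitted_genes] <- compute_Fstar(mv$s2[model$fitted_genes],
                                             exp(model$fitted_log_s2))
  tab <- data.frame(gene_id = mv$gene_id, mu = mv$mu, s2 = mv$s2,
                    fstar = fstar,
                    fprime = unname(compute_Fprime(kept)),
                    consistency = unname(expression_consistency(kept)),
                    stringsAsFactors = FALSE)
  list(table = tab, model = model)
}
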