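## Anatomical adjustment: regression of functional similarity on the four
## anatomical similarity vectors over the stacked within+between data,
## residual standardization, and the label-shuffling permutation test.

ANATOMY_MEASURES <- c("thickness", "area", "curvature", "sulc")

#' Build the stacked regression table
#'
#' Stacks the within-person block on top of the between-person block: each
#' retained vertex contributes one row per kind, with the functional
#' similarity score as response and the four anatomical similarity scores
#' of the same vertex and kind as predictors. Rows with any missing
#' component are dropped and counted.
#'
#' @param func_within,func_between per-vertex functional similarity vectors
#'   (see [within_person_vertex_similarity()]).
#' @param anat_within,anat_between named lists of the four per-vertex
#'   anatomical similarity vectors (`thickness`, `area`, `curvature`,
#'   `sulc`), matched to the same vertices.
#' @return data frame with columns `kind` (factor within/between), `vertex`
#'   (0-based index), `y`, and the four predictors; attribute `n_dropped`
#'   counts incomplete rows removed.
#' @export
build_regression_table <- function(func_within, func_between,
                                   anat_within, anat_between) {
  n <- length(func_within)
  lens <- c(length(func_between),
            vapply(anat_within, length, integer(1)),
            vapply(anat_between, length, integer(1)))
  if (any(lens != n)) {
    stop_densim("all similarity vectors must share the vertex grid",
                "densim_input_error")
  }
  missing_m <- setdiff(ANATOMY_MEASURES, names(anat_within))
  if (length(missing_m) ||
      length(setdiff(ANATOMY_MEASURES, names(anat_between)))) {
    stop_densim(sprintf("anatomy similarity lists must contain: %s",
                        paste(ANATOMY_MEASURES, collapse = ", ")),
                "densim_input_error")
  }
  block <- function(kind, y, anat) {
    data.frame(kind = kind, vertex = seq_len(n) - 1L, y = as.numeric(y),
               thickness = as.numeric(anat$thickness),
               area = as.numeric(anat$area),
               curvature = as.numeric(anat$curvature),
               sulc = as.numeric(anat$sulc))
  }
  tab <- rbind(block("within", func_within, anat_within),
               block("between", func_between, anat_between))
  tab$kind <- factor(tab$kind, levels = c("within", "between"))
  complete <- stats::complete.cases(tab)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("build_regression_table: dropped %d incomplete row(s)",
                    n_dropped))
  }
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fit the anatomical-control regression
#'
#' Ordinary least squares of the functional similarity scores on the four
#' anatomical similarity scores (with intercept):
#' `y = b0 + b1*thickness + b2*area + b3*curvature + b4*sulc + e`.
#' Residuals are standardized by dividing by the sample standard deviation
#' of all residuals (`standardize = "sd"`, the default) or as internally
#' studentized residuals (`standardize = "studentized"`).
#'
#' @param table regression table from [build_regression_table()].
#' @param standardize residual standardization mode.
#' @return object of class `anatomy_fit`: list with `coefficients` (b0-b4),
#'   `residuals`, `std_residuals`, `kind` (per-row label), `r_squared`,
#'   `diagnostics` (residual skewness, excess kurtosis, largest absolute
#'   standardized residual), and the underlying `lm` fit in `model`.
#' @export
fit_anatomy_model <- function(table, standardize = c("sd", "studentized")) {
  standardize <- match.arg(standardize)
  if (nrow(table) < 6L) {
    stop_densim("need at least 6 rows to fit the 5-parameter model",
                "densim_input_error")
  }
  fit <- stats::lm(y ~ thickness + area + curvature + sulc, data = table)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_densim(sprintf("rank-deficient design; collinear predictor(s): %s",
                        paste(bad, collapse = ", ")),
                "densim_input_error")
  }
  res <- stats::residuals(fit)
  std <- switch(standardize,
                sd = res / stats::sd(res),
                studentized = stats::rstandard(fit))
  z <- res / stats::sd(res)
  diagnostics <- c(skewness = mean(z^3),
                   excess_kurtosis = mean(z^4) - 3,
                   max_abs_std_residual = max(abs(std)))
  structure(list(coefficients = stats::coef(fit),
                 residuals = unname(res),
                 std_residuals = unname(std),
                 kind = table$kind,
                 vertex = table$vertex,
                 r_squared = summary(fit)$r.squared,
                 diagnostics = diagnostics,
                 standardize = standardize,
                 model = fit),
            class = "anatomy_fit")
}

#' @export
print.anatomy_fit <- function(x, ...) {
  cat("Anatomical-control regression (OLS)\n")
  print(round(x$coefficients, 6))
  cat(sprintf("R-squared: %.4f; n = %d rows; residual skewness %.3f, excess kurtosis %.3f\n",
              x$r_squared, length(x$residuals),
              x$diagnostics["skewness"], x$diagnostics["excess_kurtosis"]))
  invisible(x)
}

#' Pooled-SD Cohen's d
#'
#' `d = (mean(a) - mean(b)) / sqrt((s_a^2 + s_b^2) / 2)` with sample
#' variances.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @return scalar effect size.
#' @export
cohens_d_pooled <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_densim("each group needs at least 2 values", "densim_input_error")
  }
  cohens_d_from_stats(mean(group_a), stats::sd(group_a),
                      mean(group_b), stats::sd(group_b))
}

#' Pooled-SD Cohen's d from summary statistics
#' @param mean_a,sd_a,mean_b,sd_b group means and sample SDs.
#' @return scalar effect size.
#' @export
cohens_d_from_stats <- function(mean_a, sd_a, mean_b, sd_b) {
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) {
    stop_densim("zero pooled standard deviation", "densim_input_error")
  }
  (mean_a - mean_b) / pooled
}

#' Label-shuffling permutation test of a mean difference
#'
#' Tests `mean(group_a) - mean(group_b)` against the null distribution
#' obtained by repeatedly shuffling the pooled values' group labels
#' (preserving group sizes) and recomputing the difference. The p-value is
#' the plain proportion of iterations whose permuted difference is as
#' extreme or more extreme than the observed one (`|diff|` comparison when
#' `alternative = "two.sided"`). With `exhaustive = TRUE` all label splits
#' are enumerated instead of sampled (feasible for small pooled sizes).
#'
#' @param group_a,group_b numeric score vectors (e.g. the standardized
#'   residuals of the within and between blocks).
#' @param n_iterations number of sampled label shuffles (ignored when
#'   exhaustive).
#' @param seed optional integer seed for the shuffles.
#' @param alternative `"two.sided"` (default) or `"greater"`
#'   (`mean(a) > mean(b)`).
#' @param exhaustive enumerate all `choose(n, n_a)` splits.
#' @param p_correction `"plain"` proportion (default) or `"add_one"` for
#'   the never-zero `(b + 1) / (m + 1)` estimate.
#' @return object of class `permutation_result`: observed difference, group
#'   means/SDs/sizes, iteration count, permuted-difference range, p-value,
#'   pooled-SD Cohen's d, and the seed.
#' @examples
#' r <- permutation_mean_diff_test(c(1, 2, 3), c(4, 5, 6), exhaustive = TRUE)
#' r$p_value  # 0.1: only the observed split and its mirror reach |diff| = 3
#' @export
permutation_mean_diff_test <- function(group_a, group_b,
                                       n_iterations = 10000L, seed = NULL,
                                       alternative = c("two.sided", "greater"),
                                       exhaustive = FALSE,
                                       p_correction = c("plain", "add_one")) {
  alternative <- match.arg(alternative)
  p_correction <- match.arg(p_correction)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_densim("both groups must be non-empty", "densim_input_error")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  z <- c(group_a, group_b)
  total <- sum(z)
  n <- n_a + n_b
  observed <- mean(group_a) - mean(group_b)
  ## tiny tolerance so ties with the observed value count as extreme
  eps <- 1e-12 * max(1, abs(observed))
  diff_from_sum_a <- function(s) s / n_a - (total - s) / n_b

  if (exhaustive) {
    if (choose(n, n_a) > 5e5) {
      stop_densim("pooled size too large for exhaustive enumeration",
                  "densim_input_error")
    }
    idx <- utils::combn(n, n_a)
    diffs <- apply(idx, 2L, function(i) diff_from_sum_a(sum(z[i])))
    n_iter <- length(diffs)
  } else {
    assert_count(n_iterations, "n_iterations", min = 1L)
    if (!is.null(seed)) set.seed(seed)
    diffs <- numeric(n_iterations)
    for (i in seq_len(n_iterations)) {
      s <- sum(z[sample.int(n, n_a)])
      diffs[i] <- diff_from_sum_a(s)
    }
    n_iter <- n_iterations
  }
  extreme <- switch(alternative,
                    two.sided = abs(diffs) >= abs(observed) - eps,
                    greater = diffs >= observed - eps)
  n_extreme <- sum(extreme)
  p <- switch(p_correction,
              plain = n_extreme / n_iter,
              add_one = (n_extreme + 1) / (n_iter + 1))
  structure(list(observed_diff = observed,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
                 n_a = n_a, n_b = n_b,
                 n_iterations = n_iter,
                 exhaustive = exhaustive,
                 perm_range = range(diffs),
                 p_value = p,
                 cohens_d = if (n_a >= 2L && n_b >= 2L)
                   cohens_d_pooled(group_a, group_b) else NA_real_,
                 alternative = alternative,
                 p_correction = p_correction,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s): observed diff %.4f (M_a = %.3f, SD_a = %.3f; M_b = %.3f, SD_b = %.3f)\n",
              x$alternative, if (x$exhaustive) "exhaustive" else
                sprintf("%d iterations", x$n_iterations),
              x$observed_diff, x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  cat(sprintf("permuted range [%.4f, %.4f]; p = %.6g; Cohen's d = %.3f\n",
              x$perm_range[1], x$perm_range[2], x$p_value, x$cohens_d))
  invisible(x)
}
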