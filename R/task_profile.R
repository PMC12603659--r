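## Per-task similarity profiling: grouping, Welch ANOVA, median table,
## median-vector correlation.

#' Group per-contrast scores by task
#'
#' @param scores named per-contrast score vector (names are contrast ids).
#' @param catalog a [task_catalog()] covering every contrast id.
#' @return named list of numeric vectors, one per task, in catalog task
#'   order; the group sizes partition the scores.
#' @export
group_scores_by_task <- function(scores, catalog) {
  ids <- names(scores)
  if (is.null(ids)) {
    stop_densim("`scores` must be named by contrast id", "densim_input_error")
  }
  idx <- match(ids, catalog$contrast_id)
  if (anyNA(idx)) {
    stop_densim(sprintf("contrast id(s) not in catalog: %s",
                        paste(ids[is.na(idx)], collapse = ", ")),
                "densim_catalog_error")
  }
  task <- factor(catalog$task_id[idx], levels = catalog_tasks(catalog))
  split(unname(unclass(scores)), task)
}

#' Welch's heteroscedastic one-way ANOVA across tasks
#'
#' One-way ANOVA robust to unequal group variances (Welch), with
#' `df1 = k - 1` and fractional Welch-Satterthwaite denominator degrees of
#' freedom; classical equal-variance ANOVA available via
#' `var_equal = TRUE`.
#'
#' @param groups named list of numeric score vectors (from
#'   [group_scores_by_task()]), each with >= 2 values and positive
#'   variance.
#' @param var_equal use the classical equal-variance F-test instead.
#' @return object of class `anova_result` with `statistic` (F), `df1`,
#'   `df2`, `p_value`, and `n_groups`.
#' @export
welch_anova <- function(groups, var_equal = FALSE) {
  if (length(groups) < 2L) {
    stop_densim("need at least 2 groups", "densim_input_error")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  bad <- names(groups)[vapply(groups, function(g) {
    length(g) < 2L || stats::var(g) == 0
  }, logical(1))]
  if (length(bad)) {
    stop_densim(sprintf("degenerate group(s) (n < 2 or zero variance): %s",
                        paste(bad, collapse = ", ")),
                "densim_input_error")
  }
  value <- unlist(groups, use.names = FALSE)
  task <- factor(rep(names(groups), lengths(groups)),
                 levels = names(groups))
  ht <- stats::oneway.test(value ~ task, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 df1 = unname(ht$parameter[1]),
                 df2 = unname(ht$parameter[2]),
                 p_value = ht$p.value,
                 n_groups = length(groups),
                 var_equal = var_equal),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s one-way ANOVA: F(%g, %.2f) = %.3f, p = %.4g (%d groups)\n",
              if (x$var_equal) "Classical" else "Welch",
              x$df1, x$df2, x$statistic, x$p_value, x$n_groups))
  invisible(x)
}

#' Per-task median similarity table
#'
#' Per task: the median within-person similarity, the median between-person
#' similarity, and their difference (within minus between), the quantity
#' used to rank tasks for individual-differences research. Medians use the
#' midpoint-of-central-order-statistics convention for even group sizes
#' (the `stats::median` default). Values are unrounded; round for display
#' only.
#'
#' @param within_groups,between_groups named per-task score lists covering
#'   the same tasks (see [group_scores_by_task()]).
#' @param sort_by_difference order rows by ascending difference (the
#'   conventional presentation); otherwise catalog order.
#' @return data frame of class `task_similarity_table` with columns
#'   `task_id`, `median_within`, `median_between`,
#'   `within_between_difference`, `n_within`, `n_between`.
#' @export
task_median_table <- function(within_groups, between_groups,
                              sort_by_difference = TRUE) {
  if (!setequal(names(within_groups), names(between_groups))) {
    stop_densim("within and between groups must cover the same tasks",
                "densim_input_error")
  }
  tasks <- names(within_groups)
  between_groups <- between_groups[tasks]
  if (any(lengths(within_groups) == 0L) ||
      any(lengths(between_groups) == 0L)) {
    stop_densim("empty task group", "densim_input_error")
  }
  mw <- vapply(within_groups, stats::median, numeric(1), na.rm = TRUE)
  mb <- vapply(between_groups, stats::median, numeric(1), na.rm = TRUE)
  out <- data.frame(task_id = tasks,
                    median_within = unname(mw),
                    median_between = unname(mb),
                    within_between_difference = unname(mw - mb),
                    n_within = unname(lengths(within_groups)),
                    n_between = unname(lengths(between_groups)),
                    stringsAsFactors = FALSE)
  if (sort_by_difference) {
    out <- out[order(out$within_between_difference), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("task_similarity_table", "data.frame")
  out
}

#' Correlation of the per-task median vectors
#'
#' Pearson correlation between the per-task within-person median vector and
#' the between-person median vector; a high value means tasks that are
#' reliable within a person also tend to look similar across people.
#'
#' @param table a [task_median_table()] result, or any data frame with
#'   `median_within` and `median_between` columns.
#' @return scalar Pearson correlation.
#' @export
median_vector_correlation <- function(table) {
  w <- table$median_within
  b <- table$median_between
  if (length(w) < 3L) {
    stop_densim("need at least 3 tasks", "densim_input_error")
  }
  if (stats::sd(w) == 0 || stats::sd(b) == 0) {
    stop_densim("constant median vector: correlation undefined",
                "densim_input_error")
  }
  stats::cor(w, b)
}
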