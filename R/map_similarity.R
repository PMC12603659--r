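## Whole-map (column-wise) similarity and the associated t-tests.

#' Within-person per-contrast map similarity
#'
#' For each subject, correlates the subject's Set1 and Set2 maps of every
#' contrast over the kept vertices, then averages the per-contrast
#' correlations across subjects, yielding one within-person similarity
#' score per contrast (112 with the default catalog).
#'
#' @inheritParams within_person_vertex_similarity
#' @return named numeric vector (one score per contrast) with attribute
#'   `kind = "within"`.
#' @export
within_person_map_similarity <- function(dataset, mask = dataset$mask,
                                         fisher_z = FALSE) {
  sets <- names(dataset$contrast[[1]])
  per_subject <- lapply(dataset$contrast, function(m) {
    suppressMessages(columnwise_pearson(unclass(m[[1]]), unclass(m[[2]]),
                                        mask))
  })
  out <- average_scores(per_subject, fisher_z)
  names(out) <- names(per_subject[[1]])
  attr(out, "kind") <- "within"
  out
}

#' Between-person per-contrast map similarity
#'
#' For every unordered subject pair and each set label, correlates the two
#' subjects' set-matched maps of each contrast, then averages per contrast
#' over all (pair, set) combinations.
#'
#' @inheritParams within_person_vertex_similarity
#' @return named numeric vector (one score per contrast) with attribute
#'   `kind = "between"`.
#' @export
between_person_map_similarity <- function(dataset, mask = dataset$mask,
                                          fisher_z = FALSE) {
  subjects <- names(dataset$contrast)
  if (length(subjects) < 2L) {
    stop_densim("between-person similarity needs at least 2 subjects",
                "densim_input_error")
  }
  sets <- names(dataset$contrast[[1]])
  scores <- list()
  for (i in seq_along(subjects)[-length(subjects)]) {
    for (j in seq((i + 1L), length(subjects))) {
      for (st in sets) {
        scores[[length(scores) + 1L]] <- suppressMessages(
          columnwise_pearson(unclass(dataset$contrast[[i]][[st]]),
                             unclass(dataset$contrast[[j]][[st]]), mask))
      }
    }
  }
  out <- average_scores(scores, fisher_z)
  names(out) <- names(scores[[1]])
  attr(out, "kind") <- "between"
  out
}

#' Cohort between-person map similarity
#'
#' All unordered pairwise column-wise correlations across a cohort of
#' subjects with one contrast matrix each (e.g. a single-session public
#' dataset used as a between-person reference distribution).
#'
#' @param cohort list of vertex-by-contrast matrices, one per subject, with
#'   identical shapes and contrast order.
#' @param mask optional logical keep-flag per vertex row.
#' @param aggregation `"per_pair"` (default): one mean score per subject
#'   pair, `choose(N, 2)` values; `"per_contrast"`: one mean score per
#'   contrast across pairs.
#' @return numeric vector of between-person similarity scores.
#' @export
cohort_between_similarity <- function(cohort, mask = NULL,
                                      aggregation = c("per_pair",
                                                      "per_contrast")) {
  aggregation <- match.arg(aggregation)
  if (!is.list(cohort) || length(cohort) < 2L) {
    stop_densim("`cohort` must list at least 2 subjects",
                "densim_input_error")
  }
  n <- length(cohort)
  pair_scores <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pair_scores[[length(pair_scores) + 1L]] <- suppressMessages(
        columnwise_pearson(unclass(cohort[[i]]), unclass(cohort[[j]]), mask))
    }
  }
  if (aggregation == "per_pair") {
    vapply(pair_scores, function(s) mean(s, na.rm = TRUE), numeric(1))
  } else {
    out <- rowMeans(do.call(cbind, pair_scores), na.rm = TRUE)
    names(out) <- names(pair_scores[[1]])
    out
  }
}

ttest_result <- function(ht, d, n_a, n_b, mean_a, sd_a, mean_b, sd_b,
                         type) {
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 cohens_d = d,
                 mean_a = mean_a, sd_a = sd_a, n_a = n_a,
                 mean_b = mean_b, sd_b = sd_b, n_b = n_b,
                 type = type),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.4g) = %.4f, p = %.4g, Cohen's d = %.3f\n",
              x$type, x$df, x$statistic, x$p_value, x$cohens_d))
  cat(sprintf("group a: M = %.4f, SD = %.4f, n = %d; group b: M = %.4f, SD = %.4f, n = %d\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Paired t-test of within vs between map similarity
#'
#' Classical paired t-test over contrasts (df = K - 1), two-sided, with the
#' pooled-SD Cohen's d attached. Contrasts with a missing score in either
#' vector are dropped pairwise (count reported).
#'
#' @param within,between equal-length per-contrast score vectors, paired by
#'   contrast.
#' @return a `ttest_result`.
#' @export
paired_t_test <- function(within, between) {
  if (length(within) != length(between)) {
    stop_densim("`within` and `between` must be paired by contrast",
                "densim_input_error")
  }
  ok <- !is.na(within) & !is.na(between)
  if (sum(!ok) > 0) {
    message(sprintf("paired_t_test: dropped %d incomplete pair(s); K = %d",
                    sum(!ok), sum(ok)))
  }
  w <- within[ok]; b <- between[ok]
  if (length(w) < 2L) {
    stop_densim("need at least 2 complete pairs", "densim_input_error")
  }
  if (stats::sd(w - b) == 0) {
    stop_densim("zero variance of paired differences", "densim_input_error")
  }
  ht <- stats::t.test(w, b, paired = TRUE)
  ttest_result(ht, cohens_d_pooled(w, b),
               length(w), length(b), mean(w), stats::sd(w),
               mean(b), stats::sd(b), "paired")
}

#' Welch two-sample t-test
#'
#' Heteroscedastic two-sample t-test with Welch-Satterthwaite fractional
#' degrees of freedom, two-sided; used to compare two similarity-score
#' collections of unequal size (e.g. a two-person dataset against a larger
#' cohort).
#'
#' @param scores_a,scores_b numeric vectors, each with >= 2 values and
#'   positive variance.
#' @return a `ttest_result`.
#' @export
welch_t_test <- function(scores_a, scores_b) {
  a <- scores_a[!is.na(scores_a)]
  b <- scores_b[!is.na(scores_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_densim("each collection needs at least 2 values",
                "densim_input_error")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop_densim("degenerate variance in both collections",
                "densim_input_error")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  ttest_result(ht, cohens_d_pooled(a, b),
               length(a), length(b), mean(a), stats::sd(a),
               mean(b), stats::sd(b), "welch")
}
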