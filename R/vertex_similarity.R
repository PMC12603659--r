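## Per-vertex (row-wise) within- and between-person similarity.

dataset_matrices <- function(dataset, measure) {
  subjects <- names(dataset$contrast)
  sets <- names(dataset$contrast[[1]])
  if (identical(measure, "functional")) {
    lapply(dataset$contrast, function(x) x[sets])
  } else {
    lapply(dataset$anatomy, function(per_set) {
      out <- lapply(sets, function(st) {
        m <- per_set[[st]][[measure]]
        if (is.null(m)) {
          stop_densim(sprintf("measure '%s' not present in dataset", measure),
                      "densim_input_error")
        }
        m
      })
      names(out) <- sets
      out
    })
  }
}

#' Within-person per-vertex similarity
#'
#' For each subject, correlates the subject's Set1 row with the Set2 row at
#' every vertex (across the 112 contrast columns for functional data, or
#' across the paired scan sessions for an anatomical measure), then averages
#' the per-subject correlation vectors element-wise into one mean similarity
#' score per vertex. Raw correlations are averaged (no Fisher transform)
#' unless `fisher_z = TRUE`.
#'
#' @param dataset a `densim_dataset` (from [generate_dataset()] or
#'   [assemble_dataset()]).
#' @param measure `"functional"` or one of the anatomy measures
#'   (`"thickness"`, `"area"`, `"curvature"`, `"sulc"`).
#' @param mask optional logical keep-flag; defaults to the dataset mask.
#' @param fisher_z average through Fisher's z instead of raw r.
#' @return numeric vector of per-vertex scores with attributes `kind`
#'   (`"within"`) and `measure`.
#' @export
within_person_vertex_similarity <- function(dataset, measure = "functional",
                                            mask = dataset$mask,
                                            fisher_z = FALSE) {
  mats <- dataset_matrices(dataset, measure)
  sets <- names(mats[[1]])
  if (length(sets) < 2L) {
    stop_densim("within-person similarity needs both sets",
                "densim_input_error")
  }
  per_subject <- lapply(mats, function(m) {
    suppressMessages(rowwise_pearson(unclass(m[[1]]), unclass(m[[2]]), mask))
  })
  out <- average_scores(per_subject, fisher_z)
  attr(out, "kind") <- "within"
  attr(out, "measure") <- measure
  out
}

#' Between-person per-vertex similarity
#'
#' For every unordered subject pair and each set label, correlates the
#' set-matched rows of the two subjects at every vertex, then averages
#' element-wise over all (pair, set) combinations. With two subjects this
#' is the mean of the Set1 cross-person and Set2 cross-person correlation
#' vectors. Sets are never crossed between people.
#'
#' @inheritParams within_person_vertex_similarity
#' @return numeric vector of per-vertex scores with attributes `kind`
#'   (`"between"`) and `measure`.
#' @export
between_person_vertex_similarity <- function(dataset, measure = "functional",
                                             mask = dataset$mask,
                                             fisher_z = FALSE) {
  mats <- dataset_matrices(dataset, measure)
  subjects <- names(mats)
  if (length(subjects) < 2L) {
    stop_densim("between-person similarity needs at least 2 subjects",
                "densim_input_error")
  }
  sets <- names(mats[[1]])
  scores <- list()
  for (i in seq_along(subjects)[-length(subjects)]) {
    for (j in seq((i + 1L), length(subjects))) {
      for (st in sets) {
        scores[[length(scores) + 1L]] <- suppressMessages(
          rowwise_pearson(unclass(mats[[i]][[st]]),
                          unclass(mats[[j]][[st]]), mask))
      }
    }
  }
  out <- average_scores(scores, fisher_z)
  attr(out, "kind") <- "between"
  attr(out, "measure") <- measure
  out
}
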