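#' Construct a task catalog
#'
#' A task catalog maps each statistical contrast to the task it was computed
#' from. It fixes the column order of every contrast matrix in a dataset and
#' drives the per-task grouping of map-level similarity scores.
#'
#' @param task_ids character vector of unique task identifiers, in display
#'   order.
#' @param n_contrasts integer vector, one entry per task: how many contrasts
#'   that task contributes. All entries must be >= 1.
#' @return A data frame of class `task_catalog` with columns `contrast_id`
#'   and `task_id`; one row per contrast, ordered task by task.
#' @examples
#' cat3 <- task_catalog(c("A", "B"), c(2, 3))
#' nrow(cat3)  # 5 contrasts
#' @export
task_catalog <- function(task_ids, n_contrasts) {
  if (anyDuplicated(task_ids)) {
    stop_densim("task identifiers must be unique", "densim_config_error")
  }
  if (length(task_ids) != length(n_contrasts)) {
    stop_densim("`task_ids` and `n_contrasts` must have equal length",
                "densim_config_error")
  }
  n_contrasts <- vapply(seq_along(n_contrasts), function(i) {
    assert_count(n_contrasts[i], sprintf("n_contrasts[%s]", task_ids[i]))
  }, integer(1))
  task_id <- rep(task_ids, n_contrasts)
  contrast_id <- unlist(lapply(seq_along(task_ids), function(i) {
    sprintf("%s_c%d", task_ids[i], seq_len(n_contrasts[i]))
  }), use.names = FALSE)
  out <- data.frame(contrast_id = contrast_id, task_id = task_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("task_catalog", "data.frame")
  out
}

#' Default 22-task cognitive-control catalog
#'
#' Returns the default catalog of 22 cognitive-control task identifiers
#' (color-shape and number-letter switching, n-back, Sternberg, Stroop
#' variants, flanker, go/no-go, attention tasks, and so on) whose contrast
#' counts sum to 112. The per-task split of the 112 contrasts is a package
#' convention: 5 contrasts per task, with 6 for the two multi-component
#' batteries (inhibit/switch/update and the executive-function composite),
#' which probe more conditions than the single-paradigm tasks.
#'
#' @return A `task_catalog` with 22 tasks and 112 contrasts.
#' @examples
#' cat22 <- default_task_catalog()
#' length(unique(cat22$task_id))  # 22
#' nrow(cat22)                    # 112
#' @export
default_task_catalog <- function() {
  tasks <- c("ISU", "CLRSHP", "NUMLIST", "SRC", "NUMLET", "EF", "SIMON",
             "COUNTSW", "GRIDUP", "O-ATTN", "GNG", "STERN", "RANDNUM",
             "STROOP", "C-ATTN", "NUM-STR", "ARR-STR", "FLANKER", "SPA-WM",
             "COM-STR", "N-BACK", "ITEMREC")
  n <- ifelse(tasks %in% c("ISU", "EF"), 6L, 5L)
  task_catalog(tasks, n)
}

#' Tasks of a catalog, in catalog order
#' @param catalog a `task_catalog`.
#' @return character vector of task identifiers.
#' @export
catalog_tasks <- function(catalog) {
  unique(catalog$task_id)
}
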