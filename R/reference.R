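#' Published per-task median similarity reference table
#'
#' Median within-person and between-person map similarity for the default
#' 22-task cognitive-control battery, as reported for a dense-sampling
#' split-half study of two highly sampled adults. The raw imaging data
#' behind these medians are not distributed; the table is shipped so that
#' the table arithmetic (difference column, median-vector correlation) can
#' be exercised and so the simulator's default per-task variance profile
#' can emulate a realistic spread of task reliabilities.
#'
#' @return data frame with columns `task_id`, `median_within`,
#'   `median_between` (22 rows, one per task of [default_task_catalog()]).
#' @examples
#' ref <- task_median_reference()
#' head(ref)
#' @export
task_median_reference <- function() {
  path <- system.file("extdata", "task_median_reference.tsv",
                      package = "densim", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "numeric"))
}
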