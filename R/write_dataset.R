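## Export of a generated dataset as per-run overlays plus a run manifest,
## so the assembly stage can be exercised (and round-tripped) on files.

#' Write a dataset as per-run overlays with a manifest
#'
#' Writes one overlay file per hemisphere per contrast per subject per set
#' (set k stored as task repetition k), plus one file per hemisphere per
#' anatomy session, a YAML run manifest, and a JSON truth sidecar (expected
#' per-task similarities, seed, masked vertex indices). Assembling the
#' written tree with [identity_set_assignment()] reproduces the generated
#' matrices exactly.
#'
#' @param dataset a `densim_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param format overlay format: `"tsv"`, `"mgh"`, or `"gifti"`.
#' @return path of the written manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("tsv", "mgh", "gifti")) {
  format <- match.arg(format)
  ext <- c(tsv = "tsv", mgh = "mgh", gifti = "gii")[[format]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nvh <- attr(dataset$contrast[[1]][[1]], "n_vertices_per_hemisphere")
  catalog <- dataset$catalog
  contrast_runs <- list()
  anatomy_runs <- list()
  for (s in names(dataset$contrast)) {
    for (si in seq_along(dataset$contrast[[s]])) {
      st <- names(dataset$contrast[[s]])[si]
      m <- dataset$contrast[[s]][[st]]
      for (task in catalog_tasks(catalog)) {
        ids <- catalog$contrast_id[catalog$task_id == task]
        files <- list(lh = list(), rh = list())
        for (cid in ids) {
          for (h in c("lh", "rh")) {
            rows <- if (h == "lh") seq_len(nvh) else nvh + seq_len(nvh)
            rel <- file.path(s, sprintf("rep%d", si),
                             sprintf("%s.%s.%s", cid, h, ext))
            dir.create(file.path(dir, dirname(rel)), recursive = TRUE,
                       showWarnings = FALSE)
            write_overlay(m[rows, cid], file.path(dir, rel), format)
            files[[h]][[cid]] <- rel
          }
        }
        contrast_runs[[length(contrast_runs) + 1L]] <-
          list(subject = s, task = task, repetition = si, session = si,
               files = files)
      }
    }
  }
  for (s in names(dataset$anatomy)) {
    for (st in names(dataset$anatomy[[s]])) {
      for (measure in names(dataset$anatomy[[s]][[st]])) {
        a <- dataset$anatomy[[s]][[st]][[measure]]
        sessions <- attr(a, "sessions")
        for (k in seq_along(sessions)) {
          files <- list()
          for (h in c("lh", "rh")) {
            rows <- if (h == "lh") seq_len(nvh) else nvh + seq_len(nvh)
            rel <- file.path(s, "anat",
                             sprintf("%s.ses%02d.%s.%s", measure,
                                     sessions[k], h, ext))
            dir.create(file.path(dir, dirname(rel)), recursive = TRUE,
                       showWarnings = FALSE)
            write_overlay(a[rows, k], file.path(dir, rel), format)
            files[[h]] <- rel
          }
          anatomy_runs[[length(anatomy_runs) + 1L]] <-
            list(subject = s, session = sessions[k], measure = measure,
                 files = files)
        }
      }
    }
  }
  manifest <- list(n_vertices_per_hemisphere = nvh,
                   contrast_runs = contrast_runs,
                   anatomy_runs = anatomy_runs)
  manifest_file <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_file)
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    jsonlite::write_json(
      list(task_id = truth$task_id,
           rho_within = truth$rho_within,
           rho_between = truth$rho_between,
           masked_vertices_0based = which(!truth$mask) - 1L,
           seed = truth$seed),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(manifest_file)
}
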