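## Assembly of per-subject, per-set matrices from per-run overlays: the
## randomized split-half assignment of task repetitions, left-then-right
## hemisphere concatenation, the odd/even anatomy session split, and the
## complete-data vertex mask.

#' Read a run manifest
#'
#' A run manifest lists, per subject, the overlay files of each task
#' repetition (one file per hemisphere per contrast) and of each anatomy
#' scan session (one file per hemisphere per measure). YAML or JSON,
#' chosen by extension. Relative file paths are resolved against the
#' manifest's directory. Expected structure:
#'
#' ```yaml
#' n_vertices_per_hemisphere: 100
#' contrast_runs:
#' - subject: sub1
#'   task: N-BACK
#'   repetition: 1
#'   session: 5
#'   files:
#'     lh: {"N-BACK_c1": "sub1/rep1/N-BACK_c1.lh.tsv", ...}
#'     rh: {...}
#' anatomy_runs:
#' - subject: sub1
#'   session: 1
#'   measure: thickness
#'   files: {lh: "...", rh: "..."}
#' ```
#'
#' @param path manifest file (`.yaml`/`.yml` or `.json`).
#' @return object of class `run_manifest`.
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_densim(sprintf("manifest '%s' does not exist", path),
                "densim_manifest_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    stop_densim(sprintf("unsupported manifest format '%s'", ext),
                "densim_manifest_error")
  }
  raw$base_dir <- dirname(normalizePath(path))
  validate_run_manifest(raw)
}

validate_run_manifest <- function(x) {
  for (field in c("contrast_runs", "anatomy_runs")) {
    if (is.null(x[[field]]) || !length(x[[field]])) {
      stop_densim(sprintf("manifest lacks '%s' records", field),
                  "densim_manifest_error")
    }
  }
  structure(x, class = "run_manifest")
}

manifest_path <- function(manifest, rel) {
  if (is.null(manifest$base_dir) || grepl("^(/|[A-Za-z]:)", rel)) {
    rel
  } else {
    file.path(manifest$base_dir, rel)
  }
}

contrast_run_index <- function(manifest) {
  recs <- manifest$contrast_runs
  data.frame(subject = vapply(recs, function(r) as.character(r$subject), ""),
             task = vapply(recs, function(r) as.character(r$task), ""),
             repetition = vapply(recs, function(r) as.integer(r$repetition),
                                 0L),
             i = seq_along(recs),
             stringsAsFactors = FALSE)
}

#' Randomly assign task repetitions to split-half sets
#'
#' For every (subject, task) pair the manifest must hold exactly two
#' repetitions (the test and retest administrations). A fair coin from the
#' seeded generator sends repetition 1 to Set1 or Set2; repetition 2 goes
#' to the other set, so every task contributes exactly one repetition to
#' each set. Randomizing the assignment avoids systematic practice-effect
#' differences between the sets.
#'
#' @param manifest a `run_manifest`.
#' @param seed integer seed; same manifest + seed reproduce the assignment.
#' @return data frame of class `set_assignment` with columns `subject`,
#'   `task`, `repetition`, `set`; attribute `seed`.
#' @export
assign_runs_to_sets <- function(manifest, seed) {
  seed <- assert_count(seed, "seed", min = 0L)
  idx <- contrast_run_index(manifest)
  pairs <- unique(idx[c("subject", "task")])
  pairs <- pairs[order(pairs$subject, pairs$task), , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    reps <- sort(idx$repetition[idx$subject == pairs$subject[k] &
                                  idx$task == pairs$task[k]])
    if (!identical(reps, c(1L, 2L))) {
      stop_densim(sprintf("subject %s task %s: need exactly repetitions 1 and 2, found (%s)",
                          pairs$subject[k], pairs$task[k],
                          paste(reps, collapse = ", ")),
                  "densim_manifest_error")
    }
  }
  set.seed(seed)
  first_to_set1 <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    sets <- if (first_to_set1[k]) c("Set1", "Set2") else c("Set2", "Set1")
    data.frame(subject = pairs$subject[k], task = pairs$task[k],
               repetition = 1:2, set = sets, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("set_assignment", "data.frame")
  out
}

#' Fixed repetition-to-set assignment
#'
#' Deterministic assignment sending repetition k to Set k, useful for exact
#' round-trips of datasets whose overlays were written set by set.
#'
#' @param manifest a `run_manifest`.
#' @return a `set_assignment`.
#' @export
identity_set_assignment <- function(manifest) {
  idx <- contrast_run_index(manifest)
  out <- data.frame(subject = idx$subject, task = idx$task,
                    repetition = idx$repetition,
                    set = sprintf("Set%d", idx$repetition),
                    stringsAsFactors = FALSE)
  class(out) <- c("set_assignment", "data.frame")
  out
}

read_hemi_overlay <- function(manifest, rel, nvh, format) {
  v <- read_overlay(manifest_path(manifest, rel), format = format)
  if (is.matrix(v)) v <- v[, 1]
  if (!is.null(nvh) && length(v) != nvh) {
    stop_densim(sprintf("'%s' has %d vertices, expected %d", rel,
                        length(v), nvh),
                "densim_assembly_error")
  }
  v
}

#' Assemble a vertex-by-contrast matrix for one subject and set
#'
#' For each task, picks the repetition assigned to the requested set, reads
#' its per-contrast overlays, horizontally concatenates contrasts in
#' catalog order within each hemisphere, and vertically concatenates the
#' left hemisphere block on top of the right, producing the whole-brain
#' matrix (2 x vertices-per-hemisphere rows). Values are copied unchanged.
#'
#' @param manifest a `run_manifest`.
#' @param assignment a `set_assignment` covering the subject's tasks.
#' @param subject_id,set_id which matrix to build (`set_id` is `"Set1"` or
#'   `"Set2"`).
#' @param catalog [task_catalog()] fixing the contrast column order.
#' @param format overlay format passed to [read_overlay()].
#' @return a `contrast_matrix` (matrix with subject/set attributes).
#' @export
assemble_contrast_matrix <- function(manifest, assignment, subject_id,
                                     set_id, catalog, format = "auto") {
  idx <- contrast_run_index(manifest)
  nvh <- manifest$n_vertices_per_hemisphere
  tasks <- catalog_tasks(catalog)
  lh_cols <- list(); rh_cols <- list()
  for (task in tasks) {
    a <- assignment[assignment$subject == subject_id &
                      assignment$task == task &
                      assignment$set == set_id, , drop = FALSE]
    if (nrow(a) != 1L) {
      stop_densim(sprintf("no unique repetition of task %s assigned to %s for %s",
                          task, set_id, subject_id),
                  "densim_assembly_error")
    }
    k <- idx$i[idx$subject == subject_id & idx$task == task &
                 idx$repetition == a$repetition]
    if (length(k) != 1L) {
      stop_densim(sprintf("manifest lacks run record: %s task %s repetition %d",
                          subject_id, task, a$repetition),
                  "densim_assembly_error")
    }
    rec <- manifest$contrast_runs[[k]]
    ids <- catalog$contrast_id[catalog$task_id == task]
    for (cid in ids) {
      for (h in c("lh", "rh")) {
        rel <- rec$files[[h]][[cid]]
        if (is.null(rel)) {
          stop_densim(sprintf("missing %s overlay for contrast %s (%s, %s)",
                              h, cid, subject_id, set_id),
                      "densim_assembly_error")
        }
        v <- read_hemi_overlay(manifest, rel, nvh, format)
        if (is.null(nvh)) nvh <- length(v)
        if (h == "lh") lh_cols[[cid]] <- v else rh_cols[[cid]] <- v
      }
    }
  }
  lh <- do.call(cbind, lh_cols[catalog$contrast_id])
  rh <- do.call(cbind, rh_cols[catalog$contrast_id])
  if (nrow(lh) != nrow(rh)) {
    stop_densim("hemispheres have unequal vertex counts",
                "densim_assembly_error")
  }
  m <- rbind(lh, rh)
  colnames(m) <- catalog$contrast_id
  structure(m, subject_id = subject_id, set_id = set_id,
            n_vertices_per_hemisphere = nrow(lh),
            class = c("contrast_matrix", class(m)))
}

#' Split anatomy scan sessions into odd/even sets
#'
#' Odd-numbered sessions go to Set1, even-numbered to Set2, each in
#' ascending order. If the two parities yield unequal counts, both lists
#' are truncated to the shorter length (dropping the latest sessions), so
#' the two sets have equal, pairable column counts.
#'
#' @param session_indices integer session numbers.
#' @return list with `set1` and `set2` integer vectors.
#' @examples
#' split_anatomy_sessions(1:9)  # set1 = 1,3,5,7 (9 dropped), set2 = 2,4,6,8
#' @export
split_anatomy_sessions <- function(session_indices) {
  s <- sort(unique(as.integer(session_indices)))
  odd <- s[s %% 2L == 1L]
  even <- s[s %% 2L == 0L]
  if (length(odd) == 0L || length(even) == 0L) {
    stop_densim("need at least one odd- and one even-numbered session",
                "densim_assembly_error")
  }
  k <- min(length(odd), length(even))
  list(set1 = odd[seq_len(k)], set2 = even[seq_len(k)])
}

#' Assemble a vertex-by-session anatomy matrix
#'
#' Columns are the requested set's scan sessions in ascending order (odd
#' sessions for Set1, even for Set2, truncated to equal counts); rows are
#' the left hemisphere block then the right, as in
#' [assemble_contrast_matrix()].
#'
#' @inheritParams assemble_contrast_matrix
#' @param measure anatomy measure name (e.g. `"thickness"`).
#' @return an `anatomy_matrix`.
#' @export
assemble_anatomy_matrix <- function(manifest, subject_id, set_id, measure,
                                    format = "auto") {
  recs <- manifest$anatomy_runs
  mine <- Filter(function(r) {
    identical(as.character(r$subject), subject_id) &&
      identical(as.character(r$measure), measure)
  }, recs)
  if (!length(mine)) {
    stop_densim(sprintf("no anatomy runs for %s measure %s", subject_id,
                        measure),
                "densim_assembly_error")
  }
  sessions <- vapply(mine, function(r) as.integer(r$session), 0L)
  split <- split_anatomy_sessions(sessions)
  wanted <- if (identical(set_id, "Set1")) split$set1 else split$set2
  nvh <- manifest$n_vertices_per_hemisphere
  cols <- lapply(wanted, function(ses) {
    rec <- mine[[match(ses, sessions)]]
    lh <- read_hemi_overlay(manifest, rec$files$lh, nvh, format)
    rh <- read_hemi_overlay(manifest, rec$files$rh, nvh, format)
    if (length(lh) != length(rh)) {
      stop_densim(sprintf("session %d: hemispheres have unequal vertex counts",
                          ses),
                  "densim_assembly_error")
    }
    c(lh, rh)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("ses%02d", wanted)
  structure(m, subject_id = subject_id, set_id = set_id, measure = measure,
            sessions = wanted,
            n_vertices_per_hemisphere = nrow(m) %/% 2L,
            class = c("anatomy_matrix", class(m)))
}

#' Complete-data vertex mask
#'
#' A vertex row is kept only if it carries no missing value in any matrix
#' entering the analysis (functional and anatomical, all subjects and
#' sets); rows failing anywhere are removed everywhere, avoiding missing
#' cases in the similarity and regression stages.
#'
#' @param matrices list of matrices sharing the row count.
#' @return logical keep-flag per vertex row, with attribute
#'   `retained_count`; the removed count is reported with a message.
#' @export
compute_complete_mask <- function(matrices) {
  if (!length(matrices)) {
    stop_densim("no matrices supplied", "densim_input_error")
  }
  n <- nrow(matrices[[1]])
  if (any(vapply(matrices, nrow, 0L) != n)) {
    stop_densim("matrices have differing row counts", "densim_input_error")
  }
  keep <- rep(TRUE, n)
  for (m in matrices) {
    keep <- keep & rowSums(is.na(m)) == 0L
  }
  attr(keep, "retained_count") <- sum(keep)
  message(sprintf("compute_complete_mask: retained %d of %d vertices (%d removed)",
                  sum(keep), n, n - sum(keep)))
  keep
}

#' Assemble a full dataset from a run manifest
#'
#' Convenience orchestration: assigns repetitions to sets (seeded, or via a
#' supplied assignment), assembles every contrast and anatomy matrix, and
#' computes the complete-data mask.
#'
#' @param manifest a `run_manifest`.
#' @param catalog a [task_catalog()].
#' @param seed seed for [assign_runs_to_sets()]; ignored when `assignment`
#'   is given.
#' @param assignment optional `set_assignment` (e.g.
#'   [identity_set_assignment()]).
#' @param format overlay format.
#' @return a `densim_dataset` (without simulation truth).
#' @export
assemble_dataset <- function(manifest, catalog = default_task_catalog(),
                             seed = 1L, assignment = NULL,
                             format = "auto") {
  if (is.null(assignment)) {
    assignment <- assign_runs_to_sets(manifest, seed)
  }
  subjects <- unique(contrast_run_index(manifest)$subject)
  sets <- c("Set1", "Set2")
  measures <- unique(vapply(manifest$anatomy_runs,
                            function(r) as.character(r$measure), ""))
  contrast <- lapply(subjects, function(s) {
    out <- lapply(sets, function(st) {
      assemble_contrast_matrix(manifest, assignment, s, st, catalog, format)
    })
    names(out) <- sets
    out
  })
  names(contrast) <- subjects
  anatomy <- lapply(subjects, function(s) {
    per_set <- lapply(sets, function(st) {
      out <- lapply(measures, function(m) {
        assemble_anatomy_matrix(manifest, s, st, m, format)
      })
      names(out) <- measures
      out
    })
    names(per_set) <- sets
    per_set
  })
  names(anatomy) <- subjects
  all_mats <- c(unlist(lapply(contrast, unname), recursive = FALSE),
                unlist(lapply(anatomy, function(a) {
                  unlist(lapply(a, unname), recursive = FALSE)
                }), recursive = FALSE))
  mask <- suppressMessages(compute_complete_mask(all_mats))
  structure(list(contrast = contrast, anatomy = anatomy, mask = mask,
                 catalog = catalog, truth = NULL,
                 assignment = assignment, manifest = manifest),
            class = "densim_dataset")
}
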