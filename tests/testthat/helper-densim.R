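## Shared fixtures and independent oracles.

## truncate doubles to float32 (MGH storage precision); NA stays NA
to_float32 <- function(x) {
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 "numeric", n = length(x), size = 4L)
  out[is.na(x)] <- NA_real_
  out
}

## brute-force two-pass Pearson correlation of two vectors
brute_pearson <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

## a small two-task simulation config with equal variances everywhere
toy_sim_config <- function(n_vertices_per_hemisphere = 50, seed = 1,
                           n_contrasts = c(3, 4),
                           sigma2 = c(0.25, 0.25, 0.5), ...) {
  specs <- default_task_specs(
    task_catalog(paste0("T", seq_along(n_contrasts)), n_contrasts),
    sigma2_shared = sigma2[1], sigma2_person = sigma2[2],
    sigma2_noise = sigma2[3])
  sim_config(n_vertices_per_hemisphere, task_specs = specs, seed = seed, ...)
}

## in-memory run manifest with just the fields the set-assignment needs
toy_assignment_manifest <- function(subjects = c("s1", "s2"),
                                    tasks = paste0("T", 1:3)) {
  runs <- list()
  for (s in subjects) {
    for (tk in tasks) {
      for (r in 1:2) {
        runs[[length(runs) + 1L]] <-
          list(subject = s, task = tk, repetition = r, session = r)
      }
    }
  }
  structure(list(n_vertices_per_hemisphere = 4L,
                 contrast_runs = runs,
                 anatomy_runs = list(list(subject = subjects[1], session = 1,
                                          measure = "thickness",
                                          files = list()))),
            class = "run_manifest")
}

## dataset constructed from explicit matrices (bypassing the generator)
manual_dataset <- function(contrast, anatomy = NULL, mask = NULL) {
  n <- nrow(contrast[[1]][[1]])
  structure(list(contrast = contrast, anatomy = anatomy,
                 mask = if (is.null(mask)) rep(TRUE, n) else mask,
                 catalog = NULL, truth = NULL),
            class = "densim_dataset")
}
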