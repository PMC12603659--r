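test_that("set assignment is balanced, deterministic, and a fair coin", {
  man <- toy_assignment_manifest(tasks = paste0("T", 1:22))
  a1 <- assign_runs_to_sets(man, seed = 5)
  ## every (subject, task) contributes one repetition per set
  for (s in unique(a1$subject)) {
    per_task <- table(a1$task[a1$subject == s], a1$set[a1$subject == s])
    expect_true(all(per_task == 1L))
  }
  expect_identical(assign_runs_to_sets(man, seed = 5), a1)
  expect_false(identical(assign_runs_to_sets(man, seed = 6), a1))

  ## repetition 1 lands in Set1 about half the time across seeds
  man1 <- toy_assignment_manifest(subjects = "s1", tasks = "T1")
  hits <- sum(vapply(1:1000, function(seed) {
    a <- assign_runs_to_sets(man1, seed)
    a$set[a$repetition == 1L] == "Set1"
  }, logical(1)))
  expect_gt(hits, 500 - 3 * sqrt(250))
  expect_lt(hits, 500 + 3 * sqrt(250))
})

test_that("manifests without both repetitions are rejected", {
  man <- toy_assignment_manifest(subjects = "s1", tasks = "T1")
  man$contrast_runs <- man$contrast_runs[1]
  expect_error(assign_runs_to_sets(man, 1), "repetitions 1 and 2")
})

test_that("hemisphere concatenation is left block then right, catalog order", {
  dir <- withr::local_tempdir()
  cat1 <- task_catalog("A", 2)
  files <- list(lh = list(), rh = list())
  for (cid in cat1$contrast_id) {
    for (h in c("lh", "rh")) {
      base <- if (h == "lh") 0 else 100
      off <- if (cid == "A_c1") 0 else 10
      p <- file.path(dir, sprintf("%s_%s.tsv", cid, h))
      write_overlay(base + off + 1:3, p)
      files[[h]][[cid]] <- p
    }
  }
  man <- structure(list(
    n_vertices_per_hemisphere = 3L,
    contrast_runs = list(
      list(subject = "s1", task = "A", repetition = 1, session = 1,
           files = files),
      list(subject = "s1", task = "A", repetition = 2, session = 2,
           files = files)),
    anatomy_runs = list(list(subject = "s1", session = 1,
                             measure = "thickness", files = list()))),
    class = "run_manifest")
  m <- assemble_contrast_matrix(man, identity_set_assignment(man), "s1",
                                "Set1", cat1)
  expect_identical(dim(m), c(6L, 2L))
  expect_identical(colnames(m), c("A_c1", "A_c2"))
  expect_equal(unname(m[, "A_c1"]), c(1:3, 101:103))   # lh rows 0-2
  expect_equal(unname(m[, "A_c2"]), c(11:13, 111:113))
  ## a missing overlay aborts with the contrast named
  man2 <- man
  man2$contrast_runs[[1]]$files$rh$A_c2 <- NULL
  expect_error(assemble_contrast_matrix(man2, identity_set_assignment(man2),
                                        "s1", "Set1", cat1),
               "A_c2")
})

test_that("anatomy sessions split odd/even with truncation", {
  expect_identical(split_anatomy_sessions(1:8),
                   list(set1 = c(1L, 3L, 5L, 7L), set2 = c(2L, 4L, 6L, 8L)))
  expect_identical(split_anatomy_sessions(1:9)$set1, c(1L, 3L, 5L, 7L))
  expect_identical(split_anatomy_sessions(c(3, 1, 2)),
                   list(set1 = 1L, set2 = 2L))
  expect_error(split_anatomy_sessions(c(2, 4)), "odd")
})

test_that("complete-data mask removes a vertex missing anywhere", {
  m1 <- matrix(rnorm(24), nrow = 6)
  m2 <- matrix(rnorm(12), nrow = 6)
  expect_identical(sum(suppressMessages(compute_complete_mask(list(m1, m2)))),
                   6L)
  m2[3, 2] <- NA
  mask <- suppressMessages(compute_complete_mask(list(m1, m2)))
  expect_identical(attr(mask, "retained_count"), 5L)
  expect_false(mask[3])
  expect_message(compute_complete_mask(list(m1, m2)), "retained 5 of 6")
  expect_error(compute_complete_mask(list(m1, m2[1:4, ])), "row counts")
})

test_that("assembled overlays round-trip the generator exactly", {
  dir <- withr::local_tempdir()
  cfg <- toy_sim_config(30, seed = 17, medial_mask_fraction = 0.1)
  ds <- generate_dataset(cfg)
  for (fmt in c("tsv", "gifti")) {
    sub <- file.path(dir, fmt)
    mf <- write_dataset(ds, sub, format = fmt)
    man <- read_run_manifest(mf)
    asm <- assemble_dataset(man, catalog = ds$catalog,
                            assignment = identity_set_assignment(man))
    for (s in names(ds$contrast)) {
      for (st in names(ds$contrast[[s]])) {
        expect_equal(unclass(asm$contrast[[s]][[st]])[, ],
                     unclass(ds$contrast[[s]][[st]])[, ],
                     tolerance = 0, info = fmt)
      }
      expect_equal(unclass(asm$anatomy[[s]]$Set2$sulc)[, ],
                   unclass(ds$anatomy[[s]]$Set2$sulc)[, ], tolerance = 0)
    }
    ## the complete-data mask equals the generator's truth mask
    expect_identical(as.logical(asm$mask), ds$truth$mask)
    expect_identical(attr(asm$mask, "retained_count"), sum(ds$truth$mask))
  }
})
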