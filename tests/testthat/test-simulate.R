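test_that("expected_similarity follows the variance-ratio formula", {
  expect_equal(expected_similarity(1, 1, 2), c(within = 0.5, between = 0.25))
  expect_equal(expected_similarity(1, 0, 1), c(within = 0.5, between = 0.5))
  expect_equal(expected_similarity(0.6, 0.3, 0.1),
               c(within = 0.9, between = 0.6))
  expect_error(expected_similarity(0, 0, 0), "undefined")
  expect_error(expected_similarity(-1, 0, 1), "must be >=")
})

test_that("default catalog partitions 112 contrasts over 22 tasks", {
  cat22 <- default_task_catalog()
  expect_length(catalog_tasks(cat22), 22L)
  expect_identical(nrow(cat22), 112L)
  expect_false(anyDuplicated(cat22$contrast_id) > 0)
  ## every contrast maps to exactly one task
  expect_true(all(table(cat22$contrast_id) == 1L))
})

test_that("generated matrices have config-forced dimensions", {
  cfg <- toy_sim_config(100, n_contrasts = c(2, 3, 5))
  ds <- generate_dataset(cfg)
  expect_length(ds$contrast, 2L)
  for (s in names(ds$contrast)) {
    for (st in names(ds$contrast[[s]])) {
      expect_identical(dim(ds$contrast[[s]][[st]]), c(200L, 10L))
    }
    expect_identical(dim(ds$anatomy[[s]]$Set1$thickness), c(200L, 4L))
  }
})

test_that("same seed reproduces the dataset bit for bit", {
  cfg <- toy_sim_config(40, seed = 99, medial_mask_fraction = 0.2)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$contrast, d2$contrast)
  expect_identical(d1$anatomy, d2$anatomy)
  expect_identical(d1$mask, d2$mask)
  d3 <- generate_dataset(toy_sim_config(40, seed = 100,
                                        medial_mask_fraction = 0.2))
  expect_false(identical(d1$contrast, d3$contrast))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(0), "must be >=")
  specs <- default_task_specs(task_catalog("A", 3),
                              sigma2_shared = -0.1, sigma2_person = 0.2,
                              sigma2_noise = 0.2)
  expect_error(sim_config(10, task_specs = specs), "non-negative")
  specs0 <- default_task_specs(task_catalog("A", 3), 0, 0, 0)
  expect_error(sim_config(10, task_specs = specs0), "positive variance")
  expect_error(sim_config(10, medial_mask_fraction = 1), "< 1")
})

test_that("masked vertices are NA everywhere and recorded in the truth", {
  cfg <- toy_sim_config(50, seed = 5, medial_mask_fraction = 0.3)
  ds <- generate_dataset(cfg)
  expect_identical(sum(!ds$mask), 30L)  # floor(0.3 * 100)
  bad <- which(!ds$mask)
  expect_true(all(is.na(ds$contrast$sub1$Set2[bad, ])))
  expect_true(all(is.na(ds$anatomy$sub2$Set1$curvature[bad, ])))
  expect_true(all(!is.na(ds$contrast$sub1$Set1[ds$mask, ])))
  expect_identical(ds$truth$mask, as.logical(ds$mask))
})

test_that("truth similarities respect the within >= between ordering", {
  cfg <- toy_sim_config(10, n_contrasts = c(4, 4, 4),
                        sigma2 = c(0.2, 0.3, 0.5))
  tr <- generate_dataset(cfg)$truth
  expect_true(all(tr$rho_within >= tr$rho_between))
  expect_true(all(tr$rho_within >= 0 & tr$rho_within <= 1))
  cfg0 <- toy_sim_config(10, sigma2 = c(0.5, 0, 0.5))
  tr0 <- generate_dataset(cfg0)$truth
  expect_equal(tr0$rho_within, tr0$rho_between)
})

test_that("empirical vertex similarities match the analytic expectation", {
  cfg <- toy_sim_config(1500, seed = 11, n_contrasts = c(56, 56),
                        sigma2 = c(0.25, 0.25, 0.5))
  ds <- generate_dataset(cfg)
  w <- mean(within_person_vertex_similarity(ds))
  b <- mean(between_person_vertex_similarity(ds))
  expect_lt(abs(w - 0.5), 0.03)
  expect_lt(abs(b - 0.25), 0.03)
  ## within > between by much more than chance at these sizes
  expect_gt(w - b, 0.2)
})

test_that("the within-between gap grows with the person variance", {
  gap <- function(s2p, seed) {
    cfg <- toy_sim_config(150, seed = seed, n_contrasts = c(56, 56),
                          sigma2 = c(0.2, s2p, 0.6))
    ds <- generate_dataset(cfg)
    mean(within_person_vertex_similarity(ds)) -
      mean(between_person_vertex_similarity(ds))
  }
  grid <- c(0, 0.2, 0.5)
  gaps <- sapply(grid, function(s2p) {
    mean(sapply(1:20, function(seed) gap(s2p, seed)))
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("anatomy coupling inflates the expected within-person similarity", {
  cfg0 <- toy_sim_config(20, anatomy_coupling = 0)
  cfg1 <- toy_sim_config(20, anatomy_coupling = 0.8)
  expect_true(all(generate_dataset(cfg1)$truth$rho_within >
                    generate_dataset(cfg0)$truth$rho_within))
})
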