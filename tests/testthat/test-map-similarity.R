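make_map_dataset <- function(n = 40, k = 6, seed = 1, n_subjects = 2) {
  set.seed(seed)
  mats <- lapply(seq_len(n_subjects), function(i) {
    out <- lapply(1:2, function(s) {
      m <- matrix(rnorm(n * k), nrow = n)
      colnames(m) <- sprintf("T1_c%d", seq_len(k))
      m
    })
    names(out) <- c("Set1", "Set2")
    out
  })
  names(mats) <- paste0("sub", seq_len(n_subjects))
  manual_dataset(mats)
}

test_that("map similarity averages per-contrast correlations over subjects", {
  ds <- make_map_dataset(seed = 2)
  w <- within_person_map_similarity(ds)
  manual <- (unname(columnwise_pearson(ds$contrast$sub1$Set1,
                                       ds$contrast$sub1$Set2)) +
               unname(columnwise_pearson(ds$contrast$sub2$Set1,
                                         ds$contrast$sub2$Set2))) / 2
  expect_equal(unname(unclass(w)), manual, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_identical(names(w), sprintf("T1_c%d", 1:6))

  ds$contrast$sub1$Set2 <- ds$contrast$sub1$Set1
  ds$contrast$sub2$Set2 <- ds$contrast$sub2$Set1
  expect_equal(unname(unclass(within_person_map_similarity(ds))),
               rep(1, 6), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("between-person map similarity averages set-matched pairs", {
  ds <- make_map_dataset(seed = 3)
  b <- between_person_map_similarity(ds)
  manual <- (unname(columnwise_pearson(ds$contrast$sub1$Set1,
                                       ds$contrast$sub2$Set1)) +
               unname(columnwise_pearson(ds$contrast$sub1$Set2,
                                         ds$contrast$sub2$Set2))) / 2
  expect_equal(unname(unclass(b)), manual, tolerance = 1e-14,
               ignore_attr = TRUE)
  ## invariant to subject relabeling
  ds2 <- ds; ds2$contrast <- rev(ds2$contrast)
  expect_equal(unclass(between_person_map_similarity(ds2)), unclass(b),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("paired t-test matches hand computation and the K - 1 df rule", {
  b <- rnorm(3)
  w <- b + c(1, 2, 3)
  r <- paired_t_test(w, b)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_identical(r$df, 2)
  set.seed(5)
  w112 <- rnorm(112, 0.37, 0.2); b112 <- rnorm(112, 0.18, 0.13)
  expect_identical(paired_t_test(w112, b112)$df, 111)
  expect_error(paired_t_test(b, b), "zero variance")
})

test_that("Welch t-test matches the direct formulas", {
  a <- c(1, 2, 3, 5); b <- c(2, 3)
  r <- welch_t_test(a, b)
  se2 <- var(a) / 4 + var(b) / 2
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 2)^2 / 1)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$df, df_hand, tolerance = 1e-10)
  ## balanced equal-variance case reduces to Student's t with 2n - 2 df
  set.seed(6)
  x <- rnorm(10); y <- rnorm(10)
  y <- (y - mean(y)) / sd(y) * sd(x)  # force equal sample variance
  rw <- welch_t_test(x, y)
  expect_equal(rw$df, 18, tolerance = 1e-10)
  expect_equal(rw$statistic, t.test(x, y, var.equal = TRUE)$statistic[[1]],
               tolerance = 1e-10)
})

test_that("cohort between-person similarity aggregates pairwise correlations", {
  set.seed(7)
  cohort <- lapply(1:4, function(i) {
    m <- matrix(rnorm(30 * 5), nrow = 30)
    colnames(m) <- sprintf("T1_c%d", 1:5)
    m
  })
  per_pair <- cohort_between_similarity(cohort)
  expect_length(per_pair, choose(4, 2))
  per_contrast <- cohort_between_similarity(cohort,
                                            aggregation = "per_contrast")
  expect_length(per_contrast, 5)
  ## identical subjects correlate perfectly
  same <- cohort_between_similarity(list(cohort[[1]], cohort[[1]],
                                         cohort[[1]]))
  expect_equal(same, rep(1, 3), tolerance = 1e-12)
  expect_error(cohort_between_similarity(cohort[1]), "at least 2")
  ## a known-variance cohort recovers the analytic between-person value
  cfgc <- toy_sim_config(400, seed = 8, n_contrasts = c(56, 56),
                         sigma2 = c(0.25, 0.25, 0.5), n_subjects = 10)
  dsc <- generate_dataset(cfgc)
  one_each <- lapply(dsc$contrast, function(x) x$Set1)
  sc <- cohort_between_similarity(one_each)
  expect_length(sc, choose(10, 2))
  expect_lt(abs(mean(sc) - 0.25), 0.05)
})
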