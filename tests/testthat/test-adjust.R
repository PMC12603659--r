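make_anat_lists <- function(n, seed = 1) {
  set.seed(seed)
  list(within = list(thickness = rnorm(n), area = rnorm(n),
                     curvature = rnorm(n), sulc = rnorm(n)),
       between = list(thickness = rnorm(n), area = rnorm(n),
                      curvature = rnorm(n), sulc = rnorm(n)))
}

test_that("regression table stacks within then between and drops incomplete rows", {
  an <- make_anat_lists(10)
  fw <- rnorm(10); fb <- rnorm(10)
  tab <- build_regression_table(fw, fb, an$within, an$between)
  expect_identical(nrow(tab), 20L)
  expect_identical(levels(tab$kind), c("within", "between"))
  expect_identical(as.character(tab$kind[1:10]), rep("within", 10))
  expect_equal(tab$y, c(fw, fb))

  ## one missing anatomy value drops only that vertex's within row
  an$within$sulc[3] <- NA
  tab2 <- suppressMessages(build_regression_table(fw, fb, an$within,
                                                  an$between))
  expect_identical(nrow(tab2), 19L)
  expect_identical(attr(tab2, "n_dropped"), 1L)
  expect_false(any(tab2$kind == "within" & tab2$vertex == 2L))
  expect_true(any(tab2$kind == "between" & tab2$vertex == 2L))
})

test_that("exact linear responses are recovered with zero residuals", {
  an <- make_anat_lists(10, seed = 2)
  y_w <- 0.1 + 0.5 * an$within$thickness
  y_b <- 0.1 + 0.5 * an$between$thickness
  tab <- build_regression_table(y_w, y_b, an$within, an$between)
  ## lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_anatomy_model(tab))
  expect_equal(unname(fit$coefficients),
               c(0.1, 0.5, 0, 0, 0), tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("coefficients solve the normal equations", {
  an <- make_anat_lists(8, seed = 3)
  set.seed(4)
  fw <- rnorm(8); fb <- rnorm(8)
  tab <- build_regression_table(fw, fb, an$within, an$between)
  fit <- fit_anatomy_model(tab)
  X <- cbind(1, tab$thickness, tab$area, tab$curvature, tab$sulc)
  beta <- solve(t(X) %*% X, t(X) %*% tab$y)
  expect_equal(unname(fit$coefficients), as.numeric(beta),
               tolerance = 1e-10)
  ## residuals sum to zero with an intercept; standardized: mean 0, SD 1
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  expect_equal(mean(fit$std_residuals), 0, tolerance = 1e-10)
  expect_equal(sd(fit$std_residuals), 1, tolerance = 1e-10)
})

test_that("collinear predictors produce a named error", {
  an <- make_anat_lists(10, seed = 5)
  an$within$sulc <- an$within$curvature
  an$between$sulc <- an$between$curvature
  tab <- build_regression_table(rnorm(10), rnorm(10), an$within, an$between)
  expect_error(fit_anatomy_model(tab), "sulc")
})

test_that("pooled Cohen's d matches hand computations and printed values", {
  expect_equal(cohens_d_pooled(c(1, 5), c(2, 4)), 0)
  expect_equal(cohens_d_pooled(c(1, 2), c(0, 1)), sqrt(2),
               tolerance = 1e-12)
  ## summary-statistic form on rounded published residual and map stats
  expect_equal(cohens_d_from_stats(0.43, 0.82, -0.43, 0.98), 0.95,
               tolerance = 0.005)
  expect_equal(cohens_d_from_stats(0.37, 0.2, 0.18, 0.13), 1.13,
               tolerance = 0.005)
  expect_error(cohens_d_pooled(c(1, 1), c(1, 1)), "pooled")
})

test_that("exhaustive permutation enumerates all label splits", {
  r <- permutation_mean_diff_test(c(1, 2, 3), c(4, 5, 6), exhaustive = TRUE)
  expect_identical(r$n_iterations, 20L)  # choose(6, 3)
  expect_equal(r$observed_diff, -3)
  expect_equal(r$p_value, 0.1)           # observed split and its mirror
  expect_equal(r$perm_range, c(-3, 3))
  ## identical groups: every permutation is as extreme
  r0 <- permutation_mean_diff_test(c(1, 2, 3), c(1, 2, 3),
                                   exhaustive = TRUE)
  expect_equal(r0$observed_diff, 0)
  expect_equal(r0$p_value, 1)
})

test_that("sampled permutation converges to the exhaustive p-value", {
  r <- permutation_mean_diff_test(c(1, 2, 3), c(4, 5, 6),
                                  n_iterations = 50000, seed = 1)
  expect_lt(abs(r$p_value - 0.1), 3 * sqrt(0.1 * 0.9 / 50000))
  ## second fixture, n = 10 pooled values
  set.seed(20)
  a <- rnorm(5); b <- rnorm(5) + 1
  p_ex <- permutation_mean_diff_test(a, b, exhaustive = TRUE)$p_value
  r2 <- permutation_mean_diff_test(a, b, n_iterations = 50000, seed = 2)
  expect_lt(abs(r2$p_value - p_ex),
            3 * sqrt(p_ex * (1 - p_ex) / 50000) + 1e-6)
})

test_that("permutation test is deterministic given a seed and respects options", {
  a <- rnorm(30, 0.3); b <- rnorm(30)
  r1 <- permutation_mean_diff_test(a, b, n_iterations = 500, seed = 7)
  r2 <- permutation_mean_diff_test(a, b, n_iterations = 500, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$perm_range, r2$perm_range)
  r3 <- permutation_mean_diff_test(a, b, n_iterations = 500, seed = 7,
                                   p_correction = "add_one")
  expect_gt(r3$p_value, 0)
  r4 <- permutation_mean_diff_test(a, b, n_iterations = 500, seed = 7,
                                   alternative = "greater")
  expect_lte(abs(r4$p_value - r1$p_value / 2), 0.05)
  expect_error(permutation_mean_diff_test(numeric(0), b), "non-empty")
})

test_that("residualization shrinks an anatomy-carried similarity gap", {
  ## construct scores where the within/between gap is partly mediated by
  ## anatomical similarity: y depends on thickness, and thickness differs
  ## by kind
  set.seed(31)
  n <- 1000
  an <- list(within = list(thickness = rnorm(n, 0.5, 0.1),
                           area = rnorm(n, 0, 0.1),
                           curvature = rnorm(n, 0, 0.1),
                           sulc = rnorm(n, 0, 0.1)),
             between = list(thickness = rnorm(n, 0.1, 0.1),
                            area = rnorm(n, 0, 0.1),
                            curvature = rnorm(n, 0, 0.1),
                            sulc = rnorm(n, 0, 0.1)))
  y_w <- 0.1 + 0.6 * an$within$thickness + rnorm(n, 0, 0.05) + 0.02
  y_b <- 0.1 + 0.6 * an$between$thickness + rnorm(n, 0, 0.05)
  tab <- build_regression_table(y_w, y_b, an$within, an$between)
  fit <- fit_anatomy_model(tab)
  z_raw <- (tab$y - mean(tab$y)) / sd(tab$y)
  gap_raw <- mean(z_raw[tab$kind == "within"]) -
    mean(z_raw[tab$kind == "between"])
  gap_res <- mean(fit$std_residuals[tab$kind == "within"]) -
    mean(fit$std_residuals[tab$kind == "between"])
  expect_lt(gap_res, gap_raw)
  expect_gt(gap_res, 0)  # the direct (non-anatomical) offset survives
})

test_that("permutation power grows with the person-specific variance", {
  run_p <- function(s2p, seed) {
    cfg <- toy_sim_config(150, seed = seed, n_contrasts = c(56, 56),
                          sigma2 = c(0.2, s2p, 0.8 - s2p))
    ds <- generate_dataset(cfg)
    fw <- within_person_vertex_similarity(ds)
    fb <- between_person_vertex_similarity(ds)
    aw <- lapply(c(thickness = "thickness", area = "area",
                   curvature = "curvature", sulc = "sulc"),
                 function(m) within_person_vertex_similarity(ds, m))
    ab <- lapply(c(thickness = "thickness", area = "area",
                   curvature = "curvature", sulc = "sulc"),
                 function(m) between_person_vertex_similarity(ds, m))
    tab <- build_regression_table(fw, fb, aw, ab)
    fit <- fit_anatomy_model(tab)
    permutation_mean_diff_test(fit$std_residuals[tab$kind == "within"],
                               fit$std_residuals[tab$kind == "between"],
                               n_iterations = 500, seed = seed)
  }
  r <- run_p(0.3, 1)
  expect_gt(r$observed_diff, 0)
  expect_lt(r$p_value, 0.05)
})
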