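#' Analytic similarity expectations of the variance-components model
#'
#' Under the generative model `x = g + p + e` with independent Gaussian
#' shared (`g`), person-specific (`p`), and session-noise (`e`) components,
#' the expected Pearson correlation between two sessions of the same person
#' is `(s2_shared + s2_person) / (s2_shared + s2_person + s2_noise)`, and
#' between matched sessions of two people it is
#' `s2_shared / (s2_shared + s2_person + s2_noise)`.
#'
#' @param sigma2_shared,sigma2_person,sigma2_noise non-negative variance
#'   components; not all zero.
#' @return named numeric vector `c(within = ..., between = ...)`.
#' @examples
#' expected_similarity(1, 1, 2)  # within 0.5, between 0.25
#' @export
expected_similarity <- function(sigma2_shared, sigma2_person, sigma2_noise) {
  assert_scalar_number(sigma2_shared, "sigma2_shared", min = 0)
  assert_scalar_number(sigma2_person, "sigma2_person", min = 0)
  assert_scalar_number(sigma2_noise, "sigma2_noise", min = 0)
  total <- sigma2_shared + sigma2_person + sigma2_noise
  if (total == 0) {
    stop_densim("all variance components are zero: similarity undefined",
                "densim_config_error")
  }
  c(within = (sigma2_shared + sigma2_person) / total,
    between = sigma2_shared / total)
}

#' Default per-task variance components
#'
#' Builds the simulator's per-task `(sigma2_shared, sigma2_person,
#' sigma2_noise)` table from a catalog and a per-task reliability profile.
#' By default the profile is taken from [task_median_reference()]: each
#' task's shared variance is set to its reference between-person median
#' (floored at 0), the person variance to the within-minus-between gap
#' (floored at 0), and the noise variance tops the total up to 1, so the
#' model's expected similarities emulate the published spread of task
#' reliabilities. Pass explicit variances to override.
#'
#' @param catalog a [task_catalog()]; default [default_task_catalog()].
#' @param sigma2_shared,sigma2_person,sigma2_noise optional scalars or
#'   per-task vectors; when given they replace the reference-derived
#'   profile.
#' @return data frame with columns `task_id`, `n_contrasts`,
#'   `sigma2_shared`, `sigma2_person`, `sigma2_noise`.
#' @export
default_task_specs <- function(catalog = default_task_catalog(),
                               sigma2_shared = NULL, sigma2_person = NULL,
                               sigma2_noise = NULL) {
  tasks <- catalog_tasks(catalog)
  n_contrasts <- as.integer(table(factor(catalog$task_id, levels = tasks)))
  if (is.null(sigma2_shared) || is.null(sigma2_person) ||
      is.null(sigma2_noise)) {
    ref <- task_median_reference()
    idx <- match(tasks, ref$task_id)
    if (anyNA(idx)) {
      ## catalogs without reference rows fall back to a flat profile
      rho_b <- rep(0.18, length(tasks))
      rho_w <- rep(0.37, length(tasks))
    } else {
      rho_b <- pmax(ref$median_between[idx], 0)
      rho_w <- pmax(ref$median_within[idx], rho_b)
    }
    shared <- rho_b
    person <- rho_w - rho_b
    noise <- 1 - rho_w
  } else {
    shared <- rep_len(sigma2_shared, length(tasks))
    person <- rep_len(sigma2_person, length(tasks))
    noise <- rep_len(sigma2_noise, length(tasks))
  }
  data.frame(task_id = tasks, n_contrasts = n_contrasts,
             sigma2_shared = shared, sigma2_person = person,
             sigma2_noise = noise, stringsAsFactors = FALSE)
}

#' Default anatomy variance components
#'
#' Anatomical measures are highly stable across sessions within a person
#' and substantially shared across people; the defaults give all four
#' measures a large shared component, a moderate person-specific component,
#' and small session noise (expected within-person similarity 0.95,
#' between-person 0.6).
#'
#' @param measures character vector of measure names.
#' @param sigma2_shared,sigma2_person,sigma2_noise scalars or per-measure
#'   vectors.
#' @return data frame with columns `measure`, `sigma2_shared`,
#'   `sigma2_person`, `sigma2_noise`.
#' @export
default_anatomy_specs <- function(measures = c("thickness", "area",
                                               "curvature", "sulc"),
                                  sigma2_shared = 0.6,
                                  sigma2_person = 0.35,
                                  sigma2_noise = 0.05) {
  data.frame(measure = measures,
             sigma2_shared = rep_len(sigma2_shared, length(measures)),
             sigma2_person = rep_len(sigma2_person, length(measures)),
             sigma2_noise = rep_len(sigma2_noise, length(measures)),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the surface-data simulator.
#'
#' @param n_vertices_per_hemisphere vertices per hemisphere; the generated
#'   matrices have twice this many rows (left block then right block).
#' @param n_subjects number of simulated people (default 2, the
#'   dense-sampling design).
#' @param n_sets number of split-half sets; the pipeline expects 2.
#' @param n_anatomy_sessions_per_set anatomy scan sessions per set
#'   (default 4).
#' @param task_specs per-task variance table, see [default_task_specs()].
#' @param anatomy_specs per-measure variance table, see
#'   [default_anatomy_specs()].
#' @param medial_mask_fraction fraction in `[0, 1)` of vertices flagged
#'   missing in every matrix (emulating the medial wall).
#' @param anatomy_coupling coefficient `>= 0` adding `coupling * q` of the
#'   thickness person-component to every contrast's person component, so
#'   that anatomy genuinely explains part of the functional similarity gap.
#' @param seed integer root seed; all sub-streams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_vertices_per_hemisphere,
                       n_subjects = 2L,
                       n_sets = 2L,
                       n_anatomy_sessions_per_set = 4L,
                       task_specs = default_task_specs(),
                       anatomy_specs = default_anatomy_specs(),
                       medial_mask_fraction = 0,
                       anatomy_coupling = 0,
                       seed = 1L) {
  n_vertices_per_hemisphere <-
    assert_count(n_vertices_per_hemisphere, "n_vertices_per_hemisphere")
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 1L)
  n_sets <- assert_count(n_sets, "n_sets", min = 2L)
  n_anatomy_sessions_per_set <-
    assert_count(n_anatomy_sessions_per_set, "n_anatomy_sessions_per_set",
                 min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  assert_scalar_number(medial_mask_fraction, "medial_mask_fraction", min = 0)
  if (medial_mask_fraction >= 1) {
    stop_densim("`medial_mask_fraction` must be < 1", "densim_config_error")
  }
  assert_scalar_number(anatomy_coupling, "anatomy_coupling", min = 0)
  need <- c("task_id", "n_contrasts", "sigma2_shared", "sigma2_person",
            "sigma2_noise")
  if (!is.data.frame(task_specs) || !all(need %in% names(task_specs))) {
    stop_densim("`task_specs` must have columns task_id, n_contrasts and the three sigma2 components",
                "densim_config_error")
  }
  vars <- as.matrix(task_specs[c("sigma2_shared", "sigma2_person",
                                 "sigma2_noise")])
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop_densim("task variance components must be finite and non-negative",
                "densim_config_error")
  }
  if (any(rowSums(vars) == 0)) {
    stop_densim("each task needs at least one positive variance component",
                "densim_config_error")
  }
  avars <- as.matrix(anatomy_specs[c("sigma2_shared", "sigma2_person",
                                     "sigma2_noise")])
  if (any(!is.finite(avars)) || any(avars < 0) || any(rowSums(avars) == 0)) {
    stop_densim("anatomy variance components must be finite, non-negative, and not all zero",
                "densim_config_error")
  }
  structure(list(n_vertices_per_hemisphere = n_vertices_per_hemisphere,
                 n_subjects = n_subjects,
                 n_sets = n_sets,
                 n_anatomy_sessions_per_set = n_anatomy_sessions_per_set,
                 task_specs = task_specs,
                 anatomy_specs = anatomy_specs,
                 medial_mask_fraction = medial_mask_fraction,
                 anatomy_coupling = anatomy_coupling,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d subjects x %d sets, %d vertices/hemisphere, %d tasks / %d contrasts, mask %.0f%%, coupling %.3g, seed %d\n",
              x$n_subjects, x$n_sets, x$n_vertices_per_hemisphere,
              nrow(x$task_specs), sum(x$task_specs$n_contrasts),
              100 * x$medial_mask_fraction, x$anatomy_coupling, x$seed))
  invisible(x)
}

rnorm_mat <- function(n_row, sd_per_col) {
  matrix(stats::rnorm(n_row * length(sd_per_col)), nrow = n_row) %*%
    diag(x = sd_per_col, nrow = length(sd_per_col))
}

#' Generate a synthetic split-half surface dataset
#'
#' Draws contrast and anatomy matrices from the variance-components model:
#' per vertex `v`, contrast `c` of task `t`, subject `i`, set `s`,
#' `x(v,c,i,s) = g(v,c) + p(v,c,i) + e(v,c,i,s)` with
#' `g ~ N(0, sigma2_shared(t))`, `p ~ N(0, sigma2_person(t))` independent
#' across subjects, and `e ~ N(0, sigma2_noise(t))` independent across
#' sets. Anatomy matrices follow the analogous model per measure with one
#' noise draw per scan session. Components are independent across vertices
#' (no spatial autocorrelation): Pearson-based similarity statistics are
#' invariant to spatial smoothness in expectation, and independence keeps
#' the analytic expectations exact. When `anatomy_coupling > 0`, the
#' thickness person-component is added (scaled) into every contrast's
#' person component with unit contrast loading, so anatomical similarity
#' genuinely carries part of the within/between gap.
#'
#' Masked vertices (the synthetic medial wall) are drawn uniformly at
#' random once per dataset and set to `NA` in every matrix. The same seed
#' always reproduces the dataset bit for bit.
#'
#' @param config a [sim_config()].
#' @return object of class `densim_dataset`: a list with elements
#'   `contrast` (per subject, per set, vertex-by-contrast matrix),
#'   `anatomy` (per subject, per set, per measure, vertex-by-session
#'   matrix), `mask` (logical keep-flag per vertex row), `catalog`,
#'   `truth` (per-task expected within/between similarity and the applied
#'   mask), and `config`.
#' @examples
#' cfg <- sim_config(100, seed = 7,
#'                   task_specs = default_task_specs(task_catalog("A", 8)))
#' ds <- generate_dataset(cfg)
#' dim(ds$contrast$sub1$Set1)  # 200 x 8
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_densim("`config` must be a sim_config", "densim_config_error")
  }
  nvh <- config$n_vertices_per_hemisphere
  n_vertices <- 2L * nvh
  specs <- config$task_specs
  aspecs <- config$anatomy_specs
  n_contrasts <- sum(specs$n_contrasts)
  subjects <- sprintf("sub%d", seq_len(config$n_subjects))
  sets <- sprintf("Set%d", seq_len(config$n_sets))
  measures <- aspecs$measure
  catalog <- task_catalog(specs$task_id, specs$n_contrasts)

  ## per-contrast component standard deviations, in catalog order
  task_of <- match(catalog$task_id, specs$task_id)
  sd_g <- sqrt(specs$sigma2_shared[task_of])
  sd_p <- sqrt(specs$sigma2_person[task_of])
  sd_e <- sqrt(specs$sigma2_noise[task_of])

  n_streams <- 2L +                                   # mask + shared functional
    config$n_subjects +                               # person functional
    config$n_subjects * config$n_sets +               # set noise
    length(measures) * (1L + config$n_subjects +      # anatomy shared/person
                          config$n_subjects * config$n_sets)
  seeds <- derive_subseeds(config$seed, n_streams)
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    seeds[k]
  }

  set.seed(next_seed())
  n_masked <- floor(config$medial_mask_fraction * n_vertices)
  masked_idx <- if (n_masked > 0) sample.int(n_vertices, n_masked) else integer(0)
  keep <- rep(TRUE, n_vertices)
  keep[masked_idx] <- FALSE

  set.seed(next_seed())
  g <- rnorm_mat(n_vertices, sd_g)
  p <- lapply(subjects, function(s) {
    set.seed(next_seed())
    rnorm_mat(n_vertices, sd_p)
  })
  names(p) <- subjects
  e <- lapply(subjects, function(s) {
    out <- lapply(sets, function(st) {
      set.seed(next_seed())
      rnorm_mat(n_vertices, sd_e)
    })
    names(out) <- sets
    out
  })
  names(e) <- subjects

  ## anatomy components; h/q are per-vertex vectors, u per session
  h <- list(); q <- list(); u <- list()
  for (m in measures) {
    spec <- aspecs[aspecs$measure == m, ]
    set.seed(next_seed())
    h[[m]] <- stats::rnorm(n_vertices, sd = sqrt(spec$sigma2_shared))
    q[[m]] <- lapply(subjects, function(s) {
      set.seed(next_seed())
      stats::rnorm(n_vertices, sd = sqrt(spec$sigma2_person))
    })
    names(q[[m]]) <- subjects
    u[[m]] <- lapply(subjects, function(s) {
      out <- lapply(sets, function(st) {
        set.seed(next_seed())
        matrix(stats::rnorm(n_vertices * config$n_anatomy_sessions_per_set,
                            sd = sqrt(spec$sigma2_noise)),
               nrow = n_vertices)
      })
      names(out) <- sets
      out
    })
    names(u[[m]]) <- subjects
  }

  coupled_measure <- if (config$anatomy_coupling > 0) measures[1L] else NULL

  ## coupling loading: unit magnitude per contrast, alternating sign, so the
  ## anatomy person-deviation contributes across-contrast variance (a
  ## contrast-constant term would vanish under row-centering)
  w_loading <- rep_len(c(1, -1), n_contrasts)
  contrast <- lapply(subjects, function(s) {
    p_eff <- p[[s]]
    if (!is.null(coupled_measure)) {
      p_eff <- p_eff + config$anatomy_coupling *
        outer(q[[coupled_measure]][[s]], w_loading)
    }
    out <- lapply(sets, function(st) {
      x <- g + p_eff + e[[s]][[st]]
      x[!keep, ] <- NA_real_
      colnames(x) <- catalog$contrast_id
      structure(x, subject_id = s, set_id = st,
                n_vertices_per_hemisphere = nvh,
                class = c("contrast_matrix", class(x)))
    })
    names(out) <- sets
    out
  })
  names(contrast) <- subjects

  anatomy <- lapply(subjects, function(s) {
    per_set <- lapply(seq_along(sets), function(si) {
      st <- sets[si]
      out <- lapply(measures, function(m) {
        a <- h[[m]] + q[[m]][[s]] + u[[m]][[s]][[st]]
        a[!keep, ] <- NA_real_
        ## session numbering: Set1 holds odd-numbered scans, Set2 even
        sess <- seq(si, by = config$n_sets,
                    length.out = config$n_anatomy_sessions_per_set)
        colnames(a) <- sprintf("ses%02d", sess)
        structure(a, subject_id = s, set_id = st, measure = m,
                  sessions = sess,
                  n_vertices_per_hemisphere = nvh,
                  class = c("anatomy_matrix", class(a)))
      })
      names(out) <- measures
      out
    })
    names(per_set) <- sets
    per_set
  })
  names(anatomy) <- subjects

  ## analytic expectations; exact when coupling = 0. With coupling the
  ## per-vertex added person variance is coupling^2 * q(v)^2; using its mean
  ## (coupling^2 * sigma2_person of the coupled measure) gives a first-order
  ## approximation of the mean similarity.
  extra <- if (is.null(coupled_measure)) 0 else {
    config$anatomy_coupling^2 *
      aspecs$sigma2_person[aspecs$measure == coupled_measure]
  }
  rho <- t(vapply(seq_len(nrow(specs)), function(i) {
    expected_similarity(specs$sigma2_shared[i],
                        specs$sigma2_person[i] + extra,
                        specs$sigma2_noise[i])
  }, numeric(2)))
  truth <- list(task_id = specs$task_id,
                rho_within = rho[, "within"],
                rho_between = rho[, "between"],
                mask = keep,
                seed = config$seed)

  structure(list(contrast = contrast, anatomy = anatomy, mask = keep,
                 catalog = catalog, truth = truth, config = config),
            class = "densim_dataset")
}

#' @export
print.densim_dataset <- function(x, ...) {
  cat(sprintf("densim_dataset: %d subjects x %d sets, %d vertex rows (%d kept), %d contrasts, %d anatomy measures\n",
              length(x$contrast), length(x$contrast[[1]]),
              length(x$mask), sum(x$mask),
              ncol(x$contrast[[1]][[1]]),
              length(x$anatomy[[1]][[1]])))
  invisible(x)
}
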