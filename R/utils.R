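#' @keywords internal
"_PACKAGE"

## Input-validation helpers shared across modules. Errors are classed so the
## pipeline orchestrator can tag the failing stage.

stop_densim <- function(msg, class = "densim_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_densim(sprintf("`%s` must be a single finite number", name),
                "densim_config_error")
  }
  if (strict_min && x <= min) {
    stop_densim(sprintf("`%s` must be > %s", name, min), "densim_config_error")
  }
  if (!strict_min && x < min) {
    stop_densim(sprintf("`%s` must be >= %s", name, min), "densim_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop_densim(sprintf("`%s` must be a single integer", name),
                "densim_config_error")
  }
  if (x < min) {
    stop_densim(sprintf("`%s` must be >= %d", name, min), "densim_config_error")
  }
  invisible(as.integer(x))
}

## Deterministic sub-seeds: one root seed drives independent generation
## streams per component (mask, shared maps, per-subject, per-set, anatomy),
## so partial regeneration with the same root reproduces the same stream.
derive_subseeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## Full-precision number formatting for text outputs (TSV); round-trips
## doubles exactly through as.numeric().
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  out
}
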