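## Row- and column-wise Pearson kernels.
##
## Both kernels use the centered cross-product form
##   r = sum((a - mean a)(b - mean b)) / sqrt(sum((a - mean a)^2) sum((b - mean b)^2))
## vectorized over rows (or columns). Rows touched by the mask or containing
## the missing sentinel (NA) yield NA, as do rows/columns with zero variance
## (correlation undefined); nothing is imputed.

#' Row-wise Pearson correlation of two matrices
#'
#' For each row (vertex), the Pearson correlation of the corresponding rows
#' of `A` and `B` across columns. This is the per-vertex similarity
#' operation: with contrast matrices the correlation runs across the
#' contrast columns; with anatomy matrices it runs across the paired scan
#' sessions.
#'
#' @param A,B numeric matrices of identical dimensions, at least 2 columns.
#' @param mask optional logical keep-flag per row (see
#'   [compute_complete_mask()]); excluded rows yield `NA`.
#' @return numeric vector of per-row correlations in `[-1, 1]`, `NA` where
#'   the mask excludes the row, a value is missing, or a row has zero
#'   variance. The number of zero-variance rows is attached as attribute
#'   `n_zero_variance` and reported with a message when positive.
#' @export
rowwise_pearson <- function(A, B, mask = NULL) {
  if (!is.matrix(A) || !is.matrix(B) || !all(dim(A) == dim(B))) {
    stop_densim("`A` and `B` must be matrices with identical dimensions",
                "densim_input_error")
  }
  if (ncol(A) < 2L) {
    stop_densim("need at least 2 columns to correlate", "densim_input_error")
  }
  keep <- !(rowSums(is.na(A)) > 0L | rowSums(is.na(B)) > 0L)
  if (!is.null(mask)) {
    if (length(mask) != nrow(A)) {
      stop_densim("`mask` length must equal the row count",
                  "densim_input_error")
    }
    keep <- keep & mask
  }
  r <- rep(NA_real_, nrow(A))
  if (any(keep)) {
    Ak <- A[keep, , drop = FALSE]
    Bk <- B[keep, , drop = FALSE]
    Ac <- Ak - rowMeans(Ak)
    Bc <- Bk - rowMeans(Bk)
    ssa <- rowSums(Ac * Ac)
    ssb <- rowSums(Bc * Bc)
    rk <- rowSums(Ac * Bc) / sqrt(ssa * ssb)
    rk[ssa == 0 | ssb == 0] <- NA_real_
    r[keep] <- rk
  }
  n_zero <- sum(keep) - sum(!is.na(r))
  if (n_zero > 0) {
    message(sprintf("rowwise_pearson: %d zero-variance row(s) set to NA",
                    n_zero))
  }
  attr(r, "n_zero_variance") <- n_zero
  r
}

#' Column-wise Pearson correlation of two matrices
#'
#' For each column (contrast map), the Pearson correlation of the
#' corresponding columns of `A` and `B` over the kept vertex rows. This is
#' the whole-map similarity operation.
#'
#' @inheritParams rowwise_pearson
#' @return named numeric vector (one value per column); `NA` for
#'   zero-variance columns, with attribute `n_zero_variance` and a message
#'   when positive.
#' @export
columnwise_pearson <- function(A, B, mask = NULL) {
  if (!is.matrix(A) || !is.matrix(B) || !all(dim(A) == dim(B))) {
    stop_densim("`A` and `B` must be matrices with identical dimensions",
                "densim_input_error")
  }
  if (!is.null(colnames(A)) && !is.null(colnames(B)) &&
      !identical(colnames(A), colnames(B))) {
    stop_densim("`A` and `B` have different contrast column orders",
                "densim_input_error")
  }
  keep <- !(rowSums(is.na(A)) > 0L | rowSums(is.na(B)) > 0L)
  if (!is.null(mask)) {
    if (length(mask) != nrow(A)) {
      stop_densim("`mask` length must equal the row count",
                  "densim_input_error")
    }
    keep <- keep & mask
  }
  if (sum(keep) < 2L) {
    stop_densim("fewer than 2 complete vertex rows", "densim_input_error")
  }
  Ak <- A[keep, , drop = FALSE]
  Bk <- B[keep, , drop = FALSE]
  Ac <- sweep(Ak, 2L, colMeans(Ak))
  Bc <- sweep(Bk, 2L, colMeans(Bk))
  ssa <- colSums(Ac * Ac)
  ssb <- colSums(Bc * Bc)
  r <- colSums(Ac * Bc) / sqrt(ssa * ssb)
  r[ssa == 0 | ssb == 0] <- NA_real_
  names(r) <- colnames(A)
  n_zero <- sum(is.na(r))
  if (n_zero > 0) {
    message(sprintf("columnwise_pearson: %d zero-variance column(s) set to NA",
                    n_zero))
  }
  attr(r, "n_zero_variance") <- n_zero
  r
}

## mean across a list of equally shaped score vectors, optionally through
## Fisher's z (off by default: published pipelines of this design average
## raw r values)
average_scores <- function(score_list, fisher_z = FALSE) {
  m <- do.call(cbind, score_list)
  if (fisher_z) {
    tanh(rowMeans(atanh(m)))
  } else {
    rowMeans(m)
  }
}
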