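# Internal helpers shared across modules.

#' @keywords internal
.is_beta_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

#' @keywords internal
.assert_beta_matrix <- function(bm, allow_na = TRUE, arg = "bm") {
  if (!.is_beta_matrix(bm)) {
    stop(sprintf("'%s' must be a numeric matrix with CpG rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(bm))) stop(sprintf("'%s' has duplicated CpG ids", arg))
  if (anyDuplicated(colnames(bm))) stop(sprintf("'%s' has duplicated sample ids", arg))
  if (!allow_na && anyNA(bm)) stop(sprintf("'%s' contains missing values", arg))
  invisible(TRUE)
}

#' @keywords internal
.is_residual <- function(bm) isTRUE(attr(bm, "is_residual"))

#' @keywords internal
.assert_fraction_matrix <- function(fm, tol = 1e-8) {
  if (!is.matrix(fm) || !is.numeric(fm) || is.null(rownames(fm)) || is.null(colnames(fm))) {
    stop("fraction matrix must be numeric with sample rownames and cell-type colnames")
  }
  if (any(fm < -tol)) stop("fraction matrix has negative entries")
  if (any(abs(rowSums(fm) - 1) > 1e-6)) {
    stop("fraction matrix rows must sum to 1")
  }
  invisible(TRUE)
}

# Align a beta matrix, fraction matrix and per-sample covariates on the
# intersection of their sample ids, preserving the beta matrix column order.
#' @keywords internal
.align_samples <- function(bm, fm, meta = NULL) {
  ids <- colnames(bm)
  if (!all(ids %in% rownames(fm))) {
    stop("every sample in the beta matrix needs a row in the fraction matrix")
  }
  fm <- fm[ids, , drop = FALSE]
  if (!is.null(meta)) {
    if (!all(ids %in% meta$sample_id)) {
      stop("every sample in the beta matrix needs a metadata row")
    }
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  }
  list(bm = bm, fm = fm, meta = meta)
}

#' @keywords internal
.rmse <- function(a, b) sqrt(mean((a - b)^2))

# Column-wise z-scoring with zero-variance guard; returns the scaled matrix.
#' @keywords internal
.zscore_cols <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}
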