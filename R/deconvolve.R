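# Reference-based estimation of cell-type fractions from bulk methylomes.

# Huber IRLS regression without intercept: y ~ X b, weights
# w_i = min(1, c * s / |r_i|) with s the MAD-based scale of the residuals.
#' @keywords internal
.huber_irls <- function(X, y, c_tune = 1.345, maxit = 50L, tol = 1e-8) {
  b <- stats::lm.fit(X, y)$coefficients
  b[is.na(b)] <- 0
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% b)
    s <- stats::median(abs(r)) / 0.6745
    if (!is.finite(s) || s < 1e-10) break
    w <- pmin(1, c_tune * s / pmax(abs(r), 1e-12))
    b_new <- stats::lm.wfit(X, y, w)$coefficients
    b_new[is.na(b_new)] <- 0
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  b
}

#' Estimate cell-type fractions by reference-based deconvolution
#'
#' For each bulk sample, regresses its beta values at the reference marker
#' CpGs on the reference profiles (no intercept: the reference columns span
#' the expected signal). Negative coefficients are truncated to zero and
#' each sample's coefficients renormalized to sum to one, so every output
#' row is a point on the cell-type simplex.
#'
#' @param bm CpG x sample bulk beta matrix.
#' @param ref Marker x cell-type reference matrix of mean beta values.
#' @param method `"robust"` (default) for iteratively reweighted least
#'   squares with a Huber loss, emulating the robust partial-correlation
#'   behaviour of standard DNAm deconvolvers; `"nnls"` for non-negative
#'   least squares, a deterministic convex alternative.
#' @return A sample x cell-type fraction matrix with non-negative entries
#'   and unit row sums.
#' @examples
#' ref <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, dimnames = list(c("cg1", "cg2"), c("A", "B")))
#' bulk <- matrix(0.6 * ref[, "A"] + 0.4 * ref[, "B"], 2,
#'                dimnames = list(c("cg1", "cg2"), "s1"))
#' estimate_fractions(bulk, ref, method = "nnls")
#' @export
estimate_fractions <- function(bm, ref, method = c("robust", "nnls")) {
  method <- match.arg(method)
  .assert_beta_matrix(bm)
  shared <- intersect(rownames(ref), rownames(bm))
  if (length(shared) < 2L) stop("need at least 2 marker CpGs shared between bulk and reference")
  if (ncol(ref) < 2L) stop("reference must contain at least 2 cell types")
  X <- ref[shared, , drop = FALSE]
  Y <- bm[shared, , drop = FALSE]
  if (anyNA(Y)) stop("bulk matrix has missing values at marker CpGs; run qc_and_impute() first")
  out <- matrix(0, ncol(Y), ncol(X), dimnames = list(colnames(Y), colnames(X)))
  for (s in seq_len(ncol(Y))) {
    y <- Y[, s]
    b <- if (method == "robust") {
      .huber_irls(X, y)
    } else {
      pracma::lsqnonneg(X, y)$x
    }
    b[b < 0] <- 0
    if (sum(b) <= 0) {
      warning(sprintf("sample '%s': all coefficients zero; returning uniform fractions",
                      colnames(Y)[s]))
      b <- rep(1, ncol(X))
    }
    out[s, ] <- b / sum(b)
  }
  out
}

#' Collapse fine cell-type fractions into broader groups
#'
#' Sums fraction columns according to a grouping, e.g. merging naive and
#' memory lymphocyte subsets into single B/CD4T/CD8T fractions, or seven
#' brain cell types into neurons, glia and endothelial/stromal. Cell types
#' not named in any group pass through unchanged; row sums are preserved.
#'
#' @param fm Sample x cell-type fraction matrix.
#' @param grouping Named list mapping each coarse label to a character
#'   vector of fine cell-type labels. The fine labels must be disjoint
#'   across groups and present in `colnames(fm)`.
#' @return A sample x (coarse + passthrough) fraction matrix.
#' @export
collapse_fractions <- function(fm, grouping) {
  if (!is.list(grouping) || is.null(names(grouping))) {
    stop("'grouping' must be a named list of character vectors")
  }
  fine <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(fine)) {
    stop(sprintf("cell type '%s' appears in more than one group", fine[duplicated(fine)][1L]))
  }
  missing <- setdiff(fine, colnames(fm))
  if (length(missing)) stop(sprintf("unknown cell type in grouping: '%s'", missing[1L]))
  coarse <- vapply(grouping, function(members) {
    rowSums(fm[, members, drop = FALSE])
  }, numeric(nrow(fm)))
  if (nrow(fm) == 1L) coarse <- matrix(coarse, 1L, dimnames = list(rownames(fm), names(grouping)))
  passthrough <- setdiff(colnames(fm), fine)
  out <- cbind(coarse, fm[, passthrough, drop = FALSE])
  rownames(out) <- rownames(fm)
  out
}
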