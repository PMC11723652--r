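# Reading, writing, QC and transformation of DNAm beta-value matrices.
#
# Conventions: beta matrices are numeric matrices with CpG ids as rownames and
# sample ids as colnames, values in [0,1] (residualized matrices, flagged with
# attr "is_residual", may fall outside). Files are tab-delimited (CSV detected
# by extension), UTF-8, "NA" for missing, CpG ids in the first column.

#' @keywords internal
.file_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' @keywords internal
.read_id_matrix <- function(path, what = "matrix") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = .file_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop(sprintf("%s '%s': need an id column plus data columns", what, path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("%s '%s': duplicated row id '%s'", what, path, ids[duplicated(ids)][1L]))
  }
  cn <- colnames(df)[-1L]
  if (anyDuplicated(cn)) {
    stop(sprintf("%s '%s': duplicated column id '%s'", what, path, cn[duplicated(cn)][1L]))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf("%s '%s': non-numeric value '%s' at row '%s', column '%s'",
                     what, path, col[bad[1L]], ids[bad[1L]], cn[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  colnames(m) <- cn
  m
}

#' Read a DNAm beta-value matrix
#'
#' Reads a delimited text file with CpG identifiers in the first column and
#' sample identifiers in the header into a CpG x sample numeric matrix. If a
#' matching detection p-value matrix is supplied, beta values whose detection
#' p-value exceeds 0.01 are set to missing, the usual rule for Illumina array
#' data where a failed detection call invalidates the measurement.
#'
#' @param path Path to a TSV (or CSV, by extension) beta matrix.
#' @param detection_p Optional path to a detection p-value matrix with the
#'   same CpGs and samples.
#' @param is_residual Set to `TRUE` when reading residualized methylation
#'   values, which are not constrained to `[0,1]`.
#' @param detection_threshold Detection p-value above which a beta value is
#'   treated as missing (default 0.01).
#' @return A numeric CpG x sample matrix, possibly containing `NA`.
#' @seealso [write_beta_matrix()], [qc_and_impute()]
#' @export
read_beta_matrix <- function(path, detection_p = NULL, is_residual = FALSE,
                             detection_threshold = 0.01) {
  m <- .read_id_matrix(path, "beta matrix")
  if (!is_residual) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("beta matrix '%s': value %g out of [0,1] at row '%s', column '%s'",
                   path, m[bad[1L, , drop = FALSE]],
                   rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    }
  }
  if (!is.null(detection_p)) {
    p <- .read_id_matrix(detection_p, "detection p-value matrix")
    if (!identical(dim(p), dim(m)) ||
        !identical(rownames(p), rownames(m)) || !identical(colnames(p), colnames(m))) {
      stop("detection p-value matrix must match the beta matrix CpGs and samples")
    }
    m[!is.na(p) & p > detection_threshold] <- NA_real_
  }
  attr(m, "is_residual") <- isTRUE(is_residual)
  m
}

#' Write a beta-value matrix
#'
#' Writes the matrix in the same dialect [read_beta_matrix()] reads:
#' delimited text, CpG ids in a leading `cpg_id` column, `NA` for missing.
#'
#' @param bm CpG x sample numeric matrix.
#' @param path Output path; `.csv` extension selects comma delimiting.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(bm, path) {
  .assert_beta_matrix(bm)
  df <- data.frame(cpg_id = rownames(bm), bm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .file_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a delimited table with one row per sample. Required columns:
#' `sample_id`, `age` (years, finite and positive). Optional: `sex` (0/1),
#' `disease` (ordinal integer, 0 = control), `cohort`.
#'
#' @param path Path to the metadata TSV/CSV.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = .file_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  for (col in c("sample_id", "age")) {
    if (!col %in% colnames(df)) stop(sprintf("metadata '%s' lacks column '%s'", path, col))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop(sprintf("metadata '%s': duplicated sample_id", path))
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age) | df$age <= 0)) {
    stop(sprintf("metadata '%s': ages must be finite and positive", path))
  }
  df
}

#' Read a cell-type DNAm reference matrix
#'
#' Reads a marker-CpG x cell-type matrix of mean beta values used for
#' reference-based deconvolution. Every entry must lie in `[0,1]` and every
#' marker row must discriminate at least one pair of cell types.
#'
#' @param path Path to the reference TSV/CSV.
#' @return A numeric marker x cell-type matrix.
#' @export
read_reference_matrix <- function(path) {
  m <- .read_id_matrix(path, "reference matrix")
  if (anyNA(m)) stop(sprintf("reference matrix '%s' contains missing values", path))
  if (any(m < 0 | m > 1)) stop(sprintf("reference matrix '%s' has values outside [0,1]", path))
  flat <- apply(m, 1L, function(r) max(r) - min(r) <= 0)
  if (any(flat)) {
    stop(sprintf("reference matrix '%s': marker '%s' does not discriminate any cell types",
                 path, rownames(m)[which(flat)[1L]]))
  }
  m
}

#' Read a cell-type fraction matrix
#'
#' @param path Path to a sample x cell-type TSV/CSV of fractions.
#' @return A numeric sample x cell-type matrix with unit row sums.
#' @export
read_fraction_matrix <- function(path) {
  m <- .read_id_matrix(path, "fraction matrix")
  .assert_fraction_matrix(m)
  m
}

#' Write a sample x cell-type fraction matrix
#'
#' @param fm Fraction matrix as returned by [estimate_fractions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fraction_matrix <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .file_sep(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Coverage filtering and k-nearest-neighbour imputation
#'
#' Removes CpGs observed in fewer than `coverage_threshold` of samples, then
#' imputes the remaining missing beta values by averaging, per missing entry,
#' the `k` nearest CpG rows (Euclidean distance over the samples both rows
#' observe) that carry a value for that sample. Originally non-missing
#' entries are never altered.
#'
#' @param bm CpG x sample beta matrix, possibly with `NA`.
#' @param coverage_threshold Minimum fraction of non-missing samples a CpG
#'   must have to be retained (default 0.99; use 0.75 for a ">25% NA" rule).
#' @param k Number of neighbouring CpG rows averaged per imputation.
#' @param seed Unused beyond reproducibility bookkeeping: the procedure is
#'   deterministic, with distance ties broken by row order.
#' @return A beta matrix with no missing values.
#' @export
qc_and_impute <- function(bm, coverage_threshold = 0.99, k = 5, seed = 0) {
  .assert_beta_matrix(bm)
  if (k < 1) stop("'k' must be a positive integer")
  keep <- rowMeans(!is.na(bm)) >= coverage_threshold
  if (!any(keep)) stop("coverage filtering removed every CpG")
  out <- bm[keep, , drop = FALSE]
  if (!anyNA(out)) {
    attr(out, "is_residual") <- .is_residual(bm)
    return(out)
  }
  if (k > nrow(out) - 1L) stop("'k' exceeds the number of candidate neighbour CpGs")
  miss_rows <- which(rowSums(is.na(out)) > 0)
  complete <- out
  for (i in miss_rows) {
    x <- out[i, ]
    obs <- !is.na(x)
    # distances to all other rows over mutually observed samples
    for (j in which(!obs)) {
      donor <- which(!is.na(out[, j]))
      donor <- setdiff(donor, i)
      if (!length(donor)) stop(sprintf("no donor CpG observed for sample '%s'", colnames(out)[j]))
      d <- vapply(donor, function(r) {
        shared <- obs & !is.na(out[r, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((x[shared] - out[r, shared])^2))
      }, numeric(1L))
      ord <- donor[order(d)][seq_len(min(k, length(donor)))]
      complete[i, j] <- mean(out[ord, j])
    }
  }
  attr(complete, "is_residual") <- .is_residual(bm)
  complete
}

#' Convert between beta values and M-values
#'
#' M-values are the logit2 transform of beta values,
#' \eqn{M = \log_2(\beta / (1 - \beta))}; the inverse is
#' \eqn{\beta = 2^M / (1 + 2^M)}. Beta values of exactly 0 or 1 are clipped
#' to `[eps, 1 - eps]` with a warning so that the transform stays finite.
#'
#' @param x Numeric value, vector or matrix.
#' @param direction `"beta_to_m"` or `"m_to_beta"`.
#' @param eps Clipping bound for degenerate beta values (default `1e-6`).
#' @return Transformed values with the shape of `x`.
#' @export
beta_m_convert <- function(x, direction = c("beta_to_m", "m_to_beta"),
                           eps = 1e-6) {
  direction <- match.arg(direction)
  if (direction == "beta_to_m") {
    if (any(x < 0 | x > 1, na.rm = TRUE)) stop("beta values must lie in [0,1]")
    if (any(x <= 0 | x >= 1, na.rm = TRUE)) {
      warning(sprintf("beta values of 0 or 1 clipped to [%g, %g]", eps, 1 - eps))
      x <- pmin(pmax(x, eps), 1 - eps)
    }
    log2(x / (1 - x))
  } else {
    p <- 2^x
    p / (1 + p)
  }
}

#' @rdname beta_m_convert
#' @export
beta2m <- function(x, eps = 1e-6) beta_m_convert(x, "beta_to_m", eps)

#' @rdname beta_m_convert
#' @export
m2beta <- function(x) beta_m_convert(x, "m_to_beta")
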