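# Cell-type specific differential methylation with age: interaction model
# between age and cell-type fractions (per-CpG OLS, shared design), and the
# bulk fraction-adjusted age model.

# Fit Y (CpG x sample) against a shared design X (sample x p) by OLS and
# return coefficients, standard errors, t, p per CpG.
#' @keywords internal
.fit_shared_design <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop(sprintf("rank-deficient design matrix (rank %d < %d columns); check fractions and covariates",
                 qrX$rank, p))
  }
  coef <- t(qr.coef(qrX, t(Y)))            # CpG x p
  fitted <- coef %*% t(X)
  res <- Y - fitted
  df <- n - p
  resid_var <- rowSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  se <- sqrt(outer(resid_var, xtx_inv_diag))
  tstat <- coef / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  colnames(coef) <- colnames(se) <- colnames(tstat) <- colnames(pval) <- colnames(X)
  list(coef = coef, se = se, tstat = tstat, pval = pval,
       resid_var = resid_var, df = df)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} m p_{(j)} / j},
#' delegated to [stats::p.adjust()] after input validation.
#'
#' @param pvals Numeric vector of p-values in `[0,1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' @keywords internal
.build_covariate_matrix <- function(meta, covariates) {
  if (!length(covariates)) return(NULL)
  bad <- setdiff(covariates, c("sex", "disease"))
  if (length(bad)) stop(sprintf("unsupported covariate '%s'", bad[1L]))
  cm <- sapply(covariates, function(v) {
    if (!v %in% colnames(meta)) stop(sprintf("metadata lacks covariate column '%s'", v))
    as.numeric(meta[[v]])
  })
  cm <- matrix(cm, nrow = nrow(meta), dimnames = list(NULL, covariates))
  if (anyNA(cm)) stop("covariates contain missing values")
  cm
}

#' @keywords internal
.new_celldmc <- function(fit, cell_types, gamma_cols, cpg_ids, mode,
                         covariates, fdr_threshold, n, age_center) {
  gamma <- fit$coef[, gamma_cols, drop = FALSE]
  tstat <- fit$tstat[, gamma_cols, drop = FALSE]
  pval <- fit$pval[, gamma_cols, drop = FALSE]
  colnames(gamma) <- colnames(tstat) <- colnames(pval) <- cell_types
  fdr <- apply(pval, 2L, bh_fdr)
  if (length(cpg_ids) == 1L) fdr <- matrix(fdr, 1L)
  dimnames(fdr) <- dimnames(pval)
  structure(list(
    cpg_ids = cpg_ids,
    cell_types = cell_types,
    mu = NULL,  # filled by the caller (baseline columns of the design)
    gamma = gamma,
    tstat = tstat,
    pval = pval,
    fdr = fdr,
    covar_coeffs = if (length(covariates)) {
      fit$coef[, covariates, drop = FALSE]
    } else NULL,
    resid_var = fit$resid_var,
    df = fit$df,
    n = n,
    mode = mode,
    covariates = covariates,
    fdr_threshold = fdr_threshold,
    age_center = age_center
  ), class = "celldmc")
}

#' Detect cell-type specific age-associated CpGs (age-DMCTs)
#'
#' Fits, per CpG, the interaction model
#' \deqn{\beta_{cs} = \sum_t \mu_{ct} \hat f_{ts} + \sum_t \gamma_{ct} \hat f_{ts} Age_s
#'   + \theta_c Sex_s + \phi_c Disease_s + \epsilon_{cs}}
#' by ordinary least squares with no global intercept (the cell-type
#' baseline terms play that role, since the fractions sum to one). The
#' interaction coefficient \eqn{\gamma_{ct}} estimates the within-cell-type
#' methylation change per year of age; a CpG is called an age-DMCT in cell
#' type *t* when the Benjamini-Hochberg FDR of its two-sided t-test,
#' computed within that cell type across all CpGs, falls below
#' `fdr_threshold`. Age is centred at its sample mean before forming
#' interactions, which decorrelates baseline and slope estimates without
#' changing the slopes.
#'
#' @param bm CpG x sample beta matrix (no missing values).
#' @param fm Sample x cell-type fraction matrix.
#' @param meta Sample metadata with `sample_id` and `age`; needed columns
#'   for any requested covariates. Alternatively supply `ages` directly.
#' @param covariates Character subset of `c("sex", "disease")`.
#' @param fdr_threshold FDR below which a coefficient is flagged (default 0.05).
#' @param ages Optional numeric vector of ages (one per `colnames(bm)`),
#'   bypassing `meta`.
#' @return A `celldmc` object: matrices `mu`, `gamma`, `tstat`, `pval`,
#'   `fdr` (CpG x cell type), residual variances and fit metadata. Use
#'   [dmct_calls()] to extract significant CpGs and
#'   [as.data.frame.celldmc()] for the long table.
#' @export
fit_celldmc <- function(bm, fm, meta = NULL, covariates = character(),
                        fdr_threshold = 0.05, ages = NULL) {
  .assert_beta_matrix(bm, allow_na = FALSE)
  al <- .align_samples(bm, fm, meta)
  fm <- al$fm
  meta <- al$meta
  if (is.null(ages)) {
    if (is.null(meta)) stop("supply 'meta' or 'ages'")
    ages <- meta$age
  }
  n <- ncol(bm)
  Tn <- ncol(fm)
  cm <- .build_covariate_matrix(meta, covariates)
  if (n < 2 * Tn + length(covariates) + 2) {
    stop("too few samples for the interaction design")
  }
  age_center <- mean(ages)
  age_c <- ages - age_center
  X <- cbind(fm, fm * age_c, cm)
  colnames(X) <- c(colnames(fm), paste0(colnames(fm), ":age"), covariates)
  fit <- .fit_shared_design(X, bm)
  out <- .new_celldmc(fit, colnames(fm), paste0(colnames(fm), ":age"),
                      rownames(bm), "celldmc", covariates, fdr_threshold,
                      n, age_center)
  out$mu <- fit$coef[, seq_len(Tn), drop = FALSE]
  colnames(out$mu) <- colnames(fm)
  out
}

#' Detect bulk age-associated CpGs (age-DMCs)
#'
#' Fits, per CpG, the fraction-adjusted bulk model
#' \deqn{\beta_{cs} = \sum_t \mu_{ct} \hat f_{ts} + \gamma_c Age_s + \dots + \epsilon_{cs}}
#' with a single age coefficient per CpG and cell-type fractions as
#' covariates. Results are reported under the pseudo cell type `"bulk"`.
#'
#' @inheritParams fit_celldmc
#' @return A `celldmc` object with `cell_types = "bulk"`.
#' @export
fit_bulk_dmc <- function(bm, fm, meta = NULL, covariates = character(),
                         fdr_threshold = 0.05, ages = NULL) {
  .assert_beta_matrix(bm, allow_na = FALSE)
  al <- .align_samples(bm, fm, meta)
  fm <- al$fm
  meta <- al$meta
  if (is.null(ages)) {
    if (is.null(meta)) stop("supply 'meta' or 'ages'")
    ages <- meta$age
  }
  n <- ncol(bm)
  Tn <- ncol(fm)
  cm <- .build_covariate_matrix(meta, covariates)
  if (n < Tn + length(covariates) + 3) stop("too few samples for the bulk design")
  age_center <- mean(ages)
  age_c <- ages - age_center
  X <- cbind(fm, age = age_c, cm)
  colnames(X) <- c(colnames(fm), "age", covariates)
  fit <- .fit_shared_design(X, bm)
  out <- .new_celldmc(fit, "bulk", "age", rownames(bm), "bulk",
                      covariates, fdr_threshold, n, age_center)
  out$mu <- fit$coef[, seq_len(Tn), drop = FALSE]
  colnames(out$mu) <- colnames(fm)
  out
}

#' Extract significant age-DMCT CpG ids
#'
#' @param fit A `celldmc` object.
#' @param cell_type Cell type whose calls to extract.
#' @param fdr_threshold FDR cutoff (defaults to the fit's threshold).
#' @param rank_by_t If `TRUE`, order the returned CpGs by decreasing
#'   absolute t-statistic (the significance ordering used for top-k
#'   truncation); otherwise keep matrix row order.
#' @return Character vector of CpG ids.
#' @export
dmct_calls <- function(fit, cell_type, fdr_threshold = fit$fdr_threshold,
                       rank_by_t = TRUE) {
  stopifnot(inherits(fit, "celldmc"))
  if (!cell_type %in% fit$cell_types) stop(sprintf("unknown cell type '%s'", cell_type))
  hits <- which(fit$fdr[, cell_type] < fdr_threshold)
  if (rank_by_t && length(hits)) {
    hits <- hits[order(-abs(fit$tstat[hits, cell_type]))]
  }
  fit$cpg_ids[hits]
}

#' @export
as.data.frame.celldmc <- function(x, ...) {
  long <- do.call(rbind, lapply(x$cell_types, function(ct) {
    data.frame(cpg_id = x$cpg_ids,
               cell_type = ct,
               gamma = x$gamma[, ct],
               tstat = x$tstat[, ct],
               pval = x$pval[, ct],
               fdr = x$fdr[, ct],
               is_dmct = x$fdr[, ct] < x$fdr_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' @export
print.celldmc <- function(x, ...) {
  cat(sprintf("%s fit: %d CpGs x %d samples, cell types: %s\n",
              if (x$mode == "celldmc") "Cell-type interaction (age-DMCT)" else "Bulk age-DMC",
              length(x$cpg_ids), x$n, paste(x$cell_types, collapse = ", ")))
  counts <- colSums(x$fdr < x$fdr_threshold)
  cat(sprintf("age-DMCT calls at FDR < %g:\n", x$fdr_threshold))
  print(counts)
  invisible(x)
}
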