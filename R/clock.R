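# Elastic-net / lasso age clocks: intrinsic (trained on fraction-adjusted
# residuals), semi-intrinsic (cell-type specific CpGs, raw betas) and bulk.

#' Regress cell-type fractions out of a beta matrix
#'
#' Per CpG, fits an OLS model of methylation on the cell-type fractions
#' (plus any extra per-sample covariates) and returns the residuals. An
#' intercept column is included; because fractions sum to one it is
#' collinear with them and the pivoted QR drops whichever column is
#' redundant, which leaves the residuals unchanged. The output carries
#' `attr(, "is_residual") = TRUE` and is no longer confined to `[0,1]`.
#'
#' @param bm CpG x sample beta matrix.
#' @param fm Sample x cell-type fraction matrix (may be `NULL` to adjust
#'   for `extra_covariates` only).
#' @param extra_covariates Optional numeric matrix/data.frame of per-sample
#'   nuisance covariates (e.g. sex, cohort indicators), rows aligned with
#'   `colnames(bm)`.
#' @return Residual matrix, same shape and dimnames as `bm`.
#' @export
residualize <- function(bm, fm = NULL, extra_covariates = NULL) {
  .assert_beta_matrix(bm, allow_na = FALSE)
  n <- ncol(bm)
  D <- matrix(1, n, 1, dimnames = list(colnames(bm), "intercept"))
  if (!is.null(fm)) {
    al <- .align_samples(bm, fm)
    # fractions summing to one already span the intercept
    if (all(abs(rowSums(al$fm) - 1) < 1e-6)) {
      D <- al$fm
    } else {
      D <- cbind(D, al$fm)
    }
  }
  if (!is.null(extra_covariates)) {
    ec <- as.matrix(extra_covariates)
    if (nrow(ec) != n) stop("extra_covariates rows must match the samples")
    D <- cbind(D, ec)
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning(sprintf("residualize: dropped %d collinear design column(s)",
                    ncol(D) - qrD$rank))
  }
  res <- t(qr.resid(qrD, t(bm)))
  dimnames(res) <- dimnames(bm)
  attr(res, "is_residual") <- TRUE
  res
}

#' @keywords internal
.clock_design <- function(bm, clock_cpgs, standardize, train_means = NULL,
                          max_missing = 0.2) {
  present <- clock_cpgs %in% rownames(bm)
  if (mean(present) < 1 - max_missing) {
    stop(sprintf("%d of %d clock CpGs missing from the data; prediction unreliable",
                 sum(!present), length(clock_cpgs)))
  }
  x <- matrix(NA_real_, ncol(bm), length(clock_cpgs),
              dimnames = list(colnames(bm), clock_cpgs))
  x[, clock_cpgs[present]] <- t(bm[clock_cpgs[present], , drop = FALSE])
  if (standardize) {
    x[, present] <- .zscore_cols(x[, present, drop = FALSE])
    x[, !present] <- 0        # mean imputation is 0 after z-scoring
  } else if (any(!present)) {
    if (is.null(train_means)) stop("no training means available to impute missing clock CpGs")
    for (cg in clock_cpgs[!present]) x[, cg] <- train_means[cg]
  }
  if (any(!present)) {
    warning(sprintf("imputed %d missing clock CpG(s) with the training mean",
                    sum(!present)))
  }
  x
}

#' @keywords internal
.new_cts_clock <- function(mode, target_cell_type, cpg_ids, weights, intercept,
                           alpha, lambda, standardize, train_row_means,
                           train_row_sds, seed, extra = list()) {
  stopifnot(length(cpg_ids) == length(weights), length(cpg_ids) > 0,
            lambda > 0, alpha > 0, alpha <= 1)
  structure(c(list(
    mode = mode, target_cell_type = target_cell_type,
    cpg_ids = cpg_ids, weights = weights, intercept = intercept,
    alpha = alpha, lambda = lambda, standardize = standardize,
    train_row_means = train_row_means, train_row_sds = train_row_sds,
    seed = seed), extra), class = "cts_clock")
}

#' Train an elastic-net age clock with external or cross-validated selection
#'
#' Fits the full elastic-net regularization path (`glmnet`, 100 lambdas,
#' `lambda.min.ratio = 1e-4`) on the training samples restricted to the
#' candidate CpGs (typically age-DMCTs from [fit_celldmc()]). The penalty
#' is selected either on an external selection cohort — the model with the
#' lowest selection-set root-mean-square error wins, ties going to the
#' larger (sparser) lambda — or, when no selection set is given, by
#' internal 10-fold cross-validation on the training set.
#'
#' Modes: `"intrinsic"` clocks are trained and applied on residuals after
#' regressing out cell-type fractions (see [residualize()]); both supplied
#' matrices must be residualized. `"semi_intrinsic"` clocks use the same
#' candidate CpGs on unadjusted beta values. `"bulk"` clocks are trained
#' on unadjusted betas with candidates from [fit_bulk_dmc()] (or, as in
#' accuracy-decomposition workflows, residualized genome-wide data).
#'
#' When `standardize = TRUE` the clock operates on per-cohort z-scores:
#' each CpG is standardized across the samples of the cohort it is being
#' fitted to or applied on (the standardized-residual workflow).
#'
#' @param train_bm Training beta (or residual) matrix, CpG x sample.
#' @param train_ages Numeric ages, one per training sample.
#' @param candidate_cpgs Character vector of candidate clock CpGs.
#' @param mode `"intrinsic"`, `"semi_intrinsic"` or `"bulk"`.
#' @param select_bm,select_ages Optional external selection cohort.
#' @param alpha Elastic-net mixing parameter (0.5 for the clocks, 1 = lasso).
#' @param standardize Z-score CpGs within each cohort (default `TRUE`).
#' @param nfolds Folds for internal CV when no selection set is given.
#' @param seed Seed controlling fold assignment.
#' @param target_cell_type Optional label recorded on the model.
#' @return A `cts_clock` object; see [predict.cts_clock()].
#' @export
train_clock <- function(train_bm, train_ages, candidate_cpgs,
                        mode = c("intrinsic", "semi_intrinsic", "bulk"),
                        select_bm = NULL, select_ages = NULL,
                        alpha = 0.5, standardize = TRUE, nfolds = 10,
                        seed = 0, target_cell_type = NULL) {
  mode <- match.arg(mode)
  if (!length(candidate_cpgs)) stop("empty candidate CpG set")
  if (mode == "intrinsic") {
    if (!.is_residual(train_bm)) {
      stop("intrinsic mode requires a residualized training matrix (see residualize())")
    }
    if (!is.null(select_bm) && !.is_residual(select_bm)) {
      stop("intrinsic mode requires a residualized selection matrix")
    }
  }
  dropped <- setdiff(candidate_cpgs, rownames(train_bm))
  if (length(dropped)) {
    warning(sprintf("%d candidate CpG(s) absent from the training matrix; dropped",
                    length(dropped)))
    candidate_cpgs <- intersect(candidate_cpgs, rownames(train_bm))
    if (!length(candidate_cpgs)) stop("no candidate CpGs left after dropping")
  }
  xtr_raw <- t(train_bm[candidate_cpgs, , drop = FALSE])
  train_row_means <- colMeans(xtr_raw)
  train_row_sds <- apply(xtr_raw, 2, stats::sd)
  xtr <- if (standardize) .zscore_cols(xtr_raw) else xtr_raw

  if (!is.null(select_bm)) {
    if (is.null(select_ages) || ncol(select_bm) < 5L) {
      stop("selection set needs ages and at least 5 samples")
    }
    if (identical(dim(select_bm), dim(train_bm)) &&
        identical(dimnames(select_bm), dimnames(train_bm)) &&
        isTRUE(all.equal(select_bm, train_bm, check.attributes = FALSE))) {
      warning("selection set equals the training set; lambda is the in-sample optimum (overfit)")
    }
    fit <- glmnet::glmnet(xtr, train_ages, alpha = alpha, nlambda = 100,
                          lambda.min.ratio = 1e-4,
                          standardize = !standardize)
    xsel <- .clock_design(select_bm, candidate_cpgs, standardize, train_row_means)
    preds <- stats::predict(fit, xsel)
    rmse <- sqrt(colMeans((preds - select_ages)^2))
    idx <- which.min(rmse)       # lambdas decreasing: first minimum = larger lambda
    lambda <- fit$lambda[idx]
    w <- as.numeric(fit$beta[, idx])
    intercept <- fit$a0[idx]
    sel_rmse <- rmse[idx]
  } else {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(xtr)))
    cv <- glmnet::cv.glmnet(xtr, train_ages, alpha = alpha, nlambda = 100,
                            lambda.min.ratio = 1e-4, foldid = foldid,
                            standardize = !standardize)
    lambda <- cv$lambda.min
    idx <- which(cv$glmnet.fit$lambda == lambda)[1L]
    w <- as.numeric(cv$glmnet.fit$beta[, idx])
    intercept <- cv$glmnet.fit$a0[idx]
    sel_rmse <- sqrt(cv$cvm[idx])
  }
  .new_cts_clock(mode, target_cell_type, candidate_cpgs, w,
                 unname(intercept), alpha, lambda, standardize,
                 train_row_means, train_row_sds, seed,
                 extra = list(selection_rmse = unname(sel_rmse)))
}

#' Stratified 10-bag nested cross-validation clock (hepatocyte-style)
#'
#' Implements the nested procedure used to build a cell-type specific
#' clock from a single cohort: the samples are split into `n_bags` bags by
#' stratified sampling within age quintiles; for each fold, the cell-type
#' interaction model ([fit_celldmc()], or the bulk model when
#' `dmc_mode = "bulk"`) is re-fitted on the remaining bags and the
#' significant age-DMCTs of the target cell type extracted. The fold DMCT
#' lists are harmonized to the minimum count k across folds, keeping each
#' fold's top-k CpGs by absolute t-statistic. A lasso path
#' (`alpha = 1`, shared lambda grid) is fitted per fold on its top-k CpGs
#' and applied to the held-out bag; the lambda minimizing the pooled
#' out-of-bag RMSE is selected, and the final model is refitted at that
#' lambda on all samples using the top-k DMCTs from a fit on all samples.
#'
#' @param bm CpG x sample beta matrix.
#' @param fm Sample x cell-type fraction matrix.
#' @param meta Sample metadata (or pass `ages`).
#' @param target_cell_type Cell type whose age-DMCTs drive the clock.
#' @param alpha Penalty mixing (default 1, lasso).
#' @param fdr_threshold DMCT significance threshold per fold (default 0.05).
#' @param n_bags Number of bags (default 10).
#' @param covariates Covariates for the DMCT model (default none).
#' @param dmc_mode `"celldmc"` (default) or `"bulk"` for the fraction-
#'   adjusted bulk age model (liver-style clock).
#' @param seed Seed for the stratified bag assignment.
#' @param ages Optional ages vector bypassing `meta`.
#' @return A `cts_clock` with extra fields `k`, `oob` (pooled out-of-bag
#'   predictions: `sample_id`, `bag`, `predicted_age`, `chronological_age`)
#'   and `oob_rmse`.
#' @export
train_clock_cv10 <- function(bm, fm, meta = NULL, target_cell_type,
                             alpha = 1, fdr_threshold = 0.05, n_bags = 10,
                             covariates = character(),
                             dmc_mode = c("celldmc", "bulk"),
                             seed = 0, ages = NULL) {
  dmc_mode <- match.arg(dmc_mode)
  .assert_beta_matrix(bm, allow_na = FALSE)
  al <- .align_samples(bm, fm, meta)
  fm <- al$fm
  meta <- al$meta
  if (is.null(ages)) ages <- meta$age
  n <- ncol(bm)
  if (n < 50L) stop("need at least 50 samples for the nested procedure")
  if (dmc_mode == "celldmc" && stats::sd(fm[, target_cell_type]) <= 0.01) {
    stop(sprintf("fraction of '%s' is nearly constant; interaction model is uninformative",
                 target_cell_type))
  }

  # stratified bag assignment: shuffle within age quintiles, deal round-robin
  set.seed(seed)
  qs <- unique(stats::quantile(ages, probs = seq(0, 1, 0.2)))
  strata <- cut(ages, breaks = qs, include.lowest = TRUE, labels = FALSE)
  bag <- integer(n)
  pos <- 0L
  for (s in sort(unique(strata))) {
    idx <- sample(which(strata == s))
    bag[idx] <- ((pos + seq_along(idx) - 1L) %% n_bags) + 1L
    pos <- pos + length(idx)
  }

  dmct_mode_fun <- function(cols) {
    if (dmc_mode == "celldmc") {
      fit_celldmc(bm[, cols, drop = FALSE], fm[cols, , drop = FALSE],
                  ages = ages[cols], covariates = covariates,
                  fdr_threshold = fdr_threshold)
    } else {
      fit_bulk_dmc(bm[, cols, drop = FALSE], fm[cols, , drop = FALSE],
                   ages = ages[cols], covariates = covariates,
                   fdr_threshold = fdr_threshold)
    }
  }
  target <- if (dmc_mode == "celldmc") target_cell_type else "bulk"

  fold_dmcts <- vector("list", n_bags)
  for (f in seq_len(n_bags)) {
    fit_f <- dmct_mode_fun(bag != f)
    hits <- dmct_calls(fit_f, target, fdr_threshold, rank_by_t = TRUE)
    if (!length(hits)) {
      stop(sprintf("fold %d yielded zero age-DMCTs; use more data or a higher fdr_threshold", f))
    }
    fold_dmcts[[f]] <- hits
  }
  k <- min(lengths(fold_dmcts))
  fold_dmcts <- lapply(fold_dmcts, function(h) h[seq_len(k)])

  # shared lasso lambda grid across folds: from the largest per-fold
  # lambda_max down four decades
  lmax <- 0
  for (f in seq_len(n_bags)) {
    tr <- bag != f
    x <- scale(t(bm[fold_dmcts[[f]], tr, drop = FALSE]))
    x[!is.finite(x)] <- 0
    y <- ages[tr] - mean(ages[tr])
    lmax <- max(lmax, max(abs(crossprod(x, y))) / (sum(tr) * max(alpha, 1e-3)))
  }
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))

  oob_pred <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(n_bags)) {
    tr <- bag != f
    xtr <- t(bm[fold_dmcts[[f]], tr, drop = FALSE])
    fit_f <- glmnet::glmnet(xtr, ages[tr], alpha = alpha, lambda = grid,
                            standardize = TRUE)
    xte <- t(bm[fold_dmcts[[f]], !tr, drop = FALSE])
    # glmnet may stop the path early; interpolate onto the common grid
    oob_pred[!tr, ] <- stats::predict(fit_f, xte, s = grid, exact = FALSE)
  }
  rmse <- sqrt(colMeans((oob_pred - ages)^2))
  lambda <- grid[which.min(rmse)]

  final_dmct_fit <- dmct_mode_fun(rep(TRUE, n))
  final_hits <- dmct_calls(final_dmct_fit, target, fdr_threshold, rank_by_t = TRUE)
  if (length(final_hits) < 1L) stop("no age-DMCTs on the full data set")
  final_cpgs <- final_hits[seq_len(min(k, length(final_hits)))]
  xall <- t(bm[final_cpgs, , drop = FALSE])
  final_fit <- glmnet::glmnet(xall, ages, alpha = alpha, lambda = grid,
                              standardize = TRUE)
  co <- stats::coef(final_fit, s = lambda, exact = FALSE)
  w <- as.numeric(co[-1L])
  intercept <- co[1L]

  oob_at_lambda <- oob_pred[, which.min(rmse)]
  clock <- .new_cts_clock(
    mode = "semi_intrinsic", target_cell_type = target,
    cpg_ids = final_cpgs, weights = w, intercept = as.numeric(intercept),
    alpha = alpha, lambda = lambda, standardize = FALSE,
    train_row_means = colMeans(xall), train_row_sds = apply(xall, 2, stats::sd),
    seed = seed,
    extra = list(
      k = k,
      bag = stats::setNames(bag, colnames(bm)),
      oob = data.frame(sample_id = colnames(bm), bag = bag,
                       predicted_age = oob_at_lambda,
                       chronological_age = ages,
                       stringsAsFactors = FALSE),
      oob_rmse = min(rmse)))
  clock
}

#' Predict age with a trained clock
#'
#' Applies the linear clock
#' \eqn{\hat{age}_s = b_0 + \sum_c w_c x_{cs}} where \eqn{x_{cs}} is the
#' (residualized and/or standardized, per the model's flags) methylation of
#' clock CpG c. For intrinsic clocks applied to raw beta values, supply
#' `fractions`: the cohort is residualized with its own cell-type fractions
#' before prediction. With `standardize = TRUE` models, CpGs are z-scored
#' within the target cohort, so predictions are cohort-relative. Clock CpGs
#' absent from the data are imputed with the training mean (zero on the
#' standardized scale) with a warning; if more than 20\% are missing the
#' prediction is refused.
#'
#' @param object A `cts_clock`.
#' @param bm CpG x sample beta (or residual) matrix.
#' @param fractions Sample x cell-type fraction matrix, required for
#'   intrinsic clocks applied to unadjusted data.
#' @param ages Optional chronological ages to attach to the output.
#' @param ... Unused.
#' @return A `data.frame` with `sample_id`, `predicted_age`,
#'   `chronological_age` (NA when unknown) and `age_accel` (NA; see
#'   [age_acceleration()]).
#' @export
predict.cts_clock <- function(object, bm, fractions = NULL, ages = NULL, ...) {
  .assert_beta_matrix(bm, allow_na = FALSE)
  if (object$mode == "intrinsic" && !.is_residual(bm)) {
    if (is.null(fractions)) {
      stop("intrinsic clock on unadjusted data: supply 'fractions' to residualize")
    }
    bm <- residualize(bm, fractions)
  }
  x <- .clock_design(bm, object$cpg_ids, object$standardize,
                     object$train_row_means)
  pred <- drop(x %*% object$weights) + object$intercept
  data.frame(sample_id = colnames(bm),
             predicted_age = unname(pred),
             chronological_age = if (is.null(ages)) NA_real_ else ages,
             age_accel = NA_real_,
             stringsAsFactors = FALSE)
}

#' Epigenetic age acceleration
#'
#' Age acceleration is the residual of predicted age regressed on
#' chronological age within the cohort, so it is zero-mean by construction
#' and invariant to constant prediction offsets and calibration slope.
#'
#' @param preds Prediction `data.frame` from [predict.cts_clock()] with
#'   `chronological_age` filled in (at least 5 samples).
#' @return The same `data.frame` with `age_accel` filled.
#' @export
age_acceleration <- function(preds) {
  ok <- is.finite(preds$chronological_age)
  if (sum(ok) < 5L) stop("need at least 5 samples with chronological age")
  if (stats::sd(preds$chronological_age[ok]) == 0) {
    stop("chronological age is constant; acceleration undefined")
  }
  fit <- stats::lm(predicted_age ~ chronological_age, data = preds[ok, ])
  preds$age_accel[ok] <- stats::residuals(fit)
  preds
}

#' @export
print.cts_clock <- function(x, ...) {
  cat(sprintf("Cell-type specific age clock (%s%s)\n", x$mode,
              if (!is.null(x$target_cell_type)) paste0(", ", x$target_cell_type) else ""))
  cat(sprintf("  CpGs: %d (%d non-zero), alpha = %g, lambda = %.4g, standardize = %s\n",
              length(x$cpg_ids), sum(x$weights != 0), x$alpha, x$lambda,
              x$standardize))
  if (!is.null(x$oob_rmse)) cat(sprintf("  pooled out-of-bag RMSE: %.3f years\n", x$oob_rmse))
  invisible(x)
}

#' @export
coef.cts_clock <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights),
                  c("(Intercept)", object$cpg_ids))
}

#' Serialize a clock model to JSON
#'
#' @param model A `cts_clock`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "cts_clock"))
  fields <- c("mode", "target_cell_type", "cpg_ids", "weights", "intercept",
              "alpha", "lambda", "standardize", "train_row_means",
              "train_row_sds", "seed")
  obj <- model[fields]
  obj$package_version <- as.character(utils::packageVersion("ctsclock"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a clock model from JSON
#'
#' @param path JSON path written by [write_clock()].
#' @return A `cts_clock`.
#' @export
read_clock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  .new_cts_clock(obj$mode,
                 if (is.null(obj$target_cell_type)) NULL else obj$target_cell_type,
                 obj$cpg_ids, obj$weights, obj$intercept, obj$alpha,
                 obj$lambda, obj$standardize,
                 stats::setNames(obj$train_row_means, obj$cpg_ids),
                 stats::setNames(obj$train_row_sds, obj$cpg_ids),
                 if (is.null(obj$seed)) 0 else obj$seed)
}
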