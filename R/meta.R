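# Per-cohort effect estimation, inverse-variance meta-analysis
# (fixed and DerSimonian-Laird random effects), permutation co-localization
# and set-enrichment tests.

#' Per-cohort association effect
#'
#' Ordinary least squares of an outcome (a cell-type fraction, or the age
#' acceleration of a clock) on a phenotype (age, or an ordinal disease
#' status with 0 = control), adjusting for optional covariates. Returns
#' the phenotype coefficient with its standard error, t and two-sided p,
#' ready for pooling with [meta_inverse_variance()].
#'
#' @param y Numeric outcome vector.
#' @param x Numeric phenotype vector.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (e.g. sex, age); collinear columns are dropped with a warning.
#' @return A list: `effect`, `se`, `t`, `p`, `n`.
#' @export
study_effect <- function(y, x, covariates = NULL) {
  if (length(y) != length(x)) stop("'y' and 'x' lengths differ")
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (length(y) < ncov + 3L) stop("too few samples for the regression")
  if (stats::sd(x) == 0) stop("phenotype 'x' is constant")
  dat <- data.frame(y = y, x = x)
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    if (is.null(colnames(cm))) colnames(cm) <- paste0("cov", seq_len(ncol(cm)))
    dat <- cbind(dat, as.data.frame(cm))
  }
  fit <- stats::lm(y ~ ., data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    warning(sprintf("dropped collinear covariate(s): %s",
                    paste(names(co)[is.na(co)], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  if (!"x" %in% rownames(sm)) stop("phenotype coefficient not estimable")
  list(effect = unname(sm["x", 1L]), se = unname(sm["x", 2L]),
       t = unname(sm["x", 3L]), p = unname(sm["x", 4L]), n = length(y))
}

#' Fixed- and random-effects inverse-variance meta-analysis
#'
#' Pools per-study effects with inverse-variance weights. Fixed effect:
#' \eqn{w_i = 1/SE_i^2}, pooled \eqn{\sum w_i \theta_i / \sum w_i}, SE
#' \eqn{\sqrt{1/\sum w_i}}. Between-study variance by DerSimonian-Laird:
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2 / \sum w))} with
#' Cochran's \eqn{Q = \sum w_i (\theta_i - \hat\theta_F)^2}; random-effects
#' weights are \eqn{1/(SE_i^2 + \tau^2)}. P-values use the normal
#' approximation; heterogeneity p from \eqn{\chi^2_{k-1}};
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#'
#' @param effects Numeric vector of study effects (at least 2).
#' @param ses Matching vector of standard errors, all positive.
#' @param labels Optional study labels.
#' @return A `meta_ivw` object with `fixed`, `random` (each: estimate, se,
#'   z, p), `tau2`, `Q`, `I2`, `p_het`, `k` and the per-study table.
#' @export
meta_inverse_variance <- function(effects, ses, labels = NULL) {
  k <- length(effects)
  if (k < 2L) stop("need at least 2 studies")
  if (length(ses) != k) stop("'effects' and 'ses' lengths differ")
  if (any(!is.finite(ses) | ses <= 0)) stop("all standard errors must be positive")
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  w <- 1 / ses^2
  fixed_est <- sum(w * effects) / sum(w)
  fixed_se <- sqrt(1 / sum(w))
  Q <- sum(w * (effects - fixed_est)^2)
  df <- k - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  rand_est <- sum(wr * effects) / sum(wr)
  rand_se <- sqrt(1 / sum(wr))
  zp <- function(est, se) {
    z <- est / se
    list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(
    fixed = zp(fixed_est, fixed_se),
    random = zp(rand_est, rand_se),
    tau2 = tau2, Q = Q, I2 = I2,
    p_het = stats::pchisq(Q, df, lower.tail = FALSE),
    k = k,
    studies = data.frame(label = labels, effect = effects, se = ses,
                         stringsAsFactors = FALSE)
  ), class = "meta_ivw")
}

#' @export
print.meta_ivw <- function(x, ...) {
  cat(sprintf("Inverse-variance meta-analysis of %d studies\n", x$k))
  cat(sprintf("  fixed:  %.4f (SE %.4f), p = %.3g\n",
              x$fixed$estimate, x$fixed$se, x$fixed$p))
  cat(sprintf("  random: %.4f (SE %.4f), p = %.3g  [tau2 = %.4f]\n",
              x$random$estimate, x$random$se, x$random$p, x$tau2))
  cat(sprintf("  heterogeneity: Q = %.3f, I2 = %.1f%%, p = %.3g\n",
              x$Q, x$I2, x$p_het))
  invisible(x)
}

#' CpGs falling in promoter windows around transcription start sites
#'
#' Membership is by distance only (strand ignored), 1-based inclusive:
#' a CpG is in a window when some TSS satisfies |pos - tss| <= flank.
#'
#' @param cpg_pos `data.frame` with columns `cpg_id`, `chr`, `pos`.
#' @param tss_pos `data.frame` with columns `chr`, `tss`.
#' @param flank Window half-width in bp (default 1000).
#' @return Character vector of in-window CpG ids.
#' @export
cpgs_in_tss_windows <- function(cpg_pos, tss_pos, flank = 1000) {
  hits <- logical(nrow(cpg_pos))
  for (ch in unique(cpg_pos$chr)) {
    tss <- sort(tss_pos$tss[tss_pos$chr == ch])
    if (!length(tss)) next
    sel <- which(cpg_pos$chr == ch)
    pos <- cpg_pos$pos[sel]
    i <- findInterval(pos, tss)
    d_lo <- ifelse(i >= 1, pos - tss[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(tss), tss[pmin(i + 1, length(tss))] - pos, Inf)
    hits[sel] <- pmin(d_lo, d_hi) <= flank
  }
  cpg_pos$cpg_id[hits]
}

#' Permutation co-localization test
#'
#' Tests whether a set of age-DMCTs maps into promoter windows of
#' deconvolution marker genes more often than same-size random draws from
#' the tested universe. The empirical one-tailed p-value uses add-one
#' smoothing, \eqn{p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)}, so it
#' is never exactly zero.
#'
#' @param dmcts Character vector of DMCT CpG ids (subset of `universe`).
#' @param window_cpgs CpG ids lying inside the marker promoter windows
#'   (e.g. from [cpgs_in_tss_windows()]).
#' @param universe All tested CpG ids.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return An `enrichment_result` list: `overlap`, `expected` (null mean),
#'   `statistic`, `pval`, `method`, `null` (the permuted counts).
#' @export
colocalization_permutation <- function(dmcts, window_cpgs, universe,
                                       n_perm = 1000, seed = 0) {
  if (!all(dmcts %in% universe)) stop("'dmcts' must be a subset of 'universe'")
  if (n_perm < 100) warning("fewer than 100 permutations; p-value resolution is coarse")
  window_set <- unique(window_cpgs)
  observed <- sum(dmcts %in% window_set)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    sum(sample(universe, length(dmcts)) %in% window_set)
  }, numeric(1L))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(overlap = observed, expected = mean(null),
                 statistic = mean(null), pval = p,
                 method = "permutation", null = null),
            class = "enrichment_result")
}

#' One-tailed set enrichment (Fisher exact or binomial)
#'
#' Fisher: hypergeometric upper-tail probability of the overlap between
#' `setA` and `setB` within `universe`. Binomial: probability of at least
#' the observed overlap under X ~ Binomial(|setA|, p0) for a supplied
#' background rate p0 (used when setB's universe is external, e.g. mQTL
#' catalogues).
#'
#' @param setA,setB Character CpG sets (`setB` unused for binomial beyond
#'   the overlap count).
#' @param universe Character universe (fisher; must contain both sets).
#' @param method `"fisher"` or `"binomial"`.
#' @param p0 Background success rate for the binomial test.
#' @return An `enrichment_result` list: `overlap`, `expected`,
#'   `statistic` (odds ratio for fisher, expected count for binomial),
#'   `pval`, `method`.
#' @export
set_enrichment <- function(setA, setB, universe = NULL,
                           method = c("fisher", "binomial"), p0 = NULL) {
  method <- match.arg(method)
  setA <- unique(setA)
  setB <- unique(setB)
  k <- length(intersect(setA, setB))
  if (method == "fisher") {
    if (is.null(universe) || !length(universe)) stop("fisher test needs a non-empty universe")
    universe <- unique(universe)
    if (!all(setA %in% universe) || !all(setB %in% universe)) {
      stop("both sets must be subsets of the universe")
    }
    nA <- length(setA)
    nB <- length(setB)
    N <- length(universe)
    p <- stats::phyper(k - 1, nB, N - nB, nA, lower.tail = FALSE)
    or <- (k * (N - nA - nB + k)) / max((nA - k) * (nB - k), .Machine$double.eps)
    structure(list(overlap = k, expected = nA * nB / N, statistic = or,
                   pval = p, method = "fisher"),
              class = "enrichment_result")
  } else {
    if (is.null(p0) || p0 <= 0 || p0 >= 1) stop("binomial test needs 0 < p0 < 1")
    n <- length(setA)
    p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    structure(list(overlap = k, expected = n * p0, statistic = n * p0,
                   pval = p, method = "binomial"),
              class = "enrichment_result")
  }
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s enrichment: overlap = %d, expected = %.2f, p = %.4g\n",
              x$method, x$overlap, x$expected, x$pval))
  invisible(x)
}
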