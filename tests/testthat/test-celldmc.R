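# Interaction model for cell-type specific age effects, bulk age model,
# and BH FDR.

test_that("bh_fdr reproduces the hand-computed step-up procedure", {
  expect_equal(bh_fdr(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 4 * 0.02 / 3, 0.04), tolerance = 1e-10)
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.03, 10)), rep(0.03, 10))
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("with one cell type the interaction model is simple regression on age", {
  bm <- make_beta(20, 30, seed = 21)
  fm <- matrix(1, 30, 1, dimnames = list(colnames(bm), "only"))
  ages <- seq(25, 83, length.out = 30)
  fit <- fit_celldmc(bm, fm, ages = ages)
  slopes <- apply(bm, 1, function(y) stats::coef(stats::lm(y ~ ages))[2])
  expect_equal(unname(fit$gamma[, "only"]), unname(slopes), tolerance = 1e-10)
  bulk <- fit_bulk_dmc(bm, fm, ages = ages)
  expect_equal(unname(bulk$gamma[, "bulk"]), unname(fit$gamma[, "only"]),
               tolerance = 1e-12)
})

test_that("coefficients match a brute-force normal-equations solver", {
  set.seed(22)
  bm <- make_beta(5, 20, seed = 22)
  fm <- make_fractions(20, c("A", "B"), seed = 23)
  rownames(fm) <- colnames(bm)
  ages <- runif(20, 30, 70)
  sex <- rep(0:1, 10)
  meta <- data.frame(sample_id = colnames(bm), age = ages, sex = sex)
  fit <- fit_celldmc(bm, fm, meta, covariates = "sex")
  age_c <- ages - mean(ages)
  X <- cbind(fm, fm * age_c, sex)
  for (i in 1:5) {
    beta_hat <- solve(t(X) %*% X, t(X) %*% bm[i, ])
    expect_equal(unname(fit$mu[i, ]), unname(beta_hat[1:2, 1]), tolerance = 1e-8)
    expect_equal(unname(fit$gamma[i, ]), unname(beta_hat[3:4, 1]), tolerance = 1e-8)
    expect_equal(unname(fit$covar_coeffs[i, "sex"]), unname(beta_hat[5, 1]),
                 tolerance = 1e-8)
  }
})

test_that("fit is equivariant under relabelling of cell types", {
  bm <- make_beta(15, 40, seed = 24)
  fm <- make_fractions(40, c("A", "B", "C"), seed = 25)
  rownames(fm) <- colnames(bm)
  ages <- runif(40, 30, 70)
  f1 <- fit_celldmc(bm, fm, ages = ages)
  f2 <- fit_celldmc(bm, fm[, c("C", "A", "B")], ages = ages)
  expect_equal(f2$gamma[, colnames(f1$gamma)], f1$gamma, tolerance = 1e-10)
  expect_equal(f2$fdr[, colnames(f1$fdr)], f1$fdr, tolerance = 1e-10)
})

test_that("planted lymphocyte effects are detected with high sensitivity and low FDR", {
  sc <- small_scenario("i", n_cpgs = 2000, n_samples = 150,
                       n_markers = 300, n_dmcts = 150)
  ds <- simulate_mixture(sc, seed = 31)
  f <- estimate_fractions(ds$bulk, ds$reference, method = "nnls")
  fit <- fit_celldmc(ds$bulk, f, ages = as.numeric(ds$ages))
  calls <- dmct_calls(fit, "lymphocytes")
  expect_gte(mean(ds$truth %in% calls), 0.8)
  expect_lte(mean(!(calls %in% ds$truth)), 0.1)
  # detections confined to the planted cell type
  off <- length(dmct_calls(fit, "granulocytes")) +
    length(dmct_calls(fit, "monocytes"))
  expect_lte(off, 0.05 * max(1, length(calls)))
})

test_that("null data produce almost no calls in either model", {
  sc <- small_scenario("i", n_cpgs = 1000, n_samples = 120,
                       n_markers = 200, n_dmcts = 0)
  ds <- simulate_mixture(sc, seed = 32)
  f <- estimate_fractions(ds$bulk, ds$reference, method = "nnls")
  fit <- fit_celldmc(ds$bulk, f, ages = as.numeric(ds$ages))
  for (ct in fit$cell_types) {
    expect_lte(length(dmct_calls(fit, ct)), 0.01 * length(fit$cpg_ids))
  }
  bulkfit <- fit_bulk_dmc(ds$bulk, f, ages = as.numeric(ds$ages))
  expect_lte(length(dmct_calls(bulkfit, "bulk")), 0.01 * length(fit$cpg_ids))
})

test_that("bulk model recovers a slope common to all cell types", {
  set.seed(33)
  n <- 100
  fm <- make_fractions(n, c("A", "B"), seed = 34)
  ages <- runif(n, 30, 70)
  s <- 0.004
  bm <- t(sapply(1:10, function(i) {
    0.3 + s * (ages - 50) + rnorm(n, 0, 0.01)
  }))
  dimnames(bm) <- list(sprintf("cg%02d", 1:10), rownames(fm))
  fit <- fit_bulk_dmc(bm, fm, ages = ages)
  expect_lt(abs(mean(fit$gamma) - s), 5e-4)
})

test_that("FDR is controlled when fractions hover at the simplex barycentre", {
  # beta independent of age; fractions tightly concentrated around (1/3,1/3,1/3)
  set.seed(35)
  called <- replicate(50, {
    n <- 60
    fm <- make_fractions(n, c("A", "B", "C"), seed = sample.int(1e6, 1),
                         conc = c(60, 60, 60))
    ages <- runif(n, 30, 70)
    bm <- matrix(runif(200 * n, 0.2, 0.8), 200, n,
                 dimnames = list(sprintf("cg%03d", 1:200), rownames(fm)))
    fit <- fit_celldmc(bm, fm, ages = ages)
    mean(fit$fdr < 0.05)
  })
  se <- stats::sd(called) / sqrt(length(called))
  expect_lte(mean(called), 0.05 + 3 * se)
})

test_that("rank-deficient designs are refused with a clear error", {
  bm <- make_beta(5, 30, seed = 36)
  fm <- matrix(1 / 3, 30, 3,
               dimnames = list(colnames(bm), c("A", "B", "C")))
  expect_error(fit_celldmc(bm, fm, ages = runif(30, 30, 70)),
               "rank-deficient")
})

test_that("the long-format table carries one record per CpG and cell type", {
  bm <- make_beta(6, 40, seed = 37)
  fm <- make_fractions(40, c("A", "B"), seed = 38)
  rownames(fm) <- colnames(bm)
  fit <- fit_celldmc(bm, fm, ages = runif(40, 30, 70))
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 6 * 2)
  expect_true(all(tab$fdr >= tab$pval))
})
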