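# Residualization, elastic-net clock training/selection, prediction,
# age acceleration, nested 10-bag training.

test_that("residualize reduces to centring when beta is independent of fractions", {
  bm <- make_beta(10, 20, seed = 41)
  fm_const <- matrix(1 / 3, 20, 3,
                     dimnames = list(colnames(bm), c("A", "B", "C")))
  res <- suppressWarnings(residualize(bm, fm_const))
  expect_equal(res, bm - rowMeans(bm), ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(attr(res, "is_residual"))
})

test_that("residualize annihilates exactly fraction-linear data and leaves orthogonal residuals", {
  set.seed(42)
  fm <- make_fractions(50, c("A", "B", "C"), seed = 43)
  lin <- fm %*% matrix(runif(3 * 8, 0, 1), 3, 8)
  bm <- t(lin)
  dimnames(bm) <- list(sprintf("cg%02d", 1:8), rownames(fm))
  res <- residualize(bm, fm)
  expect_lt(max(abs(res)), 1e-10)

  bm2 <- make_beta(8, 50, seed = 44)
  colnames(bm2) <- rownames(fm)
  res2 <- residualize(bm2, fm)
  for (ct in colnames(fm)) {
    expect_lt(max(abs(cor(t(res2), fm[, ct]))), 1e-8)
  }
})

test_that("a planted linear CpG-age signal is found with external selection", {
  set.seed(45)
  n <- 80
  ages_tr <- runif(n, 30, 70)
  ages_se <- runif(n, 30, 70)
  make_cohort <- function(ages) {
    bm <- matrix(runif(50 * n, 0.2, 0.8), 50, n,
                 dimnames = list(sprintf("cg%02d", 1:50),
                                 sprintf("s%03d", seq_len(n))))
    bm["cg01", ] <- (ages - 30) / 50  # exact encoding of age
    bm
  }
  tr <- make_cohort(ages_tr)
  se <- make_cohort(ages_se)
  ck <- train_clock(tr, ages_tr, rownames(tr), mode = "semi_intrinsic",
                    select_bm = se, select_ages = ages_se,
                    standardize = FALSE)
  p <- predict(ck, se)$predicted_age
  expect_lt(sqrt(mean((p - ages_se)^2)), 1)
  expect_gt(cor(p, ages_se), 0.99)
})

test_that("selection on the training set itself warns about overfitting", {
  set.seed(46)
  n <- 40
  ages <- runif(n, 30, 70)
  bm <- matrix(runif(20 * n, 0.2, 0.8), 20, n,
               dimnames = list(sprintf("cg%02d", 1:20), sprintf("s%03d", 1:n)))
  bm[1, ] <- (ages - 30) / 50
  expect_warning(
    train_clock(bm, ages, rownames(bm), mode = "bulk",
                select_bm = bm, select_ages = ages),
    "overfit")
})

test_that("predict applies the linear clock form and imputation rules", {
  ck <- ctsclock:::.new_cts_clock(
    mode = "bulk", target_cell_type = NULL, cpg_ids = "cg01",
    weights = 1, intercept = 50, alpha = 0.5, lambda = 0.1,
    standardize = FALSE, train_row_means = c(cg01 = 0.3),
    train_row_sds = c(cg01 = 0.1), seed = 0)
  bm <- matrix(0.2, 1, 3, dimnames = list("cg01", c("a", "b", "c")))
  expect_equal(predict(ck, bm)$predicted_age, rep(50.2, 3))

  # one absent clock CpG (within the 20% allowance) -> training-mean imputed
  ids6 <- sprintf("cg%02d", 1:6)
  ck2 <- ctsclock:::.new_cts_clock(
    mode = "bulk", target_cell_type = NULL, cpg_ids = ids6,
    weights = c(1, 0, 0, 0, 0, 1), intercept = 50, alpha = 0.5, lambda = 0.1,
    standardize = FALSE,
    train_row_means = stats::setNames(c(0.3, 0.3, 0.3, 0.3, 0.3, 0.4), ids6),
    train_row_sds = stats::setNames(rep(0.1, 6), ids6), seed = 0)
  bm2 <- matrix(0.2, 5, 2, dimnames = list(ids6[1:5], c("a", "b")))
  expect_warning(p <- predict(ck2, bm2), "imputed")
  expect_equal(p$predicted_age, rep(50 + 0.2 + 0.4, 2))
  # too many missing CpGs is an error
  ck3 <- ctsclock:::.new_cts_clock(
    mode = "bulk", target_cell_type = NULL,
    cpg_ids = paste0("cg", 1:10), weights = rep(1, 10), intercept = 0,
    alpha = 0.5, lambda = 0.1, standardize = FALSE,
    train_row_means = stats::setNames(rep(0.5, 10), paste0("cg", 1:10)),
    train_row_sds = stats::setNames(rep(0.1, 10), paste0("cg", 1:10)),
    seed = 0)
  bm3 <- matrix(0.5, 2, 2, dimnames = list(c("cg1", "cg2"), c("a", "b")))
  expect_error(predict(ck3, bm3), "missing")
})

test_that("training-cohort predictions re-derive as intercept + z-scored design", {
  set.seed(47)
  n <- 60
  ages <- runif(n, 30, 70)
  bm <- matrix(runif(30 * n, 0.2, 0.8), 30, n,
               dimnames = list(sprintf("cg%02d", 1:30), sprintf("s%03d", 1:n)))
  bm[1:5, ] <- bm[1:5, ] + rep((ages - 50) / 100, each = 5)
  ck <- train_clock(bm, ages, rownames(bm), mode = "semi_intrinsic", seed = 1)
  p <- predict(ck, bm)$predicted_age
  xz <- scale(t(bm[ck$cpg_ids, ]))
  manual <- drop(xz %*% ck$weights) + ck$intercept
  expect_equal(p, unname(manual), tolerance = 1e-8)
})

test_that("age acceleration is the cohort regression residual", {
  chron <- c(20, 30, 40, 50, 60, 70)
  preds <- data.frame(sample_id = letters[1:6], predicted_age = chron,
                      chronological_age = chron, age_accel = NA_real_)
  expect_equal(age_acceleration(preds)$age_accel, rep(0, 6))

  # constant offset is absorbed by the intercept
  preds$predicted_age <- chron + 5
  expect_equal(age_acceleration(preds)$age_accel, rep(0, 6))

  # one sample 10 years above the line: residual = 10 * (1 - leverage)
  preds$predicted_age <- chron
  preds$predicted_age[3] <- chron[3] + 10
  acc <- age_acceleration(preds)$age_accel
  h3 <- 1 / 6 + (40 - 45)^2 / sum((chron - 45)^2)
  expect_equal(acc[3], 10 * (1 - h3), tolerance = 1e-10)
  expect_equal(mean(acc), 0, tolerance = 1e-12)

  expect_error(age_acceleration(data.frame(
    sample_id = letters[1:5], predicted_age = 1:5,
    chronological_age = rep(50, 5), age_accel = NA_real_)), "constant")
})

test_that("intrinsic and semi-intrinsic clocks coincide under constant fractions", {
  set.seed(48)
  n <- 80
  ages <- runif(n, 30, 70)
  bm <- matrix(runif(40 * n, 0.2, 0.8), 40, n,
               dimnames = list(sprintf("cg%02d", 1:40), sprintf("s%03d", 1:n)))
  bm[1:8, ] <- bm[1:8, ] + rep((ages - 50) / 120, each = 8)
  fm <- matrix(c(0.5, 0.3, 0.2), n, 3, byrow = TRUE,
               dimnames = list(colnames(bm), c("A", "B", "C")))
  res <- suppressWarnings(residualize(bm, fm))
  ck_in <- train_clock(res, ages, rownames(bm), mode = "intrinsic", seed = 2)
  ck_sin <- train_clock(bm, ages, rownames(bm), mode = "semi_intrinsic", seed = 2)
  p_in <- predict(ck_in, res)$predicted_age
  p_sin <- predict(ck_sin, bm)$predicted_age
  expect_lt(max(abs(p_in - p_sin)), 1e-6)
})

test_that("intrinsic mode insists on residualized matrices", {
  bm <- make_beta(10, 30, seed = 50)
  expect_error(train_clock(bm, runif(30, 30, 70), rownames(bm),
                           mode = "intrinsic"), "residualized")
})

test_that("nested 10-bag training partitions samples and is seed-reproducible", {
  sc <- small_scenario("i", n_cpgs = 1200, n_samples = 110,
                       n_markers = 250, n_dmcts = 150)
  ds <- simulate_mixture(sc, seed = 51)
  f <- estimate_fractions(ds$bulk, ds$reference, method = "nnls")
  ck <- train_clock_cv10(ds$bulk, f, target_cell_type = "lymphocytes",
                         ages = as.numeric(ds$ages), seed = 3)
  expect_equal(sort(ck$oob$sample_id), sort(colnames(ds$bulk)))
  expect_true(all(table(ck$oob$bag) >= floor(110 / 10)))
  expect_equal(length(ck$cpg_ids), ck$k)
  ck2 <- train_clock_cv10(ds$bulk, f, target_cell_type = "lymphocytes",
                          ages = as.numeric(ds$ages), seed = 3)
  expect_identical(ck$weights, ck2$weights)
  expect_identical(ck$oob, ck2$oob)
  expect_gt(cor(ck$oob$predicted_age, ck$oob$chronological_age), 0.8)
})

test_that("nested training errors when a fold finds no age-DMCTs", {
  sc <- small_scenario("i", n_cpgs = 600, n_samples = 80,
                       n_markers = 150, n_dmcts = 0)
  ds <- simulate_mixture(sc, seed = 52)
  f <- estimate_fractions(ds$bulk, ds$reference, method = "nnls")
  expect_error(
    train_clock_cv10(ds$bulk, f, target_cell_type = "lymphocytes",
                     ages = as.numeric(ds$ages), seed = 4),
    "zero age-DMCTs")
})

test_that("clock JSON serialization round-trips", {
  set.seed(53)
  n <- 50
  ages <- runif(n, 30, 70)
  bm <- matrix(runif(20 * n, 0.2, 0.8), 20, n,
               dimnames = list(sprintf("cg%02d", 1:20), sprintf("s%03d", 1:n)))
  bm[1:4, ] <- bm[1:4, ] + rep((ages - 50) / 100, each = 4)
  ck <- train_clock(bm, ages, rownames(bm), mode = "bulk", seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock(ck, path)
  back <- read_clock(path)
  expect_equal(back$weights, ck$weights)
  expect_equal(back$intercept, ck$intercept)
  expect_equal(predict(back, bm)$predicted_age,
               predict(ck, bm)$predicted_age, tolerance = 1e-12)
})
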