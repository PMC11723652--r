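# Synthetic DNAm mixtures of three blood cell types (granulocytes,
# monocytes, lymphocytes) with planted lymphocyte age-DMCTs, for
# benchmarking intrinsic versus semi-intrinsic clock construction.
#
# Design: each cell type has a basis matrix of 10,000 CpGs x 200 samples
# with i.i.d. Beta draws of mean 0.25 ("unmethylated"); each cell type
# owns 1000 marker CpGs that stay unmethylated in it but are drawn with
# mean 0.75 ("methylated") in the other two types. 1000 lymphocyte
# age-DMCTs are planted on the M-value scale as
# M = log2(0.1/0.9) + (age - 30) * effS + N(0, effS), then converted back
# to beta. Bulk profiles are convex mixtures of the per-sample cell-type
# profiles under Dirichlet-drawn fractions; scenarios (ii)/(iv) couple the
# lymphocyte fraction to age by a Gaussian-copula whole-row permutation.

#' @keywords internal
.rdirichlet <- function(n, conc) {
  g <- matrix(stats::rgamma(n * length(conc), shape = conc, rate = 1),
              n, length(conc), byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(conc)
  sw
}

#' Define a mixture-simulation scenario
#'
#' The four scenarios cross two design axes: whether the planted
#' lymphocyte age-DMCTs overlap the lymphocyte marker CpGs
#' (`"iii"`/`"iv"`: 900 of the 1000 DMCTs are markers, leaving 100 markers
#' cell-type specific so that a deconvolution reference can still be
#' built), and whether the lymphocyte fraction increases with age
#' (`"ii"`/`"iv"`).
#'
#' @param scenario One of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param n_cpgs,n_samples Problem size (defaults 10,000 CpGs, 200 samples).
#' @param n_markers_per_type Marker CpGs per cell type (default 1000).
#' @param n_age_dmcts Planted lymphocyte age-DMCTs (default 1000; may be 0
#'   to simulate purely composition-driven aging).
#' @param n_overlapping_markers In scenarios iii/iv, how many DMCTs are
#'   lymphocyte markers (default 900; must be < `n_markers_per_type`).
#' @param beta_low_shape,beta_high_shape Beta-distribution shape pairs for
#'   unmethylated and methylated draws; the defaults `c(10, 30)` and
#'   `c(30, 10)` realize the design means of 0.25 and 0.75.
#' @param effS Age effect size on the M-value scale, per year (default 0.1).
#' @param noise_sd Gaussian noise SD on the planted M-values (default
#'   `effS`; set 0 to suppress noise).
#' @param age_range Ages are drawn uniformly on this interval (default
#'   `c(30, 75)`, preserving the age-30 anchor of the planted M-value
#'   formula); supply `ages_pool` to bootstrap from a real age vector.
#' @param ages_pool Optional numeric vector of donor ages to bootstrap from.
#' @param dirichlet_conc Dirichlet concentration for the cell-type
#'   fractions (default `c(30, 4, 16)`: granulocyte-dominant blood-like
#'   mixtures with mean fractions 0.6/0.08/0.32).
#' @param fraction_age_rho Target Spearman correlation between the
#'   lymphocyte fraction and age in scenarios ii/iv (default 0.5).
#' @param seed Default seed for datasets generated from this scenario.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(scenario = c("i", "ii", "iii", "iv"),
                         n_cpgs = 10000, n_samples = 200,
                         n_markers_per_type = 1000, n_age_dmcts = 1000,
                         n_overlapping_markers = 900,
                         beta_low_shape = c(10, 30),
                         beta_high_shape = c(30, 10),
                         effS = 0.1, noise_sd = effS,
                         age_range = c(30, 75), ages_pool = NULL,
                         dirichlet_conc = c(granulocytes = 30,
                                            monocytes = 4,
                                            lymphocytes = 16),
                         fraction_age_rho = 0.5, seed = 0) {
  scenario <- match.arg(scenario)
  markers_overlap <- scenario %in% c("iii", "iv")
  fraction_age_trend <- scenario %in% c("ii", "iv")
  if (markers_overlap && n_overlapping_markers >= n_markers_per_type) {
    stop("n_overlapping_markers must leave some markers cell-type specific")
  }
  if (n_cpgs < 3 * n_markers_per_type + n_age_dmcts) {
    stop("n_cpgs too small for the requested markers and age-DMCTs")
  }
  if (effS <= 0) stop("effS must be positive")
  structure(list(
    scenario = scenario,
    n_cpgs = n_cpgs, n_samples = n_samples,
    cell_types = c("granulocytes", "monocytes", "lymphocytes"),
    n_markers_per_type = n_markers_per_type,
    n_age_dmcts = n_age_dmcts,
    n_overlapping_markers = n_overlapping_markers,
    beta_low_shape = beta_low_shape, beta_high_shape = beta_high_shape,
    effS = effS, noise_sd = noise_sd,
    age_range = age_range, ages_pool = ages_pool,
    dirichlet_conc = dirichlet_conc,
    markers_overlap = markers_overlap,
    fraction_age_trend = fraction_age_trend,
    fraction_age_rho = fraction_age_rho,
    seed = seed
  ), class = "sim_scenario")
}

#' Generate a synthetic mixture data set from a scenario
#'
#' Draws per-sample cell-type basis profiles, plants the lymphocyte
#' age-DMCTs, mixes them under Dirichlet fractions (rank-coupled to age in
#' trend scenarios) and builds a deconvolution reference from an
#' independent realization of the basis matrices restricted to the marker
#' CpGs not used as age-DMCTs. Fully reproducible for a given seed.
#'
#' @param sc A `sim_scenario`.
#' @param seed Seed for this data set (defaults to the scenario's seed).
#' @param keep_basis Also return the per-cell-type basis matrices (large;
#'   default `FALSE`).
#' @return A `sim_dataset` list: `bulk` (CpG x sample beta matrix),
#'   `true_fractions` (sample x cell type), `ages`, `truth` (planted DMCT
#'   CpG ids, all in lymphocytes), `reference` (marker x cell type),
#'   `marker_ids` (per cell type), `scenario`.
#' @export
simulate_mixture <- function(sc, seed = sc$seed, keep_basis = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(seed)
  n <- sc$n_samples
  m <- sc$n_cpgs
  K <- sc$n_markers_per_type
  types <- sc$cell_types

  cpg_ids <- sprintf("cg%05d", seq_len(m))
  sample_ids <- sprintf("s%03d", seq_len(n))
  marker_ids <- list(
    granulocytes = cpg_ids[seq_len(K)],
    monocytes = cpg_ids[K + seq_len(K)],
    lymphocytes = cpg_ids[2 * K + seq_len(K)]
  )
  background <- cpg_ids[(3 * K + 1):m]
  truth <- if (sc$n_age_dmcts == 0) {
    character(0)
  } else if (sc$markers_overlap) {
    n_over <- min(sc$n_overlapping_markers, sc$n_age_dmcts)
    c(marker_ids$lymphocytes[seq_len(n_over)],
      background[seq_len(sc$n_age_dmcts - n_over)])
  } else {
    background[seq_len(sc$n_age_dmcts)]
  }

  ages <- if (!is.null(sc$ages_pool)) {
    # bootstrap from the donor age pool (index-based: a length-1 pool must
    # not trigger sample()'s 1:n expansion)
    sc$ages_pool[sample.int(length(sc$ages_pool), n, replace = TRUE)]
  } else {
    stats::runif(n, sc$age_range[1], sc$age_range[2])
  }

  # basis matrices: i.i.d. Beta draws per CpG and sample
  draw_basis <- function(own) {
    b <- matrix(stats::rbeta(m * n, sc$beta_low_shape[1], sc$beta_low_shape[2]),
                m, n, dimnames = list(cpg_ids, sample_ids))
    for (other in setdiff(types, own)) {
      rows <- marker_ids[[other]]
      b[rows, ] <- stats::rbeta(length(rows) * n,
                                sc$beta_high_shape[1], sc$beta_high_shape[2])
    }
    b
  }
  basis <- lapply(types, draw_basis)
  names(basis) <- types

  if (length(truth)) {
    mval0 <- log2(0.1 / 0.9)
    shift <- matrix(rep(ages - 30, each = length(truth)), length(truth), n)
    noise <- if (sc$noise_sd > 0) {
      matrix(stats::rnorm(length(truth) * n, 0, sc$noise_sd), length(truth), n)
    } else 0
    basis$lymphocytes[truth, ] <- m2beta(mval0 + shift * sc$effS + noise)
  }

  fr <- .rdirichlet(n, sc$dirichlet_conc)
  colnames(fr) <- types
  if (sc$fraction_age_trend) {
    # Gaussian-copula whole-row coupling: permute fraction rows so the
    # lymphocyte fraction tracks age at roughly the target Spearman rho
    rho <- sc$fraction_age_rho
    z_age <- stats::qnorm(rank(ages, ties.method = "first") / (n + 1))
    u <- rho * z_age + sqrt(1 - rho^2) * stats::rnorm(n)
    ord_target <- order(u)
    fr <- fr[order(fr[, "lymphocytes"]), , drop = FALSE][order(ord_target), , drop = FALSE]
  }
  rownames(fr) <- sample_ids

  bulk <- matrix(0, m, n, dimnames = list(cpg_ids, sample_ids))
  for (t in types) {
    bulk <- bulk + sweep(basis[[t]], 2, fr[, t], "*")
  }

  # reference from an independent realization, markers not used as DMCTs
  ref_markers <- lapply(types, function(t) setdiff(marker_ids[[t]], truth))
  names(ref_markers) <- types
  ref_rows <- unlist(ref_markers, use.names = FALSE)
  ref_basis <- lapply(types, draw_basis)
  names(ref_basis) <- types
  reference <- vapply(types, function(t) {
    rowMeans(ref_basis[[t]][ref_rows, , drop = FALSE])
  }, numeric(length(ref_rows)))
  rownames(reference) <- ref_rows

  structure(list(
    bulk = bulk,
    true_fractions = fr,
    ages = stats::setNames(ages, sample_ids),
    truth = truth,
    truth_cell_type = "lymphocytes",
    reference = reference,
    marker_ids = marker_ids,
    scenario = sc,
    seed = seed,
    basis = if (keep_basis) basis else NULL
  ), class = "sim_dataset")
}

#' Benchmark intrinsic versus semi-intrinsic clocks on simulated mixtures
#'
#' For each scenario and replicate: generates independent training and
#' validation mixture sets, estimates cell-type fractions by deconvolution
#' against the held-out-marker reference, detects lymphocyte age-DMCTs
#' with [fit_celldmc()], trains an intrinsic and a semi-intrinsic
#' lymphocyte clock ([train_clock()] with internal 10-fold CV) and records
#' each clock's RMSE and Pearson correlation on the validation set. Per
#' scenario, the two paradigms are compared by a two-tailed paired
#' Wilcoxon test on the validation RMSEs.
#'
#' @param scenarios Character vector of scenario labels (default all four).
#' @param n_reps Replicates per scenario (default 50).
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @param sc_args Extra arguments passed to [sim_scenario()].
#' @param deconv_method Deconvolution method (default `"robust"`).
#' @param fdr_threshold DMCT threshold (default 0.05).
#' @param alpha Elastic-net mixing for the clocks (default 0.5).
#' @return A `paradigm_benchmark` object: `results` (one row per scenario
#'   x replicate x paradigm with `rmse`, `pcc`, `n_dmcts`), `summary`
#'   (median RMSEs and the paired Wilcoxon p-value per scenario) and the
#'   count of dropped replicates.
#' @export
run_paradigm_benchmark <- function(scenarios = c("i", "ii", "iii", "iv"),
                                   n_reps = 50, seed = 0, sc_args = list(),
                                   deconv_method = "robust",
                                   fdr_threshold = 0.05, alpha = 0.5) {
  if (n_reps < 1) stop("n_reps must be positive")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(scenarios) * n_reps * 2L),
                  nrow = length(scenarios) * n_reps)
  rows <- list()
  dropped <- 0L
  idx <- 0L
  for (scn in scenarios) {
    sc <- do.call(sim_scenario, c(list(scenario = scn), sc_args))
    for (r in seq_len(n_reps)) {
      idx <- idx + 1L
      train <- simulate_mixture(sc, seed = seeds[idx, 1])
      valid <- simulate_mixture(sc, seed = seeds[idx, 2])
      f_tr <- estimate_fractions(train$bulk, train$reference, method = deconv_method)
      f_va <- estimate_fractions(valid$bulk, valid$reference, method = deconv_method)
      dm <- fit_celldmc(train$bulk, f_tr, ages = train$ages,
                        fdr_threshold = fdr_threshold)
      cands <- dmct_calls(dm, "lymphocytes", fdr_threshold)
      if (!length(cands)) {
        dropped <- dropped + 1L
        next
      }
      res_tr <- residualize(train$bulk[cands, , drop = FALSE], f_tr)
      clock_in <- train_clock(res_tr, train$ages, cands, mode = "intrinsic",
                              alpha = alpha, seed = seeds[idx, 2])
      clock_sin <- train_clock(train$bulk[cands, , drop = FALSE], train$ages,
                               cands, mode = "semi_intrinsic",
                               alpha = alpha, seed = seeds[idx, 2])
      p_in <- predict(clock_in, valid$bulk[cands, , drop = FALSE],
                      fractions = f_va)$predicted_age
      p_sin <- predict(clock_sin, valid$bulk[cands, , drop = FALSE])$predicted_age
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scn, rep = r,
        paradigm = c("intrinsic", "semi_intrinsic"),
        rmse = c(.rmse(p_in, valid$ages), .rmse(p_sin, valid$ages)),
        pcc = c(stats::cor(p_in, valid$ages), stats::cor(p_sin, valid$ages)),
        n_dmcts = length(cands),
        stringsAsFactors = FALSE)
    }
  }
  total <- length(scenarios) * n_reps
  if (dropped > 0.2 * total) {
    stop(sprintf("benchmark failed: %d of %d replicates had zero lymphocyte DMCTs",
                 dropped, total))
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(unique(results$scenario), function(scn) {
    sub <- results[results$scenario == scn, ]
    rin <- sub$rmse[sub$paradigm == "intrinsic"]
    rsin <- sub$rmse[sub$paradigm == "semi_intrinsic"]
    pw <- if (length(rin) >= 2) {
      stats::wilcox.test(rin, rsin, paired = TRUE)$p.value
    } else NA_real_
    data.frame(scenario = scn,
               median_rmse_intrinsic = stats::median(rin),
               median_rmse_semi_intrinsic = stats::median(rsin),
               median_pcc_intrinsic = stats::median(sub$pcc[sub$paradigm == "intrinsic"]),
               median_pcc_semi_intrinsic = stats::median(sub$pcc[sub$paradigm == "semi_intrinsic"]),
               wilcoxon_p = pw,
               n_reps = length(rin),
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, summary = summary, dropped = dropped,
                 seed = seed), class = "paradigm_benchmark")
}

#' @export
print.paradigm_benchmark <- function(x, ...) {
  cat("Intrinsic vs semi-intrinsic clock benchmark on simulated mixtures\n")
  print(x$summary, row.names = FALSE)
  if (x$dropped) cat(sprintf("dropped replicates (zero DMCTs): %d\n", x$dropped))
  invisible(x)
}

#' Write a simulated data set as the standard TSV triple plus truth
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed). Writes `beta.tsv`,
#'   `fractions.tsv`, `meta.tsv`, `reference.tsv` and `truth.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(ds$bulk, file.path(dir, "beta.tsv"))
  write_fraction_matrix(ds$true_fractions, file.path(dir, "fractions.tsv"))
  utils::write.table(
    data.frame(sample_id = names(ds$ages), age = as.numeric(ds$ages),
               stringsAsFactors = FALSE),
    file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  df <- data.frame(cpg_id = rownames(ds$reference), ds$reference,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "reference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cpg_id = ds$truth,
               cell_type = rep(ds$truth_cell_type, length(ds$truth)),
               stringsAsFactors = FALSE),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
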