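# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# small CpG x sample beta matrix with ids
make_beta <- function(n_cpgs = 10, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n_cpgs * n_samples, 0.05, 0.95), n_cpgs, n_samples,
              dimnames = list(sprintf("cg%03d", seq_len(n_cpgs)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# two-cell-type reference with well-separated profiles
make_reference <- function(n_markers = 50, cell_types = c("A", "B"), seed = 2) {
  set.seed(seed)
  K <- length(cell_types)
  m <- matrix(stats::runif(n_markers * K, 0.05, 0.95), n_markers, K,
              dimnames = list(sprintf("cg%03d", seq_len(n_markers)), cell_types))
  # force discrimination
  m[, 1] <- pmin(m[, 1], 0.45)
  m[, K] <- pmax(m[, K], 0.55)
  m
}

# noiseless bulk mixtures of a reference under given fractions
make_mixture_bulk <- function(ref, fractions) {
  bulk <- ref %*% t(fractions)
  colnames(bulk) <- rownames(fractions)
  bulk
}

# simplex fraction matrix
make_fractions <- function(n_samples, cell_types, seed = 3, conc = NULL) {
  set.seed(seed)
  K <- length(cell_types)
  if (is.null(conc)) conc <- rep(2, K)
  g <- matrix(stats::rgamma(n_samples * K, shape = conc), n_samples, K,
              byrow = TRUE)
  f <- g / rowSums(g)
  dimnames(f) <- list(sprintf("s%02d", seq_len(n_samples)), cell_types)
  f
}

# tiny scenario for fast end-to-end tests
small_scenario <- function(scenario = "i", n_cpgs = 1500, n_samples = 120,
                           n_markers = 300, n_dmcts = 200, n_overlap = 150,
                           ...) {
  sim_scenario(scenario, n_cpgs = n_cpgs, n_samples = n_samples,
               n_markers_per_type = n_markers, n_age_dmcts = n_dmcts,
               n_overlapping_markers = n_overlap, ...)
}

expect_simplex <- function(fm, tol = 1e-8) {
  expect_true(all(fm >= -tol))
  expect_true(all(abs(rowSums(fm) - 1) < tol))
}
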