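# Shared fixtures and independent oracles. The large synthetic library and
# its model are built once per test run, on first use.

.fixture_cache <- new.env(parent = emptyenv())

# training library (2,000 compounds x 3 replicates), its CNL model, and a
# held-out 400-compound library generated from the same loss chemistry
synth_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    catalog <- loss_catalog(seed = 101)
    train <- generate_library(n_compounds = 2000, catalog = catalog,
                              seed = 202)
    model <- suppressMessages(cmd_build(train$spectra, verbose = FALSE))
    heldout <- generate_library(n_compounds = 400, catalog = catalog,
                                seed = 303)
    .fixture_cache$fx <- list(catalog = catalog, train = train,
                              model = model, heldout = heldout)
  }
  .fixture_cache$fx
}

# one-spectrum model: precursor 1000 Da, single CNL at the water loss;
# every count is hand-computable
water_model <- function() {
  build_model(list(cnl_spectrum("w", 1000, 18.011)))
}

# a small random model for oracle comparisons
random_model <- function(n_spectra = 30, seed = 7) {
  sp <- cnldeconv:::with_seed(seed, lapply(seq_len(n_spectra), function(i) {
    prec <- runif(1, 150, 900)
    k <- sample(3:12, 1)
    cnl <- runif(k, 0, prec)
    cnl_spectrum(sprintf("R%03d", i), prec, cnl[cnl <= 1000])
  }))
  build_model(sp)
}

# independent all-bin window-sum oracle: scans every bin centre
naive_window_sum <- function(prob, grid, mass, tol) {
  centers <- grid$lo + (seq_len(grid$n_bins) - 1) * grid$step
  sum(prob[abs(centers - mass) <= tol + 1e-9])
}

# independent two-pass Pearson correlation
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# noiseless Gaussian trace helper
gaussian_trace <- function(mz, apex, width, amplitude, times) {
  xic_trace(mz, times, amplitude * exp(-(times - apex)^2 / (2 * width^2)))
}
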