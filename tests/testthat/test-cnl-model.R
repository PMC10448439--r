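test_that("TP binary vector sets one bit per occupied bin", {
  g <- cnl_grid()
  v <- tp_binary_vector(cnl_spectrum("x", 1000, 18.011), g)
  expect_equal(sum(v), 1)
  expect_true(v[18011 + 1])
  # empty spectrum: all-zero vector
  expect_equal(sum(tp_binary_vector(cnl_spectrum("x", 300, numeric(0)), g)), 0)
  # two CNLs rounding into one bin set the bit once
  v2 <- tp_binary_vector(cnl_spectrum("x", 1000, c(18.0114, 18.0106)), g)
  expect_equal(sum(v2), 1)
  expect_true(v2[18011 + 1])
})

test_that("TN binary vector is the masked complement of the TP vector", {
  g <- cnl_grid()
  sp <- cnl_spectrum("x", 1000, 18.011)
  tn <- tn_binary_vector(sp, g)
  expect_equal(sum(tn), 1000000)
  expect_false(tn[18011 + 1])
  # empty spectrum at precursor 300: ones exactly at bins 0..300000
  tn2 <- tn_binary_vector(cnl_spectrum("x", 300, numeric(0)), g)
  expect_equal(sum(tn2), 300001)
  expect_true(all(tn2[1:300001]))
  expect_false(any(tn2[300002:g$n_bins]))
})

test_that("TP and TN vectors partition the bins up to the precursor bin", {
  g <- cnl_grid()
  fx <- synth_fixture()
  merged <- merge_library(fx$train$spectra[seq_len(3 * 30)])
  for (m in merged) {
    sp <- to_cnl(m, g)
    tp <- tp_binary_vector(sp, g)
    tn <- tn_binary_vector(sp, g)
    expect_false(any(tp & tn))
    pb <- bin_index(g, min(sp$precursor_mz, g$hi))
    covered <- tp | tn
    expect_true(all(covered[seq_len(pb + 1)]))
    expect_false(any(covered[(pb + 2):g$n_bins]))
  }
})

test_that("one-spectrum model reproduces the hand-computed Laplace arithmetic", {
  m <- water_model()
  i <- 18011 + 1
  expect_identical(m$tp_counts[i], 2)
  expect_true(all(m$tp_counts[-i] == 1))
  expect_identical(sum(m$tp_counts), 1000002)
  expect_identical(m$tp_prob[i], 2 / 1000002)
  # TN side: complement under a precursor at the grid top
  expect_identical(m$tn_counts[i], 1)
  expect_true(all(m$tn_counts[-i] == 2))
  # window sums at tolerance 0.005: 10 smoothed bins + the occupied one
  expect_equal(sum_window(m$tp_prob, m$grid, 18.011, 0.005), 12 / 1000002,
               tolerance = 1e-12)
  expect_gt(score_cnl(m, 18.011, 0.005), 0)
})

test_that("model counts are additive over spectra", {
  sp <- cnl_spectrum("a", 1000, 18.011)
  sp2 <- cnl_spectrum("b", 1000, 18.011)
  m <- build_model(list(sp, sp2))
  expect_identical(m$tp_counts[18011 + 1], 3)
  expect_identical(m$n_compounds, 2L)
  expect_error(build_model(list()), "no CNL spectra")
})

test_that("streamed accumulation equals explicit binary-vector summation", {
  g <- cnl_grid()
  sp <- cnldeconv:::with_seed(13, lapply(1:20, function(i) {
    prec <- runif(1, 120, 400)
    cnl_spectrum(sprintf("S%02d", i), prec, runif(sample(2:8, 1), 0, prec))
  }))
  m <- build_model(sp, g)
  tp_ref <- Reduce(`+`, lapply(sp, function(s) as.integer(tp_binary_vector(s, g))))
  tn_ref <- Reduce(`+`, lapply(sp, function(s) as.integer(tn_binary_vector(s, g))))
  expect_equal(m$tp_counts, tp_ref + 1)
  expect_equal(m$tn_counts, tn_ref + 1)
})

test_that("both probability distributions normalize to one and stay positive", {
  for (m in list(water_model(), random_model(), synth_fixture()$model)) {
    expect_lt(abs(sum(m$tp_prob) - 1), 1e-9)
    expect_lt(abs(sum(m$tn_prob) - 1), 1e-9)
    expect_true(all(m$tp_counts >= 1))
    expect_true(all(m$tn_counts >= 1))
    expect_gt(min(m$tp_prob), 0)
    expect_gt(min(m$tn_prob), 0)
  }
})

test_that("windowed sums match the all-bin oracle and grow with tolerance", {
  m <- random_model()
  g <- m$grid
  set.seed(91)
  masses <- runif(200, 0, 1000)
  tols <- sample(c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2), 200,
                 replace = TRUE)
  for (k in seq_len(200)) {
    expect_identical(sum_window(m$tp_prob, g, masses[k], tols[k]),
                     naive_window_sum(m$tp_prob, g, masses[k], tols[k]))
  }
  # monotonicity in tolerance
  for (mass in masses[1:20]) {
    s_tp <- vapply(c(0.001, 0.005, 0.01, 0.05, 0.2),
                   function(t) sum_window(m$tp_prob, g, mass, t), numeric(1))
    s_tn <- vapply(c(0.001, 0.005, 0.01, 0.05, 0.2),
                   function(t) sum_window(m$tn_prob, g, mass, t), numeric(1))
    expect_true(all(diff(s_tp) >= 0))
    expect_true(all(diff(s_tn) >= 0))
  }
})

test_that("scores stay within [-1, 1] across the canonical tolerances", {
  m <- random_model()
  set.seed(5)
  masses <- runif(50, 0, 1000)
  for (tol in c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)) {
    s <- score_cnl(m, masses, tol)
    expect_true(all(s >= -1 & s <= 1))
  }
  expect_error(score_cnl(m, 1500, 0.005), "outside grid")
})

test_that("fragment classification follows the strict threshold rule", {
  m <- synth_fixture()$model
  water <- 18.010565
  cf <- classify_fragment(m, 300, 300 - water, tolerance = 0.005,
                          threshold = 0.00)
  expect_true(cf$accepted)
  expect_gt(cf$score, 0)
  expect_equal(cf$cnl, water)
  # fragment above the precursor is rejected outright with score -1
  expect_warning(bad <- classify_fragment(m, 300, 301), "rejected")
  expect_false(bad$accepted)
  expect_identical(bad$score, -1)
  # threshold +1 accepts nothing, even the dominant loss
  cf1 <- classify_fragment(m, 300, 300 - water, threshold = 1)
  expect_false(cf1$accepted)
  # precursor beyond the grid: CNL off grid is rejected with a warning
  expect_warning(off <- classify_fragment(m, 1200, 150), "rejected")
  expect_false(off$accepted)
})

test_that("model save/load round-trips bitwise and validates its format", {
  m <- random_model(n_spectra = 10, seed = 3)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$tp_prob, m$tp_prob)
  expect_identical(m2$tn_prob, m$tn_prob)
  expect_identical(m2$tp_counts, m$tp_counts)
  expect_identical(m2$grid, m$grid)
  # probabilities are internally consistent with the stored counts
  expect_equal(m2$tp_prob, m2$tp_counts / sum(m2$tp_counts),
               tolerance = 1e-12)
  # truncated file yields an error, not a partial model
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:100], f)
  expect_error(load_model(f), "cannot read model file")
  # wrong container version refused
  saveRDS(list(format_version = "cnl_model/999"), f)
  expect_error(load_model(f), "unsupported format version")
  unlink(f)
})
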