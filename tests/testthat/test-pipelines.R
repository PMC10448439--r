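test_that("the build pipeline equals the module operations called by hand", {
  lib <- generate_library(n_compounds = 25, seed = 55)
  f <- tempfile(fileext = ".msp")
  write_msp(lib$spectra, f)
  model <- suppressMessages(cmd_build(f, verbose = FALSE))
  counts <- attr(model, "counts")
  # stage counts match direct module calls
  sp <- read_library(f)
  sp <- filter_library(sp, "positive", 5000)
  merged <- merge_library(sp)
  cnls <- lapply(merged, to_cnl)
  expect_equal(unname(counts),
               c(length(lib$spectra), length(sp), length(merged),
                 length(cnls)))
  expect_equal(model$n_compounds, 25L)
  # and the model equals one built from those spectra directly
  ref <- build_model(cnls)
  expect_equal(model$tp_counts, ref$tp_counts)
  expect_equal(model$tn_counts, ref$tn_counts)
  unlink(f)
})

test_that("rebuilding from the same library writes a bit-identical model file", {
  lib <- generate_library(n_compounds = 10, seed = 77)
  f <- tempfile(fileext = ".msp")
  write_msp(lib$spectra, f)
  m1 <- tempfile(fileext = ".rds")
  m2 <- tempfile(fileext = ".rds")
  suppressMessages(cmd_build(f, out_model = m1, verbose = FALSE))
  suppressMessages(cmd_build(f, out_model = m2, verbose = FALSE))
  expect_identical(readBin(m1, "raw", file.size(m1)),
                   readBin(m2, "raw", file.size(m2)))
  unlink(c(f, m1, m2))
})

test_that("scoring via the pipeline matches direct classification row-for-row", {
  fx <- synth_fixture()
  prec <- 350.2
  frags <- c(prec - 18.010565, prec - 17.026549, prec - 123.4567, 200.01)
  cfg <- run_config()
  res <- cmd_score(fx$model, prec, frags, config = cfg)
  ref <- classify_fragment(fx$model, prec, frags,
                           tolerance = cfg$tolerance,
                           threshold = cfg$threshold)
  expect_equal(res, ref, ignore_attr = TRUE)
  # empty fragment list: empty table, no error
  empty <- cmd_score(fx$model, prec, numeric(0))
  expect_equal(nrow(empty), 0)
  # threshold +1 accepts nothing
  none <- cmd_score(fx$model, prec, frags,
                    config = run_config(threshold = 1))
  expect_false(any(none$accepted))
  # fragment list from a file
  ff <- tempfile()
  writeLines(sprintf("%.6f", frags), ff)
  res2 <- cmd_score(fx$model, prec, ff, config = cfg)
  expect_equal(res2$score, res$score, tolerance = 1e-9)
  unlink(ff)
})

test_that("config precedence is defaults < YAML file < explicit arguments", {
  cfg <- run_config()
  expect_equal(cfg$bin_width, 0.001)
  expect_equal(cfg$tolerance, 0.005)
  expect_equal(cfg$threshold, 0.00)
  expect_equal(cfg$mass_window, 0.020)
  expect_equal(cfg$min_snr, 2)
  expect_equal(cfg$min_consecutive, 3)
  expect_equal(cfg$corr_threshold, 0.57)
  expect_equal(cfg$tr_diff_threshold, 0.025)
  expect_equal(cfg$n_decoys, 200)
  expect_null(cfg$seed)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("tolerance: 0.01", "n_decoys: 17"), yml)
  cfg2 <- run_config(config_file = yml)
  expect_equal(cfg2$tolerance, 0.01)
  expect_equal(cfg2$n_decoys, 17)
  cfg3 <- run_config(config_file = yml, tolerance = 0.2)
  expect_equal(cfg3$tolerance, 0.2)
  expect_equal(cfg3$n_decoys, 17)
  expect_error(run_config(no_such_key = 1), "unknown config key")
  unlink(yml)
})

test_that("deconvolution combines methods conjunctively on simulated scans", {
  fx <- synth_fixture()
  prec_mz <- 350.20
  water_frag <- prec_mz - 18.010565
  feats <- data.frame(
    mz = c(prec_mz, water_frag, 250.10),
    apex = c(5.0, 5.0, 5.15),
    width = 0.02,
    amplitude = c(2000, 900, 800),
    is_precursor = c(TRUE, FALSE, FALSE),
    is_true_fragment = c(FALSE, TRUE, FALSE))
  sim <- generate_chromatogram(feats, noise_sd = 2, seed = 13)
  res <- suppressMessages(
    cmd_deconvolve(fx$model, sim$scans, prec_mz, apex_time = 5.0))
  expect_true(all(c("score_cnl", "correlation", "tr_diff", "accepted") %in%
                    names(res)))
  # the coeluting frequent-loss fragment passes all three methods
  wrow <- res[which.min(abs(res$mz - water_frag)), ]
  expect_true(wrow$cnl_accepted)
  expect_true(wrow$correlation_accepted)
  expect_true(wrow$tr_diff_accepted)
  expect_true(wrow$accepted)
  # the offset interferent fails the time-domain methods
  irow <- res[which.min(abs(res$mz - 250.10)), ]
  expect_false(irow$tr_diff_accepted)
  expect_false(irow$accepted)
  # combined verdict is exactly the conjunction of the per-method columns
  expect_equal(res$accepted,
               res$cnl_accepted & res$correlation_accepted &
                 res$tr_diff_accepted)
  # cnl-only deconvolution equals cmd_score on the surviving trace centres
  res_cnl <- suppressMessages(
    cmd_deconvolve(fx$model, sim$scans, prec_mz, apex_time = 5.0,
                   methods = "cnl"))
  ref <- cmd_score(fx$model, prec_mz, res_cnl$mz)
  expect_equal(res_cnl$score_cnl, ref$score, tolerance = 1e-12)
  expect_equal(res_cnl$cnl_accepted, ref$accepted)
  # adding methods never accepts more fragments
  expect_true(all(res$accepted <= res_cnl$accepted[match(round(res$mz, 4),
                                                         round(res_cnl$mz, 4))]))
  # a missing precursor trace is fatal
  expect_error(suppressMessages(
    cmd_deconvolve(fx$model, sim$scans, 999.9)), "precursor trace absent")
})

test_that("evaluation pipeline emits a deterministic full grid", {
  fx <- synth_fixture()
  spectra <- fx$heldout$spectra[1:60]
  cfg <- run_config(n_decoys = 3, seed = 9)
  tols <- c(0.005, 0.02)
  thrs <- seq(-1, 1, by = 0.1)
  e1 <- suppressMessages(cmd_evaluate(fx$model, spectra, config = cfg,
                                      tolerances = tols, thresholds = thrs,
                                      strata = "cnl_range"))
  e2 <- suppressMessages(cmd_evaluate(fx$model, spectra, config = cfg,
                                      tolerances = tols, thresholds = thrs))
  expect_identical(as.data.frame(e1$grid), as.data.frame(e2$grid))
  expect_equal(nrow(e1$grid), length(tols) * length(thrs))
  expect_false(is.null(e1$strata))
  expect_true(all(e1$strata$n_tp + e1$strata$n_fn +
                    e1$strata$n_fp + e1$strata$n_tn > 0))
})
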