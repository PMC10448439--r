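#' Build a CNL model from library files
#'
#' The full model-building workflow: read the libraries, filter by
#' ionization mode and resolution, merge replicates per compound, convert to
#' CNL spectra and accumulate the smoothed occurrence model. Stage counts
#' (entries read, after filtering, unique compounds, CNL spectra) are logged
#' in a machine-parsable `stage=... count=...` form and attached to the
#' result as attribute `counts`.
#'
#' @param library_paths Character vector of MSP/MGF file paths, or a list of
#'   [fragment_spectrum()] given directly.
#' @param out_model Optional path; when given the model is written there
#'   with [save_model()].
#' @param config A [run_config()].
#' @param verbose Log stage counts?
#' @return The `cnl_model`, invisibly when `out_model` is given.
#' @export
cmd_build <- function(library_paths, out_model = NULL, config = run_config(),
                      verbose = TRUE) {
  spectra <- if (is.character(library_paths)) {
    unlist(lapply(library_paths, read_library), recursive = FALSE)
  } else {
    library_paths
  }
  n_read <- length(spectra)
  log_stage("read", entries = n_read, verbose = verbose)
  spectra <- filter_library(spectra, mode = config$mode,
                            min_resolution = config$min_resolution)
  n_filtered <- length(spectra)
  log_stage("filter", entries = n_filtered, verbose = verbose)
  if (n_filtered == 0) {
    stop(sprintf("no spectra survive filtering (read=%d, filtered=0)", n_read))
  }
  merged <- merge_library(spectra, bin_width = config$bin_width)
  log_stage("merge", compounds = length(merged), verbose = verbose)
  grid <- config_grid(config)
  cnl_spectra <- suppressWarnings(lapply(merged, to_cnl, grid = grid))
  cnl_spectra <- Filter(function(s) length(s$cnls) > 0, cnl_spectra)
  log_stage("cnl", spectra = length(cnl_spectra), verbose = verbose)
  if (length(cnl_spectra) == 0) {
    stop("no CNL spectra remain after conversion")
  }
  model <- build_model(cnl_spectra, grid = grid,
                       build_params = list(bin_width = config$bin_width,
                                           mode = config$mode,
                                           min_resolution = config$min_resolution))
  attr(model, "counts") <- c(read = n_read, filtered = n_filtered,
                             compounds = length(merged),
                             cnl_spectra = length(cnl_spectra))
  if (!is.null(out_model)) {
    save_model(model, out_model)
    log_stage("save", path = out_model, verbose = verbose)
    return(invisible(model))
  }
  model
}

#' Score a candidate fragment list against a model
#'
#' Runs [classify_fragment()] on every candidate and returns (optionally
#' writes) the decision table.
#'
#' @param model A `cnl_model` or a model file path.
#' @param precursor_mz Precursor ion m/z in Da.
#' @param fragments Numeric vector of candidate fragment m/z, or a path to a
#'   delimited text file with one m/z per line.
#' @param config A [run_config()] (uses `tolerance`, `threshold`).
#' @param out Optional TSV output path.
#' @return The decision data frame.
#' @export
cmd_score <- function(model, precursor_mz, fragments,
                      config = run_config(), out = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(fragments)) {
    fragments <- scan(fragments, what = numeric(), quiet = TRUE,
                      comment.char = "#")
  }
  res <- if (length(fragments) == 0) {
    data.frame(fragment_mz = numeric(), cnl = numeric(),
               sum_p_tp = numeric(), sum_p_tn = numeric(),
               score = numeric(), accepted = logical())
  } else {
    classify_fragment(model, precursor_mz, fragments,
                      tolerance = config$tolerance,
                      threshold = config$threshold)
  }
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  res
}

#' Evaluate a model with labeled database-style cases
#'
#' Builds TP cases from the raw spectra and TN decoy cases per spectrum,
#' sweeps the ROC grid, and optionally writes the rate table and a
#' stratified summary.
#'
#' @param model A `cnl_model` or model file path.
#' @param library_paths MSP/MGF paths or a list of [fragment_spectrum()].
#' @param config A [run_config()] (uses `n_decoys`, `tolerance` for decoy
#'   exclusion, `seed`).
#' @param tolerances,thresholds Grid axes; defaults as in [roc_grid()].
#' @param strata `"cnl_range"` for a CNL mass-range stratification at the
#'   configured operating point, or `NULL`.
#' @param out Optional TSV path for the grid.
#' @return List: `grid` ([roc_grid()] result), `cases` (labeled case data
#'   frame), `strata` (stratified rates or `NULL`).
#' @export
cmd_evaluate <- function(model, library_paths, config = run_config(),
                         tolerances = c(0.001, 0.005, 0.010, 0.020, 0.050,
                                        0.100, 0.200),
                         thresholds = seq(-1, 1, by = 0.01),
                         strata = NULL, out = NULL) {
  if (is.character(model)) model <- load_model(model)
  spectra <- if (is.character(library_paths)) {
    unlist(lapply(library_paths, read_library), recursive = FALSE)
  } else {
    library_paths
  }
  grid <- model$grid
  tp <- make_tp_cases(spectra, grid = grid)
  tn <- make_tn_cases(spectra, n_decoys = config$n_decoys,
                      exclusion_tol = config$tolerance, grid = grid,
                      seed = config$seed)
  cases <- rbind(tp, tn)
  log_stage("cases", tp = nrow(tp), tn = nrow(tn))
  roc <- roc_grid(model, cases, tolerances = tolerances,
                  thresholds = thresholds)
  strat <- NULL
  if (identical(strata, "cnl_range")) {
    acc <- score_cnl(model, cases$cnl, config$tolerance) > config$threshold
    strat <- stratified_rates(cases, acc, cnl_range_strata(cases))
  }
  if (!is.null(out)) {
    utils::write.table(as.data.frame(roc), out, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(grid = roc, cases = cases, strata = strat)
}

#' Deconvolute an MS2 scan series around a precursor feature
#'
#' Groups the scans into XICs, quality-controls the candidate fragment
#' traces, applies the requested methods (CNL score, peak-shape correlation,
#' apex retention-time difference) and AND-combines their verdicts.
#'
#' @param model A `cnl_model` or model file path (needed when `"cnl"` is
#'   among `methods`).
#' @param scans Long-format scan data frame (`scan_time`, `mz`,
#'   `intensity`) or a path to such a delimited file (TSV with header).
#' @param precursor_mz Precursor ion m/z in Da.
#' @param apex_time Optional known precursor apex time (minutes); default
#'   the apex of the precursor's own XIC.
#' @param config A [run_config()].
#' @param methods Subset of `c("cnl", "correlation", "tr_diff")`.
#' @return Data frame, one row per QC-surviving candidate trace: `mz`,
#'   `cnl`, per-method statistics and verdicts, and the combined `accepted`.
#' @export
cmd_deconvolve <- function(model, scans, precursor_mz, apex_time = NULL,
                           config = run_config(),
                           methods = c("cnl", "correlation", "tr_diff")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("cnl" %in% methods && is.character(model)) model <- load_model(model)
  if (is.character(scans)) {
    scans <- utils::read.table(scans, header = TRUE, sep = "\t")
  }
  traces <- group_xics(scans, mass_window = config$mass_window)
  centers <- vapply(traces, function(t) t$mz_center, numeric(1))
  ip <- which(abs(centers - precursor_mz) <= config$mass_window / 2)
  if (length(ip) == 0) stop("precursor trace absent from scan series")
  ip <- ip[which.min(abs(centers[ip] - precursor_mz))]
  ptrace <- traces[[ip]]
  apex <- apex_time %||% ptrace$time[which.max(ptrace$intensity)]
  tspan <- range(ptrace$time)
  feat <- precursor_feature(precursor_mz, apex,
                            tspan[1] - 1e-9, tspan[2] + 1e-9, ptrace)
  cand <- traces[-ip]
  cand <- Filter(function(t) qc_filter(t, config$min_snr,
                                       config$min_consecutive), cand)
  log_stage("qc", candidates = length(traces) - 1, surviving = length(cand))
  rows <- lapply(cand, function(tr) {
    row <- data.frame(mz = tr$mz_center, cnl = precursor_mz - tr$mz_center)
    dec <- list()
    if ("cnl" %in% methods) {
      cf <- suppressWarnings(
        classify_fragment(model, precursor_mz, tr$mz_center,
                          tolerance = config$tolerance,
                          threshold = config$threshold))
      row$score_cnl <- cf$score
      dec$cnl <- method_decision("cnl", cf$score, config$threshold)
      row$cnl_accepted <- dec$cnl$accepted
    }
    if ("correlation" %in% methods) {
      r <- peak_correlation(feat$trace, tr)
      row$correlation <- r
      dec$correlation <- method_decision("correlation", r,
                                         config$corr_threshold)
      row$correlation_accepted <- dec$correlation$accepted
    }
    if ("tr_diff" %in% methods) {
      d <- apex_difference(feat, tr)
      row$tr_diff <- d
      dec$tr_diff <- method_decision("tr_diff", d, config$tr_diff_threshold)
      row$tr_diff_accepted <- dec$tr_diff$accepted
    }
    row$accepted <- combine_decisions(dec)
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mz = numeric(), cnl = numeric(), accepted = logical())
  }
  rownames(out) <- NULL
  out
}

#' Generate and write a synthetic library
#'
#' Wraps [generate_library()], writes the spectra as MSP and the ground
#' truth as TSV.
#'
#' @param out_msp Output MSP path.
#' @param out_truth Optional TSV path for the ground-truth loss table.
#' @param ... Passed to [generate_library()].
#' @return The `synthetic_library`, invisibly.
#' @export
cmd_simulate <- function(out_msp, out_truth = NULL, ...) {
  lib <- generate_library(...)
  write_msp(lib$spectra, out_msp)
  log_stage("simulate", compounds = lib$params$n_compounds,
            spectra = length(lib$spectra), path = out_msp)
  if (!is.null(out_truth)) {
    utils::write.table(lib$truth, out_truth, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(lib)
}
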