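#' Labeled true-positive CNL cases from raw library spectra
#'
#' One TP case per (spectrum, fragment): the fragment's CNL together with its
#' compound key and precursor m/z. Evaluation deliberately runs on the raw
#' replicate spectra, not the merged per-compound spectra the model is built
#' from, so well-measured compounds weigh in proportion to their evidence.
#' Fragments above the precursor or with CNLs off the grid emit no case.
#'
#' @param spectra List of [fragment_spectrum()] (raw, unmerged).
#' @param grid The [cnl_grid()] bounding valid CNLs.
#' @return Data frame with columns `compound_key`, `spectrum_id`,
#'   `precursor_mz`, `cnl`, `label` (all `"TP"`).
#' @export
make_tp_cases <- function(spectra, grid = cnl_grid()) {
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    cnl <- sp$precursor_mz - sp$peaks$mz
    cnl <- cnl[cnl >= grid$lo & cnl <= grid$hi]
    if (length(cnl) == 0) return(NULL)
    data.frame(compound_key = sp$compound_key, spectrum_id = i,
               precursor_mz = sp$precursor_mz, cnl = cnl, label = "TP")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(compound_key = character(), spectrum_id = integer(),
                      precursor_mz = numeric(), cnl = numeric(),
                      label = character())
  }
  rownames(out) <- NULL
  out
}

#' Labeled true-negative (decoy) CNL cases
#'
#' For each spectrum, `n_decoys` random fragment masses are drawn uniformly
#' on `[min_mass, precursor_mz]` and checked against every true fragment of
#' that compound across all of its spectra: any draw within `exclusion_tol`
#' of a true fragment is redrawn (rejection sampling, capped at 10,000
#' attempts per decoy; on failure the decoy is dropped with a warning). The
#' surviving masses are converted to CNLs; CNLs off the grid are dropped.
#'
#' @param spectra List of [fragment_spectrum()].
#' @param n_decoys Decoys per spectrum; default 200.
#' @param min_mass Lower bound of the decoy fragment mass range in Da;
#'   default 50.
#' @param exclusion_tol Exclusion tolerance around true fragment masses in
#'   Da; use the same tolerance the scores will be computed at.
#' @param grid The [cnl_grid()].
#' @param seed Optional integer seed for reproducible decoy sets.
#' @return Data frame with the same columns as [make_tp_cases()], `label`
#'   all `"TN"`.
#' @export
make_tn_cases <- function(spectra, n_decoys = 200, min_mass = 50,
                          exclusion_tol = 0.005, grid = cnl_grid(),
                          seed = NULL) {
  keys <- vapply(spectra, function(s) s$compound_key, character(1))
  frag_by_key <- lapply(split(seq_along(spectra), keys), function(ix) {
    sort(unlist(lapply(spectra[ix], function(s) s$peaks$mz)))
  })
  with_seed(seed, {
    rows <- lapply(seq_along(spectra), function(i) {
      sp <- spectra[[i]]
      if (sp$precursor_mz <= min_mass) {
        warning(sprintf("%s: precursor %.3f Da <= min_mass, no decoys",
                        sp$compound_key, sp$precursor_mz))
        return(NULL)
      }
      truth <- frag_by_key[[sp$compound_key]]
      d <- stats::runif(n_decoys, min_mass, sp$precursor_mz)
      near_truth <- function(x) {
        j <- findInterval(x, truth)
        lo <- ifelse(j >= 1, x - truth[pmax(j, 1)], Inf)
        hi <- ifelse(j < length(truth), truth[pmin(j + 1, length(truth))] - x, Inf)
        pmin(lo, hi) <= exclusion_tol
      }
      bad <- near_truth(d)
      attempts <- rep(1L, n_decoys)
      while (any(bad)) {
        if (all(attempts[bad] >= 10000L)) break
        d[bad] <- stats::runif(sum(bad), min_mass, sp$precursor_mz)
        attempts[bad] <- attempts[bad] + 1L
        bad <- near_truth(d)
      }
      if (any(bad)) {
        warning(sprintf("%s: dropped %d decoy(s) after 10,000 attempts",
                        sp$compound_key, sum(bad)))
        d <- d[!bad]
      }
      cnl <- sp$precursor_mz - d
      cnl <- cnl[cnl >= grid$lo & cnl <= grid$hi]
      if (length(cnl) == 0) return(NULL)
      data.frame(compound_key = sp$compound_key, spectrum_id = i,
                 precursor_mz = sp$precursor_mz, cnl = cnl, label = "TN")
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(compound_key = character(), spectrum_id = integer(),
                        precursor_mz = numeric(), cnl = numeric(),
                        label = character())
    }
    rownames(out) <- NULL
    out
  })
}

#' Detection-rate metrics at one operating point
#'
#' Confusion counts and the percentage rates used throughout the evaluation:
#' TPr = 100 TP/(TP+FN), FPr = 100 FP/(FP+TN), FDr = 100 FP/(FP+TP) and the
#' reduction rate 100 (FN+TN)/(TP+FP+TN+FN), i.e. the share of candidate
#' fragments rejected. FDr is reported as `NA` (missing, not zero) when
#' nothing is accepted.
#'
#' @param label Character vector of case labels, `"TP"` or `"TN"`.
#' @param accepted Logical vector of predictions, one per case.
#' @param tolerance,threshold Optional operating-point annotations carried
#'   into the output row.
#' @return One-row data frame: `tolerance`, `threshold`, `n_tp`, `n_fn`,
#'   `n_fp`, `n_tn`, `tpr`, `fpr`, `fdr`, `reduction_rate` (rates in
#'   percent).
#' @export
compute_rates <- function(label, accepted, tolerance = NA_real_,
                          threshold = NA_real_) {
  stopifnot(length(label) == length(accepted), length(label) > 0,
            all(label %in% c("TP", "TN")))
  n_tp <- sum(label == "TP" & accepted)
  n_fn <- sum(label == "TP" & !accepted)
  n_fp <- sum(label == "TN" & accepted)
  n_tn <- sum(label == "TN" & !accepted)
  data.frame(
    tolerance = tolerance, threshold = threshold,
    n_tp = n_tp, n_fn = n_fn, n_fp = n_fp, n_tn = n_tn,
    tpr = if (n_tp + n_fn > 0) 100 * n_tp / (n_tp + n_fn) else NA_real_,
    fpr = if (n_fp + n_tn > 0) 100 * n_fp / (n_fp + n_tn) else NA_real_,
    fdr = if (n_fp + n_tp > 0) 100 * n_fp / (n_fp + n_tp) else NA_real_,
    reduction_rate = 100 * (n_fn + n_tn) / length(label))
}

#' ROC grid over mass tolerances and score thresholds
#'
#' Scores every case once per tolerance with [score_cnl()], then sweeps the
#' score threshold (acceptance is `score > threshold`, strict) and computes a
#' [compute_rates()] row per grid cell. Deterministic given the cases.
#'
#' @param model A [build_model()] result.
#' @param cases Data frame of labeled cases ([make_tp_cases()] /
#'   [make_tn_cases()], row-bound).
#' @param tolerances Mass tolerances in Da; default the canonical seven
#'   (0.001, 0.005, 0.010, 0.020, 0.050, 0.100, 0.200).
#' @param thresholds Score thresholds; default `seq(-1, 1, by = 0.01)`.
#' @return An object of class `roc_result`: a data frame of rate rows with
#'   attribute `selected` (see [select_optimum()]).
#' @export
roc_grid <- function(model, cases,
                     tolerances = c(0.001, 0.005, 0.010, 0.020, 0.050,
                                    0.100, 0.200),
                     thresholds = seq(-1, 1, by = 0.01)) {
  stopifnot(nrow(cases) > 0)
  res <- lapply(tolerances, function(tol) {
    sc <- score_cnl(model, cases$cnl, tol)
    do.call(rbind, lapply(thresholds, function(thr) {
      compute_rates(cases$label, sc > thr, tolerance = tol, threshold = thr)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("roc_result", "data.frame")
  out
}

#' Select an operating point from a ROC grid
#'
#' Convenience selector: maximizes the Youden index (TPr - FPr); ties break
#' to the smaller tolerance, then the larger threshold (the more conservative
#' cell). The full grid remains the primary result; this is one defensible
#' summary of it, not the only one.
#'
#' @param grid A [roc_grid()] result.
#' @return The selected grid row (one-row data frame).
#' @export
select_optimum <- function(grid) {
  g <- as.data.frame(grid)
  g <- g[!is.na(g$tpr) & !is.na(g$fpr), , drop = FALSE]
  if (nrow(g) == 0) stop("select_optimum: no cells with defined TPr and FPr")
  youden <- g$tpr - g$fpr
  o <- order(-youden, g$tolerance, -g$threshold)
  g[o[1], , drop = FALSE]
}

#' Detection rates within strata
#'
#' Applies [compute_rates()] within each stratum (e.g. CNL mass ranges or
#' collision energies). Empty strata yield no row rather than a zero row.
#'
#' @param cases Labeled case data frame.
#' @param accepted Logical predictions, one per case.
#' @param strata Factor/character vector assigning each case to a stratum.
#' @return Data frame with one rate row per non-empty stratum, first column
#'   `stratum`.
#' @export
stratified_rates <- function(cases, accepted, strata) {
  stopifnot(nrow(cases) == length(accepted), nrow(cases) == length(strata))
  parts <- split(seq_len(nrow(cases)), strata, drop = TRUE)
  out <- do.call(rbind, lapply(names(parts), function(s) {
    ix <- parts[[s]]
    cbind(stratum = s, compute_rates(cases$label[ix], accepted[ix]))
  }))
  rownames(out) <- NULL
  out
}

#' Assign cases to CNL mass-range strata
#'
#' Cut points follow the ranges used when examining how performance varies
#' with CNL mass: 0-100, 100-200, 200-300 and 300+ Da by default.
#'
#' @param cases Labeled case data frame with a `cnl` column.
#' @param breaks Ascending cut points in Da.
#' @return Character vector of stratum labels.
#' @export
cnl_range_strata <- function(cases, breaks = c(0, 100, 200, 300, 1000)) {
  as.character(cut(cases$cnl, breaks = breaks, include.lowest = TRUE,
                   right = FALSE, dig.lab = 7))
}
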