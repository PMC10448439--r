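#' True-positive binary vector of a CNL spectrum
#'
#' The grid-length 0/1 vector with ones at the bins of the spectrum's CNLs.
#' Duplicate CNLs falling in one bin set the bit once.
#'
#' @param cnl_spectrum A `cnl_spectrum` from [to_cnl()].
#' @param grid The [cnl_grid()].
#' @return Logical vector of length `grid$n_bins` (bin `i` at position
#'   `i + 1`).
#' @export
tp_binary_vector <- function(cnl_spectrum, grid = cnl_grid()) {
  stopifnot(inherits(cnl_spectrum, "cnl_spectrum"))
  v <- logical(grid$n_bins)
  idx <- bin_index(grid, cnl_spectrum$cnls)
  if (anyNA(idx)) stop("CNL outside grid in tp_binary_vector")
  v[idx + 1L] <- TRUE
  v
}

#' True-negative binary vector of a CNL spectrum
#'
#' The complement of the TP vector, with all bins at CNL masses above the
#' precursor ion mass forced to zero: a CNL larger than the precursor is
#' physically impossible for that compound, so its absence carries no
#' true-negative information.
#'
#' @inheritParams tp_binary_vector
#' @return Logical vector of length `grid$n_bins`.
#' @export
tn_binary_vector <- function(cnl_spectrum, grid = cnl_grid()) {
  v <- !tp_binary_vector(cnl_spectrum, grid)
  pb <- precursor_bin(grid, cnl_spectrum$precursor_mz)
  if (pb < grid$n_bins - 1L) v[(pb + 2L):grid$n_bins] <- FALSE
  v
}

# highest grid bin reachable for a compound: the precursor's bin, clamped to
# the grid top when the precursor lies above it
precursor_bin <- function(grid, precursor_mz) {
  bin_index(grid, min(precursor_mz, grid$hi))
}

#' Build the CNL occurrence-probability model
#'
#' Accumulates per-compound TP and TN binary vectors over the grid, applies
#' Laplace (+1) smoothing to every bin of both distributions, and normalizes
#' each by its own total to obtain `P(CNL | TP)` and `P(CNL | TN)`. Under a
#' flat prior the posterior class probabilities are proportional to these
#' conditionals, which is what the score in [score_cnl()] contrasts.
#'
#' Counts are accumulated streamingly: the peak working set is a handful of
#' grid-length vectors, never the full per-compound vector stack.
#'
#' @param cnl_spectra List of `cnl_spectrum`, one per compound (merge
#'   replicates first with [merge_library()]).
#' @param grid The [cnl_grid()].
#' @param build_params Optional list of build metadata (bin width, mode,
#'   minimum resolution) stored with the model.
#' @return An object of class `cnl_model` with fields `grid`, `tp_counts`,
#'   `tn_counts` (smoothed occurrence counts), `tp_prob`, `tn_prob`
#'   (normalized probabilities), `n_compounds`, `build_params`.
#' @examples
#' sp <- structure(list(compound_key = "x", precursor_mz = 1000,
#'                      cnls = 18.011), class = "cnl_spectrum")
#' m <- build_model(list(sp))
#' m$tp_counts[18011 + 1]   # 2: one occurrence plus the +1 smoothing
#' @export
build_model <- function(cnl_spectra, grid = cnl_grid(), build_params = list()) {
  if (length(cnl_spectra) == 0) stop("build_model: no CNL spectra supplied")
  idx1 <- lapply(cnl_spectra, function(sp) {
    stopifnot(inherits(sp, "cnl_spectrum"))
    ix <- bin_index(grid, sp$cnls)
    ix <- ix[!is.na(ix)]
    unique(as.integer(ix)) + 1L            # 1-based, one bit per bin
  })
  tp_raw <- tabulate(unlist(idx1), nbins = grid$n_bins)
  # TN coverage: spectrum i contributes ones at all bins <= its precursor bin;
  # cov[b] = number of compounds whose precursor bin is >= b
  pb1 <- vapply(cnl_spectra,
                function(sp) as.integer(precursor_bin(grid, sp$precursor_mz)) + 1L,
                integer(1))
  cov <- rev(cumsum(rev(tabulate(pb1, nbins = grid$n_bins))))
  tn_raw <- cov - tp_raw
  if (any(tn_raw < 0)) stop("internal error: negative TN count")
  tp_counts <- tp_raw + 1
  tn_counts <- tn_raw + 1
  structure(list(grid = grid,
                 tp_counts = tp_counts,
                 tn_counts = tn_counts,
                 tp_prob = tp_counts / sum(tp_counts),
                 tn_prob = tn_counts / sum(tn_counts),
                 n_compounds = length(cnl_spectra),
                 build_params = build_params),
            class = "cnl_model")
}

#' @export
print.cnl_model <- function(x, ...) {
  cat(sprintf("<cnl_model> %d compounds, grid %g-%g Da step %g\n",
              x$n_compounds, x$grid$lo, x$grid$hi, x$grid$step))
  invisible(x)
}

#' Sum a probability vector over a mass window
#'
#' Sums `prob` over every bin whose centre mass lies in the closed interval
#' `[cnl_mass - tolerance, cnl_mass + tolerance]`, clipped to the grid. With
#' a 0.010 Da tolerance and a CNL mass of 18, this is the summed probability
#' of the bins at 17.990 through 18.010 (21 bins).
#'
#' @param prob Probability (or count) vector over the grid.
#' @param grid The [cnl_grid()].
#' @param cnl_mass Window centre in Da; must lie on the grid.
#' @param tolerance Half-width of the window in Da (>= 0).
#' @return The summed probability mass.
#' @export
sum_window <- function(prob, grid, cnl_mass, tolerance) {
  stopifnot(length(cnl_mass) == 1, tolerance >= 0)
  if (is.na(bin_index(grid, cnl_mass))) {
    stop(sprintf("CNL mass %.4f Da outside grid [%g, %g]",
                 cnl_mass, grid$lo, grid$hi))
  }
  b <- window_bounds(grid, cnl_mass, tolerance)
  sum(prob[(b[1, "lo"]:b[1, "hi"]) + 1])
}

# windowed TP/TN probability sums for a vector of CNL masses; NA rows for
# out-of-grid masses
window_sums <- function(model, cnl_mass, tolerance) {
  g <- model$grid
  ok <- !is.na(bin_index(g, cnl_mass))
  b <- window_bounds(g, cnl_mass, tolerance)
  tp <- rep(NA_real_, length(cnl_mass))
  tn <- rep(NA_real_, length(cnl_mass))
  for (i in which(ok)) {
    r <- (b[i, "lo"]:b[i, "hi"]) + 1
    tp[i] <- sum(model$tp_prob[r])
    tn[i] <- sum(model$tn_prob[r])
  }
  cbind(sum_p_tp = tp, sum_p_tn = tn)
}

#' score_CNL of a candidate cumulative neutral loss
#'
#' The normalized contrast of the windowed TP and TN probability masses,
#' `(sum P(TP) - sum P(TN)) / (sum P(TP) + sum P(TN))`, bounded in
#' `[-1, 1]` with neutral point 0. The +1 smoothing in [build_model()]
#' guarantees a strictly positive denominator.
#'
#' @param model A [build_model()] result.
#' @param cnl_mass CNL mass(es) in Da, within the grid.
#' @param tolerance Mass tolerance in Da (window half-width).
#' @return Numeric vector of scores in `[-1, 1]`.
#' @export
score_cnl <- function(model, cnl_mass, tolerance) {
  stopifnot(inherits(model, "cnl_model"))
  if (anyNA(bin_index(model$grid, cnl_mass))) {
    stop("score_cnl: CNL mass outside grid")
  }
  s <- window_sums(model, cnl_mass, tolerance)
  (s[, "sum_p_tp"] - s[, "sum_p_tn"]) / (s[, "sum_p_tp"] + s[, "sum_p_tn"])
}

#' Classify a candidate fragment of a precursor ion
#'
#' Converts the fragment to its CNL (`precursor_mz - fragment_mz`), scores it
#' with [score_cnl()], and accepts it when the score strictly exceeds the
#' threshold (so a threshold of +1 accepts nothing and ties are rejections).
#' Fragments above the precursor, or whose CNL falls off the grid, are
#' rejected outright with score -1.
#'
#' @param model A [build_model()] result.
#' @param precursor_mz Precursor ion m/z in Da.
#' @param fragment_mz Candidate fragment m/z in Da (vectorized).
#' @param tolerance Mass tolerance in Da; default 0.005.
#' @param threshold Score threshold; default 0.00.
#' @return A data.frame with one row per fragment: `fragment_mz`, `cnl`,
#'   `sum_p_tp`, `sum_p_tn`, `score`, `accepted`, plus attribute `threshold`.
#' @export
classify_fragment <- function(model, precursor_mz, fragment_mz,
                              tolerance = 0.005, threshold = 0.00) {
  stopifnot(inherits(model, "cnl_model"), length(precursor_mz) == 1)
  cnl <- precursor_mz - fragment_mz
  valid <- fragment_mz <= precursor_mz & !is.na(bin_index(model$grid, cnl))
  if (any(!valid)) {
    warning(sprintf("%d fragment(s) rejected outright (above precursor or CNL off grid)",
                    sum(!valid)))
  }
  out <- data.frame(fragment_mz = fragment_mz, cnl = cnl,
                    sum_p_tp = NA_real_, sum_p_tn = NA_real_,
                    score = -1, accepted = FALSE)
  if (any(valid)) {
    s <- window_sums(model, cnl[valid], tolerance)
    out$sum_p_tp[valid] <- s[, "sum_p_tp"]
    out$sum_p_tn[valid] <- s[, "sum_p_tn"]
    out$score[valid] <- (s[, "sum_p_tp"] - s[, "sum_p_tn"]) /
      (s[, "sum_p_tp"] + s[, "sum_p_tn"])
    out$accepted[valid] <- out$score[valid] > threshold
  }
  attr(out, "threshold") <- threshold
  attr(out, "tolerance") <- tolerance
  out
}

# current model container format version
.model_format_version <- "cnl_model/1"

#' Save / load a CNL model
#'
#' The model is written as a versioned R serialization (RDS) holding the
#' named count and probability arrays, the grid and the build metadata.
#' Round trips are bit-exact. Loading a file with a different format version,
#' or a truncated/corrupt file, raises an error rather than returning a
#' partial model.
#'
#' @param model A `cnl_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `cnl_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnl_model"))
  obj <- unclass(model)
  obj$format_version <- .model_format_version
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format_version, .model_format_version)) {
    stop("model file '", path, "' has unsupported format version: ",
         if (is.list(obj)) obj$format_version %||% "<none>" else "<not a model>")
  }
  obj$format_version <- NULL
  grid <- obj$grid
  class(grid) <- "cnl_grid"
  obj$grid <- grid
  class(obj) <- "cnl_model"
  obj
}
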