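#' CNL mass grid
#'
#' The fixed grid on which cumulative neutral losses (CNLs) are binned:
#' 0--1000 Da in 0.001 Da steps, i.e. 1,000,001 bin centres at exact
#' multiples of the step. All model vectors ([build_model()]) are indexed on
#' this grid. Bin indices are 0-based so that `index * step` is the bin
#' centre mass; R vectors holding per-bin values store bin `i` at position
#' `i + 1`.
#'
#' @param lo Lower grid edge in Da.
#' @param hi Upper grid edge in Da.
#' @param step Bin width in Da.
#' @return An object of class `cnl_grid` with fields `lo`, `hi`, `step`,
#'   `n_bins`.
#' @examples
#' g <- cnl_grid()
#' g$n_bins                 # 1000001
#' bin_index(g, 18.011)     # 18011
#' @export
cnl_grid <- function(lo = 0, hi = 1000, step = 0.001) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step),
            length(lo) == 1, length(hi) == 1, length(step) == 1,
            step > 0, hi > lo)
  n_bins <- as.integer(round((hi - lo) / step)) + 1L
  structure(list(lo = lo, hi = hi, step = step, n_bins = n_bins),
            class = "cnl_grid")
}

#' @export
print.cnl_grid <- function(x, ...) {
  cat(sprintf("<cnl_grid> %g-%g Da, step %g Da, %d bins\n",
              x$lo, x$hi, x$step, x$n_bins))
  invisible(x)
}

#' Nearest-bin index of a mass on the CNL grid
#'
#' Masses are assigned to the nearest bin centre. Masses further than half a
#' step outside the grid edges are out-of-grid and map to `NA`.
#'
#' @param grid A [cnl_grid()].
#' @param mass Numeric vector of masses in Da.
#' @return Integer-valued numeric vector of 0-based bin indices (`NA` when
#'   out of grid).
#' @export
bin_index <- function(grid, mass) {
  stopifnot(inherits(grid, "cnl_grid"))
  idx <- round((mass - grid$lo) / grid$step)
  idx[mass < grid$lo - grid$step / 2 | mass > grid$hi + grid$step / 2] <- NA_real_
  pmin(pmax(idx, 0), grid$n_bins - 1)
}

#' Bin centre mass for a 0-based grid index
#'
#' @param grid A [cnl_grid()].
#' @param index 0-based bin indices.
#' @return Masses in Da.
#' @export
bin_center <- function(grid, index) grid$lo + index * grid$step

# 0-based inclusive index bounds of the closed window [mass - tol, mass + tol],
# by bin-centre membership, clipped to the grid. The 1e-6-bin guard absorbs
# float rounding so that e.g. 18 +/- 0.01 yields exactly bins 17990..18010.
window_bounds <- function(grid, mass, tolerance) {
  lo_i <- ceiling((mass - tolerance - grid$lo) / grid$step - 1e-6)
  hi_i <- floor((mass + tolerance - grid$lo) / grid$step + 1e-6)
  cbind(lo = pmax(lo_i, 0), hi = pmin(hi_i, grid$n_bins - 1))
}
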