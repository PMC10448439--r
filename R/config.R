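#' Run configuration with canonical defaults
#'
#' All tunables in one record, with the defaults every command starts from:
#' model bin width 0.001 Da on the 0-1000 Da grid, scoring mass tolerance
#' 0.005 Da and score threshold 0.00, XIC grouping window 0.020 Da, S/N > 2
#' with at least 3 consecutive mean-exceeding scans, correlation threshold
#' 0.57, apex retention-time difference threshold 0.025 min, 200 decoys per
#' spectrum and no seed. Precedence is defaults < YAML config file <
#' explicit arguments.
#'
#' @param config_file Optional YAML file whose keys override the defaults.
#' @param ... Named overrides applied last (must be known keys).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- list(
    bin_width = 0.001,
    grid_lo = 0, grid_hi = 1000, grid_step = 0.001,
    tolerance = 0.005,
    threshold = 0.00,
    mass_window = 0.020,
    min_snr = 2,
    min_consecutive = 3,
    corr_threshold = 0.57,
    tr_diff_threshold = 0.025,
    n_decoys = 200,
    mode = "positive",
    min_resolution = 5000,
    seed = NULL)
  apply_over <- function(cfg, over, origin) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s) from ", origin, ": ",
           paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(config_file)) {
    cfg <- apply_over(cfg, yaml::read_yaml(config_file), config_file)
  }
  over <- list(...)
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(nzchar(names(over))))
    cfg <- apply_over(cfg, over, "arguments")
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %s = %s\n", k,
                if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}

config_grid <- function(config) {
  cnl_grid(config$grid_lo, config$grid_hi, config$grid_step)
}
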