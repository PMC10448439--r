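# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. seed = NULL runs in the ambient RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Structured, machine-parsable stage log: "[cnldeconv] stage=<s> <k>=<v> ..."
log_stage <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[cnldeconv] stage=", stage)
  if (length(kv)) {
    msg <- paste(msg, paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  }
  message(msg)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
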