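#' Common neutral-loss vocabulary
#'
#' The high-frequency neutral losses every synthetic library shares, with
#' the probability that each appears in a given compound's spectrum. The
#' defaults are the four classic small-molecule losses — water (18.011 Da),
#' ammonia (17.027 Da), methanol (32.026 Da) and C2H4O2 (60.021 Da) — at
#' frequencies 0.6, 0.3, 0.2 and 0.15.
#'
#' @param masses Loss masses in Da, in (0, 1000).
#' @param frequencies Per-compound occurrence probabilities in (0, 1].
#' @return A data frame of class `loss_vocabulary` with columns `mass`,
#'   `frequency`.
#' @export
loss_vocabulary <- function(masses = c(18.010565, 17.026549, 32.026215,
                                       60.021130),
                            frequencies = c(0.6, 0.3, 0.2, 0.15)) {
  stopifnot(length(masses) == length(frequencies),
            all(masses > 0), all(masses < 1000),
            all(frequencies > 0), all(frequencies <= 1))
  structure(data.frame(mass = masses, frequency = frequencies),
            class = c("loss_vocabulary", "data.frame"))
}

#' Shared catalog of recurring secondary neutral losses
#'
#' Real fragmentation chemistry re-uses neutral losses far beyond the
#' handful of textbook ones: the observed CNL occurrence distribution is
#' heavy-tailed, with many moieties recurring across tens of compounds. The
#' catalog emulates that tail: `n` loss masses drawn uniformly on
#' `mass_range`, carrying Zipf-like sampling weights (`rank^-exponent`,
#' assigned in random order so mass and frequency are independent).
#' Compound-specific losses are drawn from this catalog when building a
#' library, so distinct compound sets generated from one catalog share
#' chemistry the way distinct database subsets do.
#'
#' @param n Catalog size; default 64.
#' @param mass_range Mass range in Da; default 12-250 (small neutral
#'   moieties).
#' @param zipf_exponent Weight decay exponent; default 0.5 (mild
#'   concentration; every catalog loss still recurs at library scale).
#' @param seed Optional seed.
#' @return A data frame of class `loss_catalog` with columns `mass`,
#'   `weight` (weights sum to 1).
#' @export
loss_catalog <- function(n = 64, mass_range = c(12, 250),
                         zipf_exponent = 0.5, seed = NULL) {
  stopifnot(n >= 1, length(mass_range) == 2, mass_range[1] > 0,
            mass_range[2] > mass_range[1], zipf_exponent >= 0)
  with_seed(seed, {
    masses <- sort(stats::runif(n, mass_range[1], mass_range[2]))
    w <- sample((seq_len(n))^(-zipf_exponent))
    structure(data.frame(mass = masses, weight = w / sum(w)),
              class = c("loss_catalog", "data.frame"))
  })
}

#' Generate a synthetic fragmentation spectral library with known truth
#'
#' Each compound receives (a) every vocabulary loss independently with its
#' stated frequency and (b) `n_random_losses` secondary losses, each drawn
#' from the shared [loss_catalog()] (weighted, without replacement) with
#' probability `1 - unique_loss_frac` or as a compound-unique uniform mass
#' otherwise. Fragments are `precursor - loss`; losses that would push the
#' fragment below `min_fragment_mz` are not assigned. Every replicate
#' spectrum carries independent Gaussian m/z jitter on its fragments.
#' Precursor masses follow a lognormal distribution (median ~300 Da)
#' truncated to `precursor_range`.
#'
#' @param n_compounds Number of compounds; default 2000.
#' @param vocabulary A [loss_vocabulary()].
#' @param catalog A [loss_catalog()]; pass the same catalog to generate
#'   held-out libraries sharing the training chemistry. Default draws a
#'   fresh one from the current RNG stream.
#' @param n_random_losses Secondary losses per compound; default 5.
#' @param unique_loss_frac Probability that a secondary loss is
#'   compound-unique rather than drawn from the catalog; default 0.1.
#' @param replicate_count Replicate spectra per compound; default 3.
#' @param mass_jitter_sd Per-replicate fragment m/z jitter sd in Da;
#'   default 0.001.
#' @param precursor_meanlog,precursor_sdlog Lognormal parameters of the
#'   precursor mass distribution; defaults `log(300)` and 0.35.
#' @param precursor_range Truncation range in Da; default `c(100, 1000)`.
#' @param min_fragment_mz Smallest recordable fragment m/z in Da; default 50
#'   (typical lower scan bound).
#' @param seed Optional seed; identical seeds give identical libraries.
#' @return A list of class `synthetic_library`: `spectra` (list of
#'   [fragment_spectrum()], `replicate_count` per compound), `truth` (data
#'   frame `compound_key`, `precursor_mz`, `loss_mass`, `loss_type` in
#'   {vocabulary, catalog, unique}), `vocabulary`, `catalog`, `params`.
#' @export
generate_library <- function(n_compounds = 2000,
                             vocabulary = loss_vocabulary(),
                             catalog = NULL,
                             n_random_losses = 5,
                             unique_loss_frac = 0.1,
                             replicate_count = 3,
                             mass_jitter_sd = 0.001,
                             precursor_meanlog = log(300),
                             precursor_sdlog = 0.35,
                             precursor_range = c(100, 1000),
                             min_fragment_mz = 50,
                             seed = NULL) {
  stopifnot(n_compounds >= 1, replicate_count >= 1, n_random_losses >= 0,
            unique_loss_frac >= 0, unique_loss_frac <= 1)
  with_seed(seed, {
    if (is.null(catalog)) catalog <- loss_catalog()
    stopifnot(inherits(catalog, "loss_catalog"))
    # truncated lognormal precursors, by rejection
    prec <- numeric(0)
    while (length(prec) < n_compounds) {
      p <- stats::rlnorm(n_compounds, precursor_meanlog, precursor_sdlog)
      prec <- c(prec, p[p >= precursor_range[1] & p <= precursor_range[2]])
    }
    prec <- prec[seq_len(n_compounds)]
    spectra <- vector("list", n_compounds * replicate_count)
    truth <- vector("list", n_compounds)
    energies <- c(0, 20, 40)
    k <- 0L
    for (i in seq_len(n_compounds)) {
      key <- sprintf("syn%05d", i)
      max_loss <- prec[i] - min_fragment_mz
      vm <- vocabulary$mass[stats::runif(nrow(vocabulary)) <
                              vocabulary$frequency]
      vm <- vm[vm <= max_loss]
      is_unique <- stats::runif(n_random_losses) < unique_loss_frac
      allowed <- which(catalog$mass <= max_loss)
      n_cat <- min(sum(!is_unique), length(allowed))
      cm <- if (n_cat > 0) {
        pick <- allowed[sample.int(length(allowed), n_cat,
                                   prob = catalog$weight[allowed])]
        catalog$mass[pick]
      } else {
        numeric(0)
      }
      n_uni <- n_random_losses - n_cat
      um <- if (n_uni > 0 && max_loss > 12) {
        stats::runif(n_uni, 12, max_loss)
      } else {
        numeric(0)
      }
      losses <- c(vm, cm, um)
      type <- c(rep("vocabulary", length(vm)), rep("catalog", length(cm)),
                rep("unique", length(um)))
      dup <- duplicated(losses)
      losses <- losses[!dup]
      type <- type[!dup]
      if (length(losses) == 0) {
        # a compound that drew nothing still fragments somehow: give it one
        # compound-unique loss so every spectrum has a peak
        losses <- stats::runif(1, 12, max(max_loss, 13))
        type <- "unique"
      }
      truth[[i]] <- data.frame(compound_key = key, precursor_mz = prec[i],
                               loss_mass = losses, loss_type = type)
      for (r in seq_len(replicate_count)) {
        frag <- prec[i] - losses +
          stats::rnorm(length(losses), 0, mass_jitter_sd)
        inten <- stats::rlnorm(length(losses), log(1000), 1)
        k <- k + 1L
        spectra[[k]] <- fragment_spectrum(
          compound_key = key, precursor_mz = prec[i],
          peaks = data.frame(mz = frag, intensity = inten),
          adduct_mode = "positive", resolution = 30000,
          collision_energy = energies[(r - 1L) %% 3L + 1L])
      }
    }
    structure(list(spectra = spectra,
                   truth = do.call(rbind, truth),
                   vocabulary = vocabulary,
                   catalog = catalog,
                   params = list(n_compounds = n_compounds,
                                 n_random_losses = n_random_losses,
                                 unique_loss_frac = unique_loss_frac,
                                 replicate_count = replicate_count,
                                 mass_jitter_sd = mass_jitter_sd,
                                 precursor_meanlog = precursor_meanlog,
                                 precursor_sdlog = precursor_sdlog,
                                 precursor_range = precursor_range,
                                 min_fragment_mz = min_fragment_mz)),
              class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf("<synthetic_library> %d compounds x %d replicates = %d spectra\n",
              x$params$n_compounds, x$params$replicate_count,
              length(x$spectra)))
  invisible(x)
}

#' Simulate a chromatographic MS2 scan series with known labels
#'
#' Builds centroided MS2 scans on a uniform time grid: every feature is a
#' Gaussian elution profile plus additive baseline noise, sampled at
#' `scan_rate`. True fragments share the precursor apex; interferents carry
#' their own offsets. One feature must be flagged as the precursor.
#'
#' @param features Data frame with columns `mz` (Da), `apex` (minutes),
#'   `width` (Gaussian sigma, minutes), `amplitude` (counts),
#'   `is_precursor` (logical, exactly one `TRUE`), `is_true_fragment`
#'   (logical).
#' @param scan_rate Scans per second; default 6 Hz.
#' @param time_range Simulated window in minutes; default covers all apexes
#'   +/- 5 widths.
#' @param noise_sd Baseline noise sd in counts (half-normal, so intensities
#'   stay non-negative); default 2.
#' @param intensity_threshold Centroiding intensity cutoff in counts:
#'   intensities below it are recorded as zero, as vendor conversion and
#'   centroiding thresholds do in real data. Default `3 * noise_sd`, so a
#'   noise-only m/z channel yields a mostly-zero, spiky trace.
#' @param mz_jitter_sd Per-scan m/z jitter sd in Da; default 0.002.
#' @param seed Optional seed.
#' @return A list: `scans` (long data frame `scan_time`, `mz`, `intensity`),
#'   `precursor` (a [precursor_feature()] built from the noiseless precursor
#'   profile), `labels` (the input `features` with a `trace_mz` column).
#' @export
generate_chromatogram <- function(features, scan_rate = 6,
                                  time_range = NULL, noise_sd = 2,
                                  intensity_threshold = 3 * noise_sd,
                                  mz_jitter_sd = 0.002, seed = NULL) {
  features <- as.data.frame(features)
  need <- c("mz", "apex", "width", "amplitude", "is_precursor",
            "is_true_fragment")
  stopifnot(all(need %in% names(features)),
            sum(features$is_precursor) == 1,
            all(features$width > 0), scan_rate > 0)
  if (is.null(time_range)) {
    time_range <- c(min(features$apex - 5 * features$width),
                    max(features$apex + 5 * features$width))
  }
  with_seed(seed, {
    dt <- 1 / (scan_rate * 60)             # minutes between scans
    times <- seq(time_range[1], time_range[2], by = dt)
    rows <- lapply(seq_len(nrow(features)), function(i) {
      f <- features[i, ]
      y <- f$amplitude * exp(-(times - f$apex)^2 / (2 * f$width^2)) +
        abs(stats::rnorm(length(times), 0, noise_sd))
      y[y < intensity_threshold] <- 0
      data.frame(scan_time = times,
                 mz = f$mz + stats::rnorm(length(times), 0, mz_jitter_sd),
                 intensity = y,
                 feature = i)
    })
    scans <- do.call(rbind, rows)
    p <- which(features$is_precursor)
    prec_y <- features$amplitude[p] *
      exp(-(times - features$apex[p])^2 / (2 * features$width[p]^2))
    prec_trace <- xic_trace(features$mz[p], times, prec_y)
    precursor <- precursor_feature(features$mz[p], features$apex[p],
                                   time_range[1] - dt, time_range[2] + dt,
                                   prec_trace)
    labels <- features
    labels$trace_mz <- features$mz
    list(scans = scans[order(scans$scan_time), c("scan_time", "mz", "intensity")],
         precursor = precursor, labels = labels)
  })
}
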