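#' Construct a single library fragment spectrum
#'
#' One entry of a fragmentation spectral library: a compound identifier, the
#' precursor ion m/z, the ionization mode and a fragment peak list. Peaks are
#' sorted ascending by m/z. Intensities are carried along but are never used
#' by the CNL model, which treats every recorded fragment equally.
#'
#' @param compound_key Opaque identifier string. Prefer an InChIKey, else a
#'   SMILES, else a normalized name (see [compound_key()]).
#' @param precursor_mz Precursor ion m/z in Da (> 0).
#' @param peaks Two-column matrix or data.frame `(mz, intensity)`; m/z > 0.
#' @param adduct_mode `"positive"` or `"negative"`.
#' @param resolution Optional mass resolution (dimensionless); `NA` if the
#'   library entry does not state one.
#' @param collision_energy Optional collision energy in eV.
#' @return An object of class `fragment_spectrum`.
#' @export
fragment_spectrum <- function(compound_key, precursor_mz, peaks,
                              adduct_mode = c("positive", "negative"),
                              resolution = NA_real_,
                              collision_energy = NA_real_) {
  adduct_mode <- match.arg(adduct_mode)
  stopifnot(is.character(compound_key), length(compound_key) == 1,
            nzchar(compound_key),
            is.numeric(precursor_mz), length(precursor_mz) == 1,
            precursor_mz > 0)
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) < 2) stop("peaks must have columns mz, intensity")
  names(peaks)[1:2] <- c("mz", "intensity")
  peaks <- peaks[, c("mz", "intensity")]
  if (nrow(peaks) == 0) stop("fragment_spectrum requires at least one peak")
  if (any(peaks$mz <= 0)) stop("all peak m/z must be > 0")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(compound_key = compound_key,
                 precursor_mz = precursor_mz,
                 adduct_mode = adduct_mode,
                 resolution = as.numeric(resolution),
                 collision_energy = as.numeric(collision_energy),
                 peaks = peaks),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat(sprintf("<fragment_spectrum> %s  precursor %.4f Da  %s mode  %d peaks\n",
              x$compound_key, x$precursor_mz, x$adduct_mode, nrow(x$peaks)))
  invisible(x)
}

#' Derive the compound identity key for a library entry
#'
#' InChIKey when present, else SMILES, else the case-folded,
#' whitespace-normalized name. Libraries annotate "unique chemical
#' constituents" inconsistently; this ladder keeps replicate entries of one
#' chemical under one key without requiring structure resolution.
#'
#' @param name Compound name (may be `NA`/empty).
#' @param inchikey InChIKey string or `NA`.
#' @param smiles SMILES string or `NA`.
#' @return A single key string, or `NA_character_` if all inputs are empty.
#' @export
compound_key <- function(name = NA, inchikey = NA, smiles = NA) {
  pick <- function(x) !is.na(x) && nzchar(trimws(x))
  if (pick(inchikey)) return(trimws(inchikey))
  if (pick(smiles)) return(trimws(smiles))
  if (pick(name)) {
    nm <- tolower(trimws(name))
    return(gsub("\\s+", " ", nm))
  }
  NA_character_
}

#' Read a fragmentation spectral library
#'
#' Parses an MSP (NIST text dialect) or MGF file into a list of
#' [fragment_spectrum()] objects. Entries missing a precursor m/z or a peak
#' list are skipped with a warning; the number skipped is attached as
#' attribute `n_skipped`.
#'
#' @param path File path.
#' @param format `"msp"` or `"mgf"`; default guesses from the file extension.
#' @return List of `fragment_spectrum` with attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("auto", "msp", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, msp = "msp", mgf = "mgf",
                     stop("cannot guess library format from extension: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "msp") parse_msp(lines) else parse_mgf(lines)
}

# ---- MSP (NIST text dialect) ------------------------------------------------

# Header lines "Key: value" until "Num Peaks: n", then n "mz intensity" lines.
# Entries are separated by blank lines.
parse_msp <- function(lines) {
  out <- list()
  n_skipped <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    hdr <- list()
    peaks <- NULL
    while (i <= n && nzchar(trimws(lines[i]))) {
      ln <- lines[i]
      m <- regmatches(ln, regexec("^\\s*([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) == 3) {
        key <- tolower(gsub("[ _]", "", m[2]))
        val <- trimws(m[3])
        if (key == "numpeaks") {
          npk <- suppressWarnings(as.integer(val))
          i <- i + 1L
          pk <- list()
          while (i <= n && nzchar(trimws(lines[i])) &&
                 grepl("^\\s*[0-9]", lines[i])) {
            flds <- strsplit(trimws(lines[i]), "[\\s;,]+", perl = TRUE)[[1]]
            pk[[length(pk) + 1L]] <- suppressWarnings(as.numeric(flds[1:2]))
            i <- i + 1L
          }
          if (length(pk)) {
            peaks <- do.call(rbind, pk)
            colnames(peaks) <- c("mz", "intensity")
          }
          if (!is.na(npk) && length(pk) != npk) {
            warning(sprintf("MSP entry '%s': Num Peaks says %d, found %d",
                            hdr$name %||% "?", npk, length(pk)))
          }
          next
        }
        hdr[[key]] <- val
      }
      i <- i + 1L
    }
    sp <- msp_entry_to_spectrum(hdr, peaks)
    if (is.null(sp)) n_skipped <- n_skipped + 1L else out[[length(out) + 1L]] <- sp
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

msp_entry_to_spectrum <- function(hdr, peaks) {
  prec <- suppressWarnings(as.numeric(hdr$precursormz %||% hdr$precursor))
  if (length(prec) != 1 || is.na(prec) || prec <= 0 || is.null(peaks) ||
      nrow(peaks) == 0 || anyNA(peaks)) {
    warning("skipping malformed library entry (missing precursor m/z or peaks): ",
            hdr$name %||% "<unnamed>")
    return(NULL)
  }
  key <- compound_key(name = hdr$name %||% NA,
                      inchikey = hdr$inchikey %||% NA,
                      smiles = hdr$smiles %||% NA)
  if (is.na(key)) {
    warning("skipping library entry with no usable identifier")
    return(NULL)
  }
  mode <- tolower(hdr$ionmode %||% hdr$mode %||% "positive")
  mode <- if (grepl("^n", mode)) "negative" else "positive"
  peaks <- peaks[peaks[, 1] > 0, , drop = FALSE]
  if (nrow(peaks) == 0) {
    warning("skipping library entry with no valid peaks: ", key)
    return(NULL)
  }
  fragment_spectrum(
    compound_key = key,
    precursor_mz = prec,
    peaks = peaks,
    adduct_mode = mode,
    resolution = suppressWarnings(as.numeric(hdr$resolution %||% NA)),
    collision_energy = parse_energy(hdr$collisionenergy %||% NA))
}

parse_energy <- function(x) {
  if (is.na(x)) return(NA_real_)
  m <- regmatches(x, regexpr("[0-9.]+", x))
  if (length(m)) suppressWarnings(as.numeric(m)) else NA_real_
}

# ---- MGF --------------------------------------------------------------------

parse_mgf <- function(lines) {
  out <- list()
  n_skipped <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^\\s*BEGIN IONS", lines[i], ignore.case = TRUE)) {
      i <- i + 1L
    }
    if (i > n) break
    i <- i + 1L
    hdr <- list()
    pk <- list()
    while (i <= n && !grepl("^\\s*END IONS", lines[i], ignore.case = TRUE)) {
      ln <- trimws(lines[i])
      if (grepl("=", ln, fixed = TRUE)) {
        key <- tolower(sub("=.*$", "", ln))
        hdr[[gsub("[ _]", "", key)]] <- sub("^[^=]*=", "", ln)
      } else if (grepl("^[0-9]", ln)) {
        flds <- strsplit(ln, "[\\s]+", perl = TRUE)[[1]]
        pk[[length(pk) + 1L]] <- suppressWarnings(
          as.numeric(c(flds[1], if (length(flds) > 1) flds[2] else "0")))
      }
      i <- i + 1L
    }
    i <- i + 1L
    prec <- suppressWarnings(
      as.numeric(strsplit(hdr$pepmass %||% "", "\\s+")[[1]][1]))
    peaks <- if (length(pk)) do.call(rbind, pk) else NULL
    if (length(prec) != 1 || is.na(prec) || prec <= 0 || is.null(peaks) ||
        anyNA(peaks)) {
      warning("skipping malformed MGF entry: ", hdr$title %||% "<untitled>")
      n_skipped <- n_skipped + 1L
      next
    }
    colnames(peaks) <- c("mz", "intensity")
    mode <- if (grepl("-", hdr$charge %||% "1+", fixed = TRUE)) {
      "negative"
    } else {
      "positive"
    }
    key <- compound_key(name = hdr$title %||% NA,
                        inchikey = hdr$inchikey %||% NA,
                        smiles = hdr$smiles %||% NA)
    if (is.na(key)) {
      warning("skipping MGF entry with no usable identifier")
      n_skipped <- n_skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- fragment_spectrum(
      compound_key = key, precursor_mz = prec, peaks = peaks,
      adduct_mode = mode,
      resolution = suppressWarnings(as.numeric(hdr$resolution %||% NA)),
      collision_energy = parse_energy(hdr$collisionenergy %||% NA))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write spectra to an MSP library file
#'
#' NIST text dialect; m/z written with six decimals so that synthetic
#' libraries round-trip through [read_library()].
#'
#' @param spectra List of [fragment_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      paste0("Name: ", sp$compound_key),
      paste0("PrecursorMZ: ", sprintf("%.6f", sp$precursor_mz)),
      paste0("Ion_mode: ", if (sp$adduct_mode == "positive") "P" else "N"),
      if (!is.na(sp$resolution)) paste0("Resolution: ", sp$resolution),
      if (!is.na(sp$collision_energy)) {
        paste0("Collision_energy: ", sp$collision_energy)
      },
      paste0("Num Peaks: ", nrow(sp$peaks)),
      sprintf("%.6f %.1f", sp$peaks$mz, sp$peaks$intensity),
      ""), con)
  }
  invisible(path)
}

#' Filter a spectral library by ionization mode and mass resolution
#'
#' Retains entries recorded in the requested ionization mode with a mass
#' resolution at or above `min_resolution`. Entries whose resolution is not
#' annotated are retained by default (library metadata is inconsistently
#' annotated and dropping them would silently empty many libraries); set
#' `strict = TRUE` to drop them.
#'
#' @param spectra List of [fragment_spectrum()].
#' @param mode `"positive"` or `"negative"`.
#' @param min_resolution Minimum mass resolution; default 5000.
#' @param strict Drop entries with no resolution annotation?
#' @return Filtered list.
#' @export
filter_library <- function(spectra, mode = c("positive", "negative"),
                           min_resolution = 5000, strict = FALSE) {
  mode <- match.arg(mode)
  keep <- vapply(spectra, function(sp) {
    if (sp$adduct_mode != mode) return(FALSE)
    if (is.na(sp$resolution)) return(!strict)
    sp$resolution >= min_resolution
  }, logical(1))
  spectra[keep]
}

#' Merge replicate spectra of one compound
#'
#' All spectra sharing a compound key are pooled so that each compound
#' contributes exactly one spectrum to the model regardless of how many
#' replicate measurements the library holds. The union of fragment m/z
#' values is collapsed by single-linkage chaining at `bin_width`: values
#' whose neighbour gaps are all within `bin_width` form one cluster,
#' represented by the mean m/z of its members.
#'
#' @param spectra List of [fragment_spectrum()] sharing one `compound_key`.
#' @param bin_width Collapse window in Da (default 0.001).
#' @return An object of class `merged_spectrum` with fields `compound_key`,
#'   `precursor_mz`, `fragment_mzs`.
#' @export
merge_compound <- function(spectra, bin_width = 0.001) {
  if (length(spectra) == 0) stop("merge_compound requires at least one spectrum")
  keys <- vapply(spectra, function(s) s$compound_key, character(1))
  if (length(unique(keys)) != 1) {
    stop("merge_compound: spectra carry different compound keys: ",
         paste(unique(keys), collapse = ", "))
  }
  precs <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  if (diff(range(precs)) > 0.01) {
    stop(sprintf("conflicting precursor m/z for compound '%s' (range %.4f-%.4f Da)",
                 keys[1], min(precs), max(precs)))
  }
  mz <- sort(unlist(lapply(spectra, function(s) s$peaks$mz)))
  # single-linkage: start a new cluster where the neighbour gap exceeds bin_width
  grp <- cumsum(c(1, diff(mz) > bin_width))
  frag <- as.numeric(tapply(mz, grp, mean))
  structure(list(compound_key = keys[1],
                 precursor_mz = mean(precs),
                 fragment_mzs = frag),
            class = "merged_spectrum")
}

#' Merge a whole library into one spectrum per compound
#'
#' Groups spectra by `compound_key` and applies [merge_compound()] to each
#' group.
#'
#' @inheritParams merge_compound
#' @return List of `merged_spectrum`, one per unique compound.
#' @export
merge_library <- function(spectra, bin_width = 0.001) {
  keys <- vapply(spectra, function(s) s$compound_key, character(1))
  lapply(split(spectra, factor(keys, levels = unique(keys))),
         merge_compound, bin_width = bin_width)
}

#' Construct a CNL spectrum directly
#'
#' Normally produced by [to_cnl()]; the constructor is exposed for building
#' models from externally computed CNL lists.
#'
#' @param compound_key Compound identifier.
#' @param precursor_mz Precursor ion m/z in Da.
#' @param cnls Cumulative neutral losses in Da, each in `[0, 1000]`.
#' @return An object of class `cnl_spectrum`.
#' @export
cnl_spectrum <- function(compound_key, precursor_mz, cnls) {
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0,
            all(cnls >= 0), all(cnls <= 1000))
  structure(list(compound_key = compound_key, precursor_mz = precursor_mz,
                 cnls = sort(as.numeric(cnls)), n_dropped = 0L),
            class = "cnl_spectrum")
}

#' Convert a merged spectrum to cumulative neutral losses
#'
#' Each CNL is the precursor ion mass minus a fragment m/z. CNLs outside the
#' model grid range (negative, i.e. fragment above precursor, or above
#' 1000 Da) are dropped; the number dropped is recorded in the `n_dropped`
#' field and reported with a warning. Fragments above the precursor are
#' treated as isotope/noise signals and removed here rather than at merging.
#'
#' @param merged A `merged_spectrum` from [merge_compound()].
#' @param grid The [cnl_grid()] bounding valid CNLs.
#' @return An object of class `cnl_spectrum` with fields `compound_key`,
#'   `precursor_mz` and `cnls` (sorted ascending).
#' @export
to_cnl <- function(merged, grid = cnl_grid()) {
  stopifnot(inherits(merged, "merged_spectrum"))
  cnl <- merged$precursor_mz - merged$fragment_mzs
  ok <- cnl >= grid$lo & cnl <= grid$hi
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(sprintf("%s: dropped %d CNL(s) outside [%g, %g] Da",
                    merged$compound_key, n_dropped, grid$lo, grid$hi))
  }
  structure(list(compound_key = merged$compound_key,
                 precursor_mz = merged$precursor_mz,
                 cnls = sort(cnl[ok]),
                 n_dropped = n_dropped),
            class = "cnl_spectrum")
}
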