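#' One-dimensional NMR spectrum
#'
#' Container for a single 1D \eqn{^1}H-NMR spectrum: a strictly ascending
#' chemical-shift axis (ppm) and one real-valued intensity per axis point.
#' Input axes in descending file order (the usual NMR convention) are
#' re-sorted to ascending on construction.
#'
#' @param sample_id Single string identifying the sample.
#' @param ppm Numeric vector of chemical shifts in ppm.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#'
#' @return An object of class `nmr_spectrum`: a list with elements
#'   `sample_id`, `ppm` (ascending) and `intensity`.
#' @examples
#' sp <- nmr_spectrum("s1", seq(-0.5, 10, by = 0.01), rnorm(1051))
#' range(sp$ppm)
#' @export
nmr_spectrum <- function(sample_id, ppm, intensity) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have the same length (sample '", sample_id, "')")
  }
  if (length(ppm) < 2L) stop("a spectrum needs at least two points")
  if (anyNA(ppm) || anyNA(intensity) || any(!is.finite(intensity))) {
    stop("non-finite values in spectrum '", sample_id, "'")
  }
  o <- order(ppm)
  ppm <- ppm[o]
  intensity <- intensity[o]
  if (any(diff(ppm) <= 0)) {
    stop("ppm axis of '", sample_id, "' is not strictly monotone")
  }
  structure(list(sample_id = sample_id, ppm = ppm, intensity = intensity),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.3f to %.3f ppm\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Read a spectrum from a two-column ASCII file
#'
#' Expects one (ppm, intensity) pair per line, whitespace- or
#' comma-delimited; lines starting with `#` are skipped. The file name stem
#' becomes the sample id.
#'
#' @param path Path to the file.
#' @param sample_id Optional explicit sample id; defaults to the file stem.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty spectrum file: ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  if (any(lengths(parts) < 2L)) stop("malformed line in ", path)
  ppm <- as.numeric(vapply(parts, `[[`, "", 1L))
  intensity <- as.numeric(vapply(parts, `[[`, "", 2L))
  nmr_spectrum(sample_id, ppm, intensity)
}

#' Write a spectrum to a two-column ASCII file
#'
#' @param spec An [nmr_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  utils::write.table(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Preprocessing configuration
#'
#' Parameters of the spectral preprocessing chain: chemical-shift reference
#' calibration, bucketing and total-area normalization.
#'
#' @param reference_ppm Target position of the reference (TMSP) peak, ppm.
#' @param reference_search_window ppm pair searched for the reference apex.
#' @param bin_width Bucket width in ppm.
#' @param ppm_range ppm pair `(low, high)` tiled by the buckets.
#' @param exclusion_regions List of ppm pairs; any bucket overlapping one of
#'   these (the residual water resonance by default) is dropped entirely.
#' @param normalization_total Row total after total-area normalization.
#'
#' @return A list of class `preprocess_config`.
#' @examples
#' cfg <- preprocess_config(ppm_range = c(0, 10))
#' @export
preprocess_config <- function(reference_ppm = 0.0,
                              reference_search_window = c(-0.2, 0.2),
                              bin_width = 0.02,
                              ppm_range = c(-0.5, 10.0),
                              exclusion_regions = list(c(4.3, 6.5)),
                              normalization_total = 1.0) {
  stopifnot(bin_width > 0, length(ppm_range) == 2L, ppm_range[1] < ppm_range[2],
            length(reference_search_window) == 2L,
            reference_search_window[1] < reference_search_window[2],
            normalization_total > 0)
  for (reg in exclusion_regions) {
    if (length(reg) != 2L || reg[1] >= reg[2]) {
      stop("each exclusion region must be a (low, high) pair with low < high")
    }
  }
  structure(list(reference_ppm = reference_ppm,
                 reference_search_window = reference_search_window,
                 bin_width = bin_width,
                 ppm_range = ppm_range,
                 exclusion_regions = exclusion_regions,
                 normalization_total = normalization_total),
            class = "preprocess_config")
}

#' Calibrate the chemical-shift axis on the reference peak
#'
#' Rigidly shifts the ppm axis so that the intensity maximum inside the
#' reference search window lands exactly on `reference_ppm` (0.00 ppm for
#' TMSP). Apex ties are broken toward the candidate closest to the target
#' position. Intensities are unchanged; calibration is idempotent.
#'
#' @param spec An [nmr_spectrum()].
#' @param cfg A [preprocess_config()].
#' @return The calibrated spectrum.
#' @export
calibrate_reference <- function(spec, cfg = preprocess_config()) {
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(cfg, "preprocess_config"))
  win <- cfg$reference_search_window
  idx <- which(spec$ppm >= win[1] & spec$ppm <= win[2])
  if (length(idx) == 0L) {
    stop(sprintf("no axis points inside reference search window [%g, %g] ppm",
                 win[1], win[2]))
  }
  vals <- spec$intensity[idx]
  cand <- idx[vals >= max(vals) - .Machine$double.eps * abs(max(vals))]
  apex <- cand[which.min(abs(spec$ppm[cand] - cfg$reference_ppm))]
  shift <- spec$ppm[apex] - cfg$reference_ppm
  nmr_spectrum(spec$sample_id, spec$ppm - shift, spec$intensity)
}

#' Baseline correction
#'
#' Optional simple baseline operation. `"none"` is the identity.
#' `"rolling_min_subtract"` subtracts a running-minimum envelope computed
#' over a window of `window` axis points; the envelope is floored at zero so
#' the corrected intensity never exceeds the input.
#'
#' @param spec An [nmr_spectrum()].
#' @param method `"none"` or `"rolling_min_subtract"`.
#' @param window Odd number of axis points in the running-minimum window.
#' @return The corrected spectrum.
#' @export
correct_baseline <- function(spec, method = c("none", "rolling_min_subtract"),
                             window = 101L) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  method <- match.arg(method)
  if (method == "none") return(spec)
  n <- length(spec$intensity)
  half <- max(1L, as.integer(window) %/% 2L)
  env <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    min(spec$intensity[lo:hi])
  }, numeric(1))
  env <- pmax(env, 0)
  nmr_spectrum(spec$sample_id, spec$ppm, spec$intensity - env)
}
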