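# Trapezoidal integral of a spectrum over [lo, hi], with linear
# interpolation at the window edges so contiguous windows add exactly.
trapz_window <- function(ppm, intensity, lo, hi) {
  if (lo >= hi) stop("integration window must have low < high")
  if (lo < ppm[1] || hi > ppm[length(ppm)]) {
    stop(sprintf("window [%g, %g] outside spectrum range [%g, %g]",
                 lo, hi, ppm[1], ppm[length(ppm)]))
  }
  inside <- ppm > lo & ppm < hi
  xs <- c(lo, ppm[inside], hi)
  ys <- c(stats::approx(ppm, intensity, xout = lo)$y,
          intensity[inside],
          stats::approx(ppm, intensity, xout = hi)$y)
  pracma::trapz(xs, ys)
}

# Half-open bucket intervals [low, low + width) tiling ppm_range from its
# low end; buckets with a positive-length overlap of an exclusion region
# are dropped entirely.
bin_intervals <- function(cfg) {
  lo <- cfg$ppm_range[1]
  hi <- cfg$ppm_range[2]
  w <- cfg$bin_width
  n <- floor((hi - lo) / w + 1e-9)
  lows <- lo + (seq_len(n) - 1L) * w
  highs <- lows + w
  keep <- rep(TRUE, n)
  for (reg in cfg$exclusion_regions) {
    keep <- keep & !(lows < reg[2] & highs > reg[1])
  }
  data.frame(low = lows[keep], high = highs[keep],
             center = (lows[keep] + highs[keep]) / 2)
}

#' Segment a spectrum into fixed-width buckets
#'
#' Tiles `cfg$ppm_range` with half-open `[low, low + bin_width)` intervals
#' anchored at the range's low end, drops every bucket that overlaps an
#' exclusion region (the 4.3-6.5 ppm residual water resonance by default),
#' and integrates the intensity over each retained bucket by the
#' trapezoidal rule on the native ppm grid. Bucket ids are the interval
#' centres printed to three decimals.
#'
#' @param spec A calibrated [nmr_spectrum()].
#' @param cfg A [preprocess_config()].
#' @return A list with `values` (numeric vector of bucket integrals) and
#'   `bin_ids` (character vector of bucket centres).
#' @examples
#' cfg <- preprocess_config(ppm_range = c(0, 10))
#' sp <- nmr_spectrum("s", seq(-0.5, 10.5, by = 0.005), rep(1, 2201))
#' b <- bin_spectrum(sp, cfg)
#' length(b$values)  # 390 buckets: 500 candidates minus 110 water buckets
#' @export
bin_spectrum <- function(spec, cfg = preprocess_config()) {
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(cfg, "preprocess_config"))
  rng <- range(spec$ppm)
  if (rng[1] > cfg$ppm_range[1] || rng[2] < cfg$ppm_range[2]) {
    stop(sprintf(
      "spectrum '%s' [%g, %g] does not cover the binning range [%g, %g]",
      spec$sample_id, rng[1], rng[2], cfg$ppm_range[1], cfg$ppm_range[2]))
  }
  iv <- bin_intervals(cfg)
  vals <- mapply(function(lo, hi) trapz_window(spec$ppm, spec$intensity, lo, hi),
                 iv$low, iv$high)
  list(values = as.numeric(vals), bin_ids = sprintf("%.3f", iv$center))
}

#' Build a bucket feature matrix from a set of spectra
#'
#' Applies reference calibration, optional baseline correction and
#' bucketing to each spectrum and stacks the bucket rows in input order.
#'
#' @param specs List of [nmr_spectrum()] objects with unique sample ids.
#' @param cfg A [preprocess_config()].
#' @param baseline Baseline method passed to [correct_baseline()].
#' @param normalize If `TRUE` (default) apply [normalize_total_area()].
#' @return A [feature_matrix()] of bucket integrals.
#' @export
assemble_feature_matrix <- function(specs, cfg = preprocess_config(),
                                    baseline = "none", normalize = TRUE) {
  stopifnot(length(specs) > 0L)
  ids <- vapply(specs, function(s) s$sample_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids among spectra: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(specs, function(s) {
    s <- calibrate_reference(s, cfg)
    s <- correct_baseline(s, baseline)
    bin_spectrum(s, cfg)
  })
  bin_ids <- rows[[1]]$bin_ids
  v <- do.call(rbind, lapply(rows, `[[`, "values"))
  fm <- feature_matrix(v, ids, bin_ids)
  if (normalize) fm <- normalize_total_area(fm, cfg)
  fm
}

#' Metabolite assignment table
#'
#' Maps each metabolite to the ppm windows over which its signal area is
#' integrated. Assignments are consumed as input (from literature or
#' reference databases), never derived.
#'
#' @param df Data frame with columns `metabolite`, `window_low_ppm`,
#'   `window_high_ppm` (repeated rows for multi-window metabolites).
#' @param cfg Optional [preprocess_config()]; a warning is issued for
#'   windows overlapping an exclusion region.
#' @return The validated data frame, class `assignment_table`.
#' @export
assignment_table <- function(df, cfg = NULL) {
  req <- c("metabolite", "window_low_ppm", "window_high_ppm")
  if (!all(req %in% names(df))) {
    stop("assignment table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("assignment table is empty")
  if (any(df$window_low_ppm >= df$window_high_ppm)) {
    stop("every assignment window must have low < high")
  }
  if (!is.null(cfg)) {
    for (reg in cfg$exclusion_regions) {
      hit <- df$window_low_ppm < reg[2] & df$window_high_ppm > reg[1]
      if (any(hit)) {
        warning("assignment window(s) overlap exclusion region [",
                reg[1], ", ", reg[2], "] ppm for: ",
                paste(unique(df$metabolite[hit]), collapse = ", "))
      }
    }
  }
  df <- df[, req]
  class(df) <- c("assignment_table", "data.frame")
  df
}

#' @rdname assignment_table
#' @param path CSV path with the three assignment columns.
#' @export
read_assignment_table <- function(path, cfg = NULL) {
  assignment_table(utils::read.csv(path, stringsAsFactors = FALSE), cfg)
}

#' Integrate metabolite signal areas
#'
#' Relative concentration of each metabolite as the sum of trapezoidal
#' integrals of the spectrum over that metabolite's assignment windows.
#'
#' @param spec A calibrated [nmr_spectrum()].
#' @param at An [assignment_table()].
#' @return Named numeric vector, one relative concentration per metabolite.
#' @export
integrate_metabolite_regions <- function(spec, at) {
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(at, "assignment_table"))
  mets <- unique(at$metabolite)
  vals <- vapply(mets, function(m) {
    rows <- at[at$metabolite == m, , drop = FALSE]
    sum(mapply(function(lo, hi) trapz_window(spec$ppm, spec$intensity, lo, hi),
               rows$window_low_ppm, rows$window_high_ppm))
  }, numeric(1))
  names(vals) <- mets
  vals
}
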