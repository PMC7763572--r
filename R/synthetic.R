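#' Salivary metabolite reference panel
#'
#' Group-wise means and standard deviations of the relative (signal-area)
#' concentrations of 31 salivary metabolites quantified by 1D \eqn{^1}H-NMR
#' in a periodontitis treatment cohort: 12 generalized-periodontitis
#' patients sampled at baseline (`B`) and three months after non-surgical
#' therapy (`AT`), and 11 independent healthy individuals (`HI`). The
#' reported per-metabolite p-values of the accompanying group comparisons
#' (Kruskal-Wallis across the three groups, paired Wilcoxon B vs AT,
#' Mann-Whitney HI vs AT) are included as `p_kw`, `p_wilcoxon`,
#' `p_mannwhitney`. Units are arbitrary integrated-signal-area units.
#'
#' These moments are the default generative parameters of
#' [generate_feature_table()].
#'
#' @return Data frame with one row per metabolite and columns `name`,
#'   `mean_B`, `sd_B`, `mean_AT`, `sd_AT`, `mean_HI`, `sd_HI`, `p_kw`,
#'   `p_wilcoxon`, `p_mannwhitney`.
#' @export
salivary_metabolite_panel <- function() {
  tab <- c(
    "alanine",       2318.68,  2156.2,   835.16,   400.38,   731.26,  324.31, 0.099, 0.052, 0.740,
    "acetate",      82191.52, 63733.79, 119495.6, 38614.2, 180849.4, 63915.1, 0.002, 0.176, 0.004,
    "propionate",   10620.21,  8802.07, 18185.02, 14457.12, 16615.03, 9427.33, 0.327, 0.204, 0.880,
    "glycine",       4896.88,  3390.89,  4134.86,  1717.69,  3252.59, 1542.33, 0.446, 0.470, 0.347,
    "butyrate",       460.82,   573.65,   811.82,   726.82,   540.03,  563.16, 0.187, 0.151, 0.288,
    "taurine",       1551.22,   886.83,  1053.22,   447.67,   946.69,  452.63, 0.089, 0.151, 0.782,
    "ethanol",        170.8,    126.63,   294,      248.31,   529.93,  325.07, 0.003, 0.204, 0.037,
    "proline",        389.02,   498.62,   363.87,   218.22,   176,     122.96, 0.076, 0.910, 0.016,
    "succinate",     1270.54,  2849.59,  1783.53,  1496.6,   3052.11, 3424.66, 0.022, 0.129, 0.651,
    "leucine",       1639.75,  1527.77,   689.34,   441.56,   697.94,  171.73, 0.035, 0.042, 0.230,
    "valine",        1077.09,  1001.68,   305.23,   335.29,   551.16,  245.92, 0.005, 0.001, 0.009,
    "isovalerate",    479.45,   450.54,   536.68,   453.33,   438.91,  235.4,  0.868, 0.910, 0.805,
    "isocaproate",    148.83,   168.95,   222.04,   144.81,   315.28,  274.43, 0.162, 0.151, 0.566,
    "acetoin",        201.97,   167.61,   210.34,   165.32,   510.06,  283.17, 0.002, 0.910, 0.002,
    "tyrosine",       509.97,   456.14,   307.53,   210.88,   270.99,  232.4,  0.472, 0.129, 0.442,
    "methylamine",    298.9,    354.4,    169.15,    73.67,   274.34,   96.61, 0.064, 0.301, 0.006,
    "phenylalanine", 1177.75,  1088.23,   479.24,   169.59,   547.29,  188.64, 0.036, 0.034, 0.566,
    "isoleucine",     636.39,   714.79,   143.31,    98.65,   193.49,   79.1,  0.012, 0.007, 0.104,
    "galactose",       80.22,    93.82,   140.2,    166.6,    139.57,  285.92, 0.738, 0.176, 0.644,
    "lactate",       3359.7,   2674.72,  5413.35,  5361.44,  1349.14, 1394.03, 0.019, 0.470, 0.011,
    "aspartate",      155.65,   104.89,   106.12,    94.69,    58.25,   37.36, 0.068, 0.129, 0.185,
    "creatine",       295.84,   307.4,    226.62,   413.65,   494.94,  558.86, 0.080, 0.301, 0.021,
    "choline",        848.12,   834.16,   879.44,   908.5,   1372.24,  526.06, 0.041, 0.970, 0.023,
    "methanol",       564.8,    343,     1452.51,  2117.43,   637.3,   739.04, 0.134, 0.052, 0.079,
    "pyruvate",       470.4,    460.62,   961.51,   731.33,  1077.92, 1722.88, 0.192, 0.129, 0.288,
    "formate",        776.5,   1976.83,  1656.13,  2726.19,   513.89,  799.4,  0.206, 0.016, 0.176,
    "glucose",        161.94,   188.36,    74.34,    83.34,    70.2,    97.73, 0.365, 0.380, 0.667,
    "sarcosine",      253.02,   279.33,   244.6,    257.13,   202.9,    75.21, 0.980, 0.970, 0.878,
    "hypoxanthine",   167,      303.72,    33.43,    20.06,    30.65,   20.27, 0.010, 0.012, 0.740,
    "uracil",         383.07,   622.49,    61.67,    49.7,     74.81,   65.7,  0.030, 0.005, 1.000,
    "isopropanol",    181.78,   134.02,   293.53,   221.85,   406.78,  247.21, 0.048, 0.307, 0.260)
  m <- matrix(tab, ncol = 10, byrow = TRUE)
  df <- data.frame(name = m[, 1], apply(m[, -1], 2, as.numeric),
                   stringsAsFactors = FALSE)
  names(df) <- c("name", "mean_B", "sd_B", "mean_AT", "sd_AT", "mean_HI",
                 "sd_HI", "p_kw", "p_wilcoxon", "p_mannwhitney")
  df
}

#' Illustrative 1H peak library for spectrum rendering
#'
#' One or two Lorentzian singlets per panel metabolite at typical
#' \eqn{^1}H chemical shifts, used by [render_spectrum()]. Illustrative
#' line positions only: no J-coupling multiplet structure is modelled.
#'
#' @return Data frame with columns `metabolite`, `center_ppm`,
#'   `rel_height`, `width_ppm` (half width at half maximum).
#' @export
default_peak_library <- function() {
  p <- list(
    alanine = c(1.48), acetate = c(1.92), propionate = c(1.05, 2.18),
    glycine = c(3.56), butyrate = c(0.90, 1.56), taurine = c(3.26, 3.42),
    ethanol = c(1.18, 3.66), proline = c(2.00, 3.33), succinate = c(2.41),
    leucine = c(0.96, 1.71), valine = c(0.99, 1.04),
    isovalerate = c(0.91, 2.05), isocaproate = c(0.87),
    acetoin = c(1.37, 2.22), tyrosine = c(6.90, 7.19),
    methylamine = c(2.61), phenylalanine = c(7.33, 7.42),
    isoleucine = c(0.94, 1.01), galactose = c(3.65, 3.98),
    lactate = c(1.33, 4.11), aspartate = c(2.68, 2.80),
    creatine = c(3.03, 3.93), choline = c(3.20), methanol = c(3.36),
    pyruvate = c(2.37), formate = c(8.46), glucose = c(3.47, 3.72),
    sarcosine = c(2.73, 3.60), hypoxanthine = c(8.19, 8.21),
    uracil = c(5.80, 7.54), isopropanol = c(1.17, 4.02))
  do.call(rbind, lapply(names(p), function(m) {
    data.frame(metabolite = m, center_ppm = p[[m]],
               rel_height = 1 / length(p[[m]]), width_ppm = 0.004,
               stringsAsFactors = FALSE)
  }))
}

#' Simulation configuration
#'
#' Parameters of the cohort generator. Defaults reproduce the study
#' design: 12 paired baseline/post-therapy subjects and 11 independent
#' healthy individuals.
#'
#' @param n_pairs Number of paired subjects (one B and one AT sample each).
#' @param n_healthy Number of independent healthy (HI) samples.
#' @param rho Within-subject correlation of the B/AT pair, in `[0, 1)`.
#' @param kappa Effect multiplier: each group mean is moved to
#'   `grand + kappa * (mean_g - grand)` where `grand` is the unweighted
#'   mean of the three group means. `kappa = 1` reproduces the panel
#'   moments; larger values widen group separation.
#' @param noise_floor Lower clip applied to generated concentrations
#'   (default 0, i.e. zero-truncation).
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param distribution `"truncated_normal"` (Gaussian, clipped below) or
#'   `"lognormal_matched"` (lognormal with moment-matched mean/SD, paired
#'   through a Gaussian copula).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 12L, n_healthy = 11L, rho = 0.8,
                              kappa = 1.0, noise_floor = 0, seed = 1L,
                              distribution = c("truncated_normal",
                                               "lognormal_matched")) {
  distribution <- match.arg(distribution)
  if (!(rho >= 0 && rho < 1)) stop("rho must be in [0, 1)")
  stopifnot(n_pairs >= 2L, n_healthy >= 2L, kappa > 0, noise_floor >= 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_healthy = as.integer(n_healthy),
                 rho = rho, kappa = kappa, noise_floor = noise_floor,
                 seed = as.integer(seed), distribution = distribution),
            class = "simulation_config")
}

# draw n values with given mean/sd from the configured marginal family,
# using standard-normal deviates z (so pairing is a Gaussian copula)
draw_marginal <- function(z, mu, sigma, cfg) {
  if (sigma == 0) return(rep(mu, length(z)) )
  if (cfg$distribution == "truncated_normal") {
    pmax(mu + sigma * z, cfg$noise_floor)
  } else {
    if (mu <= 0) stop("lognormal_matched needs positive means")
    s2 <- log(1 + (sigma / mu)^2)
    pmax(exp(log(mu) - s2 / 2 + sqrt(s2) * z), cfg$noise_floor)
  }
}

sim_group_means <- function(panel, kappa) {
  grand <- (panel$mean_B + panel$mean_AT + panel$mean_HI) / 3
  list(grand = grand,
       B = grand + kappa * (panel$mean_B - grand),
       AT = grand + kappa * (panel$mean_AT - grand),
       HI = grand + kappa * (panel$mean_HI - grand))
}

#' Generate a synthetic cohort feature table
#'
#' Draws per-subject metabolite concentrations with the statistical
#' structure of the study: paired B/AT samples share a latent subject
#' effect inducing within-subject correlation `rho`, HI samples are
#' independent, and each group's marginal mean/SD follows the panel
#' moments with the group-mean separation scaled by `kappa`.
#'
#' @param panel Data frame as returned by [salivary_metabolite_panel()]
#'   (columns `name`, `mean_B`, `sd_B`, `mean_AT`, `sd_AT`, `mean_HI`,
#'   `sd_HI`).
#' @param cfg A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements `features`
#'   (a [feature_matrix()], rows `P01_B ... P12_B, P01_AT ..., H01 ...`),
#'   `metadata` (a [sample_metadata()]) and `truth` (the generating panel
#'   and config).
#' @examples
#' ds <- generate_feature_table(cfg = simulation_config(seed = 7))
#' dim(ds$features)  # 35 samples x 31 metabolites
#' @export
generate_feature_table <- function(panel = salivary_metabolite_panel(),
                                   cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"), nrow(panel) > 0L)
  mu <- sim_group_means(panel, cfg$kappa)
  np <- cfg$n_pairs
  nh <- cfg$n_healthy
  nm <- nrow(panel)
  withr::with_seed(cfg$seed, {
    vB <- matrix(0, np, nm)
    vAT <- matrix(0, np, nm)
    vHI <- matrix(0, nh, nm)
    for (j in seq_len(nm)) {
      z1 <- stats::rnorm(np)
      z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * stats::rnorm(np)
      zh <- stats::rnorm(nh)
      vB[, j] <- draw_marginal(z1, mu$B[j], panel$sd_B[j], cfg)
      vAT[, j] <- draw_marginal(z2, mu$AT[j], panel$sd_AT[j], cfg)
      vHI[, j] <- draw_marginal(zh, mu$HI[j], panel$sd_HI[j], cfg)
    }
  })
  subj <- sprintf("P%02d", seq_len(np))
  ids <- c(paste0(subj, "_B"), paste0(subj, "_AT"), sprintf("H%02d", seq_len(nh)))
  md <- sample_metadata(data.frame(
    sample_id = ids,
    subject_id = c(subj, subj, sprintf("H%02d", seq_len(nh))),
    group = c(rep("B", np), rep("AT", np), rep("HI", nh)),
    stringsAsFactors = FALSE))
  fm <- feature_matrix(rbind(vB, vAT, vHI), ids, panel$name)
  structure(list(features = fm, metadata = md,
                 truth = list(panel = panel, config = cfg)),
            class = "synthetic_dataset")
}

#' Generate a null cohort (no group effect)
#'
#' Identical sampling machinery to [generate_feature_table()], but every
#' group's mean is replaced by the metabolite grand mean and a common
#' pooled SD is used for all three groups, so the groups are exchangeable
#' and any detected group difference is a false positive. The pairing
#' structure (within-subject correlation `rho`) is retained.
#'
#' @inheritParams generate_feature_table
#' @return A `synthetic_dataset`.
#' @export
generate_null_dataset <- function(panel = salivary_metabolite_panel(),
                                  cfg = simulation_config()) {
  grand <- (panel$mean_B + panel$mean_AT + panel$mean_HI) / 3
  pooled_sd <- sqrt((panel$sd_B^2 + panel$sd_AT^2 + panel$sd_HI^2) / 3)
  null_panel <- panel
  null_panel$mean_B <- null_panel$mean_AT <- null_panel$mean_HI <- grand
  null_panel$sd_B <- null_panel$sd_AT <- null_panel$sd_HI <- pooled_sd
  ds <- generate_feature_table(null_panel, cfg)
  ds$truth$panel <- null_panel
  ds
}

#' Render a 1D spectrum from metabolite concentrations
#'
#' Builds an intensity trace as a sum of concentration-scaled Lorentzian
#' lines on a regular ppm grid. Each peak contributes
#' `conc * rel_height * w^2 / ((x - center - delta)^2 + w^2)` with `w` the
#' half width at half maximum, so its analytic area is
#' `conc * rel_height * w * pi`. A TMSP reference line is always added at
#' 0.00 ppm. All line centres (TMSP included) are perturbed by one
#' per-sample global shift `delta ~ N(0, shift_jitter_sd)`, and white
#' Gaussian noise of SD `noise_sd` is added.
#'
#' @param concentrations Named numeric vector, metabolite -> concentration.
#' @param peaks Peak library data frame (see [default_peak_library()]).
#' @param cfg A [preprocess_config()]; the grid spans its `ppm_range`.
#' @param noise_sd,shift_jitter_sd Noise and global-shift SDs.
#' @param seed Optional integer seed for the jitter and noise draws.
#' @param grid_step Grid spacing in ppm.
#' @param sample_id Sample id of the returned spectrum.
#' @param tmsp_height Apex height of the TMSP reference line.
#' @return An [nmr_spectrum()].
#' @export
render_spectrum <- function(concentrations, peaks = default_peak_library(),
                            cfg = preprocess_config(), noise_sd = 0,
                            shift_jitter_sd = 0, seed = NULL,
                            grid_step = 0.001, sample_id = "synthetic",
                            tmsp_height = 1.0) {
  mets <- names(concentrations)
  if (is.null(mets)) stop("concentrations must be a named vector")
  missing <- setdiff(mets, unique(peaks$metabolite))
  if (length(missing) > 0L) {
    stop("no peak list for metabolite(s): ", paste(missing, collapse = ", "))
  }
  draw <- function() {
    delta <- if (shift_jitter_sd > 0) stats::rnorm(1, 0, shift_jitter_sd) else 0
    x <- seq(cfg$ppm_range[1], cfg$ppm_range[2], by = grid_step)
    y <- tmsp_height * 0.003^2 / ((x - 0 - delta)^2 + 0.003^2)
    for (m in mets) {
      pk <- peaks[peaks$metabolite == m, , drop = FALSE]
      for (k in seq_len(nrow(pk))) {
        w <- pk$width_ppm[k]
        y <- y + concentrations[[m]] * pk$rel_height[k] * w^2 /
          ((x - pk$center_ppm[k] - delta)^2 + w^2)
      }
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(x), 0, noise_sd)
    nmr_spectrum(sample_id, x, y)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Render every sample of a synthetic dataset to spectra
#'
#' @param ds A `synthetic_dataset` from [generate_feature_table()].
#' @param ... Passed to [render_spectrum()] (peak library, config, noise).
#' @param seed Integer seed; sample `i` uses `seed + i`.
#' @return Named list of [nmr_spectrum()] objects, one per sample row.
#' @export
render_dataset <- function(ds, ..., seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ids <- rownames(ds$features)
  specs <- lapply(seq_along(ids), function(i) {
    conc <- fm_values(ds$features)[i, ]
    render_spectrum(conc, ..., seed = seed + i, sample_id = ids[i])
  })
  names(specs) <- ids
  specs
}
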