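#' Pipeline configuration
#'
#' Declares the input mode and every stage parameter of the end-to-end
#' workflow: input (simulated cohort, pre-binned/metabolite CSV, or a
#' directory of spectrum files) -> preprocessing -> paired MPLS with a
#' permutation test -> three-group OPLS-DA with Monte Carlo CV and a
#' permutation test -> per-metabolite statistics table.
#'
#' @param mode One of `"simulate"`, `"features_csv"`, `"spectra_dir"`.
#' @param output_dir Directory for persisted intermediates and the report.
#' @param features_csv,metadata_csv,spectra_dir Input paths (per mode; a
#'   metadata CSV is required for the two file modes).
#' @param preprocess A [preprocess_config()] (spectra mode).
#' @param simulation A [simulation_config()] (simulate mode); its seed is
#'   overridden by the master `seed`.
#' @param mpls_components,oplsda_predictive,oplsda_orthogonal Component
#'   counts of the two models.
#' @param scale Unit-variance scaling inside every model fit (see
#'   [fit_pls()]); recommended for metabolite-concentration tables.
#' @param cv A [cv_config()]; its seed is overridden by the master `seed`.
#' @param n_perm Permutations for both permutation tests.
#' @param seed Master seed governing simulation, CV splits and
#'   permutations; re-runs with the same config are bit-identical.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "features_csv", "spectra_dir"),
                            output_dir = tempfile("salivanmr_run_"),
                            features_csv = NULL, metadata_csv = NULL,
                            spectra_dir = NULL,
                            preprocess = preprocess_config(),
                            simulation = simulation_config(),
                            mpls_components = 2L,
                            oplsda_predictive = 2L, oplsda_orthogonal = 1L,
                            scale = FALSE,
                            cv = cv_config(), n_perm = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "features_csv" && (is.null(features_csv) || is.null(metadata_csv))) {
    stop("features_csv mode needs features_csv and metadata_csv paths")
  }
  if (mode == "spectra_dir" && (is.null(spectra_dir) || is.null(metadata_csv))) {
    stop("spectra_dir mode needs spectra_dir and metadata_csv paths")
  }
  structure(list(mode = mode, output_dir = output_dir,
                 features_csv = features_csv, metadata_csv = metadata_csv,
                 spectra_dir = spectra_dir, preprocess = preprocess,
                 simulation = simulation, mpls_components = mpls_components,
                 oplsda_predictive = oplsda_predictive,
                 oplsda_orthogonal = oplsda_orthogonal, scale = isTRUE(scale),
                 cv = cv,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_inputs <- function(cfg) {
  if (cfg$mode == "simulate") {
    sim <- cfg$simulation
    sim$seed <- cfg$seed
    ds <- generate_feature_table(cfg = sim)
    list(fm = ds$features, md = ds$metadata, truth = ds$truth)
  } else if (cfg$mode == "features_csv") {
    list(fm = read_feature_matrix(cfg$features_csv),
         md = read_metadata(cfg$metadata_csv), truth = NULL)
  } else {
    files <- sort(list.files(cfg$spectra_dir, full.names = TRUE,
                             pattern = "\\.(txt|tsv|csv|dat)$"))
    files <- files[normalizePath(files) != normalizePath(cfg$metadata_csv)]
    if (length(files) == 0L) stop("no spectrum files in ", cfg$spectra_dir)
    specs <- lapply(files, read_spectrum)
    list(fm = assemble_feature_matrix(specs, cfg$preprocess),
         md = read_metadata(cfg$metadata_csv), truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, persisting each intermediate under
#' `cfg$output_dir`: the feature matrix and metadata (`features.csv`,
#' `metadata.csv`), MPLS score coordinates and permutation test
#' (`mpls_scores.tsv`, `mpls_validation.json`), OPLS-DA scores, Monte
#' Carlo CV and permutation test (`oplsda_scores.tsv`,
#' `oplsda_validation.json`), the per-metabolite statistics table
#' (`metabolite_stats.tsv`) with a long-format boxplot companion
#' (`metabolite_long.tsv`), and a machine-readable run report
#' (`report.json`). A single master seed drives simulation, CV splits and
#' permutations, so identical configurations reproduce byte-identical
#' reports.
#'
#' @param cfg A [pipeline_config()].
#' @return The run report, invisibly: a list echoing the configuration
#'   and carrying both validation summaries and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  inp <- pipeline_inputs(cfg)
  fm <- inp$fm
  md <- inp$md
  write_feature_matrix(fm, file.path(cfg$output_dir, "features.csv"))
  write_metadata(md, file.path(cfg$output_dir, "metadata.csv"))
  cv <- cfg$cv
  cv$seed <- cfg$seed

  # paired MPLS on the B/AT samples
  ba <- md$group %in% c("B", "AT")
  fm_ba <- feature_matrix(fm_values(fm)[ba, , drop = FALSE],
                          md$sample_id[ba], colnames(fm))
  md_ba <- md[ba, , drop = FALSE]
  mpls_fit <- fit_mpls_paired(fm_ba, md_ba, cfg$mpls_components,
                              scale = cfg$scale)
  sc <- model_scores(mpls_fit)
  utils::write.table(cbind(sample_id = rownames(fm_ba), group =
                             as.character(md_ba$group), sc),
                     file.path(cfg$output_dir, "mpls_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  mpls_spec <- mpls_model(cfg$mpls_components, scale = cfg$scale)
  mpls_cv <- monte_carlo_cv(fm_ba, md_ba, mpls_spec, cv)
  mpls_perm <- permutation_test(fm_ba, md_ba, mpls_spec,
                                cv, n_perm = cfg$n_perm, seed = cfg$seed)

  # three-group OPLS-DA
  op_spec <- oplsda_model(cfg$oplsda_predictive, cfg$oplsda_orthogonal,
                          scale = cfg$scale)
  op_fit <- fit_oplsda(fm_values(fm), align_metadata(fm, md)$group,
                       cfg$oplsda_predictive, cfg$oplsda_orthogonal,
                       scale = cfg$scale)
  sc2 <- model_scores(op_fit)
  utils::write.table(cbind(sample_id = rownames(fm),
                           group = as.character(md$group), sc2),
                     file.path(cfg$output_dir, "oplsda_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  op_cv <- monte_carlo_cv(fm, md, op_spec, cv)
  op_perm <- permutation_test(fm, md, op_spec, cv, n_perm = cfg$n_perm,
                              seed = cfg$seed)

  # univariate layer
  stats_tab <- build_metabolite_stats_table(fm, md)
  utils::write.table(stats_tab, file.path(cfg$output_dir, "metabolite_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(metabolite_long_table(fm, md),
                     file.path(cfg$output_dir, "metabolite_long.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("salivanmr")),
    seed = cfg$seed, mode = cfg$mode,
    n_samples = nrow(fm), n_features = ncol(fm),
    mpls = list(n_components = cfg$mpls_components,
                cv_accuracy = mpls_cv$mean_accuracy,
                per_run_accuracy = mpls_cv$per_run_accuracy,
                confusion = mpls_cv$pooled_confusion,
                permutation_p = mpls_perm$p_value,
                observed_stat = mpls_perm$observed_stat),
    oplsda = list(n_predictive = cfg$oplsda_predictive,
                  n_orthogonal = cfg$oplsda_orthogonal,
                  cv_accuracy = op_cv$mean_accuracy,
                  per_run_accuracy = op_cv$per_run_accuracy,
                  confusion = op_cv$pooled_confusion,
                  permutation_p = op_perm$p_value,
                  observed_stat = op_perm$observed_stat),
    cv = list(n_runs = cv$n_runs, test_fraction = cv$test_fraction,
              unit = cv$unit),
    n_perm = cfg$n_perm,
    paths = list(features = "features.csv", metadata = "metadata.csv",
                 mpls_scores = "mpls_scores.tsv",
                 oplsda_scores = "oplsda_scores.tsv",
                 metabolite_stats = "metabolite_stats.tsv"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_report(report, cfg$output_dir)
  invisible(report)
}

#' Write a run report as JSON
#'
#' @param report Report list from [run_pipeline()].
#' @param dir Output directory.
#' @return The report path, invisibly.
#' @export
write_report <- function(report, dir) {
  path <- file.path(dir, "report.json")
  rep <- report
  rep$elapsed_sec <- NULL  # keep the persisted report byte-reproducible
  rep$mpls$confusion <- as.data.frame.matrix(rep$mpls$confusion)
  rep$oplsda$confusion <- as.data.frame.matrix(rep$oplsda$confusion)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
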