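#' Monte Carlo cross-validation configuration
#'
#' @param n_runs Number of random train/test splits.
#' @param test_fraction Fraction of units held out per run, in (0, 1).
#' @param unit Resampling unit: `"subject"` (default; a subject's B and AT
#'   samples never straddle the split) or `"sample"`.
#' @param stratified Stratify the draw so each stratum contributes
#'   `ceiling(test_fraction * n)` units per run.
#' @param seed Master seed; run `r` uses the substream `seed + r`, so
#'   results do not depend on execution order.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_runs = 100L, test_fraction = 1 / 3,
                      unit = c("subject", "sample"), stratified = TRUE,
                      seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(n_runs >= 1L, test_fraction > 0, test_fraction < 1)
  structure(list(n_runs = as.integer(n_runs), test_fraction = test_fraction,
                 unit = unit, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# ---- model specifications (what monte_carlo_cv refits each run) ---------

#' Model specifications for cross-validation
#'
#' Lightweight descriptions of the three discrimination models, consumed
#' by [monte_carlo_cv()] and [permutation_test()], which refit them on
#' every training split.
#'
#' @param n_components,n_predictive,n_orthogonal Component counts.
#' @param scale Unit-variance scaling inside each fit (see [fit_pls()]).
#' @return A list of class `model_spec`.
#' @export
mpls_model <- function(n_components = 2L, scale = FALSE) {
  structure(list(kind = "mpls", n_components = n_components, paired = TRUE,
                 scale = isTRUE(scale)),
            class = "model_spec")
}

#' @rdname mpls_model
#' @export
oplsda_model <- function(n_predictive = 2L, n_orthogonal = 1L, scale = FALSE) {
  structure(list(kind = "oplsda", n_predictive = n_predictive,
                 n_orthogonal = n_orthogonal, paired = FALSE,
                 scale = isTRUE(scale)),
            class = "model_spec")
}

#' @rdname mpls_model
#' @export
plsda_model <- function(n_components = 2L, scale = FALSE) {
  structure(list(kind = "plsda", n_components = n_components, paired = FALSE,
                 scale = isTRUE(scale)),
            class = "model_spec")
}

fit_model_spec <- function(spec, fm, md) {
  switch(spec$kind,
         mpls = fit_mpls_paired(fm, md, spec$n_components, scale = spec$scale),
         oplsda = fit_oplsda(fm_values(fm), align_metadata(fm, md)$group,
                             spec$n_predictive, spec$n_orthogonal,
                             scale = spec$scale),
         plsda = fit_plsda(fm_values(fm), align_metadata(fm, md)$group,
                           spec$n_components, scale = spec$scale),
         stop("unknown model kind: ", spec$kind))
}

#' Confusion matrix and overall accuracy
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_levels Fixed row/column order of the matrix.
#' @return List with `confusion` (rows = true class, columns = predicted)
#'   and `accuracy` (= trace / total).
#' @export
confusion_and_accuracy <- function(true_labels, predicted_labels, class_levels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_levels)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(true_labels, levels = class_levels),
              factor(predicted_labels, levels = class_levels))
  cm <- matrix(as.integer(cm), nrow = length(class_levels),
               dimnames = list(true = class_levels, predicted = class_levels))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

# subjects (or samples) with their stratum key; for subject units the
# stratum is the sorted set of groups the subject's samples belong to,
# so paired B/AT subjects form one stratum and HI subjects another
cv_units <- function(md, unit) {
  if (unit == "subject") {
    us <- unique(md$subject_id)
    key <- vapply(us, function(s) {
      paste(sort(unique(as.character(md$group[md$subject_id == s]))),
            collapse = "+")
    }, "")
    data.frame(unit = us, stratum = key, stringsAsFactors = FALSE)
  } else {
    data.frame(unit = md$sample_id,
               stratum = as.character(md$group), stringsAsFactors = FALSE)
  }
}

draw_test_units <- function(units, cv) {
  if (cv$stratified) {
    # singleton strata (possible under permuted labels) are pooled so the
    # per-stratum ceiling cannot inflate the overall test fraction
    tab <- table(units$stratum)
    stratum <- units$stratum
    stratum[stratum %in% names(tab)[tab < 2]] <- ".pooled"
    unlist(lapply(split(units$unit, stratum), function(u) {
      sample(u, max(1L, ceiling(cv$test_fraction * length(u))))
    }), use.names = FALSE)
  } else {
    sample(units$unit, max(1L, ceiling(cv$test_fraction * nrow(units))))
  }
}

#' Monte Carlo cross-validation of a discrimination model
#'
#' Repeatedly holds out a random stratified set of units (subjects by
#' default, so a paired subject's two samples are always on the same side
#' of the split), refits the model on the remaining samples, and predicts
#' the held-out samples. Accuracy is pooled over runs via the summed
#' confusion matrix. If a draw leaves a class absent from the training
#' split it is re-drawn (at most 10 times per run, then an error).
#'
#' @param fm A [feature_matrix()].
#' @param md A [sample_metadata()].
#' @param model_spec A [mpls_model()], [oplsda_model()] or [plsda_model()].
#' @param cv A [cv_config()].
#' @param record_splits If `TRUE`, store the held-out unit set of every
#'   run in the result (`test_units`), e.g. to audit train/test leakage.
#' @return A list of class `validation_result`: `per_run_accuracy`,
#'   `mean_accuracy` (pooled = correct/total of the pooled confusion),
#'   `pooled_confusion`, `n_runs`.
#' @export
monte_carlo_cv <- function(fm, md, model_spec, cv = cv_config(),
                           record_splits = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cv, "cv_config"),
            inherits(model_spec, "model_spec"))
  md <- align_metadata(fm, md)
  if (model_spec$paired && cv$unit != "subject") {
    stop("paired models require subject-level splitting")
  }
  class_levels <- as.character(levels(droplevels(md$group)))
  units <- cv_units(md, cv$unit)
  per_run <- numeric(cv$n_runs)
  splits <- if (record_splits) vector("list", cv$n_runs) else NULL
  pooled <- matrix(0L, length(class_levels), length(class_levels),
                   dimnames = list(true = class_levels, predicted = class_levels))
  X <- fm_values(fm)
  for (r in seq_len(cv$n_runs)) {
    fitted <- NULL
    withr::with_seed(cv$seed + r, {
      # re-draw (up to 10 times) when a class is missing from training or
      # the training split cannot support the requested components
      for (attempt in 1:10) {
        test_units <- draw_test_units(units, cv)
        in_test <- if (cv$unit == "subject") md$subject_id %in% test_units
                   else md$sample_id %in% test_units
        train_groups <- unique(as.character(md$group[!in_test]))
        if (!setequal(train_groups, class_levels)) next
        fm_train <- feature_matrix(X[!in_test, , drop = FALSE],
                                   md$sample_id[!in_test], colnames(X))
        fitted <- tryCatch(
          fit_model_spec(model_spec, fm_train, md[!in_test, , drop = FALSE]),
          error = function(e) NULL)
        if (!is.null(fitted)) break
      }
    })
    if (is.null(fitted)) {
      stop("run ", r, ": could not draw a feasible training split ",
           "(all classes present, enough samples) after 10 attempts")
    }
    fm_test <- feature_matrix(X[in_test, , drop = FALSE],
                              md$sample_id[in_test], colnames(X))
    md_test <- md[in_test, , drop = FALSE]
    if (model_spec$kind == "mpls") {
      keep <- md_test$group %in% c("B", "AT")
      fm_test <- feature_matrix(X[in_test, , drop = FALSE][keep, , drop = FALSE],
                                md_test$sample_id[keep], colnames(X))
      md_test <- md_test[keep, , drop = FALSE]
    }
    pred <- predict_labels(fitted, fm_test, md_test)
    ca <- confusion_and_accuracy(as.character(md_test$group), pred,
                                 class_levels)
    per_run[r] <- ca$accuracy
    pooled <- pooled + ca$confusion
    if (record_splits) splits[[r]] <- test_units
  }
  structure(list(per_run_accuracy = per_run,
                 mean_accuracy = sum(diag(pooled)) / sum(pooled),
                 pooled_confusion = pooled, n_runs = cv$n_runs,
                 test_units = splits),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %d Monte Carlo CV runs, pooled accuracy %.3f\n",
              x$n_runs, x$mean_accuracy))
  print(x$pooled_confusion)
  invisible(x)
}

# Relabel the metadata, keeping sample/subject ids. Degenerate draws are
# excluded: the identity relabelling carries no null information, and for
# the paired scheme the total inversion is excluded as well because a
# two-class model is invariant under swapping every pair (it yields the
# observed accuracy by symmetry, not by chance).
permute_metadata <- function(md, scheme) {
  grp <- as.character(md$group)
  if (scheme == "within_subject") {
    pm <- pairing_map(md)
    if (nrow(pm) < 2L) stop("need at least two pairs to permute")
    repeat {
      flip <- stats::runif(nrow(pm)) < 0.5
      if (any(flip) && !all(flip)) break
    }
    for (i in which(flip)) {
      bi <- md$sample_id == pm$sample_B[i]
      ai <- md$sample_id == pm$sample_AT[i]
      grp[bi] <- "AT"
      grp[ai] <- "B"
    }
  } else {
    repeat {
      perm <- sample(grp)
      if (any(perm != grp)) break
    }
    grp <- perm
  }
  md$group <- factor(grp, levels = levels(md$group))
  md
}

#' Permutation test on cross-validated model accuracy
#'
#' The observed statistic is (by default) the pooled Monte Carlo CV
#' accuracy of the model on the true labels. Each permutation relabels
#' the samples — for paired models by independently swapping or not the
#' B/AT labels within each subject (preserving the pairing); otherwise by
#' a full shuffle of the group labels — and recomputes the statistic with
#' the same CV configuration. The identity relabelling is excluded
#' (redrawn), as is, for paired models, the total inversion, under which
#' a two-class model is invariant. The add-one estimator
#' `p = (b + 1) / (N + 1)`, with ties counted in `b`, guarantees
#' `p >= 1 / (N + 1)` and never returns zero.
#'
#' @param fm A [feature_matrix()].
#' @param md A [sample_metadata()].
#' @param model_spec A model specification (see [mpls_model()]).
#' @param cv A [cv_config()] used for every statistic evaluation.
#' @param n_perm Number of permutations.
#' @param seed Seed of the permutation draws (permutation `k` uses
#'   substream `seed + k`).
#' @param scheme `"auto"` (within-subject swaps for paired models, full
#'   shuffle otherwise), `"within_subject"` or `"full"`.
#' @param stat_fn Optional replacement statistic `function(fm, md)`;
#'   defaults to pooled CV accuracy via [monte_carlo_cv()].
#' @return A list of class `permutation_result`: `observed_stat`,
#'   `permuted_stats`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(fm, md, model_spec, cv = cv_config(),
                             n_perm = 100L, seed = cv$seed,
                             scheme = c("auto", "within_subject", "full"),
                             stat_fn = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1L)
  md <- align_metadata(fm, md)
  if (scheme == "auto") {
    scheme <- if (isTRUE(model_spec$paired)) "within_subject" else "full"
  }
  if (is.null(stat_fn)) {
    stat_fn <- function(fm, md) monte_carlo_cv(fm, md, model_spec, cv)$mean_accuracy
  }
  observed <- stat_fn(fm, md)
  permuted <- vapply(seq_len(n_perm), function(k) {
    md_k <- withr::with_seed(seed + k, permute_metadata(md, scheme))
    stat_fn(fm, md_k)
  }, numeric(1))
  b <- sum(permuted >= observed - 1e-12)
  structure(list(observed_stat = observed, permuted_stats = permuted,
                 p_value = (b + 1) / (n_perm + 1), n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4f, %d permutations, p = %.4f\n",
              x$observed_stat, x$n_perm, x$p_value))
  invisible(x)
}
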