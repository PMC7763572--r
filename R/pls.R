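# ---- class encoding ----------------------------------------------------

# Two classes: one +1/-1 column (first level = +1).
# Three or more: 0/1 indicator matrix, one column per level.
encode_classes <- function(labels, class_levels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), class_levels)
  if (length(bad) > 0L) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (length(class_levels) < 2L) stop("need at least two classes")
  if (length(class_levels) == 2L) {
    matrix(ifelse(labels == class_levels[1], 1, -1), ncol = 1,
           dimnames = list(NULL, paste(class_levels, collapse = "_vs_")))
  } else {
    Y <- sapply(class_levels, function(l) as.numeric(labels == l))
    matrix(Y, ncol = length(class_levels),
           dimnames = list(NULL, class_levels))
  }
}

# Inverse of encode_classes on predicted scores: class of the maximal
# encoding column (two-class: sign rule); ties go to the first level.
decode_classes <- function(Yhat, class_levels) {
  if (length(class_levels) == 2L) {
    ifelse(Yhat[, 1] >= 0, class_levels[1], class_levels[2])
  } else {
    class_levels[apply(Yhat, 1, which.max)]
  }
}

infer_levels <- function(labels) {
  if (is.factor(labels)) as.character(levels(droplevels(labels)))
  else unique(as.character(labels))
}

# ---- NIPALS core (assumes centered inputs) ------------------------------

nipals_core <- function(E, F, n_components, tol = 1e-10, max_iter = 500L) {
  n <- nrow(E)
  p <- ncol(E)
  if (n_components > min(n - 1L, p)) {
    stop("n_components (", n_components, ") exceeds what ", n, " samples x ",
         p, " features can support")
  }
  W <- P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(F), n_components)
  T <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    u <- F[, which.max(apply(F, 2, stats::var)), drop = TRUE]
    w_old <- rep(0, p)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps * 1e3) {
        stop("X residual exhausted at component ", a,
             "; reduce n_components")
      }
      w <- w / nw
      t_sc <- drop(E %*% w)
      q <- drop(crossprod(F, t_sc)) / sum(t_sc^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      if (iter >= max_iter) {
        stop("NIPALS did not converge within ", max_iter,
             " iterations for component ", a)
      }
      w_old <- w
      u <- drop(F %*% q) / sum(q^2)
    }
    # sign convention: largest-|.| weight element positive
    s <- sign(w[which.max(abs(w))])
    if (s == 0) s <- 1
    w <- s * w; t_sc <- s * t_sc; q <- s * q
    ss_t <- sum(t_sc^2)
    if (ss_t < .Machine$double.eps * 1e3) {
      stop("degenerate score at component ", a, "; reduce n_components")
    }
    p_load <- drop(crossprod(E, t_sc)) / ss_t
    E <- E - tcrossprod(t_sc, p_load)
    F <- F - tcrossprod(t_sc, q)
    W[, a] <- w; P[, a] <- p_load; Q[, a] <- q; T[, a] <- t_sc
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(W = W, P = P, Q = Q, T = T, B = B)
}

#' Fit a PLS regression model by NIPALS
#'
#' Partial least squares regression of a (possibly multi-column) response
#' encoding on a feature matrix, fitted by the NIPALS algorithm with
#' deflation of both blocks. Columns are mean-centred internally (the
#' centring vectors are stored in the model); no variance scaling is
#' applied. Weight vectors follow a fixed sign convention (largest-
#' magnitude element positive) so fits are bit-reproducible, and score
#' columns are mutually orthogonal.
#'
#' @param X Numeric matrix, samples x features.
#' @param Y Numeric response matrix (class encoding or continuous).
#' @param n_components Number of latent components.
#' @param tol Convergence tolerance on the weight vector.
#' @param max_iter Maximum NIPALS iterations per component.
#' @param scale If `TRUE`, scale each column to unit variance after
#'   centring (the training SDs are stored in the model and reapplied at
#'   prediction time; constant columns are left unscaled). Off by
#'   default: bucket tables are already brought to a common scale by
#'   total-area normalization, but unit-variance scaling is the standard
#'   choice for metabolite-concentration tables whose features span
#'   orders of magnitude.
#' @return An object of class `latent_model` with fields `kind`, `X_mean`,
#'   `X_sd` (or `NULL`), `Y_mean`, `W`, `P`, `Q`, `T` (scores), `B`
#'   (regression coefficients) and `n_components`.
#' @export
fit_pls <- function(X, Y, n_components = 2L, tol = 1e-10, max_iter = 500L,
                    scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  X_mean <- colMeans(X)
  Y_mean <- colMeans(Y)
  E <- sweep(X, 2, X_mean)
  X_sd <- NULL
  if (isTRUE(scale)) {
    X_sd <- apply(E, 2, stats::sd)
    X_sd[X_sd < .Machine$double.eps * 1e3] <- 1  # constant columns untouched
    E <- sweep(E, 2, X_sd, `/`)
  }
  F <- sweep(Y, 2, Y_mean)
  if (all(abs(F) < .Machine$double.eps * 1e3)) stop("Y has no variation")
  core <- nipals_core(E, F, n_components, tol, max_iter)
  structure(c(list(kind = "PLS", X_mean = X_mean, X_sd = X_sd,
                   Y_mean = Y_mean, class_levels = NULL,
                   n_components = n_components),
              core),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> %s: %d predictive component(s)%s, %d features\n",
              x$kind, x$n_components,
              if (!is.null(x$W_orth)) sprintf(" + %d orthogonal", ncol(x$W_orth)) else "",
              length(x$X_mean)))
  invisible(x)
}

#' PLS discriminant analysis
#'
#' Fits [fit_pls()] against a class-membership encoding: a single +1/-1
#' column for two classes, a 0/1 indicator matrix for three or more.
#'
#' @param X Numeric matrix, samples x features.
#' @param labels Class labels (factor levels, or order of first
#'   appearance, fix the class order; the first class is the +1 class and
#'   the tie-break class).
#' @param n_components Number of latent components.
#' @param scale Unit-variance scaling, as in [fit_pls()].
#' @return A `latent_model` of kind `"PLSDA"` with `class_levels` set.
#' @export
fit_plsda <- function(X, labels, n_components = 2L, scale = FALSE) {
  class_levels <- infer_levels(labels)
  Y <- encode_classes(labels, class_levels)
  m <- fit_pls(X, Y, n_components, scale = scale)
  m$kind <- "PLSDA"
  m$class_levels <- class_levels
  m
}

# ---- multilevel (paired) decomposition ----------------------------------

#' Split paired data into within- and between-subject variation
#'
#' Decomposes each sample row as
#' `x = grand_mean + (subject_mean - grand_mean) + (x - subject_mean)`.
#' For a two-sample (B/AT) pair the within rows are `+d/2` and `-d/2`
#' where `d` is the subject's B minus AT difference, so the within part
#' isolates the treatment effect from between-subject variation.
#'
#' @param fm A [feature_matrix()] (or plain matrix with rownames).
#' @param md A [sample_metadata()] covering the rows of `fm`.
#' @return A list of class `multilevel_split` with `X_within` (samples x
#'   features, rows in `fm` order), `X_between` (subjects x features),
#'   `grand_mean`, `subject_order` and `subject_of` (subject per row).
#' @export
multilevel_decompose <- function(fm, md) {
  X <- if (inherits(fm, "feature_matrix")) fm_values(fm) else as.matrix(fm)
  md <- align_metadata(feature_matrix(X, rownames(X), colnames(X)), md)
  subj <- md$subject_id
  counts <- table(subj)
  if (any(counts < 2L)) {
    stop("subject(s) with a single sample cannot be decomposed: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  subject_order <- unique(subj)
  grand <- colMeans(X)
  subj_means <- do.call(rbind, lapply(subject_order, function(s) {
    colMeans(X[subj == s, , drop = FALSE])
  }))
  rownames(subj_means) <- subject_order
  X_within <- X - subj_means[subj, , drop = FALSE]
  X_between <- sweep(subj_means, 2, grand)
  structure(list(X_within = X_within, X_between = X_between,
                 grand_mean = grand, subject_order = subject_order,
                 subject_of = subj),
            class = "multilevel_split")
}

#' Multilevel (paired) PLS-DA
#'
#' The paired pre/post discrimination model: the baseline (`B`) and
#' after-treatment (`AT`) samples are reduced to their within-subject
#' variation by [multilevel_decompose()], and a PLS-DA model with a two-
#' level encoding (`B` = +1, `AT` = -1) is fitted on the within part.
#' Scores of this model are the coordinates of the paired score plot.
#'
#' @param fm A [feature_matrix()] containing the B and AT samples (other
#'   groups are ignored).
#' @param md A [sample_metadata()].
#' @param n_components Number of latent components.
#' @param scale Unit-variance scaling of the within-subject matrix, as in
#'   [fit_pls()].
#' @return A `latent_model` of kind `"MPLS"`.
#' @export
fit_mpls_paired <- function(fm, md, n_components = 2L, scale = FALSE) {
  md <- align_metadata(fm, md)
  keep <- md$group %in% c("B", "AT")
  if (!any(keep)) stop("no B/AT samples for the paired model")
  X <- fm_values(fm)[keep, , drop = FALSE]
  mdp <- md[keep, , drop = FALSE]
  paired <- intersect(mdp$subject_id[mdp$group == "B"],
                      mdp$subject_id[mdp$group == "AT"])
  full <- mdp$subject_id %in% paired
  if (sum(full) < 4L) stop("need at least two complete B/AT pairs")
  X <- X[full, , drop = FALSE]
  mdp <- mdp[full, , drop = FALSE]
  split <- multilevel_decompose(feature_matrix(X, mdp$sample_id, colnames(X)), mdp)
  m <- fit_plsda(split$X_within, factor(mdp$group, levels = c("B", "AT")),
                 n_components, scale = scale)
  m$kind <- "MPLS"
  m
}

# ---- OPLS-DA ------------------------------------------------------------

#' Orthogonal PLS discriminant analysis
#'
#' OPLS-DA: orthogonal-signal-correction components that capture X
#' variation uncorrelated with the class encoding are removed first, then
#' predictive PLS components are fitted on the filtered matrix. Each
#' orthogonal weight is the current first X-loading projected off the
#' column space of `X'Y`, which makes every orthogonal score exactly
#' uncorrelated with every encoding column. With `n_orthogonal = 0` the
#' model reduces to plain PLS-DA.
#'
#' @param X Numeric matrix, samples x features.
#' @param labels Class labels (two or more classes; three or more use a
#'   dummy encoding with a class-of-maximum decision rule).
#' @param n_predictive Number of predictive components.
#' @param n_orthogonal Number of orthogonal components removed.
#' @param scale Unit-variance scaling, as in [fit_pls()].
#' @return A `latent_model` of kind `"OPLSDA"` with additional fields
#'   `W_orth`, `P_orth`, `T_orth`.
#' @export
fit_oplsda <- function(X, labels, n_predictive = 2L, n_orthogonal = 1L,
                       scale = FALSE) {
  X <- as.matrix(X)
  class_levels <- infer_levels(labels)
  Y <- encode_classes(labels, class_levels)
  X_mean <- colMeans(X)
  Y_mean <- colMeans(Y)
  E <- sweep(X, 2, X_mean)
  X_sd <- NULL
  if (isTRUE(scale)) {
    X_sd <- apply(E, 2, stats::sd)
    X_sd[X_sd < .Machine$double.eps * 1e3] <- 1
    E <- sweep(E, 2, X_sd, `/`)
  }
  F <- sweep(Y, 2, Y_mean)
  p <- ncol(E)
  if (n_orthogonal > 0 && n_predictive + n_orthogonal > min(nrow(E) - 1L, p)) {
    stop("n_predictive + n_orthogonal exceeds the rank budget of the data")
  }
  W_orth <- P_orth <- matrix(0, p, n_orthogonal)
  T_orth <- matrix(0, nrow(E), n_orthogonal)
  for (j in seq_len(n_orthogonal)) {
    C <- crossprod(E, F)                       # p x k, spans the Y-predictive space
    sv <- svd(C)
    keep <- sv$d > max(sv$d) * 1e-12
    Wy <- sv$u[, keep, drop = FALSE]
    comp1 <- nipals_core(E, F, 1L)
    w_o <- drop(comp1$P[, 1] - Wy %*% crossprod(Wy, comp1$P[, 1]))
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10) {
      stop("no Y-orthogonal variation left for orthogonal component ", j)
    }
    w_o <- w_o / nw
    s <- sign(w_o[which.max(abs(w_o))]); if (s == 0) s <- 1
    w_o <- s * w_o
    t_o <- drop(E %*% w_o)
    p_o <- drop(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    W_orth[, j] <- w_o; P_orth[, j] <- p_o; T_orth[, j] <- t_o
  }
  core <- nipals_core(E, F, n_predictive)
  structure(c(list(kind = "OPLSDA", X_mean = X_mean, X_sd = X_sd,
                   Y_mean = Y_mean,
                   class_levels = class_levels, n_components = n_predictive,
                   W_orth = W_orth, P_orth = P_orth, T_orth = T_orth),
              core),
            class = "latent_model")
}

# remove stored orthogonal variation from new (centred) data
osc_filter <- function(model, Xc) {
  if (is.null(model$W_orth) || ncol(model$W_orth) == 0L) return(Xc)
  for (j in seq_len(ncol(model$W_orth))) {
    t_o <- drop(Xc %*% model$W_orth[, j])
    Xc <- Xc - tcrossprod(t_o, model$P_orth[, j])
  }
  Xc
}

#' Predict the response encoding for new samples
#'
#' @param object A fitted `latent_model`.
#' @param newdata Numeric matrix with the model's feature count.
#' @param ... Unused.
#' @return Predicted response matrix on the encoding scale.
#' @export
predict.latent_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$X_mean)) {
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object$X_mean))
  }
  Xc <- sweep(X, 2, object$X_mean)
  if (!is.null(object$X_sd)) Xc <- sweep(Xc, 2, object$X_sd, `/`)
  Xc <- osc_filter(object, Xc)
  sweep(Xc %*% object$B, 2, object$Y_mean, `+`)
}

#' Predict class labels
#'
#' Centres the new samples with the stored centring vector, removes
#' orthogonal variation for OPLS-DA models, evaluates the regression form
#' of the model and assigns each sample to the class with the maximal
#' predicted encoding (two classes: sign rule). Ties break to the first
#' class in `class_levels`. For multilevel (`MPLS`) models the new
#' samples are first reduced to their own within-subject variation, so
#' `md` is required and every predicted subject needs both its B and AT
#' samples.
#'
#' @param model A fitted `latent_model` with `class_levels`.
#' @param X_new Numeric matrix of new samples.
#' @param md A [sample_metadata()]; required for `MPLS` models.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, X_new, md = NULL) {
  stopifnot(inherits(model, "latent_model"))
  if (is.null(model$class_levels)) stop("model has no class encoding")
  X <- if (inherits(X_new, "feature_matrix")) fm_values(X_new) else as.matrix(X_new)
  if (model$kind == "MPLS") {
    if (is.null(md)) stop("MPLS prediction needs sample metadata")
    fmx <- feature_matrix(X, rownames(X), colnames(X))
    split <- multilevel_decompose(fmx, md)
    X <- split$X_within
  }
  Yhat <- predict(model, X)
  unname(decode_classes(Yhat, model$class_levels))
}

#' Predictive (and orthogonal) scores of a fitted model
#'
#' @param model A fitted `latent_model`.
#' @return Data frame of score coordinates (`t1`, `t2`, ..., plus
#'   `t_orth1`, ... for OPLS-DA), one row per training sample.
#' @export
model_scores <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  out <- as.data.frame(model$T)
  names(out) <- paste0("t", seq_len(ncol(model$T)))
  if (!is.null(model$T_orth) && ncol(model$T_orth) > 0L) {
    orth <- as.data.frame(model$T_orth)
    names(orth) <- paste0("t_orth", seq_len(ncol(orth)))
    out <- cbind(out, orth)
  }
  out
}
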