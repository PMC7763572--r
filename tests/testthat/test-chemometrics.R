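test_that("multilevel decomposition: hand arithmetic, zero pairs, exact reconstruction", {
  fm <- feature_matrix(rbind(c(4, 0), c(0, 2)), c("s1_B", "s1_AT"), c("f1", "f2"))
  md <- sample_metadata(data.frame(sample_id = c("s1_B", "s1_AT"),
                                   subject_id = "s1", group = c("B", "AT")))
  sp <- multilevel_decompose(fm, md)
  expect_equal(unname(sp$X_within), rbind(c(2, -1), c(-2, 1)))

  fm2 <- feature_matrix(rbind(c(3, 3), c(3, 3)), c("s1_B", "s1_AT"), c("f1", "f2"))
  expect_equal(unname(multilevel_decompose(fm2, md)$X_within),
               matrix(0, 2, 2))

  set.seed(3)
  ds <- generate_feature_table(toy_panel(5), simulation_config(n_pairs = 6, seed = 3))
  ba <- ba_subset(ds)
  sp3 <- multilevel_decompose(ba$fm, ba$md)
  recon <- sweep(sp3$X_within, 2, sp3$grand_mean, `+`) +
    sp3$X_between[sp3$subject_of, ]
  expect_equal(unname(recon), unname(unclass(ba$fm)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a subject with a single sample cannot be decomposed
  md1 <- sample_metadata(data.frame(sample_id = c("s1_B", "s1_AT", "h1"),
                                    subject_id = c("s1", "s1", "h1"),
                                    group = c("B", "AT", "HI")))
  fm3 <- feature_matrix(matrix(1:6, 3), c("s1_B", "s1_AT", "h1"), c("f1", "f2"))
  expect_error(multilevel_decompose(fm3, md1), "single sample")
})

test_that("NIPALS PLS recovers a rank-1 structure and classifies a separable toy exactly", {
  set.seed(11)
  t_true <- rnorm(12)
  p_true <- c(2, -1, 0.5, 3)
  X <- t_true %*% t(p_true)
  m <- fit_pls(X, matrix(t_true), n_components = 1)
  p_dir <- p_true / sqrt(sum(p_true^2))
  expect_gt(abs(sum(m$W[, 1] * p_dir)), 0.9999)
  resid <- sweep(X, 2, m$X_mean) - m$T %*% t(m$P)
  expect_lt(max(abs(resid)), 1e-10)

  Xt <- rbind(c(1, 0, 0), c(1.1, 0, 0.1), c(-1, 0.2, 0), c(-0.9, 0.1, 0.1))
  lab <- c("a", "a", "b", "b")
  mt <- fit_plsda(Xt, lab, 1)
  expect_identical(predict_labels(mt, Xt), lab)

  # scores orthogonal on generic data
  set.seed(12)
  Xr <- matrix(rnorm(200), 20, 10)
  Yr <- matrix(rnorm(20))
  mr <- fit_pls(Xr, Yr, 3)
  g <- crossprod(mr$T)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("single-response PLS agrees with a direct non-iterative oracle and with mixOmics", {
  set.seed(21)
  X <- matrix(rnorm(15 * 8), 15, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rnorm(15)
  Xn <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(NULL, paste0("f", 1:8)))
  m <- fit_pls(X, matrix(y), 3)
  pred_pkg <- drop(predict(m, Xn))
  orc <- pls1_oracle(X, y, 3)
  expect_equal(pred_pkg, orc$predict(Xn), tolerance = 1e-6)

  mo <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  pred_mo <- predict(mo, Xn)$predict[, 1, 3]
  expect_equal(unname(pred_pkg), unname(pred_mo), tolerance = 1e-6)

  # unit-variance scaling stored in the model equals fitting pre-scaled data
  ms <- fit_pls(X, matrix(y), 2, scale = TRUE)
  Xsc <- base::scale(X)
  mref <- fit_pls(Xsc, matrix(y), 2)
  Xn_sc <- base::scale(Xn, center = attr(Xsc, "scaled:center"),
                       scale = attr(Xsc, "scaled:scale"))
  expect_equal(drop(predict(ms, Xn)), drop(predict(mref, Xn_sc)),
               tolerance = 1e-10)
})

test_that("paired MPLS separates a constant treatment shift, negates under label swap, and ignores subject order", {
  # every metabolite shifted by a constant between B and AT, no noise
  n <- 6; p <- 4
  set.seed(31)
  base <- matrix(rnorm(n * p, 10, 2), n, p)
  shift <- c(1, -0.5, 2, 0.3)
  X <- rbind(base, sweep(base, 2, shift, `-`))
  ids <- c(paste0("s", 1:n, "_B"), paste0("s", 1:n, "_AT"))
  md <- sample_metadata(data.frame(sample_id = ids,
                                   subject_id = rep(paste0("s", 1:n), 2),
                                   group = rep(c("B", "AT"), each = n)))
  fm <- feature_matrix(X, ids, paste0("f", 1:p))
  m <- fit_mpls_paired(fm, md, 1)
  t1 <- m$T[, 1]
  expect_true(all(t1[1:n] > 0) && all(t1[(n + 1):(2 * n)] < 0) ||
                all(t1[1:n] < 0) && all(t1[(n + 1):(2 * n)] > 0))

  # swapping B and AT labels mirrors the model: scores agree up to one
  # global sign (the deterministic weight-sign convention may reabsorb the
  # flip) and predictions swap with the labels
  md_sw <- md
  md_sw$group <- factor(ifelse(md$group == "B", "AT", "B"), levels = levels(md$group))
  m_sw <- fit_mpls_paired(fm, md_sw, 1)
  expect_equal(abs(m_sw$T[, 1]), abs(t1), tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(predict_labels(m_sw, fm, md_sw), as.character(md_sw$group))

  # permuting subject (row) order permutes but does not change the scores
  perm <- c(seq(2, 2 * n, by = 2), seq(1, 2 * n, by = 2))
  fm_p <- feature_matrix(X[perm, ], ids[perm], paste0("f", 1:p))
  m_p <- fit_mpls_paired(fm_p, md, 1)
  expect_equal(m_p$T[match(ids, ids[perm]), 1], t1, tolerance = 1e-9,
               ignore_attr = TRUE)

  # strong-signal cohort: resubstitution accuracy 100%
  ds <- generate_feature_table(cfg = simulation_config(kappa = 2, seed = 13))
  ba <- ba_subset(ds)
  mm <- fit_mpls_paired(ba$fm, ba$md, 2)
  pred <- predict_labels(mm, ba$fm, ba$md)
  expect_identical(pred, as.character(ba$md$group))
})

test_that("OPLS-DA: reduces to PLS-DA at zero orthogonal components and strips a Y-orthogonal nuisance", {
  set.seed(41)
  X <- matrix(rnorm(20 * 6), 20, 6)
  lab <- rep(c("a", "b"), each = 10)
  m0 <- fit_oplsda(X, lab, n_predictive = 2, n_orthogonal = 0)
  mp <- fit_plsda(X, lab, 2)
  expect_equal(m0$T, mp$T, tolerance = 1e-8)

  # y-correlated direction + larger-variance y-orthogonal nuisance
  y <- rep(c(1, -1), each = 12)
  set.seed(42)
  nuis <- rnorm(24, sd = 4)
  nuis <- nuis - mean(nuis)
  nuis <- nuis - y * sum(nuis * y) / sum(y * y)  # exactly orthogonal to y
  d_sig <- c(1, 1, 0, 0, 0, 0) / sqrt(2)
  d_nui <- c(0, 0, 0, 0, 1, -1) / sqrt(2)
  X2 <- y %*% t(d_sig) + nuis %*% t(d_nui) + matrix(rnorm(24 * 6, sd = 0.01), 24, 6)
  m1 <- fit_oplsda(X2, rep(c("a", "b"), each = 12), 1, 1)
  expect_gt(abs(cor(m1$T[, 1], y)), 0.99)
  expect_gt(abs(sum(m1$P_orth[, 1] * d_nui) /
                  sqrt(sum(m1$P_orth[, 1]^2))), 0.99)

  # orthogonal scores are exactly uncorrelated with the class encoding
  expect_lt(abs(cor(m1$T_orth[, 1], y)), 1e-8)

  ds <- generate_feature_table(cfg = simulation_config(kappa = 2, seed = 14))
  mfull <- fit_oplsda(unclass(ds$features), ds$metadata$group, 2, 1)
  Yenc <- salivanmr:::encode_classes(as.character(ds$metadata$group),
                                     mfull$class_levels)
  cors <- abs(cor(mfull$T_orth, Yenc))
  expect_lt(max(cors), 1e-8)

  # predictive-score variance is non-increasing in the orthogonal count
  v <- vapply(0:2, function(k) {
    sum(apply(fit_oplsda(unclass(ds$features), ds$metadata$group, 2, k)$T, 2, var))
  }, numeric(1))
  expect_true(all(diff(v) <= 1e-8))

  expect_error(fit_oplsda(X2[1:5, ], rep(c("a", "b"), c(3, 2)), 4, 3), "rank")
})

test_that("label prediction: tie-break to the first class, feature-count mismatch is an error", {
  X <- rbind(c(1, 0), c(2, 0.5), c(-1, 1), c(-2, -0.5))
  m <- fit_plsda(X, c("a", "a", "b", "b"), 1)
  # the centroid is exactly on the boundary of a symmetric two-class model
  expect_identical(predict_labels(m, matrix(m$X_mean, 1)), "a")
  expect_error(predict_labels(m, matrix(1, 1, 5)), "features")

  # strong-signal three-group cohort: held-out accuracy above 0.9 (unit-
  # variance scaling, the appropriate treatment for concentration tables)
  ds <- generate_feature_table(cfg = simulation_config(kappa = 2, seed = 15))
  v <- monte_carlo_cv(ds$features, ds$metadata,
                      oplsda_model(2, 1, scale = TRUE),
                      cv_config(n_runs = 15, seed = 3))
  expect_gt(v$mean_accuracy, 0.9)
})
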