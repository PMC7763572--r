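test_that("Kruskal-Wallis: rank-arithmetic oracle, degenerate case, two-group identity with the normal U statistic", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 7.2)
  expect_equal(kw$H, kruskal_wallis_oracle(g))
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2))), list(H = 0, p = 1))

  # two groups: H equals the squared tie-corrected normal U statistic
  set.seed(5)
  a <- round(rnorm(11, 10, 2), 1)  # rounding induces some ties
  b <- round(rnorm(12, 11, 2), 1)
  H <- kruskal_wallis(list(a, b))$H
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  expect_equal(H, z^2, tolerance = 1e-9)
})

test_that("signed-rank test: exact enumeration oracle, zero-pair handling, antisymmetry", {
  before <- c(2, 4, 6, 8, 10)
  after <- c(1, 2, 3, 4, 5)  # differences 1..5, all positive
  w <- wilcoxon_signed_rank(before, after)
  expect_equal(w$W, 15)
  expect_equal(w$p, 2 / 32)

  set.seed(6)
  b2 <- rnorm(8); a2 <- b2 + rnorm(8, 0.4)
  mine <- wilcoxon_signed_rank(b2, a2)
  orc <- wilcoxon_exact_oracle(b2 - a2)
  expect_equal(mine$W, orc$W)
  expect_equal(mine$p, orc$p, tolerance = 1e-9)

  # swapping the two time points leaves p unchanged
  expect_equal(wilcoxon_signed_rank(a2, b2)$p, mine$p)

  # zero differences are dropped and counted; all-zero input is an error
  w3 <- wilcoxon_signed_rank(c(1, 2, 3, 3), c(1, 1, 1, 3))
  expect_equal(w3$n_dropped, 2)
  expect_equal(w3$n_effective, 2)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "no informative pairs")
})

test_that("Mann-Whitney: enumeration oracle, tie plateau, monotone response to location shift", {
  m <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  expect_equal(m$p, 2 / 6, tolerance = 1e-9)
  orc <- mann_whitney_exact_oracle(c(1, 2), c(3, 4))
  expect_equal(m$p, orc$p, tolerance = 1e-9)

  set.seed(7)
  a <- rnorm(6); b <- rnorm(5, 0.5)
  mine <- mann_whitney_u(a, b)
  orc2 <- mann_whitney_exact_oracle(a, b)
  expect_equal(mine$U, orc2$U)
  expect_equal(mine$p, orc2$p, tolerance = 1e-9)

  # identical multisets: central U, p indistinguishable from 1
  eq <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$U, 4.5)
  expect_gt(eq$p, 0.99)

  # p decreases as the separation between fixed samples grows (shifts
  # chosen so the pooled samples stay tie-free and the path stays exact)
  base <- c(0.1, 0.5, 0.9, 1.3, 1.7)
  ps <- vapply(c(0.05, 0.5, 1.1, 2.3), function(s) mann_whitney_u(base, base + s)$p,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("exact and normal-approximate p-values agree near the enumeration cutoffs", {
  set.seed(8)
  d <- rnorm(20)                      # signed-rank, tie-free n = 20
  exact <- wilcoxon_signed_rank(d + 10, rep(10, 20))$p
  approx <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(exact - approx), 0.02)

  a <- rnorm(20); b <- rnorm(20, 0.3)  # U test at the 400-pair boundary
  exact2 <- mann_whitney_u(a, b)$p
  approx2 <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(exact2 - approx2), 0.02)
})

test_that("Benjamini-Hochberg: fixed points, dominance, idempotence, step-up oracle", {
  expect_equal(benjamini_hochberg(rep(0.5, 7)), rep(0.5, 7))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_error(benjamini_hochberg(c(0.2, 0)), "0, 1")

  set.seed(9)
  for (i in 1:5) {
    p <- runif(17)^2
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # recomputing from the same raw p-values reproduces the adjustment,
    # and adjusted values are monotone nondecreasing in sorted order
    expect_identical(benjamini_hochberg(p), adj)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("FDR over the panel's reported p-values reproduces the published significance pattern", {
  panel <- salivary_metabolite_panel()
  adj_kw <- benjamini_hochberg(panel$p_kw)
  expect_setequal(panel$name[adj_kw < 0.05],
                  c("acetate", "ethanol", "valine", "acetoin"))
  adj_wx <- benjamini_hochberg(panel$p_wilcoxon)
  expect_identical(panel$name[adj_wx < 0.05], "valine")
})

test_that("the per-metabolite statistics table is internally consistent and matches the cohort structure", {
  ds <- generate_feature_table(cfg = simulation_config(seed = 21))
  tab <- build_metabolite_stats_table(ds$features, ds$metadata)
  expect_identical(nrow(tab), 31L)
  expect_true(all(tab$fdr_kw >= tab$p_kw - 1e-12))
  expect_equal(tab$fdr_kw, benjamini_hochberg(tab$p_kw))
  expect_equal(tab$fdr_wilcoxon, benjamini_hochberg(tab$p_wilcoxon_paired))
  expect_equal(tab$fdr_mannwhitney, benjamini_hochberg(tab$p_mannwhitney))

  # valine falls after therapy, matching the generating panel direction
  val <- tab[tab$metabolite == "valine", ]
  expect_gt(val$mean_B - val$mean_AT, 0)

  ba <- ba_subset(ds)
  expect_error(build_metabolite_stats_table(ba$fm, ba$md), "HI")

  long <- metabolite_long_table(ds$features, ds$metadata)
  expect_identical(nrow(long), 35L * 31L)
})

test_that("the table-building procedure holds its type-I error on null cohorts", {
  reps <- 40
  pmat <- do.call(rbind, lapply(seq_len(reps), function(i) {
    ds <- generate_null_dataset(toy_panel(5),
                                simulation_config(n_pairs = 12, n_healthy = 11,
                                                  rho = 0.5, seed = 5000 + i))
    tab <- build_metabolite_stats_table(ds$features, ds$metadata)
    c(tab$p_kw, tab$p_wilcoxon_paired, tab$p_mannwhitney)
  }))
  # 40 x 15 p-values per family; discrete rank tests make the attainable
  # level slightly below 0.05, so test against a generous binomial band
  rate <- mean(pmat < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.09)
  # BH within a null replicate almost never declares a discovery
  ds0 <- generate_null_dataset(toy_panel(5),
                               simulation_config(n_pairs = 12, n_healthy = 11,
                                                 seed = 99))
  tab0 <- build_metabolite_stats_table(ds0$features, ds0$metadata)
  expect_lte(sum(tab0$fdr_kw < 0.05), 1)
})

test_that("clinical t-tests: Welch and paired forms with documented degenerate errors", {
  expect_error(clinical_t_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               "degenerate")
  expect_error(clinical_t_tests(c(1, 2, 3), c(2, 3, 4), paired = TRUE),
               "degenerate")  # constant difference, zero variance
  expect_error(clinical_t_tests(c(2, 2, 2), c(5, 5, 5), paired = FALSE),
               "degenerate")

  eq <- clinical_t_tests(c(1, 2, 3, 4), c(1, 2, 3, 4), paired = FALSE)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  set.seed(10)
  x <- rnorm(12); y <- rnorm(12, 1)
  ref <- t.test(y, x, paired = TRUE)
  mine <- clinical_t_tests(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})
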