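# Independent brute-force / closed-form oracles used to check the package
# implementations. These never call the code paths they verify.

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns
# (tie-free absolute differences assumed).
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p <- 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs))
  list(W = w_obs, p = min(1, p))
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n, na) group
# labelings (tie-free pooled sample assumed).
mann_whitney_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  idx_all <- utils::combn(na + nb, na)
  u_all <- apply(idx_all, 2, u_of)
  p <- 2 * min(mean(u_all >= u_obs), mean(u_all <= u_obs))
  list(U = u_obs, p = min(1, p))
}

# Kruskal-Wallis H by direct rank arithmetic (no tie correction; use on
# tie-free data only).
kruskal_wallis_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  off <- 0
  h <- 0
  for (g in groups) {
    ri <- r[seq_along(g) + off]
    off <- off + length(g)
    h <- h + length(g) * (mean(ri) - (n + 1) / 2)^2
  }
  12 / (n * (n + 1)) * h
}

# Step-up BH adjustment written directly from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  run_min <- 1
  for (i in m:1) {
    run_min <- min(run_min, p[o[i]] * m / i)
    adj_sorted[i] <- run_min
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Direct (non-iterative) single-response PLS: w = X'y normalized, with
# deflation of both blocks; regression coefficients via W (P'W)^-1 q.
pls1_oracle <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- matrix(0, ncol(X), ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t_sc <- drop(E %*% w)
    p_load <- drop(crossprod(E, t_sc)) / sum(t_sc^2)
    q[a] <- sum(f * t_sc) / sum(t_sc^2)
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - t_sc * q[a]
    W[, a] <- w; P[, a] <- p_load
  }
  B <- W %*% solve(crossprod(P, W), matrix(q, ncol = 1))
  list(predict = function(Xn) drop(sweep(as.matrix(Xn), 2, xm) %*% B) + ym)
}

# Lorentzian lineshape with apex height h and half width at half maximum w;
# analytic area h * w * pi.
lorentzian <- function(x, center, h, w) h * w^2 / ((x - center)^2 + w^2)

# small synthetic cohort panel with well-behaved moments (mean >> sd so
# zero-truncation mass is negligible)
toy_panel <- function(n_metab = 4, mean_B = 1000, mean_AT = 600, mean_HI = 800,
                      sd = 100) {
  data.frame(name = paste0("m", seq_len(n_metab)),
             mean_B = mean_B, sd_B = sd, mean_AT = mean_AT, sd_AT = sd,
             mean_HI = mean_HI, sd_HI = sd, stringsAsFactors = FALSE)
}

ba_subset <- function(ds) {
  md <- ds$metadata
  ba <- md$group %in% c("B", "AT")
  X <- as.matrix(unclass(ds$features))
  list(fm = feature_matrix(X[ba, , drop = FALSE], md$sample_id[ba],
                           colnames(X)),
       md = md[ba, , drop = FALSE])
}
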