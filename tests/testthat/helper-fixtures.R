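# shared fixtures: everything is generated in code at test time

# a mapping comfortably inside the hypothesis space, so that short noise-free
# runs never touch the clip box (needed by exact-algebra oracles)
safe_mapping <- function(n = 1) {
  new_mapping(
    w_star = runif(n, 0.6, 1.4),
    b_star = runif(n, -0.1, 0.1)
  )
}

# small standard design reused across files
fixture_design <- function(seed = 101) make_design(seed = seed)

# one-sided Monte-Carlo (bootstrap) p-value for mean(a) > mean(b)
boot_mean_gt_p <- function(a, b, B = 2000, seed = 1) {
  d <- withr::with_seed(seed, replicate(B, {
    mean(sample(a, length(a), replace = TRUE)) -
      mean(sample(b, length(b), replace = TRUE))
  }))
  (1 + sum(d <= 0)) / (B + 1)
}

# brute-force exact null of the Wilcoxon signed-rank statistic: enumerate all
# 2^n sign patterns of |d| and return the two-sided p for the observed V
signed_rank_exact_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}
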