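# Shared fixtures, all generated in code.

# noise-free 27-run reference experiment: responses lie exactly on the
# published quadratic surfaces
ref_design_exact <- function(seed = 1) {
  d <- bbd_design(default_medium_factors(), center_replicates = 3, seed = seed)
  simulate_bbd_responses(d, models = reference_models(), noise_sd = 0)
}

# 1000 points on a rank-4 affine manifold inside the 6-dim unit cube: the
# canonical fixture a 4-dim embedding can represent exactly
affine_manifold <- function(n = 1000, seed = 11) {
  set.seed(seed)
  Z <- matrix(stats::runif(n * 4), n)
  W <- matrix(stats::rnorm(24), 4, 6)
  A <- Z %*% W
  rng <- apply(A, 2, range)
  A <- sweep(sweep(A, 2, rng[1, ], `-`), 2, rng[2, ] - rng[1, ], `/`) * 0.8 + 0.1
  colnames(A) <- paste0("a", 1:6)
  A
}

# brute-force two-loop one-way ANOVA used as an independent oracle
anova_bruteforce <- function(data) {
  groups <- split(data$zone_mm, data$source)
  grand <- mean(data$zone_mm)
  ss_b <- 0
  ss_w <- 0
  for (g in groups) {
    ss_b <- ss_b + length(g) * (mean(g) - grand)^2
    for (v in g) ss_w <- ss_w + (v - mean(g))^2
  }
  list(ss_between = ss_b, ss_within = ss_w,
       df_between = length(groups) - 1,
       df_within = length(data$zone_mm) - length(groups))
}
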