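test_that("reconstructed carbon screening reproduces the published ANOVA", {
  sc <- reference_screening("carbon")
  g <- make_screening_groups(sc$means, within_ss_total = sc$ss_error, n_per_group = 6)
  a <- one_way_anova(g)
  expect_equal(round(a$SS[1], 2), 70.95)
  expect_equal(round(a$F[1], 2), 9.55)
  expect_equal(a$DF[1:2], c(6, 35))
  expect_lt(a$p[1], 0.05)
})

test_that("reconstructed nitrogen screening reproduces the published ANOVA", {
  sn <- reference_screening("nitrogen")
  g <- make_screening_groups(sn$means, within_ss_total = sn$ss_error, n_per_group = 6)
  a <- one_way_anova(g)
  expect_equal(round(a$SS[1], 2), 214.33)
  expect_equal(round(a$F[1], 3), 18.692)
  expect_equal(a$DF[1:2], c(4, 25))
})

test_that("one-way ANOVA agrees with the brute-force oracle on random data", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    sizes <- sample(2:8, k, replace = TRUE)
    dat <- data.frame(
      source = rep(letters[1:k], sizes),
      zone_mm = rnorm(sum(sizes), mean = 20 + 2 * rep(seq_len(k), sizes), sd = 1.5))
    a <- one_way_anova(dat)
    bf <- anova_bruteforce(dat)
    expect_equal(a$SS[1], bf$ss_between, tolerance = 1e-9)
    expect_equal(a$SS[2], bf$ss_within, tolerance = 1e-9)
    expect_equal(a$DF[1], bf$df_between)
    expect_equal(a$DF[2], bf$df_within)
    # SS and DF additivity
    expect_equal(a$SS[3], a$SS[1] + a$SS[2], tolerance = 1e-9)
    expect_equal(a$DF[3], a$DF[1] + a$DF[2])
  }
})

test_that("degenerate ANOVA inputs are handled explicitly", {
  flat <- data.frame(source = rep(c("a", "b"), each = 3), zone_mm = rep(20, 6))
  a <- one_way_anova(flat)
  expect_equal(a$SS[1], 0)
  expect_equal(a$F[1], 0)

  sep <- data.frame(source = rep(c("a", "b"), each = 3), zone_mm = rep(c(20, 25), each = 3))
  a2 <- one_way_anova(sep)   # zero within-group variance, unequal means
  expect_equal(a2$F[1], Inf)
  expect_equal(a2$p[1], 0)

  expect_error(
    one_way_anova(data.frame(source = c("a", "a", "b"), zone_mm = c(20, 21, 22))),
    "fewer than 2 replicates")
})

test_that("Duncan grouping reproduces the carbon-source letter structure", {
  sc <- reference_screening("carbon")
  d <- duncan_mrt(sc$means, n_per_group = 6, ms_error = sc$ms_error,
                  df_error = sc$df_error, alpha = 0.05)
  lett <- setNames(strsplit(d$letters, ""), d$group)
  # cellulose and fructose share a letter held by no other source
  shared <- intersect(lett$cellulose, lett$fructose)
  expect_gt(length(shared), 0)
  others <- setdiff(d$group, c("cellulose", "fructose"))
  expect_false(any(shared %in% unlist(lett[others])))
  # starch sits in a group of its own
  expect_false(any(lett$starch %in% unlist(lett[setdiff(d$group, "starch")])))
  # the middle block (lactose..glycerol) is one homogeneous stretch
  mid <- c("lactose", "glucose", "maltose", "glycerol")
  expect_length(unique(unlist(lett[mid])), 1)
})

test_that("Duncan grouping reproduces the nitrogen-source letter structure", {
  sn <- reference_screening("nitrogen")
  d <- duncan_mrt(sn$means, n_per_group = 6, ms_error = sn$ms_error,
                  df_error = sn$df_error, alpha = 0.05)
  lett <- setNames(strsplit(d$letters, ""), d$group)
  expect_gt(length(intersect(lett$urea, lett$l_glutamic_acid)), 0)
  expect_gt(length(intersect(lett$peptone, lett$yeast_extract)), 0)
  # tryptone differs from both blocks
  expect_false(any(lett$tryptone %in% c(lett$urea, lett$peptone)))
  # lowest mean carries letter 'a'
  expect_match(d$letters[which.min(d$mean)], "a")
})

test_that("Duncan letters are invariant under input permutation", {
  sc <- reference_screening("carbon")
  d1 <- duncan_mrt(sc$means, 6, sc$ms_error, sc$df_error)
  set.seed(7)
  d2 <- duncan_mrt(sample(sc$means), 6, sc$ms_error, sc$df_error)
  expect_equal(d1[order(d1$group), ], d2[order(d2$group), ], ignore_attr = TRUE)
})

test_that("Duncan limiting behaviour: alpha -> 0 merges, ms -> 0 separates", {
  m <- c(a = 20, b = 21, c = 22)
  merged <- duncan_mrt(m, 6, ms_error = 1, df_error = 15, alpha = 1e-8)
  expect_length(unique(merged$letters), 1)
  split <- duncan_mrt(m, 6, ms_error = 1e-10, df_error = 15, alpha = 0.05)
  expect_length(unique(split$letters), 3)
  # identical means always share their letters
  tied <- duncan_mrt(c(a = 20, b = 20, c = 26), 6, 0.5, 15)
  expect_equal(tied$letters[tied$group == "a"], tied$letters[tied$group == "b"])
})

test_that("correlation screen is symmetric with unit diagonal", {
  x <- seq_len(10)
  tab <- data.frame(x = x, y = -x, z = rnorm(10))
  cc <- correlation_screen(tab)
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc["x", "y"], -1)
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
})

test_that("a constant attribute yields NA correlations, not zero", {
  tab <- data.frame(x = 1:5, const = rep(3, 5))
  cc <- correlation_screen(tab)
  expect_true(is.na(cc["x", "const"]))
  expect_equal(cc["const", "const"], 1)
})

test_that("cellulose shows the strongest factor correlation with the PA2DSS response", {
  d <- simulate_bbd_responses(bbd_design(default_medium_factors(), 3, seed = 8),
                              noise_sd = 0.5, seed = 8)
  cc <- correlation_screen(d)
  r <- abs(cc[sapply(d$factors, `[[`, "name"), "PA2DSS"])
  expect_equal(names(which.max(r)), "cellulose")
})
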