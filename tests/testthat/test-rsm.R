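ref <- reference_models()

test_that("printed models evaluated at the optimized composition give the published predictions", {
  pt <- c(5, 0, 3.77, 0.5)
  expect_equal(round(predict_response(ref$SA2BSS, pt), 2), 30.66)
  expect_equal(round(predict_response(ref$PA2DSS, pt), 2), 27.84)
})

test_that("noise-free fits recover the generating coefficients", {
  d <- ref_design_exact()
  for (resp in c("SA2BSS", "PA2DSS")) {
    fit <- fit_quadratic(d, resp, "natural")
    truth <- ref[[resp]]$coefficients
    err <- abs(fit$model$coefficients - truth) / pmax(abs(truth), 1e-3)
    expect_lt(max(err), 1e-6)
    expect_equal(fit$diagnostics$r2, 1, tolerance = 1e-9)
    expect_equal(fit$diagnostics$df_residual, 12)   # 27 runs, 15 terms
  }
})

test_that("prediction is exact and guarded against extrapolation", {
  f <- default_medium_factors()
  const <- quadratic_model(
    setNames(c(7, rep(0, 14)), names(ref$SA2BSS$coefficients)), f, "natural")
  expect_equal(predict_response(const, c(20, 2.5, 2.5, 2.5)), 7)
  expect_equal(predict_response(const, c(5, 0, 0, 0.5)), 7)
  expect_error(predict_response(ref$SA2BSS, c(50, 0, 3, 1)), "extrapolate")
  expect_equal(predict_response(ref$SA2BSS, c(50, 0, 3, 1), extrapolate = TRUE),
               drop(c(1, 50, 0, 3, 1, 0, 150, 50, 0, 0, 3, 2500, 0, 9, 1) %*%
                      ref$SA2BSS$coefficients))
})

test_that("model ANOVA partitions the corrected total", {
  d <- simulate_bbd_responses(bbd_design(default_medium_factors(), 3, seed = 21),
                              noise_sd = 0.5, seed = 21)
  fit <- fit_quadratic(d, "SA2BSS")
  a <- model_anova(fit$model, d, "SA2BSS")
  expect_equal(a$SS[3], a$SS[1] + a$SS[2], tolerance = 1e-9)
  expect_gte(attr(a, "r2"), 0.9)
  expect_lte(attr(a, "r2"), 1.0)
  expect_equal(attr(a, "r2"), fit$diagnostics$r2, tolerance = 1e-9)

  d0 <- ref_design_exact()
  fit0 <- fit_quadratic(d0, "SA2BSS")
  a0 <- model_anova(fit0$model, d0, "SA2BSS")
  expect_lt(a0$SS[2], 1e-9 * a0$SS[3])
  expect_equal(a0$F[1], Inf)
  expect_equal(a0$p[1], 0)
})

test_that("adjusted R2 bridges the published fit and comparison tables", {
  expect_equal(round(adjusted_r2(0.96, 27, 15), 2), 0.91)
  expect_equal(round(adjusted_r2(0.95, 27, 15), 2), 0.89)
  expect_equal(adjusted_r2(1, 27, 15), 1)
  expect_equal(adjusted_r2(1, 10, 4), 1)
  expect_error(adjusted_r2(0.9, 15, 15), "undefined")
})

test_that("fitted values satisfy hat-matrix consistency at the design points", {
  d <- simulate_bbd_responses(bbd_design(default_medium_factors(), 3, seed = 22),
                              noise_sd = 0.5, seed = 22)
  fit <- fit_quadratic(d, "PA2DSS")
  manual <- apply(d$natural, 1, function(p) predict_response(fit$model, p))
  ss_res <- sum((d$responses$PA2DSS - manual)^2)
  expect_equal(ss_res, fit$diagnostics$ss_residual, tolerance = 1e-9)
})

test_that("coded and natural fits predict identically", {
  d <- simulate_bbd_responses(bbd_design(default_medium_factors(), 3, seed = 23),
                              noise_sd = 0.5, seed = 23)
  fn <- fit_quadratic(d, "SA2BSS", "natural")
  fc <- fit_quadratic(d, "SA2BSS", "coded")
  expect_false(isTRUE(all.equal(fn$model$coefficients, fc$model$coefficients)))
  set.seed(24)
  f <- default_medium_factors()
  pts <- sapply(f, function(s) runif(25, s$low, s$high))
  pn <- apply(pts, 1, function(p) predict_response(fn$model, p))
  pc <- apply(pts, 1, function(p) predict_response(fc$model, p))
  expect_equal(pn, pc, tolerance = 1e-9)
})

test_that("surface slices agree with pointwise prediction", {
  m <- ref$SA2BSS
  sl <- surface_slice(m, c("urea", "ammonium_sulfate"), n = 11)
  corner <- sl[sl$urea == 0 & sl$ammonium_sulfate == 0, ]
  expect_equal(corner$predicted,
               predict_response(m, c(20, 0, 0, 2.5)), tolerance = 1e-12)
  # a constant model gives a flat slice at b0
  const <- quadratic_model(
    setNames(c(5, rep(0, 14)), names(m$coefficients)), m$factors, "natural")
  expect_equal(unique(surface_slice(const, c("cellulose", "urea"))$predicted), 5)
  # quadratic surface over a box attains its slice maximum on the boundary
  sl2 <- surface_slice(m, c("urea", "ammonium_sulfate"), n = 41)
  top <- sl2[which.max(sl2$predicted), ]
  on_boundary <- top$urea %in% c(0, 5) | top$ammonium_sulfate %in% c(0, 5)
  expect_true(on_boundary)
  expect_error(surface_slice(m, c("urea", "nope")), "unknown factor")
})

test_that("model comparison ranks by adjusted R2 and flags the winner", {
  cmp <- compare_models(c(RSM = 0.91, ANN = 0.83))
  expect_equal(cmp$model[1], "RSM")
  expect_true(cmp$selected[1] && !cmp$selected[2])
  cmp2 <- compare_models(c(RSM = 0.89, ANN = 0.81))
  expect_equal(cmp2$model[cmp2$selected], "RSM")
  tie <- compare_models(c(A = 0.9, B = 0.9))
  expect_equal(sum(tie$selected), 2)
  expect_equal(tie$model, c("A", "B"))   # stable order among ties
  expect_error(compare_models(numeric(0)), "invalid")
})

test_that("insufficient or degenerate designs are rejected", {
  d <- ref_design_exact()
  short <- d
  keep <- 1:14
  short$coded <- short$coded[keep, ]; short$natural <- short$natural[keep, ]
  short$responses <- short$responses[keep, , drop = FALSE]
  expect_error(fit_quadratic(short, "SA2BSS"), "insufficient data")
})
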