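coef_names <- function(k) {
  pairs <- utils::combn(k, 2)
  c("b0", paste0("b", seq_len(k)),
    paste0("b", pairs[1, ], pairs[2, ]),
    paste0("b", seq_len(k), seq_len(k)))
}

# Expanded second-degree basis [X_i, X_i*X_j (i<j), X_i^2] for a runs x k
# matrix of factor settings; column names follow the b-coefficient scheme.
quadratic_basis <- function(X) {
  k <- ncol(X)
  pairs <- utils::combn(k, 2)
  inter <- sapply(seq_len(ncol(pairs)), function(j) X[, pairs[1, j]] * X[, pairs[2, j]])
  if (is.null(dim(inter))) inter <- matrix(inter, nrow = nrow(X))
  B <- cbind(X, inter, X^2)
  colnames(B) <- coef_names(k)[-1]
  B
}

#' Construct a second-degree polynomial response model
#'
#' The model is
#' \deqn{Y = b_0 + \sum_i b_i X_i + \sum_{i<j} b_{ij} X_i X_j + \sum_i b_{ii} X_i^2}
#' relating k factor settings to a predicted response (here: medium component
#' concentrations in g/L to an inhibition-zone diameter in mm).
#'
#' @param coefficients Named numeric vector with entries `b0`, `b1`..`bk`,
#'   `b12`..`b(k-1)k`, `b11`..`bkk` (1 + 2k + choose(k,2) values).
#' @param factors List of `factor_spec` objects giving the factor identities
#'   and design bounds.
#' @param units_mode `"natural"` (coefficients act on g/L concentrations) or
#'   `"coded"` (on -1..+1 coded levels). Recorded and enforced at prediction.
#' @return Object of class `quadratic_model`.
#' @export
quadratic_model <- function(coefficients, factors, units_mode = c("natural", "coded")) {
  units_mode <- match.arg(units_mode)
  check_factors(factors)
  k <- length(factors)
  want <- coef_names(k)
  if (!setequal(names(coefficients), want))
    stop("coefficients must be named ", paste(want, collapse = ", "))
  structure(
    list(coefficients = coefficients[want], factors = factors, units_mode = units_mode),
    class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, digits = 5, ...) {
  cat(sprintf("quadratic response model (%d factors, %s units)\n",
              length(x$factors), x$units_mode))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Published quadratic inhibition-zone models of the cultivation study
#'
#' The two fitted second-degree models (natural units, g/L) for the
#' inhibition-zone diameter of the Bacillus biocontrol cultivation broth
#' against the aflatoxigenic Aspergillus flavus isolates SA2BSS and PA2DSS,
#' over cellulose, urea, ammonium sulfate and dipotassium phosphate. These
#' coefficient sets are the package's reference ground truth: the
#' synthetic-data generator draws designed experiments from them.
#'
#' @return Named list of two `quadratic_model` objects (`SA2BSS`, `PA2DSS`).
#' @examples
#' m <- reference_models()
#' predict_response(m$SA2BSS, c(5, 0, 3.77, 0.5))  # 30.66 mm
#' @export
reference_models <- function() {
  f <- default_medium_factors()
  sa <- c(b0 = 38.98960, b1 = -0.33876, b2 = -1.49165, b3 = -1.59720, b4 = -3.70852,
          b12 = 0.00000, b13 = 0.00667, b14 = 0.05278, b23 = 0.25333, b24 = -0.01667,
          b34 = 0.15000, b11 = 0.00512, b22 = 0.17111, b33 = 0.03111, b44 = 0.52779)
  pa <- c(b0 = 24.21942, b1 = -0.10015, b2 = 0.48611, b3 = 1.52500, b4 = 0.23958,
          b12 = -0.02000, b13 = 0.00222, b14 = 0.02500, b23 = -0.12000, b24 = 0.05000,
          b34 = -0.25000, b11 = 0.00414, b22 = 0.00222, b33 = -0.10444, b44 = -0.01736)
  list(SA2BSS = quadratic_model(sa, f, "natural"),
       PA2DSS = quadratic_model(pa, f, "natural"))
}

#' Fit the second-degree response-surface model by least squares
#'
#' Ordinary least squares on the expanded basis `[1, X_i, X_i X_j, X_i^2]`.
#' Inference (coefficient standard errors, t and p values, model F) follows
#' the standard linear-model theory on the residual degrees of freedom;
#' R-squared is computed on corrected totals.
#'
#' @param design A `bbd_design` whose `responses` contain `response`.
#' @param response Name of the response column (mm).
#' @param units_mode Fit on `"natural"` concentrations (default; the scale on
#'   which reference coefficient sets are reported) or on `"coded"` levels.
#' @return List with components `model` (a `quadratic_model`) and
#'   `diagnostics` (coefficient table with SE/t/p, `r2`, `adj_r2`, `f`,
#'   `p`, `ss_model`, `ss_residual`, `df_residual`, `sigma`).
#' @export
fit_quadratic <- function(design, response, units_mode = c("natural", "coded")) {
  units_mode <- match.arg(units_mode)
  stopifnot(inherits(design, "bbd_design"))
  if (!response %in% names(design$responses))
    stop("response '", response, "' not found in design (have: ",
         paste(names(design$responses), collapse = ", "), ")")
  y <- design$responses[[response]]
  X <- if (units_mode == "natural") design$natural else design$coded
  k <- ncol(X)
  n_terms <- 1 + 2 * k + choose(k, 2)
  if (nrow(X) <= n_terms)
    stop("insufficient data: ", nrow(X), " runs cannot identify ", n_terms,
         " coefficients with a residual degree of freedom")
  B <- quadratic_basis(X)
  # column equilibration: natural-unit bases mix scales (e.g. cellulose^2 up
  # to ~1200 against phosphate interactions < 1), and scaling each column to
  # unit max-abs keeps the QR solve near machine precision
  scl <- apply(abs(B), 2, max)
  dat <- data.frame(y = y, sweep(B, 2, scl, `/`), check.names = FALSE)
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular fit: aliased terms ", paste(aliased, collapse = ", "))
  }
  # summary.lm warns on an exactly interpolating fit; coefficient inference
  # is then meaningless but the coefficients themselves remain valid
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit) / c(1, scl)
  names(cf)[1] <- "b0"
  ct <- sm$coefficients
  ct[, 1:2] <- ct[, 1:2] / c(1, scl)   # estimates and SEs back on raw scale
  rownames(ct)[1] <- "b0"
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_res <- fit$df.residual
  df_mod <- n_terms - 1
  fstat <- if (ss_res <= 1e-12 * max(ss_tot, 1)) Inf else (ss_mod / df_mod) / (ss_res / df_res)
  pval <- if (is.infinite(fstat)) 0 else stats::pf(fstat, df_mod, df_res, lower.tail = FALSE)
  r2 <- if (ss_tot > 0) ss_mod / ss_tot else NA_real_
  list(
    model = quadratic_model(cf, design$factors, units_mode),
    diagnostics = list(
      coefficients = ct, r2 = r2,
      adj_r2 = adjusted_r2(r2, nrow(X), n_terms),
      f = fstat, p = pval,
      ss_model = ss_mod, ss_residual = ss_res, ss_total = ss_tot,
      df_model = df_mod, df_residual = df_res, sigma = sm$sigma))
}

#' Evaluate a quadratic model at a medium composition
#'
#' @param model A `quadratic_model`.
#' @param point Numeric vector of k factor settings in natural units (g/L),
#'   in factor order (names optional).
#' @param extrapolate Allow points outside the factor design bounds. Off by
#'   default: a second-degree surface fitted over a Box-Behnken box has no
#'   validity outside it.
#' @return Predicted response (mm), a single number.
#' @examples
#' m <- reference_models()$PA2DSS
#' predict_response(m, c(5, 0, 3.77, 0.5))  # 27.84 mm
#' @export
predict_response <- function(model, point, extrapolate = FALSE) {
  stopifnot(inherits(model, "quadratic_model"))
  k <- length(model$factors)
  if (length(point) != k) stop("point must have ", k, " values")
  nm <- factor_names(model$factors)
  if (!is.null(names(point))) point <- point[nm]
  if (!extrapolate) {
    lo <- vapply(model$factors, `[[`, numeric(1), "low")
    hi <- vapply(model$factors, `[[`, numeric(1), "high")
    bad <- which(point < lo - 1e-8 | point > hi + 1e-8)
    if (length(bad))
      stop("out of range: factor '", nm[bad[1]], "' = ", point[bad[1]],
           " outside [", lo[bad[1]], ", ", hi[bad[1]],
           "]; the fitted surface does not extrapolate (set extrapolate = TRUE to override)")
  }
  x <- if (model$units_mode == "coded") natural_to_coded(point, model$factors) else point
  drop(c(1, quadratic_basis(matrix(x, nrow = 1))) %*% model$coefficients)
}

# vectorised prediction over the rows of a natural-unit matrix
predict_response_matrix <- function(model, X) {
  x <- if (model$units_mode == "coded") natural_to_coded(X, model$factors) else X
  drop(cbind(1, quadratic_basis(x)) %*% model$coefficients)
}

#' Model ANOVA for a fitted response surface
#'
#' Corrected-total partition `SS_model + SS_residual = SS_total` with the
#' model F ratio and its p-value from the upper F tail.
#'
#' @param model A `quadratic_model` (typically from [fit_quadratic()]).
#' @param design,response The design and response column the model was
#'   fitted to.
#' @return An `anova_table` with rows model / residual / total, plus an
#'   `r2` attribute.
#' @export
model_anova <- function(model, design, response) {
  stopifnot(inherits(design, "bbd_design"))
  y <- design$responses[[response]]
  if (is.null(y)) stop("response '", response, "' not found in design")
  fitted <- predict_response_matrix(model, design$natural)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  ss_mod <- ss_tot - ss_res
  k <- length(model$factors)
  df_mod <- 2 * k + choose(k, 2)
  df_res <- length(y) - df_mod - 1
  fval <- if (ss_res <= 1e-12 * max(ss_tot, 1)) Inf else (ss_mod / df_mod) / (ss_res / df_res)
  pval <- if (is.infinite(fval)) 0 else stats::pf(fval, df_mod, df_res, lower.tail = FALSE)
  out <- data.frame(
    source = c("model", "residual", "total"),
    SS = c(ss_mod, ss_res, ss_tot),
    DF = c(df_mod, df_res, df_mod + df_res),
    MS = c(ss_mod / df_mod, ss_res / df_res, NA_real_),
    F = c(fval, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_))
  class(out) <- c("anova_table", "data.frame")
  attr(out, "r2") <- if (ss_tot > 0) ss_mod / ss_tot else NA_real_
  out
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - p)` with `p` the number of model terms
#' including the intercept; penalizes R-squared for model size and is the
#' yardstick used to choose between competing model families.
#'
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param n_runs Number of observations.
#' @param n_terms Number of fitted coefficients including the intercept.
#' @return Adjusted R-squared.
#' @examples
#' adjusted_r2(0.96, 27, 15)  # 0.91
#' @export
adjusted_r2 <- function(r2, n_runs, n_terms) {
  if (n_runs <= n_terms) stop("adjusted R2 undefined: n_runs <= n_terms")
  1 - (1 - r2) * (n_runs - 1) / (n_runs - n_terms)
}

#' Evaluate a response surface over a two-factor grid
#'
#' Varies two factors over their natural design ranges while holding the
#' remaining factors fixed (default: the design center), mirroring the usual
#' 3D response-surface plots.
#'
#' @param model A `quadratic_model`.
#' @param vary Character vector of two distinct factor names.
#' @param fixed Optional named vector of settings for the other factors.
#' @param n Grid resolution per axis.
#' @return Tidy data frame: one row per grid node with the two varied factor
#'   columns and `predicted` (mm).
#' @export
surface_slice <- function(model, vary, fixed = NULL, n = 25) {
  nm <- factor_names(model$factors)
  if (length(vary) != 2 || anyDuplicated(vary)) stop("'vary' must be two distinct factor names")
  unknown <- setdiff(vary, nm)
  if (length(unknown)) stop("unknown factor name: ", paste(unknown, collapse = ", "))
  point <- vapply(model$factors, `[[`, numeric(1), "center")
  names(point) <- nm
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), nm)
    if (length(unknown)) stop("unknown factor name: ", paste(unknown, collapse = ", "))
    point[names(fixed)] <- fixed
  }
  fs <- model$factors[match(vary, nm)]
  g1 <- seq(fs[[1]]$low, fs[[1]]$high, length.out = n)
  g2 <- seq(fs[[2]]$low, fs[[2]]$high, length.out = n)
  grid <- expand.grid(g1, g2)
  names(grid) <- vary
  X <- matrix(rep(point, each = nrow(grid)), nrow = nrow(grid), dimnames = list(NULL, nm))
  X[, vary[1]] <- grid[[1]]
  X[, vary[2]] <- grid[[2]]
  grid$predicted <- predict_response_matrix(model, X)
  grid
}

#' Rank competing models by adjusted R-squared
#'
#' @param entries Named numeric vector of adjusted R-squared values, one per
#'   model (e.g. `c(RSM = 0.91, ANN = 0.83)`).
#' @return Data frame sorted by descending adjusted R-squared with a
#'   `selected` flag on the maximum (all tied maxima flagged, input order
#'   preserved among ties).
#' @export
compare_models <- function(entries) {
  if (length(entries) < 1) stop("invalid argument: no models to compare")
  if (is.null(names(entries))) stop("'entries' must be named")
  ord <- order(-entries)  # stable: ties keep input order
  out <- data.frame(model = names(entries)[ord], adj_r2 = unname(entries[ord]))
  out$selected <- out$adj_r2 >= max(out$adj_r2) - 1e-12
  out
}
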