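#' Simulate responses of a designed experiment from known quadratic surfaces
#'
#' Evaluates each true model at every design run and adds i.i.d. Gaussian
#' replicate noise, producing a complete synthetic experiment table. With
#' `noise_sd = 0` the responses equal the surface values exactly. The
#' default truth is the pair of published reference models, and the default
#' noise (0.5 mm) yields model fits with R-squared near 0.95-0.96 on the
#' 27-run design, matching the precision the real experiment achieved.
#'
#' @param design A `bbd_design`.
#' @param models Named list of `quadratic_model`s acting as ground truth;
#'   one response column per model is produced.
#' @param noise_sd Replicate noise standard deviation in mm (>= 0).
#' @param seed Seed for the noise draws (required when `noise_sd > 0`).
#' @return The design with the simulated `responses` filled in.
#' @examples
#' d <- bbd_design(default_medium_factors(), 3, seed = 1)
#' d <- simulate_bbd_responses(d, noise_sd = 0)
#' d$responses$SA2BSS[1:3]
#' @export
simulate_bbd_responses <- function(design, models = reference_models(),
                                   noise_sd = 0.5, seed = NULL) {
  stopifnot(inherits(design, "bbd_design"), noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required when noise_sd > 0")
  for (m in models) {
    if (!identical(factor_names(m$factors), factor_names(design$factors)))
      stop("model factors do not match design factors")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design$natural)
  for (nm in names(models)) {
    mu <- predict_response_matrix(models[[nm]], design$natural)
    design$responses[[nm]] <- mu + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  }
  design
}

#' Build screening replicate groups with exact means and error sum of squares
#'
#' Constructs a long-format screening dataset whose group means equal
#' `means` exactly and whose total within-group sum of squares equals
#' `within_ss_total` exactly: each group receives `n_per_group` replicates
#' alternating `mean + d` and `mean - d` with
#' `d = sqrt(within_ss_total / (n_groups * n_per_group))`, so every group
#' carries an equal share of the error SS. This reconstructs a screening
#' experiment from its published summary statistics (group means plus the
#' ANOVA error SS) when the raw replicates are unavailable.
#'
#' @param means Named vector of group means (mm).
#' @param within_ss_total Total within-group (error) sum of squares (mm^2).
#' @param n_per_group Replicates per group; must be even so the +/- d pairs
#'   preserve the mean.
#' @return Data frame with columns `source`, `zone_mm`.
#' @examples
#' g <- make_screening_groups(c(a = 20, b = 25), within_ss_total = 8, n_per_group = 4)
#' tapply(g$zone_mm, g$source, mean)
#' @export
make_screening_groups <- function(means, within_ss_total, n_per_group) {
  if (is.null(names(means))) stop("'means' must be named")
  if (within_ss_total < 0) stop("within_ss_total must be >= 0")
  if (n_per_group %% 2 != 0)
    stop("unsupported: n_per_group must be even (replicates are mean +/- d pairs)")
  d <- sqrt(within_ss_total / (length(means) * n_per_group))
  data.frame(
    source = rep(names(means), each = n_per_group),
    zone_mm = as.vector(vapply(means, function(m)
      m + rep(c(d, -d), n_per_group / 2), numeric(n_per_group))))
}

#' Published screening summaries of the cultivation study
#'
#' Group mean inhibition-zone diameters, error mean square and error degrees
#' of freedom from the carbon-source and nitrogen-source screening rounds of
#' the Bacillus biocontrol study (six replicates per source). Together with
#' [make_screening_groups()] these reconstruct datasets whose one-way ANOVA
#' reproduces the published screening statistics exactly.
#'
#' @param which `"carbon"` or `"nitrogen"`.
#' @return List with `means` (named, mm), `ms_error`, `df_error`,
#'   `ss_error`, `n_per_group`.
#' @export
reference_screening <- function(which = c("carbon", "nitrogen")) {
  which <- match.arg(which)
  if (which == "carbon") {
    list(means = c(starch = 22.33333, lactose = 23.83333, glucose = 23.83333,
                   maltose = 24.16667, glycerol = 24.33333, fructose = 26.16667,
                   cellulose = 26.33333),
         ms_error = 1.24, df_error = 35, ss_error = 43.33333, n_per_group = 6)
  } else {
    list(means = c(peptone = 25.00000, yeast_extract = 25.00000,
                   tryptone = 28.16667, l_glutamic_acid = 30.33333,
                   urea = 31.50000),
         ms_error = 2.87, df_error = 25, ss_error = 71.66667, n_per_group = 6)
  }
}
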