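#' Define a desirability goal
#'
#' Derringer-Suich goal for one factor or response: `minimize` and
#' `maximize` are one-sided ramps raised to the `weight` exponent,
#' `in_range` is an indicator (1 inside `[low, high]`, 0 outside), and
#' `target` is a two-sided ramp peaking at `target`.
#'
#' @param variable Name of a factor or of a response model.
#' @param kind One of `"minimize"`, `"maximize"`, `"in_range"`, `"target"`.
#' @param low,high Bounds of the ramp (for responses these are typically the
#'   observed response range). May be left `NULL` for response goals and
#'   resolved later from data by [optimize_medium()].
#' @param weight Ramp exponent in `[1, 5]` (default 3); larger weights
#'   demand values closer to the ideal end before awarding desirability.
#' @param target Target value (only for `kind = "target"`).
#' @return List of class `desirability_goal`.
#' @export
desirability_goal <- function(variable, kind = c("minimize", "maximize", "in_range", "target"),
                              low = NULL, high = NULL, weight = 3, target = NULL) {
  kind <- match.arg(kind)
  if (!is.null(low) && !is.null(high) && low >= high)
    stop("invalid argument: goal '", variable, "' needs low < high")
  if (weight < 1 || weight > 5) stop("invalid argument: weight must be in [1, 5]")
  if (kind == "target" && is.null(target)) stop("a target goal needs a target value")
  structure(list(variable = variable, kind = kind, low = low, high = high,
                 weight = weight, target = target),
            class = "desirability_goal")
}

#' Score one value against a desirability goal
#'
#' @param goal A [desirability_goal()] with resolved bounds.
#' @param value Finite numeric value of the goal's variable.
#' @return Desirability `d` in `[0, 1]`.
#' @examples
#' g <- desirability_goal("SA2BSS", "maximize", low = 10, high = 40, weight = 3)
#' desirability_score(g, 30.66)  # ((30.66-10)/30)^3
#' @export
desirability_score <- function(goal, value) {
  if (!is.finite(value)) stop("invalid argument: value must be finite")
  if (is.null(goal$low) || is.null(goal$high))
    stop("goal '", goal$variable, "' has unresolved bounds")
  lo <- goal$low; hi <- goal$high; w <- goal$weight
  switch(goal$kind,
         minimize = min(1, max(0, (hi - value) / (hi - lo)))^w,
         maximize = min(1, max(0, (value - lo) / (hi - lo)))^w,
         in_range = as.numeric(value >= lo & value <= hi),
         target = {
           tg <- goal$target
           if (value <= lo || value >= hi) 0
           else if (value <= tg) ((value - lo) / (tg - lo))^w
           else ((hi - value) / (hi - tg))^w
         })
}

#' Overall desirability
#'
#' Geometric mean of the per-goal desirabilities; any fully undesirable goal
#' (`d = 0`) forces `D = 0`.
#'
#' @param ds Numeric vector of per-goal desirabilities in `[0, 1]`.
#' @return Overall `D` in `[0, 1]`.
#' @export
overall_desirability <- function(ds) {
  if (length(ds) == 0) stop("invalid argument: no desirabilities given")
  if (any(ds < 0 | ds > 1)) stop("desirabilities must lie in [0, 1]")
  if (any(ds == 0)) return(0)
  exp(mean(log(ds)))
}

resolve_goals <- function(goals, models, factors, data = NULL) {
  nm <- factor_names(factors)
  lapply(goals, function(g) {
    if (!is.null(g$low) && !is.null(g$high)) return(g)
    if (g$variable %in% nm) {
      f <- factors[[match(g$variable, nm)]]
      g$low <- f$low; g$high <- f$high
    } else if (g$variable %in% names(models)) {
      if (is.null(data) || !g$variable %in% colnames(data))
        stop("goal '", g$variable, "': no bounds given and no observed data to derive them from")
      g$low <- min(data[, g$variable]); g$high <- max(data[, g$variable])
    } else stop("goal variable '", g$variable, "' is neither a factor nor a model name")
    g
  })
}

#' The goal set of the cultivation-medium optimization
#'
#' Minimize the costly carbon and organic nitrogen sources (cellulose,
#' urea), keep the two mineral salts anywhere in their design range, and
#' maximize both predicted inhibition-zone responses — all with weight 3.
#' Factor-goal bounds default to the design ranges; response bounds are left
#' unresolved and are derived from observed data at optimization time.
#'
#' @param response_names Names of the response models (default the two
#'   reference isolates).
#' @return List of `desirability_goal` objects.
#' @export
default_goals <- function(response_names = c("SA2BSS", "PA2DSS")) {
  c(list(desirability_goal("cellulose", "minimize"),
         desirability_goal("urea", "minimize"),
         desirability_goal("ammonium_sulfate", "in_range"),
         desirability_goal("dipotassium_phosphate", "in_range")),
    lapply(response_names, function(r) desirability_goal(r, "maximize")))
}

#' Optimize medium composition by overall desirability
#'
#' Maximizes the geometric-mean desirability of all goals over the factor
#' box using a seeded multi-start bounded simplex search (Nelder-Mead with
#' out-of-box penalty and final clamping). Starts include every box corner,
#' the center, and seeded uniform points. Factor goals are evaluated on the
#' candidate point, response goals on the quadratic-model predictions there.
#' Ties in `D` are broken toward lower total nutrient mass.
#'
#' @param models Named list of `quadratic_model` objects (one per response).
#' @param goals List of [desirability_goal()]s; see [default_goals()].
#' @param factors Factor specs bounding the search (default: factors of the
#'   first model).
#' @param data Optional matrix/data frame with observed response columns,
#'   used to resolve response-goal bounds that were left `NULL`.
#' @param seed Seed for the random starts.
#' @param n_starts Total number of starts (default 64, including the
#'   corners and center).
#' @return Object of class `optimization_result`: `point` (named g/L
#'   vector), `predicted` (named mm vector), `desirabilities` (per goal),
#'   `D`, and a `trace` summary of the multi-start search.
#' @export
optimize_medium <- function(models, goals, factors = NULL, data = NULL, seed,
                            n_starts = 64) {
  if (missing(seed)) stop("a seed is required for the multi-start search")
  stopifnot(is.list(models), length(models) >= 1, !is.null(names(models)))
  if (is.null(factors)) factors <- models[[1]]$factors
  nm <- check_factors(factors)
  goals <- resolve_goals(goals, models, factors, data)
  lo <- vapply(factors, `[[`, numeric(1), "low")
  hi <- vapply(factors, `[[`, numeric(1), "high")
  k <- length(factors)

  eval_point <- function(p) {
    preds <- vapply(models, predict_response, numeric(1), point = p, extrapolate = TRUE)
    ds <- vapply(goals, function(g) {
      v <- if (g$variable %in% nm) p[match(g$variable, nm)] else preds[g$variable]
      desirability_score(g, v)
    }, numeric(1))
    names(ds) <- vapply(goals, `[[`, character(1), "variable")
    list(preds = preds, ds = ds, D = overall_desirability(ds))
  }
  objective <- function(p) {
    viol <- sum(pmax(0, lo - p)) + sum(pmax(0, p - hi))
    -eval_point(pmin(hi, pmax(lo, p)))$D + viol
  }

  corners <- as.matrix(expand.grid(lapply(seq_len(k), function(j) c(lo[j], hi[j]))))
  set.seed(seed)
  n_rand <- max(0, n_starts - nrow(corners) - 1)
  starts <- rbind(corners, (lo + hi) / 2,
                  if (n_rand > 0)
                    matrix(stats::runif(n_rand * k, rep(lo, each = n_rand),
                                        rep(hi, each = n_rand)), ncol = k))
  best_p <- NULL; best_D <- -Inf; n_improved <- 0L
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    p <- pmin(hi, pmax(lo, o$par))
    D <- eval_point(p)$D
    better <- D > best_D + 1e-9 ||
      (abs(D - best_D) <= 1e-9 && !is.null(best_p) && sum(p) < sum(best_p) - 1e-9)
    if (better) { best_p <- p; best_D <- D; n_improved <- n_improved + 1L }
  }
  names(best_p) <- nm
  ev <- eval_point(best_p)
  if (best_D == 0)
    warning("overall desirability is 0 everywhere searched; returning the least-bad point")
  structure(list(point = best_p, predicted = ev$preds,
                 desirabilities = ev$ds, D = ev$D,
                 goals = goals,
                 trace = list(n_starts = nrow(starts), n_improved = n_improved,
                              seed = seed)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("desirability optimum (D =", round(x$D, 4), ")\n")
  cat("  composition (g/L):", paste(sprintf("%s=%.2f", names(x$point), x$point),
                                    collapse = ", "), "\n")
  cat("  predicted responses (mm):",
      paste(sprintf("%s=%.2f", names(x$predicted), x$predicted), collapse = ", "), "\n")
  invisible(x)
}
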