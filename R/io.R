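#' Read and validate a CSV table
#'
#' Thin wrapper over [utils::read.csv()] that checks required columns exist
#' and that they parse as numbers, reporting the offending row and column.
#'
#' @param path CSV file with a header row (decimal point, comma separator).
#' @param required Character vector of column names that must be present.
#' @param numeric_cols Columns that must be fully numeric (default: all
#'   required columns).
#' @return The validated data frame.
#' @export
load_table <- function(path, required = character(), numeric_cols = required) {
  if (!file.exists(path)) stop("validation error: file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("validation error: missing column(s): ", paste(missing_cols, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("validation error: non-numeric value in column '", cl, "', row ", bad[1],
           " ('", df[[cl]][bad[1]], "')")
    if (anyNA(v))
      stop("validation error: missing value in column '", cl, "', row ",
           which(is.na(v))[1])
    df[[cl]] <- v
  }
  df
}

#' Write / read a quadratic model as JSON
#'
#' The file records factor names and bounds, the units mode, and the named
#' coefficient set, so a model round-trips exactly.
#'
#' @param model A `quadratic_model`.
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the `quadratic_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  obj <- list(
    units_mode = model$units_mode,
    factors = lapply(model$factors, function(f) f[c("name", "low", "high")]),
    coefficients = as.list(model$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  factors <- lapply(seq_len(nrow(obj$factors)), function(i)
    factor_spec(obj$factors$name[i], obj$factors$low[i], obj$factors$high[i]))
  quadratic_model(unlist(obj$coefficients), factors, obj$units_mode)
}

#' Run the full medium-optimization workflow
#'
#' Composes the package end to end: (optional) screening statistics, a
#' response-surface fit per response, (optional) the autoencoder/MLP branch
#' with validation on the original runs, model comparison by adjusted
#' R-squared, and desirability optimization over the fitted quadratic
#' models. Every seed is taken from `config` so a report re-runs to
#' identical numbers.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{design}{a `bbd_design` with response columns (e.g. from
#'       [simulate_bbd_responses()]); required.}
#'     \item{responses}{response column names to model (default: all).}
#'     \item{screening}{optional named list of screening data frames
#'       (`source`, `zone_mm`).}
#'     \item{goals}{desirability goals (default [default_goals()] over the
#'       modelled responses).}
#'     \item{ann}{`FALSE` to skip the neural branch, or a list with
#'       `normalization` (spec), `autoencoder_config`, `predictor_config`
#'       and `n_augment`.}
#'     \item{seed}{master seed; required.}
#'   }
#' @param out Optional path; when given, the report is written there as JSON.
#' @return Report list: `screening`, `rsm` (per-response coefficients and
#'   diagnostics), `ann` (per-response validation metrics), `comparison`,
#'   `optimum`, and a `provenance` block with the seeds and package version.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.null(config$design)) stop("stage config: a design with responses is required")
  if (is.null(config$seed)) stop("stage config: an explicit seed is required")
  design <- config$design
  responses <- config$responses %||% names(design$responses)
  report <- list()

  if (!is.null(config$screening)) {
    report$screening <- lapply(config$screening, function(dat) {
      a <- one_way_anova(dat)
      gm <- tapply(dat$zone_mm, dat$source, mean)
      n <- unique(table(dat$source))
      dunc <- if (length(n) == 1)
        duncan_mrt(gm[order(names(gm))], n, a$MS[2], a$DF[2]) else NULL
      list(anova = as.data.frame(a), duncan = dunc)
    })
  }

  fits <- lapply(responses, function(r) fit_quadratic(design, r, "natural"))
  names(fits) <- responses
  report$rsm <- lapply(fits, function(f)
    list(coefficients = as.list(round(f$model$coefficients, 5)),
         r2 = f$diagnostics$r2, adj_r2 = f$diagnostics$adj_r2,
         f = f$diagnostics$f, p = f$diagnostics$p))

  adj <- vapply(fits, function(f) f$diagnostics$adj_r2, numeric(1))
  names(adj) <- paste0("RSM_", responses)

  ann_on <- !isFALSE(config$ann)
  if (ann_on) {
    ann_cfg <- if (is.list(config$ann)) config$ann else list()
    spec <- ann_cfg$normalization %||% default_normalization()
    n_aug <- ann_cfg$n_augment %||% 10000
    fac_nm <- factor_names(design$factors)
    ann_res <- list()
    for (r in responses) {
      cols <- cbind(design$natural, matrix(design$responses[[r]], ncol = 1,
                                           dimnames = list(NULL, r)))
      norm <- rescale(cols, spec, "to_unit")
      ae_cfg <- ann_cfg$autoencoder_config %||% autoencoder_config(seed = config$seed)
      ae <- train_autoencoder(norm, ae_cfg)
      aug <- augment(ae, n_samples = n_aug, seed = config$seed + 1)
      pr_cfg <- ann_cfg$predictor_config %||% predictor_config(seed = config$seed + 2)
      pred <- train_predictor(aug[, fac_nm, drop = FALSE], aug[, r], pr_cfg)
      val <- validate_on_original(pred, norm[, fac_nm, drop = FALSE], norm[, r])
      n_orig <- nrow(norm)
      ann_res[[r]] <- list(autoencoder = ae$report, validation = val,
                           adj_r2 = adjusted_r2(val$r2, n_orig, 2))
      adj[paste0("ANN_", r)] <- ann_res[[r]]$adj_r2
    }
    report$ann <- ann_res
  }

  report$comparison <- compare_models(adj)

  goals <- config$goals %||% default_goals(responses)
  models <- lapply(fits, `[[`, "model")
  opt <- optimize_medium(models, goals, factors = design$factors,
                         data = as.matrix(design$responses[, responses, drop = FALSE]),
                         seed = config$seed)
  report$optimum <- list(point = as.list(round(opt$point, 4)),
                         predicted = as.list(round(opt$predicted, 4)),
                         D = opt$D)
  report$provenance <- list(seed = config$seed,
                            package = "medopt",
                            version = as.character(utils::packageVersion("medopt")))
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
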