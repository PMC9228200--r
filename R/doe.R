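#' Define a design factor
#'
#' A factor is a medium component varied over a concentration range. The
#' three levels of a Box-Behnken design are the low bound, the midpoint and
#' the high bound, coded -1/0/+1.
#'
#' @param name Factor name (single string), e.g. `"cellulose"`.
#' @param low,high Concentration bounds in g/L, `low < high`.
#' @return An object of class `factor_spec` with fields `name`, `low`,
#'   `high` and the derived `center` and `half_range`.
#' @examples
#' factor_spec("cellulose", 5, 35)
#' @export
factor_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L, length(high) == 1L)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("factor '", name, "': need finite low < high (got ", low, ", ", high, ")")
  structure(
    list(name = name, low = low, high = high,
         center = (low + high) / 2, half_range = (high - low) / 2),
    class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("factor %s: %g to %g g/L (center %g)\n", x$name, x$low, x$high, x$center))
  invisible(x)
}

#' The four medium factors of the cultivation study
#'
#' Cellulose (carbon source, 5-35 g/L), urea (organic nitrogen, 0-5 g/L),
#' ammonium sulfate (inorganic nitrogen, 0-5 g/L) and dipotassium phosphate
#' (phosphorus source, 0.5-4.5 g/L) — the factor ranges of the Bacillus
#' biocontrol cultivation experiment this package models.
#'
#' @return A list of four `factor_spec` objects.
#' @export
default_medium_factors <- function() {
  list(factor_spec("cellulose", 5, 35),
       factor_spec("urea", 0, 5),
       factor_spec("ammonium_sulfate", 0, 5),
       factor_spec("dipotassium_phosphate", 0.5, 4.5))
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")

check_factors <- function(factors) {
  if (!is.list(factors) || !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("'factors' must be a list of factor_spec objects")
  nm <- factor_names(factors)
  if (anyDuplicated(nm)) stop("duplicate factor names: ", paste(nm[duplicated(nm)], collapse = ", "))
  invisible(nm)
}

#' Generate a three-level Box-Behnken design
#'
#' For k factors the design consists of the 4*choose(k,2) edge-midpoint runs
#' (for each factor pair, the four (+/-1, +/-1) combinations with all other
#' factors at their center) plus `center_replicates` all-center runs. The
#' canonical pre-permutation ordering is factor pairs in lexicographic index
#' order with within-pair order (-1,-1), (+1,-1), (-1,+1), (+1,+1), and the
#' center runs last; `run_order` is a seeded random permutation of that list.
#'
#' @param factors List of at least three `factor_spec` objects.
#' @param center_replicates Number of center-point runs (>= 1; replication at
#'   the center estimates pure experimental error).
#' @param seed Integer seed for the run-order permutation (required; designs
#'   are always reproducible).
#' @return An object of class `bbd_design`: a list with `factors`, the
#'   `coded` run matrix (entries -1/0/+1, canonical order), the `natural`
#'   matrix (g/L), `run_order` (the randomized execution order as a
#'   permutation of row indices) and a `responses` data frame (initially
#'   empty) for measured or simulated response columns.
#' @examples
#' d <- bbd_design(default_medium_factors(), center_replicates = 3, seed = 1)
#' nrow(d$coded)  # 27 runs
#' @export
bbd_design <- function(factors, center_replicates = 3, seed) {
  nm <- check_factors(factors)
  k <- length(factors)
  if (k < 3) stop("unsupported design: Box-Behnken requires at least 3 factors (got ", k, ")")
  if (!is.numeric(center_replicates) || length(center_replicates) != 1L ||
      center_replicates < 1 || center_replicates != round(center_replicates))
    stop("invalid argument: center_replicates must be an integer >= 1")
  if (missing(seed)) stop("a seed is required: unseeded design generation is not supported")

  pairs <- utils::combn(k, 2)
  block <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  coded <- matrix(0, nrow = 4 * ncol(pairs) + center_replicates, ncol = k,
                  dimnames = list(NULL, nm))
  row <- 1L
  for (j in seq_len(ncol(pairs))) {
    for (b in seq_len(4L)) {
      coded[row, pairs[, j]] <- block[b, ]
      row <- row + 1L
    }
  }
  run_order <- local({ set.seed(seed); sample.int(nrow(coded)) })
  des <- structure(
    list(factors = factors, coded = coded,
         natural = coded_to_natural(coded, factors),
         run_order = run_order,
         responses = data.frame(row.names = seq_len(nrow(coded)))),
    class = "bbd_design")
  des
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d factors, %d runs (%d center)\n",
              ncol(x$coded), nrow(x$coded), sum(rowSums(x$coded != 0) == 0)))
  cat("factors:", paste(factor_names(x$factors), collapse = ", "), "\n")
  if (ncol(x$responses)) cat("responses:", paste(names(x$responses), collapse = ", "), "\n")
  invisible(x)
}

#' Convert factor settings between coded and natural units
#'
#' The level mapping is the affine map `natural = center + coded * (high - low)/2`
#' applied per factor; the two representations are bijective and converting
#' back and forth is the identity.
#'
#' @param x Numeric matrix (runs x factors) or vector of length k.
#' @param factors List of `factor_spec` objects, in column order.
#' @return Matrix (or vector) in the other representation.
#' @seealso [map_units()] for the checked, direction-explicit interface.
#' @export
coded_to_natural <- function(x, factors) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  hr <- vapply(factors, `[[`, numeric(1), "half_range")
  out <- sweep(sweep(x, 2, hr, `*`), 2, ctr, `+`)
  colnames(out) <- factor_names(factors)
  if (vec) out[1, ] else out
}

#' @rdname coded_to_natural
#' @export
natural_to_coded <- function(x, factors) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  hr <- vapply(factors, `[[`, numeric(1), "half_range")
  out <- sweep(sweep(x, 2, ctr, `-`), 2, hr, `/`)
  colnames(out) <- factor_names(factors)
  if (vec) out[1, ] else out
}

#' Map a run matrix between unit systems with range checking
#'
#' @param x Runs x factors matrix (or length-k vector).
#' @param factors List of `factor_spec` objects in column order.
#' @param direction `"coded_to_natural"` or `"natural_to_coded"`.
#' @param tol Numerical slack allowed beyond the exact bounds.
#' @return The mapped matrix or vector.
#' @export
map_units <- function(x, factors, direction = c("coded_to_natural", "natural_to_coded"),
                      tol = 1e-8) {
  direction <- match.arg(direction)
  nm <- check_factors(factors)
  m <- if (is.null(dim(x))) matrix(x, nrow = 1, dimnames = list(NULL, nm)) else x
  if (ncol(m) != length(factors)) stop("x has ", ncol(m), " columns but ", length(factors), " factors given")
  lo <- if (direction == "coded_to_natural") rep(-1, length(factors)) else vapply(factors, `[[`, numeric(1), "low")
  hi <- if (direction == "coded_to_natural") rep(1, length(factors)) else vapply(factors, `[[`, numeric(1), "high")
  for (j in seq_along(factors)) {
    bad <- which(m[, j] < lo[j] - tol | m[, j] > hi[j] + tol)
    if (length(bad))
      stop("out of range: factor '", nm[j], "', run ", bad[1], " has value ", m[bad[1], j],
           " outside [", lo[j], ", ", hi[j], "]")
  }
  if (direction == "coded_to_natural") coded_to_natural(x, factors) else natural_to_coded(x, factors)
}

#' Write / read a design as CSV
#'
#' The file has a `run` column (canonical row index), one column per factor
#' in natural units (g/L), and any response columns (mm).
#'
#' @param design A `bbd_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `bbd_design` (responses included when present).
#' @export
write_design_csv <- function(design, path) {
  df <- data.frame(run = seq_len(nrow(design$natural)), design$natural, check.names = FALSE)
  if (ncol(design$responses)) df <- cbind(df, design$responses)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param factors Factor specs naming the columns expected in the file.
#' @export
read_design_csv <- function(path, factors) {
  nm <- check_factors(factors)
  df <- load_table(path, required = c("run", nm))
  nat <- as.matrix(df[, nm, drop = FALSE])
  extra <- setdiff(names(df), c("run", nm))
  structure(
    list(factors = factors,
         coded = natural_to_coded(nat, factors),
         natural = nat,
         run_order = seq_len(nrow(nat)),
         responses = df[, extra, drop = FALSE]),
    class = "bbd_design")
}
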