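#' One-way ANOVA for source-screening experiments
#'
#' Partitions the variation of inhibition-zone diameters measured under
#' several candidate carbon or nitrogen sources into a between-group and a
#' within-group (error) component, using the standard fixed-effects one-way
#' analysis of variance. The fit itself is delegated to [stats::lm()]; this
#' wrapper validates the screening data, assembles the source/SS/DF/MS/F/p
#' table and handles the degenerate zero-error case explicitly.
#'
#' @param data Data frame with columns `source` (group label) and `zone_mm`
#'   (replicate inhibition-zone diameter, mm). At least two groups with at
#'   least two replicates each.
#' @param effect_label Row label for the between-group effect.
#' @return An object of class `anova_table`: a data frame with rows for the
#'   effect, the error and the corrected total, and columns
#'   `source`, `SS`, `DF`, `MS`, `F`, `p`.
#' @examples
#' d <- make_screening_groups(c(a = 20, b = 24), within_ss_total = 4, n_per_group = 4)
#' one_way_anova(d)
#' @export
one_way_anova <- function(data, effect_label = "source") {
  stopifnot(is.data.frame(data), all(c("source", "zone_mm") %in% names(data)))
  y <- data$zone_mm
  g <- factor(data$source)
  if (!all(is.finite(y)) || any(y <= 0)) stop("zone_mm values must be finite and positive")
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2))
    stop("degrees-of-freedom error: group(s) with fewer than 2 replicates: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  # suppressed warning: anova() flags F-tests on zero-residual fits, a case
  # handled explicitly below
  a <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ss_b <- a$`Sum Sq`[1]; df_b <- a$Df[1]
  ss_w <- a$`Sum Sq`[2]; df_w <- a$Df[2]
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  if (ms_w <= .Machine$double.eps * max(1, ms_b)) {
    # no replicate scatter: equal means give F = 0, unequal means F = +Inf
    fval <- if (ss_b <= 1e-12 * max(1, sum(y^2))) 0 else Inf
    pval <- if (is.infinite(fval)) 0 else 1
  } else {
    fval <- ms_b / ms_w
    pval <- stats::pf(fval, df_b, df_w, lower.tail = FALSE)
  }
  out <- data.frame(
    source = c(effect_label, "error", "total"),
    SS = c(ss_b, ss_w, ss_b + ss_w),
    DF = c(df_b, df_w, df_b + df_w),
    MS = c(ms_b, ms_w, NA_real_),
    F = c(fval, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- x
  y$p <- ifelse(is.na(y$p), NA, sprintf("%.6f", y$p))  # match 6-dp reporting style
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

# Duncan's protected significance level for a stretch of p ordered means.
duncan_alpha <- function(alpha, p) 1 - (1 - alpha)^(p - 1)

# Least significant range for a stretch of p means: studentized-range
# quantile at Duncan's protection level, scaled by the standard error of a
# group mean. qtukey() evaluates the range CDF numerically, so arbitrary
# error degrees of freedom are supported without recourse to printed tables.
duncan_lsr <- function(p, df_error, ms_error, n, alpha) {
  stats::qtukey(1 - duncan_alpha(alpha, p), nmeans = p, df = df_error) *
    sqrt(ms_error / n)
}

#' Duncan's multiple range test
#'
#' Post-ANOVA step-down multiple comparison of group means. A stretch of
#' `p` consecutive ordered means is declared homogeneous when its range does
#' not exceed the least significant range
#' `R_p = q(1 - alpha_p, p, df) * sqrt(MS_error / n)` with protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)`; inner stretches are only tested
#' inside stretches already declared significant (the classical step-down
#' rule, so a non-significant span is never contradicted by an inner pair).
#' Maximal homogeneous stretches receive letters, `"a"` starting at the
#' stretch containing the smallest mean; groups sharing any letter are not
#' significantly different.
#'
#' @param means Named numeric vector of group means (mm).
#' @param n_per_group Common number of replicates per group (balanced data).
#' @param ms_error Error mean square from the one-way ANOVA (mm^2), > 0.
#' @param df_error Error degrees of freedom.
#' @param alpha Nominal significance level (default 0.05).
#' @return An object of class `duncan_grouping`: data frame with columns
#'   `group`, `mean`, `letters`, sorted by ascending mean.
#' @examples
#' m <- c(A = 20, B = 20.4, C = 26)
#' duncan_mrt(m, n_per_group = 6, ms_error = 1.2, df_error = 15)
#' @export
duncan_mrt <- function(means, n_per_group, ms_error, df_error, alpha = 0.05) {
  if (is.null(names(means)) || anyDuplicated(names(means)))
    stop("'means' must be a uniquely named vector")
  if (length(n_per_group) != 1L)
    stop("unsupported: unbalanced groups are not implemented; supply a single ",
         "common n (harmonic-mean n is a possible extension)")
  stopifnot(ms_error > 0, df_error >= 1, alpha > 0, alpha < 1)
  k <- length(means)
  ord <- order(means)           # ascending
  m <- means[ord]

  lsr <- vapply(seq_len(max(k, 2)), function(p)
    if (p < 2) 0 else duncan_lsr(p, df_error, ms_error, n_per_group, alpha), numeric(1))

  # Top-down recursion over stretches [i, j] of the sorted means: a stretch
  # whose range is within R_p is homogeneous and is not subdivided.
  homog <- matrix(FALSE, k, k)
  visit <- function(i, j) {
    if (i > j) return(invisible())
    if (homog[i, j]) return(invisible())
    p <- j - i + 1L
    if (p == 1L || (m[j] - m[i]) <= lsr[p] + 1e-12) {
      homog[i, j] <<- TRUE
    } else {
      visit(i, j - 1L)
      visit(i + 1L, j)
    }
    invisible()
  }
  visit(1L, k)

  # maximal homogeneous stretches, left to right
  all_segs <- which(homog, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(all_segs)), function(r) {
    i <- all_segs[r, 1]; j <- all_segs[r, 2]
    !any(all_segs[, 1] <= i & all_segs[, 2] >= j &
           (all_segs[, 1] < i | all_segs[, 2] > j))
  }, logical(1))
  segs <- lapply(which(keep), function(r) c(all_segs[r, 1], all_segs[r, 2]))
  segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]

  letter_sets <- rep("", k)
  for (s in seq_along(segs)) {
    idx <- segs[[s]][1]:segs[[s]][2]
    letter_sets[idx] <- paste0(letter_sets[idx], letters[s])
  }
  out <- data.frame(group = names(m), mean = unname(m), letters = letter_sets)
  class(out) <- c("duncan_grouping", "data.frame")
  out
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat("Duncan's multiple range test (groups sharing a letter do not differ)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Pairwise correlation screen of a designed-experiment table
#'
#' Exploratory Pearson correlation matrix over all attributes (factor
#' concentrations and responses) of a design, used to flag strong
#' factor-response dependencies and inconsistent attributes before
#' modelling.
#'
#' @param design A `bbd_design` with at least one response column, or a
#'   plain numeric data frame / matrix of attributes.
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a constant attribute are `NA` (undefined, not zero).
#' @export
correlation_screen <- function(design) {
  tab <- if (inherits(design, "bbd_design")) {
    cbind(design$natural, as.matrix(design$responses))
  } else as.matrix(as.data.frame(design))
  if (nrow(tab) < 3) stop("need at least 3 rows for a correlation screen")
  if (anyNA(tab)) stop("missing values are not allowed")
  cc <- suppressWarnings(stats::cor(tab))
  diag(cc) <- 1
  cc
}
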