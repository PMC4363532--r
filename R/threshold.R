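# Disease-associated coexpression threshold: two-sample KS on inverted
# empirical CDFs, plus chi-square verification of the resulting dichotomy.

#' Inverted empirical CDFs (survival fractions) of coexpression levels
#'
#' For each candidate threshold `t`, computes the fraction of gene pairs
#' whose coexpression level is at or above `t`, per group:
#' `F_d(t) = Prob(C_d >= t)` and `F_n(t) = Prob(C_n >= t)`. The inequality is
#' inverted relative to an ordinary CDF because interest is in strong
#' coexpression; `>=` is inclusive, so `F(0) = 1` and values are multiples of
#' `1/n_pairs`.
#'
#' @param table A [coexpression_table()]. Rows with undefined correlations
#'   are dropped (with a message).
#' @param grid `"observed"` (default): the sorted union of all observed `C_d`
#'   and `C_n` values plus 0 and 1 -- exact, since the fractions only change
#'   at observed values. `"uniform"`: a regular grid from 0 to 1.
#' @param step Grid spacing for `grid = "uniform"` (default 1e-4).
#' @return An object of class `"survival_curve"`: list with `thresholds`,
#'   `F_d`, `F_n`, `n_pairs`.
#' @export
survival_curves <- function(table, grid = c("observed", "uniform"),
                            step = 1e-4) {
  grid <- match.arg(grid)
  ok <- stats::complete.cases(table[c("C_d", "C_n")])
  if (!any(ok)) stop("no gene pairs with defined coexpression levels")
  if (any(!ok))
    message(sum(!ok), " pair(s) with undefined coexpression dropped")
  C_d <- table$C_d[ok]
  C_n <- table$C_n[ok]

  thresholds <- switch(grid,
    observed = sort(unique(c(0, C_d, C_n, 1))),
    uniform  = seq(0, 1, by = step))
  F_d <- vapply(thresholds, function(t) mean(C_d >= t), numeric(1L))
  F_n <- vapply(thresholds, function(t) mean(C_n >= t), numeric(1L))
  structure(list(thresholds = thresholds, F_d = F_d, F_n = F_n,
                 n_pairs = sum(ok)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curves over", length(x$thresholds), "thresholds,",
      x$n_pairs, "gene pairs per group\n")
  invisible(x)
}

#' Threshold maximizing the deviation between the group curves
#'
#' The optimal coexpression threshold `C*` is the grid point at which the
#' absolute deviation `|F_d(t) - F_n(t)|` between the inverted CDFs is
#' maximal (the two-sample Kolmogorov-Smirnov statistic `D`). If several
#' thresholds achieve the maximum, the largest one is reported: it selects
#' the most stringent strong class, and unlike the smallest achieving
#' threshold it cannot collapse into the weak-coexpression noise floor when
#' the deviation plateaus (ties against the plateau are common on
#' near-null data).
#'
#' @param curve A [survival_curves()] result.
#' @return List with `C_star` (the threshold) and `D` (the maximum
#'   deviation, in `[0, 1]`), satisfying
#'   `D == abs(F_n(C_star) - F_d(C_star))` exactly.
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  dev <- abs(curve$F_d - curve$F_n)
  D <- max(dev)
  list(C_star = max(curve$thresholds[dev == D]), D = D)
}

#' Asymptotic two-sample Kolmogorov-Smirnov p-value
#'
#' Evaluates the Kolmogorov tail function
#' `Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) * exp(-2 k^2 lambda^2)` at
#' `lambda = sqrt(n_d * n_n / (n_d + n_n)) * D`, truncating the series once
#' terms fall below 1e-16. Note the caveat documented in the package
#' vignette: when the two "samples" are the per-pair coexpression levels of
#' the same gene panel, they are dependent statistics, so this p-value is an
#' asymptotic reference figure rather than an exact test level.
#'
#' @param D KS deviation in `[0, 1]`.
#' @param n_d,n_n Sizes of the two samples (here: number of gene pairs per
#'   group).
#' @return p-value in `(0, 1]`.
#' @examples
#' ks_pvalue(0.2789, 190, 190) # far below 0.01
#' @export
ks_pvalue <- function(D, n_d, n_n) {
  if (!is.numeric(D) || length(D) != 1L || D < 0 || D > 1)
    stop("`D` must be a single value in [0, 1]")
  if (n_d < 1L || n_n < 1L) stop("sample sizes must be at least 1")
  lambda <- sqrt(n_d * n_n / (n_d + n_n)) * D
  if (lambda == 0) return(1)
  total <- 0
  for (k in seq_len(1000L)) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-16) break
  }
  min(1, max(2 * total, 0))
}

#' Dichotomize gene pairs at a coexpression threshold
#'
#' Per group, pairs with coexpression level at or above `C_star` form the
#' strong class (inclusive `>=`, matching the inverted-CDF definition) and
#' the remainder the weak class.
#'
#' @param table A [coexpression_table()].
#' @param C_star Threshold in `[0, 1]`.
#' @return A 2x2 integer matrix of counts, rows `strong`/`weak`, columns
#'   `disease`/`normal`. Each column sums to the number of pairs with
#'   defined levels.
#' @export
dichotomize <- function(table, C_star) {
  if (!is.numeric(C_star) || length(C_star) != 1L || C_star < 0 || C_star > 1)
    stop("`C_star` must be a single value in [0, 1]")
  ok <- stats::complete.cases(table[c("C_d", "C_n")])
  C_d <- table$C_d[ok]
  C_n <- table$C_n[ok]
  matrix(c(sum(C_d >= C_star), sum(C_d < C_star),
           sum(C_n >= C_star), sum(C_n < C_star)),
         nrow = 2L,
         dimnames = list(class = c("strong", "weak"),
                         group = c("disease", "normal")))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Association between the strong/weak coexpression class and the group,
#' computed without continuity correction (1 degree of freedom).
#'
#' @param table 2x2 matrix of non-negative counts with all row and column
#'   sums positive.
#' @return List with `chi2` (the statistic) and `p` (upper-tail p-value).
#' @examples
#' chi_square(matrix(c(45, 145, 98, 92), 2)) # chi2 = 31.4957
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("`table` must be a 2x2 contingency table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column marginals must be positive")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), p = res$p.value)
}
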