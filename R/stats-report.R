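#' Two-sided Mann-Whitney U test
#'
#' Nonparametric comparison of two independent samples. The exact null
#' distribution is used when both samples have at most 8 observations and
#' there are no ties (`mode = "auto"`); otherwise the normal approximation
#' with tie and continuity corrections is used (with the continuity
#' correction the approximate p agrees with the exact one to within 0.02
#' at n = 8 per group). The reported statistic is `min(U_x, U_y)`.
#'
#' @param x,y numeric samples (nonempty).
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @return A list of class `stat_result`: `test_name`, `statistic` (U),
#'   `p_value`, `n_per_group`, `method_detail`, `degenerate` (TRUE when
#'   all values across both groups are identical, in which case p = 1).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  u_x <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u_y <- length(x) * length(y) - u_x
  u <- min(u_x, u_y)
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(test_name = "Mann-Whitney U",
                          statistic = u, p_value = 1,
                          n_per_group = c(length(x), length(y)),
                          method_detail = "degenerate",
                          degenerate = TRUE),
                     class = "stat_result"))
  }
  exact <- switch(mode,
                  exact = TRUE,
                  approx = FALSE,
                  auto = length(x) <= 8 && length(y) <= 8 && !ties)
  if (exact && ties)
    stop("exact mode requires tie-free data")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(test_name = "Mann-Whitney U",
                 statistic = u, p_value = wt$p.value,
                 n_per_group = c(length(x), length(y)),
                 method_detail = if (exact) "exact"
                                 else "normal-approximation",
                 degenerate = FALSE),
            class = "stat_result")
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction; `df = (r - 1) * (c - 1)`.
#'
#' @param counts nonnegative integer matrix with >= 2 rows and >= 2
#'   columns and no zero row/column margin.
#' @return A `stat_result` with `statistic` (X-squared), `p_value`, and
#'   `method_detail` giving the degrees of freedom.
#' @export
chi_square_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("table needs >= 2 rows and >= 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: every row and column must have a positive total")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(test_name = "Pearson chi-square",
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value,
                 n_per_group = rowSums(counts),
                 method_detail = sprintf("df=%d", unname(ct$parameter)),
                 degenerate = FALSE),
            class = "stat_result")
}

#' Two-proportion chi-square comparison of one event class
#'
#' Compares the prevalence of one release-pattern class between two
#' groups: builds the 2x2 table `[[k_a, n_a - k_a], [k_b, n_b - k_b]]`
#' and applies the uncorrected Pearson chi-square test (df = 1).
#'
#' @param k_a,n_a events of the class and total events in group A.
#' @param k_b,n_b same for group B.
#' @return A `stat_result` (see [chi_square_rxc()]).
#' @export
chi_square_pairwise <- function(k_a, n_a, k_b, n_b) {
  if (k_a < 0 || k_a > n_a || k_b < 0 || k_b > n_b)
    stop("need 0 <= k <= n in both groups")
  chi_square_rxc(rbind(c(k_a, n_a - k_a), c(k_b, n_b - k_b)))
}

#' Reconstruct an integer count from a printed percentage
#'
#' Audit utility for published tables that print class percentages and
#' group sizes: returns `round(percent / 100 * n)` and the consistency
#' residual `|count / n * 100 - percent|` in percentage points; a residual
#' above 0.5 raises a warning (the printed percent and n are mutually
#' inconsistent).
#'
#' @param percent printed percentage in `[0, 100]`.
#' @param n group size (> 0).
#' @return A list with `count` (integer) and `residual_pct`.
#' @export
reconstruct_counts <- function(percent, n) {
  if (percent < 0 || percent > 100) stop("percent must be in [0, 100]")
  if (n <= 0) stop("n must be > 0")
  count <- round(percent / 100 * n)
  residual <- abs(count / n * 100 - percent)
  if (residual > 0.5)
    warning(sprintf("percent %.4g and n %d are inconsistent (residual %.2f pp)",
                    percent, n, residual))
  list(count = as.integer(count), residual_pct = residual)
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s; n = %s)\n",
              x$test_name, x$statistic, x$p_value, x$method_detail,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Summarize a multi-group experiment with planned comparisons
#'
#' For each group: n, mean, SEM, median, and the empirical cumulative
#' distribution. For each planned pair: a two-sided Mann-Whitney U test.
#' Empty groups are excluded with a warning.
#'
#' @param groups named list of numeric vectors (one per condition).
#' @param comparisons list of character pairs naming groups to compare;
#'   default: all pairs.
#' @return A list of class `experiment_report` with `summary` (data.frame:
#'   group, n, mean, sem, median), `ecdfs` (named list of [stats::ecdf()]
#'   functions), and `tests` (data.frame: group_a, group_b, statistic,
#'   p_value, method).
#' @export
summarize_experiment <- function(groups, comparisons = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  empty <- vapply(groups, function(g) length(g) == 0, logical(1))
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(g)
      if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else 0, numeric(1)),
    median = vapply(groups, stats::median, numeric(1)),
    row.names = NULL)
  if (is.null(comparisons) && length(groups) >= 2)
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- lapply(comparisons, function(pr) {
    if (!all(pr %in% names(groups)))
      stop("comparison references unknown group: ",
           paste(pr, collapse = " vs "))
    r <- mann_whitney_u(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(group_a = pr[1], group_b = pr[2], statistic = r$statistic,
               p_value = r$p_value, method = r$method_detail)
  })
  tests <- if (length(tests)) do.call(rbind, tests)
           else data.frame(group_a = character(0), group_b = character(0),
                           statistic = numeric(0), p_value = numeric(0),
                           method = character(0))
  structure(list(summary = summary,
                 ecdfs = lapply(groups, stats::ecdf),
                 tests = tests),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment summary:\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$tests)) {
    cat("Planned comparisons (Mann-Whitney U, two-sided):\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
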