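#' Frame-level classification accuracy
#'
#' Successes over successes plus failures.
#'
#' @param predictions,labels Equal-length vectors (length >= 1).
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) < 1L)
    stop("`predictions` and `labels` must be equal-length and non-empty",
         call. = FALSE)
  mean(predictions == labels)
}

#' Differential classification accuracy
#'
#' The shift-robustness metric: cross-position accuracy minus the same-
#' position BASELINE accuracy under the same normalization,
#' `y = x - x_baseline`. Zero means electrode shift costs nothing; negative
#' values quantify the degradation.
#'
#' @param x Accuracy (fraction) of the evaluated strategy.
#' @param x_baseline Accuracy (fraction) of the same-position baseline.
#' @return The difference, as a fraction (multiply by 100 for points).
#' @export
differential_accuracy <- function(x, x_baseline) {
  stopifnot(all(x >= 0 & x <= 1), all(x_baseline >= 0 & x_baseline <= 1))
  x - x_baseline
}

#' Per-subject mean differential accuracy
#'
#' Averages the differential accuracy over the electrode-position combinations
#' (6 directed pairs for single-position strategies, 3 test positions for
#' pooled ones) within each (normalization, strategy, subject) cell; these
#' per-subject means are the observation units fed to the statistical tests.
#' Baseline rows (train position == test position) are excluded.
#'
#' @param table A tibble with columns `normalization`, `strategy`, `subject`,
#'   `train_pos`, `test_pos`, `y`.
#' @return Tibble with one row per (normalization, strategy, subject) and the
#'   mean difference `mean_y`.
#' @export
aggregate_subject_means <- function(table) {
  stopifnot(all(c("normalization", "strategy", "subject", "train_pos",
                  "test_pos", "y") %in% names(table)))
  table |>
    dplyr::filter(.data$train_pos != .data$test_pos |
                    .data$strategy %in% c("ada", "mix")) |>
    dplyr::group_by(.data$normalization, .data$strategy, .data$subject) |>
    dplyr::summarise(mean_y = mean(.data$y), n_combos = dplyr::n(),
                     .groups = "drop")
}

#' Window-length sweep grid
#'
#' The cells of the window-length sweep: all combinations of normalization
#' window and feature-extraction window, 200--1000 ms in 200 ms steps by
#' default (25 cells with normalization, 5 without when `norm_windows` is
#' empty).
#'
#' @param norm_windows Normalization windows in ms (empty vector for the
#'   no-normalization sweep).
#' @param feature_windows Feature windows in ms.
#' @return Tibble with columns `norm_window` (`NA` for no normalization) and
#'   `feature_window`, one row per cell.
#' @export
sweep_grid <- function(norm_windows = seq(200, 1000, by = 200),
                       feature_windows = seq(200, 1000, by = 200)) {
  if (length(norm_windows) == 0L)
    return(tibble::tibble(norm_window = NA_real_,
                          feature_window = feature_windows))
  tidyr_grid <- expand.grid(norm_window = norm_windows,
                            feature_window = feature_windows)
  tibble::as_tibble(tidyr_grid[order(tidyr_grid$norm_window,
                                     tidyr_grid$feature_window), ])
}

#' Select the best sweep cell
#'
#' Means the accuracy of each (norm window, feature window) cell over its
#' replicates (position combinations and subjects) and returns the argmax
#' cell; ties break toward the smaller feature window, then the smaller
#' normalization window.
#'
#' @param sweep Tibble with columns `norm_window`, `feature_window`,
#'   `accuracy` (one row per replicate per cell).
#' @param grid Optional [sweep_grid()] the sweep must cover; missing cells
#'   raise an error listing them.
#' @return List with `norm_window`, `feature_window`, `mean_accuracy`.
#' @export
select_best <- function(sweep, grid = NULL) {
  stopifnot(all(c("norm_window", "feature_window", "accuracy") %in%
                  names(sweep)))
  cells <- sweep |>
    dplyr::group_by(.data$norm_window, .data$feature_window) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop")
  if (!is.null(grid)) {
    have <- paste(cells$norm_window, cells$feature_window)
    want <- paste(grid$norm_window, grid$feature_window)
    miss <- setdiff(want, have)
    if (length(miss) > 0L)
      stop("sweep grid incomplete; missing cells: ",
           paste(miss, collapse = "; "), call. = FALSE)
  }
  ord <- order(-cells$mean_accuracy, cells$feature_window, cells$norm_window)
  best <- cells[ord[1L], ]
  list(norm_window = best$norm_window, feature_window = best$feature_window,
       mean_accuracy = best$mean_accuracy)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test with mid-ranks for ties: exact
#' p-value by enumeration for small untied samples, otherwise a normal
#' approximation with tie-corrected variance and continuity correction
#' (delegates to [stats::wilcox.test()], which implements exactly this
#' policy).
#'
#' @param a,b Numeric samples (each non-empty).
#' @return List with `rank_sum` (rank sum of `a`), `statistic` (Mann-Whitney
#'   U of `a`), `p_value` (two-sided), and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) < 50 && length(b) < 50
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  u <- unname(wt$statistic)
  list(rank_sum = u + length(a) * (length(a) + 1) / 2, statistic = u,
       p_value = wt$p.value, exact = exact)
}

#' Bonferroni correction
#'
#' `p' = min(1, m * p)`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons (default: `length(p_values)`; must be at
#'   least that).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("`m` must be at least the number of p-values", call. = FALSE)
  pmin(1, m * p_values)
}

#' Scheirer-Ray-Hare two-way rank test
#'
#' Nonparametric two-factor test: all `N` observations are mid-ranked, the
#' two-way ANOVA sums of squares are computed on the ranks, and each effect's
#' statistic is `H = SS_effect / MS_total` with `MS_total = SS_total /
#' (N - 1)` computed from the mid-ranks. Because mid-ranking shrinks
#' `SS_total` by exactly the factor `D = 1 - sum(t^3 - t) / (N^3 - N)` (over
#' tie-group sizes `t`), this `H` equals the untied-rank statistic
#' `12 SS_effect / (N (N + 1))` divided by `D` — the standard tie correction,
#' applied once. With `tie_correct = FALSE` the untied-rank denominator
#' `N (N + 1) / 12` is used instead (no correction). Each `H` is referred to
#' the chi-square distribution with the effect's ANOVA degrees of freedom.
#' The design must be complete and balanced (equal cell counts); with a
#' single-level second factor the factor-A statistic reduces exactly to
#' Kruskal-Wallis (including ties).
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (coerced) of the same length as `values`.
#' @param tie_correct Apply the tie-correction divisor `D` (default `TRUE`).
#' @return Tibble with rows `A`, `B`, `A:B` and columns `effect`, `H`, `df`,
#'   `p_value`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b, tie_correct = TRUE) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  n <- length(values)
  if (length(fa) != n || length(fb) != n)
    stop("`values`, `factor_a`, `factor_b` must have equal length", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  tab <- table(fa, fb)
  if (any(tab == 0L))
    stop("missing cells: the design must be complete", call. = FALSE)
  if (length(unique(as.vector(tab))) != 1L)
    stop("unbalanced designs are rejected (unequal cell counts)", call. = FALSE)
  if (nlevels(fa) < 2L)
    stop("`factor_a` needs at least 2 levels", call. = FALSE)
  r <- rank(values)  # mid-ranks
  grand <- mean(r)
  ss <- function(groups) {
    means <- tapply(r, groups, mean)
    sizes <- tapply(r, groups, length)
    sum(sizes * (means - grand)^2)
  }
  ss_a <- ss(fa)
  ss_b <- if (nlevels(fb) > 1L) ss(fb) else 0
  ss_cells <- ss(interaction(fa, fb, drop = FALSE))
  ss_ab <- max(ss_cells - ss_a - ss_b, 0)
  ss_tot <- sum((r - grand)^2)
  # mid-rank SS_total equals (N^3 - N) * D / 12, so dividing by it applies
  # the tie correction exactly once; the uncorrected variant uses the
  # untied-rank denominator
  ms_tot <- if (tie_correct) ss_tot / (n - 1) else n * (n + 1) / 12
  h_of <- function(ss_eff) {
    if (ms_tot <= 0) return(0)
    ss_eff / ms_tot
  }
  df <- c(nlevels(fa) - 1L, max(nlevels(fb) - 1L, 0L),
          (nlevels(fa) - 1L) * max(nlevels(fb) - 1L, 0L))
  H <- c(h_of(ss_a), h_of(ss_b), h_of(ss_ab))
  p <- ifelse(df > 0, stats::pchisq(H, pmax(df, 1L), lower.tail = FALSE), NA_real_)
  if (ms_tot <= 0) p[df > 0] <- 1  # all values tied: no evidence of any effect
  tibble::tibble(effect = c("A", "B", "A:B"), H = H, df = df, p_value = p)
}
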