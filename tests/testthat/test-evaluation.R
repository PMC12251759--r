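test_that("accuracy and differential accuracy follow their definitions", {
  expect_equal(accuracy(c(1, 1, 2, 3), c(1, 1, 2, 2)), 0.75)
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
  expect_equal(differential_accuracy(0.65, 0.70), -0.05)
  expect_equal(differential_accuracy(0.5, 0.5), 0)
  a <- 0.62; b <- 0.57
  expect_equal(differential_accuracy(a, b), -differential_accuracy(b, a))
})

test_that("per-subject means match a hand-grouped recomputation", {
  set.seed(17)
  combos <- expand.grid(train_pos = c("l", "c", "r"), test_pos = c("l", "c", "r"),
                        subject = sprintf("s%02d", 1:17),
                        normalization = c("swn", "none"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$train_pos != combos$test_pos, ]
  tab <- tibble::as_tibble(combos)
  tab$strategy <- "vanilla"
  tab$y <- rnorm(nrow(tab), sd = 0.05)
  got <- aggregate_subject_means(tab)
  expect_equal(nrow(got), 17 * 2)
  expect_true(all(got$n_combos == 6))
  manual <- stats::aggregate(y ~ normalization + subject, tab, mean)
  for (i in seq_len(nrow(manual))) {
    row <- got[got$normalization == manual$normalization[i] &
                 got$subject == manual$subject[i], ]
    expect_equal(row$mean_y, manual$y[i], tolerance = 1e-12)
  }
  # degenerate cases
  one <- tab[1:2, ]; one$y <- c(-0.02, -0.04); one$subject <- "sA"
  expect_equal(aggregate_subject_means(one)$mean_y, -0.03)
  z <- tab; z$y <- 0
  expect_true(all(aggregate_subject_means(z)$mean_y == 0))
})

test_that("sweep grids have the documented cell counts and argmax selection", {
  expect_equal(nrow(sweep_grid()), 25)
  expect_equal(nrow(sweep_grid(norm_windows = numeric(0))), 5)
  # argmax against a brute-force scan over a random 25-cell sweep
  set.seed(23)
  grid <- sweep_grid()
  sweep <- grid[rep(seq_len(25), each = 6), ]
  sweep$accuracy <- runif(nrow(sweep), 0.3, 0.8)
  best <- select_best(sweep, grid)
  means <- tapply(sweep$accuracy,
                  paste(sweep$norm_window, sweep$feature_window), mean)
  expect_equal(best$mean_accuracy, max(means), tolerance = 1e-12)
  brute <- names(means)[which.max(means)]
  expect_equal(paste(best$norm_window, best$feature_window), brute)
  # tie-break toward the smaller feature window, then smaller norm window
  tied <- grid; tied$accuracy <- 0.5
  b2 <- select_best(tied)
  expect_equal(c(b2$norm_window, b2$feature_window), c(200, 200))
  # single-cell grid returns that cell
  single <- tibble::tibble(norm_window = 600, feature_window = 1000,
                           accuracy = c(0.7, 0.72))
  b3 <- select_best(single)
  expect_equal(b3$mean_accuracy, 0.71)
  expect_error(select_best(sweep[sweep$feature_window != 600, ], grid),
               "missing cells")
})

test_that("wilcoxon rank-sum matches exact enumeration on small samples", {
  # a = 1:3, b = 4:6 -> one-sided tail 1/C(6,3), two-sided p = 0.1
  r <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$rank_sum, 1 + 2 + 3)
  expect_true(r$exact)
  # enumeration oracle: all label assignments of the pooled sample
  enum_p <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled); na <- length(a)
    rk <- rank(pooled)
    obs <- sum(rk[seq_len(na)])
    all_sums <- apply(utils::combn(n, na), 2, function(ix) sum(rk[ix]))
    mu <- na * (n + 1) / 2
    mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-12)
  }
  set.seed(29)
  for (rep in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1:50, na + nb)      # distinct -> no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, enum_p(a, b),
                 tolerance = 1e-9)
  }
  # identical multisets: no evidence against the null
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  # shift invariance
  set.seed(31)
  a <- rnorm(8); b <- rnorm(9)
  r1 <- wilcoxon_rank_sum(a, b); r2 <- wilcoxon_rank_sum(a + 5, b + 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$rank_sum, r2$rank_sum)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("bonferroni scales and caps p-values", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.2, 0.04), 2), c(0.4, 0.08))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("Scheirer-Ray-Hare reduces to Kruskal-Wallis and handles ties", {
  set.seed(37)
  for (rep in 1:10) {
    vals <- sample(1:12, 12, replace = TRUE) + rnorm(12, sd = 1e-6)
    fa <- rep(c("a", "b", "c"), each = 4)
    srh <- scheirer_ray_hare(vals, fa, rep("only", 12))
    kw <- stats::kruskal.test(vals, factor(fa))
    expect_lt(abs(srh$H[srh$effect == "A"] - unname(kw$statistic)), 1e-9)
    expect_lt(abs(srh$p_value[srh$effect == "A"] - kw$p.value), 1e-9)
  }
  # heavy ties with the correction on
  vals <- c(1, 1, 2, 2, 1, 3, 3, 3, 2, 1, 2, 3)
  srh <- scheirer_ray_hare(vals, rep(c("a", "b", "c"), each = 4),
                           rep("only", 12))
  kw <- stats::kruskal.test(vals, factor(rep(c("a", "b", "c"), each = 4)))
  expect_lt(abs(srh$H[1] - unname(kw$statistic)), 1e-9)
  # all equal values: no effect, p = 1
  srh0 <- scheirer_ray_hare(rep(5, 12), rep(c("a", "b"), each = 6),
                            rep(c("x", "y"), 6))
  expect_true(all(srh0$H == 0))
  expect_true(all(srh0$p_value[srh0$df > 0] == 1))
  # contract errors
  expect_error(scheirer_ray_hare(1:5, c("a", "a", "b", "b", "b"),
                                 c("x", "y", "x", "y", "y")), "unbalanced")
  expect_error(scheirer_ray_hare(1:4, c("a", "a", "a", "a"),
                                 c("x", "x", "y", "y")), "2 levels")
})

test_that("a two-factor effect is detected where it exists", {
  set.seed(41)
  fa <- rep(c("swn", "none"), each = 12)
  fb <- rep(rep(c("tl", "ada", "mix"), each = 4), 2)
  vals <- rnorm(24, sd = 0.2) + ifelse(fa == "swn", 2, 0)
  srh <- scheirer_ray_hare(vals, fa, fb)
  expect_lt(srh$p_value[srh$effect == "A"], 0.01)
  expect_gt(srh$p_value[srh$effect == "B"], 0.05)
})
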