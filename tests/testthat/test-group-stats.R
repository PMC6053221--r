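# exhaustive two-sided Fisher p by hypergeometric enumeration
enumerate_fisher_p <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tb[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher's exact test matches enumeration and handles edge tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1)

  tb <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tb)$p_two_sided, enumerate_fisher_p(tb))
  expect_equal(fisher_exact_2x2(tb)$p_two_sided, 0.4857142857, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(tb)$odds_ratio, 9)

  # zero margin: untestable, p = 1 by convention
  degen <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$p_two_sided, 1)

  # invariance under row and column swaps
  set.seed(8)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 12), 2)
    p <- fisher_exact_2x2(tb)$p_two_sided
    expect_equal(fisher_exact_2x2(tb[2:1, ])$p_two_sided, p)
    expect_equal(fisher_exact_2x2(tb[, 2:1])$p_two_sided, p)
    expect_equal(p, fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p agrees with enumeration for all small tables", {
  # every 2x2 table with margins from totals up to 24 (full sweep to 40
  # lives in the acceptance suite)
  for (m in 1:12) for (n in 1:12) for (k in 1:(m + n - 1)) {
    support <- max(0, k - n):min(k, m)
    for (a in support) {
      tb <- matrix(c(a, m - a, k - a, n - (k - a)), 2, byrow = TRUE)
      expect_equal(fisher_exact_2x2(tb)$p_two_sided, enumerate_fisher_p(tb),
                   tolerance = 1e-12)
    }
  }
})

test_that("large balanced tables approach the chi-square p", {
  tb <- matrix(c(1020, 8980, 920, 9080), 2, byrow = TRUE)
  p_f <- fisher_exact_2x2(tb)$p_two_sided
  p_c <- chisq.test(tb, correct = FALSE)$p.value
  expect_lt(abs(p_f - p_c), 0.005)
})

test_that("log-factorial arithmetic stays exact at Table-scale counts", {
  tb <- matrix(c(3479, 13901, 3107, 13105), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tb)$p_two_sided, fisher.test(tb)$p.value,
               tolerance = 1e-10)
})

test_that("condition contingency tables are assembled from counts", {
  counts <- list(
    near_membrane_fraction(c(rep(1, 30), rep(70, 70)),
                           compartment = "active_zone",
                           condition = "low_freq"),
    near_membrane_fraction(c(rep(1, 20), rep(70, 80)),
                           compartment = "active_zone",
                           condition = "high_freq"),
    near_membrane_fraction(c(rep(1, 5), rep(70, 95)),
                           compartment = "glial_facing",
                           condition = "low_freq"))
  tb <- build_condition_contingency(counts, c("low_freq", "high_freq"),
                                    compartment = "active_zone")
  expect_equal(unname(tb), matrix(c(30, 70, 20, 80), 2, byrow = TRUE))
  expect_error(build_condition_contingency(counts,
               c("low_freq", "high_freq"), compartment = "glial_facing"),
               "missing condition")
  expect_error(build_condition_contingency(counts, "low_freq"), "exactly two")
})

test_that("Kruskal-Wallis H matches the classical rank formula", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_wallis_dunn(groups)
  # tie-free: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  expect_equal(res$H, 7.2)
  expect_equal(res$df, 2L)
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adj <= 1))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))

  set.seed(14)
  g2 <- list(x = rnorm(12), y = rnorm(15), z = rnorm(9))
  r2 <- kruskal_wallis_dunn(g2)
  x <- unlist(g2); grp <- rep(names(g2), lengths(g2))
  rk <- rank(x); N <- length(x)
  rb <- tapply(rk, grp, mean)
  H_manual <- 12 / (N * (N + 1)) *
    sum(lengths(g2) * (rb[names(g2)] - (N + 1) / 2)^2)
  expect_equal(r2$H, H_manual)
})

test_that("degenerate and two-group Dunn behaviour is sane", {
  same <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  r <- kruskal_wallis_dunn(same)
  expect_equal(r$H, 0)
  expect_true(all(r$pairwise$p_adj == 1))

  # two groups: z sign follows the rank-sum direction
  lo <- c(1, 2, 3, 4); hi <- c(10, 11, 12, 13)
  r2 <- kruskal_wallis_dunn(list(lo = lo, hi = hi))
  expect_lt(r2$pairwise$z[1], 0)   # lo minus hi
  r3 <- kruskal_wallis_dunn(list(hi = hi, lo = lo))
  expect_gt(r3$pairwise$z[1], 0)
  # Bonferroni multiplier defaults to the single comparison here
  expect_equal(r2$pairwise$p_adj, r2$pairwise$p)
})

test_that("ties are handled through the corrected variance", {
  g <- list(a = c(1, 1, 2, 3), b = c(1, 2, 2, 4), c = c(3, 3, 4, 4))
  r <- kruskal_wallis_dunn(g)
  kw <- kruskal.test(unlist(g), factor(rep(names(g), lengths(g))))
  expect_equal(r$H, unname(kw$statistic))
  x <- unlist(g); N <- length(x)
  ties <- table(x)
  base_var <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(rank(x), rep(names(g), lengths(g)), mean)
  z_ab <- (rb[["a"]] - rb[["b"]]) / sqrt(base_var * (1 / 4 + 1 / 4))
  expect_equal(r$pairwise$z[r$pairwise$group1 == "a" &
                              r$pairwise$group2 == "b"], unname(z_ab))
})
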