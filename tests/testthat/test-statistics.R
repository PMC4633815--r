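test_that("the repeated-measures ANOVA matches a sums-of-squares oracle", {
  tbl <- random_amplitude_table(8, seed = 91)
  got <- rm_anova_3way(tbl)
  oracle <- rm_anova_oracle(tbl)
  oracle$effect <- gsub("cue", "validity", oracle$effect)
  for (i in seq_len(nrow(oracle))) {
    row <- got[got$effect == oracle$effect[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$df1, oracle$df1[i])
    expect_equal(row$df2, oracle$df2[i])
    expect_equal(row$F, oracle$F[i], tolerance = 1e-8)
  }
})

test_that("ANOVA degrees of freedom follow the design", {
  tbl <- random_amplitude_table(28, seed = 92)
  got <- rm_anova_3way(tbl)
  comp <- got[got$effect == "component", ]
  expect_equal(c(comp$df1, comp$df2), c(2, 54))
  expect_equal(got$df2[got$effect == "category"], 27)
  expect_true(all(got$p >= 0 & got$p <= 1))
})

test_that("a null factor main effect yields F = 0", {
  # per-subject cue shifts that cancel exactly across subjects: the cue
  # marginal means are equal, so the validity sum of squares vanishes while
  # its subject-interaction error term stays positive
  tbl <- random_amplitude_table(6, seed = 93)
  delta <- c(1, -1, 2, -2, 0.5, -0.5)
  names(delta) <- sprintf("S%02d", 1:6)
  inv <- tbl$cue == "invalid"
  tbl$amplitude_uv <- ave(tbl$amplitude_uv, paste(tbl$subject, tbl$component,
                                                  tbl$category))
  tbl$amplitude_uv[inv] <- tbl$amplitude_uv[inv] + delta[tbl$subject[inv]]
  got <- rm_anova_3way(tbl)
  expect_lt(got$F[got$effect == "validity"], 1e-10)
})

test_that("missing cells are reported by name", {
  tbl <- random_amplitude_table(4, seed = 94)
  tbl <- tbl[!(tbl$subject == "S02" & tbl$component == "P400" &
                 tbl$category == "face" & tbl$cue == "invalid"), ]
  expect_error(rm_anova_3way(tbl), "S02/P400/face/invalid")
})

test_that("paired t behaves classically", {
  a <- c(1.2, 0.8, 1.9, 1.1, 1.4)
  b <- c(0.9, 0.7, 1.5, 1.2, 1.0)
  got <- paired_t_two_tailed(a, b, "toy")
  # brute-force formula oracle
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(abs(t_ref), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # a = b -> t = 0, p = 1
  eq <- paired_t_two_tailed(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # swapping the conditions negates t and keeps p
  same <- paired_t_two_tailed(c(1, 2, 3, 2), c(2, 1, 2, 3))
  swap <- paired_t_two_tailed(c(2, 1, 2, 3), c(1, 2, 3, 2))
  expect_equal(same$t, -swap$t)
  expect_equal(same$p, swap$p)
})

test_that("cluster statistics sum the supra-threshold t values", {
  ts <- c(0.1, 2.2, 2.5, 2.3, 0.4, -2.6, -2.2, 1.0)
  cl <- erpcue:::find_clusters(ts, 2.0)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$sum_t[1], 7.0)          # 2.2 + 2.5 + 2.3
  expect_equal(cl$start[1], 2)
  expect_equal(cl$end[1], 4)
  expect_equal(cl$sum_t[2], -4.8)
  expect_equal(cl$sign, c(1, -1))
})

test_that("identical conditions produce no clusters", {
  set.seed(95)
  x <- matrix(rnorm(8 * 40), 8, 40)
  res <- cluster_permutation_test(x, x, n_perm = 100, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$tseries == 0))  # zero-variance rule: t = 0
})

test_that("Monte-Carlo p agrees with exhaustive enumeration", {
  set.seed(96)
  n <- 6
  base <- matrix(rnorm(n * 20), n, 20)
  eff <- matrix(0, n, 20); eff[, 8:12] <- 1.4
  a <- base + eff
  b <- matrix(rnorm(n * 20), n, 20)
  exact <- cluster_test_exact(a, b)
  expect_gt(nrow(exact$clusters), 0)
  mc <- cluster_permutation_test(a, b, n_perm = 3000, seed = 2)
  expect_equal(nrow(mc$clusters), nrow(exact$clusters))
  for (i in seq_len(nrow(exact$clusters))) {
    p_ex <- exact$clusters$p[i]
    se <- sqrt(max(p_ex * (1 - p_ex), 1 / 3000) / 3000)
    expect_lt(abs(mc$clusters$p[i] - p_ex), 3 * se + 1e-12)
  }
})

test_that("exact p values live on the permutation lattice", {
  set.seed(97)
  a <- matrix(rnorm(2 * 15, mean = 3), 2, 15)
  b <- matrix(rnorm(2 * 15), 2, 15)
  res <- cluster_test_exact(a, b)
  if (nrow(res$clusters) > 0)
    expect_true(all(res$clusters$p %in% c(0.25, 0.5, 0.75, 1)))
  # antisymmetry under condition swap: same clusters, flipped sign
  set.seed(98)
  a2 <- matrix(rnorm(6 * 25, mean = 0.8), 6, 25)
  b2 <- matrix(rnorm(6 * 25), 6, 25)
  r1 <- cluster_test_exact(a2, b2)
  r2 <- cluster_test_exact(b2, a2)
  expect_equal(r1$clusters$sum_t, -r2$clusters$sum_t)
  expect_equal(r1$clusters$p, r2$clusters$p)
  expect_error(cluster_test_exact(matrix(0, 15, 4), matrix(1, 15, 4)),
               "14")
})

test_that("exact cluster p values are super-uniform under the null", {
  set.seed(99)
  n_sim <- 150
  alphas <- c(0.05, 0.1, 0.25)
  min_p <- rep(NA_real_, n_sim)
  for (i in seq_len(n_sim)) {
    a <- matrix(rnorm(8 * 30), 8, 30)
    b <- matrix(rnorm(8 * 30), 8, 30)
    res <- cluster_test_exact(a, b)
    min_p[i] <- if (nrow(res$clusters) == 0) 1 else min(res$clusters$p)
  }
  for (al in alphas) {
    rate <- mean(min_p <= al)
    se <- sqrt(al * (1 - al) / n_sim)
    expect_lte(rate, al + 3 * se)
  }
})

test_that("larger injected effects never shrink the detected cluster", {
  set.seed(100)
  n <- 10
  noise_a <- matrix(rnorm(n * 60), n, 60)
  noise_b <- matrix(rnorm(n * 60), n, 60)
  stat_at <- function(gain) {
    eff <- matrix(0, n, 60); eff[, 25:35] <- gain
    res <- cluster_permutation_test(noise_a + eff, noise_b, n_perm = 200,
                                    seed = 5)
    cl <- res$clusters[res$clusters$sign > 0, ]
    if (nrow(cl) == 0) 0 else max(cl$sum_t)
  }
  stats <- vapply(c(0.5, 1, 1.5, 2, 3), stat_at, numeric(1))
  expect_true(all(diff(stats) >= 0))
})

test_that("the family-wise error rate is controlled at the nominal level", {
  res <- fwer_simulation(n_datasets = 200, n_subjects = 12, n_samples = 150,
                         n_perm = 400, seed = 6)
  expect_lte(res$fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  # a vanishing cluster-forming threshold lets nothing through
  res0 <- fwer_simulation(n_datasets = 20, n_subjects = 8, n_samples = 50,
                          n_perm = 100, threshold_p = 1e-12, seed = 7)
  expect_equal(res0$fwer, 0)
})
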