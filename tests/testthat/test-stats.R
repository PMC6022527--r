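test_that("the exponential fit is exact on noiseless data and stationary", {
  x <- 3:7
  y <- 52.87 * exp(0.2194 * x)
  f <- fit_exponential(x, y)
  expect_equal(f$A, 52.87, tolerance = 1e-8)
  expect_equal(f$b, 0.2194, tolerance = 1e-8)
  # the patient curve spans a factor ~2.4 between 3 and 7 cm
  expect_equal(exp(f$b * 4), 2.4, tolerance = 0.02)
  # stationarity: perturbing the optimum cannot reduce the SSE
  yn <- y * exp(rnorm(5, 0, 0.05))
  fn <- fit_exponential(x, yn)
  sse <- function(A, b) sum((yn - A * exp(b * x))^2)
  s0 <- sse(fn$A, fn$b)
  for (dA in c(-1e-4, 1e-4)) for (db in c(-1e-7, 1e-7))
    expect_gte(sse(fn$A + dA, fn$b + db), s0 - 1e-9)
  expect_error(fit_exponential(1:2, c(1, 2)), "n >= 3")
  expect_error(fit_exponential(1:4, c(1, -1, 2, 3)), "positive")
})

test_that("fit parameters transform predictably under unit rescaling", {
  set.seed(31)
  x <- runif(40, 3, 7)
  y <- 50 * exp(0.2 * x) * exp(rnorm(40, 0, 0.2))
  f1 <- fit_exponential(x, y)
  f2 <- fit_exponential(x, y * 1000)       # uGy -> nGy
  expect_equal(f2$A, 1000 * f1$A, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  f3 <- fit_exponential(x * 10, y)         # cm -> mm
  expect_equal(f3$b, f1$b / 10, tolerance = 1e-9)
})

test_that("the paired t-test matches the textbook formula", {
  before <- c(0.21, 0.18, 0.25, 0.16)
  after <- c(0.020, 0.015, 0.024, 0.013)
  r <- paired_test(before, after)
  d <- before - after
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
  same <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_test(1:3, 1:4), "equal-length")
})

test_that("ANOVA and Tukey-Kramer agree with the studentized-range oracle", {
  g <- list(a = c(1, 2, 3, 2), b = c(1, 2, 3, 2), c = c(1, 2, 3, 2))
  r0 <- anova_tukey(g)
  expect_equal(r0$anova$statistic, 0, tolerance = 1e-12)
  set.seed(5)
  g2 <- list(L = rnorm(9, 0.25, 0.05), M = rnorm(7, 0.18, 0.05),
             S = rnorm(11, 0.14, 0.05))
  r <- anova_tukey(g2)
  # oracle: Tukey-Kramer adjusted p for L vs S recomputed from ptukey
  ns <- vapply(g2, length, 1L)
  mse <- sum(vapply(g2, function(v) sum((v - mean(v))^2), 1)) / (sum(ns) - 3)
  se <- sqrt(mse / 2 * (1 / ns[["L"]] + 1 / ns[["S"]]))
  q <- abs(mean(g2$L) - mean(g2$S)) / se
  p_hand <- ptukey(q, nmeans = 3, df = sum(ns) - 3, lower.tail = FALSE)
  p_pkg <- r$tukey$p_adj[r$tukey$comparison %in% c("S-L", "L-S")]
  expect_equal(p_pkg, p_hand, tolerance = 1e-6)
  # Tukey-adjusted p is never below the unadjusted pairwise t p
  p_t <- t.test(g2$L, g2$S, var.equal = TRUE)$p.value
  expect_gte(p_pkg, p_t - 1e-12)
  expect_error(anova_tukey(g2["L"]), ">= 2 groups")
})

test_that("pearson matches the closed form and rejects degenerate input", {
  x <- c(1, 2, 4, 7, 9)
  y <- c(2.2, 2.8, 4.5, 7.9, 9.1)
  r <- pearson(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$statistic, r_hand, tolerance = 1e-12)
  expect_equal(pearson(x, 2 * x)$statistic, 1, tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  # invariance under affine rescaling
  expect_equal(pearson(10 * x + 3, y / 1000)$statistic, r$statistic,
               tolerance = 1e-12)
})

test_that("exponential fit recovers generator parameters across noisy cohorts", {
  As <- bs <- cover <- numeric(200)
  for (k in seq_len(200)) {
    co <- generate_cohort(cohort_config(seed = 1000 + k))
    f <- fit_exponential(co$compression_cc / 10, co$k_out * 1000)
    As[k] <- f$A; bs[k] <- f$b
    cover[k] <- abs(f$b - 0.2194) <= 2 * f$b_se
  }
  expect_lt(abs(median(As) - 52.87) / 52.87, 0.05)
  expect_lt(abs(median(bs) - 0.2194) / 0.2194, 0.05)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.995)
})
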