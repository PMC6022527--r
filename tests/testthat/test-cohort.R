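test_that("cohorts are bit-identical for a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 11))
  b <- generate_cohort(cohort_config(seed = 11))
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_config(seed = 12))
  expect_false(identical(a$k_out, c_$k_out))
})

test_that("the default cohort mirrors the study design", {
  co <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(co), 82)
  expect_equal(as.vector(table(co$group)[c("L", "M", "S")]), c(27, 22, 33))
  m <- vapply(split(co$k_out, co$group), mean, 1)
  expect_true(m[["L"]] > m[["M"]] && m[["M"]] > m[["S"]])
  expect_true(all(co$k_in < co$k_out) && all(co$k_out > 0))
  expect_true(all(co$kvp_cc >= 26 & co$kvp_cc <= 32))
  expect_true(all(co$mas_cc >= 36 & co$mas_cc <= 237))
  # group compression means within 2 sd-of-mean of the study values
  ref <- list(L = c(67.3, 7.8, 27), M = c(59.4, 7.7, 22), S = c(43.9, 9.3, 33))
  for (g in names(ref)) {
    x <- co$compression_cc[co$group == g]
    expect_lt(abs(mean(x) - ref[[g]][1]),
              2 * ref[[g]][2] / sqrt(ref[[g]][3]), label = g)
  }
  # collar ratio: median inside/outside in the observed 6-10% band
  expect_gt(median(co$k_in / co$k_out), 0.06)
  expect_lt(median(co$k_in / co$k_out), 0.10)
})

test_that("a noiseless cohort recovers the generating exponential exactly", {
  nl <- generate_cohort(cohort_config(noise_cv = 0, seed = 4))
  f <- fit_exponential(nl$compression_cc / 10, nl$k_out * 1000)
  expect_equal(f$A, 52.87, tolerance = 1e-6)
  expect_equal(f$b, 0.2194, tolerance = 1e-6)
})

test_that("BMI correlation approaches the target in large cohorts", {
  big <- generate_cohort(cohort_config(
    n_per_group = c(L = 3300, M = 3300, S = 3400), seed = 2))
  expect_lt(abs(cor(big$bmi, big$k_out) - 0.48), 0.05)
})

test_that("cohort files round-trip and invalid rows are rejected", {
  co <- generate_cohort(cohort_config(seed = 6))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-9)
  expect_equal(as.vector(table(back$group)[c("L", "M", "S")]), c(27, 22, 33))
  bad <- co; bad$k_in[3] <- bad$k_out[3] * 1.5
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_cohort(f2), "row 3")
  unlink(c(f, f2))
})

test_that("empty groups produce an empty table", {
  co <- generate_cohort(cohort_config(n_per_group = c(L = 0, M = 0, S = 0)))
  expect_equal(nrow(co), 0)
  expect_error(cohort_config(seed = NA), "invalid seed")
})
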