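test_that("cohort-stats scenario bundles are deterministic and stamped", {
  r1 <- run_scenario(run_config("cohort-stats", seed = 9))
  r2 <- run_scenario(run_config("cohort-stats", seed = 9))
  expect_identical(r1$cohort, r2$cohort)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  expect_equal(r1$manifest$seed, 9L)
  expect_true(nzchar(r1$manifest$config_hash))
  expect_lt(r1$stats$paired$all$p_value, 0.001)
})

test_that("the compression sweep produces a positive exponent", {
  r <- run_scenario(run_config("phantom-sweep", seed = 13, histories = 1.8e5,
                               overrides = list(compressions_cm = c(3, 5, 7))))
  expect_true(all(diff(r$sweep$surface_kerma_uGy_per_view) > 0))
  expect_gt(r$fit$b, 0)
})

test_that("bundles are written with a manifest when out_dir is set", {
  out <- file.path(tempdir(), "msc_bundle")
  r <- run_scenario(run_config("cohort-stats", seed = 3, out_dir = out))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "cohort.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 3L)
  unlink(out, recursive = TRUE)
})
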