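test_that("design matrix dummy-codes the 2x2 factorial against the references", {
  co <- generate_cohort(synth_cohort_config(n_per_cell = 6, seed = 1))$cohort
  d <- build_design_matrix(co, model_spec())
  expect_equal(colnames(d$X),
               c("intercept", "novelty_novel", "diagnosis_TD",
                 "novelty_novel:diagnosis_TD"))
  expect_true(all(d$X[, "intercept"] == 1))
  expect_equal(d$X[, "novelty_novel"] * d$X[, "diagnosis_TD"],
               unname(d$X[, "novelty_novel:diagnosis_TD"]))
  ref_rows <- co$diagnosis == "ADHD" & co$novelty == "familiar"
  expect_true(all(rowSums(d$X[ref_rows, -1, drop = FALSE]) == 0))

  # swapped references flip the dummies
  d2 <- build_design_matrix(co, model_spec(NULL, "TD", "novel"))
  expect_equal(colnames(d2$X)[2:3], c("novelty_familiar", "diagnosis_ADHD"))
})

test_that("covariate models get the eight-term three-way expansion, z-scored", {
  co <- generate_cohort(synth_cohort_config(n_per_cell = 6, seed = 2))$cohort
  d <- build_design_matrix(co, model_spec("immersion"))
  expect_equal(ncol(d$X), 8)
  zc <- d$X[, "z_immersion"]
  expect_equal(mean(zc), 0, tolerance = 1e-12)
  expect_equal(sd(zc), 1, tolerance = 1e-12)
  expect_equal(zc * d$X[, "diagnosis_TD"] * d$X[, "novelty_novel"],
               unname(d$X[, "z_immersion:diagnosis_TD:novelty_novel"]))
  expect_equal(d$z_scale, sd(co$immersion))
})

test_that("degenerate designs fail loudly", {
  co <- generate_cohort(synth_cohort_config(n_per_cell = 6, seed = 3))$cohort
  half <- cohort_table(as.data.frame(co)[co$diagnosis == "ADHD", ])
  expect_error(build_design_matrix(half, model_spec()), "empty design cell")

  few <- cohort_table(as.data.frame(co)[c(1, 7, 13, 19), ])
  expect_error(build_design_matrix(few, model_spec()), "more rows than columns")
})

test_that("zscore centres, scales by n-1 SD, and is idempotent", {
  z <- zscore(c(1, 2, 3))
  expect_equal(mean(z$values), 0)
  expect_equal(sd(z$values), 1)
  expect_equal(zscore(c(10, 20))$values, c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(zscore(z$values)$values, z$values)
  expect_error(zscore(rep(5, 4)), "constant")
})

test_that("sampling is bit-reproducible under the same seed and keeps sigma > 0", {
  co <- generate_cohort(synth_cohort_config(n_per_cell = 8, seed = 4))$cohort
  d <- build_design_matrix(co)
  p1 <- sample_posterior(d, config = quick_config(99))
  p2 <- sample_posterior(d, config = quick_config(99))
  expect_identical(p1$draws, p2$draws)
  expect_true(all(p1$draws[, "sigma"] > 0))
  expect_equal(nrow(p1$draws), 2 * 500)  # chains x (samples - warmup)

  p3 <- sample_posterior(d, config = quick_config(100))
  expect_false(identical(p1$draws, p3$draws))
})

test_that("posterior matches the least-squares solution under weak priors", {
  sim <- generate_cohort(synth_cohort_config(seed = 5))
  d <- build_design_matrix(sim$cohort)
  pd <- sample_posterior(d, prior_spec(), sampler_config(base_seed = 5))
  ols <- qr.solve(d$X, d$y)
  post_means <- colMeans(pd$draws[, colnames(d$X)])
  expect_true(all(abs(post_means - ols) < 0.5))
})

test_that("a constant response does not crash and collapses sigma", {
  df <- tiny_cohort_df()
  df <- df[rep(1:4, each = 4), ]
  df$id <- paste0("r", seq_len(nrow(df)))
  df$stm_hits <- 10L; df$ltm_hits <- 5L  # retention identically 50
  co <- cohort_table(df)
  d <- build_design_matrix(co)
  pd <- sample_posterior(d, config = quick_config(7))
  expect_true(all(pd$draws[, "sigma"] > 0))
  expect_lt(median(pd$draws[, "sigma"]), 1)
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(42)
  good <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "theta"))
  rep_good <- rhat(good, chain = rep(1:4, each = 1000))
  expect_lt(rep_good$table$rhat, 1.01)
  expect_true(rep_good$pass)

  bad <- matrix(c(rnorm(1000, 0), rnorm(1000, 5)), ncol = 1,
                dimnames = list(NULL, "theta"))
  rep_bad <- rhat(bad, chain = rep(1:2, each = 1000))
  expect_gt(rep_bad$table$rhat, 1.1)
  expect_false(rep_bad$pass)

  # chains that are exact copies: no between-chain variance, only the
  # split-halves term remains
  one <- rnorm(1000)
  copies <- matrix(rep(one, 4), ncol = 1, dimnames = list(NULL, "theta"))
  rep_copy <- rhat(copies, chain = rep(1:4, each = 1000))
  expect_equal(rep_copy$table$rhat, 1, tolerance = 5e-2)

  expect_error(rhat(good, chain = rep(1, 4000)), "2 chains")
})

test_that("ESS is near the draw count for iid draws and far below for sticky ones", {
  set.seed(8)
  iid <- matrix(rnorm(8000), ncol = 1, dimnames = list(NULL, "x"))
  r1 <- rhat(iid, chain = rep(1:4, each = 2000))
  expect_gt(r1$table$ess, 4000)

  ar <- as.numeric(arima.sim(list(ar = 0.95), 2000))
  sticky <- matrix(rep(ar, 2) + rnorm(4000, 0, 1e-3), ncol = 1,
                   dimnames = list(NULL, "x"))
  r2 <- rhat(sticky, chain = rep(1:2, each = 2000))
  expect_lt(r2$table$ess, 1000)
})

test_that("draw export is one labelled row per retained draw", {
  co <- generate_cohort(synth_cohort_config(n_per_cell = 6, seed = 6))$cohort
  pd <- sample_posterior(build_design_matrix(co), config = quick_config(3))
  path <- withr::local_tempfile(fileext = ".csv")
  export_draws(pd, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), nrow(pd$draws))
  expect_equal(names(back)[1:2], c("chain", "draw_index"))
  expect_equal(back$sigma, unname(pd$draws[, "sigma"]), tolerance = 1e-6)
})
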