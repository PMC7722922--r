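test_that("retention formula matches its definition and permits hypermnesia", {
  expect_equal(compute_retention(10, 5), 50)
  expect_equal(compute_retention(20, 20), 100)
  expect_equal(compute_retention(8, 10), 125)  # ltm > stm is not clipped
  expect_error(compute_retention(0, 3), "undefined")
  expect_error(compute_retention(21, 3), "0\\.\\.20")
})

test_that("retention is scale-free over integer multiples", {
  for (s in 1:5) {
    for (l in 0:s) {
      ks <- seq_len(20 %/% s)
      vals <- compute_retention(ks * s, ks * l)
      expect_true(all(abs(vals - vals[1]) < 1e-12))
    }
  }
})

test_that("cohort construction validates, recomputes retention, drops bad rows", {
  df <- tiny_cohort_df()
  co <- cohort_table(df)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 4)
  expect_equal(co$retention, c(50, 125, 75, 100))

  # stm = 0 rows are excluded with a warning, not an error
  df0 <- rbind(df, data.frame(id = "z", diagnosis = "TD", novelty = "novel",
                              stm_hits = 0L, ltm_hits = 0L, novelty_seeking = NA,
                              immersion = NA, exploration_tiles = NA))
  expect_warning(co0 <- cohort_table(df0), "stm_hits = 0")
  expect_equal(nrow(co0), 4)

  bad <- df; bad$diagnosis[1] <- "controls"
  expect_warning(cob <- cohort_table(bad), "unparseable")
  expect_equal(nrow(cob), 3)

  dup <- df; dup$id[2] <- "a1"
  expect_error(cohort_table(dup), "unique")
  expect_error(cohort_table(df[0, ]), "empty")
  expect_error(cohort_table(df[, -4]), "missing mandatory")

  oob <- df; oob$immersion[1] <- 31
  expect_error(cohort_table(oob), "-30, 30")
})

test_that("a stored retention column is ignored and recomputed from counts", {
  df <- tiny_cohort_df()
  df$retention <- c(1, 2, 3, 4)  # wrong on purpose
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  co <- load_cohort(path)
  expect_equal(co$retention, compute_retention(co$stm_hits, co$ltm_hits))
})

test_that("load_cohort honours a schema column map and rejects broken files", {
  df <- tiny_cohort_df()
  names(df)[names(df) == "stm_hits"] <- "recall_day1"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_cohort(path), "missing mandatory")
  co <- load_cohort(path, schema = c(stm_hits = "recall_day1"))
  expect_equal(co$stm_hits, tiny_cohort_df()$stm_hits)
  expect_error(load_cohort(path, schema = c(stm_hits = "nope")), "absent column")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,diagnosis,novelty,stm_hits,ltm_hits", empty)
  expect_error(load_cohort(empty), "empty")
  expect_error(load_cohort("does-not-exist.csv"), "no such file")
})

test_that("write/load round trip is the identity on random cohorts", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:50) {
    sim <- generate_cohort(synth_cohort_config(n_per_cell = 3, seed = seed))
    co <- sim$cohort
    # random missingness pattern in the covariates
    set.seed(seed)
    for (col in c("novelty_seeking", "immersion", "exploration_tiles")) {
      co[[col]][runif(nrow(co)) < 0.3] <- NA
    }
    write_cohort(co, path)
    back <- load_cohort(path)
    expect_equal(back$id, co$id)
    expect_identical(back$stm_hits, co$stm_hits)
    expect_identical(back$ltm_hits, co$ltm_hits)
    expect_identical(back$exploration_tiles, co$exploration_tiles)
    expect_equal(back$retention, co$retention, tolerance = 1e-9)
    expect_equal(back$novelty_seeking, co$novelty_seeking, tolerance = 1e-9)
    expect_equal(back$immersion, co$immersion, tolerance = 1e-9)
    expect_equal(as.character(back$diagnosis), as.character(co$diagnosis))
    expect_equal(as.character(back$novelty), as.character(co$novelty))
  }
  expect_error(write_cohort(structure(list(), class = "cohort_table"), path))
})

test_that("cell sizes are reported per factorial cell", {
  co <- generate_cohort(synth_cohort_config(n_per_cell = 5, seed = 2))$cohort
  cs <- cell_sizes(co)
  expect_equal(sort(names(cs)),
               sort(c("ADHD-familiar", "ADHD-novel", "TD-familiar", "TD-novel")))
  expect_true(all(cs == 5L))
})
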