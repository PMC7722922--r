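test_that("trajectory parsing keeps order, drops bad rows, warns on gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,x,y,z", "100,1,64,1", "200,2,64,2", "300,3,64,3"), path)
  log <- parse_trajectory(path)
  expect_s3_class(log, "trajectory_log")
  expect_equal(nrow(log), 3)

  writeLines(c("t_ms,x,y,z", "100,1,64,1", "100,2,64,2", "300,3,64,3"), path)
  expect_warning(log2 <- parse_trajectory(path), "strictly increasing")
  expect_equal(nrow(log2), 2)

  writeLines(c("t_ms,x,y,z", "100,1,64,1", "200,oops,64,2", "300,3,64,3"), path)
  expect_warning(log3 <- parse_trajectory(path), "non-numeric")
  expect_equal(nrow(log3), 2)

  writeLines(c("t_ms,x,y,z", "0,0,64,0", "1000,1,64,1", "2000,2,64,2"), path)
  expect_warning(parse_trajectory(path), "100 ms")

  writeLines("t_ms,x,y,z", path)
  expect_error(parse_trajectory(path), "empty")
})

test_that("a 600 s session at 10 Hz yields 6001 samples", {
  log <- generate_trajectory(arena_config(duration_s = 600, seed = 3))
  expect_equal(nrow(log), 6001)
  expect_equal(diff(log$t_ms[1:5]), rep(100, 4))
})

test_that("tile indexing is floor division on the (x, z) plane", {
  log <- trajectory_log(walk_frame(c(0.5, 1.9, 2.1), c(0.5, 0.5, 0.5)))
  tv <- tile_visits(log, tile_size = 2)
  expect_equal(unique_tile_count(tv), 2)
  expect_setequal(paste(tv$visited$i, tv$visited$j), c("0 0", "1 0"))
  expect_equal(sum(tv$per_tile_counts), 3)

  # stationary log occupies exactly one tile regardless of length
  still <- trajectory_log(walk_frame(rep(3.3, 40), rep(7.7, 40)))
  expect_equal(unique_tile_count(tile_visits(still)), 1)

  # integer sweep of [0,10)^2 with tile size 2 -> 25 tiles
  g <- expand.grid(x = 0:9, z = 0:9)
  sweep <- trajectory_log(walk_frame(g$x, g$z))
  expect_equal(unique_tile_count(tile_visits(sweep, 2)),
               brute_force_tiles(g$x, g$z, 2))
  expect_equal(unique_tile_count(tile_visits(sweep, 2)), 25)

  # negative coordinates map to negative indices, no shifting
  neg <- trajectory_log(walk_frame(c(-0.5, -2.1), c(-0.5, 0.5)))
  tvn <- tile_visits(neg, 2)
  expect_setequal(paste(tvn$visited$i, tvn$visited$j), c("-1 -1", "-2 0"))
})

test_that("unique_tile_count is permutation/duplication invariant and monotone", {
  set.seed(11)
  x <- cumsum(rnorm(150)); z <- cumsum(rnorm(150))
  base <- unique_tile_count(tile_visits(trajectory_log(walk_frame(x, z))))

  perm <- sample(150)
  log_p <- trajectory_log(walk_frame(x[perm], z[perm]))  # re-timestamped
  expect_equal(unique_tile_count(tile_visits(log_p)), base)

  dup <- trajectory_log(walk_frame(c(x, x[37]), c(z, z[37])))
  expect_equal(unique_tile_count(tile_visits(dup)), base)

  counts <- vapply(seq(10, 150, by = 20), function(k) {
    unique_tile_count(tile_visits(trajectory_log(walk_frame(x[1:k], z[1:k]))))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("tile counts at size 1 equal the brute-force floored-pair count", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:80, 1)
    x <- runif(n, -30, 30); z <- runif(n, -30, 30)
    log <- trajectory_log(walk_frame(x, z))
    expect_equal(unique_tile_count(tile_visits(log, 1)),
                 brute_force_tiles(x, z, 1))
  }
})

test_that("occupancy difference maps count participants once per tile", {
  a <- trajectory_log(walk_frame(c(0.1, 0.2, 1.4), c(0.1, 0.2, 0.2)), "p1")
  b <- trajectory_log(walk_frame(c(10.5, 10.6), c(10.5, 10.5)), "p2")
  m <- occupancy_difference_map(list(a), list(b))
  expect_equal(m["0", "0"], 1L)   # repeated samples still contribute 1
  expect_equal(m["5", "5"], -1L)
  expect_equal(sum(m != 0), 2)

  # self-difference is identically zero
  m0 <- occupancy_difference_map(list(a, b), list(a, b))
  expect_true(all(m0 == 0))

  # antisymmetry and the participant-count bound
  set.seed(5)
  mk <- function(id) trajectory_log(
    walk_frame(cumsum(rnorm(60)), cumsum(rnorm(60))), id)
  ga <- lapply(1:5, function(i) mk(paste0("a", i)))
  gb <- lapply(1:5, function(i) mk(paste0("b", i)))
  mab <- occupancy_difference_map(ga, gb)
  mba <- occupancy_difference_map(gb, ga)
  expect_identical(plain_matrix(mab),
                   -plain_matrix(mba)[rownames(mab), colnames(mab)])
  expect_true(all(mab >= -5 & mab <= 5))

  env_a <- trajectory_log(walk_frame(1, 1), "e1", environment = "mansion")
  env_b <- trajectory_log(walk_frame(1, 1), "e2", environment = "island")
  expect_error(occupancy_difference_map(list(env_a), list(env_b)), "mixed environments")
})

test_that("occupancy maps export as TSV with a JSON sidecar", {
  a <- trajectory_log(walk_frame(c(0.5, 3.5), c(0.5, 3.5)), "p1")
  b <- trajectory_log(walk_frame(5.5, 5.5), "p2")
  m <- occupancy_difference_map(list(a), list(b))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_map(m, path)
  back <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(plain_matrix(m)))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$tile_size, 2)
})

test_that("trajectory CSV round trip preserves samples", {
  log <- generate_trajectory(arena_config(duration_s = 30, seed = 9), "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(log, path)
  back <- parse_trajectory(path, participant_id = "rt")
  expect_equal(nrow(back), nrow(log))
  expect_equal(back$x, log$x, tolerance = 1e-6)
})
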