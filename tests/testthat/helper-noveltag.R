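# fixtures built in code: tiny cohorts, trajectory frames, quick sampler
# settings for unit tests (acceptance tests use the full default settings)

tiny_cohort_df <- function() {
  data.frame(
    id = c("a1", "a2", "t1", "t2"),
    diagnosis = c("ADHD", "ADHD", "TD", "TD"),
    novelty = c("familiar", "novel", "familiar", "novel"),
    stm_hits = c(10L, 8L, 12L, 20L),
    ltm_hits = c(5L, 10L, 9L, 20L),
    novelty_seeking = c(55.2, NA, 43.1, 40.8),
    immersion = c(5.5, -2.25, NA, 12),
    exploration_tiles = c(700L, 850L, NA, 900L),
    stringsAsFactors = FALSE
  )
}

quick_config <- function(seed = 1L) {
  sampler_config(n_chains = 2, n_samples_per_chain = 700, n_warmup = 200,
                 base_seed = seed)
}

walk_frame <- function(x, z, dt = 100) {
  data.frame(t_ms = seq_along(x) * dt, x = x, y = 64, z = z)
}

.zero_slopes_for_test <- function() {
  covs <- c("novelty_seeking", "immersion", "exploration_tiles")
  cells <- c("ADHD-familiar", "ADHD-novel", "TD-familiar", "TD-novel")
  lapply(setNames(covs, covs), function(...) setNames(rep(0, 4), cells))
}

# brute-force tile oracle: distinct floored (x, z) pairs
brute_force_tiles <- function(x, z, tile_size) {
  nrow(unique(cbind(floor(x / tile_size), floor(z / tile_size))))
}

# matrix values + dimnames only, shedding occupancy-map attributes
plain_matrix <- function(m) {
  matrix(as.vector(m), nrow = nrow(m), dimnames = dimnames(m))
}

# textbook balanced two-way ANOVA, computed from cell means only
balanced_anova_oracle <- function(y, f1, f2) {
  cells <- split(y, interaction(f1, f2))
  n <- unique(lengths(cells))
  stopifnot(length(n) == 1)
  cm <- vapply(cells, mean, 0)
  m <- matrix(cm, 2, 2)  # rows: f1 levels, cols: f2 levels
  grand <- mean(y)
  ss1 <- 2 * n * sum((rowMeans(m) - grand)^2)
  ss2 <- 2 * n * sum((colMeans(m) - grand)^2)
  ssint <- n * sum((m - outer(rowMeans(m), colMeans(m), "+") + grand)^2)
  sse <- sum(vapply(cells, function(v) sum((v - mean(v))^2), 0))
  dfe <- length(y) - 4
  list(F1 = (ss1 / 1) / (sse / dfe), F2 = (ss2 / 1) / (sse / dfe),
       Fint = (ssint / 1) / (sse / dfe), sse = sse, dfe = dfe)
}
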