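COVARIATE_NAMES <- c("novelty_seeking", "immersion", "exploration_tiles")

# control-variable means/SDs per cell used as simulation defaults
.default_covariate_params <- function() {
  cells <- cell_names()
  mk <- function(means, sds) {
    m <- rbind(mean = means, sd = sds)
    colnames(m) <- cells
    m
  }
  list(
    novelty_seeking = mk(c(54.82, 56.82, 43.00, 40.25),
                         c(12.33, 7.92, 6.78, 10.08)),
    immersion = mk(c(5.76, 0.53, -5.82, -1.76),
                   c(9.30, 11.82, 10.94, 15.68)),
    exploration_tiles = mk(c(740.76, 854.94, 783.12, 902.53),
                           c(182.87, 167.83, 178.56, 153.87))
  )
}

.zero_slopes <- function() {
  lapply(stats::setNames(COVARIATE_NAMES, COVARIATE_NAMES),
         function(...) stats::setNames(rep(0, 4), cell_names()))
}

#' Configuration of a synthetic study cohort
#'
#' Defaults emulate the study design: a 2x2 factorial (diagnosis x
#' novelty) with 17 participants per cell; STM recall drawn as
#' Binomial(20, p) with a lower encoding probability for the patient group;
#' cell retention means whose pairwise differences mirror the reported
#' group contrasts (the absolute anchor of 75 for TD-familiar is a
#' simulation convention, since only differences are identified by the
#' analysis); a common residual SD of 13; and control-variable means/SDs
#' per cell taken from the observed cohort summaries.
#'
#' @param n_per_cell Participants per cell (>= 2).
#' @param p_stm Named encoding probabilities `c(ADHD = , TD = )` for the
#'   Binomial(20, p) STM draw.
#' @param retention_means Named cell means of latent retention (percent).
#' @param retention_sd Common residual SD of latent retention.
#' @param covariate_params List per covariate of a 2 x 4 matrix
#'   (rows mean/sd, columns cells).
#' @param covariate_slopes List per covariate of named per-cell slopes:
#'   retention change per one configured cell SD of the covariate
#'   (default all 0).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synth_cohort_config` list.
#' @export
synth_cohort_config <- function(n_per_cell = 17,
                                p_stm = c(ADHD = 0.42, TD = 0.55),
                                retention_means = c("ADHD-familiar" = 52,
                                                    "ADHD-novel" = 67,
                                                    "TD-familiar" = 75,
                                                    "TD-novel" = 71),
                                retention_sd = 13,
                                covariate_params = .default_covariate_params(),
                                covariate_slopes = .zero_slopes(),
                                seed = 1L) {
  stopifnot(n_per_cell >= 2, all(p_stm > 0 & p_stm < 1),
            all(DIAGNOSIS_LEVELS %in% names(p_stm)),
            all(cell_names() %in% names(retention_means)),
            retention_sd > 0,
            all(COVARIATE_NAMES %in% names(covariate_params)),
            all(COVARIATE_NAMES %in% names(covariate_slopes)))
  for (cv in COVARIATE_NAMES) {
    stopifnot(all(covariate_params[[cv]]["sd", ] > 0))
  }
  structure(list(n_per_cell = as.integer(n_per_cell), p_stm = p_stm,
                 retention_means = retention_means, retention_sd = retention_sd,
                 covariate_params = covariate_params,
                 covariate_slopes = covariate_slopes,
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Per participant: STM ~ Binomial(20, p[diagnosis]), redrawn until >= 1;
#' covariates ~ Normal(cell mean, cell SD) (immersion truncated to its
#' [-30, 30] scale, exploration rounded to a nonnegative count); latent
#' retention ~ Normal(cell mean + sum of slope x cell-z-scored covariate,
#' SD); LTM = round(STM x retention / 100) clamped to 0..20. The returned
#' cohort carries the retention recomputed from the discretised counts, so
#' it is noisier than the latent value — exactly the discretisation a real
#' word-list study has.
#'
#' @param config A [synth_cohort_config()].
#' @return List with `cohort` (a [cohort_table()]) and `truth` (a
#'   `synthetic_truth`: the config echo, configured contrasts, realized
#'   cell means, realized pooled covariate SDs and the implied per-pooled-SD
#'   slopes that a pooled-z model fit estimates).
#' @export
generate_cohort <- function(config = synth_cohort_config()) {
  stopifnot(inherits(config, "synth_cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_cell
  rows <- list()
  latent <- numeric(0)
  for (cell in cell_names()) {
    parts <- strsplit(cell, "-", fixed = TRUE)[[1]]
    diag <- parts[1]; nov <- parts[2]
    stm <- stats::rbinom(n, WORD_LIST_LENGTH, config$p_stm[[diag]])
    while (any(stm == 0L)) {
      stm[stm == 0L] <- stats::rbinom(sum(stm == 0L), WORD_LIST_LENGTH,
                                      config$p_stm[[diag]])
    }
    covs <- lapply(COVARIATE_NAMES, function(cv) {
      pars <- config$covariate_params[[cv]][, cell]
      v <- stats::rnorm(n, pars[["mean"]], pars[["sd"]])
      if (cv == "immersion") v <- pmin(pmax(v, -30), 30)
      if (cv == "exploration_tiles") v <- pmax(round(v), 0)
      v
    })
    names(covs) <- COVARIATE_NAMES
    mu <- rep(config$retention_means[[cell]], n)
    for (cv in COVARIATE_NAMES) {
      pars <- config$covariate_params[[cv]][, cell]
      z_cell <- (covs[[cv]] - pars[["mean"]]) / pars[["sd"]]
      mu <- mu + config$covariate_slopes[[cv]][[cell]] * z_cell
    }
    ret <- stats::rnorm(n, mu, config$retention_sd)
    ltm <- pmin(pmax(round(stm * ret / 100), 0), WORD_LIST_LENGTH)
    rows[[cell]] <- data.frame(
      id = sprintf("%s_%02d", gsub("-", "_", cell), seq_len(n)),
      diagnosis = diag, novelty = nov, stm_hits = stm, ltm_hits = ltm,
      novelty_seeking = covs$novelty_seeking, immersion = covs$immersion,
      exploration_tiles = covs$exploration_tiles,
      stringsAsFactors = FALSE
    )
    latent <- c(latent, ret)
  }
  tbl <- do.call(rbind, rows)
  cohort <- cohort_table(tbl, provenance = paste0("synthetic(seed=", config$seed, ")"))

  cfg_means <- config$retention_means
  configured_contrasts <- c(
    "ADHD-familiar vs TD-familiar" = unname(cfg_means["ADHD-familiar"] - cfg_means["TD-familiar"]),
    "ADHD-novel vs TD-novel" = unname(cfg_means["ADHD-novel"] - cfg_means["TD-novel"]),
    "ADHD-novel vs ADHD-familiar" = unname(cfg_means["ADHD-novel"] - cfg_means["ADHD-familiar"]),
    "TD-novel vs TD-familiar" = unname(cfg_means["TD-novel"] - cfg_means["TD-familiar"])
  )
  cell_of <- paste(cohort$diagnosis, cohort$novelty, sep = "-")
  realized_means <- vapply(cell_names(),
                           function(cl) mean(cohort$retention[cell_of == cl]), 0)
  # a pooled-z model fit estimates slope_cell * sd_pooled / sd_cell
  pooled_sd <- vapply(COVARIATE_NAMES, function(cv) stats::sd(cohort[[cv]]), 0)
  implied <- lapply(stats::setNames(COVARIATE_NAMES, COVARIATE_NAMES), function(cv) {
    cell_sd <- config$covariate_params[[cv]]["sd", cell_names()]
    config$covariate_slopes[[cv]][cell_names()] * pooled_sd[[cv]] / cell_sd
  })
  truth <- structure(list(config = config,
                          configured_contrasts = configured_contrasts,
                          realized_cell_means = realized_means,
                          pooled_covariate_sd = pooled_sd,
                          implied_pooled_slopes = implied),
                     class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' STM-matched pseudo-random condition assignment
#'
#' Emulates matching participants to the familiar or novel condition based
#' on immediate-recall performance: participants are ranked by STM score
#' (ties broken at random), consecutive pairs are split with one member
#' randomly assigned to each condition, and an odd leftover is assigned at
#' random. The two conditions therefore start from near-identical baseline
#' recall distributions while remaining randomised within pairs.
#'
#' @param stm_scores Numeric STM hit counts for one diagnosis group
#'   (length >= 2).
#' @param seed Integer seed for the pair splits.
#' @return Character vector of `"familiar"`/`"novel"` in input order;
#'   condition sizes differ by at most 1.
#' @export
pseudo_random_match <- function(stm_scores, seed = 1L) {
  stopifnot(is.numeric(stm_scores), length(stm_scores) >= 2L)
  set.seed(seed)
  n <- length(stm_scores)
  ord <- order(stm_scores, stats::runif(n))
  labels <- character(n)
  i <- 1L
  while (i + 1L <= n) {
    flip <- stats::runif(1) < 0.5
    labels[ord[i]] <- if (flip) "familiar" else "novel"
    labels[ord[i + 1L]] <- if (flip) "novel" else "familiar"
    i <- i + 2L
  }
  if (i == n) {
    labels[ord[n]] <- if (stats::runif(1) < 0.5) "familiar" else "novel"
  }
  labels
}

#' Configuration of a synthetic exploration session
#'
#' Defaults describe a study-scale session: a 120 x 120 block arena, the
#' game's nominal walking speed of 4.3 blocks/s, positions logged every
#' 100 ms, and a session duration drawn uniformly from 10--20 minutes.
#' `persistence` (0..1) controls how straight the walk is;
#' `revisit_avoidance` (0..1) is the propensity to turn away from tiles
#' already visited, the generator's exploration dial.
#'
#' @param bounds Arena extent in blocks, `c(width, depth)`.
#' @param speed Walking speed in blocks per second.
#' @param persistence Turning persistence in [0, 1).
#' @param revisit_avoidance Revisit-avoidance strength in [0, 1].
#' @param duration_s Session length in seconds, or `NULL` to draw
#'   uniformly from [600, 1200].
#' @param dt_ms Sampling interval (default 100 ms).
#' @param seed Integer seed.
#' @return An `arena_config` list.
#' @export
arena_config <- function(bounds = c(120, 120), speed = 4.3,
                         persistence = 0.7, revisit_avoidance = 0.5,
                         duration_s = NULL, dt_ms = 100, seed = 1L) {
  stopifnot(length(bounds) == 2L, all(bounds > 0), speed > 0,
            persistence >= 0, persistence < 1,
            revisit_avoidance >= 0, revisit_avoidance <= 1,
            dt_ms > 0)
  if (!is.null(duration_s)) stopifnot(duration_s > 0)
  structure(list(bounds = bounds, speed = speed, persistence = persistence,
                 revisit_avoidance = revisit_avoidance,
                 duration_s = duration_s, dt_ms = dt_ms, seed = as.integer(seed)),
            class = "arena_config")
}

#' Generate a synthetic exploration trajectory
#'
#' A persistent random walk reflected at the arena walls and sampled every
#' `dt_ms`: the heading diffuses with a turning noise shrinking in
#' `persistence`, and when the tile two blocks ahead has already been
#' visited the walker turns away with probability `revisit_avoidance` —
#' higher avoidance yields more unique tiles, mimicking more exploratory
#' play. Deterministic under the config seed.
#'
#' @param config An [arena_config()].
#' @param participant_id,environment Tags for the resulting log.
#' @return A [trajectory_log()] with `floor(duration_s * 1000 / dt_ms) + 1`
#'   samples.
#' @export
generate_trajectory <- function(config = arena_config(),
                                participant_id = "synthetic",
                                environment = NA_character_) {
  stopifnot(inherits(config, "arena_config"))
  set.seed(config$seed)
  duration <- if (is.null(config$duration_s)) stats::runif(1, 600, 1200) else config$duration_s
  n_steps <- floor(duration * 1000 / config$dt_ms)
  step_len <- config$speed * config$dt_ms / 1000
  w <- config$bounds[1]; h <- config$bounds[2]
  turn_sd <- (1 - config$persistence) * pi

  # visited 2x2 tiles tracked on a logical grid for the avoidance lookahead
  vis <- matrix(FALSE, nrow = ceiling(w / 2) + 1L, ncol = ceiling(h / 2) + 1L)
  x <- numeric(n_steps + 1L); z <- numeric(n_steps + 1L)
  x[1] <- w / 2; z[1] <- h / 2
  theta <- stats::runif(1, 0, 2 * pi)
  turn_noise <- stats::rnorm(n_steps, 0, turn_sd)
  avoid_u <- stats::runif(n_steps)
  # steering side is sticky (rare flips), so the walker sweeps the frontier
  # of the visited region instead of oscillating left/right
  side_flip <- stats::runif(n_steps) < 0.005
  sgn <- if (stats::runif(1) < 0.5) 1 else -1
  # candidate turn offsets, gentlest first
  offsets <- c(pi / 4, pi / 2, 3 * pi / 4, pi)
  look <- 3  # lookahead distance in blocks
  cx <- x[1]; cz <- z[1]
  vis[floor(cx / 2) + 1L, floor(cz / 2) + 1L] <- TRUE
  tile_new <- function(ang) {
    lx <- cx + look * cos(ang); lz <- cz + look * sin(ang)
    lx >= 0 && lx < w && lz >= 0 && lz < h &&
      !vis[floor(lx / 2) + 1L, floor(lz / 2) + 1L]
  }
  for (s in seq_len(n_steps)) {
    theta <- theta + turn_noise[s]
    if (side_flip[s]) sgn <- -sgn
    if (config$revisit_avoidance > 0 && s %% 5L == 0L &&
        avoid_u[s] < config$revisit_avoidance && !tile_new(theta)) {
      # steer by the gentlest turn that points at an unvisited tile,
      # preferring the sticky side
      for (off in offsets) {
        if (tile_new(theta + sgn * off)) { theta <- theta + sgn * off; break }
        if (tile_new(theta - sgn * off)) { theta <- theta - sgn * off; break }
      }
    }
    nx <- cx + step_len * cos(theta)
    nz <- cz + step_len * sin(theta)
    if (nx < 0) { nx <- -nx; theta <- pi - theta }
    if (nx > w) { nx <- 2 * w - nx; theta <- pi - theta }
    if (nz < 0) { nz <- -nz; theta <- -theta }
    if (nz > h) { nz <- 2 * h - nz; theta <- -theta }
    cx <- nx; cz <- nz
    vis[floor(cx / 2) + 1L, floor(cz / 2) + 1L] <- TRUE
    x[s + 1L] <- cx; z[s + 1L] <- cz
  }
  samples <- data.frame(t_ms = seq(0, n_steps) * config$dt_ms,
                        x = x, y = 64, z = z)
  trajectory_log(samples, participant_id = participant_id,
                 environment = environment)
}
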