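#' Per-group covariate slope posteriors from a three-way fit
#'
#' For each experimental cell, sums the covariate main-effect draws with
#' the covariate-interaction draws selected by the cell's dummy pattern,
#' giving the cell's retention change per one SD of the covariate.
#' Invariant to the dummy reference choice.
#'
#' @param draws A `posterior_draws` from a covariate x diagnosis x novelty
#'   model.
#' @return Named list of four slope draw vectors, one per cell.
#' @export
slope_posteriors <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  spec <- draws$design$spec
  if (is.null(spec$covariate)) {
    stop("slope_posteriors expects a covariate interaction model")
  }
  pn <- colnames(draws$draws)
  cov_name <- paste0("z_", spec$covariate)
  cd <- grep(paste0("^", cov_name, ":diagnosis_[^:]+$"), pn, value = TRUE)
  cn <- grep(paste0("^", cov_name, ":novelty_[^:]+$"), pn, value = TRUE)
  cdn <- grep(paste0("^", cov_name, ":diagnosis_.+:novelty_.+$"), pn, value = TRUE)
  out <- lapply(cell_names(), function(cell) {
    d <- .cell_dummies(cell, spec)
    draws$draws[, cov_name] +
      d[["diag"]] * draws$draws[, cd] +
      d[["nov"]] * draws$draws[, cn] +
      d[["diag"]] * d[["nov"]] * draws$draws[, cdn]
  })
  stats::setNames(out, cell_names())
}

.summarise_draws <- function(d, rope) {
  rs <- rope_fraction(d, rope)
  list(b = mean(d), hdi = rs$hdi, pct_outside_rope = rs$pct_outside,
       rope = rs, verdict = decide(rs))
}

#' Fit the main novelty x diagnosis retention model
#'
#' Runs the full decision pipeline for the primary analysis: builds the
#' dummy-coded 2x2 design, samples the posterior under the weakly
#' informative priors, reconstructs the four cell posteriors, and
#' evaluates the four reported contrasts (between diagnoses within each
#' novelty condition, and between novelty conditions within each
#' diagnosis) against the ROPE.
#'
#' @param cohort A [cohort_table()] with all four cells populated.
#' @param priors A [prior_spec()].
#' @param config A [sampler_config()].
#' @param rope ROPE bounds in percent retention (default [-5, 5]).
#' @param reference_diagnosis,reference_novelty Dummy references; all
#'   reported quantities are invariant to them.
#' @return A `main_model_result`: per-cell posterior summaries, the four
#'   `posterior_contrast`s, the convergence report and the raw draws.
#' @export
fit_main_model <- function(cohort, priors = prior_spec(),
                           config = sampler_config(), rope = DEFAULT_ROPE,
                           reference_diagnosis = "ADHD",
                           reference_novelty = "familiar") {
  spec <- model_spec(NULL, reference_diagnosis, reference_novelty)
  design <- build_design_matrix(cohort, spec)
  draws <- sample_posterior(design, priors, config)
  if (!is.null(draws$convergence) && !draws$convergence$pass) {
    warning("main model: convergence not reached (split-Rhat >= 1.01)")
  }
  groups <- group_posteriors(draws)
  pairs <- list(
    "ADHD-familiar vs TD-familiar" = c("ADHD-familiar", "TD-familiar"),
    "ADHD-novel vs TD-novel" = c("ADHD-novel", "TD-novel"),
    "ADHD-novel vs ADHD-familiar" = c("ADHD-novel", "ADHD-familiar"),
    "TD-novel vs TD-familiar" = c("TD-novel", "TD-familiar")
  )
  contrasts <- lapply(pairs, function(pr) contrast(groups[[pr[1]]], groups[[pr[2]]], rope))
  group_summaries <- lapply(groups, function(g) {
    h <- hdi(g)
    list(mean = mean(g), hdi = h)
  })
  structure(list(groups = group_summaries, group_draws = groups,
                 contrasts = contrasts, rope = rope,
                 convergence = draws$convergence, draws = draws,
                 n = nrow(design$X), cell_counts = design$cell_counts),
            class = "main_model_result")
}

#' @export
print.main_model_result <- function(x, ...) {
  cat("Main model: retention ~ novelty x diagnosis, n =", x$n, "\n")
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %-14s mean %.2f, 95%% HDI [%.2f, %.2f]\n",
                nm, g$mean, g$hdi$lower, g$hdi$upper))
  }
  cat("Contrasts (ROPE [", x$rope[1], ",", x$rope[2], "]):\n")
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %-28s b = %6.2f, HDI [%6.2f, %6.2f], %6.2f%% outside -> %s\n",
                nm, ct$b, ct$hdi$lower, ct$hdi$upper, ct$rope$pct_outside,
                ct$verdict$verdict))
  }
  invisible(x)
}

#' Fit a covariate x diagnosis x novelty retention model
#'
#' Z-scores the chosen control variable over all rows entering the model,
#' fits the eight-term three-way interaction model, and summarises the
#' per-cell slopes (retention change per covariate SD) and one slope
#' contrast between two cells against the ROPE.
#'
#' @param cohort A [cohort_table()].
#' @param covariate `"novelty_seeking"`, `"immersion"` or
#'   `"exploration_tiles"`. Rows missing it are dropped (listwise, per
#'   model); each cell must keep at least 3 rows.
#' @param priors,config,rope,reference_diagnosis,reference_novelty As in
#'   [fit_main_model()].
#' @param contrast_cells Length-2 character: the two cells whose slope
#'   difference is reported (default TD-novel vs ADHD-novel).
#' @return A `covariate_model_result`: raw covariate mean/SD per cell,
#'   per-cell slope summaries, the slope contrast, z-transform parameters,
#'   convergence report and draws.
#' @export
fit_covariate_model <- function(cohort, covariate, priors = prior_spec(),
                                config = sampler_config(), rope = DEFAULT_ROPE,
                                reference_diagnosis = "ADHD",
                                reference_novelty = "familiar",
                                contrast_cells = c("TD-novel", "ADHD-novel")) {
  stopifnot(length(contrast_cells) == 2L, all(contrast_cells %in% cell_names()))
  if (!covariate %in% c("novelty_seeking", "immersion", "exploration_tiles")) {
    stop("unknown covariate: ", covariate)
  }
  if (all(is.na(cohort[[covariate]]))) stop("covariate ", covariate, " is absent")
  spec <- model_spec(covariate, reference_diagnosis, reference_novelty)
  design <- build_design_matrix(cohort, spec)
  if (any(design$cell_counts < 3)) {
    stop("fewer than 3 rows per cell after listwise deletion for ", covariate)
  }
  draws <- sample_posterior(design, priors, config)
  if (!is.null(draws$convergence) && !draws$convergence$pass) {
    warning(covariate, " model: convergence not reached (split-Rhat >= 1.01)")
  }
  slopes <- slope_posteriors(draws)
  slope_summaries <- lapply(slopes, .summarise_draws, rope = rope)
  ct <- contrast(slopes[[contrast_cells[1]]], slopes[[contrast_cells[2]]], rope)

  df <- design$data
  cell_stats <- lapply(cell_names(), function(cell) {
    parts <- strsplit(cell, "-", fixed = TRUE)[[1]]
    v <- df[[covariate]][df$diagnosis == parts[1] & df$novelty == parts[2]]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  names(cell_stats) <- cell_names()

  structure(list(covariate = covariate, cell_stats = cell_stats,
                 slopes = slope_summaries, slope_draws = slopes,
                 slope_contrast = ct, contrast_cells = contrast_cells,
                 z_center = design$z_center, z_scale = design$z_scale,
                 rope = rope, convergence = draws$convergence, draws = draws,
                 n = nrow(design$X)),
            class = "covariate_model_result")
}

#' @export
print.covariate_model_result <- function(x, ...) {
  cat("Covariate model: retention ~", x$covariate, "x diagnosis x novelty, n =",
      x$n, "\n")
  for (nm in names(x$slopes)) {
    s <- x$slopes[[nm]]
    st <- x$cell_stats[[nm]]
    cat(sprintf("  %-14s %8.2f (%6.2f)  b = %6.2f, HDI [%6.2f, %6.2f], %6.2f%% outside\n",
                nm, st[["mean"]], st[["sd"]], s$b, s$hdi$lower, s$hdi$upper,
                s$pct_outside_rope))
  }
  cat(sprintf("Slope contrast %s vs %s: b_delta = %.2f, HDI [%.2f, %.2f], %.2f%% outside\n",
              x$contrast_cells[1], x$contrast_cells[2], x$slope_contrast$b,
              x$slope_contrast$hdi$lower, x$slope_contrast$hdi$upper,
              x$slope_contrast$rope$pct_outside))
  invisible(x)
}
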