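DEFAULT_ROPE <- c(-5, 5)

#' Highest density interval of posterior draws
#'
#' The shortest contiguous window of the sorted draws containing
#' `ceiling(mass * n)` draws; for a unimodal posterior this is the
#' `mass`-HDI. Ties between equally short windows are broken toward the
#' smallest lower bound, so the estimator is deterministic given the draws.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass to cover (default 0.95).
#' @return List with `lower`, `upper`, `mass`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(is.numeric(draws), mass > 0, mass < 1)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("hdi needs at least 100 draws for a stable estimate")
  sorted <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(list(lower = sorted[1], upper = sorted[n], mass = mass))
  widths <- sorted[m:n] - sorted[seq_len(n - m + 1L)]
  i <- which.min(widths)  # which.min returns the first (smallest lower bound)
  list(lower = sorted[i], upper = sorted[i + m - 1L], mass = mass)
}

#' ROPE overlap of a posterior
#'
#' Fraction of the pooled posterior draws inside a region of practical
#' equivalence (default [-5, 5] percent retention: differences smaller than
#' one word out of twenty are treated as zero). Boundary draws count as
#' inside (closed interval). The 95% HDI is computed alongside with strict
#' containment flags.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param rope Length-2 numeric, lower < upper.
#' @return A `rope_summary`: `rope_lower`, `rope_upper`, `pct_inside`,
#'   `pct_outside` (summing to 100 exactly), `hdi`, `hdi_fully_outside`,
#'   `hdi_fully_inside`.
#' @export
rope_fraction <- function(draws, rope = DEFAULT_ROPE) {
  stopifnot(is.numeric(draws), length(rope) == 2L, rope[1] < rope[2])
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L) stop("rope_fraction needs at least 100 draws")
  pct_inside <- 100 * mean(draws >= rope[1] & draws <= rope[2])
  h <- hdi(draws, 0.95)
  structure(list(
    rope_lower = rope[1], rope_upper = rope[2],
    pct_inside = pct_inside, pct_outside = 100 - pct_inside,
    hdi = h,
    hdi_fully_outside = h$upper < rope[1] || h$lower > rope[2],
    hdi_fully_inside = h$lower >= rope[1] && h$upper <= rope[2]
  ), class = "rope_summary")
}

#' @export
print.rope_summary <- function(x, ...) {
  cat(sprintf("ROPE [%g, %g]: %.2f%% inside, %.2f%% outside; 95%% HDI [%.2f, %.2f]\n",
              x$rope_lower, x$rope_upper, x$pct_inside, x$pct_outside,
              x$hdi$lower, x$hdi$upper))
  invisible(x)
}

#' Three-way equivalence verdict
#'
#' An effect is `significant` when at least 95% of the posterior lies
#' outside the ROPE (the effect is non-zero with >= 95% probability),
#' `practically_zero` when the ROPE covers at least 95% of the posterior,
#' and `undecided` otherwise. Both thresholds are closed (>= 95).
#'
#' @param summary A [rope_fraction()] result.
#' @return A `verdict`: list with `verdict` (one of the three labels) and
#'   `basis` echoing the percentages that produced it.
#' @export
decide <- function(summary) {
  stopifnot(inherits(summary, "rope_summary"))
  v <- if (summary$pct_outside >= 95) "significant"
  else if (summary$pct_inside >= 95) "practically_zero"
  else "undecided"
  structure(list(verdict = v,
                 basis = c(pct_inside = summary$pct_inside,
                           pct_outside = summary$pct_outside)),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("%s (%.2f%% outside / %.2f%% inside the ROPE)\n",
              x$verdict, x$basis[["pct_outside"]], x$basis[["pct_inside"]]))
  invisible(x)
}

cell_names <- function() {
  c("ADHD-familiar", "ADHD-novel", "TD-familiar", "TD-novel")
}

# dummy indicator pair (diagnosis dummy, novelty dummy) for a named cell
# under the reference levels of a model_spec
.cell_dummies <- function(cell, spec) {
  parts <- strsplit(cell, "-", fixed = TRUE)[[1]]
  c(diag = as.numeric(parts[1] != spec$reference_diagnosis),
    nov = as.numeric(parts[2] != spec$reference_novelty))
}

#' Per-group retention posteriors from a factorial fit
#'
#' Rebuilds each experimental cell's posterior by summing, draw by draw,
#' the intercept with the coefficient draws selected by that cell's dummy
#' pattern. Because the sum reproduces the cell mean whatever the dummy
#' reference, the result is invariant to the coding choice.
#'
#' @param draws A `posterior_draws` from the 2x2 factorial model.
#' @return Named list of four numeric draw vectors, one per cell
#'   (`ADHD-familiar`, `ADHD-novel`, `TD-familiar`, `TD-novel`).
#' @export
group_posteriors <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  spec <- draws$design$spec
  if (!is.null(spec$covariate)) {
    stop("group_posteriors expects the 2x2 factorial model (no covariate)")
  }
  pn <- colnames(draws$draws)
  if (length(pn) != 5L) stop("not a 2x2 factorial fit: parameters ", length(pn))
  nov_col <- grep("^novelty_[^:]+$", pn, value = TRUE)
  diag_col <- grep("^diagnosis_[^:]+$", pn, value = TRUE)
  int_col <- grep(":", pn, fixed = TRUE, value = TRUE)
  out <- lapply(cell_names(), function(cell) {
    d <- .cell_dummies(cell, spec)
    draws$draws[, "intercept"] +
      d[["nov"]] * draws$draws[, nov_col] +
      d[["diag"]] * draws$draws[, diag_col] +
      d[["nov"]] * d[["diag"]] * draws$draws[, int_col]
  })
  stats::setNames(out, cell_names())
}

#' Posterior contrast between two draw sequences
#'
#' Elementwise difference `a - b` over the pooled draws, summarised by the
#' posterior mean (the reported effect size b), the 95% HDI, the ROPE
#' overlap and the equivalence verdict.
#'
#' @param draws_a,draws_b Equal-length numeric draw vectors (same pooled
#'   draws, e.g. two cells of [group_posteriors()]).
#' @param rope ROPE bounds (default [-5, 5]).
#' @return A `posterior_contrast`: `difference` (draws), `b` (mean), `hdi`,
#'   `rope`, `verdict`.
#' @export
contrast <- function(draws_a, draws_b, rope = DEFAULT_ROPE) {
  stopifnot(is.numeric(draws_a), is.numeric(draws_b))
  if (length(draws_a) != length(draws_b)) {
    stop("contrast needs equal draw counts (same pooled posterior)")
  }
  diff <- draws_a - draws_b
  rs <- rope_fraction(diff, rope)
  structure(list(difference = diff, b = mean(diff), hdi = rs$hdi,
                 rope = rs, verdict = decide(rs)),
            class = "posterior_contrast")
}

#' @export
print.posterior_contrast <- function(x, ...) {
  cat(sprintf("b = %.2f, 95%% HDI [%.2f, %.2f], %.2f%% outside ROPE -> %s\n",
              x$b, x$hdi$lower, x$hdi$upper, x$rope$pct_outside,
              x$verdict$verdict))
  invisible(x)
}
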