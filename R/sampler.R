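#' Prior specification for the retention models
#'
#' Default priors: a weakly informative Student-t prior on the intercept
#' (df 3, location 50, scale 30 — encoding that patients typically retain
#' about half the words), a weakly informative half-Student-t prior on the
#' residual SD (df 3, scale 10), and flat improper priors on all other
#' coefficients so that positive and negative effects (and zero) are
#' equally likely a priori.
#'
#' Either component can be set to `"flat"`: a flat intercept prior is
#' uniform on the real line; a flat sigma prior is uniform on log(sigma)
#' (the standard noninformative choice, under which the coefficient
#' posterior has the closed multivariate-t form).
#'
#' @param intercept `"flat"` or a list with `df`, `location`, `scale`.
#' @param sigma `"flat"` or a list with `df`, `scale` (half-t, location 0).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(intercept = list(df = 3, location = 50, scale = 30),
                       sigma = list(df = 3, scale = 10)) {
  norm_t <- function(x, what) {
    if (identical(x, "flat")) return(list(type = "flat"))
    stopifnot(is.list(x), x$df > 0, x$scale > 0)
    loc <- if (what == "intercept") x$location else 0
    list(type = if (what == "intercept") "student_t" else "half_t",
         df = x$df, location = loc, scale = x$scale)
  }
  structure(list(intercept = norm_t(intercept, "intercept"),
                 sigma = norm_t(sigma, "sigma"),
                 coefficients = list(type = "flat")),
            class = "prior_spec")
}

#' Sampler settings
#'
#' Defaults follow the analysis convention of four independent chains with
#' 2000 samples each, the first 1000 of which are discarded as warm-up,
#' leaving 4000 pooled posterior draws.
#'
#' @param n_chains Number of independent chains (>= 2 for diagnostics).
#' @param n_samples_per_chain Total iterations per chain, warm-up included.
#' @param n_warmup Iterations discarded per chain; step sizes adapt only
#'   during warm-up.
#' @param base_seed Integer seed; chain `c` is seeded `base_seed + c`.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_chains = 4, n_samples_per_chain = 2000,
                           n_warmup = 1000, base_seed = 1L) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_samples_per_chain > n_warmup,
            is.finite(base_seed))
  structure(list(n_chains = as.integer(n_chains),
                 n_samples_per_chain = as.integer(n_samples_per_chain),
                 n_warmup = as.integer(n_warmup),
                 base_seed = as.integer(base_seed),
                 algorithm = "adaptive_metropolis_within_gibbs"),
            class = "sampler_config")
}

#' Model descriptor for the retention regressions
#'
#' Describes one of the two model shapes used in the pipeline: the 2x2
#' factorial `retention ~ novelty * diagnosis`, or the three-way covariate
#' interaction `retention ~ covariate * diagnosis * novelty` with the
#' covariate z-scored over all rows entering the model.
#'
#' @param covariate `NULL` for the main factorial model, or one of
#'   `"novelty_seeking"`, `"immersion"`, `"exploration_tiles"`.
#' @param reference_diagnosis,reference_novelty Dummy-coding reference
#'   levels. Group posteriors and contrasts are invariant to this choice.
#' @return A `model_spec` list.
#' @export
model_spec <- function(covariate = NULL,
                       reference_diagnosis = "ADHD",
                       reference_novelty = "familiar") {
  if (!is.null(covariate)) {
    covariate <- match.arg(covariate,
                           c("novelty_seeking", "immersion", "exploration_tiles"))
  }
  structure(list(covariate = covariate,
                 reference_diagnosis = match.arg(reference_diagnosis, DIAGNOSIS_LEVELS),
                 reference_novelty = match.arg(reference_novelty, NOVELTY_LEVELS)),
            class = "model_spec")
}

#' z-transform a covariate
#'
#' Centers and scales by the sample SD (n - 1 denominator), pooled over all
#' values supplied — slopes fitted on the result are "per one SD" of the
#' covariate in the modelled sample.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with `values` (standardized), `mean`, `sd`.
#' @export
zscore <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (anyNA(values)) stop("zscore: missing values must be removed first")
  s <- stats::sd(values)
  if (s == 0) stop("zscore: constant input has no scale")
  list(values = (values - mean(values)) / s, mean = mean(values), sd = s)
}

#' Build the design matrix for a retention model
#'
#' Dummy-codes the two factors against the references declared in the
#' [model_spec()] (reference cell = all dummies 0), forms interaction
#' columns as elementwise products, and z-scores the covariate (pooled over
#' the rows entering the model) when one is requested. Rows missing any
#' model variable are dropped with a warning.
#'
#' @param cohort A [cohort_table()].
#' @param spec A [model_spec()].
#' @return A `design_matrix`: list with `X` (named columns, `intercept`
#'   first), `y` (retention, percent), the spec, z-transform parameters
#'   (when a covariate is used), per-cell counts and the retained cohort
#'   rows.
#' @export
build_design_matrix <- function(cohort, spec = model_spec()) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "model_spec"))
  df <- as.data.frame(cohort)
  vars <- c("retention", "diagnosis", "novelty", spec$covariate)
  keep <- stats::complete.cases(df[vars])
  if (!all(keep)) {
    warning(sum(!keep), " row(s) dropped from the model: missing ",
            paste(vars[colSums(is.na(df[vars])) > 0], collapse = "/"))
    df <- df[keep, , drop = FALSE]
  }
  cells <- table(df$diagnosis, df$novelty)
  if (any(cells == 0)) {
    stop("empty design cell(s): ",
         paste(outer(rownames(cells), colnames(cells), paste, sep = "-")[cells == 0],
               collapse = ", "))
  }
  diag_lab <- setdiff(DIAGNOSIS_LEVELS, spec$reference_diagnosis)
  nov_lab <- setdiff(NOVELTY_LEVELS, spec$reference_novelty)
  d_diag <- as.numeric(df$diagnosis == diag_lab)
  d_nov <- as.numeric(df$novelty == nov_lab)
  z_info <- NULL
  if (is.null(spec$covariate)) {
    X <- cbind(intercept = 1, stats::setNames(data.frame(d_nov, d_diag, d_nov * d_diag),
               c(paste0("novelty_", nov_lab), paste0("diagnosis_", diag_lab),
                 paste0("novelty_", nov_lab, ":diagnosis_", diag_lab))))
  } else {
    z_info <- zscore(df[[spec$covariate]])
    zc <- z_info$values
    cov_name <- paste0("z_", spec$covariate)
    X <- data.frame(intercept = 1, zc, d_diag, d_nov,
                    zc * d_diag, zc * d_nov, d_diag * d_nov, zc * d_diag * d_nov)
    names(X) <- c("intercept", cov_name,
                  paste0("diagnosis_", diag_lab), paste0("novelty_", nov_lab),
                  paste0(cov_name, ":diagnosis_", diag_lab),
                  paste0(cov_name, ":novelty_", nov_lab),
                  paste0("diagnosis_", diag_lab, ":novelty_", nov_lab),
                  paste0(cov_name, ":diagnosis_", diag_lab, ":novelty_", nov_lab))
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) {
    stop("flat coefficient priors need more rows than columns (",
         nrow(X), " <= ", ncol(X), ")")
  }
  structure(list(X = X, y = df$retention, spec = spec,
                 z_center = z_info$mean, z_scale = z_info$sd,
                 cell_counts = cells, data = df),
            class = "design_matrix")
}

# log prior densities (unnormalised where harmless)
.lp_intercept <- function(b0, prior) {
  if (prior$type == "flat") return(0)
  stats::dt((b0 - prior$location) / prior$scale, df = prior$df, log = TRUE) -
    log(prior$scale)
}

.lp_log_sigma <- function(log_sigma, prior) {
  # density over log(sigma): half-t on sigma plus the Jacobian sigma;
  # the flat choice is uniform on log(sigma), i.e. p(sigma) ~ 1/sigma
  if (prior$type == "flat") return(0)
  sigma <- exp(log_sigma)
  stats::dt(sigma / prior$scale, df = prior$df, log = TRUE) - log(prior$scale) +
    log(2) + log_sigma
}

#' Draw from the posterior of a Gaussian linear retention model
#'
#' Samples `y ~ Normal(X beta, sigma^2)` under a [prior_spec()] with a
#' Metropolis-within-Gibbs scheme built around the model's partial
#' conjugacy: the non-intercept coefficients (flat priors) are drawn
#' exactly from their conditional normal; the intercept is updated by
#' independence Metropolis with its conditional-likelihood normal as
#' proposal, so the acceptance ratio reduces to the Student-t prior ratio
#' and acceptance stays near 1; sigma is proposed from the conjugate
#' inverse-gamma conditional implied by a flat log-sigma prior and
#' Metropolis-corrected for the half-t prior. Under fully flat priors
#' every step is exact Gibbs. Chains start at the least-squares solution
#' (residual SD for sigma), jittered per chain, and chain `c` is seeded
#' `base_seed + c` for exact reproducibility.
#'
#' @param design A [build_design_matrix()] result.
#' @param priors A [prior_spec()].
#' @param config A [sampler_config()].
#' @param prior_only If `TRUE`, the likelihood is switched off and the
#'   chains target the prior itself; only proper priors are allowed, so the
#'   design must be intercept-only.
#' @return A `posterior_draws` object: pooled post-warm-up draw matrix
#'   (named coefficients plus `sigma`), per-draw chain labels, the config
#'   and priors, and a `convergence` report from [rhat()].
#' @export
sample_posterior <- function(design, priors = prior_spec(),
                             config = sampler_config(), prior_only = FALSE) {
  stopifnot(inherits(design, "design_matrix"), inherits(priors, "prior_spec"),
            inherits(config, "sampler_config"))
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (prior_only) {
    if (p != 1L || priors$intercept$type == "flat" || priors$sigma$type == "flat") {
      stop("prior-only sampling needs proper priors and an intercept-only design")
    }
  }

  ip <- priors$intercept; sp <- priors$sigma
  n_iter <- config$n_samples_per_chain
  n_warm <- config$n_warmup
  n_keep <- n_iter - n_warm

  if (prior_only) {
    # adaptive random-walk on (intercept, log sigma) targeting the prior;
    # exercises the same prior-density code as the posterior sampler
    log_prior <- function(b0, log_sigma) {
      .lp_intercept(b0, ip) + .lp_log_sigma(log_sigma, sp)
    }
    run_chain <- function(chain_idx) {
      set.seed(config$base_seed + chain_idx)
      b0 <- ip$location + stats::rnorm(1, 0, 0.1 * ip$scale)
      log_sigma <- log(sp$scale) + stats::rnorm(1, 0, 0.1)
      lp_cur <- log_prior(b0, log_sigma)
      s_b <- ip$scale; s_s <- 1
      draws <- matrix(NA_real_, n_keep, 2L)
      for (it in seq_len(n_iter)) {
        prop <- b0 + s_b * stats::rnorm(1)
        lp_p <- log_prior(prop, log_sigma)
        a <- exp(min(0, lp_p - lp_cur))
        if (stats::runif(1) < a) { b0 <- prop; lp_cur <- lp_p }
        if (it <= n_warm) s_b <- s_b * exp((a - 0.44) / it^0.6)
        ls_p <- log_sigma + s_s * stats::rnorm(1)
        lp_p <- log_prior(b0, ls_p)
        a <- exp(min(0, lp_p - lp_cur))
        if (stats::runif(1) < a) { log_sigma <- ls_p; lp_cur <- lp_p }
        if (it <= n_warm) s_s <- s_s * exp((a - 0.44) / it^0.6)
        if (it > n_warm) draws[it - n_warm, ] <- c(b0, exp(log_sigma))
      }
      draws
    }
    chains <- lapply(seq_len(config$n_chains), run_chain)
  } else {
    # least-squares quantities for initialization and the conjugate steps
    XtX_inv <- chol2inv(chol(crossprod(X)))
    beta_ols <- drop(XtX_inv %*% crossprod(X, y))
    resid_ols <- y - drop(X %*% beta_ols)
    sigma_ols <- sqrt(sum(resid_ols^2) / max(n - p, 1))
    if (!is.finite(sigma_ols) || sigma_ols <= 0) sigma_ols <- 1e-3
    has_rest <- p > 1L
    if (has_rest) {
      Xr <- X[, -1L, drop = FALSE]
      U <- chol(crossprod(Xr))                        # Xr'Xr = U'U
      Xry <- drop(crossprod(Xr, y))
      s_vec <- colSums(Xr)
      m_y <- backsolve(U, forwardsolve(t(U), Xry))
      m_1 <- backsolve(U, forwardsolve(t(U), s_vec))
      # intercept marginal given sigma (rest integrated out under flat
      # priors): Normal(b0_marg, sigma^2 / one_M_one)
      one_M_one <- n - sum(s_vec * m_1)
      b0_marg <- (sum(y) - sum(Xry * m_1)) / one_M_one
    } else {
      one_M_one <- n
      b0_marg <- mean(y)
    }
    log_halft_sigma <- function(sigma) {
      if (sp$type == "flat") 0 else
        stats::dt(sigma / sp$scale, df = sp$df, log = TRUE) + log(sigma)
    }
    log_t_intercept <- function(b0) {
      if (ip$type == "flat") 0 else
        stats::dt((b0 - ip$location) / ip$scale, df = ip$df, log = TRUE)
    }
    run_chain <- function(chain_idx) {
      set.seed(config$base_seed + chain_idx)
      beta <- beta_ols + sigma_ols * 0.1 * stats::rnorm(p) * sqrt(diag(XtX_inv))
      sigma <- sigma_ols * exp(stats::rnorm(1, 0, 0.1))
      resid <- y - drop(X %*% beta)
      ssr <- sum(resid * resid)
      if (!is.finite(ssr)) stop("non-finite residuals at initialization")
      draws <- matrix(NA_real_, n_keep, p + 1L)
      for (it in seq_len(n_iter)) {
        # sigma: conjugate inverse-gamma proposal (exact under a flat
        # log-sigma prior), Metropolis-corrected for the half-t prior
        sig_prop <- sqrt(max(ssr, 1e-12) / stats::rchisq(1, n))
        log_a <- log_halft_sigma(sig_prop) - log_halft_sigma(sigma)
        if (log(stats::runif(1)) < log_a) sigma <- sig_prop
        # intercept: independence proposal from its marginal likelihood
        # (other coefficients integrated out); the normal terms cancel,
        # leaving the t-prior ratio, so (b0, rest) is a near-exact joint
        # draw of beta | sigma
        b0_prop <- stats::rnorm(1, b0_marg, sigma / sqrt(one_M_one))
        log_a <- log_t_intercept(b0_prop) - log_t_intercept(beta[1])
        if (log(stats::runif(1)) < log_a) beta[1] <- b0_prop
        # remaining coefficients: exact conditional normal (flat priors)
        if (has_rest) {
          mean_r <- m_y - beta[1] * m_1
          beta[-1L] <- mean_r + sigma * backsolve(U, stats::rnorm(p - 1L))
        }
        resid <- y - drop(X %*% beta)
        ssr <- sum(resid * resid)
        if (it > n_warm) draws[it - n_warm, ] <- c(beta, sigma)
      }
      draws
    }
    chains <- lapply(seq_len(config$n_chains), run_chain)
  }

  draws <- do.call(rbind, chains)
  colnames(draws) <- c(colnames(X), "sigma")
  out <- structure(
    list(draws = draws,
         chain = rep(seq_len(config$n_chains), each = n_keep),
         config = config, priors = priors,
         parameters = colnames(draws), design = design,
         prior_only = prior_only),
    class = "posterior_draws")
  out$convergence <- if (config$n_chains >= 2L && n_keep >= 4L) rhat(out) else NULL
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$draws), "pooled draws x",
      ncol(x$draws), "parameters,", x$config$n_chains, "chains\n")
  sm <- t(apply(x$draws, 2, function(d) c(mean = mean(d), sd = stats::sd(d))))
  print(round(sm, 3))
  if (!is.null(x$convergence)) {
    cat(if (x$convergence$pass) "All split-Rhat < 1.01\n" else
      "WARNING: convergence not reached (split-Rhat >= 1.01)\n")
  }
  invisible(x)
}

#' Split-R-hat and effective sample size
#'
#' Computes per-parameter split-R-hat (each retained chain is halved; the
#' statistic compares between- and within-half variances) and a standard
#' autocorrelation-based effective-sample-size estimate. Convergence is
#' declared when every split-R-hat is below 1.01.
#'
#' @param draws A `posterior_draws` object, or a numeric draw matrix
#'   (columns = parameters) with `chain` supplied.
#' @param chain Integer chain label per row when `draws` is a matrix.
#' @return A `convergence_report`: data frame of `parameter`, `rhat`,
#'   `ess`, plus a `pass` flag.
#' @export
rhat <- function(draws, chain = NULL) {
  if (inherits(draws, "posterior_draws")) {
    chain <- draws$chain
    draws <- draws$draws
  }
  stopifnot(is.matrix(draws), !is.null(chain), length(chain) == nrow(draws))
  chains <- split(seq_len(nrow(draws)), chain)
  if (length(chains) < 2L) stop("split-Rhat needs at least 2 chains")
  len <- unique(lengths(chains))
  if (length(len) != 1L) stop("chains must have equal length")
  if (len < 4L) stop("need at least 4 retained draws per chain")

  half <- floor(len / 2)
  per_param <- function(v) {
    # v: vector of pooled draws for one parameter
    segs <- lapply(chains, function(idx) {
      x <- v[idx]
      list(x[seq_len(half)], x[half + seq_len(half)])
    })
    segs <- unlist(segs, recursive = FALSE)
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, stats::var, 0)
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) {
      rh <- if (B == 0) 1 else Inf
    } else {
      var_plus <- (half - 1) / half * W + B / half
      rh <- sqrt(var_plus / W)
    }
    # ESS from chain-averaged autocorrelations, initial positive sequence
    ess <- NA_real_
    if (W > 0) {
      max_lag <- min(half - 1L, 200L)
      acfs <- vapply(segs, function(x)
        stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1],
        numeric(max_lag + 1L))
      var_plus <- (half - 1) / half * W + B / half
      rho <- 1 - (W - rowMeans(acfs * rep(vars, each = max_lag + 1L))) / var_plus
      # Geyer: sum consecutive pairs while positive
      tau <- 1
      t <- 2L
      while (t + 1L <= length(rho)) {
        pair <- rho[t] + rho[t + 1L]
        if (!is.finite(pair) || pair < 0) break
        tau <- tau + 2 * pair
        t <- t + 2L
      }
      ess <- length(segs) * half / tau
    }
    c(rh, ess)
  }
  stats_mat <- t(apply(draws, 2, per_param))
  report <- data.frame(parameter = colnames(draws),
                       rhat = stats_mat[, 1], ess = stats_mat[, 2],
                       row.names = NULL)
  structure(list(table = report, pass = all(report$rhat < 1.01)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  print(transform(x$table, rhat = round(rhat, 4), ess = round(ess)))
  cat(if (x$pass) "Converged: all split-Rhat < 1.01\n" else
    "NOT converged: some split-Rhat >= 1.01\n")
  invisible(x)
}

#' Export posterior draws as CSV
#'
#' One row per retained draw: `chain`, `draw_index` (within chain), then
#' the named parameters.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  idx <- stats::ave(seq_along(draws$chain), draws$chain, FUN = seq_along)
  out <- data.frame(chain = draws$chain, draw_index = idx, draws$draws,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
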