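# polynomial rolling hash over the deparsed analysis-relevant settings;
# changes iff a setting changes (exact integer arithmetic below 2^53)
.config_hash <- function(obj) {
  txt <- paste(deparse(obj, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every analysis-relevant setting. The defaults reproduce the
#' reference analysis conventions: ROPE [-5, 5], four chains of 2000 draws
#' with 1000 warm-up, Student-t(3, 50, 30) intercept and half-t(3, 0, 10)
#' sigma priors.
#'
#' @param cohort_path Cohort CSV to load, or `NULL` to simulate.
#' @param trajectories_dir Directory of per-participant trajectory CSVs
#'   named `<id>.csv`, or `NULL`.
#' @param synth A [synth_cohort_config()] used when `cohort_path` is
#'   `NULL`.
#' @param priors,sampler A [prior_spec()] and [sampler_config()].
#' @param rope ROPE bounds.
#' @param reference_diagnosis,reference_novelty Dummy references.
#' @param covariates Control variables to model and test.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param seed Master seed: overrides the sampler base seed and the
#'   synthetic generator seed so one integer pins the whole run.
#' @param verbose Emit progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_path = NULL, trajectories_dir = NULL,
                            synth = synth_cohort_config(),
                            priors = prior_spec(), sampler = sampler_config(),
                            rope = DEFAULT_ROPE,
                            reference_diagnosis = "ADHD",
                            reference_novelty = "familiar",
                            covariates = COVARIATE_NAMES,
                            out_dir = NULL, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) {
    sampler$base_seed <- as.integer(seed)
    synth$seed <- as.integer(seed)
  }
  structure(list(cohort_path = cohort_path, trajectories_dir = trajectories_dir,
                 synth = synth, priors = priors, sampler = sampler, rope = rope,
                 reference_diagnosis = reference_diagnosis,
                 reference_novelty = reference_novelty,
                 covariates = covariates, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.contrast_report <- function(ct) {
  list(b = ct$b, hdi = c(ct$hdi$lower, ct$hdi$upper),
       pct_outside_rope = ct$rope$pct_outside, verdict = ct$verdict$verdict)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort assembly (loaded or simulated), trajectory
#' parsing and tile metrics when a trajectory directory is given, the main
#' novelty x diagnosis model with its four contrasts, one covariate
#' interaction model per available control variable, the two-way ANOVAs of
#' the control variables, and report assembly. Fully deterministic under
#' the configured seeds; every exclusion is logged.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list (also written as JSON/markdown plus CSV
#'   draw files and TSV occupancy maps when `out_dir` is set): main-model
#'   decision table, covariate tables, ANOVA tables, convergence summary
#'   and run metadata (seed, config hash, versions).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

  # --- cohort assembly -----------------------------------------------------
  if (is.null(config$cohort_path)) {
    say("simulating cohort (seed ", config$synth$seed, ")")
    sim <- generate_cohort(config$synth)
    cohort <- sim$cohort
  } else {
    say("loading cohort from ", config$cohort_path)
    cohort <- load_cohort(config$cohort_path)
  }

  # --- telemetry -----------------------------------------------------------
  occupancy <- NULL
  if (!is.null(config$trajectories_dir)) {
    files <- list.files(config$trajectories_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("pipeline stage telemetry: no trajectory CSVs in ",
                                  config$trajectories_dir)
    say("parsing ", length(files), " trajectory log(s)")
    logs <- lapply(files, parse_trajectory)
    names(logs) <- vapply(logs, attr, "", "participant_id")
    tiles <- vapply(logs, function(lg) unique_tile_count(tile_visits(lg)), 0L)
    matched <- intersect(names(tiles), cohort$id)
    if (length(matched) < length(tiles)) {
      warning("telemetry: ", length(tiles) - length(matched),
              " log(s) with no matching cohort id")
    }
    cohort$exploration_tiles[match(matched, cohort$id)] <- tiles[matched]
    novel_ids <- cohort$id[cohort$novelty == "novel"]
    logs_novel <- logs[names(logs) %in% novel_ids]
    logs_familiar <- logs[!names(logs) %in% novel_ids]
    if (length(logs_novel) > 0L && length(logs_familiar) > 0L) {
      occupancy <- occupancy_difference_map(logs_novel, logs_familiar)
    }
  }

  # --- main model ----------------------------------------------------------
  say("fitting main model (retention ~ novelty x diagnosis)")
  main <- fit_main_model(cohort, config$priors, config$sampler, config$rope,
                         config$reference_diagnosis, config$reference_novelty)

  # --- covariate models and ANOVAs ----------------------------------------
  covariate_results <- list()
  anova_results <- list()
  for (cv in config$covariates) {
    if (all(is.na(cohort[[cv]]))) {
      say("skipping ", cv, ": no data")
      next
    }
    say("fitting covariate model for ", cv)
    covariate_results[[cv]] <- fit_covariate_model(
      cohort, cv, config$priors, config$sampler, config$rope,
      config$reference_diagnosis, config$reference_novelty)
    anova_results[[cv]] <- two_way_anova(cohort[[cv]], cohort$diagnosis,
                                         cohort$novelty)
  }

  # --- report assembly -----------------------------------------------------
  analysis_settings <- config[c("synth", "priors", "sampler", "rope",
                                "reference_diagnosis", "reference_novelty",
                                "covariates", "cohort_path", "trajectories_dir")]
  report <- list(
    metadata = list(
      seed = config$sampler$base_seed,
      config_hash = .config_hash(analysis_settings),
      rope = config$rope,
      n_chains = config$sampler$n_chains,
      n_samples_per_chain = config$sampler$n_samples_per_chain,
      n_warmup = config$sampler$n_warmup,
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("noveltag")),
      n_participants = nrow(cohort),
      cell_sizes = as.list(cell_sizes(cohort))
    ),
    main_model = list(
      n = main$n,
      groups = lapply(main$groups, function(g)
        list(mean = g$mean, hdi = c(g$hdi$lower, g$hdi$upper))),
      contrasts = lapply(main$contrasts, .contrast_report),
      convergence = list(pass = main$convergence$pass,
                         max_rhat = max(main$convergence$table$rhat))
    ),
    covariate_models = lapply(covariate_results, function(cm) {
      list(
        n = cm$n,
        cells = lapply(cm$cell_stats, function(st)
          list(mean = st[["mean"]], sd = st[["sd"]], n = st[["n"]])),
        slopes = lapply(cm$slopes, function(s)
          list(b = s$b, hdi = c(s$hdi$lower, s$hdi$upper),
               pct_outside_rope = s$pct_outside_rope,
               verdict = s$verdict$verdict)),
        slope_contrast = c(list(cells = cm$contrast_cells),
                           .contrast_report(cm$slope_contrast)),
        convergence = list(pass = cm$convergence$pass,
                           max_rhat = max(cm$convergence$table$rhat))
      )
    }),
    anovas = lapply(anova_results, function(at) {
      lapply(seq_len(nrow(at)), function(i)
        list(effect = at$effect[i], ss = at$ss[i],
             df = c(at$df[i], attr(at, "residual_df")),
             F = at$F[i], p = at$p[i], partial_eta_sq = at$partial_eta_sq[i]))
    })
  )

  bundle <- structure(list(report = report, cohort = cohort, main = main,
                           covariate_models = covariate_results,
                           anovas = anova_results, occupancy = occupancy),
                      class = "report_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(render_report_md(bundle), file.path(config$out_dir, "report.md"))
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    export_draws(main$draws, file.path(config$out_dir, "draws_main.csv"))
    for (cv in names(covariate_results)) {
      export_draws(covariate_results[[cv]]$draws,
                   file.path(config$out_dir, paste0("draws_", cv, ".csv")))
      write_anova_table(anova_results[[cv]],
                        file.path(config$out_dir, paste0("anova_", cv, ".csv")))
    }
    if (!is.null(occupancy)) {
      write_occupancy_map(occupancy,
                          file.path(config$out_dir, "occupancy_novel_vs_familiar.tsv"))
    }
    say("report written to ", config$out_dir)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}

#' Render a report bundle as markdown
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of markdown lines mirroring the decision and
#'   covariate tables.
#' @export
render_report_md <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  r <- bundle$report
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  lines <- c(
    "# Behavioral-tagging analysis report",
    "",
    sprintf("Seed %d, config %s, %d participants; ROPE [%g, %g]; %d chains x %d draws (%d warm-up).",
            r$metadata$seed, r$metadata$config_hash, r$metadata$n_participants,
            r$metadata$rope[1], r$metadata$rope[2], r$metadata$n_chains,
            r$metadata$n_samples_per_chain, r$metadata$n_warmup),
    "",
    "## Main model: retention ~ novelty x diagnosis",
    "",
    "| Contrast | b | 95% HDI | % outside ROPE | Verdict |",
    "|---|---|---|---|---|"
  )
  for (nm in names(r$main_model$contrasts)) {
    ct <- r$main_model$contrasts[[nm]]
    lines <- c(lines, sprintf("| %s | %s | [%s, %s] | %s | %s |",
                              nm, fmt(ct$b), fmt(ct$hdi[1]), fmt(ct$hdi[2]),
                              fmt(ct$pct_outside_rope), ct$verdict))
  }
  for (cv in names(r$covariate_models)) {
    cm <- r$covariate_models[[cv]]
    lines <- c(lines, "",
               sprintf("## Control variable: %s (n = %d)", cv, cm$n), "",
               "| Group | Mean (SD) | Slope b | 95% HDI | % outside ROPE |",
               "|---|---|---|---|---|")
    for (cell in names(cm$slopes)) {
      s <- cm$slopes[[cell]]
      st <- cm$cells[[cell]]
      lines <- c(lines, sprintf("| %s | %s (%s) | %s | [%s, %s] | %s |",
                                cell, fmt(st$mean), fmt(st$sd), fmt(s$b),
                                fmt(s$hdi[1]), fmt(s$hdi[2]),
                                fmt(s$pct_outside_rope)))
    }
    sc <- cm$slope_contrast
    lines <- c(lines, "",
               sprintf("Slope contrast %s vs %s: b_delta = %s, 95%% HDI [%s, %s], %s%% outside ROPE (%s).",
                       sc$cells[1], sc$cells[2], fmt(sc$b), fmt(sc$hdi[1]),
                       fmt(sc$hdi[2]), fmt(sc$pct_outside_rope), sc$verdict))
  }
  if (length(r$anovas) > 0L) {
    lines <- c(lines, "", "## Two-way ANOVAs of control variables", "",
               "| Variable | Effect | F | df | p | partial eta^2 |",
               "|---|---|---|---|---|---|")
    for (cv in names(r$anovas)) {
      for (row in r$anovas[[cv]]) {
        lines <- c(lines, sprintf("| %s | %s | %s | (%d, %d) | %s | %s |",
                                  cv, row$effect, fmt(row$F), row$df[1], row$df[2],
                                  formatC(row$p, format = "g", digits = 3),
                                  fmt(row$partial_eta_sq)))
      }
    }
  }
  lines
}
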