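#' Two-way factorial ANOVA with partial eta squared
#'
#' Fits `values ~ diagnosis * novelty` with sum-to-zero factor coding and
#' reports Type III sums of squares (identical to sequential sums in
#' balanced designs, the appropriate choice for the mildly unbalanced
#' cells that listwise exclusions leave), F tests against the residual
#' mean square with both degrees of freedom, and partial eta squared
#' `SS_effect / (SS_effect + SS_residual)` per effect.
#'
#' @param values Numeric response (one of the control variables).
#' @param diagnosis,novelty Factor sequences (two levels each observed).
#' @param ss_type `"III"` (default) or `"II"` for a sensitivity check.
#' @return An `anova_table`: data frame with one row per effect
#'   (`diagnosis`, `novelty`, `diagnosis:novelty`) carrying `ss`, `df`,
#'   `F`, `p`, `partial_eta_sq`, plus attributes `residual_ss`,
#'   `residual_df` and the per-cell counts.
#' @export
two_way_anova <- function(values, diagnosis, novelty, ss_type = c("III", "II")) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.numeric(values), length(diagnosis) == length(values),
            length(novelty) == length(values))
  keep <- stats::complete.cases(values, diagnosis, novelty)
  values <- values[keep]
  diagnosis <- factor(as.character(diagnosis[keep]))
  novelty <- factor(as.character(novelty[keep]))
  if (nlevels(diagnosis) != 2L || nlevels(novelty) != 2L) {
    stop("both factors must have exactly two observed levels")
  }
  cells <- table(diagnosis, novelty)
  if (any(cells < 2)) stop("need at least 2 observations per cell")
  if (stats::sd(values) == 0) stop("constant response")

  df <- data.frame(y = values, diagnosis = diagnosis, novelty = novelty)
  fit <- stats::lm(y ~ diagnosis * novelty, data = df,
                   contrasts = list(diagnosis = stats::contr.sum,
                                    novelty = stats::contr.sum))
  tab <- car::Anova(fit, type = ss_type)
  tab <- as.data.frame(tab)
  resid_row <- rownames(tab) == "Residuals"
  ss_res <- tab$`Sum Sq`[resid_row]
  df_res <- tab$Df[resid_row]
  effects <- c("diagnosis", "novelty", "diagnosis:novelty")
  eff <- tab[rownames(tab) %in% effects, , drop = FALSE]
  eff <- eff[effects, ]
  out <- data.frame(
    effect = effects,
    ss = eff$`Sum Sq`,
    df = eff$Df,
    F = eff$`F value`,
    p = eff$`Pr(>F)`,
    partial_eta_sq = eff$`Sum Sq` / (eff$`Sum Sq` + ss_res),
    row.names = NULL
  )
  structure(out, class = c("anova_table", "data.frame"),
            residual_ss = ss_res, residual_df = df_res,
            cell_counts = cells, ss_type = ss_type)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (Type", attr(x, "ss_type"), "SS), residual df =",
      attr(x, "residual_df"), "\n")
  tab <- as.data.frame(x)
  tab$ss <- round(tab$ss, 2)
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA table as CSV
#'
#' @param table An [two_way_anova()] result.
#' @param path Output path; residual SS/df are appended as a final row.
#' @return Invisibly, `path`.
#' @export
write_anova_table <- function(table, path) {
  stopifnot(inherits(table, "anova_table"))
  out <- as.data.frame(table)
  out <- rbind(out, data.frame(effect = "residuals", ss = attr(table, "residual_ss"),
                               df = attr(table, "residual_df"), F = NA, p = NA,
                               partial_eta_sq = NA))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
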