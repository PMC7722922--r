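DIAGNOSIS_LEVELS <- c("ADHD", "TD")
NOVELTY_LEVELS <- c("familiar", "novel")
ENVIRONMENT_LEVELS <- c("mansion", "island")
WORD_LIST_LENGTH <- 20L

COHORT_COLUMNS <- c(
  "id", "diagnosis", "novelty", "stm_hits", "ltm_hits", "retention",
  "novelty_seeking", "immersion", "exploration_tiles", "environment"
)

#' Retention score from free-recall hit counts
#'
#' The percentage of initially recalled words retained over 24 h:
#' `ltm_hits / stm_hits * 100`. Values above 100 (more words recalled after
#' the delay than immediately) are permitted and not clipped.
#'
#' @param stm_hits Integer count of words recalled immediately (0--20).
#' @param ltm_hits Integer count of words recalled after 24 h (0--20).
#' @return Retention in percent. Vectorised over both arguments.
#' @examples
#' compute_retention(10, 5)   # 50
#' compute_retention(8, 10)   # 125, hypermnesia is kept as-is
#' @export
compute_retention <- function(stm_hits, ltm_hits) {
  stopifnot(is.numeric(stm_hits), is.numeric(ltm_hits))
  if (any(stm_hits < 0 | stm_hits > WORD_LIST_LENGTH, na.rm = TRUE) ||
      any(ltm_hits < 0 | ltm_hits > WORD_LIST_LENGTH, na.rm = TRUE)) {
    stop("hit counts must lie in 0..", WORD_LIST_LENGTH,
         " (word list has ", WORD_LIST_LENGTH, " items)")
  }
  if (any(stm_hits == 0, na.rm = TRUE)) {
    stop("retention is undefined when stm_hits = 0; exclude the record")
  }
  ltm_hits / stm_hits * 100
}

#' Construct a validated cohort table
#'
#' A `cohort_table` is a data frame of one row per participant carrying the
#' two design factors (diagnosis ADHD/TD, novelty familiar/novel), the
#' STM/LTM free-recall hit counts, the derived retention score and the
#' optional control covariates. Retention is always recomputed from the
#' counts, never taken on trust.
#'
#' @param records Data frame with at least columns `id`, `diagnosis`,
#'   `novelty`, `stm_hits`, `ltm_hits`. Optional: `novelty_seeking`,
#'   `immersion`, `exploration_tiles`, `environment`. Extra columns are
#'   dropped.
#' @param provenance Character tag recording where the cohort came from
#'   (file path or generator seed).
#' @return A `cohort_table` (data frame subclass) with recomputed
#'   `retention` and factor-encoded design columns.
#' @export
cohort_table <- function(records, provenance = "constructed") {
  stopifnot(is.data.frame(records))
  required <- c("id", "diagnosis", "novelty", "stm_hits", "ltm_hits")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("empty cohort")
  out <- data.frame(
    id = as.character(records$id),
    diagnosis = factor(as.character(records$diagnosis), levels = DIAGNOSIS_LEVELS),
    novelty = factor(as.character(records$novelty), levels = NOVELTY_LEVELS),
    stm_hits = as.integer(records$stm_hits),
    ltm_hits = as.integer(records$ltm_hits),
    stringsAsFactors = FALSE
  )
  for (col in c("novelty_seeking", "immersion")) {
    out[[col]] <- if (col %in% names(records)) as.numeric(records[[col]]) else NA_real_
  }
  out$exploration_tiles <- if ("exploration_tiles" %in% names(records)) {
    as.integer(records$exploration_tiles)
  } else NA_integer_
  out$environment <- if ("environment" %in% names(records)) {
    factor(as.character(records$environment), levels = ENVIRONMENT_LEVELS)
  } else factor(rep(NA_character_, nrow(out)), levels = ENVIRONMENT_LEVELS)

  bad_factor <- is.na(out$diagnosis) | is.na(out$novelty)
  if (any(bad_factor)) {
    warning(sum(bad_factor), " row(s) dropped: unparseable diagnosis/novelty")
    out <- out[!bad_factor, , drop = FALSE]
  }
  bad_counts <- is.na(out$stm_hits) | is.na(out$ltm_hits) |
    out$stm_hits < 0L | out$stm_hits > WORD_LIST_LENGTH |
    out$ltm_hits < 0L | out$ltm_hits > WORD_LIST_LENGTH
  if (any(bad_counts)) {
    warning(sum(bad_counts), " row(s) dropped: hit counts missing or outside 0..",
            WORD_LIST_LENGTH)
    out <- out[!bad_counts, , drop = FALSE]
  }
  zero_stm <- out$stm_hits == 0L
  if (any(zero_stm)) {
    warning(sum(zero_stm), " row(s) dropped: stm_hits = 0 leaves retention undefined (",
            paste(out$id[zero_stm], collapse = ", "), ")")
    out <- out[!zero_stm, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no valid rows left in cohort")
  if (anyDuplicated(out$id)) stop("participant ids must be unique")
  if (any(out$immersion < -30 | out$immersion > 30, na.rm = TRUE)) {
    stop("immersion scores must lie in [-30, 30]")
  }
  if (any(out$exploration_tiles < 0L, na.rm = TRUE)) {
    stop("exploration_tiles must be nonnegative")
  }
  out$retention <- compute_retention(out$stm_hits, out$ltm_hits)
  out <- out[COHORT_COLUMNS]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort of", nrow(x), "participants (", attr(x, "provenance"), ")\n")
  tab <- table(diagnosis = x$diagnosis, novelty = x$novelty)
  print(tab)
  cat("Retention: mean", round(mean(x$retention), 1), "%, range [",
      round(min(x$retention), 1), ",", round(max(x$retention), 1), "]\n")
  invisible(x)
}

#' Per-cell sample sizes of a cohort
#'
#' @param cohort A [cohort_table()].
#' @return Named integer vector over the four diagnosis x novelty cells.
#' @export
cell_sizes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  tab <- table(cohort$diagnosis, cohort$novelty)
  out <- as.integer(tab)
  names(out) <- paste(rep(rownames(tab), ncol(tab)),
                      rep(colnames(tab), each = nrow(tab)), sep = "-")
  out
}

#' Read a cohort CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' `id, diagnosis, novelty, stm_hits, ltm_hits` plus the optional covariate
#' columns. Empty cells are missing values. Rows with `stm_hits = 0` or
#' undecodable factor levels are dropped with a warning; the retention
#' column, if present in the file, is ignored and recomputed from the
#' counts.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(stm_hits = "recall_day1")`.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty cohort file: ", path)
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(raw)) {
        stop("schema maps ", canon, " to absent column ", file_col)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  cohort_table(raw, provenance = path)
}

#' Write a cohort CSV
#'
#' Inverse of [load_cohort()]: writes the canonical column set with missing
#' cells as empty strings. Numeric covariates are written at full precision
#' so that a write/load round trip reproduces every field (integers exactly,
#' reals to better than 1e-9).
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) == 0L) stop("refusing to write an empty cohort")
  out <- as.data.frame(cohort)
  for (col in c("retention", "novelty_seeking", "immersion")) {
    out[[col]] <- trimws(formatC(out[[col]], digits = 15, format = "g"))
    out[[col]][out[[col]] == "NA"] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
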