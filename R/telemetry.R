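#' Parse an avatar position log
#'
#' Reads a CSV of avatar positions logged nominally every 100 ms with
#' header `t_ms,x,y,z` (milliseconds, Minecraft block units). Rows that are
#' non-numeric or break the strictly increasing timestamp order are dropped
#' with a warning. A median inter-sample gap outside [50, 200] ms triggers a
#' warning (the logger is expected to run at 10 Hz) but is not an error.
#'
#' @param path Path to the trajectory CSV.
#' @param participant_id Identifier attached to the log; defaults to the
#'   file name without extension.
#' @param environment Optional environment tag, `"mansion"` or `"island"`.
#' @return A `trajectory_log`: data frame with columns `t_ms, x, y, z`,
#'   attributes `participant_id` and `environment`.
#' @export
parse_trajectory <- function(path, participant_id = NULL, environment = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty trajectory file: ", path)
  need <- c("t_ms", "x", "y", "z")
  if (!all(need %in% names(raw))) {
    stop("trajectory file must have columns t_ms,x,y,z")
  }
  raw <- raw[need]
  num <- vapply(raw, function(col) suppressWarnings(as.numeric(col)), numeric(nrow(raw)))
  num <- matrix(num, ncol = 4L, dimnames = list(NULL, need))
  bad <- rowSums(is.na(num)) > 0L
  if (any(bad)) {
    warning(sum(bad), " non-numeric row(s) skipped in ", path)
    num <- num[!bad, , drop = FALSE]
  }
  if (nrow(num) == 0L) stop("no numeric samples in ", path)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  trajectory_log(as.data.frame(num), participant_id = participant_id,
                 environment = environment)
}

#' Construct a trajectory log from samples in memory
#'
#' @param samples Data frame with numeric columns `t_ms, x, y, z`, one row
#'   per position sample.
#' @param participant_id Identifier for the participant.
#' @param environment Optional `"mansion"` or `"island"` tag.
#' @return A `trajectory_log` with strictly increasing timestamps
#'   (violating rows dropped with a warning).
#' @export
trajectory_log <- function(samples, participant_id = "anonymous",
                           environment = NA_character_) {
  stopifnot(is.data.frame(samples), all(c("t_ms", "x", "y", "z") %in% names(samples)))
  if (nrow(samples) == 0L) stop("empty trajectory")
  samples <- samples[c("t_ms", "x", "y", "z")]
  keep <- samples$t_ms > c(-Inf, cummax(samples$t_ms)[-nrow(samples)])
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped: timestamps not strictly increasing")
    samples <- samples[keep, , drop = FALSE]
  }
  if (nrow(samples) > 1L) {
    med_gap <- stats::median(diff(samples$t_ms))
    if (med_gap < 50 || med_gap > 200) {
      warning("median inter-sample gap ", med_gap,
              " ms outside the nominal 100 ms regime [50, 200]")
    }
  }
  rownames(samples) <- NULL
  if (!is.na(environment)) environment <- match.arg(environment, ENVIRONMENT_LEVELS)
  structure(samples, participant_id = as.character(participant_id),
            environment = environment,
            class = c("trajectory_log", "data.frame"))
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat("Trajectory of", attr(x, "participant_id"), "-", nrow(x), "samples")
  if (!is.na(attr(x, "environment"))) cat(" (", attr(x, "environment"), ")", sep = "")
  cat(", t in [", min(x$t_ms), ",", max(x$t_ms), "] ms\n")
  invisible(x)
}

#' Write a trajectory log as CSV
#'
#' @param log A `trajectory_log`.
#' @param path Output path; columns `t_ms,x,y,z`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(log, path) {
  stopifnot(inherits(log, "trajectory_log"))
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tiles visited by a trajectory
#'
#' Projects each sample onto the horizontal (x, z) plane, ignores altitude,
#' and bins positions into square tiles of `tile_size` blocks anchored at
#' the world origin: a sample at (x, z) falls in tile
#' `(floor(x / tile_size), floor(z / tile_size))`. Negative coordinates map
#' to negative tile indices.
#'
#' @param log A `trajectory_log`.
#' @param tile_size Tile side length in blocks (default 2, the 2x2-block
#'   convention).
#' @param y_band Optional numeric length-2 vector; when given, only samples
#'   with `y` inside `[y_band[1], y_band[2])` are counted (per-floor view).
#' @return A `tile_visit_set`: list with `tile_size`, `visited` (data frame
#'   of unique integer tile indices `i`, `j`) and `per_tile_counts` (sample
#'   count per visited tile).
#' @export
tile_visits <- function(log, tile_size = 2, y_band = NULL) {
  stopifnot(inherits(log, "trajectory_log"), tile_size >= 1)
  df <- as.data.frame(log)
  if (!is.null(y_band)) {
    stopifnot(length(y_band) == 2L, y_band[1] < y_band[2])
    df <- df[df$y >= y_band[1] & df$y < y_band[2], , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    tiles <- data.frame(i = integer(0), j = integer(0))
    counts <- integer(0)
  } else {
    i <- as.integer(floor(df$x / tile_size))
    j <- as.integer(floor(df$z / tile_size))
    key <- paste(i, j, sep = ",")
    counts <- table(key)
    first <- !duplicated(key)
    tiles <- data.frame(i = i[first], j = j[first])
    counts <- as.integer(counts[paste(tiles$i, tiles$j, sep = ",")])
  }
  structure(
    list(tile_size = tile_size, visited = tiles, per_tile_counts = counts,
         participant_id = attr(log, "participant_id"),
         environment = attr(log, "environment")),
    class = "tile_visit_set"
  )
}

#' @export
print.tile_visit_set <- function(x, ...) {
  cat("Tile visits (", x$tile_size, "x", x$tile_size, " blocks): ",
      nrow(x$visited), " unique tiles, ", sum(x$per_tile_counts),
      " samples\n", sep = "")
  invisible(x)
}

#' Exploration score: number of unique tiles entered
#'
#' @param visits A [tile_visits()] result.
#' @return Integer count of distinct tiles; the study's exploration metric.
#' @export
unique_tile_count <- function(visits) {
  stopifnot(inherits(visits, "tile_visit_set"))
  nrow(visits$visited)
}

#' Group occupancy difference map
#'
#' For every tile, the number of distinct participants in group A whose
#' trajectory entered it minus the same count for group B (each participant
#' contributes at most 1 per tile). Positive values mark tiles favoured by
#' group A; the map of (A, B) is the exact negative of the map of (B, A).
#'
#' @param logs_a,logs_b Nonempty lists of `trajectory_log`s from the same
#'   environment.
#' @param tile_size Tile side length in blocks (default 2).
#' @return An `occupancy_map`: integer matrix with tile i-indices as rows
#'   and j-indices as columns, plus attributes `n_a`, `n_b` and the index
#'   extents.
#' @export
occupancy_difference_map <- function(logs_a, logs_b, tile_size = 2) {
  stopifnot(is.list(logs_a), is.list(logs_b),
            length(logs_a) > 0L, length(logs_b) > 0L)
  all_logs <- c(logs_a, logs_b)
  envs <- unique(stats::na.omit(vapply(all_logs, attr, "", "environment")))
  if (length(envs) > 1L) {
    stop("mixed environments in occupancy map: ", paste(envs, collapse = ", "))
  }
  visit_tiles <- function(log) unique(tile_visits(log, tile_size)$visited)
  tiles_a <- lapply(logs_a, visit_tiles)
  tiles_b <- lapply(logs_b, visit_tiles)
  all_tiles <- unique(do.call(rbind, c(tiles_a, tiles_b)))
  ir <- range(all_tiles$i); jr <- range(all_tiles$j)
  m <- matrix(0L, nrow = ir[2] - ir[1] + 1L, ncol = jr[2] - jr[1] + 1L,
              dimnames = list(as.character(ir[1]:ir[2]), as.character(jr[1]:jr[2])))
  add <- function(m, tiles, sign) {
    idx <- cbind(tiles$i - ir[1] + 1L, tiles$j - jr[1] + 1L)
    m[idx] <- m[idx] + sign
    m
  }
  for (tl in tiles_a) m <- add(m, tl, 1L)
  for (tl in tiles_b) m <- add(m, tl, -1L)
  structure(m, class = c("occupancy_map", "matrix"),
            tile_size = tile_size, n_a = length(logs_a), n_b = length(logs_b),
            i_range = ir, j_range = jr)
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat("Occupancy difference map: ", nrow(x), "x", ncol(x), " tiles (size ",
      attr(x, "tile_size"), "), groups of ", attr(x, "n_a"), " vs ",
      attr(x, "n_b"), ", values in [", min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}

#' Export an occupancy map as TSV plus a JSON sidecar of extents
#'
#' @param map An [occupancy_difference_map()] result.
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_occupancy_map <- function(map, path) {
  stopifnot(inherits(map, "occupancy_map"))
  utils::write.table(as.matrix(unclass(map)), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  meta <- list(tile_size = attr(map, "tile_size"),
               i_range = attr(map, "i_range"), j_range = attr(map, "j_range"),
               n_a = attr(map, "n_a"), n_b = attr(map, "n_b"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
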