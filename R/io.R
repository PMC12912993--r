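#' Read and write function-abundance tables
#'
#' Abundance tables are plain CSV with mandatory header `label,count`,
#' UTF-8, one row per function, counts positive integers, row order
#' preserved.  Parse errors name the offending row.
#'
#' @param path File path.
#' @return `read_abundance_table()` returns a [function_tally()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_abundance_table(function_tally(c(5, 3), c("A", "B")), f)
#' read_abundance_table(f)
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(header), c("label", "count"))) {
    stop("expected header 'label,count' in ", path)
  }
  df <- read.csv(path, header = TRUE, colClasses = c("character", "numeric"),
                 fileEncoding = "UTF-8")
  if (nrow(df) < 1) stop("no data rows in ", path)
  bad <- which(!is.finite(df$count) | df$count < 1 |
                 df$count != round(df$count))
  if (length(bad)) {
    stop(sprintf("row %d of %s: count must be a positive integer (got %s)",
                 bad[1], path, format(df$count[bad[1]])))
  }
  dup <- which(duplicated(df$label))
  if (length(dup)) {
    stop(sprintf("row %d of %s: duplicate label '%s'",
                 dup[1], path, df$label[dup[1]]))
  }
  function_tally(df$count, labels = df$label)
}

#' @rdname read_abundance_table
#' @param tally A [function_tally()].
#' @return `write_abundance_table()` returns `path` invisibly.
#' @export
write_abundance_table <- function(tally, path) {
  stopifnot(inherits(tally, "function_tally"))
  df <- data.frame(label = tally$labels, count = tally$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write diversity-size tables
#'
#' CSV with header `system,N,D`, one row per system.
#'
#' @param path File path.
#' @return `read_diversity_table()` returns a validated data.frame.
#' @export
read_diversity_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (!all(c("system", "N", "D") %in% names(df))) {
    stop("expected header 'system,N,D' in ", path)
  }
  as_diversity_size_table(df, min_records = 1)
}

#' @rdname read_diversity_table
#' @param table A diversity-size data.frame (`system`, `N`, `D`).
#' @export
write_diversity_table <- function(table, path) {
  table <- as_diversity_size_table(table, min_records = 1)
  write.csv(table[, c("system", "N", "D")], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an ensemble trajectory table with a JSON sidecar
#'
#' Writes the checkpointed `(replicate, N, D)` records of a
#' [simulate_ensemble()] result as CSV, plus a `<path>.json` sidecar
#' recording the parameters, master seed, and checkpoint schedule for a
#' full reproducibility audit.
#'
#' @param ensemble A `growth_ensemble`.
#' @param path Output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "growth_ensemble"))
  rows <- do.call(rbind, lapply(seq_along(ensemble$trajectories), function(r) {
    cp <- ensemble$trajectories[[r]]$checkpoints
    data.frame(replicate = r, N = cp$N, D = cp$D)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  sidecar <- list(
    params = unclass(ensemble$params),
    master_seed = ensemble$master_seed,
    replicates = length(ensemble$trajectories),
    checkpoints = ensemble$trajectories[[1]]$checkpoints$N,
    child_seeds = vapply(ensemble$trajectories, function(tr) tr$seed,
                         integer(1)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return `read_trajectory_csv()` returns the `(replicate, N, D)`
#'   data.frame.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (!all(c("replicate", "N", "D") %in% names(df))) {
    stop("expected header 'replicate,N,D' in ", path)
  }
  df
}

#' Write a rank-frequency distribution as CSV
#'
#' Header `rank,frequency`, ranks 1-based, frequencies in decreasing
#' order.
#'
#' @param rf A [compute_rank_frequency()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_frequency_csv <- function(rf, path) {
  stopifnot(inherits(rf, "rank_frequency"))
  df <- data.frame(rank = seq_along(rf$frequencies),
                   frequency = rf$frequencies)
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
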