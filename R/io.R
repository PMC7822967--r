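#' Read and write amplitude tables as CSV
#'
#' Long-format schema: `cell_id`, `frequency_hz`, `repeat` (1-based),
#' `pulse_index` (1-based), `amplitude_pa`. One file may hold several
#' cells and frequencies; reading returns one [amplitude_table()] per
#' (cell, frequency) combination. Missing (repeat, pulse) cells become NA
#' entries, which the train statistics skip.
#'
#' @param path File path.
#' @return `read_amplitude_csv()` returns a named list of
#'   [amplitude_table()]s (names `cell_id@frequency_hz`);
#'   `write_amplitude_csv()` returns `path` invisibly.
#' @export
read_amplitude_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[names(df) == "repeat"] <- "repeat_id"
  stop_missing_cols(df, c("cell_id", "frequency_hz", "repeat_id", "pulse_index",
                          "amplitude_pa"),
                    "amplitude CSV")
  if (min(df$pulse_index) < 1L || min(df$repeat_id) < 1L) {
    stop("repeat and pulse_index must be 1-based", call. = FALSE)
  }
  groups <- split(df, interaction(df$cell_id, df$frequency_hz, drop = TRUE))
  out <- lapply(groups, function(g) {
    nr <- max(g$repeat_id)
    np <- max(g$pulse_index)
    a <- matrix(NA_real_, nr, np)
    a[cbind(g$repeat_id, g$pulse_index)] <- g$amplitude_pa
    amplitude_table(a, frequency_hz = g$frequency_hz[1L],
                    cell_id = as.character(g$cell_id[1L]))
  })
  names(out) <- vapply(out, function(tb) {
    sprintf("%s@%g", tb$cell_id, tb$frequency_hz)
  }, "")
  out
}

#' @rdname read_amplitude_csv
#' @param tables An [amplitude_table()] or list of them.
#' @export
write_amplitude_csv <- function(tables, path) {
  if (inherits(tables, "amplitude_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "amplitude_table")))
  rows <- do.call(rbind, lapply(tables, function(tb) {
    a <- tb$amplitudes
    df <- expand.grid(repeat_id = seq_len(nrow(a)),
                      pulse_index = seq_len(ncol(a)))
    df$cell_id <- tb$cell_id
    df$frequency_hz <- tb$frequency_hz
    df$amplitude_pa <- a[cbind(df$repeat_id, df$pulse_index)]
    df[!is.na(df$amplitude_pa),
       c("cell_id", "frequency_hz", "repeat_id", "pulse_index", "amplitude_pa")]
  }))
  names(rows)[names(rows) == "repeat_id"] <- "repeat"
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write recovery-pair data as CSV
#'
#' Schema: `cell_id`, `interval_ms`, `repeat` (1-based), `p1_pa`, `p2_pa`.
#'
#' @param path File path.
#' @return `read_recovery_csv()` returns a data.frame in that schema;
#'   `write_recovery_csv()` returns `path` invisibly.
#' @export
read_recovery_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[names(df) == "repeat"] <- "repeat_id"
  stop_missing_cols(df, c("cell_id", "interval_ms", "repeat_id", "p1_pa", "p2_pa"),
                    "recovery CSV")
  if (min(df$repeat_id) < 1L) stop("repeat must be 1-based", call. = FALSE)
  names(df)[names(df) == "repeat_id"] <- "repeat"
  df
}

#' @rdname read_recovery_csv
#' @param recovery data.frame with columns `interval_ms`, `repeat`,
#'   `p1_pa`, `p2_pa` and optionally `cell_id`.
#' @param cell_id Cell id written when `recovery` lacks the column.
#' @export
write_recovery_csv <- function(recovery, path, cell_id = "synthetic") {
  if (!"cell_id" %in% names(recovery)) recovery$cell_id <- cell_id
  stop_missing_cols(recovery, c("cell_id", "interval_ms", "repeat", "p1_pa", "p2_pa"),
                    "recovery data")
  utils::write.csv(
    recovery[, c("cell_id", "interval_ms", "repeat", "p1_pa", "p2_pa")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a raw current trace
#'
#' Two-column delimited text (`time_ms`, `current_pa`), with an optional
#' JSON sidecar (same path plus `.json`) holding `pulse_times_ms`.
#' Inward currents recorded as negative deflections are rectified to
#' positive magnitudes with `polarity = "negative"`.
#'
#' @param path Trace file path (CSV or whitespace-delimited; header
#'   optional).
#' @param polarity `"positive"` or `"negative"`: the sign of evoked
#'   deflections in the file.
#' @return A data.frame `time_ms`, `current_pa` (evoked deflections
#'   positive), with attribute `"pulse_times_ms"` when a sidecar exists.
#' @export
read_trace <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = has_header, sep = sep)
  if (ncol(df) < 2L) stop("trace file needs two columns", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("time_ms", "current_pa")
  if (polarity == "negative") df$current_pa <- -df$current_pa
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "pulse_times_ms") <- meta$pulse_times_ms
  }
  df
}

#' Convert an experiment dataset's recovery pairs to release probabilities
#'
#' Divides the observed P1/P2 amplitudes by `n_sites * q_pa` and averages
#' across repeats, producing the `recovery` data.frame that
#' [assemble_fit_dataset()] expects.
#'
#' @param recovery data.frame with `interval_ms`, `p1_pa`, `p2_pa`.
#' @param n_sites,q_pa Quantal parameters defining the maximum response.
#' @return data.frame with `interval_ms`, `p1`, `p2` (one row per
#'   interval, repeat-averaged).
#' @export
recovery_pr <- function(recovery, n_sites, q_pa) {
  stop_missing_cols(recovery, c("interval_ms", "p1_pa", "p2_pa"),
                    "recovery data")
  stopifnot(is_scalar_num(n_sites), n_sites > 0, is_scalar_num(q_pa), q_pa > 0)
  agg <- stats::aggregate(cbind(p1_pa, p2_pa) ~ interval_ms, data = recovery,
                          FUN = mean)
  data.frame(
    interval_ms = agg$interval_ms,
    p1 = agg$p1_pa / (n_sites * q_pa),
    p2 = agg$p2_pa / (n_sites * q_pa)
  )
}
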