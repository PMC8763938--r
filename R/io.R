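# Plain-text I/O: CSV/TSV tables with YAML sidecar metadata, SWC
# morphologies, and schema-checked loading. Everything round-trips.

#' Write a modulated recording to CSV with a YAML sidecar
#'
#' One CSV column per sensor; `<path>.yaml` records `fs_raw`,
#' `start_time` and the carrier table.
#'
#' @param rec A [modulated_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "modulated_recording"))
  utils::write.csv(as.data.frame(rec$samples), path, row.names = FALSE)
  yaml::write_yaml(list(fs_raw = rec$fs_raw, start_time = rec$start_time,
                        carriers = list(freq = rec$carriers$freq,
                                        role = rec$carriers$role)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a modulated recording written by [write_recording()]
#'
#' @param path CSV path (expects `<path>.yaml` alongside).
#' @return A [modulated_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  df <- utils::read.csv(path, check.names = FALSE)
  modulated_recording(as.matrix(df), meta$fs_raw,
                      data.frame(freq = unlist(meta$carriers$freq),
                                 role = unlist(meta$carriers$role),
                                 stringsAsFactors = FALSE),
                      start_time = meta$start_time %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cell map as TSV
#'
#' @param cellmap Cell-map data frame.
#' @param path TSV path.
#' @return `path` / the validated cell map.
#' @export
write_cellmap <- function(cellmap, path) {
  validate_cellmap(cellmap)
  utils::write.table(cellmap, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cellmap
#' @export
read_cellmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path)
  req <- c("radial", "longitudinal")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("cell map is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(df$radial < 0 | df$radial > 1 |
                 df$longitudinal < 0 | df$longitudinal > 1)
  if (length(bad)) {
    stop("cell map row ", bad[1], ": coordinates outside [0, 1]")
  }
  for (nm in setdiff(names(df), c("slice", req))) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  df
}

#' Write / read an event table as TSV
#'
#' @param events An [event_table()].
#' @param path TSV path.
#' @return `path` / an [event_table()].
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path)
  if (!all(c("time", "type") %in% names(df))) {
    stop("event table needs 'time' and 'type' columns")
  }
  event_table(df$time, df$type,
              animal = if ("animal" %in% names(df)) df$animal else NULL)
}

#' Write / read a sweep set as wide CSV with a YAML sidecar
#'
#' Columns: `time` plus one column per sweep; the sidecar holds `fs`,
#' `onset`, `holding`, `baseline_window` and the per-sweep metadata.
#'
#' @param ss A [sweep_set()].
#' @param path CSV path.
#' @return `path` / a [sweep_set()].
#' @export
write_sweeps <- function(ss, path) {
  stopifnot(inherits(ss, "sweep_set"))
  df <- data.frame(time = (seq_len(ncol(ss$sweeps)) - 1) / ss$fs)
  for (i in seq_len(nrow(ss$sweeps))) {
    df[[paste0("sweep", i)]] <- ss$sweeps[i, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(fs = ss$fs, onset = ss$onset, holding = ss$holding,
                        baseline_window = ss$baseline_window,
                        sweep_info = as.list(ss$sweep_info)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.csv(path)
  sweeps <- t(as.matrix(df[, -1, drop = FALSE]))
  info <- if (length(meta$sweep_info)) {
    as.data.frame(meta$sweep_info)
  } else NULL
  sweep_set(sweeps, fs = meta$fs, onset = meta$onset,
            holding = meta$holding %||% NA_real_, sweep_info = info,
            baseline_window = meta$baseline_window %||% 0.05)
}

#' Write / read a position track as CSV
#'
#' @param track Data frame `t`, `x`, `y`.
#' @param path CSV path.
#' @return `path` / the track data frame.
#' @export
write_track <- function(track, path) {
  stopifnot(all(c("t", "x", "y") %in% names(track)))
  utils::write.csv(track[, c("t", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("t", "x", "y") %in% names(df))) {
    stop("track needs 't', 'x', 'y' columns")
  }
  if (is.unsorted(df$t, strictly = FALSE)) stop("timestamps must increase")
  df
}

#' Schema-checked load of any supported format
#'
#' Dispatches on `format` and returns the parsed object or raises a
#' structured error naming the offending row/field; never a partial
#' silent load.
#'
#' @param path File path.
#' @param format One of `"cellmap"`, `"events"`, `"sweeps"`, `"track"`,
#'   `"recording"`, `"swc"`, `"yaml"`.
#' @return The parsed object.
#' @export
validate_io <- function(path, format = c("cellmap", "events", "sweeps",
                                         "track", "recording", "swc",
                                         "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         cellmap = read_cellmap(path),
         events = read_events(path),
         sweeps = read_sweeps(path),
         track = read_track(path),
         recording = read_recording(path),
         swc = read_swc(path),
         yaml = yaml::read_yaml(path))
}
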