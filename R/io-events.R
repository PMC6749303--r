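#' Read an event dataset from disk
#'
#' Two on-disk containers are supported. `csv_dir` is a directory with one
#' `<event_id>.csv` per event (header `time,s1,...,sN`, time monotone from 0
#' in 1/fs steps, dot decimals) and a sidecar `<event_id>.meta.json` holding
#' at least `label` and `fs_hz`. `parquet` is a single columnar-binary file
#' written by [write_events()] (one long table, float64 samples, per-event
#' metadata in the file's key-value metadata); it round-trips samples
#' bit-identically.
#'
#' @param path Directory (`csv_dir`) or file (`parquet`).
#' @param format One of `"csv_dir"`, `"parquet"`.
#' @return An [event_dataset]; record order is lexicographic file order for
#'   `csv_dir`, write order for `parquet`. An empty directory yields an
#'   empty dataset.
#' @seealso [write_events()]
#' @export
read_events <- function(path, format = c("csv_dir", "parquet")) {
  format <- match.arg(format)
  switch(format,
         csv_dir = read_events_csv_dir(path),
         parquet = read_events_parquet(path))
}

#' Write an event dataset to disk
#'
#' @param ds An [event_dataset].
#' @param path Target directory (`csv_dir`) or file (`parquet`); created if
#'   missing.
#' @inheritParams read_events
#' @return `path`, invisibly.
#' @details CSV samples are written with 17 significant digits, so the
#'   csv round-trip is exact to double precision (well inside the 1e-9
#'   relative contract); parquet stores raw float64 and round-trips
#'   bit-identically.
#' @export
write_events <- function(ds, path, format = c("csv_dir", "parquet")) {
  stopifnot(inherits(ds, "event_dataset"))
  format <- match.arg(format)
  switch(format,
         csv_dir = write_events_csv_dir(ds, path),
         parquet = write_events_parquet(ds, path))
  invisible(path)
}

event_ids <- function(n) sprintf("event_%05d", seq_len(n))

read_events_csv_dir <- function(path) {
  if (!dir.exists(path)) stop("read_events: no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  records <- lapply(files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    meta_file <- file.path(path, paste0(id, ".meta.json"))
    if (!file.exists(meta_file))
      stop("read_events: missing sidecar ", meta_file)
    meta <- jsonlite::fromJSON(meta_file, simplifyVector = TRUE)
    if (is.null(meta$label) || is.null(meta$fs_hz))
      stop("read_events: ", meta_file, " lacks label/fs_hz")
    tab <- utils::read.csv(f, header = TRUE, check.names = FALSE)
    if (ncol(tab) < 3L || names(tab)[1] != "time")
      stop("read_events: malformed header in ", f,
           " (expected time,s1,...,sN)")
    ch <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(ch))
      stop("read_events: non-numeric sample in ", f)
    bad <- which(!is.finite(ch), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("read_events: non-finite sample in ", f, " at row ", bad[1, 1])
    fs <- as.numeric(meta$fs_hz)
    if (!is.finite(fs) || fs <= 0)
      stop("read_events: non-positive fs_hz in ", meta_file)
    extra <- meta[setdiff(names(meta), c("label", "fs_hz"))]
    accel_record(ch, fs = fs, label = as.character(meta$label),
                 meta = as.list(extra))
  })
  event_dataset(records)
}

write_events_csv_dir <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- event_ids(length(ds$records))
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    n <- nrow(r$channels)
    f <- file.path(path, paste0(ids[i], ".csv"))
    header <- paste(c("time", paste0("s", seq_len(ncol(r$channels)))),
                    collapse = ",")
    tcol <- sprintf("%.17g", (seq_len(n) - 1) / r$fs)
    body <- apply(r$channels, 1, function(row)
      paste(sprintf("%.17g", row), collapse = ","))
    writeLines(c(header, paste(tcol, body, sep = ",")), f)
    meta <- c(list(label = r$label, fs_hz = r$fs), r$meta)
    jsonlite::write_json(meta, file.path(path, paste0(ids[i], ".meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

require_arrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the parquet format requires the 'arrow' package")
}

write_events_parquet <- function(ds, path) {
  require_arrow()
  ids <- event_ids(length(ds$records))
  n_sensors <- if (length(ds$records)) ncol(ds$records[[1]]$channels) else 0L
  if (length(ds$records)) {
    mats <- lapply(ds$records, `[[`, "channels")
    tab <- data.frame(
      event_id = rep(ids, vapply(mats, nrow, integer(1))),
      do.call(rbind, mats))
    names(tab)[-1] <- paste0("s", seq_len(n_sensors))
  } else {
    tab <- data.frame(event_id = character(0))
  }
  meta <- lapply(seq_along(ds$records), function(i) {
    r <- ds$records[[i]]
    c(list(label = r$label, fs_hz = r$fs), r$meta)
  })
  names(meta) <- ids
  at <- arrow::as_arrow_table(tab)
  at$metadata$fallvibe_events <- jsonlite::toJSON(
    list(ids = ids, meta = meta, class_map = as.list(ds$class_map)),
    auto_unbox = TRUE, digits = NA)
  arrow::write_parquet(at, path)
  invisible(path)
}

read_events_parquet <- function(path) {
  require_arrow()
  if (!file.exists(path)) stop("read_events: no such file: ", path)
  at <- arrow::read_parquet(path, as_data_frame = FALSE)
  info <- jsonlite::fromJSON(at$metadata$fallvibe_events,
                             simplifyVector = FALSE)
  tab <- as.data.frame(at)
  class_map <- unlist(info$class_map)
  records <- lapply(info$ids, function(id) {
    m <- info$meta[[id]]
    rows <- tab$event_id == id
    ch <- as.matrix(tab[rows, -1, drop = FALSE])
    extra <- m[setdiff(names(m), c("label", "fs_hz"))]
    accel_record(ch, fs = as.numeric(m$fs_hz), label = as.character(m$label),
                 meta = lapply(extra, identity))
  })
  if (length(class_map) == 0) class_map <- default_class_map()
  event_dataset(records, class_map = class_map)
}

#' Segment a continuous multi-channel stream into event records
#'
#' Intended for continuous monitoring: the per-event pipeline assumes one
#' event per record, so a long stream is cut wherever any channel first
#' exceeds a trigger threshold after a quiet gap of at least one window.
#' Each record spans `[t_trigger - 0.1 * window, t_trigger + window]`,
#' clipped to the stream bounds; successive events never overlap.
#'
#' @param stream Numeric matrix, samples x sensors.
#' @param fs Sampling rate (Hz).
#' @param trigger_threshold Trigger level in g (> 0).
#' @param window Event window length in seconds (> 0).
#' @param label Label assigned to every emitted record.
#' @return List of [accel_record]; empty list for a quiet stream.
#' @export
segment_event <- function(stream, fs, trigger_threshold, window,
                          label = "unlabeled") {
  stream <- as.matrix(stream)
  stopifnot(window > 0, trigger_threshold > 0, fs > 0)
  n <- nrow(stream)
  hot <- which(apply(abs(stream) > trigger_threshold, 1, any))
  if (length(hot) == 0) return(list())
  wlen <- max(1L, round(window * fs))
  pre <- max(0L, round(0.1 * window * fs))
  # trigger = hot sample with no hot sample in the preceding `window`
  gap_ok <- c(TRUE, diff(hot) > wlen)
  triggers <- hot[gap_ok]
  records <- list()
  last_end <- -Inf   # sample index where the previous event window ended
  for (i in triggers) {
    if (i <= last_end) next
    from <- max(1L, i - pre)
    to <- min(n, i + wlen)
    if (to - from + 1L < 2L) next
    records[[length(records) + 1L]] <-
      accel_record(stream[from:to, , drop = FALSE], fs = fs, label = label,
                   meta = list(t_trigger = (i - 1) / fs))
    last_end <- to
  }
  records
}
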