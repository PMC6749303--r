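#' Activity labels understood by the package
#'
#' The six activity classes plus the `"unlabeled"` marker. Falls are the
#' positive class; everything else is negative.
#'
#' @format Character vector of length 7.
#' @export
ACTIVITY_LABELS <- c("fall", "walk", "free_jump", "rhythmic_jump",
                     "bag_drop", "ball_drop", "unlabeled")

#' Construct a single acceleration event record
#'
#' An `accel_record` holds one event: a matrix of acceleration samples
#' (rows = time, columns = sensors, units of g), the sampling rate, an
#' activity label and free-form provenance metadata.
#'
#' @param channels Numeric matrix, `n_samples x n_sensors`, acceleration in g.
#'   At least 2 samples and 2 sensors (the correlation view needs sensor
#'   pairs); all values finite.
#' @param fs Sampling rate in Hz, strictly positive.
#' @param label Activity label; one of [ACTIVITY_LABELS].
#' @param meta Named list of provenance metadata (e.g. `mass_kg`, `position`,
#'   `seed`). May be empty.
#' @return An object of class `accel_record`.
#' @examples
#' rec <- accel_record(matrix(rnorm(200, sd = 0.001), 100, 2), fs = 1652)
#' rec
#' @export
accel_record <- function(channels, fs, label = "unlabeled", meta = list()) {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  dimnames(channels) <- NULL
  if (nrow(channels) < 2L)
    stop("accel_record: need at least 2 samples, got ", nrow(channels))
  if (ncol(channels) < 2L)
    stop("accel_record: need at least 2 sensors, got ", ncol(channels))
  if (!all(is.finite(channels)))
    stop("accel_record: non-finite sample values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("accel_record: fs must be a single positive number")
  label <- match.arg(label, ACTIVITY_LABELS)
  stopifnot(is.list(meta))
  structure(list(channels = channels, fs = as.numeric(fs),
                 label = label, meta = meta),
            class = "accel_record")
}

#' @export
print.accel_record <- function(x, ...) {
  cat(sprintf("<accel_record> %s: %d samples x %d sensors @ %g Hz (%.3f s)\n",
              x$label, nrow(x$channels), ncol(x$channels), x$fs,
              nrow(x$channels) / x$fs))
  invisible(x)
}

#' Construct an event dataset
#'
#' Ordered collection of [accel_record] objects sharing a sensor count and
#' sampling rate, plus the label-to-class mapping (fall = positive,
#' everything else = negative).
#'
#' @param records List of [accel_record] objects (may be empty).
#' @param class_map Named character vector mapping activity labels to
#'   `"positive"` or `"negative"`. Defaults to fall = positive, the five
#'   non-fall activities = negative.
#' @return An object of class `event_dataset`.
#' @export
event_dataset <- function(records = list(), class_map = default_class_map()) {
  stopifnot(is.list(records))
  for (r in records)
    if (!inherits(r, "accel_record"))
      stop("event_dataset: all records must be accel_record objects")
  if (length(records) > 0) {
    ns <- vapply(records, function(r) ncol(r$channels), integer(1))
    fs <- vapply(records, function(r) r$fs, numeric(1))
    if (length(unique(ns)) != 1L)
      stop("event_dataset: records disagree on sensor count: ",
           paste(unique(ns), collapse = ", "))
    if (length(unique(fs)) != 1L)
      stop("event_dataset: records disagree on sampling rate: ",
           paste(unique(fs), collapse = ", "))
  }
  bad <- setdiff(unique(vapply(records, `[[`, "", "label")),
                 c(names(class_map), "unlabeled"))
  if (length(bad) > 0)
    stop("event_dataset: labels outside class_map: ",
         paste(bad, collapse = ", "))
  structure(list(records = records, class_map = class_map),
            class = "event_dataset")
}

#' @rdname event_dataset
#' @export
default_class_map <- function() {
  c(fall = "positive", walk = "negative", free_jump = "negative",
    rhythmic_jump = "negative", bag_drop = "negative", ball_drop = "negative")
}

#' @export
print.event_dataset <- function(x, ...) {
  n <- length(x$records)
  cat(sprintf("<event_dataset> %d events\n", n))
  if (n > 0) {
    tab <- table(vapply(x$records, `[[`, "", "label"))
    cat(sprintf("  %d sensors @ %g Hz\n",
                ncol(x$records[[1]]$channels), x$records[[1]]$fs))
    for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' @export
length.event_dataset <- function(x) length(x$records)

#' Labels of every record in a dataset
#' @param ds An [event_dataset].
#' @return Character vector of activity labels, in record order.
#' @export
event_labels <- function(ds) {
  stopifnot(inherits(ds, "event_dataset"))
  vapply(ds$records, `[[`, "", "label")
}

#' Numeric class of every record: +1 fall, -1 non-fall, NA unlabeled
#' @inheritParams event_labels
#' @return Numeric vector in {+1, -1, NA}.
#' @export
event_classes <- function(ds) {
  lab <- event_labels(ds)
  out <- rep(NA_real_, length(lab))
  out[lab != "unlabeled"] <-
    ifelse(ds$class_map[lab[lab != "unlabeled"]] == "positive", 1, -1)
  out
}

#' Subset an event dataset by record index
#' @param ds An [event_dataset].
#' @param idx Integer or logical index vector.
#' @return An [event_dataset] with the selected records, order preserved.
#' @export
subset_events <- function(ds, idx) {
  stopifnot(inherits(ds, "event_dataset"))
  event_dataset(ds$records[idx], ds$class_map)
}
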