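#' Peak value of an acceleration signal
#'
#' The maximum absolute value of a single-channel signal, in g. The first
#' of the three classification features.
#'
#' @param a Numeric vector, finite, nonempty.
#' @return Nonnegative scalar `max(|a|)`.
#' @export
peak_value <- function(a) {
  if (length(a) == 0) stop("peak_value: empty series")
  if (!all(is.finite(a))) stop("peak_value: non-finite samples")
  max(abs(a))
}

#' Signal energy of an acceleration channel
#'
#' Integrates the rectified signal `|a(t)|` over the record by the
#' trapezoidal rule at step `1/fs`. Despite the name this is the area under
#' the rectified time history (units g*s), not a squared quantity: it
#' characterizes the overall strength of the event.
#'
#' @param a Numeric vector of length >= 2.
#' @param fs Sampling rate (Hz).
#' @return Nonnegative scalar, g*s.
#' @examples
#' signal_energy(c(0, 1), fs = 1)  # single trapezoid: 0.5
#' @export
signal_energy <- function(a, fs) {
  if (length(a) < 2) stop("signal_energy: need at least 2 samples")
  if (!all(is.finite(a))) stop("signal_energy: non-finite samples")
  stopifnot(fs > 0)
  pracma::trapz((seq_along(a) - 1) / fs, abs(a))
}

#' Correlation coefficient between two sensor channels
#'
#' Pearson correlation `Cov(a1, a2) / (sd(a1) sd(a2))` between two
#' acceleration signals. Cross-sensor correlation is less sensitive to
#' local random effects than single-sensor amplitude features. If either
#' channel is constant the statistic is undefined; the uninformative value
#' 0 is returned with a warning so degenerate channels cannot poison
#' training.
#'
#' @param a1,a2 Numeric vectors of equal length >= 2.
#' @return Scalar in `[-1, 1]`.
#' @export
sensor_correlation <- function(a1, a2) {
  if (length(a1) != length(a2))
    stop("sensor_correlation: unequal lengths")
  if (length(a1) < 2) stop("sensor_correlation: need at least 2 samples")
  if (stats::sd(a1) == 0 || stats::sd(a2) == 0) {
    warning("sensor_correlation: constant channel, returning 0")
    return(0)
  }
  stats::cor(a1, a2)
}

#' Extract the three feature views from an event dataset
#'
#' Builds one matrix per view: per-sensor peak value (`n` columns), per-
#' sensor energy (`n` columns), and pairwise sensor correlation
#' (`n(n-1)/2` columns, unordered pairs in lexicographic order (1,2),
#' (1,3), ..., (n-1,n)). Rows follow dataset record order.
#'
#' @param ds A nonempty [event_dataset] with uniform sensor count.
#' @return Named list of three `feature_view` objects (`peak`, `energy`,
#'   `corr`), each with elements `view`, `matrix`, `d`.
#' @export
extract_views <- function(ds) {
  stopifnot(inherits(ds, "event_dataset"))
  if (length(ds$records) == 0) stop("extract_views: empty dataset")
  ns <- ncol(ds$records[[1]]$channels)
  pairs <- utils::combn(ns, 2)
  per_event <- lapply(seq_along(ds$records), function(i) {
    r <- ds$records[[i]]
    res <- try({
      pk <- apply(r$channels, 2, peak_value)
      en <- apply(r$channels, 2, signal_energy, fs = r$fs)
      cc <- apply(pairs, 2, function(p)
        sensor_correlation(r$channels[, p[1]], r$channels[, p[2]]))
      list(pk = pk, en = en, cc = cc)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      stop("extract_views: event ", i, ": ", attr(res, "condition")$message)
    res
  })
  mk <- function(field, nm) {
    m <- do.call(rbind, lapply(per_event, `[[`, field))
    colnames(m) <- nm
    m
  }
  peak <- mk("pk", paste0("peak_s", seq_len(ns)))
  energy <- mk("en", paste0("energy_s", seq_len(ns)))
  corr <- mk("cc", apply(pairs, 2, function(p)
    sprintf("corr_s%d_s%d", p[1], p[2])))
  list(peak = feature_view("peak", peak),
       energy = feature_view("energy", energy),
       corr = feature_view("corr", corr))
}

#' @rdname extract_views
#' @param view One of `"peak"`, `"energy"`, `"corr"`.
#' @param matrix Numeric matrix, events x features.
#' @export
feature_view <- function(view = c("peak", "energy", "corr"), matrix) {
  view <- match.arg(view)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("feature_view: non-finite entries")
  if (view %in% c("peak", "energy") && any(matrix < 0))
    stop("feature_view: negative ", view, " entries")
  if (view == "corr" && any(abs(matrix) > 1 + 1e-12))
    stop("feature_view: correlation entries outside [-1, 1]")
  structure(list(view = view, matrix = matrix, d = ncol(matrix)),
            class = "feature_view")
}

#' Export a feature view as CSV for inspection
#'
#' @param fv A `feature_view`.
#' @param path Output CSV path; header `event_id,<view>_<col>`.
#' @return `path`, invisibly.
#' @export
write_view_csv <- function(fv, path) {
  stopifnot(inherits(fv, "feature_view"))
  tab <- data.frame(event_id = event_ids(nrow(fv$matrix)), fv$matrix,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
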