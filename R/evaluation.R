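#' Confusion-matrix evaluation of fall predictions
#'
#' Computes the confusion counts and the detector metrics used for
#' vibration-based fall detection: accuracy `(TP+TN)/n`, sensitivity
#' `100 TP / (TP + FN)` (share of true falls detected), specificity
#' `100 TN / (FP + TN)` (share of non-falls correctly rejected), miss
#' rate `100 - sensitivity` (falls mistakenly reported as non-falls) and
#' false-alarm rate `100 - specificity` (non-falls mistakenly reported as
#' falls). With per-event activity tags, the false-alarm rate is also
#' broken down within each non-fall activity.
#'
#' @param pred Predicted labels in {+1, -1}.
#' @param truth True labels in {+1, -1}, same length (>= 1).
#' @param activities Optional character vector of per-event activity tags.
#' @return An object of class `eval_report`: counts `TP`, `FP`, `TN`,
#'   `FN`; percentages `accuracy`, `sensitivity`, `specificity`,
#'   `miss_rate`, `false_alarm_rate`; `per_activity_false_alarm` (named
#'   numeric, percent within each non-fall activity); `undefined`, the
#'   names of metrics with an empty denominator (reported as `NA`, never
#'   silently propagated NaN).
#' @examples
#' evaluate(c(1, 1, -1, -1), c(1, -1, -1, 1))
#' @export
evaluate <- function(pred, truth, activities = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1,
            all(pred %in% c(-1, 1)), all(truth %in% c(-1, 1)))
  TP <- sum(pred == 1 & truth == 1)
  FP <- sum(pred == 1 & truth == -1)
  TN <- sum(pred == -1 & truth == -1)
  FN <- sum(pred == -1 & truth == 1)
  undefined <- character(0)
  pct <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    100 * num / den
  }
  se <- pct(TP, TP + FN, "sensitivity")
  sp <- pct(TN, FP + TN, "specificity")
  per_act <- NULL
  if (!is.null(activities)) {
    stopifnot(length(activities) == length(pred))
    nonfall <- truth == -1
    per_act <- vapply(sort(unique(activities[nonfall])), function(a) {
      rows <- nonfall & activities == a
      100 * sum(pred[rows] == 1) / sum(rows)
    }, numeric(1))
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 accuracy = 100 * (TP + TN) / length(pred),
                 sensitivity = se, specificity = sp,
                 miss_rate = if (is.na(se)) NA_real_ else 100 - se,
                 false_alarm_rate = if (is.na(sp)) NA_real_ else 100 - sp,
                 per_activity_false_alarm = per_act,
                 undefined = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d (TP %d, FP %d, TN %d, FN %d)\n",
              x$TP + x$FP + x$TN + x$FN, x$TP, x$FP, x$TN, x$FN))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("  accuracy    ", fmt(x$accuracy), "\n")
  cat("  sensitivity ", fmt(x$sensitivity),
      " (miss rate ", fmt(x$miss_rate), ")\n", sep = "")
  cat("  specificity ", fmt(x$specificity),
      " (false alarm ", fmt(x$false_alarm_rate), ")\n", sep = "")
  if (!is.null(x$per_activity_false_alarm)) {
    cat("  false alarms by activity:\n")
    for (a in names(x$per_activity_false_alarm))
      cat(sprintf("    %-14s %.2f%%\n", a, x$per_activity_false_alarm[[a]]))
  }
  invisible(x)
}

#' Export an evaluation report as CSV
#'
#' Writes the scalar metrics as a two-column CSV and, when present, the
#' per-activity false-alarm breakdown as `activity,false_alarm_pct`.
#'
#' @param report An `eval_report`.
#' @param path Metrics CSV path.
#' @param per_activity_path Optional path for the per-activity breakdown.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, per_activity_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  scalars <- c("TP", "FP", "TN", "FN", "accuracy", "sensitivity",
               "specificity", "miss_rate", "false_alarm_rate")
  utils::write.csv(data.frame(metric = scalars,
                              value = unlist(report[scalars],
                                             use.names = FALSE)),
                   path, row.names = FALSE)
  if (!is.null(per_activity_path) &&
      !is.null(report$per_activity_false_alarm))
    utils::write.csv(data.frame(
      activity = names(report$per_activity_false_alarm),
      false_alarm_pct = as.numeric(report$per_activity_false_alarm)),
      per_activity_path, row.names = FALSE)
  invisible(path)
}

#' Relative change between two percentages
#'
#' `100 (new - old) / old`, rounded to two decimals for reporting — the
#' arithmetic behind "performance increased" columns comparing, e.g., the
#' sensitivity of two detectors at the same labeling rate.
#'
#' @param new,old Percentages; `old` must be positive.
#' @return Relative change in percent, rounded to 2 decimals.
#' @examples
#' relative_change(82.54, 54.23)  # 52.20
#' @export
relative_change <- function(new, old) {
  if (any(old <= 0)) stop("relative_change: old must be > 0")
  round(100 * (new - old) / old, 2)
}

#' Autocorrelation-template baseline classifier
#'
#' A simplified stand-in for autocorrelation-based activity recognition:
#' for each event, the normalized autocorrelation of the strongest
#' channel (largest peak) is computed up to `lag_window` lags; labeled
#' training events define one mean autocorrelation template per class,
#' and each test event is assigned the class of the nearest template in
#' Euclidean distance. This captures the idea of comparing
#' autocorrelation signatures, not any specific published algorithm's
#' internals.
#'
#' @param train_ds Labeled [event_dataset] (templates).
#' @param test_ds [event_dataset] to classify.
#' @param lag_window Number of lags (samples); must be smaller than the
#'   record length.
#' @return Numeric vector of predictions in {+1, -1} over `test_ds`.
#' @export
autocorr_baseline <- function(train_ds, test_ds, lag_window = 200) {
  stopifnot(inherits(train_ds, "event_dataset"),
            inherits(test_ds, "event_dataset"))
  nmin <- min(vapply(c(train_ds$records, test_ds$records),
                     function(r) nrow(r$channels), integer(1)))
  if (lag_window >= nmin)
    stop("autocorr_baseline: lag_window (", lag_window,
         ") must be below the shortest record length (", nmin, ")")
  sig <- function(r) {
    ch <- which.max(apply(r$channels, 2, function(a) max(abs(a))))
    a <- r$channels[, ch]
    if (stats::sd(a) == 0) return(rep(0, lag_window))
    as.numeric(stats::acf(a, lag.max = lag_window, plot = FALSE,
                          demean = TRUE)$acf)[-1]
  }
  tr <- t(vapply(train_ds$records, sig, numeric(lag_window)))
  y <- event_classes(train_ds)
  if (anyNA(y)) stop("autocorr_baseline: training records must be labeled")
  templates <- lapply(c(pos = 1, neg = -1), function(cl)
    if (any(y == cl)) colMeans(tr[y == cl, , drop = FALSE]) else NULL)
  vapply(test_ds$records, function(r) {
    s <- sig(r)
    d <- vapply(templates, function(tm)
      if (is.null(tm)) Inf else sqrt(sum((s - tm)^2)), numeric(1))
    if (d[["pos"]] <= d[["neg"]]) 1 else -1
  }, numeric(1))
}
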