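#' Fit the multi-feature semi-supervised SVM ensemble
#'
#' Tri-training over the three feature views. Three RBF base classifiers
#' (peak, energy, correlation) are first fit on the labeled rows; each
#' iteration then (i) lets every view nominate unlabeled rows from its
#' own margin band whose label the other two views agree on
#' ([select_semi_labels()]), (ii) adds each view's nominations to that
#' view's own semi-labeled set — a classifier never trains on rows it
#' nominated for itself, only on rows its two peers endorsed, which is
#' what keeps the cooperation from amplifying one view's mistakes,
#' (iii) returns any semi-labeled row whose peer-endorsed pseudo-label
#' has flipped to that view's unlabeled pool, and (iv) refits each
#' classifier on the labeled rows plus its own semi-labeled rows with
#' the semi-labeled penalty `C_star`. Iteration stops at `max_iter` or
#' as soon as an iteration makes no additions and no removals.
#'
#' @param views List of the three feature matrices in view order
#'   (peak, energy, corr), or the output of [extract_views()].
#' @param labels Numeric vector over rows: +1 (fall), -1 (non-fall) or NA
#'   (unlabeled).
#' @param semi_cfg A [semi_config].
#' @param svm_cfg An [svm_config].
#' @return An object of class `tri_ensemble`: three fitted classifiers,
#'   the majority-vote fusion in [predict.tri_ensemble()], per-iteration
#'   history (`iter`, `added`, `removed`, `n_semi`, summed over views),
#'   the stop reason, and the final per-view semi-label assignment
#'   (`semi_idx`, `semi_labels`: lists of three).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, -2), 30), matrix(rnorm(60, 2), 30))
#' views <- list(x, x + rnorm(120, sd = .1), x + rnorm(120, sd = .1))
#' y <- rep(c(-1, 1), each = 30)
#' y[sample(60, 40)] <- NA       # 1/3 labeling rate
#' ens <- fit_mfss(views, y)
#' ens$history
#' @export
fit_mfss <- function(views, labels, semi_cfg = semi_config(),
                     svm_cfg = svm_config()) {
  views <- as_view_matrices(views)
  n <- nrow(views[[1]])
  stopifnot(length(labels) == n)
  labeled <- which(!is.na(labels))
  if (length(labeled) == 0) stop("fit_mfss: no labeled rows")
  if (length(unique(labels[labeled])) < 2)
    stop("fit_mfss: both classes must be present in the labeled set")
  unlabeled <- setdiff(seq_len(n), labeled)
  semi_idx <- list(integer(0), integer(0), integer(0))   # per view
  semi_lab <- list(numeric(0), numeric(0), numeric(0))
  # per-view standardization from labeled rows only, frozen for the run
  std <- lapply(views, function(xv) {
    ref <- xv[labeled, , drop = FALSE]
    scl <- apply(ref, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    list(center = colMeans(ref), scale = scl)
  })
  view_names <- c("peak", "energy", "corr")
  fit3 <- function() {
    lapply(1:3, function(v) {
      idx <- c(labeled, semi_idx[[v]])
      fit_base(views[[v]][idx, , drop = FALSE],
               c(labels[labeled], semi_lab[[v]]),
               cfg = svm_cfg,
               semi = c(rep(FALSE, length(labeled)),
                        rep(TRUE, length(semi_idx[[v]]))),
               view = view_names[v], standardize = std[[v]])
    })
  }
  # peer-pair error on the labeled rows (strict mode): fraction of
  # labeled rows where the two peers agree on the wrong label, among
  # the rows where they agree
  peer_error <- function(v) {
    peers <- setdiff(1:3, v)
    p1 <- predict_base(fits[[peers[1]]],
                       views[[peers[1]]][labeled, , drop = FALSE])
    p2 <- predict_base(fits[[peers[2]]],
                       views[[peers[2]]][labeled, , drop = FALSE])
    agree <- p1 == p2
    if (!any(agree)) return(0.5)
    mean(p1[agree] != labels[labeled][agree])
  }
  fits <- fit3()
  prev_err <- rep(0.5, 3)
  history <- data.frame(iter = integer(0), added = integer(0),
                        removed = integer(0), n_semi = integer(0))
  reason <- if (semi_cfg$max_iter == 0) "supervised" else "max_iter"
  for (it in seq_len(semi_cfg$max_iter)) {
    added <- 0L
    removed <- 0L
    new_semi_idx <- semi_idx
    new_semi_lab <- semi_lab
    err_now <- if (semi_cfg$strict) vapply(1:3, peer_error, numeric(1))
               else rep(0, 3)
    for (v in 1:3) {
      peers <- setdiff(1:3, v)
      # flip removal: a semi row whose peer-endorsed label has changed
      # goes back to this view's unlabeled pool
      if (length(semi_idx[[v]]) > 0) {
        p1 <- predict_base(fits[[peers[1]]],
                           views[[peers[1]]][semi_idx[[v]], , drop = FALSE])
        p2 <- predict_base(fits[[peers[2]]],
                           views[[peers[2]]][semi_idx[[v]], , drop = FALSE])
        flip <- p1 == p2 & p1 != semi_lab[[v]]
        removed <- removed + sum(flip)
        new_semi_idx[[v]] <- semi_idx[[v]][!flip]
        new_semi_lab[[v]] <- semi_lab[[v]][!flip]
      }
      accept <- !semi_cfg$strict ||
        (err_now[v] < 0.5 && err_now[v] <= prev_err[v])
      if (accept) {
        pool_v <- setdiff(unlabeled, new_semi_idx[[v]])
        sel <- select_semi_labels(fits, v, views, pool_v, semi_cfg)
        if (nrow(sel) > 0) {
          added <- added + nrow(sel)
          new_semi_idx[[v]] <- c(new_semi_idx[[v]], sel$idx)
          new_semi_lab[[v]] <- c(new_semi_lab[[v]], sel$label)
        }
      }
    }
    if (semi_cfg$strict) prev_err <- err_now
    semi_idx <- new_semi_idx
    semi_lab <- new_semi_lab
    history <- rbind(history, data.frame(
      iter = it, added = added, removed = removed,
      n_semi = sum(lengths(semi_idx))))
    if (added == 0L && removed == 0L) {
      reason <- "converged"
      break
    }
    fits <- fit3()
  }
  structure(list(fits = fits, svm_cfg = svm_cfg, semi_cfg = semi_cfg,
                 history = history, stop_reason = reason,
                 labeled_idx = labeled, semi_idx = semi_idx,
                 semi_labels = semi_lab,
                 d = vapply(views, ncol, integer(1))),
            class = "tri_ensemble")
}

as_view_matrices <- function(views) {
  if (is.list(views) && all(vapply(views, inherits, TRUE, "feature_view")))
    views <- lapply(views, `[[`, "matrix")
  stopifnot(is.list(views), length(views) == 3)
  views <- lapply(views, as.matrix)
  if (length(unique(vapply(views, nrow, integer(1)))) != 1)
    stop("views disagree on row count")
  views
}

majority_vote <- function(fits, views, idx) {
  votes <- vapply(1:3, function(v)
    predict_base(fits[[v]], views[[v]][idx, , drop = FALSE]),
    numeric(length(idx)))
  votes <- matrix(votes, nrow = length(idx))
  sign(rowSums(votes))      # three +/-1 voters can never tie
}

#' @export
print.tri_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<tri_ensemble> %d labeled, %d semi-labeled ",
                     "(per view %s), %d iterations (%s)\n"),
              length(x$labeled_idx), sum(lengths(x$semi_idx)),
              paste(lengths(x$semi_idx), collapse = "/"),
              nrow(x$history), x$stop_reason))
  invisible(x)
}

#' Predict fall/non-fall labels with the fitted ensemble
#'
#' Majority vote of the three per-view predictions. Three binary voters
#' cannot tie, so no tie-break rule is needed.
#'
#' @param object A `tri_ensemble`.
#' @param views List of three feature matrices (or [extract_views()]
#'   output) with the training view widths.
#' @param ... Unused.
#' @return List with `label` (numeric +1/-1 per row) and `votes`
#'   (rows x 3 matrix of per-view votes, columns peak/energy/corr).
#' @export
predict.tri_ensemble <- function(object, views, ...) {
  views <- as_view_matrices(views)
  w <- vapply(views, ncol, integer(1))
  if (!identical(w, object$d))
    stop("predict: view widths (", paste(w, collapse = ","),
         ") do not match training widths (",
         paste(object$d, collapse = ","), ")")
  votes <- vapply(1:3, function(v)
    predict_base(object$fits[[v]], views[[v]]),
    numeric(nrow(views[[1]])))
  votes <- matrix(votes, nrow = nrow(views[[1]]),
                  dimnames = list(NULL, c("peak", "energy", "corr")))
  list(label = sign(rowSums(votes)), votes = votes)
}

#' Labeling-rate experiment
#'
#' For each labeling rate and repeat: split the dataset into train/test,
#' reveal labels for a class-stratified fraction of the training rows,
#' measure the supervised three-view vote ("initial" accuracy) and the
#' full semi-supervised ensemble ("final" accuracy) on the test rows, and
#' average over repeats. Sensitivity and specificity of the final model
#' are reported alongside.
#'
#' @param ds An [event_dataset] with labeled records.
#' @param rates Labeling rates in (0, 1].
#' @param split Training fraction in (0, 1); 0.7 mirrors the laboratory
#'   protocol, 0.56 the benchmark protocol.
#' @param n_repeats Number of random repeats averaged per rate.
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param semi_cfg,svm_cfg Ensemble configuration.
#' @return A [tibble::tibble] with one row per rate: `rate`, `initial`,
#'   `final`, `relative_gain` (all accuracies in percent; gain is
#'   `100 (final - initial) / initial`), `sensitivity`, `specificity`,
#'   `n_repeats`. Per-repeat rows are attached as attribute `"runs"`.
#' @export
labeling_rate_experiment <- function(ds, rates = c(0.2, 0.4, 0.6, 0.8),
                                     split = 0.7, n_repeats = 3, seed = 1L,
                                     semi_cfg = semi_config(),
                                     svm_cfg = svm_config()) {
  stopifnot(all(rates > 0), all(rates <= 1), split > 0, split < 1,
            n_repeats >= 1)
  views <- lapply(extract_views(ds), `[[`, "matrix")
  y <- event_classes(ds)
  if (anyNA(y)) stop("labeling_rate_experiment: dataset has unlabeled records")
  acts <- event_labels(ds)
  n <- length(y)
  runs <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    train <- sample.int(n, round(split * n))
    test <- setdiff(seq_len(n), train)
    for (rate in rates) {
      lab_idx <- stratified_subset(y[train], rate)
      if (length(unique(y[train][lab_idx])) < 2)
        stop("labeling_rate_experiment: rate ", rate,
             " leaves a class without labeled examples")
      labels_tr <- rep(NA_real_, length(train))
      labels_tr[lab_idx] <- y[train][lab_idx]
      tr_views <- lapply(views, function(v) v[train, , drop = FALSE])
      te_views <- lapply(views, function(v) v[test, , drop = FALSE])
      sup <- fit_mfss(lapply(tr_views, function(v)
        v[lab_idx, , drop = FALSE]), labels_tr[lab_idx],
        semi_cfg = semi_config(max_iter = 0, add_cap = semi_cfg$add_cap),
        svm_cfg = svm_cfg)
      fin <- fit_mfss(tr_views, labels_tr, semi_cfg = semi_cfg,
                      svm_cfg = svm_cfg)
      p0 <- predict(sup, te_views)$label
      p1 <- predict(fin, te_views)$label
      rep_eval <- evaluate(p1, y[test], activities = acts[test])
      runs[[length(runs) + 1L]] <- tibble::tibble(
        rate = rate, repeat_i = r,
        initial = 100 * mean(p0 == y[test]),
        final = 100 * mean(p1 == y[test]),
        sensitivity = rep_eval$sensitivity,
        specificity = rep_eval$specificity)
    }
  }
  runs <- do.call(rbind, runs)
  out <- do.call(rbind, lapply(sort(unique(runs$rate)), function(rt) {
    sub <- runs[runs$rate == rt, ]
    tibble::tibble(rate = rt,
                   initial = mean(sub$initial),
                   final = mean(sub$final),
                   relative_gain = relative_change(mean(sub$final),
                                                   mean(sub$initial)),
                   sensitivity = mean(sub$sensitivity),
                   specificity = mean(sub$specificity),
                   n_repeats = n_repeats)
  }))
  attr(out, "runs") <- runs
  out
}

# class-stratified index subset at a given labeling rate
stratified_subset <- function(y, rate) {
  idx <- integer(0)
  for (cl in unique(y)) {
    rows <- which(y == cl)
    k <- max(1L, round(rate * length(rows)))
    idx <- c(idx, sample(rows, k))
  }
  sort(idx)
}
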