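#' Configuration of the RBF base classifiers
#'
#' Soft-margin SVM settings shared by the three per-view classifiers. The
#' labeled-sample penalty `C` and the semi-labeled penalty `C_star`
#' correspond to the two penalty terms of the semi-supervised objective:
#' pseudo-labeled rows are trusted less, so their margin violations are
#' charged at `C_star < C` (default half).
#'
#' @param C Penalty for labeled samples (> 0).
#' @param C_star Penalty for semi-labeled samples (> 0); default `0.5 * C`.
#' @param gamma RBF kernel width, a positive number or `"median"` for the
#'   median-pairwise-distance heuristic computed on the (standardized)
#'   labeled rows: `gamma = 1 / (2 * median(dist)^2)`.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C = 1, C_star = 0.5 * C, gamma = "median") {
  stopifnot(C > 0, C_star > 0,
            identical(gamma, "median") || (is.numeric(gamma) && gamma > 0))
  structure(list(C = C, C_star = C_star, gamma = gamma),
            class = "svm_config")
}

median_gamma <- function(x) {
  if (nrow(x) > 500) x <- x[sample.int(nrow(x), 500), , drop = FALSE]
  d <- stats::median(stats::dist(x))
  if (!is.finite(d) || d <= 0) d <- 1
  1 / (2 * d^2)
}

# integer replication multiplicities realizing penalties (C, C_star)
# at a single libsvm cost value: labeled rows x m_l, semi rows x m_s,
# base cost C / m_l, requiring C / C_star ~ m_l / m_s.
penalty_multiplicities <- function(C, C_star, max_den = 8L) {
  r <- C / C_star
  den <- seq_len(max_den)
  num <- round(r * den)
  ok <- which(num >= 1 & abs(num / den - r) < 1e-6)
  if (length(ok) == 0) {            # irrational ratio: nearest within budget
    err <- abs(num / den - r)
    ok <- which.min(err)
  }
  j <- ok[1]
  list(m_l = num[j], m_s = den[j], cost = C / num[j])
}

#' Fit one soft-margin RBF base classifier
#'
#' Trains the RBF-kernel soft-margin SVM on one feature view. The
#' quadratic program is solved by libsvm (through [e1071::svm()]);
#' features are z-scored with statistics of the labeled rows only, and the
#' transform is stored with the classifier. When semi-labeled rows are
#' present they are penalized at `C_star` instead of `C`, realized by
#' replicating rows at the rational ratio `C / C_star` with a common base
#' cost (replication multiplies a row's slack penalty exactly).
#'
#' @param x Numeric matrix of feature rows (labeled first is not
#'   required; rows are tagged by `semi`).
#' @param y Labels in {+1, -1}, one per row.
#' @param cfg An [svm_config].
#' @param semi Logical vector, TRUE for semi-labeled rows; default none.
#' @param view View id stored for diagnostics.
#' @param standardize Optional list(center, scale) to reuse an existing
#'   transform; by default computed from the non-semi rows of `x`.
#' @return An object of class `base_classifier` exposing real-valued
#'   decision values via [decision_values()] (positive = fall).
#' @export
fit_base <- function(x, y, cfg = svm_config(), semi = rep(FALSE, nrow(x)),
                     view = "view", standardize = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(semi) == nrow(x))
  if (!all(y %in% c(-1, 1))) stop("fit_base: labels must be +1/-1")
  cnt <- table(factor(y, levels = c(-1, 1)))
  if (any(cnt == 0))
    stop("fit_base: need both classes among labels (got ",
         cnt[["1"]], " positive, ", cnt[["-1"]], " negative)")
  if (is.null(standardize)) {
    ref <- x[!semi, , drop = FALSE]
    ctr <- colMeans(ref)
    scl <- apply(ref, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    standardize <- list(center = ctr, scale = scl)
  }
  xs <- scale(x, standardize$center, standardize$scale)
  gamma <- cfg$gamma
  if (identical(gamma, "median"))
    gamma <- median_gamma(xs[!semi, , drop = FALSE])
  if (any(semi)) {
    mult <- penalty_multiplicities(cfg$C, cfg$C_star)
    reps <- ifelse(semi, mult$m_s, mult$m_l)
    idx <- rep(seq_len(nrow(xs)), reps)
    xs_fit <- xs[idx, , drop = FALSE]
    y_fit <- y[idx]
    cost <- mult$cost
  } else {
    xs_fit <- xs
    y_fit <- y
    cost <- cfg$C
  }
  fit <- e1071::svm(x = xs_fit, y = factor(y_fit, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = cost, scale = FALSE)
  # libsvm orients its decision value toward the first class it saw;
  # normalize so that positive decision value means the fall class (+1)
  cn <- colnames(fit$decision.values)[1]
  flip <- if (startsWith(cn, "1/")) 1 else -1
  structure(list(view = view, model = fit, standardize = standardize,
                 gamma = gamma, cfg = cfg, flip = flip,
                 n_labeled = sum(!semi), n_semi = sum(semi)),
            class = "base_classifier")
}

#' Decision values of a base classifier
#'
#' @param clf A `base_classifier`.
#' @param x New feature rows (same width as training).
#' @return Numeric vector of signed decision values; positive means the
#'   fall class, `|value| = 1` is the margin.
#' @export
decision_values <- function(clf, x) {
  stopifnot(inherits(clf, "base_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != length(clf$standardize$center))
    stop("decision_values: expected ", length(clf$standardize$center),
         " features, got ", ncol(x))
  xs <- scale(x, clf$standardize$center, clf$standardize$scale)
  p <- stats::predict(clf$model, xs, decision.values = TRUE)
  clf$flip * as.numeric(attr(p, "decision.values"))
}

#' @rdname decision_values
#' @return `predict_base` returns hard labels in {+1, -1} (sign of the
#'   decision value; exact zeros fall to -1).
#' @export
predict_base <- function(clf, x) {
  dv <- decision_values(clf, x)
  ifelse(dv > 0, 1, -1)
}

#' Semi-supervised selection and stopping configuration
#'
#' Controls one tri-training run: the margin band from which pseudo-label
#' candidates are drawn, the per-iteration cap on additions, and the
#' iteration limit.
#'
#' @param max_iter Maximum number of tri-training iterations (>= 0; 0
#'   degenerates to the purely supervised ensemble).
#' @param add_cap Per-view, per-iteration cap on additions, as a fraction
#'   of the current unlabeled pool, in (0, 1].
#' @param strict Canonical tri-training error-rate condition: when TRUE,
#'   a view accepts new pseudo-labels in an iteration only while the
#'   error rate of its two peers' agreed labels, measured on the labeled
#'   rows, is below 0.5 and has not increased since the previous
#'   iteration. Off by default: the label-flip removal rule is the
#'   stabilizer used in the base configuration.
#' @param seed Optional seed consumed by callers that randomize.
#' @return An object of class `semi_config`.
#' @export
semi_config <- function(max_iter = 20, add_cap = 0.1, strict = FALSE,
                        seed = NULL) {
  stopifnot(max_iter >= 0, add_cap > 0, add_cap <= 1,
            is.logical(strict), length(strict) == 1)
  structure(list(max_iter = max_iter, add_cap = add_cap, strict = strict,
                 seed = seed),
            class = "semi_config")
}

#' Select pseudo-label candidates for one view
#'
#' Implements margin-proximity pseudo-labeling under tri-training: from
#' the unlabeled pool, rows whose decision value under this view's
#' classifier lies in the margin band `0 < |y| <= 1` are candidates (rows
#' inside the band influence the separating hyperplane, and those closest
#' to `|y| = 1` are the most likely to be labeled correctly); a candidate
#' is kept only if the other two views' classifiers agree on its label,
#' which becomes the pseudo-label. Survivors are ranked by `||y| - 1|`
#' ascending and the top `ceiling(add_cap * pool size)` returned.
#'
#' @param fits List of the three fitted `base_classifier`s.
#' @param v Index (1-3) of the view doing the selecting.
#' @param views List of the three full feature matrices.
#' @param pool Integer indices of currently unlabeled rows.
#' @param cfg A [semi_config].
#' @return Data frame with columns `idx`, `label`, `dv`, ranked; possibly
#'   zero rows.
#' @export
select_semi_labels <- function(fits, v, views, pool, cfg = semi_config()) {
  stopifnot(length(fits) == 3, v %in% 1:3)
  if (length(pool) == 0)
    return(data.frame(idx = integer(0), label = numeric(0), dv = numeric(0)))
  dv <- decision_values(fits[[v]], views[[v]][pool, , drop = FALSE])
  band <- abs(dv) > 0 & abs(dv) <= 1
  if (!any(band))
    return(data.frame(idx = integer(0), label = numeric(0), dv = numeric(0)))
  peers <- setdiff(1:3, v)
  cand <- pool[band]
  p1 <- predict_base(fits[[peers[1]]], views[[peers[1]]][cand, , drop = FALSE])
  p2 <- predict_base(fits[[peers[2]]], views[[peers[2]]][cand, , drop = FALSE])
  agree <- p1 == p2
  cand <- cand[agree]
  if (length(cand) == 0)
    return(data.frame(idx = integer(0), label = numeric(0), dv = numeric(0)))
  dvc <- dv[band][agree]
  ord <- order(abs(abs(dvc) - 1))
  keep <- utils::head(ord, ceiling(cfg$add_cap * length(pool)))
  data.frame(idx = cand[keep], label = p1[agree][keep], dv = dvc[keep])
}
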