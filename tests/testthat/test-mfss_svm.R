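test_that("well-separated clusters are classified perfectly", {
  set.seed(3)
  x <- matrix(c(rnorm(20, -10), rnorm(20, 10)), ncol = 1)
  y <- rep(c(-1, 1), each = 20)
  clf <- fit_base(x, y, svm_config(C = 1))
  expect_equal(predict_base(clf, x), y)
  # decision values are positively oriented toward the fall class
  expect_true(all(decision_values(clf, x) * y > 0))
})

test_that("refits are deterministic and replication halves the penalty", {
  set.seed(4)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rep(c(-1, 1), 15)
  clf1 <- fit_base(x, y, svm_config(C = 2, gamma = 0.7))
  grid <- matrix(rnorm(40), ncol = 2)
  # identical inputs give the identical decision function
  clf3 <- fit_base(x, y, svm_config(C = 2, gamma = 0.7))
  expect_equal(decision_values(clf1, grid), decision_values(clf3, grid))
  # duplicating every row at half the cost leaves the solution unchanged:
  # the replication scheme used for the semi-labeled penalty is exact
  clf2 <- fit_base(rbind(x, x), c(y, y), svm_config(C = 1, gamma = 0.7),
                   standardize = clf1$standardize)
  # agreement is limited by the QP solver's own convergence tolerance
  expect_equal(decision_values(clf2, grid), decision_values(clf1, grid),
               tolerance = 1e-2)
})

test_that("the RBF kernel solves an XOR-style problem", {
  set.seed(5)
  centers <- rbind(c(-2, -2), c(2, 2), c(-2, 2), c(2, -2))
  x <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(80, sd = 0.5), 40, 2), 2, centers[i, ], "+")))
  y <- rep(c(1, 1, -1, -1), each = 40)
  clf <- fit_base(x, y, svm_config(C = 10))
  expect_gt(mean(predict_base(clf, x) == y), 0.9)
})

test_that("single-class labels raise a training error naming the counts", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_base(x, rep(1, 10)), "0 negative")
  expect_error(fit_base(x, rep(0.5, 10)), "must be \\+1/-1")
})

test_that("semi-labeled rows are penalized at C_star via replication", {
  mult <- fallvibe:::penalty_multiplicities(1, 0.5)
  expect_equal(mult$m_l, 2)
  expect_equal(mult$m_s, 1)
  expect_equal(mult$cost, 0.5)
  mult2 <- fallvibe:::penalty_multiplicities(3, 1)
  expect_equal(mult2$m_l / mult2$m_s, 3)
  expect_equal(mult2$m_l * mult2$cost, 3)
})

test_that("margin-band selection equals a brute-force re-ranking", {
  cl <- make_cluster_views(n_per_class = 40, sep = 3, seed = 8)
  labels <- cl$y
  labeled <- c(1:15, 41:55)
  pool <- setdiff(seq_along(labels), labeled)
  fits <- lapply(1:3, function(v)
    fit_base(cl$views[[v]][labeled, ], labels[labeled],
             svm_config(gamma = 0.5), view = c("peak", "energy", "corr")[v]))
  cfg <- semi_config(add_cap = 0.2)
  sel <- select_semi_labels(fits, 1, cl$views, pool, cfg)
  # brute-force oracle over the candidate list
  dv <- decision_values(fits[[1]], cl$views[[1]][pool, ])
  band <- which(abs(dv) > 0 & abs(dv) <= 1)
  p2 <- predict_base(fits[[2]], cl$views[[2]][pool[band], , drop = FALSE])
  p3 <- predict_base(fits[[3]], cl$views[[3]][pool[band], , drop = FALSE])
  keep <- band[p2 == p3]
  ord <- keep[order(abs(abs(dv[keep]) - 1))]
  expected_idx <- pool[head(ord, ceiling(0.2 * length(pool)))]
  expect_equal(sel$idx, expected_idx)
  expect_true(all(abs(sel$dv) <= 1 & abs(sel$dv) > 0))
  # selected labels are the peers' agreed labels
  expect_equal(sel$label,
               predict_base(fits[[2]],
                            cl$views[[2]][sel$idx, , drop = FALSE]))
})

test_that("selection returns nothing when no candidate sits in the band", {
  cl <- make_cluster_views(n_per_class = 30, sep = 8, sd = 0.3, seed = 9)
  labeled <- c(1:25, 31:55)
  pool <- setdiff(seq_along(cl$y), labeled)
  fits <- lapply(1:3, function(v)
    fit_base(cl$views[[v]][labeled, ], cl$y[labeled],
             svm_config(C = 50, gamma = 2)))
  dv <- decision_values(fits[[1]], cl$views[[1]][pool, , drop = FALSE])
  # restrict the pool to rows provably outside the margin band
  pool_out <- pool[abs(dv) > 1]
  expect_gt(length(pool_out), 0)
  sel <- select_semi_labels(fits, 1, cl$views, pool_out)
  expect_equal(nrow(sel), 0)
})

test_that("fully labeled data degenerates to the supervised ensemble", {
  cl <- make_cluster_views(seed = 10)
  ens <- fit_mfss(cl$views, cl$y)
  expect_equal(nrow(ens$history), 1)
  expect_equal(ens$history$added, 0)
  expect_equal(ens$stop_reason, "converged")
  expect_equal(sum(lengths(ens$semi_idx)), 0)
  sup <- fit_mfss(cl$views, cl$y, semi_cfg = semi_config(max_iter = 0))
  expect_equal(sup$stop_reason, "supervised")
  grid <- lapply(cl$views, function(v) v[1:10, ])
  expect_equal(predict(ens, grid)$label, predict(sup, grid)$label)
})

test_that("tri-training bookkeeping conserves the semi-labeled set", {
  cl <- make_cluster_views(n_per_class = 60, sep = 2.2, seed = 12)
  labels <- cl$y
  set.seed(12)
  hide <- sample(120, 90)
  labels[hide] <- NA
  ens <- fit_mfss(cl$views, labels, semi_cfg = semi_config(max_iter = 8))
  h <- ens$history
  expect_equal(sum(h$added) - sum(h$removed), sum(lengths(ens$semi_idx)))
  # semi rows come only from the originally unlabeled rows
  expect_true(all(unlist(ens$semi_idx) %in% hide))
  expect_true(all(!ens$labeled_idx %in% hide))
  # no view trains twice on the same row
  for (v in 1:3) expect_false(anyDuplicated(ens$semi_idx[[v]]) > 0)
  expect_lte(nrow(h), 8)
  expect_true(ens$stop_reason %in% c("converged", "max_iter"))
})

test_that("semi-supervision does not hurt on cluster data (paired seeds)", {
  gains <- vapply(1:10, function(s) {
    cl <- make_cluster_views(n_per_class = 50, sep = 2, seed = 100 + s)
    labels <- cl$y
    set.seed(200 + s)
    test_idx <- sample(100, 30)
    train_idx <- setdiff(1:100, test_idx)
    lab <- c(sample(train_idx[cl$y[train_idx] == -1], 7),
             sample(train_idx[cl$y[train_idx] == 1], 7))
    labels_tr <- rep(NA_real_, 100)
    labels_tr[lab] <- cl$y[lab]
    tr_views <- lapply(cl$views, function(v) v[train_idx, ])
    sup <- fit_mfss(lapply(cl$views, function(v) v[lab, ]), cl$y[lab],
                    semi_cfg = semi_config(max_iter = 0))
    fin <- fit_mfss(tr_views, labels_tr[train_idx])
    te <- lapply(cl$views, function(v) v[test_idx, ])
    mean(predict(fin, te)$label == cl$y[test_idx]) -
      mean(predict(sup, te)$label == cl$y[test_idx])
  }, numeric(1))
  expect_gte(mean(gains), 0)
})

test_that("strict error-rate mode keeps the tri-training invariants", {
  cl <- make_cluster_views(n_per_class = 60, sep = 2.2, seed = 15)
  labels <- cl$y
  set.seed(15)
  hide <- sample(120, 90)
  labels[hide] <- NA
  ens <- fit_mfss(cl$views, labels,
                  semi_cfg = semi_config(max_iter = 8, strict = TRUE))
  h <- ens$history
  expect_equal(sum(h$added) - sum(h$removed), sum(lengths(ens$semi_idx)))
  expect_true(all(unlist(ens$semi_idx) %in% hide))
  expect_true(ens$stop_reason %in% c("converged", "max_iter"))
})

test_that("majority vote equals a recount of the three per-view votes", {
  cl <- make_cluster_views(seed = 14)
  ens <- fit_mfss(cl$views, cl$y)
  newv <- lapply(cl$views, function(v) v + 0.5)
  p <- predict(ens, newv)
  expect_equal(dim(p$votes), c(60, 3))
  recount <- apply(p$votes, 1, function(v) if (sum(v) > 0) 1 else -1)
  expect_equal(p$label, recount)
  expect_true(all(p$votes %in% c(-1, 1)))
  # width mismatch is an argument error
  expect_error(predict(ens, lapply(cl$views, function(v) v[, 1, drop = FALSE])),
               "widths")
})

test_that("labeling-rate experiment reports the contracted schema", {
  ds <- small_dataset()
  tab <- labeling_rate_experiment(ds, rates = c(1.0), split = 0.7,
                                  n_repeats = 2, seed = 5)
  expect_true(all(c("rate", "initial", "final", "relative_gain") %in%
                    names(tab)))
  # at 100% labeling there is nothing to pseudo-label
  expect_equal(tab$initial, tab$final)
  expect_equal(tab$relative_gain, 0)
  runs <- attr(tab, "runs")
  expect_equal(nrow(runs), 2)
})

test_that("experiment errors when a rate starves a class of labels", {
  ds <- small_dataset()
  views <- lapply(extract_views(ds), `[[`, "matrix")
  y <- event_classes(ds)
  expect_error(fit_mfss(views, ifelse(seq_along(y) == 1, y, NA)),
               "both classes")
})
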