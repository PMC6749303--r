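test_that("confusion metrics match direct arithmetic", {
  pred <- c(rep(1, 8), rep(-1, 2), rep(-1, 90), rep(1, 10))
  truth <- c(rep(1, 10), rep(-1, 100))
  r <- evaluate(pred, truth)
  expect_equal(c(r$TP, r$FN, r$TN, r$FP), c(8, 2, 90, 10))
  expect_equal(r$sensitivity, 80)
  expect_equal(r$specificity, 900 / 10)
  expect_equal(r$miss_rate, 20)
  expect_equal(r$false_alarm_rate, 10)
  expect_equal(r$accuracy, 100 * 98 / 110)

  perfect <- evaluate(truth, truth)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$miss_rate, 0)
  expect_equal(perfect$false_alarm_rate, 0)
})

test_that("metrics equal a brute-force recount on random predictions", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.7, 0.3))
    pred <- sample(c(-1, 1), n, replace = TRUE)
    r <- evaluate(pred, truth)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (truth[j] == 1 && pred[j] == 1) tp <- tp + 1
      if (truth[j] == -1 && pred[j] == 1) fp <- fp + 1
      if (truth[j] == -1 && pred[j] == -1) tn <- tn + 1
      if (truth[j] == 1 && pred[j] == -1) fn <- fn + 1
    }
    expect_equal(c(r$TP, r$FP, r$TN, r$FN), c(tp, fp, tn, fn))
    expect_equal(r$TP + r$FP + r$TN + r$FN, n)
    # complement identities hold identically
    if (tp + fn > 0) expect_equal(r$miss_rate + r$sensitivity, 100)
    if (fp + tn > 0) expect_equal(r$false_alarm_rate + r$specificity, 100)
  }
})

test_that("per-activity false alarms aggregate to the total FP", {
  set.seed(22)
  n <- 300
  truth <- sample(c(-1, 1), n, replace = TRUE)
  pred <- sample(c(-1, 1), n, replace = TRUE)
  acts <- ifelse(truth == 1, "fall",
                 sample(c("walk", "bag_drop", "ball_drop"), n, replace = TRUE))
  r <- evaluate(pred, truth, activities = acts)
  fa <- r$per_activity_false_alarm
  counts <- vapply(names(fa), function(a)
    sum(truth == -1 & acts == a), numeric(1))
  expect_equal(sum(fa / 100 * counts), r$FP)
})

test_that("an absent class yields an explicit undefined marker", {
  r <- evaluate(c(-1, -1), c(-1, -1))
  expect_true(is.na(r$sensitivity))
  expect_true("sensitivity" %in% r$undefined)
  expect_equal(r$specificity, 100)
})

test_that("relative change reproduces the printed comparison arithmetic", {
  expect_equal(relative_change(82.54, 54.23), 52.20)
  expect_equal(relative_change(85.84, 58.45), 46.86)
  expect_equal(relative_change(90.28, 61.35), 47.16)
  expect_equal(relative_change(91.23, 63.47), 43.74)
  expect_equal(relative_change(95.48, 93.24), 2.40)
  expect_equal(relative_change(50, 50), 0)
  expect_error(relative_change(10, 0), "> 0")
})

test_that("autocorrelation baseline recovers an identical training event", {
  set.seed(23)
  recs <- c(lapply(1:3, function(i) random_record(n = 300, label = "fall")),
            lapply(1:5, function(i) random_record(n = 300, label = "walk")))
  train <- event_dataset(recs)
  test <- event_dataset(list(recs[[1]]))
  # with a single fall template equal to the test event, distance is zero
  single <- event_dataset(list(recs[[1]],
                               recs[[4]], recs[[5]], recs[[6]]))
  expect_equal(autocorr_baseline(single, test, lag_window = 50), 1)
  expect_error(autocorr_baseline(train, test, lag_window = 300),
               "lag_window")
})

test_that("single-class training data predicts that class everywhere", {
  set.seed(24)
  tr <- event_dataset(lapply(1:4, function(i)
    random_record(n = 200, label = "walk")))
  te <- event_dataset(lapply(1:3, function(i) random_record(n = 200)))
  expect_equal(autocorr_baseline(tr, te, lag_window = 40), rep(-1, 3))
})

test_that("the baseline separates classes with distinct dominant periods", {
  set.seed(25)
  mk <- function(freq, label) {
    t <- (0:399) / 200
    ch <- vapply(1:3, function(s)
      sin(2 * pi * freq * t + runif(1, 0, 2 * pi)) + rnorm(400, sd = 0.3),
      numeric(400))
    accel_record(ch, fs = 200, label = label)
  }
  train <- event_dataset(c(lapply(1:10, function(i) mk(5, "fall")),
                           lapply(1:10, function(i) mk(20, "walk"))))
  test <- event_dataset(c(lapply(1:10, function(i) mk(5, "fall")),
                          lapply(1:10, function(i) mk(20, "walk"))))
  pred <- autocorr_baseline(train, test, lag_window = 80)
  truth <- event_classes(test)
  expect_gt(mean(pred == truth), 0.9)
})

test_that("evaluation reports export as CSV", {
  r <- evaluate(c(1, -1, 1, -1), c(1, -1, -1, 1),
                activities = c("fall", "walk", "walk", "fall"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(r, f1, f2)
  tab <- utils::read.csv(f1)
  expect_equal(tab$value[tab$metric == "TP"], 1)
  act <- utils::read.csv(f2)
  expect_equal(names(act), c("activity", "false_alarm_pct"))
})
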