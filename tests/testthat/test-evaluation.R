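test_that("metrics follow the standard definitions", {
  truth <- c("x", "x", "x", "y")
  expect_equal(compute_metrics(truth, truth)$accuracy, 1)
  expect_equal(compute_metrics(truth, truth)$f1, 1)

  # binary confusion TP=2 FP=1 FN=1 TN=6 for the positive class
  t2 <- c(rep("pos", 3), rep("neg", 7))
  p2 <- c("pos", "pos", "neg", "pos", rep("neg", 6))
  m <- compute_metrics(t2, p2, class_names = c("neg", "pos"))
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$precision, 2 / 3)
  expect_equal(pos$recall, 2 / 3)
  expect_equal(pos$f1, 2 / 3)

  # all-one-class prediction on balanced two-class truth
  t3 <- rep(c("a", "b"), each = 5)
  m3 <- compute_metrics(t3, rep("a", 10), class_names = c("a", "b"))
  expect_equal(m3$accuracy, 0.5)

  expect_error(compute_metrics(c("a", "b"), "a"), "equal length")
  # class absent from truth and prediction contributes 0 and is flagged
  m4 <- compute_metrics(c("a", "a"), c("a", "a"), class_names = c("a", "b"))
  expect_identical(m4$absent_classes, "b")
  expect_equal(m4$f1, 0.5)
})

test_that("metrics agree with a brute-force confusion tally on random labels", {
  set.seed(99)
  classes <- c("u", "v", "w", "z")
  for (rep in 1:4) {
    n <- sample(50:1000, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- compute_metrics(truth, pred, classes)
    want <- naive_confusion(truth, pred, classes)
    expect_identical(unclass(unname(as.matrix(m$confusion))), unname(want))
    expect_equal(m$accuracy, sum(diag(want)) / n)
    expect_identical(unname(rowSums(m$confusion)),
                     as.numeric(table(factor(truth, classes))))
  }
})

make_separable_features <- function(n_subjects = 4L, per_subject = 6L) {
  # two classes separated far beyond within-class spread
  set.seed(123)
  rows <- list()
  for (s in seq_len(n_subjects)) for (k in seq_len(per_subject)) {
    lab <- if (k %% 2 == 0) "A" else "B"
    mu <- if (lab == "A") 0 else 50
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("s%d", s), video_id = sprintf("s%d_v%d", s, k),
      frame_index = 1L, label = lab,
      d_0000 = mu + rnorm(1), g_0000 = mu + rnorm(1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("losocv is perfect on separable data and audits subject isolation", {
  feats <- make_separable_features()
  rep <- losocv(feats)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$f1, 1)
  expect_identical(rep$n_samples, nrow(feats))
  expect_identical(length(rep$folds), 4L)
  # no subject appears in both train and test of its fold: each fold's pooled
  # sample count equals that subject's row count
  for (f in rep$folds) {
    expect_identical(length(f$truth),
                     sum(feats$subject_id == f$subject))
  }
  # confusion row sums equal per-class held-out counts
  expect_identical(unname(rowSums(rep$confusion)),
                   as.numeric(table(factor(feats$label))))
  expect_error(losocv(feats[feats$subject_id == "s1", ]), "2 subjects")
})

test_that("fold normalizers are fitted on training rows only", {
  feats <- make_separable_features()
  # make one subject's feature range extreme; only folds NOT holding it out
  # should see it in their fitted range
  feats$d_0000[feats$subject_id == "s1"] <- 1000 + seq_len(sum(feats$subject_id == "s1"))
  rep <- losocv(feats)
  hi <- vapply(rep$folds, function(f) f$normalizer$center["d_0000"] +
                 f$normalizer$scale["d_0000"], numeric(1))
  names(hi) <- vapply(rep$folds, `[[`, character(1), "subject")
  expect_lt(hi[["s1"]], 1000)          # s1 held out: its extremes unseen
  expect_true(all(hi[names(hi) != "s1"] > 1000))
})

test_that("training folds missing a class are flagged but still run", {
  feats <- make_separable_features()
  # subject s1 is the only carrier of class C
  feats$label[feats$subject_id == "s1"] <- "C"
  rep <- losocv(feats)
  expect_true(any(grepl("missing class", rep$warnings)))
  expect_identical(rep$n_samples, nrow(feats))
})

test_that("random predictions score near chance 1/K", {
  set.seed(7)
  classes <- letters[1:4]
  n <- 4000
  truth <- sample(classes, n, replace = TRUE)
  pred <- sample(classes, n, replace = TRUE)
  acc <- compute_metrics(truth, pred, classes)$accuracy
  # binomial 99.9% band around 1/4 at n = 4000
  expect_lt(abs(acc - 0.25), 3.3 * sqrt(0.25 * 0.75 / n))
})

test_that("reports serialize to JSON with the confusion matrix", {
  rep <- losocv(make_separable_features())
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  js <- jsonlite::fromJSON(path)
  expect_equal(js$accuracy, 1)
  expect_identical(js$config$kernel, "linear")
  expect_true(file.exists(paste0(path, ".confusion.tsv")))
})
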