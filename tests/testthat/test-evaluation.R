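# Stratified folds, confusion metrics, AUC, cross-validation harness.

test_that("stratified folds are balanced and reproducible", {
  labels <- rep(letters[1:10], each = 10)
  f <- stratified_kfold(labels, k = 10, seed = 4)
  # exact divisibility: every fold holds one sample of each class
  for (k in 1:10) {
    expect_equal(as.integer(table(labels[f == k])), rep(1L, 10))
  }
  expect_identical(f, stratified_kfold(labels, k = 10, seed = 4))
  # 9:1 train/validation split per round
  expect_equal(sum(f != 3), 90)
  # per-class counts across folds differ by at most one (uneven case)
  lab2 <- rep(c("a", "b"), c(23, 31))
  f2 <- stratified_kfold(lab2, k = 5, seed = 1)
  for (cl in c("a", "b")) {
    cnt <- table(factor(f2[lab2 == cl], levels = 1:5))
    expect_lte(diff(range(cnt)), 1)
  }
  expect_error(stratified_kfold(rep(c("a", "b"), c(30, 4)), k = 10),
               "fewer members.*b")
})

test_that("confusion metrics reproduce hand-computed contingency values", {
  # TP=9 FN=1 TN=8 FP=2 in one-vs-rest of the positive class
  y_true <- rep(c("pos", "neg"), c(10, 10))
  y_pred <- c(rep("pos", 9), "neg", rep("neg", 8), rep("pos", 2))
  m <- confusion_metrics(y_true, y_pred)
  # macro average of the two symmetric one-vs-rest views
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, (90 + 80) / 2)
  expect_equal(m$specificity, (80 + 90) / 2)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$fpr, 100 - m$specificity)
  # perfect prediction
  p <- confusion_metrics(y_true, y_true)
  expect_equal(p$accuracy, 100)
  expect_equal(p$fpr, 0)
})

test_that("degenerate predictors yield NA ratios with a warning, not zeros", {
  y_true <- rep(c("a", "b"), each = 5)
  y_pred <- rep("a", 10)
  expect_warning(m <- confusion_metrics(y_true, y_pred), "precision")
  expect_equal(m$accuracy, 50)
  expect_true(is.na(m$precision))
  expect_equal(m$sensitivity, 50)  # 100 for class a, 0 for class b
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(6)
  for (i in 1:20) {
    n <- 60
    y_true <- sample(c("u", "v", "w"), n, TRUE)
    y_pred <- sample(c("u", "v", "w"), n, TRUE)
    m <- suppressWarnings(confusion_metrics(y_true, y_pred))
    expect_equal(m$sensitivity + (100 - m$sensitivity), 100)
    if (!is.na(m$specificity) && !is.na(m$fpr)) {
      expect_equal(m$specificity + m$fpr, 100, tolerance = 1e-10)
    }
  }
})

test_that("AUC equals the brute-force pairwise comparison count", {
  set.seed(12)
  for (i in 1:10) {
    n <- 50
    y <- sample(c("neg", "pos"), n, TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)            # coarse scores force ties
    pos <- s[y == "pos"]; neg <- s[y == "neg"]
    wins <- 0
    for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(auc(y, s, positive = "pos"),
                 wins / (length(pos) * length(neg)))
  }
})

test_that("AUC limiting cases: separation, reversal, chance", {
  y <- rep(c("neg", "pos"), each = 20)
  s <- c(rnorm(20, 0), rnorm(20, 10))
  expect_equal(auc(y, s, positive = "pos"), 1)
  expect_equal(auc(y, -s, positive = "pos"), 0)
  expect_equal(auc(y, s, positive = "pos") + auc(y, -s, positive = "pos"), 1)
  set.seed(2)
  y2 <- rep(c("neg", "pos"), each = 2000)
  expect_lt(abs(auc(y2, rnorm(4000), positive = "pos") - 0.5), 0.02)
  expect_error(auc(rep("pos", 5), rnorm(5)), "two observed classes")
})

test_that("the cross-validation harness accounts epochs and averages folds", {
  # tiny but real: 4 classes x 12 samples of trivially separable inputs
  set.seed(40)
  n <- 48
  labs <- rep(c("p", "q", "r", "s"), each = 12)
  x <- array(rnorm(16 * 16 * 1 * n, sd = 0.05), c(16, 16, 1, n))
  lvl <- c(p = 0, q = 1, r = 2, s = 3)
  for (i in seq_len(n)) x[5:12, 5:12, , i] <- x[5:12, 5:12, , i] + lvl[labs[i]]
  cfg <- mcnn_config(input_shape = c(16, 16, 1), n_blocks = 2,
                     channel_progression = c(4, 8), fc_units = 16,
                     n_classes = 4, batch_size = 10, lr0 = 0.01, seed = 1)
  rep1 <- suppressWarnings(
    cross_validate(x, labs, cfg, k = 4, seed = 7, epochs_per_fold = 5))
  expect_equal(rep1$total_epochs, 20)      # k folds x epochs each
  df <- rep1$folds
  expect_equal(nrow(df), 5)
  num <- df[df$fold != "mean", -1]
  mean_row <- unlist(df[df$fold == "mean", -1])
  expect_equal(unname(colMeans(as.matrix(num))), unname(mean_row),
               tolerance = 1e-12)
  # the harness reports the Table-4 style layout
  txt <- format_metrics_table(rep1)
  expect_match(txt[1], "accuracy")
  expect_match(txt[length(txt)], "Mean value")
  # per-fold modality tags are bookkeeping only
  rep2 <- suppressWarnings(
    cross_validate(x, labs, cfg, k = 4, seed = 7, epochs_per_fold = 5,
                   fold_modality = c("CT", "CT", "PET", "CT")))
  expect_identical(rep2$folds$accuracy, rep1$folds$accuracy)
  expect_equal(rep2$fold_modality[3], "PET")
})
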