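# independent oracle: macro-F1 from an explicit confusion matrix
oracle_macro_f1 <- function(predicted, gold, labels) {
  f1s <- c()
  for (lab in labels) {
    tp <- sum(predicted == lab & gold == lab)
    fp <- sum(predicted == lab & gold != lab)
    fn <- sum(predicted != lab & gold == lab)
    if (tp + fp + fn == 0) next  # absent from both sides
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1s <- c(f1s, if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  mean(f1s)
}

test_that("macro-F1 matches the confusion-matrix oracle on hand-built cases", {
  sch <- toy_schema()
  # label A (lvef): TP=8 FP=2 FN=0; label B (rvef): TP=3 FP=0 FN=3
  gold <- c(rep("lvef", 8), rep("0", 2), rep("rvef", 6))
  pred <- c(rep("lvef", 8), rep("lvef", 2), rep("rvef", 3), rep("0", 3))
  ev <- evaluate_tokens(pred, gold, sch)
  f1_a <- 2 * 8 / (2 * 8 + 2 + 0)   # 0.8889
  f1_b <- 2 * 3 / (2 * 3 + 0 + 3)   # 0.6667
  expect_equal(ev$macro_f1, mean(c(f1_a, f1_b)))
  expect_equal(ev$macro_f1, oracle_macro_f1(pred, gold, c("lvef", "rvef")))
  per <- ev$per_label
  expect_equal(per$precision[per$label == "lvef"], 0.8)
  expect_equal(per$recall[per$label == "rvef"], 0.5)
})

test_that("perfect predictions give macro-F1 1 and all-null predictions give 0", {
  sch <- toy_schema()
  gold <- c("lvef", "lvef", "0", "rvef", "0")
  expect_equal(evaluate_tokens(gold, gold, sch)$macro_f1, 1)
  expect_equal(evaluate_tokens(rep("0", 5), gold, sch)$macro_f1, 0)
  expect_error(evaluate_tokens(gold[1:3], gold, sch), "length mismatch")
})

test_that("macro-F1 matches the oracle on random prediction/gold pairs", {
  sch <- fixture_schema()
  labels <- schema_labels(sch)
  set.seed(99)
  for (rep in 1:5) {
    gold <- sample(labels, 200, replace = TRUE, prob = c(0.7, rep(0.3 / 21, 21)))
    pred <- ifelse(runif(200) < 0.8, gold, sample(labels, 200, replace = TRUE))
    ev <- evaluate_tokens(pred, gold, sch)
    expect_equal(ev$macro_f1,
                 oracle_macro_f1(pred, gold, sch$measurement_types$label))
  }
})

test_that("labels absent from gold and predictions are excluded unless asked for", {
  sch <- toy_schema()
  gold <- c("lvef", "lvef", "0", "0")
  pred <- gold
  ev <- evaluate_tokens(pred, gold, sch)
  expect_equal(ev$included_labels, "lvef")
  ev0 <- evaluate_tokens(pred, gold, sch, include_absent = TRUE)
  expect_equal(ev0$macro_f1, (1 + 0) / 2)
})

test_that("the bootstrap interval is deterministic, degenerate when perfect, and brackets the estimate", {
  sch <- toy_schema()
  set.seed(7)
  n_rep <- 30
  gold <- pred <- rids <- c()
  for (r in seq_len(n_rep)) {
    g <- sample(c("lvef", "rvef", "0"), 20, replace = TRUE, prob = c(0.2, 0.2, 0.6))
    p <- ifelse(runif(20) < 0.85, g, "0")
    gold <- c(gold, g); pred <- c(pred, p); rids <- c(rids, rep(sprintf("r%d", r), 20))
  }
  b1 <- bootstrap_macro_f1(pred, gold, rids, sch, B = 200, seed = 5)
  b2 <- bootstrap_macro_f1(pred, gold, rids, sch, B = 200, seed = 5)
  expect_identical(b1, b2)
  expect_lte(b1$lo, b1$point)
  expect_gte(b1$hi, b1$point)
  expect_equal(b1$point, evaluate_tokens(pred, gold, sch)$macro_f1)

  perfect <- bootstrap_macro_f1(gold, gold, rids, sch, B = 100, seed = 5)
  expect_equal(c(perfect$lo, perfect$hi), c(1, 1))

  expect_warning(bootstrap_macro_f1(gold[1:20], gold[1:20], rids[1:20], sch, B = 10, seed = 1),
                 "single report")
})

test_that("one-vs-rest AUC matches the rank-sum oracle and its degenerate cases", {
  skip_if_not_installed("pROC")
  sch <- toy_schema()
  # one-hot scores on gold -> AUC 1
  gold <- c("lvef", "lvef", "0", "0", "rvef", "0")
  hot <- matrix(0, 6, 3, dimnames = list(NULL, c("0", "lvef", "rvef")))
  hot[cbind(seq_along(gold), match(gold, colnames(hot)))] <- 1
  r1 <- roc_per_label(hot, gold, sch)
  expect_equal(r1$per_label$auc, c(1, 1), ignore_attr = TRUE)

  # scores independent of gold -> AUC 0.5
  flat <- matrix(0.5, 6, 3, dimnames = list(NULL, c("0", "lvef", "rvef")))
  r2 <- roc_per_label(flat, gold, sch)
  expect_equal(r2$per_label$auc, c(0.5, 0.5), ignore_attr = TRUE)

  # 3 positives / 3 negatives with a given score order: Mann-Whitney oracle
  gold3 <- c("lvef", "lvef", "lvef", "0", "0", "0")
  sc <- c(0.9, 0.4, 0.7, 0.6, 0.2, 0.1)
  m <- cbind(`0` = 1 - sc, lvef = sc, rvef = 0)
  pos <- sc[1:3]; neg <- sc[4:6]
  u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(r3 <- roc_per_label(m, gold3, sch)$per_label$auc[1], u / 9)

  # label with no gold positives -> missing AUC
  expect_true(is.na(roc_per_label(m, rep("lvef", 6), sch)$per_label$auc[2]))
})
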