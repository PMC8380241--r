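test_that("confusion_matrix counts truth rows against prediction columns", {
  tax <- c("A", "B")
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         taxonomy = tax)
  expect_identical(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 2L), 2, 2,
                   dimnames = list(truth = tax, predicted = tax))[, ])
  expect_equal(attr(cm, "n_total"), 4L)

  # identity case: purely diagonal
  set.seed(2)
  labs <- sample(PHENOTYPE_CLASSES, 200, replace = TRUE)
  cmd <- confusion_matrix(labs, labs)
  expect_true(all(cmd[upper.tri(cmd) | lower.tri(cmd)] == 0))
  expect_equal(sum(diag(cmd)), 200L)

  # brute-force tally oracle on 10,000 random pairs
  set.seed(3)
  t10 <- sample(PHENOTYPE_CLASSES, 10000, replace = TRUE)
  p10 <- sample(PHENOTYPE_CLASSES, 10000, replace = TRUE)
  cm10 <- confusion_matrix(t10, p10)
  for (i in seq_len(9)) for (j in seq_len(9)) {
    expect_identical(cm10[i, j],
                     sum(t10 == PHENOTYPE_CLASSES[i] &
                           p10 == PHENOTYPE_CLASSES[j]))
  }
  # row sums = truth counts; column sums = prediction counts
  expect_identical(as.integer(rowSums(cm10)),
                   as.integer(table(factor(t10, PHENOTYPE_CLASSES))))
  expect_identical(as.integer(colSums(cm10)),
                   as.integer(table(factor(p10, PHENOTYPE_CLASSES))))

  expect_error(confusion_matrix(c("A"), c("A", "B"), c("A", "B")), "length")
  expect_error(confusion_matrix("Z", "A", c("A", "B")), "unknown")
})

test_that("per-class metrics follow the precision/sensitivity formulas", {
  cm <- confusion_matrix(rep(c("A", "B"), c(100, 100)),
                         c(rep("A", 90), rep("B", 10),
                           rep("A", 5), rep("B", 95)),
                         taxonomy = c("A", "B"))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision[1], 100 * 90 / 95)
  expect_equal(pc$sensitivity[1], 90)
  expect_equal(pc$precision[2], 100 * 95 / 105)
  expect_equal(pc$sensitivity[2], 95)
  ov <- overall_metrics(cm)
  expect_equal(ov$accuracy, 92.5)
  expect_equal(ov$misclassification, 7.5)

  # degenerate conventions: never-predicted class has NA precision, 0 sens
  cm2 <- confusion_matrix(c("A", "A", "B"), c("A", "A", "A"), c("A", "B"))
  pc2 <- per_class_metrics(cm2)
  expect_true(is.na(pc2$precision[2]))
  expect_equal(pc2$sensitivity[2], 0)

  # perfect diagonal: all 100%
  cm3 <- confusion_matrix(c("A", "B"), c("A", "B"), c("A", "B"))
  pc3 <- per_class_metrics(cm3)
  expect_true(all(pc3$precision == 100) && all(pc3$sensitivity == 100))
})

test_that("metric identities hold against the one-vs-rest oracle", {
  set.seed(5)
  for (rep_i in 1:50) {
    t <- sample(PHENOTYPE_CLASSES, 300, replace = TRUE)
    p <- sample(PHENOTYPE_CLASSES, 300, replace = TRUE)
    cm <- confusion_matrix(t, p)
    pc <- per_class_metrics(cm)
    bf <- brute_metrics(t, p, PHENOTYPE_CLASSES)
    expect_equal(pc$precision, bf$precision, tolerance = 1e-9)
    expect_equal(pc$sensitivity, bf$sensitivity, tolerance = 1e-9)
    ok <- !is.na(pc$precision)
    expect_equal(pc$precision[ok] + pc$false_discovery_rate[ok],
                 rep(100, sum(ok)), tolerance = 1e-9)
    ok <- !is.na(pc$sensitivity)
    expect_equal(pc$sensitivity[ok] + pc$false_negative_rate[ok],
                 rep(100, sum(ok)), tolerance = 1e-9)
  }
})

test_that("uniform random predictions score near chance", {
  set.seed(7)
  t <- sample(PHENOTYPE_CLASSES, 9000, replace = TRUE)
  p <- sample(PHENOTYPE_CLASSES, 9000, replace = TRUE)
  acc <- overall_metrics(confusion_matrix(t, p))$accuracy
  sd_acc <- 100 * sqrt((1 / 9) * (8 / 9) / 9000)
  expect_lt(abs(acc - 100 / 9), 3 * sd_acc)
})

test_that("split_train_test partitions and stratifies", {
  labs <- rep(PHENOTYPE_CLASSES[1:4], each = 25)
  sp <- split_train_test(labels = labs, fraction = 0.6, seed = 4)
  expect_equal(length(sp$train), 60L)
  expect_equal(length(sp$test), 40L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labs))
  expect_length(intersect(sp$train, sp$test), 0)
  # per-class proportions within one record of target
  for (cl in unique(labs)) {
    n_tr <- sum(labs[sp$train] == cl)
    expect_lte(abs(n_tr - 0.6 * 25), 1)
  }
  # seeded reproducibility
  expect_identical(split_train_test(labels = labs, seed = 4), sp)
  expect_false(identical(split_train_test(labels = labs, seed = 5), sp))
  # singleton class goes to train with a warning
  expect_warning(sp1 <- split_train_test(labels = c(labs, "other"),
                                         seed = 4), "other")
  expect_true((length(labs) + 1L) %in% sp1$train)
  expect_error(split_train_test(labels = labs, fraction = 1.2), "fraction")
})

test_that("rendered report rounds to one decimal and keeps counts", {
  cm <- confusion_matrix(rep(c("A", "B"), c(7, 3)),
                         c(rep("A", 6), "B", rep("B", 3)), c("A", "B"))
  rep_ <- render_confusion_report(cm)
  expect_equal(sum(rep_$counts), 10)
  expect_equal(rep_$overall$accuracy, 90)
  expect_identical(rep_$counts, t(render_confusion_report(cm, transpose = TRUE)$counts))
})
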