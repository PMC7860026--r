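test_that("confusion matrix arithmetic matches hand counts", {
  # perfect predictions: identity percentages
  cm <- confusion(rep(c("a", "b"), each = 5), rep(c("a", "b"), each = 5))
  expect_equal(unname(diag(cm$percent)), c(100, 100))
  expect_equal(sum(cm$unassigned), 0L)

  # 10 of class A: 9 -> A, 1 -> B
  cm2 <- confusion(rep("A", 10), c(rep("A", 9), "B"), classes = c("A", "B"))
  expect_equal(unname(cm2$percent["A", ]), c(90, 10))

  # 10 of class A: 8 -> A, 1 -> B, 1 unassigned: percentages over assigned
  cm3 <- confusion(rep("A", 10), c(rep("A", 8), "B", "unassigned"),
                   classes = c("A", "B"))
  expect_equal(unname(cm3$percent["A", ]), c(88.9, 11.1))
  expect_equal(cm3$unassigned[["A"]], 1L)
  # conservation: assigned + unassigned = samples per true class
  expect_equal(sum(cm3$counts["A", ]) + cm3$unassigned[["A"]], 10L)
  expect_error(confusion("a", c("a", "b")), "length")
})

test_that("accuracy report separates of-total and of-assigned denominators", {
  cm <- confusion(rep(c("a", "b"), each = 5), rep(c("a", "b"), each = 5))
  rep0 <- accuracy_report(cm)
  expect_equal(rep0$accuracy_of_total, 100)
  expect_equal(rep0$misclassified_of_total, 0)

  # 95 misclassified of 2505 validation samples -> 3.8%
  truth <- rep("x", 2505)
  pred <- c(rep("x", 2410), rep("y", 95))
  rep1 <- accuracy_report(confusion(truth, pred, classes = c("x", "y")))
  expect_equal(round(rep1$misclassified_of_total, 1), 3.8)
  expect_equal(round(rep1$accuracy_of_total, 1), 96.2)

  # 2 classes, counts ((8,1),(0,9)), 1 unassigned in class A
  truth2 <- c(rep("A", 10), rep("B", 9))
  pred2 <- c(rep("A", 8), "B", "unassigned", rep("B", 9))
  rep2 <- accuracy_report(confusion(truth2, pred2, classes = c("A", "B")))
  expect_equal(rep2$n_assigned, 18L)
  expect_equal(round(rep2$accuracy_of_assigned, 1), 94.4)  # 17/18
  expect_equal(rep2$n_unassigned, 1L)
})

test_that("collapsing to lineage preserves unassigned and merges within-lineage errors", {
  map <- c(carnica = "C", cecropia = "C", macedonica = "C", mellifera = "M")
  pred <- c("carnica", "macedonica", "unassigned", "mellifera")
  expect_equal(collapse_to_lineage(pred, map), c("C", "C", "unassigned", "M"))
  expect_error(collapse_to_lineage(c("unknown"), map), "no lineage mapping")
  # a cecropia -> macedonica confusion is correct at lineage level
  truth <- c("cecropia")
  pred2 <- c("macedonica")
  expect_false(pred2 == truth)
  expect_true(collapse_to_lineage(pred2, map) == map[truth])
})

test_that("lineage accuracy is never below subspecies accuracy", {
  map <- c(s1 = "L1", s2 = "L1", s3 = "L2", s4 = "L2")
  set.seed(5)
  for (i in 1:20) {
    truth <- sample(names(map), 50, replace = TRUE)
    pred <- truth
    flip <- sample(50, 10)
    pred[flip] <- sample(names(map), 10, replace = TRUE)
    acc_sub <- mean(pred == truth)
    acc_lin <- mean(map[pred] == map[truth])
    expect_gte(acc_lin, acc_sub)
  }
})

test_that("threshold sweep conserves counts and is monotone in assignment", {
  set.seed(6)
  probs <- matrix(runif(60), ncol = 3)
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("a", "b", "c")
  truth <- sample(c("a", "b", "c"), 20, replace = TRUE)
  sw <- threshold_sweep(probs, truth, thresholds = seq(0, 1, by = 0.1))
  expect_equal(sw$assigned_fraction[sw$threshold == 0], 1.0)
  expect_true(all(sw$n_assigned + sw$n_unassigned == 20L))
  expect_true(all(diff(sw$assigned_fraction) <= 0))
})

test_that("call rate counts non-missing fractions per sample and class", {
  snps <- data.frame(chrom = "c", pos = 1:4, ref = "A", alt = "C")
  g <- rbind(c(0L, 1L, 2L, NA), c(0L, 0L, 0L, 0L))
  lab <- data.frame(sample_id = c("sample1", "sample2"),
                    pool_id = "p", subspecies = c("s1", "s2"), lineage = "L")
  gm <- genotype_matrix(g, snps, labels = lab)
  cr <- call_rate(gm)
  expect_equal(unname(cr$per_sample), c(0.75, 1.0))
  expect_equal(cr$per_class[["s1"]], 0.75)
  expect_equal(cr$overall, 0.875)
})

test_that("the 2-D embedding separates classes and is deterministic", {
  gm <- separable_genotypes(n_per_class = 15L, n_snps = 40L, seed = 7)
  x <- one_hot_encode(gm)
  e1 <- embed_2d(x, seed = 3)
  e2 <- embed_2d(x, seed = 3)
  expect_identical(e1, e2)
  grp <- gm$labels$subspecies
  centA <- colMeans(e1[grp == "clsA", ])
  centB <- colMeans(e1[grp == "clsB", ])
  spread <- mean(c(
    sqrt(rowSums(sweep(e1[grp == "clsA", ], 2, centA)^2)),
    sqrt(rowSums(sweep(e1[grp == "clsB", ], 2, centB)^2))
  ))
  expect_gt(sqrt(sum((centA - centB)^2)), spread)
  # identical samples land on coincident points
  same <- genotype_matrix(rbind(gm$g[1, ], gm$g[1, ], gm$g[2, ]), gm$snps)
  es <- embed_2d(one_hot_encode(same), seed = 1)
  expect_lt(sqrt(sum((es[1, ] - es[2, ])^2)), 1e-6)
  expect_error(embed_2d(x[1:2, ], seed = 1), "at least 3")
})

test_that("label outlier flagging catches a planted mislabel and only it", {
  gm <- separable_genotypes(n_per_class = 15L, n_snps = 40L, seed = 8)
  labels <- gm$labels$subspecies
  expect_length(flag_label_outliers(gm, labels, k = 5L), 0L)
  labels_bad <- labels
  labels_bad[4] <- "clsB"  # a clsA bee mislabeled as clsB
  flagged <- flag_label_outliers(gm, labels_bad, k = 5L)
  expect_equal(flagged, rownames(gm$g)[4])
  expect_error(flag_label_outliers(gm, labels, k = 30L), "smaller")
})
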