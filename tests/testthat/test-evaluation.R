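# ROC/AUC against brute force, confusion matrices, evaluation report
# identities, and the segmentation-based translocation oracle.

test_that("trapezoidal ROC AUC equals brute-force pairwise comparison on
           random instances, including ties", {
  set.seed(71)
  for (rep_ in 1:40) {
    n <- sample(6:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- if (rep_ %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
    else runif(n)  # every third instance has heavy ties
    expect_equal(rocAuc(s, y)$auc, bruteForceAuc(s, y), tolerance = 1e-12)
  }
})

test_that("ROC endpoints and degenerate separations behave", {
  r <- rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  set.seed(72)
  # labels independent of scores: AUC near 1/2 at large n
  expect_equal(rocAuc(runif(4000), rbinom(4000, 1, 0.5))$auc, 0.5,
               tolerance = 0.05)
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  for (rep_ in 1:5) {
    y <- c(0, 1, rbinom(30, 1, 0.5))
    s <- round(runif(32), 2)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(rocAuc(s, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("confusion matrices tally predictions exactly", {
  scores <- c(0.9, 0.6, 0.4, 0.2, 0.51)
  labels <- c(1, 0, 1, 0, 1)
  cm <- confusionBinary(scores, labels)
  expect_identical(cm["active", "active"], 2L)    # 0.9, 0.51
  expect_identical(cm["active", "inactive"], 1L)  # 0.4
  expect_identical(cm["inactive", "active"], 1L)  # 0.6
  expect_identical(cm["inactive", "inactive"], 1L)
  expect_identical(sum(cm), 5L)
  # strict threshold: a score of exactly 0.5 is inactive
  expect_identical(confusionBinary(0.5, 1)["active", "inactive"], 1L)

  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.3, 0.3, 0.4),
                 c(0.5, 0.5, 0.0))
  mc <- confusionMulti(probs, c(1, 2, 2, 2))
  expect_identical(mc$counts[1, 1], 1L)
  expect_identical(mc$counts[2, 2], 1L)
  expect_identical(mc$counts[2, 3], 1L)
  expect_identical(mc$counts[2, 1], 1L)  # tie broken to lowest index
  expect_equal(rowSums(mc$percent)[rowSums(mc$counts) > 0],
               c(100, 100), ignore_attr = TRUE)
  # all-correct predictions have a diagonal matrix
  d <- confusionMulti(diag(3)[c(1, 2, 3), ], 1:3)
  expect_identical(sum(d$counts) - sum(diag(d$counts)), 0L)
})

test_that("evaluation report means recompute from per-gene values", {
  set.seed(74)
  man <- data.frame(
    gene = rep(c("KRAS", "BRAF"), each = 20),
    variant = rep(c("WT", "mut"), 20),
    annotation_class = rep(c("WT", "activating"), 20),
    stringsAsFactors = FALSE)
  scores <- ifelse(man$annotation_class == "WT", runif(40, 0, 0.45),
                   runif(40, 0.55, 1))
  rep_ <- evalReport(scores, man)
  expect_identical(nrow(rep_$perGene), 2L)
  expect_equal(rep_$meanAuc, mean(rep_$perGene$auc))
  expect_equal(rep_$meanAccuracy, mean(rep_$perGene$accuracy))
  expect_equal(rep_$perGene$auc, c(1, 1))
  expect_identical(sum(rep_$confusion), 40L)
})

test_that("the translocation oracle is monotone in activation and
           reports empty wells explicitly", {
  p <- smallSimParams()
  tr <- sampleLayout(p, 31)
  ratios <- vapply(c(0.1, 0.5, 0.9), function(a)
    oracleRatio(renderWell(tr, a, p, seed = 77)$image)$ratio, 1)
  expect_true(all(diff(ratios) > 0))
  # no transfected cells -> explicit empty result, not a number
  p0 <- smallSimParams(transfectionRate = 0)
  tr0 <- sampleLayout(p0, 31)
  r0 <- oracleRatio(renderWell(tr0, 0.5, p0, seed = 77)$image)
  expect_true(r0$empty)
  expect_true(is.na(r0$ratio))
  expect_identical(r0$nCells, 0L)
  expect_gt(r0$nNuclei, 0L)
})

test_that("oracle ratio tracks activation over a grid (rank
           correlation)", {
  p <- smallSimParams()
  alphas <- rep(c(0, 0.25, 0.5, 0.75, 1), each = 2)
  ratios <- vapply(seq_along(alphas), function(i) {
    tr <- sampleLayout(p, 300 + i)
    oracleRatio(renderWell(tr, alphas[i], p, seed = 600 + i)$image)$ratio
  }, 1)
  expect_true(all(is.finite(ratios)))
  expect_gte(cor(alphas, ratios, method = "spearman"), 0.95)
})
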