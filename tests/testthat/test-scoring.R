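# Variant aggregation, the strict 0.5 activity call, class breakdowns,
# variant-name parsing and the comparison to wildtype.

test_that("variant summaries average scores and call strictly above 0.5", {
  man <- data.frame(gene = "BRAF", variant = "V600E",
                    annotation_class = "activating")[rep(1, 3), ]
  s <- summarizeVariants(c(0.8, 0.9, 1.0), man)
  expect_equal(s$mean_score, 0.9)
  expect_identical(s$call, "active")
  expect_identical(s$n_images, 3L)
  expect_equal(s$sem, sd(c(0.8, 0.9, 1.0)) / sqrt(3))
  # the boundary: a mean of exactly 0.5 is inactive, 0.5 + eps is active
  man1 <- man[1, , drop = FALSE]
  expect_identical(summarizeVariants(0.5, man1)$call, "inactive")
  expect_identical(summarizeVariants(0.5 + 1e-9, man1)$call, "active")
  expect_identical(summarizeVariants(0.47, man1)$call, "inactive")
  expect_error(summarizeVariants(numeric(0), man[0, ]), "no scores")
})

test_that("aggregation is permutation-invariant over images", {
  set.seed(51)
  man <- data.frame(gene = rep(c("KRAS", "BRAF"), each = 6),
                    variant = rep(c("G12D", "WT", "V600E"), each = 4),
                    annotation_class = "VUS")
  sc <- runif(12)
  perm <- sample.int(12)
  s1 <- summarizeVariants(sc, man)
  s2 <- summarizeVariants(sc[perm], man[perm, ])
  expect_equal(s1, s2)
})

test_that("class breakdown counts actives per gene with totals, omitting
           absent classes", {
  summ <- data.frame(
    gene = c("KRAS", "KRAS", "BRAF"),
    variant = c("G12D", "G13D", "V600E"),
    annotation_class = c("VUS", "VUS", "activating"),
    n_images = 2L, mean_score = c(0.9, 0.2, 0.8), sem = 0,
    call = c("active", "inactive", "active"), stringsAsFactors = FALSE)
  b <- classBreakdown(summ)
  vus <- b[b$annotation_class == "VUS" & b$gene == "KRAS", ]
  expect_identical(vus$n_active, 1L)
  expect_identical(vus$n_total, 2L)
  expect_equal(vus$percent_active, 50)
  tot <- b[b$annotation_class == "VUS" & b$gene == "Total", ]
  expect_equal(tot$percent_active, 100 * tot$n_active / tot$n_total)
  expect_false("predicted" %in% b$annotation_class)  # empty class omitted
  # percentages recompute exactly from their own columns
  expect_equal(b$percent_active, 100 * b$n_active / b$n_total)
})

test_that("variant names parse to anchor positions; failures are
           reported, not dropped", {
  summ <- data.frame(
    gene = "cKIT",
    variant = c("V654A", "p.V600E", "W557_558Del", "G12_G13_Del_Ins_DC",
                "V152del", "odd-name", "WT"),
    annotation_class = "VUS", n_images = 1L,
    mean_score = seq(0.2, 0.8, length.out = 7), sem = 0,
    call = "inactive", stringsAsFactors = FALSE)
  pp <- positionProfile(summ)
  expect_identical(pp$profile$position[pp$profile$variant == "V654A"], 654L)
  expect_identical(pp$profile$position[pp$profile$variant == "p.V600E"],
                   600L)
  expect_identical(pp$profile$position[
    pp$profile$variant == "W557_558Del"], 557L)
  expect_identical(pp$profile$position[
    pp$profile$variant == "G12_G13_Del_Ins_DC"], 12L)
  expect_identical(pp$profile$position[pp$profile$variant == "V152del"],
                   152L)
  expect_true(all(diff(pp$profile$position) >= 0))  # sorted by position
  expect_setequal(pp$rejected$variant, c("odd-name", "WT"))
  expect_true(all(nzchar(pp$rejected$reason)))
})

test_that("comparison to wildtype is a Welch t test with an explicit
           degenerate-input error", {
  set.seed(52)
  a <- rnorm(20, 0.6, 0.05)
  b <- rnorm(25, 0.3, 0.08)
  got <- compareToWT(a, b)
  ref <- t.test(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p.value, ref$p.value)
  refP <- t.test(a, b, var.equal = TRUE)
  expect_equal(compareToWT(a, b, pooled = TRUE)$p.value, refP$p.value)
  expect_error(compareToWT(rep(0.5, 5), rep(0.5, 5)), "degenerate")
  expect_error(compareToWT(0.5, c(0.1, 0.2)), "at least 2")
})

test_that("type-I error of the wildtype comparison is near nominal under
           a simulated null", {
  set.seed(53)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    compareToWT(rnorm(15, 0.4, 0.1), rnorm(15, 0.4, 0.1))$p.value
  }, 1)
  rate <- mean(p < 0.05)
  # binomial 99% band around 0.05 at 400 replicates
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / reps))
  # and p-values are roughly uniform: KS distance small
  expect_lt(suppressWarnings(ks.test(p, "punif"))$statistic, 0.08)
})
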