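# Image I/O round trips and plate-stratified splitting.

test_that("well images round-trip through 16-bit multi-page TIFF", {
  f <- tempfile(fileext = ".tif")
  on.exit(unlink(f))
  set.seed(21)
  arr <- array(round(runif(32 * 32 * 3) * 65535) / 65535, c(32, 32, 3))
  img <- new("WellImage", data = arr,
             channelRoles = c("nuclear", "marker", "reporter"), path = "")
  writeWellImage(img, f)
  back <- loadWellImage(f)
  expect_equal(imageData(back), arr, tolerance = 1 / 65535)
  expect_identical(channelRoles(back), c("nuclear", "marker", "reporter"))
  # a constant full-scale page loads as constant 1.0
  ones <- new("WellImage", data = array(1, c(8, 8, 3)),
              channelRoles = c("nuclear", "marker", "reporter"), path = "")
  writeWellImage(ones, f)
  expect_true(all(imageData(loadWellImage(f)) == 1))
})

test_that("wrong channel counts raise format errors naming the path", {
  f <- tempfile(fileext = ".tif")
  on.exit(unlink(f))
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.2, 8, 8)), f,
                  bits.per.sample = 16L)
  expect_error(loadWellImage(f), "2 channels")
  expect_error(loadWellImage(f), basename(f), fixed = TRUE)
  expect_error(loadWellImage(tempfile()), "cannot read")
})

test_that("getChannel selects by role and rejects unknown roles", {
  arr <- array(0, c(4, 4, 3))
  arr[, , 2] <- 0.7
  img <- new("WellImage", data = arr,
             channelRoles = c("nuclear", "marker", "reporter"), path = "")
  expect_true(all(getChannel(img, "marker") == 0.7))
  expect_true(all(getChannel(img, "nuclear") == 0))
  expect_error(getChannel(img, "phase"), "no channel")
})

makeManifest <- function(plateSizes) {
  n <- sum(plateSizes)
  data.frame(
    image_path = sprintf("img%03d.tif", seq_len(n)),
    plate_id = rep(sprintf("P%02d", seq_along(plateSizes)), plateSizes),
    well_id = "W01", gene = "KRAS",
    variant = rep(c("WT", "G12D"), length.out = n),
    annotation_class = rep(c("WT", "activating"), length.out = n),
    stringsAsFactors = FALSE)
}

test_that("ten equal plates at 60/20/20 split exactly 6/2/2", {
  ds <- wellDataset(makeManifest(rep(4L, 10)))
  sp <- splitByPlate(ds, splitSpec(seed = 3))
  expect_identical(vapply(sp, length, 1L),
                   c(train = 24L, val = 8L, test = 8L))
  expect_identical(length(unique(plateIds(sp$train))), 6L)
  expect_identical(length(unique(plateIds(sp$val))), 2L)
  expect_identical(length(unique(plateIds(sp$test))), 2L)
})

test_that("splits are a partition: plates never straddle, nothing lost", {
  set.seed(33)
  for (rep_ in 1:10) {
    sizes <- sample(2:12, sample(3:9, 1), replace = TRUE)
    ds <- wellDataset(makeManifest(sizes))
    sp <- splitByPlate(ds, splitSpec(seed = rep_))
    plates <- lapply(sp, function(d) unique(plateIds(d)))
    expect_identical(length(intersect(plates$train, plates$val)), 0L)
    expect_identical(length(intersect(plates$train, plates$test)), 0L)
    expect_identical(length(intersect(plates$val, plates$test)), 0L)
    got <- do.call(rbind, lapply(sp, manifest))
    expect_identical(sort(got$image_path), sort(manifest(ds)$image_path))
  }
  expect_error(splitByPlate(wellDataset(makeManifest(c(5L, 5L)))),
               "at least 3 plates")
})

test_that("greedy assignment is near the exhaustive optimum for unequal
           plates and exact when fractions divide evenly", {
  ns <- asNamespace("pathscore")
  target <- c(0.6, 0.2, 0.2)
  l1 <- function(counts, total) sum(abs(counts / total - target))
  bruteBest <- function(sizes) {
    k <- length(sizes)
    best <- Inf
    for (code in 0:(3^k - 1)) {
      x <- code
      counts <- c(0, 0, 0)
      for (i in seq_len(k)) {
        counts[x %% 3 + 1] <- counts[x %% 3 + 1] + sizes[i]
        x <- x %/% 3
      }
      best <- min(best, l1(counts, sum(sizes)))
    }
    best
  }
  set.seed(44)
  for (rep_ in 1:8) {
    sizes <- sample(1:20, sample(4:7, 1), replace = TRUE)
    assign <- ns$assignPlates(sizes, as.character(seq_along(sizes)),
                              target, seed = rep_)
    counts <- vapply(c("train", "val", "test"),
                     function(s) sum(sizes[assign == s]), 1)
    expect_lte(l1(counts, sum(sizes)), bruteBest(sizes) + 0.1)
  }
  # exactly divisible case is hit exactly
  assign <- ns$assignPlates(rep(10L, 5), as.character(1:5), target, 1L)
  counts <- vapply(c("train", "val", "test"),
                   function(s) sum(10L * (assign == s)), 1)
  expect_identical(unname(counts), c(30, 10, 10))
})

test_that("splitting is deterministic under a fixed seed and writes /
           reads back losslessly", {
  ds <- wellDataset(makeManifest(c(3L, 5L, 2L, 7L, 4L)))
  s1 <- splitByPlate(ds, splitSpec(seed = 9))
  s2 <- splitByPlate(ds, splitSpec(seed = 9))
  expect_identical(lapply(s1, manifest), lapply(s2, manifest))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeSplit(s1, f)
  back <- readSplit(f)
  for (s in names(s1))
    expect_identical(manifest(back[[s]])$image_path,
                     manifest(s1[[s]])$image_path)
})

test_that("block-mean downsampling is exact area interpolation", {
  ns <- asNamespace("pathscore")
  m <- matrix(1:16, 4, 4)
  bm <- ns$blockMean(m, 2L)
  expect_equal(bm, matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                            mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2, 2))
  # resizing a constant image preserves the constant for any factor
  arr <- array(0.3, c(12, 12, 3))
  expect_true(all(abs(ns$resizeToSide(arr, 4L) - 0.3) < 1e-12))
})
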