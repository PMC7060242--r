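# Shared fixtures: small simulator settings, tiny model specs, and
# independent reference implementations used as oracles.

# Small, fast simulator settings used throughout the unit tests.
tinySimParams <- function(...) {
  simParams(fovSize = 128L, meanCells = 15, sdCells = 2,
            nucleusRadiusRange = c(4, 7), ...)
}

smallSimParams <- function(...) {
  simParams(fovSize = 256L, meanCells = 80, sdCells = 8, ...)
}

# Tiny architecture for fast forward/backward tests.
tinySpec <- function(...) {
  modelSpec(scales = c(16L, 8L), patch = 8L, filters = c(2L, 3L),
            fcWidths = c(5L), dropout = 0, nGenes = 3L, ...)
}

# Naive direct convolution ('same' padding, stride 1) as an oracle for the
# im2col + GEMM path.
naiveConv <- function(x, K) {
  d <- dim(x)
  k <- dim(K)[1]
  p <- k %/% 2
  f <- dim(K)[4]
  out <- array(0, c(d[1], d[2], f, d[4]))
  for (n in seq_len(d[4])) for (ff in seq_len(f))
    for (w in seq_len(d[2])) for (h in seq_len(d[1])) {
      s <- 0
      for (c in seq_len(d[3])) for (kx in seq_len(k)) for (ky in seq_len(k)) {
        sh <- h + ky - 1 - p
        sw <- w + kx - 1 - p
        if (sh >= 1 && sh <= d[1] && sw >= 1 && sw <= d[2])
          s <- s + x[sh, sw, c, n] * K[ky, kx, c, ff]
      }
      out[h, w, ff, n] <- s
    }
  out
}

# Brute-force AUC: probability that a random positive outranks a random
# negative, with half credit for ties.
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# A rendered two-class experiment shared by scoring tests (tiny, seeded).
makeTinyExperiment <- function(dir, nWells = 8L, alphas = c(0.05, 0.9),
                               seed = 7, plateSize = 4L,
                               params = tinySimParams()) {
  d <- data.frame(gene = "KRAS", variant = c("WT", "G12D"),
                  annotation_class = c("WT", "activating"),
                  alpha = alphas, n_wells = as.integer(nWells))
  generateExperiment(d, params, seed = seed, outDir = dir,
                     plateSize = plateSize)
}
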