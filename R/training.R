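# Seeded training loop: mini-batch Adam on a plate-stratified split.

# Recursive Adam update over the nested weight list. Gradients mirror the
# weight structure; batch-norm running statistics (rm / rv) are buffers
# and are skipped.
adamInit <- function(weights) {
  walk <- function(w) {
    if (is.list(w)) return(lapply(w, walk))
    array(0, dim = dim(w) %||% length(w))
  }
  list(m = walk(weights), v = walk(weights), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v, path) {
    if (is.list(w)) {
      for (nm in names(w) %||% seq_along(w)) {
        if (identical(nm, "rm") || identical(nm, "rv")) next
        if (is.null(g[[nm]])) next
        r <- upd(w[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        w[[nm]] <- r$w; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(w = w, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  r <- upd(weights, grads, state$m, state$v, character(0))
  list(weights = r$w, state = list(m = r$m, v = r$v, t = state$t))
}

# Derive binary or gene labels from a manifest.
datasetLabels <- function(man, head, geneLevels = NULL) {
  if (head == "activation") {
    cls <- as.character(man$annotation_class)
    bad <- setdiff(unique(cls), c("WT", "activating"))
    if (length(bad))
      stop("activation-head training needs only WT / activating wells; ",
           "found class(es): ", paste(bad, collapse = ", "),
           " (subset the manifest first)")
    as.numeric(cls == "activating")
  } else {
    g <- factor(as.character(man$gene), levels = geneLevels %||%
                  sort(unique(as.character(man$gene))))
    as.integer(g)
  }
}

# Random flips applied coherently to every patch of a matrix-layout
# pyramid (simple dihedral augmentation).
augmentPyramid <- function(pyr, flipH, flipV, patch) {
  if (!flipH && !flipV) return(pyr)
  lapply(pyr, function(x) {
    P <- nrow(x) %/% (patch * patch)
    a <- x
    dim(a) <- c(patch, patch, P, ncol(x))
    if (flipV) a <- a[patch:1, , , , drop = FALSE]
    if (flipH) a <- a[, patch:1, , , drop = FALSE]
    dim(a) <- dim(x)
    a
  })
}

#' Train the multi-scale network
#'
#' Mini-batch Adam with the reference hyperparameters by default (batch
#' 32, learning rate 1e-4), seeded end-to-end: weight initialisation,
#' epoch shuffling and dropout masks all derive from \code{config@seed},
#' so two runs with the same inputs produce identical histories. The train
#' and validation datasets must not share plates (audited before the first
#' step). After every epoch the validation loss is computed in inference
#' mode; the weights with the lowest validation loss are returned, and
#' training stops early after \code{patience} epochs without improvement.
#'
#' @param spec a [ModelSpec-class].
#' @param train,val [WellDataset-class] objects from [splitByPlate()].
#' @param config a [TrainConfig-class].
#' @param geneLevels gene order for the gene head (defaults to sorted
#'   unique genes of the training manifest).
#' @param verbose print per-epoch metrics.
#' @return a trained [DCNNModel-class]; \code{@history} holds per-epoch
#'   train/validation loss and accuracy.
#' @export
trainModel <- function(spec, train, val, config = trainConfig(),
                       geneLevels = NULL, verbose = FALSE) {
  validObject(spec); validObject(config)
  if (length(train) == 0L || length(val) == 0L)
    stop("empty training or validation split")
  shared <- intersect(unique(plateIds(train)), unique(plateIds(val)))
  if (length(shared))
    stop("train and validation share plate(s): ",
         paste(shared, collapse = ", "))
  if (spec@head == "gene" && is.null(geneLevels))
    geneLevels <- sort(unique(as.character(train@manifest$gene)))
  yTrain <- datasetLabels(train@manifest, spec@head, geneLevels)
  yVal <- datasetLabels(val@manifest, spec@head, geneLevels)

  pyrTrain <- lapply(imagePaths(train), function(p)
    imagePyramid(loadWellImage(p, train@channelRoles), spec))
  pyrVal <- lapply(imagePaths(val), function(p)
    imagePyramid(loadWellImage(p, val@channelRoles), spec))

  model <- initializeModel(spec, seed = deriveSeed(config@seed, 1L))
  weights <- model@weights
  opt <- adamInit(weights)
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  hist <- list()
  nTrain <- length(pyrTrain)

  evalSplit <- function(w, pyr, y) {
    n <- length(pyr)
    losses <- numeric(0)
    outs <- if (spec@head == "activation") numeric(n) else
      matrix(0, n, spec@nGenes)
    for (s in seq(1L, n, by = config@batchSize)) {
      e <- min(n, s + config@batchSize - 1L)
      sb <- assembleScaleBatches(pyr[s:e], spec)
      fw <- networkForward(w, spec, sb, e - s + 1L, training = FALSE)
      if (spec@head == "activation") outs[s:e] <- fw$out
      else outs[s:e, ] <- fw$out
      losses <- c(losses, modelLoss(fw$out, y[s:e], spec@head) *
                    (e - s + 1L))
    }
    acc <- if (spec@head == "activation") {
      mean((outs > 0.5) == (y == 1))
    } else {
      mean(max.col(outs, ties.method = "first") == y)
    }
    list(loss = sum(losses) / n, acc = acc, out = outs)
  }

  for (epoch in seq_len(config@maxEpochs)) {
    epochSeed <- deriveSeed(config@seed, 100L + epoch)
    res <- withSeed(epochSeed, {
      ord <- sample.int(nTrain)
      epochLoss <- 0
      epochCorrect <- 0
      for (s in seq(1L, nTrain, by = config@batchSize)) {
        e <- min(nTrain, s + config@batchSize - 1L)
        idx <- ord[s:e]
        pyrBatch <- pyrTrain[idx]
        if (config@augment) {
          pyrBatch <- lapply(pyrBatch, function(p)
            augmentPyramid(p, runif(1) < 0.5, runif(1) < 0.5, spec@patch))
        }
        sb <- assembleScaleBatches(pyrBatch, spec)
        nb <- e - s + 1L
        fw <- networkForward(weights, spec, sb, nb, training = TRUE)
        weights <- fw$weights  # batch-norm running statistics
        grads <- networkBackward(weights, spec, fw, yTrain[idx], nb)
        stepRes <- adamStep(weights, grads, opt, config@learningRate)
        weights <- stepRes$weights
        opt <- stepRes$state
        epochLoss <- epochLoss + modelLoss(fw$out, yTrain[idx],
                                           spec@head) * nb
        epochCorrect <- epochCorrect +
          if (spec@head == "activation")
            sum((fw$out > 0.5) == (yTrain[idx] == 1))
          else sum(max.col(fw$out, ties.method = "first") == yTrain[idx])
      }
      list(weights = weights, opt = opt, loss = epochLoss / nTrain,
           acc = epochCorrect / nTrain)
    })
    weights <- res$weights
    opt <- res$opt
    vl <- evalSplit(weights, pyrVal, yVal)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = res$loss, train_acc = res$acc,
      val_loss = vl$loss, val_acc = vl$acc)
    if (verbose)
      message(sprintf(
        "epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, res$loss, res$acc, vl$loss, vl$acc))
    if (vl$loss < best$loss) {
      best <- list(loss = vl$loss, weights = weights, epoch = epoch)
    } else if (epoch - best$epoch >= config@patience) {
      break
    }
  }
  new("DCNNModel", spec = spec, weights = best$weights,
      specHash = model@specHash, history = do.call(rbind, hist))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the spec and its hash; loading verifies that the
#' stored weights match the stored spec, so spec / weight mismatches are
#' caught immediately.
#'
#' @param model a [DCNNModel-class].
#' @param path checkpoint file.
#' @return \code{saveModel}: \code{path} invisibly; \code{loadModel}: the
#'   model.
#' @export
saveModel <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(spec = model@spec, weights = model@weights,
               specHash = model@specHash, history = model@history),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$specHash, objectHash(x$spec)))
    stop("checkpoint spec hash mismatch: weights do not belong to the ",
         "stored architecture")
  new("DCNNModel", spec = x$spec, weights = x$weights,
      specHash = x$specHash, history = x$history %||% data.frame())
}
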