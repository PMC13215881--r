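#' Build an encoder spec from the scaling-family rules
#'
#' The family fixes hidden size to 64 per layer (width-to-depth aspect
#' ratio of 64), one attention head per 64 hidden dimensions and a
#' feed-forward size of 4x the hidden size; dropout 0.02 on all fully
#' connected layers and on attention probabilities, initializer standard
#' deviation 0.02, layer-norm epsilon 1e-12, rectified linear
#' activation.
#'
#' @param layers Number of transformer layers (depth).
#' @param vocabSize Vocabulary size (default 20,275).
#' @param maxPositions Maximum input length (default 4,096).
#' @param dropout,attnDropout,initStd,lnEps Stated constants; override
#'   only deliberately.
#' @return An \linkS4class{EncoderSpec}.
#' @examples
#' encoderSpec(18)  # hidden 1152, 18 heads, feed-forward 4608
#' @export
encoderSpec <- function(layers, vocabSize = 20275L, maxPositions = 4096L,
                        dropout = 0.02, attnDropout = 0.02,
                        initStd = 0.02, lnEps = 1e-12) {
  stopifnot(layers >= 1)
  layers <- as.integer(layers)
  new("EncoderSpec", layers = layers, hidden = 64L * layers,
      heads = layers, intermediate = 256L * layers,
      vocabSize = as.integer(vocabSize),
      maxPositions = as.integer(maxPositions), dropout = dropout,
      attnDropout = attnDropout, initStd = initStd, lnEps = lnEps,
      activation = "relu")
}

setMethod("show", "EncoderSpec", function(object) {
  cat(sprintf(
    "EncoderSpec: %d layers, hidden %d, heads %d, ff %d, vocab %d, pos %d\n",
    object@layers, object@hidden, object@heads, object@intermediate,
    object@vocabSize, object@maxPositions))
  cat(sprintf("  parameters: %s\n",
              format(countParameters(object), big.mark = ",")))
})

#' Exact trainable-parameter count of a spec
#'
#' Enumerates every weight tensor of the tied-embedding masked-LM
#' encoder (word and learned position embeddings, per-layer Q/K/V/output
#' projections with biases, two feed-forward projections with biases,
#' all layer norms, MLM head transform + norm + tied decoder with output
#' bias) and sums element counts. The output embedding is tied to the
#' word embedding and therefore not double-counted.
#'
#' @param spec An \linkS4class{EncoderSpec}.
#' @return Exact integer-valued parameter count (as numeric).
#' @examples
#' round(countParameters(encoderSpec(18)) / 1e6)  # 316
#' @export
countParameters <- function(spec) {
  sum(vapply(.parameterShapes(spec), prod, numeric(1)))
}

#' @rdname countParameters
#' @return `parameterShapes`: named list of tensor dimension vectors.
#' @export
parameterShapes <- function(spec) .parameterShapes(spec)

#' Masking configuration
#'
#' Each gene token is independently selected with probability `prob`
#' (default 0.15); selected positions are replaced by the mask token,
#' by a random gene token, or kept unchanged according to the standard
#' 80/10/10 collator scheme. CLS, EOS and pad positions are never
#' selected.
#'
#' @param prob Masking probability.
#' @param maskFrac,randomFrac,keepFrac Replacement scheme; sums to 1.
#' @param seed Integer seed.
#' @return A \linkS4class{MaskingConfig}.
#' @export
maskingConfig <- function(prob = 0.15, maskFrac = 0.8, randomFrac = 0.1,
                          keepFrac = 0.1, seed = 1L) {
  new("MaskingConfig", prob = prob, maskFrac = maskFrac,
      randomFrac = randomFrac, keepFrac = keepFrac,
      seed = as.integer(seed))
}

#' Training configuration
#'
#' Defaults mirror the published pretraining recipe: max learning rate
#' 2e-4, cosine schedule with warm-up ratio 0.007, decoupled weight
#' decay 0.044, effective batch size 432, full precision. Desk-scale
#' runs override `batchSize` and `epochs`.
#'
#' @param learningRate,warmupRatio,weightDecay,batchSize,epochs,seed
#'   Optimization settings; `epochs` may be fractional.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 2e-4, warmupRatio = 0.007,
                        weightDecay = 0.044, batchSize = 432L,
                        epochs = 1, seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      warmupRatio = warmupRatio, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), epochs = epochs,
      seed = as.integer(seed))
}

#' Apply the masked learning objective to a batch of encodings
#'
#' @param seqs List of 0-based token-id sequences (CLS ... EOS), or a
#'   \linkS4class{TokenizedDataset}.
#' @param config A \linkS4class{MaskingConfig}.
#' @param vocabSize Vocabulary size used to draw random replacement gene
#'   tokens; inferred from the batch when NULL.
#' @return List with `input` (masked sequences), `labels` (integer
#'   vectors, NA at unselected positions, original id at selected
#'   positions). Cells with few genes may receive zero masks in a draw.
#' @export
applyMasking <- function(seqs, config = maskingConfig(),
                         vocabSize = NULL) {
  if (is(seqs, "TokenizedDataset")) seqs <- seqs@tokens
  validObject(config)
  withr::with_seed(config@seed,
                   .applyMaskingImpl(seqs, config, vocabSize))
}

.applyMaskingImpl <- function(seqs, config, vocabSize = NULL) {
  maskTok <- 1L
  nGeneTokens <- if (is.null(vocabSize))
    max(unlist(lapply(seqs, max)), 4L) - 3L else vocabSize - 4L
  input <- vector("list", length(seqs))
  labels <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    x <- seqs[[s]]
    n <- length(x)
    lab <- rep(NA_integer_, n)
    genePos <- which(x >= 4L)          # specials (ids 0..3) never masked
    if (length(genePos)) {
      sel <- genePos[runif(length(genePos)) < config@prob]
      if (length(sel)) {
        lab[sel] <- x[sel]
        r <- runif(length(sel))
        toMask <- sel[r < config@maskFrac]
        toRand <- sel[r >= config@maskFrac &
                        r < config@maskFrac + config@randomFrac]
        x[toMask] <- maskTok
        if (length(toRand))
          x[toRand] <- 3L + sample.int(nGeneTokens, length(toRand),
                                       replace = TRUE)
      }
    }
    input[[s]] <- x
    labels[[s]] <- lab
  }
  list(input = input, labels = labels)
}

#' Pretrain a masked-language-model encoder
#'
#' Minimizes cross-entropy over masked positions with AdamW under a
#' warmup + cosine learning-rate schedule. Deterministic given the seed
#' and single-threaded execution. Fractional epochs are supported (the
#' step budget is `ceiling(epochs * nCells / batchSize)`).
#'
#' @param dataset A \linkS4class{TokenizedDataset}.
#' @param spec An \linkS4class{EncoderSpec}.
#' @param masking A \linkS4class{MaskingConfig}.
#' @param config A \linkS4class{TrainConfig}.
#' @param model Optional existing \linkS4class{EncoderModel} to continue
#'   training (weights are not re-initialized).
#' @param verbose Print step losses.
#' @return An \linkS4class{EncoderModel} with a per-step loss trace.
#' @export
pretrain <- function(dataset, spec, masking = maskingConfig(),
                     config = trainConfig(), model = NULL,
                     verbose = FALSE) {
  seqs <- dataset@tokens
  if (!length(seqs)) .stopf("dataset is empty")
  if (max(lengths(seqs)) > spec@maxPositions)
    .stopf("sequence longer than spec max positions (%d > %d)",
           max(lengths(seqs)), spec@maxPositions)
  n <- length(seqs)
  bs <- min(config@batchSize, n)
  totalSteps <- max(1L, ceiling(config@epochs * n / bs))
  w <- if (is.null(model)) .initWeights(spec, config@seed)
       else model@weights
  trace <- data.frame(step = integer(0), loss = numeric(0),
                      lr = numeric(0))
  st <- .adamInit()
  withr::with_seed(config@seed + 1L, {
    perm <- sample.int(n)
    cursor <- 1L
    for (step in seq_len(totalSteps)) {
      if (cursor + bs - 1L > n) {
        perm <- sample.int(n)
        cursor <- 1L
      }
      idx <- perm[cursor:(cursor + bs - 1L)]
      cursor <- cursor + bs
      mb <- .applyMaskingImpl(seqs[idx], masking, spec@vocabSize)
      res <- .mlmLossGrad(w, spec, mb$input, mb$labels, training = TRUE)
      if (is.null(res$grads)) next
      lr <- .lrAt(step, totalSteps, config@learningRate,
                  config@warmupRatio)
      upd <- .adamStep(w, res$grads, st, lr, config@weightDecay)
      w <- upd$w; st <- upd$st
      trace <- rbind(trace, data.frame(step = step, loss = res$loss,
                                       lr = lr))
      if (verbose)
        message(sprintf("step %d/%d loss %.4f lr %.2e", step,
                        totalSteps, res$loss, lr))
    }
  })
  new("EncoderModel", spec = spec, weights = w, adapters = list(),
      precision = "fp32", baseFrozen = FALSE, lossTrace = trace)
}

#' Initialize an untrained encoder model
#' @param spec An \linkS4class{EncoderSpec}.
#' @param seed Integer seed for weight initialization.
#' @return An \linkS4class{EncoderModel}.
#' @export
initEncoder <- function(spec, seed = 1L) {
  new("EncoderModel", spec = spec,
      weights = .initWeights(spec, as.integer(seed)), adapters = list(),
      precision = "fp32", baseFrozen = FALSE,
      lossTrace = data.frame(step = integer(0), loss = numeric(0),
                             lr = numeric(0)))
}

setMethod("show", "EncoderModel", function(object) {
  cat(sprintf(
    "EncoderModel: %d layers, hidden %d, precision %s, %d adapters%s\n",
    object@spec@layers, object@spec@hidden, object@precision,
    length(object@adapters),
    if (object@baseFrozen) " (base frozen)" else ""))
  if (nrow(object@lossTrace))
    cat(sprintf("  trained %d steps, final loss %.4f\n",
                max(object@lossTrace$step),
                object@lossTrace$loss[nrow(object@lossTrace)]))
})

#' Hash of a model's base weights (provenance / freezing checks)
#'
#' Adapters live in a separate slot and are never part of the hash, so
#' the freezing contract (base weights unchanged after adapter
#' fine-tuning) is checkable by hash equality.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @return Character checksum.
#' @export
weightHash <- function(model) {
  contentHash(model@weights)
}

#' Forward pass returning per-layer hidden states and optional logits
#'
#' With dropout disabled (the default outside training) the pass is
#' deterministic given fixed weights and inputs. Hidden states are
#' returned for all layers + 1 states: state 1 is the embedding output,
#' state l+1 the output of layer l, so requesting the second-to-last
#' layer is well-defined for >= 2 layers.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param seqs List of 0-based token-id sequences.
#' @param logits Also compute masked-LM logits for all positions.
#' @return List with `hidden` (list of stacked matrices), `rows`
#'   (per-sequence row indices) and optionally `logits`.
#' @export
encoderForward <- function(model, seqs, logits = FALSE) {
  w <- .materializeWeights(model)
  fw <- .encForward(w, model@spec, seqs, training = FALSE,
                    adapters = model@adapters, cache = FALSE)
  out <- list(hidden = fw$hidden, rows = fw$rows)
  if (logits) {
    H <- fw$hidden[[model@spec@layers + 1L]]
    out$logits <- .mlmHead(w, model@spec, H, seq_len(nrow(H)))$logits
  }
  out
}

#' Mean masked cross-entropy on a held-out dataset
#'
#' The masking seed is fixed so repeated evaluation is identical; the
#' mean is taken per token over all masked positions.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param dataset A held-out \linkS4class{TokenizedDataset} (disjoint
#'   from training cells).
#' @param masking A \linkS4class{MaskingConfig}.
#' @param batchSize Cells per forward chunk.
#' @return Mean masked cross-entropy (nats).
#' @export
evaluateLoss <- function(model, dataset, masking = maskingConfig(),
                         batchSize = 32L) {
  seqs <- dataset@tokens
  if (!length(seqs)) .stopf("held-out set is empty")
  mb <- applyMasking(seqs, masking, vocabSize = model@spec@vocabSize)
  w <- .materializeWeights(model)
  tot <- 0; ntot <- 0L
  for (start in seq(1L, length(seqs), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(seqs))
    res <- .mlmLossGrad(w, model@spec, mb$input[idx], mb$labels[idx],
                        training = FALSE, adapters = model@adapters,
                        wantGrad = FALSE)
    if (res$nMasked > 0) {
      tot <- tot + res$loss * res$nMasked
      ntot <- ntot + res$nMasked
    }
  }
  if (ntot == 0L) .stopf("no positions were masked during evaluation")
  tot / ntot
}

#' Argmax masked-gene predictions of a model
#'
#' Predictions are the argmax over the full vocabulary at each masked
#' position.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param maskedBatch Output of [applyMasking()].
#' @param batchSize Cells per forward chunk.
#' @return List of per-cell integer vectors (NA at unmasked positions,
#'   predicted 0-based token id at masked positions).
#' @export
maskedPredictions <- function(model, maskedBatch, batchSize = 32L) {
  seqs <- maskedBatch$input
  labels <- maskedBatch$labels
  w <- .materializeWeights(model)
  preds <- vector("list", length(seqs))
  for (start in seq(1L, length(seqs), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(seqs))
    fw <- .encForward(w, model@spec, seqs[idx], training = FALSE,
                      adapters = model@adapters, cache = FALSE)
    H <- fw$hidden[[model@spec@layers + 1L]]
    labFlat <- unlist(labels[idx], use.names = FALSE)
    mrows <- which(!is.na(labFlat))
    p <- rep(NA_integer_, length(labFlat))
    if (length(mrows)) {
      lg <- .mlmHead(w, model@spec, H, mrows)$logits
      p[mrows] <- max.col(lg, ties.method = "first") - 1L
    }
    preds[idx] <- split(p, rep(seq_along(idx), lengths(seqs[idx])))
  }
  preds
}

#' Analytic floating-point-operation estimate for training
#'
#' Uses the standard scaling-law accounting of 6 floating-point
#' operations per parameter per processed token; monotone in both
#' arguments.
#'
#' @param spec An \linkS4class{EncoderSpec}.
#' @param tokensProcessed Number of tokens seen.
#' @return Estimated FLOPs.
#' @export
estimateFlops <- function(spec, tokensProcessed) {
  stopifnot(tokensProcessed >= 0)
  6 * countParameters(spec) * tokensProcessed
}

#' Save / load a model checkpoint directory
#'
#' The directory holds `spec.json`, a `manifest.json` of tensor names
#' and shapes, the weight values in a flat binary array file, and the
#' loss trace as CSV.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param dir Checkpoint directory.
#' @name checkpoint
#' @export
saveCheckpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- model@spec
  jsonlite::write_json(
    list(layers = sp@layers, hidden = sp@hidden, heads = sp@heads,
         intermediate = sp@intermediate, vocab_size = sp@vocabSize,
         max_positions = sp@maxPositions, dropout = sp@dropout,
         attn_dropout = sp@attnDropout, init_std = sp@initStd,
         ln_eps = sp@lnEps, activation = sp@activation,
         precision = model@precision),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  if (model@precision != "fp32")
    .stopf("use saveQuantizedCheckpoint for quantized models")
  shapes <- lapply(model@weights, function(x)
    if (is.matrix(x)) dim(x) else length(x))
  jsonlite::write_json(shapes, file.path(dir, "manifest.json"))
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (nmv in names(model@weights))
    writeBin(as.numeric(model@weights[[nmv]]), con)
  write.csv(model@lossTrace, file.path(dir, "trace.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname checkpoint
#' @export
loadCheckpoint <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "spec.json"),
                            simplifyVector = TRUE)
  spec <- encoderSpec(sj$layers, vocabSize = sj$vocab_size,
                      maxPositions = sj$max_positions,
                      dropout = sj$dropout, attnDropout = sj$attn_dropout,
                      initStd = sj$init_std, lnEps = sj$ln_eps)
  shapes <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  w <- lapply(shapes, function(dm) {
    n <- prod(dm)
    v <- readBin(con, numeric(), n)
    if (length(dm) == 2) matrix(v, dm[1], dm[2]) else v
  })
  trace <- read.csv(file.path(dir, "trace.csv"))
  new("EncoderModel", spec = spec, weights = w, adapters = list(),
      precision = "fp32", baseFrozen = FALSE, lossTrace = trace)
}
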