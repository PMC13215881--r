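.layerIndex <- function(spec, layer = c("second_to_last", "last")) {
  layer <- match.arg(layer)
  if (layer == "last") return(spec@layers + 1L)
  if (spec@layers < 2L)
    .stopf("second-to-last layer requires >= 2 layers")
  spec@layers
}

#' Extract contextual gene embeddings
#'
#' One vector per (gene token, cell): the hidden state at the gene's
#' position in that cell's rank value encoding, from the tagged layer.
#' Zero-shot analyses use the second-to-last layer, since the final
#' layer encodes features tied to the pretraining objective. Extraction
#' is pure (no weight mutation) and deterministic (dropout disabled).
#'
#' @param model An \linkS4class{EncoderModel} with >= 2 layers for
#'   second-to-last extraction.
#' @param dataset A \linkS4class{TokenizedDataset}.
#' @param layer "second_to_last" (default) or "last".
#' @param batchSize Cells per forward chunk.
#' @return An \linkS4class{EmbeddingMatrix} indexed by gene and cell,
#'   with cell annotations passed through.
#' @export
extractGeneEmbeddings <- function(model, dataset,
                                  layer = "second_to_last",
                                  batchSize = 32L) {
  li <- .layerIndex(model@spec, layer)
  seqs <- dataset@tokens
  vals <- NULL
  idxL <- list()
  for (start in seq(1L, length(seqs), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(seqs))
    fw <- encoderForward(model, seqs[idx])
    H <- fw$hidden[[li]]
    for (k in seq_along(idx)) {
      r <- fw$rows[[k]]
      x <- seqs[[idx[k]]]
      genePos <- which(x >= 4L)
      if (!length(genePos)) next
      vals <- rbind(vals, H[r[genePos], , drop = FALSE])
      idxL[[length(idxL) + 1L]] <-
        data.frame(gene = x[genePos], cell = idx[k],
                   stringsAsFactors = FALSE)
    }
  }
  index <- S4Vectors::DataFrame(do.call(rbind, idxL))
  meta <- dataset@cellMeta
  for (colnm in intersect(c("cell_id", "cell_type", "tissue", "batch",
                            "platform", "preservation"),
                          colnames(meta)))
    index[[colnm]] <- meta[[colnm]][index$cell]
  new("EmbeddingMatrix", values = vals, index = index,
      layerTag = layer, modelHash = weightHash(model))
}

#' Extract contextual cell embeddings (CLS position)
#'
#' One vector per cell: the hidden state of the CLS token at the start
#' of the rank value encoding, from the tagged layer.
#'
#' @inheritParams extractGeneEmbeddings
#' @return An \linkS4class{EmbeddingMatrix} indexed by cell.
#' @export
extractCellEmbeddings <- function(model, dataset,
                                  layer = "second_to_last",
                                  batchSize = 32L) {
  li <- .layerIndex(model@spec, layer)
  seqs <- dataset@tokens
  bad <- which(vapply(seqs, function(x) x[1] != 2L, logical(1)))
  if (length(bad))
    .stopf("cell %d does not start with CLS", bad[1])
  vals <- NULL
  for (start in seq(1L, length(seqs), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(seqs))
    fw <- encoderForward(model, seqs[idx])
    H <- fw$hidden[[li]]
    clsRows <- vapply(fw$rows, `[`, integer(1), 1L)
    vals <- rbind(vals, H[clsRows, , drop = FALSE])
  }
  index <- S4Vectors::DataFrame(cell = seq_along(seqs))
  meta <- dataset@cellMeta
  for (colnm in intersect(c("cell_id", "cell_type", "tissue", "batch",
                            "platform", "preservation", "disease"),
                          colnames(meta)))
    index[[colnm]] <- meta[[colnm]][index$cell]
  new("EmbeddingMatrix", values = vals, index = index,
      layerTag = layer, modelHash = weightHash(model))
}

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix: %d x %d (%s layer)\n",
              nrow(object@values), ncol(object@values),
              object@layerTag))
})

#' Cosine-similarity robustness suite
#'
#' Mirrors the batch-artifact comparisons: for gene embeddings,
#' (1) two randomly selected genes from the same cell (expected low),
#' (2) the same gene in two cells of the same cell type from the same
#' batch (expected high), and (3) the same gene in two cells of the
#' same cell type from different batches (high if embeddings are robust
#' to batch artifacts). For cell embeddings the arms are different cell
#' types / same type same batch / same type different batch. Zero-norm
#' vectors are excluded with a log entry; two-sided rank-sum tests are
#' computed between all arm pairs (exact for small samples).
#'
#' @param emb An \linkS4class{EmbeddingMatrix}.
#' @param nPairs Pairs sampled per arm.
#' @param seed Integer seed.
#' @return List: `arms` (named similarity vectors), `tests` (pairwise
#'   two-sided rank-sum p-values), `medians`, `log`.
#' @export
cosineSimilaritySuite <- function(emb, nPairs = 100L, seed = 1L) {
  norms <- sqrt(rowSums(emb@values^2))
  keep <- norms > 0
  log <- character(0)
  if (any(!keep))
    log <- sprintf("excluded %d zero-norm vectors", sum(!keep))
  u <- .unitRows(emb@values[keep, , drop = FALSE])
  idxTab <- emb@index[keep, , drop = FALSE]
  geneLevel <- "gene" %in% colnames(idxTab)
  arms <- withr::with_seed(as.integer(seed), {
    if (geneLevel) list(
      different_gene_same_cell = .samplePairSims(
        u, idxTab, nPairs, sameGene = FALSE, sameCell = TRUE),
      same_gene_same_batch = .samplePairSims(
        u, idxTab, nPairs, sameGene = TRUE, sameType = TRUE,
        sameBatch = TRUE),
      same_gene_cross_batch = .samplePairSims(
        u, idxTab, nPairs, sameGene = TRUE, sameType = TRUE,
        sameBatch = FALSE))
    else list(
      different_cell_type = .sampleCellPairSims(
        u, idxTab, nPairs, sameType = FALSE),
      same_type_same_batch = .sampleCellPairSims(
        u, idxTab, nPairs, sameType = TRUE, sameBatch = TRUE),
      same_type_cross_batch = .sampleCellPairSims(
        u, idxTab, nPairs, sameType = TRUE, sameBatch = FALSE))
  })
  list(arms = arms, tests = .pairwiseRankSum(arms),
       medians = vapply(arms, function(a)
         if (length(a)) median(a) else NA_real_, numeric(1)),
       log = log)
}

.sampleCellPairSims <- function(u, idxTab, nPairs, sameType = TRUE,
                                sameBatch = NULL) {
  n <- nrow(u)
  sims <- numeric(0)
  tries <- 0L
  while (length(sims) < nPairs && tries < nPairs * 60L) {
    tries <- tries + 1L
    i <- sample.int(n, 1L)
    ok <- if (sameType) idxTab$cell_type == idxTab$cell_type[i]
          else idxTab$cell_type != idxTab$cell_type[i]
    if (!is.null(sameBatch) && !is.null(idxTab$batch)) {
      ok <- ok & (if (sameBatch) idxTab$batch == idxTab$batch[i]
                  else idxTab$batch != idxTab$batch[i])
    }
    ok[i] <- FALSE
    cand <- which(ok)
    if (!length(cand)) next
    j <- cand[sample.int(length(cand), 1L)]
    sims <- c(sims, sum(u[i, ] * u[j, ]))
  }
  sims
}

#' Geometric separability index of gene embeddings
#'
#' For every embedding of every included gene, finds the nearest
#' neighbor by cosine distance (excluding itself; exact ties broken by
#' smallest row index) and reports the fraction whose neighbor is an
#' embedding of the same gene. Genes are included when they are
#' detected at least `minDetections` times; genes with a single
#' embedding are excluded and logged.
#'
#' @param emb A gene-level \linkS4class{EmbeddingMatrix}.
#' @param minDetections Minimum embeddings per included gene
#'   (the published analysis used 20).
#' @return Fraction in `[0, 1]` with attributes `n` (embeddings
#'   scored) and `log`.
#' @export
separabilityIndex <- function(emb, minDetections = 2L) {
  genes <- emb@index$gene
  cnt <- table(genes)
  keepGenes <- names(cnt)[cnt >= max(2L, minDetections)]
  log <- sprintf("included %d/%d genes (>= %d detections)",
                 length(keepGenes), length(cnt),
                 max(2L, minDetections))
  keep <- genes %in% keepGenes
  u <- .unitRows(emb@values[keep, , drop = FALSE])
  g <- genes[keep]
  if (nrow(u) < 2) .stopf("need at least 2 embeddings")
  S <- tcrossprod(u)
  diag(S) <- -Inf
  nn <- max.col(S, ties.method = "first")
  idx <- structure(mean(g[nn] == g), n = nrow(u), log = log)
  idx
}

#' Linear probe on frozen embeddings
#'
#' Trains a multinomial linear classifier (ridge-regularized, convex)
#' on frozen embedding vectors. Gene tasks: the probe trains on 80% of
#' the genes and predicts the held-out 20%, scoring macro F1 over
#' held-out genes (per-row predictions are aggregated per gene by
#' majority); repeated over seeds. Cell tasks: per-class F1 on held-out
#' cells.
#'
#' @param emb An \linkS4class{EmbeddingMatrix}.
#' @param labels Named character vector: names are gene token ids (gene
#'   tasks) or cell indices (cell tasks), values are class labels.
#' @param level "gene" or "cell".
#' @param heldFrac Held-out fraction (default 0.2).
#' @param seeds Integer seeds, one probe per seed.
#' @param lambda Ridge penalty of the probe.
#' @return A \linkS4class{ProbeResult}; gene tasks carry per-seed macro
#'   F1, cell tasks per-class F1 for the first seed.
#' @export
linearProbe <- function(emb, labels, level = c("gene", "cell"),
                        heldFrac = 0.2, seeds = 1:3, lambda = 1e-2) {
  level <- match.arg(level)
  if (level == "gene") {
    key <- as.character(emb@index$gene)
  } else {
    key <- as.character(emb@index$cell)
  }
  lab <- labels[key]
  keep <- !is.na(lab)
  X <- emb@values[keep, , drop = FALSE]
  y <- lab[keep]
  key <- key[keep]
  units <- unique(key)
  if (length(unique(y)) < 2) .stopf("need >= 2 classes")
  scores <- vapply(seeds, function(sd) {
    split <- withr::with_seed(sd, {
      held <- sample(units, max(1L, round(heldFrac * length(units))))
      held
    })
    isTest <- key %in% split
    ytr <- y[!isTest]
    missing <- setdiff(unique(y[isTest]), unique(ytr))
    if (length(missing))
      .stopf("class '%s' absent from training split", missing[1])
    fit <- glmnet::glmnet(X[!isTest, , drop = FALSE], factor(ytr),
                          family = "multinomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    pr <- predict(fit, X[isTest, , drop = FALSE], type = "class")[, 1]
    if (level == "gene") {
      agg <- vapply(split(pr, key[isTest]), function(v)
        names(sort(table(v), decreasing = TRUE))[1], character(1))
      truth <- vapply(split(y[isTest], key[isTest]), `[`, character(1), 1L)
      .macroF1(truth, agg[names(truth)])
    } else {
      .macroF1(y[isTest], pr)
    }
  }, numeric(1))
  if (level == "cell") {
    sd1 <- seeds[1]
    split <- withr::with_seed(sd1, sample(units,
      max(1L, round(heldFrac * length(units)))))
    isTest <- key %in% split
    fit <- glmnet::glmnet(X[!isTest, , drop = FALSE],
                          factor(y[!isTest]), family = "multinomial",
                          alpha = 0, lambda = lambda,
                          standardize = FALSE)
    pr <- predict(fit, X[isTest, , drop = FALSE], type = "class")[, 1]
    perClass <- .perClassF1(y[isTest], pr)
    return(new("ProbeResult", task = "cell_probe", mode = "zero_shot",
               scores = perClass,
               split = list(heldFrac = heldFrac, seeds = seeds,
                            macroF1 = scores)))
  }
  new("ProbeResult", task = "gene_probe", mode = "zero_shot",
      scores = setNames(scores, paste0("seed", seeds)),
      split = list(heldFrac = heldFrac, seeds = seeds))
}

setMethod("show", "ProbeResult", function(object) {
  cat(sprintf("ProbeResult [%s, %s]: mean F1 %.3f (n=%d scores)\n",
              object@task, object@mode, mean(object@scores),
              length(object@scores)))
})

#' Fine-tune a classifier head on the encoder
#'
#' Attaches a linear head on the CLS position (cell tasks) or on
#' gene-token positions (gene tasks) and trains with AdamW under a 1%
#' warm-up cosine schedule for one epoch by default. In full mode all
#' layers are unfrozen; with adapters attached (or a quantized base)
#' only adapters and the head update. Example budgets follow the
#' published protocol (100 cells few-shot, 10,000 full) scaled to a
#' desk profile (20 / 400) by default.
#'
#' @param model An \linkS4class{EncoderModel} (optionally quantized
#'   and/or with adapters attached).
#' @param dataset A \linkS4class{TokenizedDataset}.
#' @param labels Gene tasks: named character vector keyed by gene token
#'   id. Cell tasks: character vector with one label per dataset cell.
#' @param head "cell" (CLS position) or "gene" (gene-token positions).
#' @param mode "few_shot" or "full"; sets the example budget.
#' @param budget Override the number of training cells.
#' @param epochs,learningRate,batchSize,seed Optimization settings
#'   (1 epoch, warm-up ratio 0.01, cosine decay).
#' @param evalFrac Held-out fraction: cells (cell head) or genes (gene
#'   head).
#' @return List: `probe` (a \linkS4class{ProbeResult}), `model` (tuned)
#'   and `headWeights`.
#' @export
finetuneClassifier <- function(model, dataset, labels,
                               head = c("cell", "gene"),
                               mode = c("few_shot", "full"),
                               budget = NULL, epochs = 1,
                               learningRate = 5e-4, batchSize = 8L,
                               seed = 1L, evalFrac = 0.2) {
  head <- match.arg(head)
  mode <- match.arg(mode)
  if (is.null(budget)) budget <- if (mode == "few_shot") 20L else 400L
  spec <- model@spec
  d <- spec@hidden
  seqs <- dataset@tokens
  n <- length(seqs)

  if (head == "cell") {
    stopifnot(length(labels) == n)
    classes <- sort(unique(labels))
  } else {
    classes <- sort(unique(unname(labels)))
  }
  C <- length(classes)
  trainable <- if (model@baseFrozen) character(0) else
    names(model@weights)

  res <- withr::with_seed(as.integer(seed), {
    if (head == "cell") {
      testIdx <- sample.int(n, max(1L, round(evalFrac * n)))
      poolIdx <- setdiff(seq_len(n), testIdx)
      trainIdx <- sample(poolIdx, min(budget, length(poolIdx)))
      geneSplit <- NULL
    } else {
      geneIds <- names(labels)
      held <- sample(geneIds, max(1L, round(evalFrac * length(geneIds))))
      geneSplit <- list(train = setdiff(geneIds, held), test = held)
      trainIdx <- sample.int(n, min(budget, n))
      testIdx <- seq_len(n)
    }
    Wh <- matrix(rnorm(d * C, sd = 0.02), d, C)
    bh <- rep(0, C)
    w <- .materializeWeights(model)
    adapters <- model@adapters
    st <- .adamInit()
    stH <- .adamInit()
    totalSteps <- max(0L, ceiling(epochs * length(trainIdx) / batchSize))
    stepLosses <- numeric(0)
    if (totalSteps > 0) {
      perm <- sample(trainIdx)
      cursor <- 1L
      for (step in seq_len(totalSteps)) {
        if (cursor + batchSize - 1L > length(perm)) {
          perm <- sample(trainIdx)
          cursor <- 1L
        }
        idx <- perm[cursor:(cursor + min(batchSize, length(perm)) - 1L)]
        cursor <- cursor + batchSize
        fw <- .encForward(w, spec, seqs[idx], training = TRUE,
                          adapters = adapters, cache = TRUE)
        H <- fw$hidden[[spec@layers + 1L]]
        if (head == "cell") {
          rows <- vapply(fw$rows, `[`, integer(1), 1L)
          yIdx <- match(labels[idx], classes)
        } else {
          rows <- integer(0); yIdx <- integer(0)
          for (k in seq_along(idx)) {
            x <- seqs[[idx[k]]]
            gp <- which(x >= 4L &
                          as.character(x) %in% geneSplit$train)
            rows <- c(rows, fw$rows[[k]][gp])
            yIdx <- c(yIdx, match(labels[as.character(x[gp])], classes))
          }
          if (!length(rows)) next
        }
        Hm <- H[rows, , drop = FALSE]
        logits <- sweep(Hm %*% Wh, 2, bh, "+")
        mx <- apply(logits, 1, max)
        lse <- log(rowSums(exp(logits - mx))) + mx
        loss <- mean(lse - logits[cbind(seq_along(yIdx), yIdx)])
        stepLosses <- c(stepLosses, loss)
        P <- exp(logits - lse)
        P[cbind(seq_along(yIdx), yIdx)] <-
          P[cbind(seq_along(yIdx), yIdx)] - 1
        dlogits <- P / length(yIdx)
        gWh <- crossprod(Hm, dlogits)
        gbh <- colSums(dlogits)
        dH <- matrix(0, nrow(H), d)
        dH[rows, ] <- dlogits %*% t(Wh)
        eb <- .encBackward(w, spec, fw$cache, dH, adapters)
        lr <- .lrAt(step, totalSteps, learningRate, 0.01)
        updH <- .adamStep(list(Wh = Wh, bh = bh),
                          list(Wh = gWh, bh = gbh), stH, lr, 0)
        Wh <- updH$w$Wh; bh <- updH$w$bh; stH <- updH$st
        if (length(trainable)) {
          upd <- .adamStep(w, eb$grads, st, lr, 0,
                           trainable = trainable)
          w <- upd$w; st <- upd$st
        }
        if (length(adapters) && length(eb$adapterGrads)) {
          for (anm in names(eb$adapterGrads)) {
            ad <- adapters[[anm]]
            gA <- eb$adapterGrads[[anm]]$dA
            gB <- eb$adapterGrads[[anm]]$dB
            keyA <- paste0(anm, ".A"); keyB <- paste0(anm, ".B")
            upd <- .adamStep(setNames(list(ad@A, ad@B), c(keyA, keyB)),
                             setNames(list(gA, gB), c(keyA, keyB)),
                             st, lr, 0)
            ad@A <- upd$w[[keyA]]; ad@B <- upd$w[[keyB]]
            st <- upd$st
            adapters[[anm]] <- ad
          }
        }
      }
    }
    # evaluation
    tuned <- model
    tuned@adapters <- adapters
    if (length(trainable)) tuned@weights <- w
    fwAll <- NULL
    predLab <- character(0); truthLab <- character(0)
    for (start in seq(1L, length(testIdx), by = 16L)) {
      ii <- testIdx[start:min(start + 15L, length(testIdx))]
      fw <- .encForward(if (length(trainable)) w else
                          .materializeWeights(model),
                        spec, seqs[ii], training = FALSE,
                        adapters = adapters, cache = FALSE)
      H <- fw$hidden[[spec@layers + 1L]]
      if (head == "cell") {
        rows <- vapply(fw$rows, `[`, integer(1), 1L)
        logits <- sweep(H[rows, , drop = FALSE] %*% Wh, 2, bh, "+")
        predLab <- c(predLab,
                     classes[max.col(logits, ties.method = "first")])
        truthLab <- c(truthLab, labels[ii])
      } else {
        for (k in seq_along(ii)) {
          x <- seqs[[ii[k]]]
          gp <- which(x >= 4L & as.character(x) %in% geneSplit$test)
          if (!length(gp)) next
          rows <- fw$rows[[k]][gp]
          logits <- sweep(H[rows, , drop = FALSE] %*% Wh, 2, bh, "+")
          predLab <- c(predLab,
                       classes[max.col(logits, ties.method = "first")])
          truthLab <- c(truthLab,
                        unname(labels[as.character(x[gp])]))
          names(predLab) <- NULL
        }
      }
    }
    scores <- if (head == "cell") .perClassF1(truthLab, predLab)
              else setNames(.macroF1(truthLab, predLab), "macroF1")
    list(probe = new("ProbeResult",
                     task = paste0(head, "_classification"),
                     mode = if (mode == "few_shot") "few_shot"
                            else "fine_tune",
                     scores = scores,
                     split = list(budget = budget, seed = seed,
                                  losses = stepLosses)),
         model = tuned, headWeights = list(Wh = Wh, bh = bh))
  })
  res
}
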