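#' Build the NF4 (4-bit NormalFloat) codebook
#'
#' The 16 levels are normalized quantiles of the standard normal
#' distribution with an exact zero level and endpoints at -1 and +1:
#' 8 positive levels from `qnorm` of an evenly spaced probability grid,
#' 7 negative levels from a slightly coarser grid (the asymmetry buys
#' the exact zero), all divided by the largest magnitude. This
#' information-theoretically motivated spacing preserves the
#' distributional properties of Gaussian-distributed full-precision
#' weights better than uniform 4-bit floats or integers.
#'
#' @return An \linkS4class{NF4Codebook}.
#' @examples
#' cb <- nf4Codebook()
#' cb@levels[cb@zeroIndex]  # exactly 0
#' @export
nf4Codebook <- function() {
  offset <- 1 - 0.5 * (1 / 32 + 1 / 30)
  pos <- qnorm(seq(offset, 0.5, length.out = 9))[1:8]
  neg <- -qnorm(seq(offset, 0.5, length.out = 8))[1:7]
  lv <- sort(c(neg, 0, pos))
  lv <- lv / max(abs(lv))
  new("NF4Codebook", levels = lv, zeroIndex = which(lv == 0))
}

setMethod("show", "NF4Codebook", function(object) {
  cat("NF4Codebook: 16 levels in [-1, 1], zero at index",
      object@zeroIndex, "\n")
})

# nearest codebook level for normalized values; ties map to the lower
# code index for determinism
.nearestLevel <- function(v, levels) {
  mids <- (levels[-1] + levels[-length(levels)]) / 2
  findInterval(v, mids, left.open = TRUE)     # 0-based codes
}

#' Blockwise NF4 quantization with optional double quantization
#'
#' Values are split into blocks of `blockSize` (B1); each block is
#' scaled by its absolute maximum and every value mapped to the nearest
#' codebook level. With `doubleQuantize`, the first-level scales are
#' offset by their mean and symmetrically quantized to 8-bit integers in
#' second-level blocks of `scaleBlockSize` (B2), keeping one
#' full-precision scale per second-level block.
#'
#' @param values Numeric vector or matrix (finite).
#' @param codebook An \linkS4class{NF4Codebook}.
#' @param blockSize First-level block size B1 (default 64).
#' @param doubleQuantize Nest-quantize the scales (default FALSE).
#' @param scaleBlockSize Second-level block size B2 (default 256).
#' @return A \linkS4class{QuantizedTensor}.
#' @export
quantizeBlockwise <- function(values, codebook = nf4Codebook(),
                              blockSize = 64L, doubleQuantize = FALSE,
                              scaleBlockSize = 256L) {
  if (!all(is.finite(values))) .stopf("values must be finite")
  if (blockSize < 1) .stopf("blockSize must be >= 1")
  dm <- if (is.matrix(values)) dim(values) else length(values)
  v <- as.numeric(values)
  n <- length(v)
  nb <- ceiling(n / blockSize)
  blk <- rep(seq_len(nb), each = blockSize)[seq_len(n)]
  scales <- vapply(split(abs(v), blk), max, numeric(1))
  sc <- scales[blk]
  norm <- ifelse(sc > 0, v / sc, 0)
  codes <- .nearestLevel(norm, codebook@levels)
  if (!doubleQuantize)
    return(new("QuantizedTensor", mode = "nf4",
               codes = as.integer(codes), dim = as.integer(dm),
               blockSize = as.integer(blockSize),
               scales = unname(scales), doubleQuantized = FALSE,
               scaleCodes = integer(0), scaleScales = numeric(0),
               scaleOffset = numeric(0), scaleBlockSize = integer(0)))
  off <- mean(scales)
  cs <- scales - off
  nb2 <- ceiling(nb / scaleBlockSize)
  blk2 <- rep(seq_len(nb2), each = scaleBlockSize)[seq_len(nb)]
  s2 <- vapply(split(abs(cs), blk2), max, numeric(1))
  s2v <- s2[blk2]
  sCodes <- as.integer(round(ifelse(s2v > 0, cs / s2v, 0) * 127))
  new("QuantizedTensor", mode = "nf4", codes = as.integer(codes),
      dim = as.integer(dm), blockSize = as.integer(blockSize),
      scales = numeric(0), doubleQuantized = TRUE,
      scaleCodes = sCodes, scaleScales = unname(s2),
      scaleOffset = off, scaleBlockSize = as.integer(scaleBlockSize))
}

#' Dequantize a blockwise-quantized tensor
#'
#' Each value is its code's level times the reconstructed block scale;
#' scales are reconstructed through the nested 8-bit layer when present.
#' Shape is restored.
#'
#' @param q A \linkS4class{QuantizedTensor}.
#' @param codebook The \linkS4class{NF4Codebook} used at quantization.
#' @return Numeric vector or matrix.
#' @export
dequantizeBlockwise <- function(q, codebook = nf4Codebook()) {
  if (q@mode == "int8") return(.dequantizeInt8(q))
  if (any(q@codes < 0L | q@codes > 15L))
    .stopf("corrupted code outside 0-15")
  scales <- reconstructScales(q)
  n <- prod(q@dim)
  blk <- rep(seq_along(scales), each = q@blockSize)[seq_len(n)]
  v <- codebook@levels[q@codes + 1L] * scales[blk]
  if (length(q@dim) == 2) matrix(v, q@dim[1], q@dim[2]) else v
}

#' @rdname dequantizeBlockwise
#' @return `reconstructScales`: the per-block first-level scales after
#'   undoing the nested layer (identical to stored scales when not
#'   nested).
#' @export
reconstructScales <- function(q) {
  if (!q@doubleQuantized) return(q@scales)
  nb <- length(q@scaleCodes)
  blk2 <- rep(seq_along(q@scaleScales),
              each = q@scaleBlockSize)[seq_len(nb)]
  q@scaleCodes / 127 * q@scaleScales[blk2] + q@scaleOffset
}

setMethod("show", "QuantizedTensor", function(object) {
  cat(sprintf("QuantizedTensor (%s): %s elements, B1=%d%s\n",
              object@mode,
              format(prod(object@dim), big.mark = ","),
              object@blockSize,
              if (object@doubleQuantized)
                sprintf(", double-quantized B2=%d", object@scaleBlockSize)
              else ""))
})

# symmetric absolute-maximum 8-bit quantization, one scale per output
# row (columns of W in the x %*% W layout used here)
.quantizeInt8 <- function(W) {
  scales <- apply(abs(W), 2, max) / 127
  codes <- round(sweep(W, 2, ifelse(scales > 0, scales, 1), "/"))
  new("QuantizedTensor", mode = "int8",
      codes = as.integer(codes), dim = dim(W), blockSize = nrow(W),
      scales = unname(scales), doubleQuantized = FALSE,
      scaleCodes = integer(0), scaleScales = numeric(0),
      scaleOffset = numeric(0), scaleBlockSize = integer(0))
}

.dequantizeInt8 <- function(q) {
  m <- matrix(q@codes, q@dim[1], q@dim[2])
  sweep(m, 2, q@scales, "*")
}

.QUANT_TARGET_RE <- "_(Wq|Wk|Wv|Wo|W1|W2)$"

#' Quantize a model's linear projection weights
#'
#' `nf4dq` applies blockwise NF4 with double quantization to all linear
#' projection weights (Q/K/V/output and both feed-forward projections);
#' `int8` applies symmetric absolute-maximum 8-bit quantization per
#' output row (the inference configuration, no low-rank matrices).
#' Embeddings, biases and layer norms are retained in full precision;
#' the forward pass dequantizes on the fly and the architecture is
#' unchanged.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param precision "nf4dq" or "int8".
#' @param targets Regex selecting weight names to quantize.
#' @param blockSize,scaleBlockSize NF4 block sizes B1 and B2.
#' @return A quantized \linkS4class{EncoderModel} (base frozen).
#' @export
quantizeModel <- function(model, precision = c("nf4dq", "int8"),
                          targets = .QUANT_TARGET_RE, blockSize = 64L,
                          scaleBlockSize = 256L) {
  precision <- match.arg(precision)
  nms <- grep(targets, names(model@weights), value = TRUE)
  if (!length(nms)) .stopf("target filter '%s' matches no weights", targets)
  cb <- nf4Codebook()
  w <- model@weights
  for (nmv in nms) {
    w[[nmv]] <- if (precision == "nf4dq")
      quantizeBlockwise(w[[nmv]], cb, blockSize = blockSize,
                        doubleQuantize = TRUE,
                        scaleBlockSize = scaleBlockSize)
    else .quantizeInt8(w[[nmv]])
  }
  out <- model
  out@weights <- w
  out@precision <- precision
  out@baseFrozen <- TRUE
  out
}

# materialize full-precision weights for a forward pass
.materializeWeights <- function(model) {
  w <- model@weights
  if (model@precision == "fp32") return(w)
  cb <- nf4Codebook()
  for (nmv in names(w))
    if (is(w[[nmv]], "QuantizedTensor"))
      w[[nmv]] <- dequantizeBlockwise(w[[nmv]], cb)
  w
}

#' Attach low-rank adapters to a model
#'
#' For each target projection W (N x M), the adapter adds
#' `(alpha / r) * x A B` to the projection output, with A (N x r) drawn
#' from a zero-mean Gaussian and B (r x M) zero-initialized, so the
#' update is exactly zero at attachment. Base weights are frozen; only
#' adapters (2 N r parameters per square target) and any task head
#' update during fine-tuning. Published defaults: rank 128 / alpha 256
#' for gene-level tasks, rank 32 / alpha 64 for cell-level tasks.
#'
#' @param model An \linkS4class{EncoderModel} (full precision or
#'   quantized).
#' @param targets Which projections receive adapters (default the
#'   query/key/value projections).
#' @param rank LoRA rank r; must be smaller than every target dimension.
#' @param alpha LoRA scaling.
#' @param seed Integer seed for the Gaussian init of A.
#' @return The model with adapters attached and base frozen.
#' @export
attachLoRA <- function(model, targets = c("Wq", "Wk", "Wv"), rank = 8L,
                       alpha = 2 * rank, seed = 1L) {
  rank <- as.integer(rank)
  if (rank < 1) .stopf("rank must be >= 1")
  layerTargets <- unlist(lapply(seq_len(model@spec@layers), function(l)
    paste0("L", l, "_", targets)))
  bad <- setdiff(layerTargets, names(model@weights))
  if (length(bad))
    .stopf("adapter target(s) not present in model: %s",
           paste(bad, collapse = ", "))
  adapters <- withr::with_seed(as.integer(seed), {
    lapply(layerTargets, function(nmv) {
      wv <- model@weights[[nmv]]
      dm <- if (is(wv, "QuantizedTensor")) wv@dim else dim(wv)
      if (rank >= min(dm))
        .stopf("rank %d >= weight dimension %d for %s", rank, min(dm),
               nmv)
      new("LoRAAdapter", target = nmv,
          A = matrix(rnorm(dm[1] * rank, sd = 0.02), dm[1], rank),
          B = matrix(0, rank, dm[2]), rank = rank, alpha = alpha)
    })
  })
  names(adapters) <- layerTargets
  out <- model
  out@adapters <- adapters
  out@baseFrozen <- TRUE
  out
}

#' Trainable parameter count of attached adapters
#' @param model An \linkS4class{EncoderModel} with adapters.
#' @return Sum of `2 N r` (A and B element counts) over targets.
#' @export
adapterParameterCount <- function(model) {
  sum(vapply(model@adapters, function(a) length(a@A) + length(a@B),
             numeric(1)))
}

#' Analytic memory accounting for blockwise quantization
#'
#' Bits per parameter are exact arithmetic: `4 + 32 / B1` without
#' nesting and `4 + 8 / B1 + 32 / (B1 B2)` with double quantization
#' (each first-level scale stored as an 8-bit code plus one 32-bit
#' second-level scale per B2 block). The default B1 = 64, B2 = 256
#' yields a double-quantization saving that rounds to 0.4 bits per
#' parameter.
#'
#' @param blockSize,scaleBlockSize Block sizes B1, B2.
#' @param nParams Optional parameter count for byte totals.
#' @return List: `bitsPerParam` (with nesting), `bitsPerParamNoDQ`,
#'   `saving`, and when `nParams` given, `totalBytes` / `totalBytesNoDQ`
#'   / `fullPrecisionBytes` (FP32).
#' @examples
#' memoryFootprint(64, 256)$saving  # ~0.37, rounds to 0.4
#' @export
memoryFootprint <- function(blockSize = 64L, scaleBlockSize = 256L,
                            nParams = NULL) {
  noDQ <- 4 + 32 / blockSize
  withDQ <- 4 + 8 / blockSize + 32 / (blockSize * scaleBlockSize)
  out <- list(bitsPerParam = withDQ, bitsPerParamNoDQ = noDQ,
              saving = noDQ - withDQ)
  if (!is.null(nParams)) {
    out$totalBytes <- withDQ * nParams / 8
    out$totalBytesNoDQ <- noDQ * nParams / 8
    out$fullPrecisionBytes <- 4 * nParams
  }
  out
}

#' Serialize a quantized tensor (packed 4-bit codes)
#'
#' Codes are packed two per byte (little-end first); scales and the
#' nested layer are written as 32-bit floats / 8-bit integers, matching
#' the [memoryFootprint()] accounting.
#'
#' @param q A \linkS4class{QuantizedTensor}.
#' @param con A binary connection or file path.
#' @return Bytes written, invisibly.
#' @export
serializeQuantizedTensor <- function(q, con) {
  if (is.character(con)) {
    con <- file(con, "wb")
    on.exit(close(con))
  }
  if (q@mode == "nf4") {
    codes <- q@codes
    if (length(codes) %% 2L) codes <- c(codes, 0L)
    lo <- codes[seq(1, length(codes), by = 2)]
    hi <- codes[seq(2, length(codes), by = 2)]
    writeBin(as.raw(lo + 16L * hi), con)
    if (q@doubleQuantized) {
      writeBin(as.raw(bitwAnd(q@scaleCodes + 256L, 255L)), con)
      writeBin(q@scaleScales, con, size = 4)
      writeBin(q@scaleOffset, con, size = 4)
    } else {
      writeBin(q@scales, con, size = 4)
    }
  } else {
    writeBin(as.raw(bitwAnd(q@codes + 256L, 255L)), con)
    writeBin(q@scales, con, size = 4)
  }
  invisible(NULL)
}

#' Paired quantization-fidelity report
#'
#' For matched (gene, cell) entries, measures cosine similarity between
#' full-precision and quantized contextual gene embeddings and compares
#' the distribution against (i) the same gene in cells of a different
#' cell type and (ii) different genes in the same cell, both computed
#' from the full-precision embeddings. Two-sided rank-sum tests between
#' arms are reported. The report is symmetric in model order.
#'
#' @param full,quant Two \linkS4class{EncoderModel}s sharing
#'   architecture and tokenizer provenance.
#' @param dataset A \linkS4class{TokenizedDataset}.
#' @param nCells Number of cells to embed.
#' @param nPairs Sampled pairs per comparison arm.
#' @param seed Integer seed for the pair sampling.
#' @param layer Embedding layer tag.
#' @return List: `arms` (named list of similarity vectors), `tests`
#'   (data.frame of pairwise two-sided rank-sum p-values), `medians`.
#' @export
quantizationFidelity <- function(full, quant, dataset, nCells = 40L,
                                 nPairs = 200L, seed = 1L,
                                 layer = "second_to_last") {
  if (full@spec@layers != quant@spec@layers ||
      full@spec@hidden != quant@spec@hidden)
    .stopf("models do not share an architecture")
  idx <- seq_len(min(nCells, length(dataset@tokens)))
  ds <- subsetDataset(dataset, idx)
  eF <- extractGeneEmbeddings(full, ds, layer = layer)
  eQ <- extractGeneEmbeddings(quant, ds, layer = layer)
  key <- function(e) paste(e@index$gene, e@index$cell)
  common <- intersect(key(eF), key(eQ))
  iF <- match(common, key(eF)); iQ <- match(common, key(eQ))
  uF <- .unitRows(eF@values[iF, , drop = FALSE])
  uQ <- .unitRows(eQ@values[iQ, , drop = FALSE])
  fullVsQuant <- rowSums(uF * uQ)
  idxTab <- eF@index[iF, , drop = FALSE]
  arms <- withr::with_seed(as.integer(seed), {
    sameGeneOtherType <- .samplePairSims(
      uF, idxTab, nPairs, sameGene = TRUE, sameType = FALSE)
    diffGeneSameCell <- .samplePairSims(
      uF, idxTab, nPairs, sameGene = FALSE, sameCell = TRUE)
    list(full_vs_quant = fullVsQuant,
         same_gene_other_cell_type = sameGeneOtherType,
         different_gene_same_cell = diffGeneSameCell)
  })
  tests <- .pairwiseRankSum(arms)
  list(arms = arms, tests = tests,
       medians = vapply(arms, median, numeric(1)))
}

# sample cosine similarities between embedding rows under matching rules
.samplePairSims <- function(u, idxTab, nPairs, sameGene = TRUE,
                            sameType = TRUE, sameCell = FALSE,
                            sameBatch = NULL) {
  n <- nrow(u)
  sims <- numeric(0)
  tries <- 0L
  while (length(sims) < nPairs && tries < nPairs * 60L) {
    tries <- tries + 1L
    i <- sample.int(n, 1L)
    ok <- rep(TRUE, n)
    if (sameGene) ok <- ok & idxTab$gene == idxTab$gene[i]
    else ok <- ok & idxTab$gene != idxTab$gene[i]
    if (sameCell) ok <- ok & idxTab$cell == idxTab$cell[i]
    else ok <- ok & idxTab$cell != idxTab$cell[i]
    if (!is.null(idxTab$cell_type)) {
      if (isTRUE(sameType)) ok <- ok & idxTab$cell_type == idxTab$cell_type[i]
      else if (isFALSE(sameType))
        ok <- ok & idxTab$cell_type != idxTab$cell_type[i]
    }
    if (!is.null(sameBatch) && !is.null(idxTab$batch)) {
      if (sameBatch) ok <- ok & idxTab$batch == idxTab$batch[i]
      else ok <- ok & idxTab$batch != idxTab$batch[i]
    }
    ok[i] <- FALSE
    cand <- which(ok)
    if (!length(cand)) next
    j <- cand[sample.int(length(cand), 1L)]
    sims <- c(sims, sum(u[i, ] * u[j, ]))
  }
  sims
}

.pairwiseRankSum <- function(arms) {
  nms <- names(arms)
  out <- NULL
  for (a in seq_along(nms)) for (b in seq_along(nms)) {
    if (a >= b) next
    p <- suppressWarnings(
      wilcox.test(arms[[a]], arms[[b]], alternative = "two.sided"))$p.value
    out <- rbind(out, data.frame(arm1 = nms[a], arm2 = nms[b],
                                 p = p, stringsAsFactors = FALSE))
  }
  out
}
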