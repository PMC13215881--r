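#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom S4Vectors DataFrame DFrame
NULL

#' CountCorpus: a single-cell count corpus with study-level metadata
#'
#' Extends \linkS4class{SingleCellExperiment}. The `counts` assay holds a
#' sparse non-negative integer gene-by-cell matrix. `colData` carries the
#' per-cell annotations the tokenizer and downstream analyses rely on
#' (`cell_type`, `tissue`, `study`, `doi`, `batch`, `platform`,
#' `preservation`, `malignant`, `disease`); `rowData` carries gene
#' metadata (`protein_coding`, `gene_class`, `regulator_of`).
#'
#' @export
setClass("CountCorpus", contains = "SingleCellExperiment")

.CELL_META_COLS <- c("cell_type", "tissue", "study", "doi", "batch",
                     "platform", "preservation", "malignant", "disease")
.GENE_META_COLS <- c("protein_coding", "gene_class", "regulator_of")

setValidity("CountCorpus", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
    if (length(v) && (any(v < 0) || any(v != round(v))))
      msg <- c(msg, "counts must be non-negative integers")
  }
  miss <- setdiff(.CELL_META_COLS,
                  colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing colData columns: ",
                         paste(miss, collapse = ", ")))
  missg <- setdiff(.GENE_META_COLS,
                   colnames(SummarizedExperiment::rowData(object)))
  if (length(missg))
    msg <- c(msg, paste0("missing rowData columns: ",
                         paste(missg, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic corpus generator
#'
#' Declares the statistical structure of a simulated single-cell corpus:
#' cell-type expression programs, ubiquitously high housekeeping genes,
#' low-expression regulator genes with planted regulator-to-target
#' dependencies, log-normal library sizes, negative-binomial counts, and
#' study structure including deliberately duplicated studies that share a
#' DOI.
#'
#' @slot nGenes,nCells,nCellTypes,nTissues Corpus dimensions.
#' @slot tissueProportions Simplex weights over tissues (sums to 1).
#' @slot housekeepingFraction Fraction of genes that are ubiquitously
#'   highly expressed with low dispersion.
#' @slot regulatorCount Number of low-expression, cell-state
#'   discriminative regulator genes.
#' @slot targetsPerRegulator Targets planted per regulator.
#' @slot regulatorEffect Multiplicative effect on a target's mean when
#'   its regulator is "on" in that cell's type.
#' @slot proteinCodingFraction Fraction of genes flagged protein-coding.
#' @slot nStudies Number of base studies.
#' @slot duplicateStudyPairs Study pairs sharing a DOI (exact copies).
#' @slot malignantFraction Fraction of cells flagged malignant
#'   (high mutational burden).
#' @slot depthLogMean,depthLogSd Log-normal per-cell library size.
#' @slot nbDispersion Negative-binomial overdispersion (size = 1/disp).
#' @slot seed Integer seed; the corpus is a pure function of the config.
#' @export
setClass("CorpusConfig", representation(
  nGenes = "integer", nCells = "integer", nCellTypes = "integer",
  nTissues = "integer", tissueProportions = "numeric",
  housekeepingFraction = "numeric", regulatorCount = "integer",
  targetsPerRegulator = "integer", regulatorEffect = "numeric",
  proteinCodingFraction = "numeric",
  nStudies = "integer", duplicateStudyPairs = "integer",
  malignantFraction = "numeric",
  depthLogMean = "numeric", depthLogSd = "numeric",
  nbDispersion = "numeric", seed = "integer"))

setValidity("CorpusConfig", function(object) {
  msg <- character(0)
  if (length(object@tissueProportions) != object@nTissues)
    msg <- c(msg, "tissueProportions length must equal nTissues")
  if (abs(sum(object@tissueProportions) - 1) > 1e-9)
    msg <- c(msg, "tissueProportions must sum to 1 (tolerance 1e-9)")
  nhk <- floor(object@housekeepingFraction * object@nGenes)
  if (nhk + object@regulatorCount > object@nGenes)
    msg <- c(msg, "housekeeping and regulator gene classes exceed nGenes")
  if (object@housekeepingFraction < 0 || object@housekeepingFraction > 1)
    msg <- c(msg, "housekeepingFraction must be in [0, 1]")
  if (object@duplicateStudyPairs > object@nStudies)
    msg <- c(msg, "duplicateStudyPairs cannot exceed nStudies")
  if (length(msg)) msg else TRUE
})

#' Gene non-zero-median scaling dictionary
#'
#' Maps each detected gene to the median of its strictly positive
#' depth-normalized expression values across qualifying cells. These
#' medians are the per-gene scaling factors of the rank value encoding.
#'
#' @slot medians Named numeric vector, one strictly positive entry per
#'   detected gene.
#' @slot targetSum Per-cell normalization target sum used both when the
#'   medians were computed and when cells are encoded.
#' @export
setClass("GeneMedianDictionary",
         representation(medians = "numeric", targetSum = "numeric"))

setValidity("GeneMedianDictionary", function(object) {
  msg <- character(0)
  if (length(object@medians) && any(object@medians <= 0))
    msg <- c(msg, "all medians must be strictly positive")
  if (is.null(names(object@medians)) && length(object@medians))
    msg <- c(msg, "medians must be named by gene id")
  if (anyDuplicated(names(object@medians)))
    msg <- c(msg, "duplicate gene ids in dictionary")
  if (object@targetSum <= 0) msg <- c(msg, "targetSum must be positive")
  if (length(msg)) msg else TRUE
})

#' Token vocabulary: four special tokens plus one token per gene
#'
#' Token ids are 0-based and contiguous: pad = 0, mask = 1, CLS = 2,
#' EOS = 3, then genes in sorted gene-id order.
#'
#' @slot tokens Character vector of token strings in id order.
#' @export
setClass("TokenVocabulary", representation(tokens = "character"))

setValidity("TokenVocabulary", function(object) {
  msg <- character(0)
  if (length(object@tokens) < 5)
    msg <- c(msg, "vocabulary must contain 4 special tokens and >= 1 gene")
  if (!identical(object@tokens[1:4], c("<pad>", "<mask>", "<cls>", "<eos>")))
    msg <- c(msg, "tokens must start with <pad>, <mask>, <cls>, <eos>")
  if (anyDuplicated(object@tokens)) msg <- c(msg, "token ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Rank value encoding of a single cell
#'
#' Ordered 0-based token ids: CLS, detected in-vocabulary genes in
#' descending median-scaled expression order (ties broken by ascending
#' token id), EOS.
#'
#' @slot ids Integer vector of token ids.
#' @slot droppedGenes Number of detected genes absent from the
#'   dictionary/vocabulary and silently dropped.
#' @export
setClass("RankValueEncoding",
         representation(ids = "integer", droppedGenes = "integer"))

#' Tokenized dataset
#'
#' One token-id record per cell surviving corpus filters, with cell
#' metadata passed through and corpus-level provenance (dictionary and
#' vocabulary hashes, filter log).
#'
#' @slot tokens List of integer vectors (0-based token ids, CLS..EOS).
#' @slot cellMeta A \linkS4class{DFrame} of per-cell annotations.
#' @slot provenance List: `dictHash`, `vocabHash`, `capacity`,
#'   `droppedGenes`, `filterLog`.
#' @export
setClass("TokenizedDataset", representation(
  tokens = "list", cellMeta = "DataFrame", provenance = "list"))

setValidity("TokenizedDataset", function(object) {
  if (length(object@tokens) != nrow(object@cellMeta))
    return("record count must equal cell metadata rows")
  TRUE
})

#' Architecture of one member of the encoder scaling family
#'
#' The family is parameterized by depth alone: hidden size is 64 per
#' layer (width-to-depth aspect ratio 64), one attention head per 64
#' hidden dimensions, and a feed-forward size of 4x hidden.
#'
#' @slot layers,hidden,heads,intermediate Architecture dimensions.
#' @slot vocabSize,maxPositions Embedding table sizes.
#' @slot dropout,attnDropout,initStd,lnEps Stated constants (0.02, 0.02,
#'   0.02, 1e-12) unless overridden.
#' @slot activation Nonlinearity; rectified linear.
#' @export
setClass("EncoderSpec", representation(
  layers = "integer", hidden = "integer", heads = "integer",
  intermediate = "integer", vocabSize = "integer",
  maxPositions = "integer", dropout = "numeric", attnDropout = "numeric",
  initStd = "numeric", lnEps = "numeric", activation = "character"))

setValidity("EncoderSpec", function(object) {
  msg <- character(0)
  if (object@hidden != 64L * object@layers)
    msg <- c(msg, "hidden must equal 64 * layers (aspect ratio 64)")
  if (object@heads != object@hidden %/% 64L)
    msg <- c(msg, "heads must equal hidden / 64")
  if (object@intermediate != 4L * object@hidden)
    msg <- c(msg, "intermediate must equal 4 * hidden")
  if (length(msg)) msg else TRUE
})

#' Masking configuration for the masked learning objective
#'
#' @slot prob Per-gene masking probability (0.15).
#' @slot maskFrac,randomFrac,keepFrac Replacement scheme for selected
#'   positions (mask token / random gene token / unchanged); sums to 1.
#' @slot seed Integer seed for mask draws.
#' @export
setClass("MaskingConfig", representation(
  prob = "numeric", maskFrac = "numeric", randomFrac = "numeric",
  keepFrac = "numeric", seed = "integer"))

setValidity("MaskingConfig", function(object) {
  msg <- character(0)
  if (object@prob <= 0 || object@prob >= 1)
    msg <- c(msg, "mask probability must lie in (0, 1)")
  if (abs(object@maskFrac + object@randomFrac + object@keepFrac - 1) > 1e-9)
    msg <- c(msg, "replacement fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Pretraining / fine-tuning optimization configuration
#'
#' Defaults mirror the published pretraining recipe (max learning rate
#' 2e-4, cosine schedule with warm-up ratio 0.007, decoupled weight
#' decay 0.044, effective batch size 432, full precision); desk runs
#' override batch size and epochs.
#'
#' @slot learningRate,warmupRatio,weightDecay,batchSize,epochs,seed
#'   Optimizer settings; `epochs` may be fractional.
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", warmupRatio = "numeric",
  weightDecay = "numeric", batchSize = "integer", epochs = "numeric",
  seed = "integer"))

#' A masked-language-model transformer encoder with its weights
#'
#' @slot spec The \linkS4class{EncoderSpec}.
#' @slot weights Flat named list of weight arrays. Entries may be
#'   \linkS4class{QuantizedTensor} objects for quantized models.
#' @slot adapters Named list of low-rank adapters (possibly empty).
#' @slot precision "fp32", "nf4dq" or "int8".
#' @slot baseFrozen Whether base weights are excluded from updates.
#' @slot lossTrace data.frame(step, loss, lr) accumulated in training.
#' @export
setClass("EncoderModel", representation(
  spec = "EncoderSpec", weights = "list", adapters = "list",
  precision = "character", baseFrozen = "logical",
  lossTrace = "data.frame"))

#' Rank-frequency baseline table for masked gene prediction
#'
#' @slot table Integer vector: modal gene token id at each rank position
#'   of the reference encodings (rank 1 = first gene after CLS).
#' @slot fallback Globally most frequent gene token, used for masked
#'   ranks deeper than any reference encoding.
#' @slot refHash Provenance hash of the reference token set, used to
#'   refuse evaluation on the reference corpus itself.
#' @export
setClass("BaselineRankTable", representation(
  table = "integer", fallback = "integer", refHash = "character"))

#' Power-law fit of loss against parameters or compute
#'
#' Fitted form: loss(N) = a * N^(-alpha) + c.
#'
#' @slot alpha,prefactor,offset Fitted parameters.
#' @slot residuals Residuals of the nonlinear fit.
#' @slot loglogAlpha Slope-based exponent of the simple log-log fit
#'   (offset fixed at 0), reported for comparison.
#' @slot nonMonotone TRUE when the input series was not decreasing.
#' @export
setClass("ScalingFitResult", representation(
  alpha = "numeric", prefactor = "numeric", offset = "numeric",
  residuals = "numeric", loglogAlpha = "numeric",
  nonMonotone = "logical"))

#' NF4 (4-bit NormalFloat) codebook
#'
#' 16 strictly increasing levels in `[-1, 1]` built from standard-normal
#' quantiles with an exact zero level.
#'
#' @slot levels Numeric vector of length 16.
#' @slot zeroIndex 1-based index of the exact-zero level.
#' @export
setClass("NF4Codebook",
         representation(levels = "numeric", zeroIndex = "integer"))

setValidity("NF4Codebook", function(object) {
  msg <- character(0)
  lv <- object@levels
  if (length(lv) != 16) msg <- c(msg, "codebook must have 16 levels")
  if (any(diff(lv) <= 0)) msg <- c(msg, "levels must be strictly increasing")
  if (lv[1] != -1 || lv[16] != 1) msg <- c(msg, "endpoints must be -1 and +1")
  if (sum(lv == 0) != 1) msg <- c(msg, "exactly one level must be exactly 0")
  if (length(msg)) msg else TRUE
})

#' Blockwise-quantized tensor
#'
#' 4-bit NF4 codes with per-block absolute-maximum scales, optionally
#' double-quantized (scales offset by their mean and symmetrically
#' quantized to 8-bit in second-level blocks), or symmetric 8-bit
#' per-output-row codes for inference quantization.
#'
#' @slot mode "nf4" or "int8".
#' @slot codes Integer codes (0..15 for nf4; -127..127 for int8).
#' @slot dim Original dimensions.
#' @slot blockSize First-level block size B1 (nf4).
#' @slot scales Full-precision per-block scales (when not nested).
#' @slot doubleQuantized Whether the nested scale layer is present.
#' @slot scaleCodes,scaleScales,scaleOffset,scaleBlockSize Nested layer:
#'   8-bit scale codes, per-second-level-block scales, scalar scale mean,
#'   and second-level block size B2.
#' @export
setClass("QuantizedTensor", representation(
  mode = "character", codes = "integer", dim = "integer",
  blockSize = "integer", scales = "numeric",
  doubleQuantized = "logical", scaleCodes = "integer",
  scaleScales = "numeric", scaleOffset = "numeric",
  scaleBlockSize = "integer"))

#' Low-rank adapter (LoRA) attached to a frozen weight matrix
#'
#' The adapter adds `(alpha / r) * x A B` to the output of its target
#' projection; with `B` zero-initialized the update is exactly zero at
#' attachment.
#'
#' @slot target Name of the adapted weight.
#' @slot A Input-side matrix (nrow(W) x r), Gaussian-initialized.
#' @slot B Output-side matrix (r x ncol(W)), zero-initialized.
#' @slot rank,alpha LoRA rank r and scaling alpha.
#' @export
setClass("LoRAAdapter", representation(
  target = "character", A = "matrix", B = "matrix", rank = "integer",
  alpha = "numeric"))

#' Contextual embedding matrix
#'
#' @slot values Numeric matrix, one embedding per row.
#' @slot index A \linkS4class{DFrame} addressing each row (gene token
#'   and cell id for gene embeddings; cell id alone for cell
#'   embeddings), plus passthrough cell annotations.
#' @slot layerTag "second_to_last" or "last".
#' @slot modelHash Provenance hash of the producing model's weights.
#' @export
setClass("EmbeddingMatrix", representation(
  values = "matrix", index = "DataFrame", layerTag = "character",
  modelHash = "character"))

setValidity("EmbeddingMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@values) != nrow(object@index))
    msg <- c(msg, "index rows must match embedding rows")
  if (length(object@values) && !all(is.finite(object@values)))
    msg <- c(msg, "embedding entries must be finite")
  if (length(msg)) msg else TRUE
})

#' Classification probe / fine-tuning result
#'
#' @slot task Task label.
#' @slot mode "zero_shot", "few_shot" or "fine_tune".
#' @slot scores Numeric scores: per-seed macro F1 (gene tasks) or
#'   per-class F1 (cell tasks), all in `[0, 1]`.
#' @slot split Description of the train/test split and seeds.
#' @export
setClass("ProbeResult", representation(
  task = "character", mode = "character", scores = "numeric",
  split = "list"))

setValidity("ProbeResult", function(object) {
  if (length(object@scores) &&
      (any(object@scores < 0) || any(object@scores > 1)))
    return("F1 scores must lie in [0, 1]")
  TRUE
})

#' In silico deletion result
#'
#' @slot perCell data.frame(cell, gene, shift): cosine shift
#'   (1 - cosine similarity) of each remaining gene's embedding between
#'   the original and perturbed forward passes.
#' @slot perGene data.frame(gene, meanShift, nCells) after
#'   detection-quantile filtering.
#' @slot comparisons data.frame of pairwise group rank-sum tests.
#' @slot log Character log (skipped cells, filtered genes, ...).
#' @export
setClass("PerturbationResult", representation(
  perCell = "data.frame", perGene = "data.frame",
  comparisons = "data.frame", log = "character"))
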