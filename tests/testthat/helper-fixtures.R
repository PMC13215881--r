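# Shared fixtures, generated in code and cached for the duration of the
# test run (the cache environment persists across test files).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small synthetic corpus used by most tokenizer/embedding tests
smallCorpus <- function() {
  fixture("smallCorpus", function() {
    generateCorpus(corpusConfig(nGenes = 80L, nCells = 300L,
                                nCellTypes = 3L, seed = 42L))
  })
}

# corpus -> filtered -> dictionary/vocab/tokenized, shared pipeline
smallPipeline <- function() {
  fixture("smallPipeline", function() {
    corpus <- qcFilterCells(deduplicateStudies(smallCorpus()))
    corpus <- corpus[, !SummarizedExperiment::colData(corpus)$malignant]
    dict <- computeNonzeroMedians(corpus)
    vocab <- buildVocabulary(dict)
    ds <- tokenizeCorpus(corpus, dict, vocab, capacity = 48L)
    list(corpus = corpus, dict = dict, vocab = vocab, ds = ds)
  })
}

# a small trained model on the shared pipeline; used by embedding,
# perturbation and quantization-fidelity tests
tinyTrainedModel <- function() {
  fixture("tinyTrainedModel", function() {
    pl <- smallPipeline()
    spec <- encoderSpec(2L, vocabSize = vocabSize(pl$vocab),
                        maxPositions = 48L)
    model <- pretrain(pl$ds, spec, maskingConfig(seed = 2L),
                      trainConfig(learningRate = 1e-3, batchSize = 16L,
                                  epochs = 2, seed = 4L))
    model
  })
}

# hand-built corpus with exact counts for QC/median boundary tests
handCorpus <- function(counts, proteinCoding = NULL, malignant = NULL,
                       tissue = NULL, study = NULL, doi = NULL) {
  G <- nrow(counts); N <- ncol(counts)
  gid <- sprintf("G%04d", seq_len(G))
  cid <- sprintf("cell%05d", seq_len(N))
  rownames(counts) <- gid
  colnames(counts) <- cid
  if (is.null(proteinCoding)) proteinCoding <- rep(TRUE, G)
  if (is.null(malignant)) malignant <- rep(FALSE, N)
  if (is.null(tissue)) tissue <- rep("tissue01", N)
  if (is.null(study)) study <- rep("S001", N)
  if (is.null(doi)) doi <- rep("10.1000/x.1", N)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(
      gene_id = gid, token_id = NA_integer_,
      protein_coding = proteinCoding, gene_class = "other",
      regulator_of = "", row.names = gid),
    colData = S4Vectors::DataFrame(
      cell_id = cid, cell_type = "CT01", tissue = tissue,
      study = study, doi = doi, batch = paste0(study, "_b1"),
      platform = "cell", preservation = "fresh",
      malignant = malignant, disease = "healthy", row.names = cid))
  new("CountCorpus", sce)
}

# independent reference table of the 4-bit NormalFloat levels as
# published with the quantization scheme this package implements
NF4_REFERENCE <- c(
  -1.0, -0.6961928009986877, -0.5250730514526367, -0.39491748809814453,
  -0.28444138169288635, -0.18477343022823334, -0.09105003625154495,
  0.0, 0.07958029955625534, 0.16093020141124725, 0.24611230194568634,
  0.33791524171829224, 0.44070982933044434, 0.5626170039176941,
  0.7229568362236023, 1.0)
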