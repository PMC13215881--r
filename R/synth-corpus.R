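#' Build a synthetic corpus configuration
#'
#' The generator emulates the statistical structure the rank value
#' encoding and the masked learning objective assume: distinct cell-type
#' expression programs, ubiquitously high housekeeping genes with low
#' relative dispersion, lowly expressed regulator genes whose on/off
#' pattern discriminates cell state, planted regulator-to-target
#' dependencies, log-normal library-size variation, and deliberately
#' duplicated studies sharing a DOI.
#'
#' @param nGenes,nCells,nCellTypes,nTissues Corpus dimensions.
#' @param tissueProportions Simplex weights over tissues; must sum to 1.
#' @param housekeepingFraction Fraction of genes that are housekeeping.
#' @param regulatorCount Number of regulator genes.
#' @param targetsPerRegulator Planted targets per regulator.
#' @param regulatorEffect Fold change applied to a target's mean in cell
#'   types where its regulator is on (default 3).
#' @param proteinCodingFraction Fraction of genes flagged protein-coding.
#' @param nStudies Number of base studies.
#' @param duplicateStudyPairs How many studies are duplicated verbatim
#'   under a new study accession but an identical DOI.
#' @param malignantFraction Fraction of cells flagged as high mutational
#'   burden (a pure label; no quantitative definition is modeled).
#' @param depthLogMean,depthLogSd Log-normal library-size parameters.
#' @param nbDispersion Negative-binomial overdispersion.
#' @param seed Integer seed.
#' @return A \linkS4class{CorpusConfig}.
#' @examples
#' cfg <- corpusConfig(nGenes = 100, nCells = 200, seed = 1)
#' @export
corpusConfig <- function(nGenes = 200L, nCells = 1000L, nCellTypes = 4L,
                         nTissues = 3L,
                         tissueProportions = c(0.5, 0.3, 0.2),
                         housekeepingFraction = 0.15,
                         regulatorCount = 8L, targetsPerRegulator = 5L,
                         regulatorEffect = 3,
                         proteinCodingFraction = 0.9,
                         nStudies = 6L, duplicateStudyPairs = 1L,
                         malignantFraction = 0.1,
                         depthLogMean = log(1500), depthLogSd = 0.35,
                         nbDispersion = 0.3, seed = 1L) {
  new("CorpusConfig", nGenes = as.integer(nGenes),
      nCells = as.integer(nCells), nCellTypes = as.integer(nCellTypes),
      nTissues = as.integer(nTissues),
      tissueProportions = as.numeric(tissueProportions),
      housekeepingFraction = housekeepingFraction,
      regulatorCount = as.integer(regulatorCount),
      targetsPerRegulator = as.integer(targetsPerRegulator),
      regulatorEffect = regulatorEffect,
      proteinCodingFraction = proteinCodingFraction,
      nStudies = as.integer(nStudies),
      duplicateStudyPairs = as.integer(duplicateStudyPairs),
      malignantFraction = malignantFraction,
      depthLogMean = depthLogMean, depthLogSd = depthLogSd,
      nbDispersion = nbDispersion, seed = as.integer(seed))
}

#' Generate a seeded synthetic single-cell corpus
#'
#' Counts are drawn per cell as negative binomial with cell-type-specific
#' program means. Housekeeping genes have a high mean in every cell type
#' with low relative dispersion; regulators have low means with a
#' cell-type-specific on/off pattern; in cell types where a regulator is
#' on, its targets' means are multiplied by `regulatorEffect`. Library
#' size is log-normal per cell and applied multiplicatively to the
#' negative-binomial means before sampling. Identical `(config, seed)`
#' yields byte-identical corpora.
#'
#' @param config A \linkS4class{CorpusConfig}.
#' @return A \linkS4class{CountCorpus}.
#' @examples
#' corpus <- generateCorpus(corpusConfig(nGenes = 60, nCells = 80, seed = 7))
#' @export
generateCorpus <- function(config) {
  stopifnot(is(config, "CorpusConfig"))
  validObject(config)
  withr::with_seed(config@seed, .generateCorpusImpl(config))
}

.generateCorpusImpl <- function(cfg) {
  G <- cfg@nGenes; N <- cfg@nCells; K <- cfg@nCellTypes
  geneIds <- sprintf("G%04d", seq_len(G))

  # gene classes: housekeeping / regulator / program / other, disjoint
  nHK <- floor(cfg@housekeepingFraction * G)
  nReg <- cfg@regulatorCount
  cls <- rep("other", G)
  pool <- sample.int(G)
  hk <- pool[seq_len(nHK)]
  reg <- pool[nHK + seq_len(nReg)]
  rest <- pool[-seq_len(nHK + nReg)]
  nProg <- floor(0.6 * length(rest))
  prog <- rest[seq_len(nProg)]
  cls[hk] <- "housekeeping"; cls[reg] <- "regulator"
  cls[prog] <- "program"

  proteinCoding <- runif(G) < cfg@proteinCodingFraction

  # baseline relative expression weights
  w <- rlnorm(G, meanlog = 0, sdlog = 1.2)
  w[hk] <- rlnorm(nHK, meanlog = log(20), sdlog = 0.25)

  # program genes elevated in one cell type, depressed elsewhere
  progType <- integer(G)
  if (length(prog)) progType[prog] <- sample.int(K, length(prog), TRUE)

  # regulator on/off pattern across cell types (at least one "on" type)
  regOn <- matrix(FALSE, nrow = max(nReg, 1L), ncol = K)
  if (nReg > 0) {
    for (r in seq_len(nReg)) {
      on <- runif(K) < 0.5
      if (!any(on)) on[sample.int(K, 1)] <- TRUE
      regOn[r, ] <- on
    }
  }

  # targets per regulator: drawn from program/other genes only
  regTargets <- vector("list", nReg)
  if (nReg > 0) {
    eligible <- setdiff(seq_len(G), c(hk, reg))
    for (r in seq_len(nReg))
      regTargets[[r]] <- sort(sample(eligible,
                                     min(cfg@targetsPerRegulator,
                                         length(eligible))))
  }

  # per-cell-type mean profile (columns sum to 1)
  M <- matrix(w, nrow = G, ncol = K)
  for (k in seq_len(K)) {
    if (length(prog)) {
      up <- prog[progType[prog] == k]
      down <- setdiff(prog, up)
      M[up, k] <- M[up, k] * 6
      M[down, k] <- M[down, k] * 0.25
    }
    if (nReg > 0) {
      for (r in seq_len(nReg)) {
        M[reg[r], k] <- if (regOn[r, k]) 0.8 else 0.02
        if (regOn[r, k])
          M[regTargets[[r]], k] <- M[regTargets[[r]], k] * cfg@regulatorEffect
      }
    }
  }
  M <- sweep(M, 2, colSums(M), "/")

  # cell annotations
  tissues <- sprintf("tissue%02d", seq_len(cfg@nTissues))
  cellType <- sample.int(K, N, TRUE)
  tissue <- sample(tissues, N, TRUE, prob = cfg@tissueProportions)
  study <- sprintf("S%03d", sample.int(cfg@nStudies, N, TRUE))
  dois <- sprintf("10.1000/synth.%03d", seq_len(cfg@nStudies))
  names(dois) <- sprintf("S%03d", seq_len(cfg@nStudies))
  batch <- paste0(study, "_b", 1L + (runif(N) < 0.5))
  platform <- ifelse(sample(c(TRUE, FALSE), N, TRUE), "cell", "nucleus")
  preservation <- ifelse(runif(N) < 0.5, "fresh", "frozen")
  malignant <- runif(N) < cfg@malignantFraction
  diseases <- c("healthy", "disease_a", "disease_b")
  studyDisease <- sample(diseases, cfg@nStudies, TRUE)
  names(studyDisease) <- names(dois)

  depth <- rlnorm(N, cfg@depthLogMean, cfg@depthLogSd)
  size <- 1 / cfg@nbDispersion

  counts <- matrix(0L, nrow = G, ncol = N)
  for (j in seq_len(N)) {
    mu <- M[, cellType[j]] * depth[j]
    sz <- rep(size, G)
    sz[hk] <- size * 5          # housekeeping: low relative dispersion
    counts[, j] <- rnbinom(G, mu = mu, size = sz)
  }

  cellIds <- sprintf("cell%05d", seq_len(N))
  cellMeta <- S4Vectors::DataFrame(
    cell_id = cellIds,
    cell_type = sprintf("CT%02d", cellType),
    tissue = tissue, study = study, doi = unname(dois[study]),
    batch = batch, platform = platform, preservation = preservation,
    malignant = malignant, disease = unname(studyDisease[study]),
    row.names = cellIds)

  # duplicated studies: exact copies under a new accession, same DOI
  if (cfg@duplicateStudyPairs > 0) {
    dupOf <- sprintf("S%03d", seq_len(cfg@duplicateStudyPairs))
    for (i in seq_along(dupOf)) {
      src <- which(cellMeta$study == dupOf[i])
      if (!length(src)) next
      newStudy <- sprintf("S%03d", cfg@nStudies + i)
      extraMeta <- cellMeta[src, ]
      extraMeta$study <- newStudy
      extraMeta$batch <- sub(dupOf[i], newStudy, extraMeta$batch,
                             fixed = TRUE)
      extraIds <- sprintf("cell%05d", ncol(counts) + seq_along(src))
      extraMeta$cell_id <- extraIds
      rownames(extraMeta) <- extraIds
      counts <- cbind(counts, counts[, src, drop = FALSE])
      cellMeta <- rbind(cellMeta, extraMeta)
    }
  }
  colnames(counts) <- cellMeta$cell_id

  regOf <- rep("", G)
  if (nReg > 0)
    for (r in seq_len(nReg))
      regOf[reg[r]] <- paste(geneIds[regTargets[[r]]], collapse = ",")

  geneMeta <- S4Vectors::DataFrame(
    gene_id = geneIds, token_id = NA_integer_,
    protein_coding = proteinCoding, gene_class = cls,
    regulator_of = regOf, row.names = geneIds)
  rownames(counts) <- geneIds

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = geneMeta, colData = cellMeta)
  S4Vectors::metadata(sce)$config <- cfg
  new("CountCorpus", sce)
}

#' Inject batch-dependent technical artifacts into a corpus
#'
#' Applies, per labeled axis, (a) multiplicative depth scaling keyed by
#' the preservation label (a proxy for preservation/reference effects)
#' or by batch label, and (b) per-gene Bernoulli detection dropout keyed
#' by platform, at a higher rate for single-nucleus cells to emulate the
#' lower number of genes detected on nucleus platforms. The input corpus
#' is not modified; a new corpus is returned.
#'
#' @param corpus A \linkS4class{CountCorpus}.
#' @param axes Named list of effects. Known axes: `preservation` (named
#'   numeric depth multipliers over preservation levels), `batch` (named
#'   numeric depth multipliers over batch labels), `platform_dropout`
#'   (named numeric dropout rates over platform levels).
#' @param seed Integer seed for the dropout draws.
#' @return A new \linkS4class{CountCorpus}.
#' @examples
#' corpus <- generateCorpus(corpusConfig(nGenes = 50, nCells = 60, seed = 2))
#' shifted <- injectBatchEffects(corpus,
#'   axes = list(platform_dropout = c(cell = 0, nucleus = 0.5)), seed = 3)
#' @export
injectBatchEffects <- function(corpus, axes = list(), seed = 1L) {
  stopifnot(is(corpus, "CountCorpus"))
  known <- c("preservation", "batch", "platform_dropout")
  bad <- setdiff(names(axes), known)
  if (length(bad))
    .stopf("unknown batch-effect axis '%s'; known axes: %s",
           bad[1], paste(known, collapse = ", "))
  counts <- as.matrix(SummarizedExperiment::assay(corpus, "counts"))
  meta <- SummarizedExperiment::colData(corpus)

  applyDepth <- function(counts, labels, factors) {
    miss <- setdiff(unique(labels), names(factors))
    if (length(miss))
      .stopf("no depth factor for level(s): %s", paste(miss, collapse = ", "))
    f <- unname(factors[labels])
    round(sweep(counts, 2, f, "*"))
  }
  if (!is.null(axes$preservation))
    counts <- applyDepth(counts, meta$preservation, axes$preservation)
  if (!is.null(axes$batch))
    counts <- applyDepth(counts, meta$batch, axes$batch)

  if (!is.null(axes$platform_dropout)) {
    rates <- axes$platform_dropout
    miss <- setdiff(unique(meta$platform), names(rates))
    if (length(miss))
      .stopf("no dropout rate for platform level(s): %s",
             paste(miss, collapse = ", "))
    counts <- withr::with_seed(seed, {
      for (j in seq_len(ncol(counts))) {
        rate <- rates[[meta$platform[j]]]
        if (rate > 0) {
          det <- which(counts[, j] > 0)
          drop <- det[runif(length(det)) < rate]
          counts[drop, j] <- 0L
        }
      }
      counts
    })
  }

  out <- corpus
  SummarizedExperiment::assay(out, "counts") <-
    Matrix::Matrix(counts, sparse = TRUE)
  out
}

#' Write a corpus to disk (Matrix Market + TSV + JSON sidecar)
#'
#' @param corpus A \linkS4class{CountCorpus}.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(corpus, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  write.table(as.data.frame(SummarizedExperiment::colData(corpus)),
              file.path(dir, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(SummarizedExperiment::rowData(corpus)),
              file.path(dir, "gene_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- S4Vectors::metadata(corpus)$config
  side <- list(generator = "rankformer synthetic corpus")
  if (!is.null(cfg)) {
    side$config <- lapply(slotNames(cfg), function(s) slot(cfg, s))
    names(side$config) <- slotNames(cfg)
  }
  jsonlite::write_json(side, file.path(dir, "corpus.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a corpus written by [writeCorpus()]
#'
#' @param dir Directory containing `counts.mtx`, `cell_meta.tsv` and
#'   `gene_meta.tsv`.
#' @return A \linkS4class{CountCorpus}.
#' @export
readCorpus <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                   "CsparseMatrix")
  cellMeta <- S4Vectors::DataFrame(
    read.delim(file.path(dir, "cell_meta.tsv"), stringsAsFactors = FALSE))
  geneMeta <- S4Vectors::DataFrame(
    read.delim(file.path(dir, "gene_meta.tsv"), stringsAsFactors = FALSE))
  geneMeta$regulator_of[is.na(geneMeta$regulator_of)] <- ""
  rownames(cellMeta) <- cellMeta$cell_id
  rownames(geneMeta) <- geneMeta$gene_id
  rownames(m) <- geneMeta$gene_id
  colnames(m) <- cellMeta$cell_id
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), rowData = geneMeta, colData = cellMeta)
  new("CountCorpus", sce)
}

#' @describeIn CountCorpus-class Compact display.
#' @param object A `CountCorpus`.
#' @export
setMethod("show", "CountCorpus", function(object) {
  cat(sprintf("CountCorpus: %d genes x %d cells\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  studies: %d | tissues: %d | cell types: %d | malignant: %d\n",
              length(unique(cd$study)), length(unique(cd$tissue)),
              length(unique(cd$cell_type)), sum(cd$malignant)))
  cls <- table(SummarizedExperiment::rowData(object)$gene_class)
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
})
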