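#' Compute the gene non-zero median dictionary
#'
#' Each qualifying cell's counts are scaled to a fixed target sum; for
#' every gene the scaling factor s_g is the median of its strictly
#' positive normalized values across those cells. Cells flagged as high
#' mutational burden (malignant) are excluded when `excludeMalignant` is
#' set, and zero-total cells are always excluded. Genes never detected
#' are absent from the dictionary.
#'
#' @param corpus A \linkS4class{CountCorpus}.
#' @param excludeMalignant Exclude malignant-flagged cells (default TRUE).
#' @param targetSum Per-cell normalization target sum (default 10,000).
#' @return A \linkS4class{GeneMedianDictionary}.
#' @examples
#' corpus <- generateCorpus(corpusConfig(nGenes = 50, nCells = 60, seed = 2))
#' dict <- computeNonzeroMedians(corpus)
#' @export
computeNonzeroMedians <- function(corpus, excludeMalignant = TRUE,
                                  targetSum = 1e4) {
  stopifnot(is(corpus, "CountCorpus"))
  keep <- rep(TRUE, ncol(corpus))
  if (excludeMalignant)
    keep <- keep & !SummarizedExperiment::colData(corpus)$malignant
  m <- SummarizedExperiment::assay(corpus, "counts")[, keep, drop = FALSE]
  tot <- Matrix::colSums(m)
  m <- m[, tot > 0, drop = FALSE]
  tot <- tot[tot > 0]
  if (ncol(m) == 0)
    .stopf("no cells remain after exclusions; cannot compute medians")
  norm <- m %*% Matrix::Diagonal(x = targetSum / tot)
  trip <- Matrix::summary(methods::as(norm, "CsparseMatrix"))
  trip <- trip[trip$x > 0, , drop = FALSE]
  med <- vapply(split(trip$x, trip$i), median, numeric(1))
  genes <- rownames(corpus)[as.integer(names(med))]
  medians <- setNames(as.numeric(med), genes)
  medians <- medians[order(names(medians))]
  new("GeneMedianDictionary", medians = medians, targetSum = targetSum)
}

#' Build the token vocabulary from a median dictionary
#'
#' One token per dictionary gene plus the four special tokens (padding,
#' masking, CLS, EOS), so the total size is the gene count plus 4. Token
#' ids are 0-based and contiguous: specials first, then genes in sorted
#' gene-id order.
#'
#' @param dictionary A \linkS4class{GeneMedianDictionary}.
#' @return A \linkS4class{TokenVocabulary}.
#' @export
buildVocabulary <- function(dictionary) {
  stopifnot(is(dictionary, "GeneMedianDictionary"))
  genes <- sort(names(dictionary@medians))
  if (!length(genes)) .stopf("dictionary is empty")
  if (anyDuplicated(genes)) .stopf("duplicate gene ids in dictionary")
  new("TokenVocabulary",
      tokens = c("<pad>", "<mask>", "<cls>", "<eos>", genes))
}

#' @rdname TokenVocabulary-class
#' @param vocab A `TokenVocabulary`.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' Special-token ids (0-based)
#' @rdname TokenVocabulary-class
#' @export
padId <- function(vocab) 0L
#' @rdname TokenVocabulary-class
#' @export
maskId <- function(vocab) 1L
#' @rdname TokenVocabulary-class
#' @export
clsId <- function(vocab) 2L
#' @rdname TokenVocabulary-class
#' @export
eosId <- function(vocab) 3L

#' @rdname TokenVocabulary-class
#' @param genes Character vector of gene ids.
#' @return `tokenId`: 0-based integer ids (NA for absent genes).
#' @export
tokenId <- function(vocab, genes) {
  match(genes, vocab@tokens) - 1L
}

#' @rdname TokenVocabulary-class
#' @param ids 0-based integer token ids.
#' @export
tokenName <- function(vocab, ids) vocab@tokens[ids + 1L]

setMethod("show", "TokenVocabulary", function(object) {
  cat(sprintf("TokenVocabulary: %d tokens (%d genes + 4 special)\n",
              length(object@tokens), length(object@tokens) - 4L))
})

setMethod("show", "GeneMedianDictionary", function(object) {
  cat(sprintf(
    "GeneMedianDictionary: %d genes, target sum %g, median s_g %.3g\n",
    length(object@medians), object@targetSum, median(object@medians)))
})

#' Serialize / reload dictionary and vocabulary as JSON
#'
#' @param x Object to write.
#' @param path File path.
#' @name tokenizer-io
#' @export
writeDictionary <- function(x, path) {
  jsonlite::write_json(list(target_sum = x@targetSum,
                            medians = as.list(x@medians)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tokenizer-io
#' @export
readDictionary <- function(path) {
  j <- jsonlite::read_json(path)
  new("GeneMedianDictionary",
      medians = unlist(j$medians), targetSum = j$target_sum)
}

#' @rdname tokenizer-io
#' @export
writeVocabulary <- function(x, path) {
  jsonlite::write_json(list(tokens = x@tokens), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname tokenizer-io
#' @export
readVocabulary <- function(path) {
  new("TokenVocabulary",
      tokens = unlist(jsonlite::read_json(path)$tokens))
}

#' Quality-filter cells by detected protein-coding genes
#'
#' Retains cells that detect at least `minGenes` protein-coding genes
#' (default 7); with fewer detected genes the 15% masking objective
#' would not reliably mask a gene. The removal log is stored in the
#' returned corpus metadata and readable with [filterLog()].
#'
#' @param corpus A \linkS4class{CountCorpus}.
#' @param minGenes Minimum detected protein-coding genes (default 7).
#' @return The filtered \linkS4class{CountCorpus}.
#' @export
qcFilterCells <- function(corpus, minGenes = 7L) {
  stopifnot(is(corpus, "CountCorpus"))
  pc <- SummarizedExperiment::rowData(corpus)$protein_coding
  m <- SummarizedExperiment::assay(corpus, "counts")
  det <- Matrix::colSums(m[pc, , drop = FALSE] > 0)
  keep <- det >= minGenes
  out <- corpus[, keep]
  log <- S4Vectors::metadata(out)$filterLog
  log <- c(log, sprintf(
    "qc: removed %d/%d cells with < %d detected protein-coding genes",
    sum(!keep), length(keep), minGenes))
  S4Vectors::metadata(out)$filterLog <- log
  out
}

#' Read the accumulated filter log of a corpus
#' @param corpus A \linkS4class{CountCorpus}.
#' @return Character vector of log lines.
#' @export
filterLog <- function(corpus) {
  lg <- S4Vectors::metadata(corpus)$filterLog
  if (is.null(lg)) character(0) else lg
}

.normalizeDOI <- function(doi) {
  d <- tolower(trimws(as.character(doi)))
  d <- sub("^https?://(dx\\.)?doi\\.org/", "", d)
  d <- sub("^doi:\\s*", "", d)
  gsub("\\s+", "", d)
}

#' Deduplicate studies by DOI
#'
#' DOIs are cross-referenced between all studies so that datasets are
#' unique: among studies sharing a normalized DOI (case-folded,
#' whitespace-stripped, `doi.org` prefix removed), only the
#' lexicographically smallest study accession is retained. Studies with
#' a missing DOI are retained but flagged in the log. Idempotent.
#'
#' @param x A \linkS4class{CountCorpus}, or a data.frame/DataFrame with
#'   `study` and `doi` columns.
#' @return For a corpus: the deduplicated corpus (log via
#'   [filterLog()]). For a table: a list with `retained`, `dropped` and
#'   `log`.
#' @export
setGeneric("deduplicateStudies", function(x) {
  standardGeneric("deduplicateStudies")
})

.dedupStudyTable <- function(study, doi) {
  tab <- unique(data.frame(study = as.character(study),
                           doi = as.character(doi),
                           stringsAsFactors = FALSE))
  tab$norm <- .normalizeDOI(tab$doi)
  missing <- is.na(tab$doi) | tab$norm == "" | tab$norm == "na"
  flagged <- tab$study[missing]
  ok <- tab[!missing, , drop = FALSE]
  ok <- ok[order(ok$study), , drop = FALSE]
  retained <- vapply(split(ok$study, ok$norm), min, character(1))
  dropped <- setdiff(ok$study, retained)
  log <- c(
    sprintf("dedup: %d studies, %d distinct DOIs, dropped %d duplicates",
            nrow(tab), length(unique(ok$norm)), length(dropped)),
    if (length(dropped))
      sprintf("dedup: dropped %s", paste(sort(dropped), collapse = ", ")),
    if (length(flagged))
      sprintf("dedup: missing DOI, retained but flagged: %s",
              paste(sort(flagged), collapse = ", ")))
  list(retained = sort(c(unname(retained), flagged)),
       dropped = sort(dropped), log = log)
}

#' @rdname deduplicateStudies
#' @export
setMethod("deduplicateStudies", "CountCorpus", function(x) {
  cd <- SummarizedExperiment::colData(x)
  res <- .dedupStudyTable(cd$study, cd$doi)
  out <- x[, cd$study %in% res$retained]
  S4Vectors::metadata(out)$filterLog <-
    c(S4Vectors::metadata(out)$filterLog, res$log)
  out
})

#' @rdname deduplicateStudies
#' @export
setMethod("deduplicateStudies", "ANY", function(x) {
  .dedupStudyTable(x$study, x$doi)
})

#' Balance the corpus so no tissue exceeds a share cap
#'
#' Iteratively downsamples each over-cap tissue (uniformly, without
#' replacement, seeded) until every tissue composes at most `cap` of the
#' retained total. Deterministic given the seed.
#'
#' @param corpus A \linkS4class{CountCorpus}.
#' @param cap Maximum tissue share of the retained data (default 0.25).
#' @param seed Integer seed for the downsampling draws.
#' @return The balanced \linkS4class{CountCorpus}.
#' @export
balanceTissues <- function(corpus, cap = 0.25, seed = 1L) {
  stopifnot(is(corpus, "CountCorpus"))
  tis <- SummarizedExperiment::colData(corpus)$tissue
  nt <- table(tis)
  if (cap > 1) .stopf("cap must be <= 1")
  if (cap < 1 / length(nt))
    .stopf("cap %.3f infeasible: below 1/%d tissues", cap, length(nt))
  target <- as.numeric(nt)
  repeat {
    limit <- floor(cap * sum(target))
    if (limit < 1) .stopf("cap drives all tissues to zero cells")
    over <- target > limit
    if (!any(over)) break
    target[over] <- limit
  }
  names(target) <- names(nt)
  keep <- withr::with_seed(seed, {
    unlist(lapply(names(nt), function(t) {
      idx <- which(tis == t)
      if (length(idx) > target[[t]]) sort(sample(idx, target[[t]])) else idx
    }))
  })
  keep <- sort(keep)
  out <- corpus[, keep]
  S4Vectors::metadata(out)$filterLog <- c(
    S4Vectors::metadata(out)$filterLog,
    sprintf("balance: cap %.2f, retained %d/%d cells", cap,
            length(keep), ncol(corpus)))
  out
}

#' Rank value encode one cell
#'
#' The cell is normalized to the dictionary's target sum; each detected
#' in-vocabulary gene is scored as normalized value / s_g; genes are
#' ordered by descending score (ties broken by ascending token id for
#' reproducibility), truncated to `capacity - 2`, and wrapped in CLS /
#' EOS tokens. Rank order is invariant to the target sum since scores
#' scale uniformly within a cell. Detected genes absent from the
#' dictionary are silently dropped and counted.
#'
#' @param cellCounts Named numeric vector of counts for one cell (names
#'   are gene ids), or a 1-column matrix with rownames.
#' @param dictionary A \linkS4class{GeneMedianDictionary}.
#' @param vocab A \linkS4class{TokenVocabulary}.
#' @param capacity Maximum sequence length including CLS and EOS
#'   (must be >= 3).
#' @return A \linkS4class{RankValueEncoding}.
#' @export
rankValueEncode <- function(cellCounts, dictionary, vocab,
                            capacity = 2048L) {
  if (is.matrix(cellCounts) || is(cellCounts, "Matrix"))
    cellCounts <- setNames(as.numeric(cellCounts[, 1]),
                           rownames(cellCounts))
  if (capacity < 3) .stopf("capacity must be >= 3 (CLS + 1 gene + EOS)")
  tot <- sum(cellCounts)
  if (tot <= 0) .stopf("cell has zero total counts")
  det <- cellCounts[cellCounts > 0]
  inDict <- names(det) %in% names(dictionary@medians)
  ids <- tokenId(vocab, names(det))
  usable <- inDict & !is.na(ids)
  dropped <- sum(!usable)
  det <- det[usable]; ids <- ids[usable]
  norm <- det / tot * dictionary@targetSum
  score <- norm / dictionary@medians[names(det)]
  ord <- order(-score, ids)
  ids <- ids[ord]
  ids <- ids[seq_len(min(length(ids), capacity - 2L))]
  new("RankValueEncoding",
      ids = c(clsId(vocab), as.integer(ids), eosId(vocab)),
      droppedGenes = as.integer(dropped))
}

setMethod("show", "RankValueEncoding", function(object) {
  cat(sprintf("RankValueEncoding: %d tokens (%d genes), %d dropped\n",
              length(object@ids), length(object@ids) - 2L,
              object@droppedGenes))
})

#' Tokenize every cell of a filtered corpus
#'
#' @param corpus A filtered \linkS4class{CountCorpus}.
#' @param dictionary A \linkS4class{GeneMedianDictionary}.
#' @param vocab A \linkS4class{TokenVocabulary}.
#' @param capacity Maximum sequence length including CLS and EOS.
#' @return A \linkS4class{TokenizedDataset} with one record per cell,
#'   cell metadata passed through, and provenance hashes of the
#'   dictionary and vocabulary.
#' @export
tokenizeCorpus <- function(corpus, dictionary, vocab, capacity = 2048L) {
  stopifnot(is(corpus, "CountCorpus"))
  m <- SummarizedExperiment::assay(corpus, "counts")
  m <- methods::as(m, "CsparseMatrix")
  genes <- rownames(corpus)
  gIds <- tokenId(vocab, genes)
  sg <- dictionary@medians[genes]
  dropped <- 0L
  tokens <- vector("list", ncol(m))
  p <- m@p; i <- m@i; x <- m@x
  for (j in seq_len(ncol(m))) {
    idx <- if (p[j + 1] > p[j]) (p[j] + 1L):p[j + 1L] else integer(0)
    ri <- i[idx] + 1L
    v <- x[idx]
    tot <- sum(v)
    ok <- !is.na(gIds[ri]) & !is.na(sg[ri])
    dropped <- dropped + sum(!ok)
    ri <- ri[ok]; v <- v[ok]
    score <- (v / tot * dictionary@targetSum) / sg[ri]
    ids <- gIds[ri]
    ord <- order(-score, ids)
    ids <- ids[ord][seq_len(min(length(ri), capacity - 2L))]
    tokens[[j]] <- c(2L, as.integer(ids), 3L)
  }
  new("TokenizedDataset", tokens = tokens,
      cellMeta = SummarizedExperiment::colData(corpus),
      provenance = list(
        dictHash = contentHash(dictionary@medians),
        vocabHash = contentHash(vocab@tokens),
        capacity = as.integer(capacity), droppedGenes = dropped,
        filterLog = filterLog(corpus)))
}

setMethod("show", "TokenizedDataset", function(object) {
  len <- lengths(object@tokens)
  cat(sprintf(
    "TokenizedDataset: %d cells, lengths %d-%d (median %d), capacity %d\n",
    length(object@tokens), if (length(len)) min(len) else 0L,
    if (length(len)) max(len) else 0L,
    if (length(len)) as.integer(median(len)) else 0L,
    object@provenance$capacity))
})

#' Subset / combine helpers for tokenized datasets
#' @param x A \linkS4class{TokenizedDataset}.
#' @param idx Integer or logical cell index.
#' @return A \linkS4class{TokenizedDataset}.
#' @export
subsetDataset <- function(x, idx) {
  new("TokenizedDataset", tokens = x@tokens[idx],
      cellMeta = x@cellMeta[idx, , drop = FALSE],
      provenance = x@provenance)
}

#' Write / read a tokenized dataset as a plain-text columnar directory
#'
#' One whitespace-separated line of 0-based token ids per cell in
#' `tokens.txt`, cell metadata in `cell_meta.tsv`, and a JSON manifest
#' carrying provenance hashes.
#'
#' @param x A \linkS4class{TokenizedDataset}.
#' @param dir Directory path.
#' @name tokenized-io
#' @export
writeTokenizedDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(vapply(x@tokens, paste, character(1), collapse = " "),
             file.path(dir, "tokens.txt"))
  write.table(as.data.frame(x@cellMeta), file.path(dir, "cell_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x@provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname tokenized-io
#' @export
readTokenizedDataset <- function(dir) {
  tokens <- lapply(strsplit(readLines(file.path(dir, "tokens.txt")), " "),
                   as.integer)
  meta <- S4Vectors::DataFrame(
    read.delim(file.path(dir, "cell_meta.tsv"), stringsAsFactors = FALSE))
  prov <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  prov$capacity <- as.integer(prov$capacity)
  new("TokenizedDataset", tokens = tokens, cellMeta = meta,
      provenance = prov)
}
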