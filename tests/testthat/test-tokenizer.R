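test_that("non-zero medians match trivial cases and a brute-force oracle", {
  # 3 cells, equal totals so normalization is uniform
  counts <- rbind(c(0, 0, 3), c(1, 2, 4), c(9, 8, 3))
  corpus <- handCorpus(counts)
  dict <- computeNonzeroMedians(corpus, targetSum = 10)
  # per-cell totals are 10, so normalized values equal raw counts
  expect_equal(unname(dict@medians["G0001"]), 3)   # {3} -> 3
  expect_equal(unname(dict@medians["G0002"]), 2)   # {1,2,4} -> 2

  corpus <- generateCorpus(corpusConfig(nGenes = 60L, nCells = 50L,
                                        malignantFraction = 0,
                                        seed = 31L))
  dict <- computeNonzeroMedians(corpus)
  m <- as.matrix(SummarizedExperiment::assay(corpus, "counts"))
  norm <- sweep(m, 2, colSums(m), "/") * 1e4
  for (g in rownames(m)) {
    v <- norm[g, ][norm[g, ] > 0]
    if (length(v)) expect_equal(unname(dict@medians[g]), median(v))
    else expect_false(g %in% names(dict@medians))
  }
})

test_that("malignant cells are excluded from the median dictionary", {
  counts <- cbind(c(10, 0), c(10, 0), c(0, 10))
  corpus <- handCorpus(counts, malignant = c(FALSE, FALSE, TRUE))
  dict <- computeNonzeroMedians(corpus, targetSum = 10)
  expect_false("G0002" %in% names(dict@medians))  # only in malignant cell
  dictAll <- computeNonzeroMedians(corpus, excludeMalignant = FALSE,
                                   targetSum = 10)
  expect_true("G0002" %in% names(dictAll@medians))
  allMal <- handCorpus(counts, malignant = rep(TRUE, 3))
  expect_error(computeNonzeroMedians(allMal), "no cells remain")
})

test_that("vocabulary size is gene count + 4 and ids survive a round-trip", {
  d1 <- new("GeneMedianDictionary",
            medians = c(G1 = 1.5), targetSum = 1e4)
  expect_equal(vocabSize(buildVocabulary(d1)), 5)

  pl <- smallPipeline()
  expect_equal(vocabSize(pl$vocab), length(pl$dict@medians) + 4)
  f <- tempfile(fileext = ".json")
  writeVocabulary(pl$vocab, f)
  back <- readVocabulary(f)
  expect_identical(back@tokens, pl$vocab@tokens)
  fd <- tempfile(fileext = ".json")
  writeDictionary(pl$dict, fd)
  backd <- readDictionary(fd)
  expect_equal(backd@medians, pl$dict@medians)
  expect_equal(backd@targetSum, pl$dict@targetSum)
  unlink(c(f, fd))
})

test_that("QC retains cells at exactly the protein-coding detection threshold", {
  # cell 1: 6 coding + 10 non-coding detected; cell 2: exactly 7 coding;
  # cell 3: 8 coding
  G <- 20
  counts <- matrix(0, G, 3)
  counts[1:6, 1] <- 1; counts[11:20, 1] <- 1
  counts[1:7, 2] <- 1
  counts[1:8, 3] <- 1
  corpus <- handCorpus(counts,
                       proteinCoding = c(rep(TRUE, 10), rep(FALSE, 10)))
  filtered <- qcFilterCells(corpus)
  expect_equal(ncol(filtered), 2)
  expect_identical(colnames(filtered), c("cell00002", "cell00003"))
  expect_match(filterLog(filtered), "removed 1/3")

  # survivor count equals a direct recount on a seeded fixture
  corpus <- generateCorpus(corpusConfig(nGenes = 50L, nCells = 120L,
                                        seed = 17L))
  pc <- SummarizedExperiment::rowData(corpus)$protein_coding
  m <- as.matrix(SummarizedExperiment::assay(corpus, "counts"))
  expected <- sum(colSums(m[pc, ] > 0) >= 7)
  expect_equal(ncol(qcFilterCells(corpus)), expected)
})

test_that("DOI deduplication keeps one study per DOI and is idempotent", {
  tab <- data.frame(
    study = sprintf("S%02d", 1:10),
    doi = c(sprintf("10.1/d%d", 1:7),
            "10.1/d1", " 10.1/D2 ", "https://doi.org/10.1/d3"))
  res <- deduplicateStudies(tab)
  expect_length(res$retained, 7)
  expect_identical(res$dropped, c("S08", "S09", "S10"))
  again <- deduplicateStudies(
    tab[tab$study %in% res$retained, , drop = FALSE])
  expect_identical(again$retained, res$retained)

  distinct <- data.frame(study = c("A", "B"),
                         doi = c("10.1/x", "10.1/y"))
  expect_identical(deduplicateStudies(distinct)$retained, c("A", "B"))

  noDoi <- data.frame(study = c("A", "B"), doi = c("10.1/x", NA))
  resN <- deduplicateStudies(noDoi)
  expect_true("B" %in% resN$retained)
  expect_true(any(grepl("flagged", resN$log)))

  # corpus method drops the duplicated study's cells
  corpus <- generateCorpus(corpusConfig(nGenes = 30L, nCells = 100L,
                                        nStudies = 4L,
                                        duplicateStudyPairs = 1L,
                                        seed = 3L))
  dd <- deduplicateStudies(corpus)
  cd <- SummarizedExperiment::colData(dd)
  expect_equal(length(unique(cd$study)), length(unique(cd$doi)))
})

test_that("tissue balancing enforces the share cap", {
  counts <- matrix(rpois(20 * 200, 5), 20, 200)
  # one dominant tissue at 80%, four small ones
  tis <- rep(c("tA", "tB", "tC", "tD", "tE"), c(160, 10, 10, 10, 10))
  corpus <- handCorpus(counts, tissue = tis)
  bal <- balanceTissues(corpus, cap = 0.25, seed = 3L)
  shares <- prop.table(table(
    SummarizedExperiment::colData(bal)$tissue))
  expect_true(all(shares <= 0.25 + 1e-12))
  expect_equal(sum(SummarizedExperiment::colData(bal)$tissue != "tA"),
               40)                  # under-cap tissues untouched

  # identity when all tissues already under cap, and when cap = 1
  even <- handCorpus(counts, tissue = rep(c("tA", "tB"), 100))
  expect_equal(ncol(balanceTissues(even, cap = 0.6, seed = 1L)), 200)
  expect_equal(ncol(balanceTissues(corpus, cap = 1, seed = 1L)), 200)

  # cap below 1/n_tissues cannot be satisfied
  expect_error(balanceTissues(even, cap = 0.3, seed = 1L),
               "infeasible")
  # deterministic given seed
  b2 <- balanceTissues(corpus, cap = 0.25, seed = 3L)
  expect_identical(colnames(bal), colnames(b2))
})

test_that("rank value encoding orders by median-scaled expression", {
  dict <- new("GeneMedianDictionary",
              medians = c(A = 2.0, B = 0.5), targetSum = 1e4)
  vocab <- buildVocabulary(dict)
  enc <- rankValueEncode(c(A = 2, B = 2), dict, vocab)
  # equal normalized values: score(B) = v/0.5 > score(A) = v/2
  expect_identical(tokenName(vocab, enc@ids),
                   c("<cls>", "B", "A", "<eos>"))

  single <- rankValueEncode(c(A = 5), dict, vocab)
  expect_identical(tokenName(vocab, single@ids),
                   c("<cls>", "A", "<eos>"))

  # identical scores tie-break by ascending token id
  dictT <- new("GeneMedianDictionary",
               medians = c(A = 1, B = 1), targetSum = 1e4)
  vocabT <- buildVocabulary(dictT)
  encT <- rankValueEncode(c(A = 3, B = 3), dictT, vocabT)
  expect_identical(tokenName(vocabT, encT@ids),
                   c("<cls>", "A", "B", "<eos>"))

  # genes absent from the dictionary are dropped and counted
  encD <- rankValueEncode(c(A = 2, Z = 9), dict, vocab)
  expect_equal(encD@droppedGenes, 1L)
  expect_identical(tokenName(vocab, encD@ids),
                   c("<cls>", "A", "<eos>"))
})

test_that("rank order is invariant to the normalization target sum", {
  pl <- smallPipeline()
  m <- SummarizedExperiment::assay(pl$corpus, "counts")
  cellCounts <- setNames(as.numeric(m[, 5]), rownames(m))
  d2 <- pl$dict
  d2@targetSum <- 500                   # scores scale uniformly per cell
  e1 <- rankValueEncode(cellCounts, pl$dict, pl$vocab, capacity = 48L)
  e2 <- rankValueEncode(cellCounts, d2, pl$vocab, capacity = 48L)
  expect_identical(e1@ids, e2@ids)
})

test_that("encodings are permutations truncated at capacity", {
  pl <- smallPipeline()
  lens <- lengths(pl$ds@tokens)
  expect_true(all(lens <= 48L))
  for (x in pl$ds@tokens[1:25]) {
    genes <- x[-c(1, length(x))]
    expect_equal(anyDuplicated(genes), 0)
    expect_equal(x[1], 2L)
    expect_equal(x[length(x)], 3L)
  }
})

test_that("tokenization preserves cardinality, lengths and determinism", {
  pl <- smallPipeline()
  expect_equal(length(pl$ds@tokens), ncol(pl$corpus))
  m <- SummarizedExperiment::assay(pl$corpus, "counts")
  detected <- Matrix::colSums(m[names(pl$dict@medians), ] > 0)
  expLen <- pmin(detected, 48L - 2L) + 2L
  expect_equal(unname(lengths(pl$ds@tokens)), unname(expLen))
  ds2 <- tokenizeCorpus(pl$corpus, pl$dict, pl$vocab, capacity = 48L)
  expect_identical(ds2@tokens, pl$ds@tokens)
  expect_identical(ds2@provenance$dictHash, pl$ds@provenance$dictHash)
})

test_that("tokenizer agrees with the per-cell encoder and round-trips to disk", {
  pl <- smallPipeline()
  m <- SummarizedExperiment::assay(pl$corpus, "counts")
  for (j in c(1, 7, 20)) {
    enc <- rankValueEncode(setNames(as.numeric(m[, j]), rownames(m)),
                           pl$dict, pl$vocab, capacity = 48L)
    expect_identical(enc@ids, pl$ds@tokens[[j]])
  }
  dir <- tempfile()
  writeTokenizedDataset(pl$ds, dir)
  back <- readTokenizedDataset(dir)
  expect_identical(back@tokens, pl$ds@tokens)
  expect_identical(back@provenance$vocabHash,
                   pl$ds@provenance$vocabHash)
  unlink(dir, recursive = TRUE)
})

test_that("rank value encoding deprioritizes housekeeping genes", {
  pl <- smallPipeline()
  rd <- SummarizedExperiment::rowData(pl$corpus)
  hkIds <- tokenId(pl$vocab,
                   rd$gene_id[rd$gene_class == "housekeeping"])
  hkIds <- hkIds[!is.na(hkIds)]
  m <- SummarizedExperiment::assay(pl$corpus, "counts")
  gIds <- tokenId(pl$vocab, rownames(m))
  posRVE <- c(); posRaw <- c()
  for (j in seq_len(min(100, ncol(m)))) {
    rve <- pl$ds@tokens[[j]]
    genes <- rve[-c(1, length(rve))]
    # raw-count ordering of the same genes (ties by token id)
    v <- as.numeric(m[, j])
    det <- which(v > 0 & !is.na(gIds))
    rawOrder <- gIds[det][order(-v[det], gIds[det])]
    rawOrder <- rawOrder[rawOrder %in% genes]
    isHk <- genes %in% hkIds
    if (!any(isHk)) next
    posRVE <- c(posRVE, which(genes %in% hkIds))
    posRaw <- c(posRaw, which(rawOrder %in% hkIds))
  }
  # mean housekeeping rank is strictly deeper under rank value encoding
  expect_gt(mean(posRVE), mean(posRaw))
})
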