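test_that("embedding extraction is pure, deterministic and layer-tagged", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  sub <- subsetDataset(pl$ds, 1:6)
  hashBefore <- weightHash(model)
  e1 <- extractGeneEmbeddings(model, sub)
  e2 <- extractGeneEmbeddings(model, sub)
  expect_identical(e1@values, e2@values)
  expect_identical(weightHash(model), hashBefore)
  expect_equal(ncol(e1@values), model@spec@hidden)

  eLast <- extractGeneEmbeddings(model, sub, layer = "last")
  expect_false(isTRUE(all.equal(e1@values, eLast@values)))

  one <- initEncoder(encoderSpec(1, vocabSize = vocabSize(pl$vocab),
                                 maxPositions = 48L), 1L)
  expect_error(extractGeneEmbeddings(one, sub), ">= 2 layers")
})

test_that("gene embeddings equal slices of the full hidden-state dump", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  sub <- subsetDataset(pl$ds, 1:3)
  emb <- extractGeneEmbeddings(model, sub)
  fw <- encoderForward(model, sub@tokens)
  H <- fw$hidden[[model@spec@layers]]        # second-to-last state
  for (cidx in 1:3) {
    x <- sub@tokens[[cidx]]
    gp <- which(x >= 4L)
    rows <- which(emb@index$cell == cidx)
    expect_equal(emb@values[rows, , drop = FALSE],
                 H[fw$rows[[cidx]][gp], , drop = FALSE])
    expect_equal(emb@index$gene[rows], x[gp])
  }
})

test_that("cell embeddings come from the CLS position", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  sub <- subsetDataset(pl$ds, 1:5)
  ce <- extractCellEmbeddings(model, sub)
  expect_equal(nrow(ce@values), 5)
  fw <- encoderForward(model, sub@tokens)
  H <- fw$hidden[[model@spec@layers]]
  for (cidx in 1:5)
    expect_equal(ce@values[cidx, ], H[fw$rows[[cidx]][1], ])

  # permuting batch order permutes rows, not values
  perm <- c(3L, 1L, 5L, 2L, 4L)
  ceP <- extractCellEmbeddings(model, subsetDataset(sub, perm))
  expect_equal(ceP@values, ce@values[perm, ])

  bad <- sub
  bad@tokens[[2]][1] <- 4L
  expect_error(extractCellEmbeddings(model, bad), "CLS")
})

test_that("cosine suite: trivial geometry and planted batch robustness", {
  expect_equal(cosineSimilarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0.0)
  expect_true(is.na(cosineSimilarity(c(0, 0), c(1, 1))))

  pl <- smallPipeline()
  model <- tinyTrainedModel()
  sub <- subsetDataset(pl$ds, 1:40)
  emb <- extractGeneEmbeddings(model, sub)
  suite <- cosineSimilaritySuite(emb, nPairs = 60L, seed = 3L)
  expect_named(suite$arms, c("different_gene_same_cell",
                             "same_gene_same_batch",
                             "same_gene_cross_batch"))
  # same-gene arms exceed the different-gene arm (planted structure)
  expect_gt(suite$medians["same_gene_cross_batch"],
            suite$medians["different_gene_same_cell"])
  expect_gt(suite$medians["same_gene_same_batch"],
            suite$medians["different_gene_same_cell"])
  expect_true(all(suite$tests$p >= 0 & suite$tests$p <= 1))
})

test_that("separability index is exact on planted clusters and matches brute force", {
  mkEmb <- function(values, genes) {
    new("EmbeddingMatrix", values = values,
        index = S4Vectors::DataFrame(gene = genes,
                                     cell = seq_along(genes)),
        layerTag = "second_to_last", modelHash = "test")
  }
  # two genes, duplicated identical vectors, distinct across genes
  v <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(as.numeric(separabilityIndex(mkEmb(v, c(4L, 4L, 5L, 5L)))), 1.0)

  # well-separated planted Gaussian clusters -> 1.0
  set.seed(6)
  nG <- 6; per <- 8
  centers <- matrix(rnorm(nG * 10, sd = 30), nG, 10)
  vals <- do.call(rbind, lapply(seq_len(nG), function(g)
    centers[rep(g, per), ] + matrix(rnorm(per * 10, sd = 0.1), per, 10)))
  genes <- rep(3L + seq_len(nG), each = per)
  embG <- mkEmb(vals, genes)
  expect_equal(as.numeric(separabilityIndex(embG)), 1.0)

  # merged clusters drop below 1.0
  merged <- mkEmb(vals + matrix(rnorm(length(vals), sd = 60),
                                nrow(vals)), genes)
  expect_lt(as.numeric(separabilityIndex(merged)), 1.0)

  # equality with a brute-force all-pairs neighbor search
  bruteIndex <- function(vals, genes) {
    u <- vals / sqrt(rowSums(vals^2))
    hits <- 0
    for (i in seq_len(nrow(u))) {
      best <- -Inf; bj <- NA
      for (j in seq_len(nrow(u))) {
        if (j == i) next
        s <- sum(u[i, ] * u[j, ])
        if (s > best) { best <- s; bj <- j }
      }
      hits <- hits + (genes[bj] == genes[i])
    }
    hits / nrow(u)
  }
  for (emb in list(embG, merged))
    expect_equal(as.numeric(separabilityIndex(emb)),
                 bruteIndex(emb@values, emb@index$gene))

  # degenerate: all embeddings identical -> result stays in [0, 1]
  same <- mkEmb(matrix(1, 6, 4), rep(c(4L, 5L), each = 3))
  si <- as.numeric(separabilityIndex(same))
  expect_gte(si, 0); expect_lte(si, 1)
})

test_that("linear probe separates planted labels and matches the permutation null", {
  set.seed(12)
  n <- 240
  X <- rbind(matrix(rnorm(n / 2 * 8, mean = 2), n / 2, 8),
             matrix(rnorm(n / 2 * 8, mean = -2), n / 2, 8))
  genes <- as.character(rep(1:40, each = 6))
  labels <- setNames(rep(c("a", "b"), each = 20), as.character(1:40))
  emb <- new("EmbeddingMatrix", values = X,
             index = S4Vectors::DataFrame(gene = genes,
                                          cell = seq_len(n)),
             layerTag = "second_to_last", modelHash = "t")
  pr <- linearProbe(emb, labels, level = "gene", seeds = 1:3)
  expect_equal(unname(pr@scores), rep(1, 3))

  # permuted labels on balanced classes: macro F1 near chance
  permLabels <- setNames(sample(labels), names(labels))
  prP <- linearProbe(emb, permLabels, level = "gene", seeds = 1:6)
  expect_lt(abs(mean(prP@scores) - 0.5), 0.3)

  # determinism
  pr2 <- linearProbe(emb, labels, level = "gene", seeds = 1:3)
  expect_identical(pr@scores, pr2@scores)
})

test_that("cell-level probe on real embeddings recovers cell types above chance", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  sub <- subsetDataset(pl$ds, seq_len(min(150, length(pl$ds@tokens))))
  ce <- extractCellEmbeddings(model, sub)
  labels <- sub@cellMeta$cell_type
  names(labels) <- NULL
  pr <- linearProbe(ce, setNames(labels, seq_along(labels)),
                    level = "cell", seeds = 1L)
  chance <- 1 / length(unique(labels))
  expect_gt(mean(pr@scores), chance)
})

test_that("fine-tuning improves over zero steps and trains the head", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  labels <- pl$ds@cellMeta$cell_type
  # zero training steps leave the model unchanged
  ft0 <- finetuneClassifier(model, pl$ds, labels, head = "cell",
                            epochs = 0, seed = 2L)
  expect_identical(weightHash(ft0$model), weightHash(model))

  ft <- finetuneClassifier(model, pl$ds, labels, head = "cell",
                           mode = "full", budget = 120L, epochs = 2,
                           batchSize = 8L, seed = 2L)
  expect_gt(mean(ft$probe@scores), mean(ft0$probe@scores))
  expect_true(all(ft$probe@scores >= 0 & ft$probe@scores <= 1))
})
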