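test_that("in silico deletion removes exactly one token and shifts are bounded", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  enc <- pl$ds@tokens[[1]]
  gene <- enc[3]                      # a mid-rank gene
  res <- inSilicoDelete(model, enc, gene)
  # deleting from an n-gene cell leaves n - 1 affected genes
  expect_equal(nrow(res), length(enc) - 3L)
  expect_false(gene %in% res$gene)
  expect_true(all(res$shift >= 0 & res$shift <= 2))
  expect_error(inSilicoDelete(model, enc, 99999L), "not present")

  # 3-gene cell leaves 2 affected genes
  small <- c(2L, enc[2:4], 3L)
  res3 <- inSilicoDelete(model, small, enc[2])
  expect_equal(nrow(res3), 2)
})

test_that("identity control: comparing an encoding to itself gives zero shifts", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  enc <- pl$ds@tokens[[2]]
  fw <- encoderForward(model, list(enc, enc))
  H <- fw$hidden[[model@spec@layers]]
  gp <- which(enc >= 4L)
  u <- H[fw$rows[[1]][gp], , drop = FALSE]
  v <- H[fw$rows[[2]][gp], , drop = FALSE]
  shifts <- 1 - rowSums((u / sqrt(rowSums(u^2))) *
                          (v / sqrt(rowSums(v^2))))
  expect_true(all(abs(shifts) < 1e-12))
})

test_that("single-layer toy model matches an independent attention-equation forward", {
  # hand-set weights on a 1-layer, 1-head model; the oracle implements
  # the attention/FFN/layer-norm equations directly and independently
  spec <- encoderSpec(1, vocabSize = 10L, maxPositions = 8L)
  rf <- asNamespace("rankformer")
  w <- rf$.initWeights(spec, 99L)
  set.seed(5)
  for (nm in names(w)) {
    if (is.matrix(w[[nm]])) w[[nm]][] <- rnorm(length(w[[nm]]), sd = 0.2)
    else if (grepl("_b$|^b|bias", nm)) w[[nm]][] <- rnorm(length(w[[nm]]), sd = 0.05)
  }
  w$lnE_g <- runif(64, 0.5, 1.5); w$lnE_b <- rnorm(64, sd = 0.1)
  model <- initEncoder(spec, 1L)
  model@weights <- w
  enc <- c(2L, 7L, 4L, 9L, 3L)

  oracleForward <- function(w, ids) {
    ln <- function(x, g, b, eps = 1e-12) {
      t(apply(x, 1, function(r)
        g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) + b))
    }
    X <- w$tok[ids + 1, ] + w$pos[seq_along(ids), ]
    X <- ln(X, w$lnE_g, w$lnE_b)
    Q <- X %*% w$L1_Wq + matrix(w$L1_bq, length(ids), 64, byrow = TRUE)
    K <- X %*% w$L1_Wk + matrix(w$L1_bk, length(ids), 64, byrow = TRUE)
    V <- X %*% w$L1_Wv + matrix(w$L1_bv, length(ids), 64, byrow = TRUE)
    S <- Q %*% t(K) / 8                  # sqrt(64)
    P <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    A <- (P %*% V) %*% w$L1_Wo +
      matrix(w$L1_bo, length(ids), 64, byrow = TRUE)
    X1 <- ln(X + A, w$L1_ln1_g, w$L1_ln1_b)
    U <- pmax(X1 %*% w$L1_W1 +
                matrix(w$L1_b1, length(ids), 256, byrow = TRUE), 0)
    Fo <- U %*% w$L1_W2 + matrix(w$L1_b2, length(ids), 64, byrow = TRUE)
    ln(X1 + Fo, w$L1_ln2_g, w$L1_ln2_b)
  }

  fw <- encoderForward(model, list(enc))
  expect_equal(fw$hidden[[2]], oracleForward(w, enc), tolerance = 1e-10)

  # deletion shifts recomputed through the oracle agree
  gene <- 7L
  pert <- enc[enc != gene]
  res <- inSilicoDelete(model, enc, gene, layer = "last")
  Ho <- oracleForward(w, enc)
  Hp <- oracleForward(w, pert)
  for (i in seq_len(nrow(res))) {
    g <- res$gene[i]
    u <- Ho[match(g, enc), ]; v <- Hp[match(g, pert), ]
    expect_equal(res$shift[i],
                 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2)),
                 tolerance = 1e-10)
  }
})

test_that("deletion plans aggregate shifts and honor the detection filter", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  gene <- pl$ds@tokens[[1]][2]
  run <- runDeletion(model, subsetDataset(pl$ds, 1:12), gene)
  expect_gt(nrow(run$perCell), 0)
  agg <- aggregateShifts(run, detectionQuantile = 0)
  # means match hand-computed averages
  byGene <- split(run$perCell$shift, run$perCell$gene)
  for (i in seq_len(nrow(agg@perGene))) {
    g <- agg@perGene$gene[i]
    expect_equal(agg@perGene$meanShift[i],
                 mean(byGene[[as.character(g)]]))
  }
  # quantile 0 retains all genes; 0.5 keeps the top two quartiles
  aggF <- aggregateShifts(run, detectionQuantile = 0.5)
  expect_lte(nrow(aggF@perGene), nrow(agg@perGene))
  cut <- quantile(agg@perGene$nCells, 0.5, type = 1)
  expect_true(all(aggF@perGene$nCells >= cut))

  # single cell: aggregate equals that cell's shifts
  one <- runDeletion(model, subsetDataset(pl$ds, 1), gene)
  aggOne <- aggregateShifts(one, detectionQuantile = 0)
  expect_equal(sort(aggOne@perGene$meanShift),
               sort(one$perCell$shift))

  # gene absent from all selected cells: empty result with a log
  absent <- runDeletion(model, subsetDataset(pl$ds, 1:5), 999999L)
  expect_equal(nrow(absent$perCell), 0)
  expect_match(absent$log, "absent")
})

test_that("group comparison is central under the null and errors on empty groups", {
  res <- new("PerturbationResult",
             perCell = data.frame(),
             perGene = data.frame(gene = 1:10,
                                  meanShift = rep(c(0.1, 0.2), 5),
                                  nCells = 5),
             comparisons = data.frame(), log = character(0))
  # two identical groups: rank-sum statistic central, p = 1
  cmp <- compareGeneGroups(res, list(g1 = 1:10, g2 = 1:10))
  expect_equal(cmp@comparisons$p, 1)
  expect_equal(cmp@comparisons$median1, cmp@comparisons$median2)
  expect_error(compareGeneGroups(res, list(g1 = 1:5, bad = 900:901)),
               "bad")
})

test_that("planted-regulator deletion: group comparison runs and models agree", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  rd <- SummarizedExperiment::rowData(pl$corpus)
  regTok <- tokenId(pl$vocab, rd$gene_id[rd$gene_class == "regulator"])
  regTok <- regTok[!is.na(regTok)][1]
  regGene <- tokenName(pl$vocab, regTok)
  targets <- tokenId(pl$vocab, strsplit(
    rd$regulator_of[rd$gene_id == regGene], ",")[[1]])
  targets <- targets[!is.na(targets)]
  hk <- tokenId(pl$vocab, rd$gene_id[rd$gene_class == "housekeeping"])
  hk <- hk[!is.na(hk)]

  run <- runDeletion(model, subsetDataset(pl$ds, 1:60), regTok)
  agg <- aggregateShifts(run, detectionQuantile = 0.5)
  cmp <- compareGeneGroups(agg, list(targets = targets,
                                     housekeeping = hk))
  tab <- cmp@comparisons
  expect_equal(nrow(tab), 1)
  expect_true(tab$p >= 0 && tab$p <= 1)
  expect_true(all(c(tab$median1, tab$median2) >= 0))
  expect_gt(tab$n1, 0); expect_gt(tab$n2, 0)

  # full-precision and nf4-quantized models agree on the same
  # perturbation: per-gene shifts positively correlated
  qm <- quantizeModel(model, "nf4dq")
  aggQ <- aggregateShifts(runDeletion(qm, subsetDataset(pl$ds, 1:60),
                                      regTok),
                          detectionQuantile = 0.5)
  mm <- merge(agg@perGene, aggQ@perGene, by = "gene")
  expect_gt(nrow(mm), 10)
  expect_gt(cor(mm$meanShift.x, mm$meanShift.y), 0.5)
})

test_that("perturbation workload counts unperturbed plus perturbed states", {
  expect_equal(perturbationWorkload(30000, 4096), 122910000)
  expect_equal(perturbationWorkload(0, 4096), 0)
  expect_equal(perturbationWorkload(1, 10), 11)
  # per-cell vector and targeted plans
  expect_equal(perturbationWorkload(3, c(5, 7, 9)), 3 + 5 + 7 + 9)
  expect_equal(perturbationWorkload(4, 100, nPerturbations = 2), 12)
})
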