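test_that("NF4 codebook matches the published reference constants", {
  cb <- nf4Codebook()
  expect_equal(cb@levels, NF4_REFERENCE, tolerance = 1e-6)
  expect_identical(cb@levels[cb@zeroIndex], 0)
  expect_identical(cb@levels[1], -1)
  expect_identical(cb@levels[16], 1)
  expect_true(all(diff(cb@levels) > 0))
})

test_that("blockwise quantization assigns nearest levels (brute force oracle)", {
  cb <- nf4Codebook()
  v <- c(1.0, -0.5, 0.25, 0.0)
  q <- quantizeBlockwise(v, cb, blockSize = 4L)
  expect_equal(q@scales, 1.0)
  # brute force over all 16 levels, ties to lower index
  brute <- vapply(v / 1.0, function(z) {
    d <- abs(cb@levels - z)
    which(d == min(d))[1] - 1L
  }, integer(1))
  expect_equal(q@codes, brute)
  # 0 and +/- scale map exactly
  deq <- dequantizeBlockwise(q, cb)
  expect_equal(deq[c(1, 4)], c(1.0, 0.0))

  set.seed(3)
  z <- rnorm(500)
  qz <- quantizeBlockwise(z, cb, blockSize = 64L)
  scales <- rep(qz@scales, each = 64L)[seq_along(z)]
  bruteAll <- vapply(seq_along(z), function(i) {
    d <- abs(cb@levels - z[i] / scales[i])
    which(d == min(d))[1] - 1L
  }, integer(1))
  expect_equal(qz@codes, bruteAll)

  # degenerate all-zero block
  q0 <- quantizeBlockwise(rep(0, 8), cb, blockSize = 4L)
  expect_true(all(q0@codes == cb@zeroIndex - 1L))
  expect_equal(dequantizeBlockwise(q0, cb), rep(0, 8))
  expect_error(quantizeBlockwise(c(1, NA), cb), "finite")
})

test_that("round trip is idempotent, bounded, and exact on fixed points", {
  cb <- nf4Codebook()
  set.seed(11)
  for (gen in list(function(n) rnorm(n),
                   function(n) runif(n, -3, 3),
                   function(n) rt(n, df = 2))) {
    x <- gen(10000)
    q <- quantizeBlockwise(x, cb, blockSize = 64L)
    xd <- dequantizeBlockwise(q, cb)
    q2 <- quantizeBlockwise(xd, cb, blockSize = 64L)
    expect_identical(q2@codes, q@codes)
    # error bound: per element <= block scale * max adjacent gap / 2
    g <- max(diff(cb@levels))
    scales <- rep(q@scales, each = 64L)[seq_along(x)]
    expect_true(all(abs(x - xd) <= scales * g / 2 + 1e-12))
  }
  # fixed points reconstruct exactly
  fx <- 0.7 * cb@levels
  qf <- quantizeBlockwise(fx, cb, blockSize = 16L)
  expect_equal(dequantizeBlockwise(qf, cb), fx)
  # corrupted codes rejected
  qb <- quantizeBlockwise(rnorm(10), cb, blockSize = 4L)
  qb@codes[1] <- 99L
  expect_error(dequantizeBlockwise(qb, cb), "corrupted")
})

test_that("double quantization perturbs scales by at most one 8-bit step", {
  cb <- nf4Codebook()
  set.seed(4)
  x <- rnorm(8192)
  q1 <- quantizeBlockwise(x, cb, blockSize = 64L)
  q2 <- quantizeBlockwise(x, cb, blockSize = 64L, doubleQuantize = TRUE,
                          scaleBlockSize = 256L)
  s1 <- q1@scales
  s2 <- reconstructScales(q2)
  step <- max(abs(s1 - mean(s1))) / 127
  expect_true(all(abs(s1 - s2) <= step + 1e-12))
  # end-to-end element error within 2x the non-nested bound
  g <- max(diff(cb@levels))
  xd <- dequantizeBlockwise(q2, cb)
  scales <- rep(s1, each = 64L)[seq_along(x)]
  expect_true(all(abs(x - xd) <= 2 * scales * g / 2 + 1e-12))
  # without nesting, stored scales are reconstructed exactly
  expect_identical(reconstructScales(q1), q1@scales)
})

test_that("memory accounting is exact arithmetic", {
  expect_equal(memoryFootprint(64)$bitsPerParamNoDQ, 4.5)
  mf <- memoryFootprint(64, 256)
  expect_equal(round(mf$saving, 1), 0.4)
  expect_equal(mf$bitsPerParam, 4 + 8 / 64 + 32 / (64 * 256))
  # asymptote: bits/param -> 4 as blocks grow
  expect_equal(memoryFootprint(1e9)$bitsPerParamNoDQ, 4,
               tolerance = 1e-6)
})

test_that("serialized quantized tensors match the analytic footprint", {
  cb <- nf4Codebook()
  set.seed(9)
  n <- 64 * 1024
  x <- rnorm(n)
  q <- quantizeBlockwise(x, cb, blockSize = 64L, doubleQuantize = TRUE,
                         scaleBlockSize = 256L)
  f <- tempfile()
  serializeQuantizedTensor(q, f)
  bytes <- file.info(f)$size
  expected <- memoryFootprint(64, 256)$bitsPerParam * n / 8
  expect_lt(abs(bytes - expected) / expected, 0.05)
  # strictly smaller than full precision (FP32)
  ffull <- tempfile()
  con <- file(ffull, "wb"); writeBin(x, con, size = 4); close(con)
  expect_lt(bytes, file.info(ffull)$size)
  unlink(c(f, ffull))
})

test_that("model quantization preserves the forward pass within bands", {
  pl <- smallPipeline()
  spec <- encoderSpec(2, vocabSize = vocabSize(pl$vocab),
                      maxPositions = 48L)
  model <- tinyTrainedModel()
  seqs <- pl$ds@tokens[1:4]
  full <- encoderForward(model, seqs, logits = TRUE)$logits
  q4 <- quantizeModel(model, "nf4dq")
  q8 <- quantizeModel(model, "int8")
  l4 <- encoderForward(q4, seqs, logits = TRUE)$logits
  l8 <- encoderForward(q8, seqs, logits = TRUE)$logits
  err4 <- max(abs(l4 - full)); err8 <- max(abs(l8 - full))
  expect_gt(err4, err8)            # nf4 band wider than int8
  expect_lt(err8, 0.25 * diff(range(full)))
  expect_error(quantizeModel(model, "nf4dq", targets = "nomatch"),
               "matches no weights")

  # quantizing a zero-weight layer leaves the forward pass identical
  z <- model
  for (nm in grep("_(Wq|Wk|Wv|Wo|W1|W2)$", names(z@weights),
                  value = TRUE))
    z@weights[[nm]][] <- 0
  zq <- quantizeModel(z, "nf4dq")
  expect_equal(encoderForward(zq, seqs)$hidden,
               encoderForward(z, seqs)$hidden)
})

test_that("LoRA adapters attach with zero-init equivalence and 2Nr parameters", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  seqs <- pl$ds@tokens[1:3]
  base <- encoderForward(model, seqs)$hidden
  lm <- attachLoRA(model, rank = 8L, alpha = 16, seed = 2L)
  expect_identical(encoderForward(lm, seqs)$hidden, base)
  # trainable adapter parameters: sum of 2 N r over targets
  d <- model@spec@hidden
  expect_equal(adapterParameterCount(lm),
               3 * model@spec@layers * 2 * d * 8)
  expect_error(attachLoRA(model, rank = d), "rank")
})

test_that("quantization fidelity: identity models give similarity 1 and order holds", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  sub <- subsetDataset(pl$ds, 1:20)
  fidI <- quantizationFidelity(model, model, sub, nCells = 10L,
                               nPairs = 40L, seed = 1L)
  expect_true(all(abs(fidI$arms$full_vs_quant - 1) < 1e-12))

  fid <- quantizationFidelity(model, quantizeModel(model, "nf4dq"),
                              sub, nCells = 15L, nPairs = 60L,
                              seed = 2L)
  expect_gt(fid$medians["full_vs_quant"],
            fid$medians["same_gene_other_cell_type"])
  expect_gt(fid$medians["full_vs_quant"],
            fid$medians["different_gene_same_cell"])
  # symmetric in model order
  fidR <- quantizationFidelity(quantizeModel(model, "nf4dq"), model,
                               sub, nCells = 15L, nPairs = 60L,
                               seed = 2L)
  expect_equal(sort(fid$arms$full_vs_quant),
               sort(fidR$arms$full_vs_quant), tolerance = 1e-9)
})

test_that("QLoRA fine-tuning freezes the base: only adapters and head change", {
  pl <- smallPipeline()
  model <- tinyTrainedModel()
  qm <- attachLoRA(quantizeModel(model, "nf4dq"), rank = 4L,
                   alpha = 8, seed = 3L)
  labels <- pl$ds@cellMeta$cell_type
  hashBefore <- weightHash(qm)
  ft <- finetuneClassifier(qm, pl$ds, labels, head = "cell",
                           mode = "few_shot", budget = 12L,
                           epochs = 1, batchSize = 4L, seed = 5L)
  expect_identical(weightHash(ft$model), hashBefore)
  changed <- vapply(names(qm@adapters), function(nm)
    !identical(qm@adapters[[nm]]@B, ft$model@adapters[[nm]]@B),
    logical(1))
  expect_true(any(changed))
})
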