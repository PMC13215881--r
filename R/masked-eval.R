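#' Build the rank-frequency baseline table
#'
#' For every rank position of the rank value encodings (rank 1 is the
#' first gene after CLS; CLS/EOS are excluded from rank indexing), finds
#' the gene token most commonly observed at that position across the
#' reference corpus, breaking frequency ties by ascending token id. The
#' fallback for ranks deeper than any reference encoding is the globally
#' most frequent gene. The reference should be the corpus slice seen in
#' pretraining, never the evaluation set; the table records a provenance
#' hash so evaluation helpers can refuse the reference set itself.
#'
#' @param reference A \linkS4class{TokenizedDataset}.
#' @return A \linkS4class{BaselineRankTable}.
#' @export
buildRankBaseline <- function(reference) {
  seqs <- reference@tokens
  if (!length(seqs)) .stopf("reference corpus is empty")
  genes <- lapply(seqs, function(x) x[-c(1L, length(x))])
  maxRank <- max(lengths(genes))
  rk <- unlist(lapply(genes, seq_along), use.names = FALSE)
  tok <- unlist(genes, use.names = FALSE)
  modal <- vapply(split(tok, rk), function(v) {
    tb <- table(v)
    best <- tb[tb == max(tb)]
    min(as.integer(names(best)))        # tie -> smaller token id
  }, integer(1))
  tabAll <- table(tok)
  bestAll <- tabAll[tabAll == max(tabAll)]
  tableVec <- rep(NA_integer_, maxRank)
  tableVec[as.integer(names(modal))] <- modal
  new("BaselineRankTable", table = tableVec,
      fallback = min(as.integer(names(bestAll))),
      refHash = contentHash(seqs))
}

setMethod("show", "BaselineRankTable", function(object) {
  cat(sprintf(
    "BaselineRankTable: %d rank positions, fallback token %d\n",
    length(object@table), object@fallback))
})

#' Baseline predictions at masked positions
#'
#' The prediction at a masked position is the table entry at that
#' position's rank; predictions depend only on rank position, never on
#' cell content. Positions beyond the deepest reference rank receive
#' the fallback token.
#'
#' @param maskedBatch Output of [applyMasking()].
#' @param table A \linkS4class{BaselineRankTable}.
#' @return List of per-cell integer vectors (NA at unmasked positions).
#' @export
baselinePredict <- function(maskedBatch, table) {
  lapply(maskedBatch$labels, function(lab) {
    p <- rep(NA_integer_, length(lab))
    sel <- which(!is.na(lab))
    if (length(sel)) {
      rk <- sel - 1L                  # rank = position minus CLS
      pred <- rep(table@fallback, length(rk))
      inTab <- rk <= length(table@table)
      pred[inTab] <- table@table[rk[inTab]]
      pred[is.na(pred)] <- table@fallback
      p[sel] <- pred
    }
    p
  })
}

#' Percent of correct masked-gene predictions per cell
#'
#' Per scored cell, 100 times the fraction of masked positions whose
#' predicted token exactly matches the label. Cells with zero masked
#' positions are excluded and counted in the `excluded` attribute.
#'
#' @param predictions,labels Aligned lists of per-cell integer vectors
#'   (NA at unmasked positions).
#' @return Numeric vector of per-cell percentages with attribute
#'   `excluded`.
#' @export
percentCorrectPerCell <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    .stopf("predictions and labels differ in cell count")
  out <- numeric(0)
  excluded <- 0L
  for (s in seq_along(labels)) {
    lab <- labels[[s]]
    prd <- predictions[[s]]
    if (length(lab) != length(prd))
      .stopf("length mismatch in cell %d", s)
    m <- which(!is.na(lab))
    if (!length(m)) {
      excluded <- excluded + 1L
      next
    }
    out <- c(out, 100 * mean(prd[m] == lab[m]))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Compare a model against the rank-frequency baseline
#'
#' Draws one masked realization of the evaluation set and scores both
#' the model (argmax over the full vocabulary) and the baseline on the
#' identical masked positions (a paired comparison). Refuses to run if
#' the evaluation set is the baseline's own reference corpus.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param table A \linkS4class{BaselineRankTable}.
#' @param dataset Evaluation \linkS4class{TokenizedDataset}.
#' @param masking A \linkS4class{MaskingConfig}.
#' @return List with per-cell percent-correct vectors `model` and
#'   `baseline`.
#' @export
compareModelToBaseline <- function(model, table, dataset,
                                   masking = maskingConfig()) {
  if (identical(contentHash(dataset@tokens), table@refHash))
    .stopf("evaluation set is the baseline reference corpus itself")
  mb <- applyMasking(dataset@tokens, masking,
                     vocabSize = model@spec@vocabSize)
  predM <- maskedPredictions(model, mb)
  predB <- baselinePredict(mb, table)
  list(model = percentCorrectPerCell(predM, mb$labels),
       baseline = percentCorrectPerCell(predB, mb$labels))
}

#' Fit a power law to loss against parameters or compute
#'
#' Nonlinear least squares on `loss(N) = a * N^(-alpha) + c` via
#' Levenberg-Marquardt, initialized from the log-log slope (`alpha`),
#' `c = 0.9 * min(loss)` and the implied prefactor; a simple log-log
#' linear fit with the offset fixed at 0 is reported for comparison.
#' Deterministic given the initialization rule. A non-monotone series
#' is fitted but flagged.
#'
#' @param x Positive abscissae (parameter counts or FLOPs), length >= 3.
#' @param loss Loss values.
#' @return A \linkS4class{ScalingFitResult}.
#' @examples
#' x <- c(1e6, 3e6, 1e7, 3e7, 1e8)
#' fitPowerLaw(x, 2 * x^(-0.5) + 1)
#' @export
fitPowerLaw <- function(x, loss) {
  if (length(x) < 3) .stopf("need at least 3 points")
  if (any(x <= 0)) .stopf("abscissae must be positive")
  nonMonotone <- any(diff(loss[order(x)]) > 0)
  if (nonMonotone)
    warning("loss series is not monotone decreasing; fit flagged")
  df <- data.frame(x = x, loss = loss)
  # deterministic multi-start: offset candidates anchored at
  # 0.9 * min(loss), slope/intercept from the log-log fit of the
  # offset-corrected series; keep the lowest-SSE converged fit
  fit <- NULL
  for (cFrac in c(0.9, 0.99, 0.5, 0)) {
    cInit <- cFrac * min(loss)
    y <- pmax(loss - cInit, .Machine$double.eps)
    ll <- stats::lm(log(y) ~ log(x))
    aInit <- max(unname(-coef(ll)[2]), 1e-6)
    prefInit <- unname(exp(coef(ll)[1]))
    cand <- tryCatch(
      minpack.lm::nlsLM(loss ~ a * x^(-alpha) + c, data = df,
                        start = list(a = prefInit, alpha = aInit,
                                     c = cInit),
                        lower = c(0, 0, 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) ||
         sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2)))
      fit <- cand
  }
  llPlain <- stats::lm(log(pmax(loss, .Machine$double.eps)) ~ log(x))
  loglogAlpha <- unname(-coef(llPlain)[2])
  if (is.null(fit)) {
    return(new("ScalingFitResult", alpha = max(loglogAlpha, 0),
               prefactor = unname(exp(coef(llPlain)[1])), offset = 0,
               residuals = loss - exp(predict(llPlain)),
               loglogAlpha = loglogAlpha, nonMonotone = nonMonotone))
  }
  cf <- coef(fit)
  new("ScalingFitResult", alpha = unname(cf["alpha"]),
      prefactor = unname(cf["a"]), offset = unname(cf["c"]),
      residuals = as.numeric(stats::residuals(fit)),
      loglogAlpha = loglogAlpha, nonMonotone = nonMonotone)
}

setMethod("show", "ScalingFitResult", function(object) {
  cat(sprintf(
    "ScalingFitResult: loss = %.4g * N^(-%.4g) + %.4g (log-log alpha %.4g)%s\n",
    object@prefactor, object@alpha, object@offset, object@loglogAlpha,
    if (object@nonMonotone) " [non-monotone series]" else ""))
})
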