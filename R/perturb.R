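#' In silico deletion of a gene from one cell's encoding
#'
#' The perturbed encoding is the original with the gene's token removed
#' and subsequent tokens shifted up one rank (CLS and EOS preserved) —
#' an edit distance of exactly one token. Both encodings are forwarded
#' (dropout disabled) and, for each remaining gene, the shift is
#' `1 - cosine(original embedding, perturbed embedding)`, matched by
#' gene identity, not position. Larger shift = more affected.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param encoding Integer vector of 0-based token ids (CLS ... EOS) or
#'   a \linkS4class{RankValueEncoding}.
#' @param gene Gene token id (0-based) to delete.
#' @param layer Embedding layer tag (default second-to-last).
#' @return data.frame(gene, shift) over the remaining genes.
#' @export
inSilicoDelete <- function(model, encoding, gene,
                           layer = "second_to_last") {
  if (is(encoding, "RankValueEncoding")) encoding <- encoding@ids
  gene <- as.integer(gene)
  if (!gene %in% encoding)
    .stopf("gene token %d is not present in the encoding", gene)
  li <- .layerIndex(model@spec, layer)
  perturbed <- encoding[-match(gene, encoding)]
  fw <- encoderForward(model, list(encoding, perturbed))
  H <- fw$hidden[[li]]
  origRows <- fw$rows[[1]]; pertRows <- fw$rows[[2]]
  gOrig <- encoding[encoding >= 4L & encoding != gene]
  origPos <- origRows[which(encoding >= 4L & encoding != gene)]
  pertPos <- pertRows[which(perturbed >= 4L)]
  gPert <- perturbed[perturbed >= 4L]
  m <- match(gOrig, gPert)
  u <- .unitRows(H[origPos, , drop = FALSE])
  v <- .unitRows(H[pertPos[m], , drop = FALSE])
  data.frame(gene = gOrig, shift = 1 - rowSums(u * v))
}

#' Run an in silico deletion plan over a dataset
#'
#' Deletes `gene` from every selected cell (by default, every cell
#' whose encoding contains the gene) and collects per-(gene, cell)
#' cosine shifts. Deterministic given the checkpoint. If no selected
#' cell contains the gene the result is empty with an explanatory log,
#' never a silent zero.
#'
#' @param model An \linkS4class{EncoderModel}.
#' @param dataset A \linkS4class{TokenizedDataset}.
#' @param gene Gene token id to delete.
#' @param cells Optional integer subset of cells to consider.
#' @param layer Embedding layer tag.
#' @return List: `perCell` data.frame(cell, gene, shift), `log`.
#' @export
runDeletion <- function(model, dataset, gene, cells = NULL,
                        layer = "second_to_last") {
  gene <- as.integer(gene)
  if (is.null(cells)) cells <- seq_along(dataset@tokens)
  has <- vapply(dataset@tokens[cells], function(x) gene %in% x,
                logical(1))
  sel <- cells[has]
  if (!length(sel))
    return(list(perCell = data.frame(cell = integer(0),
                                     gene = integer(0),
                                     shift = numeric(0)),
                log = sprintf(
                  "gene token %d absent from all %d selected cells",
                  gene, length(cells))))
  perCell <- do.call(rbind, lapply(sel, function(cidx) {
    df <- inSilicoDelete(model, dataset@tokens[[cidx]], gene, layer)
    cbind(cell = cidx, df)
  }))
  list(perCell = perCell,
       log = sprintf("deleted token %d from %d/%d cells", gene,
                     length(sel), length(cells)))
}

#' Aggregate per-cell shifts into a perturbation result
#'
#' Per-gene mean shift over the cells where the gene was present,
#' restricted to genes within the configured detection quantile
#' (default the top two quartiles of detection counts, i.e. quantile
#' 0.5; 0 retains all genes).
#'
#' @param deletion Output of [runDeletion()] (or a compatible list with
#'   `perCell`).
#' @param detectionQuantile Detection-count quantile cutoff in `[0, 1)`.
#' @return A \linkS4class{PerturbationResult}.
#' @export
aggregateShifts <- function(deletion, detectionQuantile = 0.5) {
  pc <- deletion$perCell
  if (!nrow(pc)) .stopf("no cells were processed")
  agg <- do.call(rbind, lapply(split(pc, pc$gene), function(d)
    data.frame(gene = d$gene[1], meanShift = mean(d$shift),
               nCells = nrow(d))))
  rownames(agg) <- NULL
  if (detectionQuantile > 0) {
    cut <- quantile(agg$nCells, detectionQuantile, type = 1)
    kept <- agg[agg$nCells >= cut, , drop = FALSE]
    log <- c(deletion$log,
             sprintf("detection filter q=%.2f kept %d/%d genes",
                     detectionQuantile, nrow(kept), nrow(agg)))
    agg <- kept
  } else {
    log <- c(deletion$log, "detection filter disabled; all genes kept")
  }
  new("PerturbationResult", perCell = pc, perGene = agg,
      comparisons = data.frame(), log = log)
}

#' Compare perturbation impact between predefined gene groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests (exact for small samples)
#' on per-gene mean shifts between labeled gene sets, with group
#' medians — e.g. direct targets of a deleted regulator versus
#' housekeeping genes.
#'
#' @param result A \linkS4class{PerturbationResult}.
#' @param groups Named list of gene token-id vectors.
#' @return The result with `comparisons` filled: data.frame(group1,
#'   group2, median1, median2, n1, n2, statistic, p).
#' @export
compareGeneGroups <- function(result, groups) {
  agg <- result@perGene
  vals <- lapply(names(groups), function(g) {
    v <- agg$meanShift[agg$gene %in% groups[[g]]]
    if (!length(v))
      .stopf("group '%s' has no genes with aggregated shifts", g)
    v
  })
  names(vals) <- names(groups)
  if (length(vals) < 2) .stopf("need >= 2 groups")
  cmp <- NULL
  nms <- names(vals)
  for (a in seq_along(nms)) for (b in seq_along(nms)) {
    if (a >= b) next
    wt <- suppressWarnings(
      wilcox.test(vals[[a]], vals[[b]], alternative = "two.sided"))
    cmp <- rbind(cmp, data.frame(
      group1 = nms[a], group2 = nms[b],
      median1 = median(vals[[a]]), median2 = median(vals[[b]]),
      n1 = length(vals[[a]]), n2 = length(vals[[b]]),
      statistic = unname(wt$statistic), p = wt$p.value,
      stringsAsFactors = FALSE))
  }
  out <- result
  out@comparisons <- cmp
  out
}

setMethod("show", "PerturbationResult", function(object) {
  cat(sprintf(
    "PerturbationResult: %d (gene, cell) shifts, %d aggregated genes\n",
    nrow(object@perCell), nrow(object@perGene)))
  if (nrow(object@comparisons))
    for (i in seq_len(nrow(object@comparisons)))
      cat(sprintf("  %s vs %s: medians %.4g / %.4g, p = %.3g\n",
                  object@comparisons$group1[i],
                  object@comparisons$group2[i],
                  object@comparisons$median1[i],
                  object@comparisons$median2[i],
                  object@comparisons$p[i]))
})

#' Forward-pass workload of a perturbation experiment
#'
#' Genome-wide deletion processes, per cell, the unperturbed state plus
#' one perturbed state per detected gene; a targeted plan processes the
#' unperturbed state plus the applicable perturbations. For 30,000
#' cells with 4,096 detected genes each this gives
#' 30,000 x 4,097 = 122,910,000 cell states.
#'
#' @param nCells Number of cells.
#' @param genesPerCell Detected genes per cell (scalar or per-cell
#'   vector).
#' @param nPerturbations For targeted plans: perturbations applicable
#'   per cell (scalar or vector); NULL means genome-wide.
#' @return Total number of forward-pass cell states.
#' @examples
#' perturbationWorkload(30000, 4096)  # 122,910,000
#' @export
perturbationWorkload <- function(nCells, genesPerCell,
                                 nPerturbations = NULL) {
  stopifnot(nCells >= 0, all(genesPerCell >= 0))
  if (nCells == 0) return(0)
  per <- if (is.null(nPerturbations)) genesPerCell else nPerturbations
  if (length(per) == 1L) nCells * (1 + per) else sum(1 + per)
}
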