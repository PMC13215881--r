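#' @importFrom methods new is validObject slot slotNames
#' @importFrom stats median rnorm runif rbinom rnbinom rlnorm quantile
#'   wilcox.test qnorm setNames coef predict
#' @importFrom utils head write.csv read.csv
NULL

# Content checksum used for provenance (dictionary/vocabulary/weight hashes).
# serialize() at a pinned version so the digest is stable across sessions.
contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`; `NA` if either vector has zero
#'   norm.
#' @export
cosineSimilarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

# Row-normalize a matrix to unit L2 norm; zero rows left at zero.
.unitRows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Pairwise cosine similarity of rows (m x d) -> (m x m)
.cosineMatrix <- function(m) {
  u <- .unitRows(m)
  tcrossprod(u)
}

# macro F1 over the union of classes present in truth
.macroF1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

.perClassF1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1), USE.NAMES = TRUE)
}
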