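# Internal dense transformer-encoder machinery: weight initialization,
# forward pass with per-layer hidden states, hand-derived backprop, and
# AdamW with a warmup + cosine schedule. Everything operates on a flat
# named list of weight arrays so optimizer state, gradients, hashing and
# quantization can iterate over entries uniformly.
#
# Conventions:
#  - token sequences are 0-based id vectors; embedding row = id + 1
#  - batches are lists of variable-length sequences; the batch is stacked
#    into a (total tokens) x hidden matrix and attention is computed per
#    sequence, so no padding or attention masking is ever needed
#  - post-layer-norm residual blocks (BERT layout), ReLU activations

.layerParamNames <- function(l) {
  paste0("L", l, "_",
         c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "ln1_g", "ln1_b", "W1", "b1", "W2", "b2", "ln2_g", "ln2_b"))
}

# name -> dim (vector) for every trainable tensor of the masked-LM
# encoder under the documented counting convention: word + learned
# position embeddings, Q/K/V/output projections with biases, two
# feed-forward projections with biases, all layer norms, MLM head
# transform + norm + tied decoder with output bias.
.parameterShapes <- function(spec) {
  d <- spec@hidden; f <- spec@intermediate
  V <- spec@vocabSize; P <- spec@maxPositions
  shapes <- list(tok = c(V, d), pos = c(P, d), lnE_g = d, lnE_b = d)
  for (l in seq_len(spec@layers)) {
    nm <- .layerParamNames(l)
    dims <- list(c(d, d), d, c(d, d), d, c(d, d), d, c(d, d), d,
                 d, d, c(d, f), f, c(f, d), d, d, d)
    names(dims) <- nm
    shapes <- c(shapes, dims)
  }
  c(shapes, list(Wt = c(d, d), bt = d, lnH_g = d, lnH_b = d, outb = V))
}

.initWeights <- function(spec, seed = 1L) {
  shapes <- .parameterShapes(spec)
  withr::with_seed(seed, {
    w <- lapply(names(shapes), function(nm) {
      dm <- shapes[[nm]]
      if (length(dm) == 2) {
        if (grepl("^(tok|pos)$|W", nm))
          matrix(rnorm(prod(dm), sd = spec@initStd), dm[1], dm[2])
        else matrix(0, dm[1], dm[2])
      } else if (grepl("_g$", nm)) rep(1, dm) else rep(0, dm)
    })
    names(w) <- names(shapes)
    w
  })
}

.lnForward <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * istd
  list(y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, istd = istd)
}

.lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$istd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.softmaxRows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

.dropMask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  (matrix(runif(nr * nc), nr, nc) >= p) / (1 - p)
}

.applyMask <- function(x, m) if (is.null(m)) x else x * m

# returns per-sequence row index ranges in the stacked matrix
.seqRows <- function(seqs) {
  len <- lengths(seqs)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  lapply(seq_along(seqs), function(s) starts[s]:ends[s])
}

.adapterFwd <- function(X, adapters, nm, alphaOverR = NULL) {
  ad <- adapters[[nm]]
  U <- X %*% ad@A
  list(out = (ad@alpha / ad@rank) * (U %*% ad@B), U = U)
}

# Forward pass. Returns hidden states for all layers+1 states (state 1 =
# embedding output, state l+1 = output of layer l) and, when cache=TRUE,
# everything backprop needs. Dropout draws come from the caller's RNG
# scope and fire only when training=TRUE.
.encForward <- function(w, spec, seqs, training = FALSE,
                        adapters = list(), cache = FALSE) {
  L <- spec@layers; d <- spec@hidden; h <- spec@heads; dh <- d %/% h
  pdrop <- if (training) spec@dropout else 0
  adrop <- if (training) spec@attnDropout else 0
  len <- lengths(seqs)
  if (any(len > spec@maxPositions))
    .stopf("sequence length %d exceeds max positions %d",
           max(len), spec@maxPositions)
  ids <- unlist(seqs, use.names = FALSE) + 1L
  posIdx <- unlist(lapply(len, seq_len), use.names = FALSE)
  rows <- .seqRows(seqs)
  Tt <- length(ids)

  X0 <- w$tok[ids, , drop = FALSE] + w$pos[posIdx, , drop = FALSE]
  lnE <- .lnForward(X0, w$lnE_g, w$lnE_b, spec@lnEps)
  mE <- .dropMask(Tt, d, pdrop)
  X <- .applyMask(lnE$y, mE)

  hidden <- vector("list", L + 1L)
  hidden[[1L]] <- X
  caches <- if (cache) vector("list", L) else NULL

  for (l in seq_len(L)) {
    nm <- function(p) paste0("L", l, "_", p)
    Wq <- w[[nm("Wq")]]; Wk <- w[[nm("Wk")]]; Wv <- w[[nm("Wv")]]
    Q <- sweep(X %*% Wq, 2, w[[nm("bq")]], "+")
    K <- sweep(X %*% Wk, 2, w[[nm("bk")]], "+")
    V <- sweep(X %*% Wv, 2, w[[nm("bv")]], "+")
    adU <- list()
    for (tgt in c("Wq", "Wk", "Wv")) {
      anm <- nm(tgt)
      if (!is.null(adapters[[anm]])) {
        af <- .adapterFwd(X, adapters, anm)
        adU[[tgt]] <- af$U
        if (tgt == "Wq") Q <- Q + af$out
        if (tgt == "Wk") K <- K + af$out
        if (tgt == "Wv") V <- V + af$out
      }
    }
    C <- matrix(0, Tt, d)
    attnCache <- if (cache) vector("list", length(seqs)) else NULL
    for (s in seq_along(seqs)) {
      r <- rows[[s]]
      hc <- if (cache) vector("list", h) else NULL
      for (k in seq_len(h)) {
        cc <- ((k - 1L) * dh + 1L):(k * dh)
        Qh <- Q[r, cc, drop = FALSE]
        Kh <- K[r, cc, drop = FALSE]
        P <- .softmaxRows(Qh %*% t(Kh) / sqrt(dh))
        M <- .dropMask(length(r), length(r), adrop)
        Pu <- .applyMask(P, M)
        C[r, cc] <- Pu %*% V[r, cc, drop = FALSE]
        if (cache) hc[[k]] <- list(P = P, M = M)
      }
      if (cache) attnCache[[s]] <- hc
    }
    A <- sweep(C %*% w[[nm("Wo")]], 2, w[[nm("bo")]], "+")
    mA <- .dropMask(Tt, d, pdrop)
    A <- .applyMask(A, mA)
    ln1 <- .lnForward(X + A, w[[nm("ln1_g")]], w[[nm("ln1_b")]],
                      spec@lnEps)
    X1 <- ln1$y
    Upre <- sweep(X1 %*% w[[nm("W1")]], 2, w[[nm("b1")]], "+")
    U <- pmax(Upre, 0)
    Fo <- sweep(U %*% w[[nm("W2")]], 2, w[[nm("b2")]], "+")
    mF <- .dropMask(Tt, d, pdrop)
    Fo <- .applyMask(Fo, mF)
    ln2 <- .lnForward(X1 + Fo, w[[nm("ln2_g")]], w[[nm("ln2_b")]],
                      spec@lnEps)
    Xout <- ln2$y
    if (cache)
      caches[[l]] <- list(X = X, Q = Q, K = K, V = V, attn = attnCache,
                          C = C, mA = mA, ln1 = ln1, X1 = X1, U = U,
                          mF = mF, ln2 = ln2, adU = adU)
    X <- Xout
    hidden[[l + 1L]] <- X
  }
  list(hidden = hidden, rows = rows, ids = ids, posIdx = posIdx,
       cache = if (cache) list(layers = caches, lnE = lnE, mE = mE,
                               ids = ids, posIdx = posIdx, rows = rows))
}

# MLM head forward on selected rows of the final hidden state.
.mlmHead <- function(w, spec, H, mrows) {
  Hm <- H[mrows, , drop = FALSE]
  T1 <- sweep(Hm %*% w$Wt, 2, w$bt, "+")
  R <- pmax(T1, 0)
  lnH <- .lnForward(R, w$lnH_g, w$lnH_b, spec@lnEps)
  logits <- sweep(lnH$y %*% t(w$tok), 2, w$outb, "+")
  list(logits = logits, Hm = Hm, T1 = T1, lnH = lnH, Z = lnH$y)
}

# dlogits -> head grads + dH (zeros except mrows) + tied-decoder tok grad
.mlmHeadBackward <- function(w, spec, hc, dlogits, mrows, nrowsH) {
  g <- list()
  g$outb <- colSums(dlogits)
  dZ <- dlogits %*% w$tok
  gtokDec <- crossprod(dlogits, hc$Z)        # V x d
  lb <- .lnBackward(dZ, hc$lnH, w$lnH_g)
  g$lnH_g <- lb$dg; g$lnH_b <- lb$db
  dT1 <- lb$dx * (hc$T1 > 0)
  g$Wt <- crossprod(hc$Hm, dT1)
  g$bt <- colSums(dT1)
  dH <- matrix(0, nrowsH, spec@hidden)
  dH[mrows, ] <- dT1 %*% t(w$Wt)
  list(dH = dH, grads = g, gtokDec = gtokDec)
}

# Full backward through the encoder given dH at the final hidden state.
# Returns grads for every weight plus adapter grads (named list of
# list(dA, dB)).
.encBackward <- function(w, spec, cache, dH, adapters = list()) {
  L <- spec@layers; d <- spec@hidden; h <- spec@heads; dh <- d %/% h
  rows <- cache$rows
  g <- list()
  adG <- list()
  dX <- dH
  for (l in rev(seq_len(L))) {
    nm <- function(p) paste0("L", l, "_", p)
    cc0 <- cache$layers[[l]]
    lb2 <- .lnBackward(dX, cc0$ln2, w[[nm("ln2_g")]])
    g[[nm("ln2_g")]] <- lb2$dg; g[[nm("ln2_b")]] <- lb2$db
    dS2 <- lb2$dx                         # d(X1 + F)
    dF <- .applyMask(dS2, cc0$mF)
    g[[nm("W2")]] <- crossprod(cc0$U, dF)
    g[[nm("b2")]] <- colSums(dF)
    dU <- (dF %*% t(w[[nm("W2")]])) * (cc0$U > 0)
    g[[nm("W1")]] <- crossprod(cc0$X1, dU)
    g[[nm("b1")]] <- colSums(dU)
    dX1 <- dS2 + dU %*% t(w[[nm("W1")]])
    lb1 <- .lnBackward(dX1, cc0$ln1, w[[nm("ln1_g")]])
    g[[nm("ln1_g")]] <- lb1$dg; g[[nm("ln1_b")]] <- lb1$db
    dS1 <- lb1$dx                         # d(X + A)
    dA <- .applyMask(dS1, cc0$mA)
    g[[nm("Wo")]] <- crossprod(cc0$C, dA)
    g[[nm("bo")]] <- colSums(dA)
    dC <- dA %*% t(w[[nm("Wo")]])
    dQ <- matrix(0, nrow(dX), d)
    dK <- matrix(0, nrow(dX), d)
    dV <- matrix(0, nrow(dX), d)
    for (s in seq_along(rows)) {
      r <- rows[[s]]
      for (k in seq_len(h)) {
        cc <- ((k - 1L) * dh + 1L):(k * dh)
        ac <- cc0$attn[[s]][[k]]
        P <- ac$P
        dCh <- dC[r, cc, drop = FALSE]
        Pu <- .applyMask(P, ac$M)
        dV[r, cc] <- crossprod(Pu, dCh)
        dPu <- dCh %*% t(cc0$V[r, cc, drop = FALSE])
        dP <- .applyMask(dPu, ac$M)
        dS <- (dP - rowSums(dP * P)) * P / sqrt(dh)
        dQ[r, cc] <- dS %*% cc0$K[r, cc, drop = FALSE]
        dK[r, cc] <- crossprod(dS, cc0$Q[r, cc, drop = FALSE])
      }
    }
    X <- cc0$X
    g[[nm("Wq")]] <- crossprod(X, dQ); g[[nm("bq")]] <- colSums(dQ)
    g[[nm("Wk")]] <- crossprod(X, dK); g[[nm("bk")]] <- colSums(dK)
    g[[nm("Wv")]] <- crossprod(X, dV); g[[nm("bv")]] <- colSums(dV)
    dXattn <- dQ %*% t(w[[nm("Wq")]]) + dK %*% t(w[[nm("Wk")]]) +
      dV %*% t(w[[nm("Wv")]])
    for (tgt in c("Wq", "Wk", "Wv")) {
      anm <- nm(tgt)
      ad <- adapters[[anm]]
      if (!is.null(ad)) {
        dOut <- switch(tgt, Wq = dQ, Wk = dK, Wv = dV)
        sc <- ad@alpha / ad@rank
        U <- cc0$adU[[tgt]]
        adG[[anm]] <- list(dB = sc * crossprod(U, dOut),
                           dA = sc * crossprod(X, dOut %*% t(ad@B)))
        dXattn <- dXattn + sc * (dOut %*% t(ad@B)) %*% t(ad@A)
      }
    }
    dX <- dS1 + dXattn
  }
  dX <- .applyMask(dX, cache$mE)
  lbE <- .lnBackward(dX, cache$lnE, w$lnE_g)
  g$lnE_g <- lbE$dg; g$lnE_b <- lbE$db
  dX0 <- lbE$dx
  gtok <- matrix(0, spec@vocabSize, d)
  rs <- rowsum(dX0, group = cache$ids)
  gtok[as.integer(rownames(rs)), ] <- rs
  gpos <- matrix(0, spec@maxPositions, d)
  rp <- rowsum(dX0, group = cache$posIdx)
  gpos[as.integer(rownames(rp)), ] <- rp
  g$tok <- gtok
  g$pos <- gpos
  list(grads = g, adapterGrads = adG)
}

# Masked cross-entropy loss + full gradient for one batch.
# maskedSeqs: list of masked input sequences; labels: list of same-length
# integer vectors, NA at unmasked positions, original 0-based id at
# masked positions.
.mlmLossGrad <- function(w, spec, maskedSeqs, labels, training = TRUE,
                         adapters = list(), wantGrad = TRUE) {
  fw <- .encForward(w, spec, maskedSeqs, training = training,
                    adapters = adapters, cache = wantGrad)
  H <- fw$hidden[[spec@layers + 1L]]
  labFlat <- unlist(labels, use.names = FALSE)
  mrows <- which(!is.na(labFlat))
  if (!length(mrows))
    return(list(loss = NA_real_, grads = NULL, nMasked = 0L))
  lab1 <- labFlat[mrows] + 1L
  hc <- .mlmHead(w, spec, H, mrows)
  lse <- log(rowSums(exp(hc$logits - apply(hc$logits, 1, max)))) +
    apply(hc$logits, 1, max)
  loss <- mean(lse - hc$logits[cbind(seq_along(mrows), lab1)])
  if (!wantGrad)
    return(list(loss = loss, grads = NULL, nMasked = length(mrows)))
  P <- exp(hc$logits - lse)
  P[cbind(seq_along(mrows), lab1)] <-
    P[cbind(seq_along(mrows), lab1)] - 1
  dlogits <- P / length(mrows)
  hb <- .mlmHeadBackward(w, spec, hc, dlogits, mrows, nrow(H))
  eb <- .encBackward(w, spec, fw$cache, hb$dH, adapters)
  g <- c(hb$grads, eb$grads)
  g$tok <- g$tok + hb$gtokDec
  list(loss = loss, grads = g, adapterGrads = eb$adapterGrads,
       nMasked = length(mrows))
}

# ---- AdamW -----------------------------------------------------------

.adamInit <- function() list(m = list(), v = list(), t = 0L)

# Decoupled weight decay applied to 2-D weight tensors only (never to
# biases or layer-norm parameters), the standard BERT convention.
.adamStep <- function(w, g, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, trainable = names(g)) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nmv in intersect(trainable, names(g))) {
    gi <- g[[nmv]]
    if (is.null(gi)) next
    if (is.null(st$m[[nmv]])) {
      st$m[[nmv]] <- gi * 0
      st$v[[nmv]] <- gi * 0
    }
    st$m[[nmv]] <- beta1 * st$m[[nmv]] + (1 - beta1) * gi
    st$v[[nmv]] <- beta2 * st$v[[nmv]] + (1 - beta2) * gi^2
    upd <- (st$m[[nmv]] / b1t) / (sqrt(st$v[[nmv]] / b2t) + eps)
    w[[nmv]] <- w[[nmv]] - lr * upd
    if (wd > 0 && is.matrix(w[[nmv]]))
      w[[nmv]] <- w[[nmv]] - lr * wd * w[[nmv]]
  }
  list(w = w, st = st)
}

.lrAt <- function(step, total, maxLr, warmupRatio) {
  wsteps <- max(1L, floor(warmupRatio * total))
  if (step <= wsteps) return(maxLr * step / wsteps)
  if (total <= wsteps) return(maxLr)
  prog <- (step - wsteps) / (total - wsteps)
  maxLr * 0.5 * (1 + cos(pi * prog))
}
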