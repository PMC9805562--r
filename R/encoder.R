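# A small randomly initialized transformer encoder (multi-head
# self-attention + position-wise feed-forward, post-layer-norm residual
# blocks), written as explicit forward and analytic backward passes over
# one sequence. The encoder is a pluggable contract: anything that maps an
# n x d input matrix to n x d hidden states (and exposes parameters as a
# flat named list) can stand in, including a pretrained model.

#' Encoder configuration
#'
#' @param L number of self-attention layers (>= 1).
#' @param d hidden dimension (divisible by `heads`).
#' @param heads attention-head count.
#' @param d_ff feed-forward inner dimension.
#' @param max_len maximum sequence length.
#' @param seed initialization seed.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(L = 2, d = 32, heads = 4, d_ff = 4 * d,
                           max_len = 128, seed = 1) {
  if (L < 1) stopf("encoder needs L >= 1 layers")
  if (d %% heads != 0) stopf("d=%d not divisible by heads=%d", d, heads)
  structure(list(L = as.integer(L), d = as.integer(d),
                 heads = as.integer(heads), d_ff = as.integer(d_ff),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "encoder_config")
}

encoder_init <- function(cfg) {
  params <- list()
  with_seed(cfg$seed, {
    for (l in seq_len(cfg$L)) {
      p <- function(nm) paste0("enc", l, ".", nm)
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        params[[p(nm)]] <- matrix(stats::rnorm(cfg$d * cfg$d, sd = 0.02),
                                  cfg$d, cfg$d)
      for (nm in c("bq", "bk", "bv", "bo")) params[[p(nm)]] <- numeric(cfg$d)
      params[[p("W1")]] <- matrix(stats::rnorm(cfg$d * cfg$d_ff, sd = 0.02),
                                  cfg$d, cfg$d_ff)
      params[[p("b1")]] <- numeric(cfg$d_ff)
      params[[p("W2")]] <- matrix(stats::rnorm(cfg$d_ff * cfg$d, sd = 0.02),
                                  cfg$d_ff, cfg$d)
      params[[p("b2")]] <- numeric(cfg$d)
      params[[p("ln1.g")]] <- rep(1, cfg$d); params[[p("ln1.b")]] <- numeric(cfg$d)
      params[[p("ln2.g")]] <- rep(1, cfg$d); params[[p("ln2.b")]] <- numeric(cfg$d)
    }
  })
  params
}

.addrow <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

.ln_forward <- function(R, g, b, eps = 1e-5) {
  mu <- rowMeans(R)
  xc <- R - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(Y = .addrow(sweep(xhat, 2, g, "*"), b), xhat = xhat, inv = inv)
}

.ln_backward <- function(dY, cache, g) {
  dgam <- colSums(dY * cache$xhat)
  dbet <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  dR <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dR = dR, dgam = dgam, dbet = dbet)
}

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' Run the transformer encoder over one sequence
#'
#' @param params flat named parameter list from the classifier state.
#' @param X n x d input matrix (token content + position embeddings).
#' @param cfg an [encoder_config()].
#' @param pad logical vector marking padding positions; padded keys are
#'   masked out of every attention distribution, so non-pad hidden states
#'   are unaffected by padding content.
#' @param want_cache keep intermediates for [encoder_backward()].
#' @return list with `H` (n x d final hidden states) and `cache`.
#' @export
encoder_forward <- function(params, X, cfg, pad = NULL, want_cache = FALSE) {
  n <- nrow(X)
  if (n > cfg$max_len) stopf("sequence length %d exceeds max_len %d", n,
                             cfg$max_len)
  dh <- cfg$d / cfg$heads
  caches <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    p <- function(nm) params[[paste0("enc", l, ".", nm)]]
    Q <- .addrow(X %*% p("Wq"), p("bq"))
    K <- .addrow(X %*% p("Wk"), p("bk"))
    V <- .addrow(X %*% p("Wv"), p("bv"))
    O <- matrix(0, n, cfg$d)
    Ps <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
      if (!is.null(pad) && any(pad)) S[, pad] <- -1e30
      P <- exp(S - apply(S, 1, max))
      P <- P / rowSums(P)
      Ps[[h]] <- P
      O[, idx] <- P %*% V[, idx, drop = FALSE]
    }
    AttnOut <- .addrow(O %*% p("Wo"), p("bo"))
    R1 <- X + AttnOut
    ln1 <- .ln_forward(R1, p("ln1.g"), p("ln1.b"))
    X1 <- ln1$Y
    Fpre <- .addrow(X1 %*% p("W1"), p("b1"))
    Fact <- .gelu(Fpre)
    R2 <- X1 + .addrow(Fact %*% p("W2"), p("b2"))
    ln2 <- .ln_forward(R2, p("ln2.g"), p("ln2.b"))
    if (want_cache)
      caches[[l]] <- list(X = X, Q = Q, K = K, V = V, Ps = Ps, O = O,
                          ln1 = ln1, X1 = X1, Fpre = Fpre, Fact = Fact)
    X <- ln2$Y
    if (want_cache) caches[[l]]$ln2 <- ln2
  }
  list(H = X, cache = if (want_cache) caches else NULL)
}

#' Backpropagate through the transformer encoder
#'
#' @param params flat named parameter list.
#' @param cfg an [encoder_config()].
#' @param cache cache from [encoder_forward()] with `want_cache = TRUE`.
#' @param dH gradient of the loss wrt the final hidden states.
#' @return list with `dX` (gradient wrt the input matrix) and `grads`
#'   (flat named list matching the encoder parameters).
#' @export
encoder_backward <- function(params, cfg, cache, dH) {
  dh <- cfg$d / cfg$heads
  grads <- list()
  dX_next <- dH
  for (l in rev(seq_len(cfg$L))) {
    cc <- cache[[l]]
    p <- function(nm) params[[paste0("enc", l, ".", nm)]]
    g <- function(nm) paste0("enc", l, ".", nm)
    ln2b <- .ln_backward(dX_next, cc$ln2, p("ln2.g"))
    grads[[g("ln2.g")]] <- ln2b$dgam; grads[[g("ln2.b")]] <- ln2b$dbet
    dR2 <- ln2b$dR
    # R2 = X1 + gelu(X1 W1 + b1) W2 + b2
    dFact <- dR2 %*% t(p("W2"))
    grads[[g("W2")]] <- crossprod(cc$Fact, dR2)
    grads[[g("b2")]] <- colSums(dR2)
    dFpre <- dFact * .gelu_grad(cc$Fpre)
    grads[[g("W1")]] <- crossprod(cc$X1, dFpre)
    grads[[g("b1")]] <- colSums(dFpre)
    dX1 <- dR2 + dFpre %*% t(p("W1"))
    ln1b <- .ln_backward(dX1, cc$ln1, p("ln1.g"))
    grads[[g("ln1.g")]] <- ln1b$dgam; grads[[g("ln1.b")]] <- ln1b$dbet
    dR1 <- ln1b$dR
    # R1 = X + (O Wo + bo)
    dAttn <- dR1
    dO <- dAttn %*% t(p("Wo"))
    grads[[g("Wo")]] <- crossprod(cc$O, dAttn)
    grads[[g("bo")]] <- colSums(dAttn)
    dQ <- matrix(0, nrow(dO), cfg$d)
    dK <- matrix(0, nrow(dO), cfg$d)
    dV <- matrix(0, nrow(dO), cfg$d)
    for (h in seq_len(cfg$heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      P <- cc$Ps[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dP <- tcrossprod(dOh, cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, idx] <- dS %*% cc$K[, idx, drop = FALSE] / sqrt(dh)
      dK[, idx] <- crossprod(dS, cc$Q[, idx, drop = FALSE]) / sqrt(dh)
    }
    grads[[g("Wq")]] <- crossprod(cc$X, dQ); grads[[g("bq")]] <- colSums(dQ)
    grads[[g("Wk")]] <- crossprod(cc$X, dK); grads[[g("bk")]] <- colSums(dK)
    grads[[g("Wv")]] <- crossprod(cc$X, dV); grads[[g("bv")]] <- colSums(dV)
    dX_next <- dR1 + dQ %*% t(p("Wq")) + dK %*% t(p("Wk")) + dV %*% t(p("Wv"))
  }
  list(dX = dX_next, grads = grads)
}
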