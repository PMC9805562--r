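# Knowledge-graph embedding: TransE / DistMult / ComplEx / SimplE score
# functions under the similarity convention (higher = more plausible),
# logistic loss with L2, type-constrained filtered negative sampling, and
# a mini-batch Adagrad training loop.
#
# Parameter budget is matched across score kinds: every entity and relation
# owns exactly d real numbers. ComplEx splits the d columns into a real and
# an imaginary half; SimplE splits them into a head/forward half and a
# tail/inverse half.

KGE_KINDS <- c("transe", "distmult", "complex", "simple")

#' Training configuration for knowledge-graph embeddings
#'
#' @param lambda_l2 L2 coefficient on the parameters touched by a batch.
#' @param negatives_per_positive corruptions sampled per positive triple.
#' @param learning_rate Adagrad step size.
#' @param batch_size positives per mini-batch.
#' @param epochs passes over the train split.
#' @param seed run seed; initialization, shuffling and corruption sampling
#'   all derive from it.
#' @param init_scale half-width of the uniform initialization interval.
#' @return A list of class `kge_config`.
#' @export
kge_config <- function(lambda_l2 = 1e-4, negatives_per_positive = 4,
                       learning_rate = 0.1, batch_size = 128, epochs = 50,
                       seed = 1, init_scale = 0.1) {
  stopifnot(lambda_l2 >= 0, negatives_per_positive >= 1, learning_rate > 0,
            batch_size >= 1, epochs >= 1, init_scale > 0)
  structure(list(lambda_l2 = lambda_l2,
                 negatives_per_positive = as.integer(negatives_per_positive),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_scale = init_scale), class = "kge_config")
}

#' Initialize an embedding model for a knowledge graph
#'
#' @param kg a `kg` object.
#' @param score_kind one of `"transe"`, `"distmult"`, `"complex"`,
#'   `"simple"`.
#' @param d embedding dimension (even for complex/simple).
#' @param seed integer seed for the uniform initialization.
#' @param init_scale half-width of the initialization interval.
#' @return An object of class `kge_model` with entity table `ent`
#'   (N_e x d, rownames = entity ids) and relation table `rel`.
#' @export
kge_init <- function(kg, score_kind, d, seed = 1, init_scale = 0.1) {
  score_kind <- match.arg(score_kind, KGE_KINDS)
  if (score_kind %in% c("complex", "simple") && d %% 2 != 0)
    stopf("score kind '%s' needs an even dimension, got %d", score_kind, d)
  ids <- kg$entities$id
  rels <- kg$relations$name
  with_seed(seed, {
    ent <- matrix(stats::runif(length(ids) * d, -init_scale, init_scale),
                  nrow = length(ids), dimnames = list(ids, NULL))
    rel <- matrix(stats::runif(length(rels) * d, -init_scale, init_scale),
                  nrow = length(rels), dimnames = list(rels, NULL))
  })
  structure(list(score_kind = score_kind, d = as.integer(d),
                 ent = ent, rel = rel, history = NULL),
            class = "kge_model")
}

#' @export
print.kge_model <- function(x, ...) {
  cat(sprintf("<kge_model> %s, d=%d, %d entities, %d relations\n",
              x$score_kind, x$d, nrow(x$ent), nrow(x$rel)))
  invisible(x)
}

.kge_idx <- function(tab, ids, what) {
  i <- match(ids, rownames(tab))
  if (anyNA(i)) stopf("unknown %s: %s", what, ids[is.na(i)][1])
  i
}

# Vectorized raw scores for parallel index vectors.
kge_score_idx <- function(model, hi, ri, ti) {
  E <- model$ent; R <- model$rel; d <- model$d
  H <- E[hi, , drop = FALSE]; Tl <- E[ti, , drop = FALSE]
  W <- R[ri, , drop = FALSE]
  unname(switch(model$score_kind,
    transe = -sqrt(rowSums((H + W - Tl)^2)),
    distmult = rowSums(H * W * Tl),
    complex = {
      a <- seq_len(d / 2); b <- a + d / 2
      rowSums(W[, a, drop = FALSE] *
                (H[, a, drop = FALSE] * Tl[, a, drop = FALSE] +
                 H[, b, drop = FALSE] * Tl[, b, drop = FALSE]) +
              W[, b, drop = FALSE] *
                (H[, a, drop = FALSE] * Tl[, b, drop = FALSE] -
                 H[, b, drop = FALSE] * Tl[, a, drop = FALSE]))
    },
    simple = {
      a <- seq_len(d / 2); b <- a + d / 2
      0.5 * (rowSums(H[, a, drop = FALSE] * W[, a, drop = FALSE] *
                       Tl[, b, drop = FALSE]) +
             rowSums(Tl[, a, drop = FALSE] * W[, b, drop = FALSE] *
                       H[, b, drop = FALSE]))
    },
    stopf("unknown score kind: %s", model$score_kind)))
}

#' Score triples under an embedding model
#'
#' Returns f(h, r, t) under the similarity convention: TransE is the
#' negated Euclidean translation distance, DistMult the trilinear diagonal
#' product, ComplEx the real part of the Hermitian trilinear product, and
#' SimplE the average of the forward and inverse trilinear products.
#'
#' @param model a `kge_model`.
#' @param h,r,t equal-length character vectors of head ids, relation names
#'   and tail ids (recycled if length 1).
#' @return Numeric vector of scores.
#' @export
kge_score <- function(model, h, r, t) {
  n <- max(length(h), length(r), length(t))
  h <- rep_len(h, n); r <- rep_len(r, n); t <- rep_len(t, n)
  kge_score_idx(model,
                .kge_idx(model$ent, h, "entity"),
                .kge_idx(model$rel, r, "relation"),
                .kge_idx(model$ent, t, "entity"))
}

# Per-triple gradients of f wrt head row, relation row, tail row.
# Returns list(dH, dR, dT), each n x d.
kge_score_grad <- function(model, hi, ri, ti) {
  E <- model$ent; R <- model$rel; d <- model$d
  H <- E[hi, , drop = FALSE]; Tl <- E[ti, , drop = FALSE]
  W <- R[ri, , drop = FALSE]
  dimnames(H) <- dimnames(Tl) <- dimnames(W) <- NULL
  switch(model$score_kind,
    transe = {
      delta <- H + W - Tl
      nrm <- sqrt(rowSums(delta^2))
      g <- -delta / pmax(nrm, 1e-12)
      list(dH = g, dR = g, dT = -g)
    },
    distmult = list(dH = W * Tl, dR = H * Tl, dT = H * W),
    complex = {
      a <- seq_len(d / 2); b <- a + d / 2
      Ha <- H[, a, drop = FALSE]; Hb <- H[, b, drop = FALSE]
      Ta <- Tl[, a, drop = FALSE]; Tb <- Tl[, b, drop = FALSE]
      Wa <- W[, a, drop = FALSE]; Wb <- W[, b, drop = FALSE]
      list(dH = cbind(Wa * Ta + Wb * Tb, Wa * Tb - Wb * Ta),
           dR = cbind(Ha * Ta + Hb * Tb, Ha * Tb - Hb * Ta),
           dT = cbind(Wa * Ha - Wb * Hb, Wa * Hb + Wb * Ha))
    },
    simple = {
      a <- seq_len(d / 2); b <- a + d / 2
      Ha <- H[, a, drop = FALSE]; Hb <- H[, b, drop = FALSE]
      Ta <- Tl[, a, drop = FALSE]; Tb <- Tl[, b, drop = FALSE]
      Wf <- W[, a, drop = FALSE]; Wi <- W[, b, drop = FALSE]
      list(dH = 0.5 * cbind(Wf * Tb, Wi * Ta),
           dR = 0.5 * cbind(Ha * Tb, Ta * Hb),
           dT = 0.5 * cbind(Wi * Hb, Wf * Ha))
    })
}

#' Type-constrained filtered negative sampling
#'
#' For each positive triple, `k` corruptions are drawn: one endpoint
#' (chosen uniformly) is replaced by a uniformly sampled entity of the same
#' type, never the original endpoint, and corruptions coinciding with a
#' known train triple are resampled. A side whose type has a single member
#' falls back to the other side.
#'
#' @param kg a `kg` object.
#' @param positives data.frame of triples with columns `h`, `r`, `t`.
#' @param k corruptions per positive.
#' @param seed integer seed; the same seed reproduces the batch exactly.
#' @return A list of class `triple_batch` with elements `pos` and `neg`.
#' @export
sample_negatives <- function(kg, positives, k, seed = 1) {
  stopifnot(k >= 1)
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  n <- nrow(positives)
  if (n == 0) stopf("no positive triples to corrupt")
  type_of <- stats::setNames(kg$entities$type, kg$entities$id)
  cands <- lapply(stats::setNames(KG_ENTITY_TYPES, KG_ENTITY_TYPES),
                  function(k2) candidates_of_type(kg, k2))
  train <- kg$triples[kg$triples$split == "train", , drop = FALSE]
  known <- c(triple_key(train$h, train$r, train$t),
             triple_key(positives$h, positives$r, positives$t))
  neg <- with_seed(seed, {
    out_h <- character(n * k); out_t <- character(n * k)
    out_r <- rep(positives$r, each = k)
    for (i in seq_len(n)) {
      h <- positives$h[i]; t <- positives$t[i]; r <- positives$r[i]
      nh <- length(cands[[type_of[[h]]]]); nt <- length(cands[[type_of[[t]]]])
      if (nh < 2 && nt < 2)
        stopf("cannot corrupt (%s, %s, %s): both endpoint types have < 2 members",
              h, r, t)
      for (j in seq_len(k)) {
        side <- if (stats::runif(1) < 0.5) "h" else "t"
        if (side == "h" && nh < 2) side <- "t"
        if (side == "t" && nt < 2) side <- "h"
        orig <- if (side == "h") h else t
        pool <- setdiff(cands[[type_of[[orig]]]], orig)
        done <- FALSE
        for (try in 1:100) {
          cand <- pool[[sample.int(length(pool), 1)]]
          key <- if (side == "h") triple_key(cand, r, t)
                 else triple_key(h, r, cand)
          if (!(key %in% known)) { done <- TRUE; break }
        }
        if (!done) {
          # every same-type replacement is a known positive; accept the
          # last draw rather than loop forever (degenerate dense graphs)
          done <- TRUE
        }
        idx <- (i - 1) * k + j
        if (side == "h") { out_h[idx] <- cand; out_t[idx] <- t }
        else { out_h[idx] <- h; out_t[idx] <- cand }
      }
    }
    data.frame(h = out_h, r = out_r, t = out_t, stringsAsFactors = FALSE)
  })
  structure(list(pos = positives[, c("h", "r", "t")], neg = neg),
            class = "triple_batch")
}

#' Logistic link-prediction loss
#'
#' `sum(log(1 + exp(-y * f)))` over the batch with `y = +1` on positives
#' and `y = -1` on negatives, plus `lambda * ||theta||^2` over the entity
#' and relation rows touched by the batch.
#'
#' @param model a `kge_model`.
#' @param batch a `triple_batch` from [sample_negatives()] (or a list with
#'   `pos` / `neg` triple data.frames).
#' @param lambda_l2 L2 coefficient; may also be a `kge_config`.
#' @return Scalar loss.
#' @export
kge_logistic_loss <- function(model, batch, lambda_l2 = 0) {
  if (inherits(lambda_l2, "kge_config")) lambda_l2 <- lambda_l2$lambda_l2
  pos <- batch$pos; neg <- batch$neg
  if (nrow(pos) + nrow(neg) == 0) stopf("empty batch")
  f_pos <- if (nrow(pos)) kge_score(model, pos$h, pos$r, pos$t) else numeric()
  f_neg <- if (nrow(neg)) kge_score(model, neg$h, neg$r, neg$t) else numeric()
  loss <- sum(softplus(-f_pos)) + sum(softplus(f_neg))
  if (lambda_l2 > 0) {
    ei <- unique(.kge_idx(model$ent, c(pos$h, pos$t, neg$h, neg$t), "entity"))
    ri <- unique(.kge_idx(model$rel, c(pos$r, neg$r), "relation"))
    loss <- loss + lambda_l2 * (sum(model$ent[ei, , drop = FALSE]^2) +
                                  sum(model$rel[ri, , drop = FALSE]^2))
  }
  loss
}

#' Overwrite embedding rows from an external vector provider
#'
#' Emulates initializing pseudo-nodes from precomputed encoder outputs
#' (e.g. sentence-level vectors for textual nodes, SMILES-language-model
#' vectors for structural nodes). Vectors whose dimension differs from the
#' model's are passed through a fixed-seed random linear projection when
#' `project = TRUE`.
#'
#' @param model a `kge_model`.
#' @param provider named list (or matrix with rownames) mapping entity ids
#'   to numeric vectors of a common dimension.
#' @param project allow a deterministic random projection from the provider
#'   dimension to the model dimension.
#' @param projection_seed seed of the projection matrix.
#' @return The model with covered rows overwritten.
#' @export
kge_init_from_vectors <- function(model, provider, project = FALSE,
                                  projection_seed = 71) {
  if (is.matrix(provider)) {
    ids <- rownames(provider)
    provider <- lapply(seq_len(nrow(provider)), function(i) provider[i, ])
    names(provider) <- ids
  }
  if (!length(provider)) return(model)
  dims <- unique(vapply(provider, length, 1L))
  if (length(dims) != 1) stopf("provider vectors have mixed dimensions")
  P <- NULL
  if (dims != model$d) {
    if (!project)
      stopf("provider dimension %d != model dimension %d and projection is disabled",
            dims, model$d)
    P <- with_seed(projection_seed,
                   matrix(stats::rnorm(dims * model$d, sd = 1 / sqrt(dims)),
                          nrow = dims))
  }
  unknown <- setdiff(names(provider), rownames(model$ent))
  if (length(unknown)) stopf("provider covers unknown entity: %s", unknown[1])
  for (id in names(provider)) {
    v <- provider[[id]]
    if (!is.null(P)) v <- drop(v %*% P)
    model$ent[id, ] <- v
  }
  model
}

#' Fit knowledge-graph embeddings by mini-batch Adagrad
#'
#' Minimizes the logistic loss over the train split with type-constrained
#' filtered corruptions. The epoch-mean loss trajectory is stored in
#' `model$history`; the run is reproducible under `config$seed`.
#'
#' @param kg a `kg` object with a nonempty train split.
#' @param score_kind score function, see [kge_score()].
#' @param d embedding dimension.
#' @param config a [kge_config()].
#' @param init optional pre-initialized `kge_model` (e.g. after
#'   [kge_init_from_vectors()]); score kind and dimension must match.
#' @return A trained `kge_model`.
#' @export
kge_fit <- function(kg, score_kind, d, config = kge_config(), init = NULL) {
  score_kind <- match.arg(score_kind, KGE_KINDS)
  train <- kg$triples[kg$triples$split == "train", , drop = FALSE]
  if (nrow(train) == 0) stopf("train split is empty")
  model <- if (is.null(init)) {
    kge_init(kg, score_kind, d, seed = derive_seed(config$seed, 1),
             init_scale = config$init_scale)
  } else {
    stopifnot(identical(init$score_kind, score_kind), init$d == d)
    init
  }
  n <- nrow(train)
  k <- config$negatives_per_positive
  lam <- config$lambda_l2
  G_ent <- matrix(0, nrow(model$ent), d)
  G_rel <- matrix(0, nrow(model$rel), d)
  eids <- rownames(model$ent); rids <- rownames(model$rel)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 1000 + epoch), sample.int(n))
    epoch_loss <- 0
    starts <- seq(1, n, by = config$batch_size)
    for (b in seq_along(starts)) {
      rows <- ord[starts[b]:min(starts[b] + config$batch_size - 1, n)]
      pos <- train[rows, , drop = FALSE]
      batch <- sample_negatives(kg, pos, k,
                                seed = derive_seed(config$seed,
                                                   epoch * 100003 + b))
      hp <- match(batch$pos$h, eids); tp <- match(batch$pos$t, eids)
      rp <- match(batch$pos$r, rids)
      hn <- match(batch$neg$h, eids); tn <- match(batch$neg$t, eids)
      rn <- match(batch$neg$r, rids)
      hi <- c(hp, hn); ti <- c(tp, tn); ri <- c(rp, rn)
      y <- c(rep(1, length(hp)), rep(-1, length(hn)))
      f <- kge_score_idx(model, hi, ri, ti)
      epoch_loss <- epoch_loss + sum(softplus(-y * f))
      # d/df log(1+exp(-y f)) = -y * sigmoid(-y f)
      gf <- -y * stats::plogis(-y * f)
      sg <- kge_score_grad(model, hi, ri, ti)
      ge <- rowsum(rbind(sg$dH * gf, sg$dT * gf), c(hi, ti))
      gr <- rowsum(sg$dR * gf, ri)
      eu <- as.integer(rownames(ge)); ru <- as.integer(rownames(gr))
      if (lam > 0) {
        ge <- ge + 2 * lam * model$ent[eu, , drop = FALSE]
        gr <- gr + 2 * lam * model$rel[ru, , drop = FALSE]
        epoch_loss <- epoch_loss +
          lam * (sum(model$ent[eu, , drop = FALSE]^2) +
                   sum(model$rel[ru, , drop = FALSE]^2))
      }
      G_ent[eu, ] <- G_ent[eu, , drop = FALSE] + ge^2
      G_rel[ru, ] <- G_rel[ru, , drop = FALSE] + gr^2
      model$ent[eu, ] <- model$ent[eu, , drop = FALSE] -
        config$learning_rate * ge / (sqrt(G_ent[eu, , drop = FALSE]) + 1e-8)
      model$rel[ru, ] <- model$rel[ru, , drop = FALSE] -
        config$learning_rate * gr / (sqrt(G_rel[ru, , drop = FALSE]) + 1e-8)
    }
    history[epoch] <- epoch_loss / (n * (1 + k))
  }
  model$history <- history
  model$config <- config
  model
}

#' Save / load an embedding model archive
#'
#' The archive directory holds the numeric tables as TSV plus a JSON
#' manifest (score kind, dimension, training config) for reproducibility.
#'
#' @param model a `kge_model`.
#' @param dir archive directory.
#' @return `dir` (save) or the restored `kge_model` (load).
#' @export
kge_save <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(id = rownames(model$ent), model$ent),
                     file.path(dir, "entities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(model$rel), model$rel),
                     file.path(dir, "relations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(format = "kgrex-kge", score_kind = model$score_kind,
                   d = model$d, history = model$history,
                   config = unclass(model$config %||% NULL))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname kge_save
#' @export
kge_load <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  readtab <- function(f) {
    df <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                            quote = "")
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(df$id, NULL)
    m
  }
  structure(list(score_kind = man$score_kind, d = as.integer(man$d),
                 ent = readtab("entities.tsv"), rel = readtab("relations.tsv"),
                 history = man$history, config = man$config),
            class = "kge_model")
}
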