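# The marker-augmented relation classifier: input construction with
# end-of-sentence entity markers and position-ID sharing, embedding lookup
# with knowledge-graph-initialized marker slots, the small transformer
# encoder, the CLS + mention classification head, AdamW training with
# frozen lookup tables and weight averaging, and the ablation switches.

#' Ablation switches of the relation classifier
#'
#' @param share_position_ids marker tokens reuse the position ids of their
#'   in-sentence mentions (off: they continue after the SEP token's id).
#' @param freeze_embeddings keep the word and knowledge-graph lookup tables
#'   fixed during training (position embeddings and all other parameters
#'   always train).
#' @param use_cls include the CLS hidden state in the head input.
#' @param use_mentions include the two mention hidden states in the head
#'   input.
#' @param use_kg append the two KG marker tokens at all (off: the baseline
#'   model, markers never enter the encoder and the KG table is never
#'   read).
#' @return A list of class `ddie_ablation`.
#' @export
ddie_ablation <- function(share_position_ids = TRUE, freeze_embeddings = TRUE,
                          use_cls = TRUE, use_mentions = TRUE,
                          use_kg = TRUE) {
  if (!use_cls && !use_mentions)
    stopf("the classification head needs use_cls or use_mentions")
  structure(list(share_position_ids = share_position_ids,
                 freeze_embeddings = freeze_embeddings, use_cls = use_cls,
                 use_mentions = use_mentions, use_kg = use_kg),
            class = "ddie_ablation")
}

#' Training configuration of the relation classifier
#'
#' @param encoder an [encoder_config()].
#' @param d_m middle-layer dimension of the head.
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param batch_size instances per update.
#' @param epochs passes over the training instances.
#' @param seed run seed.
#' @return A list of class `ddie_config`.
#' @export
ddie_config <- function(encoder = encoder_config(), d_m = 64,
                        learning_rate = 1e-3, weight_decay = 0.01,
                        batch_size = 16, epochs = 5, seed = 1) {
  structure(list(encoder = encoder, d_m = as.integer(d_m),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "ddie_config")
}

#' Build the marker-augmented encoder input for one instance
#'
#' Layout: `[CLS] w1 ... wn [SEP] [KG1] [KG2]`, position ids sequential
#' from 0 over `[CLS] ... [SEP]`. With position sharing the two marker
#' slots carry the position ids of the DRUG1 / DRUG2 tokens; without it
#' they continue after the SEP token's id. With `use_kg = FALSE` the
#' marker slots are omitted entirely.
#'
#' @param instance one row of [build_instances()] (needs
#'   `sentence_masked`, `label`, `kg1`, `kg2`).
#' @param vocab a [build_vocab()] vocabulary.
#' @param labelset a [ddi_labelset()].
#' @param ablation a [ddie_ablation()].
#' @param max_len maximum sequence length.
#' @return A list of class `encoded_input`: `token_ids`, `position_ids`
#'   (0-based), `kg_entity_ids`, `m1_index`, `m2_index` (1-based
#'   positions of DRUG1/DRUG2), `marker_index`, `label_id`.
#' @export
build_input <- function(instance, vocab, labelset = ddi_labelset(),
                        ablation = ddie_ablation(), max_len = 128) {
  toks <- tokenize_text(instance$sentence_masked)
  if (sum(toks == "DRUG1") != 1 || sum(toks == "DRUG2") != 1)
    stopf("masked sentence must contain DRUG1 and DRUG2 exactly once (%s/%s)",
          instance$doc_id %||% "?", instance$sent_id %||% "?")
  seq_toks <- c("[CLS]", toks, "[SEP]")
  pos <- seq_along(seq_toks) - 1L
  m1 <- which(seq_toks == "DRUG1"); m2 <- which(seq_toks == "DRUG2")
  marker_index <- NULL
  kg_ids <- NULL
  if (ablation$use_kg) {
    sep_pos <- pos[length(pos)]
    mpos <- if (ablation$share_position_ids) c(pos[m1], pos[m2])
            else c(sep_pos + 1L, sep_pos + 2L)
    seq_toks <- c(seq_toks, "[KG1]", "[KG2]")
    pos <- c(pos, mpos)
    marker_index <- c(length(seq_toks) - 1L, length(seq_toks))
    kg1 <- instance$kg1 %||% NA_character_
    kg2 <- instance$kg2 %||% NA_character_
    kg_ids <- c(kg1, kg2)
  }
  if (length(seq_toks) > max_len)
    stopf("sequence of %d tokens exceeds max_len %d (doc %s, sentence %s)",
          length(seq_toks), max_len, instance$doc_id %||% "?",
          instance$sent_id %||% "?")
  label_id <- match(instance$label, labelset$labels)
  if (is.na(label_id)) stopf("unknown label: %s", instance$label)
  structure(list(token_ids = vocab_id(vocab, seq_toks),
                 tokens = seq_toks, position_ids = as.integer(pos),
                 kg_entity_ids = kg_ids, m1_index = m1, m2_index = m2,
                 marker_index = marker_index, label_id = label_id),
            class = "encoded_input")
}

#' Initialize the relation classifier
#'
#' The knowledge-graph marker table is copied from a trained embedding
#' model (rows indexed by entity id) plus a learned unknown-entity vector
#' for unlinked mentions; if the graph dimension differs from the encoder
#' dimension a fixed-seed random linear projection bridges them.
#'
#' @param vocab a [build_vocab()] vocabulary.
#' @param labelset a [ddi_labelset()].
#' @param config a [ddie_config()].
#' @param ablation a [ddie_ablation()].
#' @param kg_model optional trained [kge_fit()] model supplying the marker
#'   table.
#' @return A list of class `ddie_state` (untrained; `n_updates = 0`).
#' @export
ddie_init <- function(vocab, labelset = ddi_labelset(),
                      config = ddie_config(), ablation = ddie_ablation(),
                      kg_model = NULL) {
  enc <- config$encoder
  d <- enc$d
  params <- encoder_init(enc)
  with_seed(derive_seed(enc$seed, 17), {
    params$word_emb <- matrix(stats::rnorm(length(vocab$tokens) * d,
                                           sd = 0.02),
                              nrow = length(vocab$tokens))
    params$pos_emb <- matrix(stats::rnorm(enc$max_len * d, sd = 0.02),
                             nrow = enc$max_len)
    params$unk_kg <- stats::rnorm(d, sd = 0.02)
    c3 <- 3 * d
    params$head.W_mid <- matrix(stats::rnorm(c3 * config$d_m, sd = 0.02),
                                c3, config$d_m)
    params$head.b_mid <- numeric(config$d_m)
    params$head.W_fc <- matrix(stats::rnorm(config$d_m *
                                              length(labelset$labels),
                                            sd = 0.02),
                               config$d_m, length(labelset$labels))
    params$head.b_fc <- numeric(length(labelset$labels))
    if (!is.null(kg_model)) {
      kg_tab <- kg_model$ent
      if (ncol(kg_tab) != d) {
        P <- with_seed(derive_seed(enc$seed, 31),
                       matrix(stats::rnorm(ncol(kg_tab) * d,
                                           sd = 1 / sqrt(ncol(kg_tab))),
                              ncol(kg_tab), d))
        kg_tab <- kg_tab %*% P
      }
      params$kg_emb <- kg_tab
    } else {
      params$kg_emb <- matrix(numeric(0), 0, d)
    }
  })
  structure(list(params = params, avg_params = NULL, n_updates = 0L,
                 vocab = vocab, labelset = labelset, config = config,
                 ablation = ablation, history = NULL),
            class = "ddie_state")
}

#' @export
print.ddie_state <- function(x, ...) {
  cat(sprintf(paste0("<ddie_state> %d-layer encoder d=%d, vocab %d, ",
                     "%d classes, %d updates\n"),
              x$config$encoder$L, x$config$encoder$d, length(x$vocab$tokens),
              length(x$labelset$labels), x$n_updates))
  invisible(x)
}

# Content + position embedding lookup for one encoded input. Marker slots
# read the KG table (or the learned unknown-entity vector); everything
# else reads the word table. Returns X plus bookkeeping for backward.
ddie_embed <- function(enc_input, params) {
  n <- length(enc_input$token_ids)
  X <- params$word_emb[enc_input$token_ids, , drop = FALSE]
  kg_rows <- rep(NA_integer_, 2)
  if (!is.null(enc_input$marker_index)) {
    for (j in 1:2) {
      slot <- enc_input$marker_index[j]
      eid <- enc_input$kg_entity_ids[j]
      row <- if (!is.na(eid)) match(eid, rownames(params$kg_emb))
             else NA_integer_
      if (!is.na(row)) {
        X[slot, ] <- params$kg_emb[row, ]
        kg_rows[j] <- row
      } else {
        X[slot, ] <- params$unk_kg
      }
    }
  }
  X <- X + params$pos_emb[enc_input$position_ids + 1L, , drop = FALSE]
  list(X = X, kg_rows = kg_rows)
}

#' Class probabilities from final hidden states
#'
#' Concatenates the CLS and the two mention hidden states (ablated parts
#' replaced by zero-vectors so the head shape is stable across ablations),
#' applies the middle and output linear layers and the softmax.
#'
#' @param h_cls,h_m1,h_m2 d-vectors of final hidden states.
#' @param params flat parameter list holding `head.W_mid`, `head.b_mid`,
#'   `head.W_fc`, `head.b_fc`.
#' @param ablation a [ddie_ablation()].
#' @return A list with `probs`, `h_all`, `h_mid` (for backprop).
#' @export
ddie_classify <- function(h_cls, h_m1, h_m2, params,
                          ablation = ddie_ablation()) {
  z <- numeric(length(h_cls))
  h_all <- c(if (ablation$use_cls) h_cls else z,
             if (ablation$use_mentions) h_m1 else z,
             if (ablation$use_mentions) h_m2 else z)
  h_mid <- drop(h_all %*% params$head.W_mid) + params$head.b_mid
  h_fc <- drop(h_mid %*% params$head.W_fc) + params$head.b_fc
  list(probs = softmax_vec(h_fc), h_all = h_all, h_mid = h_mid)
}

# Forward (+ optional backward) pass for one instance. Returns loss,
# probs, and gradients as a flat list plus indexed embedding-row grads.
ddie_forward <- function(enc_input, params, cfg, ablation,
                         backward = FALSE) {
  emb <- ddie_embed(enc_input, params)
  fw <- encoder_forward(params, emb$X, cfg$encoder, want_cache = backward)
  H <- fw$H
  cls <- ddie_classify(H[1, ], H[enc_input$m1_index, ],
                       H[enc_input$m2_index, ], params, ablation)
  loss <- -log(max(cls$probs[enc_input$label_id], 1e-300))
  out <- list(loss = loss, probs = cls$probs)
  if (!backward) return(out)

  d <- cfg$encoder$d
  dlogit <- cls$probs
  dlogit[enc_input$label_id] <- dlogit[enc_input$label_id] - 1
  grads <- list()
  grads$head.W_fc <- outer(cls$h_mid, dlogit)
  grads$head.b_fc <- dlogit
  dh_mid <- drop(params$head.W_fc %*% dlogit)
  grads$head.W_mid <- outer(cls$h_all, dh_mid)
  grads$head.b_mid <- dh_mid
  dh_all <- drop(params$head.W_mid %*% dh_mid)
  dH <- matrix(0, nrow(H), d)
  if (ablation$use_cls) dH[1, ] <- dH[1, ] + dh_all[1:d]
  if (ablation$use_mentions) {
    dH[enc_input$m1_index, ] <- dH[enc_input$m1_index, ] +
      dh_all[(d + 1):(2 * d)]
    dH[enc_input$m2_index, ] <- dH[enc_input$m2_index, ] +
      dh_all[(2 * d + 1):(3 * d)]
  }
  bk <- encoder_backward(params, cfg$encoder, fw$cache, dH)
  grads <- c(grads, bk$grads)
  out$grads <- grads
  out$dX <- bk$dX
  out$kg_rows <- emb$kg_rows
  out
}

.adamw_update <- function(params, grads, opt, trainable, lr, wd, step) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^step)
    vhat <- opt$v[[nm]] / (1 - b2^step)
    decay <- if (is.matrix(params[[nm]])) wd * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + decay)
  }
  list(params = params, opt = opt)
}

#' Train the relation classifier
#'
#' Mini-batch AdamW on the cross-entropy loss. With frozen embeddings the
#' word and knowledge-graph lookup tables are bit-identical before and
#' after training; position embeddings, encoder, head and the
#' unknown-entity vector always train. After every optimizer update the
#' running arithmetic mean of all parameters is refreshed (weight
#' averaging); prediction can use either the current or the averaged
#' parameters.
#'
#' @param state a [ddie_init()] state.
#' @param instances training instances from [build_instances()].
#' @return The trained `ddie_state` with `avg_params`, `n_updates` and a
#'   per-epoch mean-loss `history`.
#' @export
ddie_train <- function(state, instances) {
  if (nrow(instances) == 0) stopf("empty training set")
  cfg <- state$config
  abl <- state$ablation
  encs <- lapply(seq_len(nrow(instances)), function(i)
    build_input(instances[i, ], state$vocab, state$labelset, abl,
                cfg$encoder$max_len))
  params <- state$params
  frozen <- if (abl$freeze_embeddings) c("word_emb", "kg_emb") else character()
  dense <- setdiff(names(params), c("word_emb", "kg_emb", "pos_emb",
                                    "unk_kg"))
  trainable <- setdiff(names(params), frozen)
  opt <- list(m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0))
  avg <- state$avg_params %||% params
  k <- state$n_updates
  n <- length(encs)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 5000 + epoch), sample.int(n))
    starts <- seq(1, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (b in seq_along(starts)) {
      rows <- ord[starts[b]:min(starts[b] + cfg$batch_size - 1, n)]
      acc <- NULL
      dW_word <- NULL; dW_pos <- NULL; dW_kg <- NULL; d_unk <- NULL
      for (i in rows) {
        res <- ddie_forward(encs[[i]], params, cfg, abl, backward = TRUE)
        epoch_loss <- epoch_loss + res$loss
        if (is.null(acc)) acc <- res$grads
        else for (nm in names(res$grads))
          acc[[nm]] <- acc[[nm]] + res$grads[[nm]]
        ei <- encs[[i]]
        # content gradients: split dX into word / kg / unk rows
        if (is.null(dW_pos))
          dW_pos <- matrix(0, nrow(params$pos_emb), cfg$encoder$d)
        pr <- rowsum(res$dX, ei$position_ids + 1L)
        pidx <- as.integer(rownames(pr))
        dW_pos[pidx, ] <- dW_pos[pidx, , drop = FALSE] + pr
        word_slots <- seq_along(ei$token_ids)
        if (!is.null(ei$marker_index))
          word_slots <- setdiff(word_slots, ei$marker_index)
        if (is.null(dW_word))
          dW_word <- matrix(0, nrow(params$word_emb), cfg$encoder$d)
        wr <- rowsum(res$dX[word_slots, , drop = FALSE],
                     ei$token_ids[word_slots])
        widx <- as.integer(rownames(wr))
        dW_word[widx, ] <- dW_word[widx, , drop = FALSE] + wr
        if (!is.null(ei$marker_index)) {
          for (j in 1:2) {
            gvec <- res$dX[ei$marker_index[j], ]
            if (!is.na(res$kg_rows[j])) {
              if (is.null(dW_kg))
                dW_kg <- matrix(0, nrow(params$kg_emb), cfg$encoder$d)
              dW_kg[res$kg_rows[j], ] <- dW_kg[res$kg_rows[j], ] + gvec
            } else {
              if (is.null(d_unk)) d_unk <- numeric(cfg$encoder$d)
              d_unk <- d_unk + gvec
            }
          }
        }
      }
      nb <- length(rows)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
      acc$pos_emb <- dW_pos / nb
      acc$word_emb <- dW_word / nb
      if (!is.null(dW_kg)) acc$kg_emb <- dW_kg / nb
      if (!is.null(d_unk)) acc$unk_kg <- d_unk / nb
      k <- k + 1L
      upd <- .adamw_update(params, acc, opt, trainable,
                           cfg$learning_rate, cfg$weight_decay, k)
      params <- upd$params; opt <- upd$opt
      for (nm in names(params))
        avg[[nm]] <- avg[[nm]] + (params[[nm]] - avg[[nm]]) / k
    }
    history[epoch] <- epoch_loss / n
  }
  state$params <- params
  state$avg_params <- avg
  state$n_updates <- k
  state$history <- c(state$history, history)
  state
}

#' Predict labels for instances
#'
#' @param state a trained `ddie_state`.
#' @param instances instance data.frame.
#' @param use_average predict with the running parameter mean (weight
#'   averaging) instead of the final parameters.
#' @return A list with `labels` (character), `label_ids` and the
#'   probability matrix `probs` (instances x classes).
#' @export
ddie_predict <- function(state, instances, use_average = TRUE) {
  params <- if (use_average && !is.null(state$avg_params)) state$avg_params
            else state$params
  cfg <- state$config
  probs <- matrix(0, nrow(instances), length(state$labelset$labels))
  colnames(probs) <- state$labelset$labels
  for (i in seq_len(nrow(instances))) {
    enc <- build_input(instances[i, ], state$vocab, state$labelset,
                       state$ablation, cfg$encoder$max_len)
    probs[i, ] <- ddie_forward(enc, params, cfg, state$ablation)$probs
  }
  ids <- max.col(probs, ties.method = "first")
  list(labels = state$labelset$labels[ids], label_ids = ids, probs = probs)
}

#' Save / load a classifier state archive
#'
#' Single-file JSON archive holding every parameter tensor (flattened with
#' its dimensions), the averaged parameters, vocabulary, label set and
#' configuration.
#'
#' @param state a `ddie_state`.
#' @param dir archive directory.
#' @return `dir` (save) or the restored state (load).
#' @export
ddie_save <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pack <- function(plist) lapply(plist, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         rn = if (is.matrix(p)) rownames(p),
         data = as.numeric(p))
  })
  obj <- list(format = "kgrex-ddie", n_updates = state$n_updates,
              params = pack(state$params),
              avg_params = if (!is.null(state$avg_params))
                pack(state$avg_params),
              vocab = state$vocab$tokens,
              labelset = list(positives = state$labelset$positives,
                              negative = state$labelset$negative),
              config = list(encoder = unclass(state$config$encoder),
                            d_m = state$config$d_m,
                            learning_rate = state$config$learning_rate,
                            weight_decay = state$config$weight_decay,
                            batch_size = state$config$batch_size,
                            epochs = state$config$epochs,
                            seed = state$config$seed),
              ablation = unclass(state$ablation),
              history = state$history)
  jsonlite::write_json(obj, file.path(dir, "state.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname ddie_save
#' @export
ddie_load <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "state.json"),
                             simplifyVector = TRUE)
  unpack <- function(plist) lapply(plist, function(p) {
    if (length(p$dim) == 2) {
      m <- matrix(p$data, p$dim[1], p$dim[2])
      if (!is.null(p$rn) && length(p$rn)) rownames(m) <- p$rn
      m
    } else as.numeric(p$data)
  })
  vocab <- structure(list(tokens = obj$vocab,
                          index = stats::setNames(seq_along(obj$vocab),
                                                  obj$vocab)),
                     class = "ddie_vocab")
  enc <- obj$config$encoder
  cfg <- ddie_config(
    encoder = encoder_config(enc$L, enc$d, enc$heads, enc$d_ff, enc$max_len,
                             enc$seed),
    d_m = obj$config$d_m, learning_rate = obj$config$learning_rate,
    weight_decay = obj$config$weight_decay,
    batch_size = obj$config$batch_size, epochs = obj$config$epochs,
    seed = obj$config$seed)
  structure(list(params = unpack(obj$params),
                 avg_params = if (!is.null(obj$avg_params))
                   unpack(obj$avg_params),
                 n_updates = as.integer(obj$n_updates), vocab = vocab,
                 labelset = ddi_labelset(obj$labelset$positives,
                                         obj$labelset$negative),
                 config = cfg,
                 ablation = do.call(ddie_ablation, obj$ablation),
                 history = obj$history),
            class = "ddie_state")
}
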