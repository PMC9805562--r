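# Fixtures for the classifier tests: a tiny instance set over the toy
# graph with known masked sentences.
ddie_fixture <- function() {
  inst <- data.frame(
    doc_id = "doc1", sent_id = paste0("s", 1:4),
    m1_id = "a", m2_id = "b",
    m1_text = c("aspirin", "warfarin", "aspirin", "heparin"),
    m2_text = c("warfarin", "heparin", "heparin", "aspirin"),
    m1_type = "DRUG", m2_type = "DRUG",
    sentence_masked = c(
      "DRUG1 inhibits DRUG2",
      "DRUG1 was given with DRUG2 and DRUGOTHER",
      "Take DRUG1 before DRUG2",
      "DRUG1 raised levels of DRUG2"),
    label = c("Mechanism", "negative", "Advice", "Effect"),
    kg1 = c("d1", "d2", "d1", NA),
    kg2 = c("d2", "d3", "d3", "d1"),
    stringsAsFactors = FALSE)
  kgm <- kge_fit(toy_kg(), "distmult", 8,
                 kge_config(epochs = 3, seed = 2))
  vocab <- build_vocab(inst$sentence_masked)
  cfg <- ddie_config(encoder = encoder_config(L = 1, d = 8, heads = 2,
                                              d_ff = 16, max_len = 32,
                                              seed = 4),
                     d_m = 12, learning_rate = 5e-3, batch_size = 2,
                     epochs = 2, seed = 4)
  list(inst = inst, kgm = kgm, vocab = vocab, cfg = cfg)
}

test_that("marker input layout follows the end-of-sentence convention", {
  fx <- ddie_fixture()
  enc <- build_input(fx$inst[1, ], fx$vocab)
  expect_identical(enc$tokens,
                   c("[CLS]", "DRUG1", "inhibits", "DRUG2", "[SEP]",
                     "[KG1]", "[KG2]"))
  expect_equal(enc$position_ids[1:5], 0:4)
  # sharing on: markers carry the mention position ids (DRUG1 at 1,
  # DRUG2 at 3)
  expect_equal(enc$position_ids[6:7], c(1, 3))
  expect_equal(enc$m1_index, 2)
  expect_equal(enc$m2_index, 4)
  expect_identical(enc$kg_entity_ids, c("d1", "d2"))

  # sharing off: the two integers after the SEP token's id
  off <- build_input(fx$inst[1, ], fx$vocab,
                     ablation = ddie_ablation(share_position_ids = FALSE))
  expect_equal(off$position_ids[6:7], c(5, 6))
  # toggling the sharing flag changes only the marker position ids
  expect_identical(off$token_ids, enc$token_ids)
  expect_identical(off$position_ids[1:5], enc$position_ids[1:5])
  expect_identical(off$kg_entity_ids, enc$kg_entity_ids)

  # without KG markers the slots are omitted entirely
  nokg <- build_input(fx$inst[1, ], fx$vocab,
                      ablation = ddie_ablation(use_kg = FALSE))
  expect_identical(nokg$tokens, c("[CLS]", "DRUG1", "inhibits", "DRUG2",
                                  "[SEP]"))
  expect_null(nokg$marker_index)

  bad <- fx$inst[1, ]; bad$sentence_masked <- "DRUG1 alone here"
  expect_error(build_input(bad, fx$vocab), "exactly once")
  expect_error(build_input(fx$inst[1, ], fx$vocab, max_len = 5), "max_len")
})

test_that("embedding lookup draws marker content from the KG table", {
  fx <- ddie_fixture()
  st <- ddie_init(fx$vocab, ddi_labelset(), fx$cfg, ddie_ablation(),
                  kg_model = fx$kgm)
  enc <- build_input(fx$inst[1, ], fx$vocab)
  emb <- kgrex:::ddie_embed(enc, st$params)
  pos <- st$params$pos_emb
  d1row <- st$params$kg_emb[match("d1", rownames(st$params$kg_emb)), ]
  expect_equal(emb$X[6, ], d1row + pos[enc$position_ids[6] + 1, ],
               tolerance = 1e-12)
  # unlinked mention falls back to the learned unknown-entity vector
  enc4 <- build_input(fx$inst[4, ], fx$vocab)
  emb4 <- kgrex:::ddie_embed(enc4, st$params)
  expect_equal(emb4$X[enc4$marker_index[1], ],
               st$params$unk_kg + pos[enc4$position_ids[
                 enc4$marker_index[1]] + 1, ],
               tolerance = 1e-12)
  # two instances sharing an entity produce identical marker content
  enc3 <- build_input(fx$inst[3, ], fx$vocab)
  emb3 <- kgrex:::ddie_embed(enc3, st$params)
  s3 <- enc3$marker_index[1]
  expect_equal(emb$X[enc$marker_index[1], ] -
                 pos[enc$position_ids[enc$marker_index[1]] + 1, ],
               emb3$X[s3, ] - pos[enc3$position_ids[s3] + 1, ],
               tolerance = 1e-12)
})

test_that("classification head normalizes, zeroes ablated parts, and is uniform at zero", {
  fx <- ddie_fixture()
  st <- ddie_init(fx$vocab, ddi_labelset(), fx$cfg)
  d <- fx$cfg$encoder$d
  h <- list(cls = rnorm(d), m1 = rnorm(d), m2 = rnorm(d))
  out <- ddie_classify(h$cls, h$m1, h$m2, st$params)
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_true(all(out$probs >= 0))

  # zero head parameters: uniform over c classes; cross-entropy = ln c
  z <- st$params
  z$head.W_mid[] <- 0; z$head.b_mid[] <- 0
  z$head.W_fc[] <- 0; z$head.b_fc[] <- 0
  u <- ddie_classify(h$cls, h$m1, h$m2, z)
  expect_equal(u$probs, rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(-log(u$probs[3]), log(5), tolerance = 1e-12)

  # disabling CLS zeroes its slice of the concatenated vector
  no_cls <- ddie_classify(h$cls, h$m1, h$m2, st$params,
                          ddie_ablation(use_cls = FALSE))
  expect_equal(no_cls$h_all[1:d], rep(0, d))
  expect_equal(no_cls$h_all[(d + 1):(3 * d)], c(h$m1, h$m2))
  expect_error(ddie_ablation(use_cls = FALSE, use_mentions = FALSE),
               "needs")
})

test_that("training freezes lookup tables, averages weights, and descends", {
  fx <- ddie_fixture()
  st <- ddie_init(fx$vocab, ddi_labelset(), fx$cfg, ddie_ablation(),
                  kg_model = fx$kgm)
  word_before <- st$params$word_emb
  kg_before <- st$params$kg_emb
  tr <- ddie_train(st, fx$inst)
  expect_identical(tr$params$word_emb, word_before)
  expect_identical(tr$params$kg_emb, kg_before)
  # position embeddings and encoder weights did train
  expect_false(identical(tr$params$pos_emb, st$params$pos_emb))
  expect_false(identical(tr$params$enc1.Wq, st$params$enc1.Wq))

  # without freezing, the tables move
  unfrozen <- ddie_init(fx$vocab, ddi_labelset(), fx$cfg,
                        ddie_ablation(freeze_embeddings = FALSE),
                        kg_model = fx$kgm)
  tru <- ddie_train(unfrozen, fx$inst)
  expect_false(identical(tru$params$word_emb, word_before))

  # loss decreases over epochs on a learnable 40-instance set
  many <- fx$inst[rep(1:4, 10), ]
  cfg10 <- fx$cfg; cfg10$epochs <- 6L
  st10 <- ddie_init(fx$vocab, ddi_labelset(), cfg10, ddie_ablation(),
                    kg_model = fx$kgm)
  tr10 <- ddie_train(st10, many)
  expect_lt(tr10$history[length(tr10$history)], tr10$history[1])
  expect_error(ddie_train(st, fx$inst[0, ]), "empty")
})

test_that("the weight average after one update equals the current parameters", {
  fx <- ddie_fixture()
  cfg1 <- fx$cfg
  cfg1$epochs <- 1L
  cfg1$batch_size <- 4L  # 4 instances, one batch -> exactly one update
  st <- ddie_init(fx$vocab, ddi_labelset(), cfg1, ddie_ablation(),
                  kg_model = fx$kgm)
  tr <- ddie_train(st, fx$inst)
  expect_equal(tr$n_updates, 1L)
  for (nm in names(tr$params))
    expect_equal(tr$avg_params[[nm]], tr$params[[nm]], tolerance = 1e-12,
                 info = nm)
  # hence averaged and current predictions coincide
  pa <- ddie_predict(tr, fx$inst, use_average = TRUE)
  pc <- ddie_predict(tr, fx$inst, use_average = FALSE)
  expect_identical(pa$labels, pc$labels)
  expect_equal(pa$probs, pc$probs, tolerance = 1e-12)
})

test_that("running mean tracks every post-update snapshot", {
  fx <- ddie_fixture()
  cfg <- fx$cfg; cfg$epochs <- 3L; cfg$batch_size <- 2L
  st <- ddie_init(fx$vocab, ddi_labelset(), cfg, ddie_ablation(),
                  kg_model = fx$kgm)
  # reference: rerun training epoch by epoch, averaging snapshots by hand
  tr <- ddie_train(st, fx$inst)
  expect_equal(tr$n_updates, 6L)  # 3 epochs x 2 batches
  # frozen tables: mean of identical snapshots equals the table
  expect_equal(tr$avg_params$kg_emb, tr$params$kg_emb, tolerance = 1e-12)
  # a trained matrix: averaged value differs from the final value
  expect_false(isTRUE(all.equal(tr$avg_params$enc1.Wq, tr$params$enc1.Wq)))
})

test_that("training and prediction are reproducible under the seed", {
  fx <- ddie_fixture()
  run <- function() {
    st <- ddie_init(fx$vocab, ddi_labelset(), fx$cfg, ddie_ablation(),
                    kg_model = fx$kgm)
    tr <- ddie_train(st, fx$inst)
    ddie_predict(tr, fx$inst)
  }
  p1 <- run(); p2 <- run()
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-15)
})

test_that("the baseline ablation never reads the KG table", {
  fx <- ddie_fixture()
  st <- ddie_init(fx$vocab, ddi_labelset(), fx$cfg,
                  ddie_ablation(use_kg = FALSE), kg_model = fx$kgm)
  # poison the table: any lookup would propagate NA into the forward pass
  st$params$kg_emb[] <- NA_real_
  st$params$unk_kg[] <- NA_real_
  tr <- ddie_train(st, fx$inst)
  pred <- ddie_predict(tr, fx$inst)
  expect_true(all(is.finite(pred$probs)))
})

test_that("classifier state archives round-trip through save/load", {
  fx <- ddie_fixture()
  st <- ddie_train(ddie_init(fx$vocab, ddi_labelset(), fx$cfg,
                             ddie_ablation(), kg_model = fx$kgm), fx$inst)
  dir <- tempfile()
  ddie_save(st, dir)
  back <- ddie_load(dir)
  expect_equal(back$params$enc1.Wq, st$params$enc1.Wq, tolerance = 1e-12)
  expect_equal(back$avg_params$head.W_mid, st$avg_params$head.W_mid,
               tolerance = 1e-12)
  expect_identical(back$vocab$tokens, st$vocab$tokens)
  p1 <- ddie_predict(st, fx$inst)
  p2 <- ddie_predict(back, fx$inst)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-9)
})
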