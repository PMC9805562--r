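test_that("score functions obey their defining identities", {
  kg <- rank_kg()
  set.seed(7)
  n <- 200
  ids <- kg$entities$id
  h <- sample(ids, n, replace = TRUE)
  t <- sample(ids, n, replace = TRUE)
  r <- sample(kg$relations$name[1:8], n, replace = TRUE)

  # DistMult is exactly symmetric under head/tail swap
  md <- kge_init(kg, "distmult", 8, seed = 1)
  expect_equal(kge_score(md, h, r, t), kge_score(md, t, r, h))

  # TransE is not, for generic vectors
  mt <- kge_init(kg, "transe", 8, seed = 1)
  expect_false(isTRUE(all.equal(kge_score(mt, h, r, t),
                                kge_score(mt, t, r, h))))

  # TransE score of all-zero vectors is 0
  mt0 <- mt
  mt0$ent[] <- 0; mt0$rel[] <- 0
  expect_equal(kge_score(mt0, "d1", "interact", "d2"), 0)

  # ComplEx with zero imaginary parts equals DistMult on the real half;
  # oracle: an independent trilinear-sum implementation
  mc <- kge_init(kg, "complex", 8, seed = 2)
  mc$ent[, 5:8] <- 0
  mc$rel[, 5:8] <- 0
  distmult_oracle <- function(E, R, h, r, t)
    vapply(seq_along(h), function(i)
      sum(E[h[i], ] * R[r[i], ] * E[t[i], ]), 1.0)
  expect_equal(kge_score(mc, h, r, t),
               distmult_oracle(mc$ent[, 1:4], mc$rel[, 1:4], h, r, t),
               tolerance = 1e-12)

  # SimplE with head = tail parts and forward = inverse vectors
  ms <- kge_init(kg, "simple", 8, seed = 3)
  ms$ent[, 5:8] <- ms$ent[, 1:4]
  ms$rel[, 5:8] <- ms$rel[, 1:4]
  expect_equal(kge_score(ms, h, r, t),
               distmult_oracle(ms$ent[, 1:4], ms$rel[, 1:4], h, r, t),
               tolerance = 1e-12)

  expect_error(kge_score(md, "nope", "interact", "d1"), "nope")
})

test_that("logistic loss matches closed forms and hand-computed L2", {
  kg <- rank_kg()
  m <- kge_init(kg, "distmult", 4, seed = 1)
  # force f = 0 for one positive: zero vectors
  m$ent[] <- 0; m$rel[] <- 0
  batch <- list(pos = data.frame(h = "d1", r = "interact", t = "d2"),
                neg = data.frame(h = character(), r = character(),
                                 t = character()))
  expect_equal(kge_logistic_loss(m, batch, 0), log(2), tolerance = 1e-12)

  # one positive at f = +10 and one negative at f = -10
  m2 <- kge_init(kg, "distmult", 4, seed = 1)
  m2$ent["d1", ] <- c(sqrt(10), 0, 0, 0)
  m2$ent["d2", ] <- c(sqrt(10), 0, 0, 0)
  m2$ent["d3", ] <- c(-sqrt(10), 0, 0, 0)
  m2$rel["interact", ] <- c(1, 0, 0, 0)
  batch2 <- list(pos = data.frame(h = "d1", r = "interact", t = "d2"),
                 neg = data.frame(h = "d1", r = "interact", t = "d3"))
  expect_equal(kge_logistic_loss(m2, batch2, 0), 2 * log(1 + exp(-10)),
               tolerance = 1e-9)

  # lambda > 0 adds exactly lambda * ||touched parameters||^2
  lam <- 0.37
  touched <- sum(m2$ent[c("d1", "d2", "d3"), ]^2) +
    sum(m2$rel["interact", ]^2)
  expect_equal(kge_logistic_loss(m2, batch2, lam),
               2 * log(1 + exp(-10)) + lam * touched, tolerance = 1e-9)
})

test_that("score gradients agree with finite differences for all kinds", {
  kg <- rank_kg()
  eps <- 1e-6
  for (kind in c("transe", "distmult", "complex", "simple")) {
    m <- kge_init(kg, kind, 8, seed = 4)
    hi <- match(c("d1", "d3"), rownames(m$ent))
    ri <- match(c("interact", "target"), rownames(m$rel))
    ti <- match(c("d2", "p1"), rownames(m$ent))
    g <- kgrex:::kge_score_grad(m, hi, ri, ti)
    for (j in c(1, 5, 8)) {
      for (case in 1:2) {
        num <- function(tab, row) {
          mp <- m; mp[[tab]][row, j] <- mp[[tab]][row, j] + eps
          mm <- m; mm[[tab]][row, j] <- mm[[tab]][row, j] - eps
          (kgrex:::kge_score_idx(mp, hi, ri, ti)[case] -
             kgrex:::kge_score_idx(mm, hi, ri, ti)[case]) / (2 * eps)
        }
        expect_equal(g$dH[case, j], num("ent", hi[case]), tolerance = 1e-5)
        expect_equal(g$dT[case, j], num("ent", ti[case]), tolerance = 1e-5)
        expect_equal(g$dR[case, j], num("rel", ri[case]), tolerance = 1e-5)
      }
    }
  }
})

test_that("negative sampling is type-constrained, filtered and seeded", {
  kg <- rank_kg()
  pos <- kg$triples[kg$triples$split == "train", c("h", "r", "t")]
  b1 <- sample_negatives(kg, pos, k = 3, seed = 11)
  b2 <- sample_negatives(kg, pos, k = 3, seed = 11)
  expect_identical(b1$neg, b2$neg)
  expect_equal(nrow(b1$neg), 3 * nrow(pos))

  type_of <- setNames(kg$entities$type, kg$entities$id)
  train_keys <- paste(pos$h, pos$r, pos$t)
  for (i in seq_len(nrow(b1$neg))) {
    p <- b1$pos[ceiling(i / 3) * 0 + (i - 1) %/% 3 + 1, ]
    nn <- b1$neg[i, ]
    # exactly one endpoint changed, type preserved, original never reused
    changed_h <- nn$h != p$h; changed_t <- nn$t != p$t
    expect_true(xor(changed_h, changed_t))
    if (changed_h) expect_equal(type_of[[nn$h]], type_of[[p$h]])
    if (changed_t) expect_equal(type_of[[nn$t]], type_of[[p$t]])
    expect_false(paste(nn$h, nn$r, nn$t) %in% train_keys)
  }

  # a single-member type forces the corruption to the other side
  kg1 <- kg_new(data.frame(id = c("d1", "d2", "d3", "c1"),
                           type = c("drug", "drug", "drug", "category"),
                           names = c("a", "b", "c", "x")),
                data.frame(h = "d1", r = "category", t = "c1"))
  pos_cat <- data.frame(h = "d1", r = "category", t = "c1")
  bc <- sample_negatives(kg1, pos_cat, k = 4, seed = 5)
  expect_true(all(bc$neg$t == "c1"))
  expect_true(all(bc$neg$h != "d1"))

  # both sides impossible -> error
  lone <- kg_new(data.frame(id = c("d1", "c1"), type = c("drug", "category"),
                            names = c("a", "b")),
                 data.frame(h = "d1", r = "category", t = "c1"))
  expect_error(sample_negatives(lone, lone$triples[, 1:3], k = 1, seed = 1),
               "cannot corrupt")
})

test_that("training descends, is seed-reproducible and leaves loss nonnegative", {
  kg <- rank_kg()
  cfg <- kge_config(epochs = 30, learning_rate = 0.1,
                    negatives_per_positive = 4, batch_size = 8, seed = 9)
  m1 <- kge_fit(kg, "distmult", 8, cfg)
  expect_lt(m1$history[length(m1$history)], m1$history[1])
  expect_true(all(m1$history >= 0))
  m2 <- kge_fit(kg, "distmult", 8, cfg)
  expect_identical(m1$ent, m2$ent)
  expect_identical(m1$rel, m2$rel)

  empty <- kg_new(kg$entities,
                  data.frame(h = "d2", r = "interact", t = "d1",
                             split = "test"))
  expect_error(kge_fit(empty, "distmult", 8, cfg), "train split")
})

test_that("vector providers overwrite rows, with optional projection", {
  kg <- rank_kg()
  m <- kge_init(kg, "distmult", 6, seed = 2)
  before <- m$ent
  prov <- list(d1 = rep(1, 6), p2 = seq(0.1, 0.6, by = 0.1))
  out <- kge_init_from_vectors(m, prov)
  expect_equal(out$ent["d1", ], rep(1, 6))
  expect_equal(out$ent["p2", ], seq(0.1, 0.6, by = 0.1))
  unchanged <- setdiff(rownames(before), names(prov))
  expect_identical(out$ent[unchanged, ], before[unchanged, ])

  expect_identical(kge_init_from_vectors(m, list())$ent, m$ent)
  expect_error(kge_init_from_vectors(m, list(d1 = rep(1, 768))),
               "projection is disabled")
  # fixed-seed projection: deterministic across calls
  p1 <- kge_init_from_vectors(m, list(d1 = rep(1, 768)), project = TRUE)
  p2 <- kge_init_from_vectors(m, list(d1 = rep(1, 768)), project = TRUE)
  expect_identical(p1$ent["d1", ], p2$ent["d1", ])
  expect_false(isTRUE(all.equal(p1$ent["d1", ], before["d1", ])))

  expect_error(kge_init_from_vectors(m, list(zz = rep(1, 6))), "zz")
})

test_that("model archives round-trip through save/load", {
  kg <- rank_kg()
  m <- kge_fit(kg, "simple", 8, kge_config(epochs = 3, seed = 5))
  dir <- tempfile()
  kge_save(m, dir)
  back <- kge_load(dir)
  expect_equal(back$ent, m$ent, tolerance = 1e-12)
  expect_equal(back$rel, m$rel, tolerance = 1e-12)
  expect_identical(back$score_kind, m$score_kind)
  expect_identical(back$d, m$d)
})
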