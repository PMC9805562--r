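# Synthetic-data generators: (a) a planted-structure heterogeneous
# knowledge graph whose triples are thresholded scores of hidden low-rank
# vectors, and (b) a templated sentence corpus whose pair labels follow a
# rule over knowledge-graph features of the mentioned drug pair.
#
# The planted vectors live in two coordinate blocks carrying two
# independent latent partitions: block A (first half) drives the
# interact / protein-type relations, block B (second half) the
# category / ATC relations. "Interact edge present" and "shared category"
# are therefore independent pair features, which the corpus label rule
# exploits.

#' Specification of a planted synthetic knowledge graph
#'
#' @param n_drug,n_protein,n_pathway,n_category,n_atc entity counts per
#'   type (>= 2 per used type).
#' @param score_kind planted score function (the generator scores pairs
#'   with it; `"distmult"` is the planted low-rank model).
#' @param d planted vector dimension (even).
#' @param threshold score threshold above which a candidate pair becomes a
#'   triple.
#' @param n_clusters latent clusters of partition A (interact communities).
#' @param center_scale norm of the cluster centers.
#' @param noise standard deviation of the per-entity noise around its
#'   center.
#' @param relation_weights named vector of planted relation weights; each
#'   relation's planted vector is its weight on its block (interact and
#'   the protein-type relations on block A, category/ATC on block B).
#'   Higher weight means denser edges. The defaults keep the secondary
#'   relations sparse so the interact relation dominates the graph, as in
#'   the real pharmaceutical KG; a corpus-oriented graph raises
#'   `category` and `atc` so every drug is annotated.
#' @param fractions named train/valid/test split fractions (sum to 1).
#' @param seed generation seed.
#' @return A list of class `synthetic_kg_spec`.
#' @export
synthetic_kg_spec <- function(n_drug = 90, n_protein = 15, n_pathway = 8,
                              n_category = 18, n_atc = 10,
                              score_kind = "distmult", d = 16,
                              threshold = 8.7, n_clusters = 16,
                              center_scale = 3.0, noise = 0.5,
                              relation_weights = c(
                                interact = 1, target = 0.75, enzyme = 0.75,
                                carrier = 0.6, transporter = 0.6,
                                pathway = 0.75, category = 0.8, atc = 0.8),
                              fractions = c(train = 0.8, valid = 0.1,
                                            test = 0.1),
                              seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, d %% 2 == 0,
            n_drug >= 2, n_protein >= 2, n_pathway >= 2, n_category >= 2,
            n_atc >= 2)
  need <- c("interact", "target", "enzyme", "carrier", "transporter",
            "pathway", "category", "atc")
  stopifnot(all(need %in% names(relation_weights)))
  structure(list(n_drug = n_drug, n_protein = n_protein,
                 n_pathway = n_pathway, n_category = n_category,
                 n_atc = n_atc, score_kind = score_kind, d = as.integer(d),
                 threshold = threshold, n_clusters = as.integer(n_clusters),
                 center_scale = center_scale, noise = noise,
                 relation_weights = relation_weights,
                 fractions = fractions, seed = as.integer(seed)),
            class = "synthetic_kg_spec")
}

.fake_smiles <- function(n) {
  alphabet <- c("C", "c", "N", "O", "S", "P", "(", ")", "=", "1", "2")
  vapply(seq_len(n), function(i) {
    len <- sample(8:14, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

#' Generate a planted heterogeneous knowledge graph
#'
#' Hidden vectors are sampled as cluster centers plus noise; every
#' admissible (head, tail) pair of each relation whose planted score
#' exceeds the threshold becomes a triple (symmetric relations emit both
#' directions). Entities get names, synonyms, fake SMILES strings and
#' descriptions so the augmentation and linking machinery is exercised;
#' the hidden ground-truth vectors and cluster assignments are returned
#' for recovery tests.
#'
#' @param spec a [synthetic_kg_spec()].
#' @return A list of class `synthetic_kg`: `kg`, `vectors` (hidden
#'   planted vectors), `clusters` (partition A), `categories` (partition
#'   B for drugs).
#' @export
generate_kg <- function(spec) {
  d <- spec$d
  # the interact/protein block takes three quarters of the dimensions,
  # the category/ATC block the rest
  ka <- as.integer(round(3 * d / 4)); kb <- d - ka
  a_cols <- seq_len(ka); b_cols <- ka + seq_len(kb)
  with_seed(spec$seed, {
    ids <- c(sprintf("D%03d", seq_len(spec$n_drug)),
             sprintf("P%03d", seq_len(spec$n_protein)),
             sprintf("SMP%02d", seq_len(spec$n_pathway)),
             sprintf("MSH%02d", seq_len(spec$n_category)),
             sprintf("ATC%02d", seq_len(spec$n_atc)))
    types <- rep(c("drug", "protein", "pathway", "category", "atc"),
                 c(spec$n_drug, spec$n_protein, spec$n_pathway,
                   spec$n_category, spec$n_atc))
    n <- length(ids)

    # cluster centers: orthonormal directions when they fit the block
    # (clean community separation), random directions otherwise
    rand_centers <- function(k, dim) {
      M <- matrix(stats::rnorm(max(k, dim) * dim), ncol = dim)
      Q <- qr.Q(qr(M))[seq_len(min(k, dim)), , drop = FALSE]
      if (k > dim)
        Q <- rbind(Q, {
          E <- matrix(stats::rnorm((k - dim) * dim), ncol = dim)
          E / sqrt(rowSums(E^2))
        })
      Q * spec$center_scale
    }
    centA <- rand_centers(spec$n_clusters, ka)
    # a handful of active category communities; the remaining category /
    # ATC vocabulary entries stay unattached (as in real thesauri)
    n_active <- min(4L, spec$n_category, spec$n_atc)
    centB <- rand_centers(n_active, kb)

    clustA <- sample.int(spec$n_clusters, n, replace = TRUE)
    catB <- sample.int(n_active, n, replace = TRUE)
    # the first n_active category/ATC nodes sit exactly on the community
    # centers; later ones are pure noise and attract no edges
    catB[types == "category"] <- seq_len(spec$n_category)
    catB[types == "atc"] <- seq_len(spec$n_atc)

    V <- matrix(stats::rnorm(n * d, sd = spec$noise), n,
                dimnames = list(ids, NULL))
    hasA <- types %in% c("drug", "protein", "pathway")
    hasB <- (types == "drug") |
      (types %in% c("category", "atc") & catB <= n_active)
    V[hasA, a_cols] <- V[hasA, a_cols] + centA[clustA[hasA], ]
    V[hasB, b_cols] <- V[hasB, b_cols] + centB[pmin(catB[hasB], n_active), ]

    schema <- kg_relation_schema()
    actual <- schema[!(schema$name %in% c("structure", "synonym",
                                          "description")), ]
    # relation planted vectors: block masks scaled by the relation weight
    rw <- spec$relation_weights
    on_a <- function(w) c(rep(w, ka), rep(0, kb))
    on_b <- function(w) c(rep(0, ka), rep(w, kb))
    relw <- list(interact = on_a(rw[["interact"]]),
                 target = on_a(rw[["target"]]),
                 enzyme = on_a(rw[["enzyme"]]),
                 carrier = on_a(rw[["carrier"]]),
                 transporter = on_a(rw[["transporter"]]),
                 pathway = on_a(rw[["pathway"]]),
                 category = on_b(rw[["category"]]),
                 atc = on_b(rw[["atc"]]))
    planted_score <- function(w, H, T2) {
      # DistMult trilinear product of hidden vectors; the planted model
      (H * matrix(w, nrow(H), d, byrow = TRUE)) %*% t(T2) -> S
      S
    }
    triples <- list()
    for (i in seq_len(nrow(actual))) {
      rn <- actual$name[i]
      dom <- .split_types(actual$domain[i]); rng <- .split_types(actual$range[i])
      hids <- ids[types %in% dom]; tids <- ids[types %in% rng]
      S <- planted_score(relw[[rn]], V[hids, , drop = FALSE],
                         V[tids, , drop = FALSE])
      hit <- which(S > spec$threshold, arr.ind = TRUE)
      if (!nrow(hit)) next
      hh <- hids[hit[, 1]]; tt <- tids[hit[, 2]]
      keep <- hh != tt
      hh <- hh[keep]; tt <- tt[keep]
      if (!length(hh)) next
      if (actual$symmetric[i]) {
        und <- hh < tt   # generate once per unordered pair, mirror below
        hh <- hh[und]; tt <- tt[und]
        if (!length(hh)) next
        triples[[rn]] <- data.frame(h = c(hh, tt), r = rn, t = c(tt, hh),
                                    stringsAsFactors = FALSE)
      } else {
        triples[[rn]] <- data.frame(h = hh, r = rn, t = tt,
                                    stringsAsFactors = FALSE)
      }
    }
    if (!length(triples))
      stopf("threshold %.3f yielded 0 triples; lower it or raise center_scale",
            spec$threshold)
    tri <- do.call(rbind, triples)
    rownames(tri) <- NULL
    tri$split <- sample(names(spec$fractions), nrow(tri), replace = TRUE,
                        prob = spec$fractions)

    syns <- paste0(tolower(ids), "-", sample(c("alpha", "beta", "gamma"),
                                             n, replace = TRUE))
    ent <- data.frame(
      id = ids, type = types,
      names = paste(ids, syns, sep = "|"),
      smiles = ifelse(types == "drug", .fake_smiles(n), NA_character_),
      description = ifelse(types == "drug",
                           sprintf("synthetic compound %s of community %d",
                                   ids, clustA), NA_character_),
      stringsAsFactors = FALSE)
    kg <- kg_new(ent, tri)
    structure(list(kg = kg, vectors = V,
                   clusters = stats::setNames(clustA, ids),
                   categories = stats::setNames(catB, ids), spec = spec),
              class = "synthetic_kg")
  })
}

#' Specification of a templated synthetic corpus
#'
#' The label rule is a data.frame over the two pair features
#' `interact` (an interact edge exists between the drugs) and
#' `shared_category` (both drugs attach to a common category node), with
#' one probability column per label of the label set; rows must cover all
#' four feature combinations and each row's probabilities sum to 1.
#'
#' @param n_sentences number of generated sentences.
#' @param p_three_mentions probability a sentence carries three mentions
#'   (otherwise two).
#' @param p_edge_pair probability the first two drugs of a sentence are
#'   sampled from an interact edge rather than at random (controls the
#'   positive rate).
#' @param label_rule rule data.frame; `NULL` for the default stochastic
#'   rule, or [label_rule_deterministic()] for the noiseless variant.
#' @param noise_flip fraction of gold labels flipped to a uniformly chosen
#'   other label.
#' @param seed generation seed.
#' @param labelset a [ddi_labelset()].
#' @return A list of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_sentences = 150, p_three_mentions = 0.4,
                                  p_edge_pair = 0.45, label_rule = NULL,
                                  noise_flip = 0, seed = 1,
                                  labelset = ddi_labelset()) {
  if (is.null(label_rule)) label_rule <- label_rule_default(labelset)
  validate_label_rule(label_rule, labelset)
  structure(list(n_sentences = as.integer(n_sentences),
                 p_three_mentions = p_three_mentions,
                 p_edge_pair = p_edge_pair, label_rule = label_rule,
                 noise_flip = noise_flip, seed = as.integer(seed),
                 labelset = labelset),
            class = "synthetic_corpus_spec")
}

#' Label rules mapping knowledge-graph pair features to label probabilities
#'
#' The default rule assigns Mechanism to interacting pairs that share a
#' category, Effect to other interacting pairs, Advice to half of the
#' non-interacting same-category pairs, and a small Int probability so
#' every positive class occurs; the deterministic variant removes all
#' stochasticity (Int then never occurs, mirroring its rarity).
#'
#' @param labelset a [ddi_labelset()].
#' @return data.frame with columns `interact`, `shared_category` and one
#'   probability column per label.
#' @export
label_rule_default <- function(labelset = ddi_labelset()) {
  r <- data.frame(interact = c(TRUE, TRUE, FALSE, FALSE),
                  shared_category = c(TRUE, FALSE, TRUE, FALSE))
  probs <- rbind(c(0.85, 0.05, 0.00, 0.10, 0.00),
                 c(0.05, 0.85, 0.00, 0.10, 0.00),
                 c(0.00, 0.00, 0.50, 0.00, 0.50),
                 c(0.00, 0.00, 0.00, 0.00, 1.00))
  colnames(probs) <- labelset$labels
  cbind(r, as.data.frame(probs))
}

#' @rdname label_rule_default
#' @export
label_rule_deterministic <- function(labelset = ddi_labelset()) {
  r <- label_rule_default(labelset)
  r[, labelset$labels] <- 0
  r[1, "Mechanism"] <- 1; r[2, "Effect"] <- 1
  r[3, "Advice"] <- 1; r[4, labelset$negative] <- 1
  r
}

validate_label_rule <- function(rule, labelset) {
  need <- c("interact", "shared_category", labelset$labels)
  miss <- setdiff(need, names(rule))
  if (length(miss))
    stopf("label rule misses column '%s' (must cover every label)", miss[1])
  combos <- paste(rule$interact, rule$shared_category)
  want <- paste(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  if (!all(want %in% combos))
    stopf("label rule must cover all four feature combinations")
  sums <- rowSums(rule[, labelset$labels, drop = FALSE])
  if (any(abs(sums - 1) > 1e-9))
    stopf("label rule rows must sum to 1")
  invisible(rule)
}

# Pair features used by the label rule.
kg_pair_features <- function(kg, e1, e2) {
  tr <- kg$triples
  it <- tr[tr$r == "interact", , drop = FALSE]
  interact <- any((it$h == e1 & it$t == e2) | (it$h == e2 & it$t == e1))
  ct <- tr[tr$r == "category", , drop = FALSE]
  shared <- length(intersect(ct$t[ct$h == e1], ct$t[ct$h == e2])) > 0
  list(interact = interact, shared_category = shared)
}

.sentence_templates <- list(
  two = c("In this study , %s was administered together with %s to healthy volunteers .",
          "Patients received %s in combination with %s during the trial .",
          "The pharmacokinetic profile of %s was measured after dosing with %s .",
          "Clinicians reviewed records of subjects taking %s and %s concurrently ."),
  three = c("In this study , %s was administered together with %s and %s to healthy volunteers .",
            "Patients received %s in combination with %s and %s during the trial .",
            "The charts mention %s , %s and %s in the same treatment course .",
            "Subjects were exposed to %s , %s and %s in randomized order ."))

#' Generate a templated corpus whose labels follow the knowledge graph
#'
#' Sentences are instantiated from neutral templates (template choice is
#' independent of the label, so the text alone carries no label signal
#' beyond the class prior); mention surfaces are drawn from the entities'
#' names and synonyms; every mention pair is annotated with a label drawn
#' from the rule applied to its knowledge-graph features.
#'
#' @param spec a [synthetic_corpus_spec()].
#' @param kg a `kg` object with at least 3 drugs.
#' @return A list with `corpus` (normalized-dialect corpus) and `linking`
#'   (a [build_linking_table()] covering every generated surface).
#' @export
generate_corpus <- function(spec, kg) {
  drugs <- kg$entities[kg$entities$type == "drug", , drop = FALSE]
  if (nrow(drugs) < 3) stopf("corpus generation needs >= 3 drugs")
  edges <- kg$triples[kg$triples$r == "interact", , drop = FALSE]
  labels <- spec$labelset$labels
  rulekey <- paste(spec$label_rule$interact, spec$label_rule$shared_category)
  with_seed(spec$seed, {
    sentences <- vector("list", spec$n_sentences)
    for (s in seq_len(spec$n_sentences)) {
      k <- if (stats::runif(1) < spec$p_three_mentions) 3L else 2L
      if (nrow(edges) > 0 && stats::runif(1) < spec$p_edge_pair) {
        e <- edges[sample.int(nrow(edges), 1), ]
        first2 <- c(e$h, e$t)
      } else {
        first2 <- sample(drugs$id, 2)
      }
      ids <- first2
      if (k == 3) ids <- c(ids, sample(setdiff(drugs$id, ids), 1))
      ids <- sample(ids)  # random order within the sentence
      surfaces <- vapply(ids, function(id) {
        nm <- entity_names(drugs$names[drugs$id == id])
        nm[[sample.int(length(nm), 1)]]
      }, "")
      tpl <- if (k == 2) sample(.sentence_templates$two, 1)
             else sample(.sentence_templates$three, 1)
      text <- do.call(sprintf, c(list(tpl), as.list(surfaces)))
      # recover exact spans from the template structure
      parts <- strsplit(tpl, "%s", fixed = TRUE)[[1]]
      starts <- integer(k); cur <- 0L
      for (j in seq_len(k)) {
        cur <- cur + nchar(parts[j])
        starts[j] <- cur
        cur <- cur + nchar(surfaces[j])
      }
      mentions <- .mention_df(sprintf("s%d.m%d", s, seq_len(k)), starts,
                              starts + nchar(surfaces), surfaces,
                              rep("DRUG", k))
      prs <- enumerate_pairs(mentions)
      plab <- character(nrow(prs))
      for (p in seq_len(nrow(prs))) {
        id1 <- ids[prs$i1[p]]; id2 <- ids[prs$i2[p]]
        feats <- kg_pair_features(kg, id1, id2)
        row <- match(paste(feats$interact, feats$shared_category), rulekey)
        pr <- as.numeric(spec$label_rule[row, labels])
        lab <- sample(labels, 1, prob = pr)
        if (spec$noise_flip > 0 && stats::runif(1) < spec$noise_flip)
          lab <- sample(setdiff(labels, lab), 1)
        plab[p] <- lab
      }
      sentences[[s]] <- list(
        id = sprintf("s%d", s), text = text, mentions = mentions,
        pairs = data.frame(e1 = mentions$id[prs$i1],
                           e2 = mentions$id[prs$i2], label = plab,
                           stringsAsFactors = FALSE))
    }
    docs <- list()
    per_doc <- 10L
    for (i in seq(1, spec$n_sentences, by = per_doc)) {
      sl <- sentences[i:min(i + per_doc - 1, spec$n_sentences)]
      docs[[length(docs) + 1]] <- list(id = sprintf("doc%d", length(docs) + 1),
                                       sentences = sl)
    }
    list(corpus = structure(docs, class = "kgrex_corpus"),
         linking = build_linking_table(kg))
  })
}

#' Rule-oracle predictions from true knowledge-graph features
#'
#' Bypasses the text entirely: predicts the argmax label of the rule row
#' matching each instance's true pair features. On a deterministic rule
#' this is the Bayes-optimal upper bound for the end-to-end classifier.
#'
#' @param kg a `kg` object.
#' @param instances instances with `kg1` / `kg2` links.
#' @param rule a label-rule data.frame.
#' @param labelset a [ddi_labelset()].
#' @return Character vector of predicted labels.
#' @export
feature_oracle_predict <- function(kg, instances,
                                   rule = label_rule_deterministic(),
                                   labelset = ddi_labelset()) {
  rulekey <- paste(rule$interact, rule$shared_category)
  vapply(seq_len(nrow(instances)), function(i) {
    e1 <- instances$kg1[i]; e2 <- instances$kg2[i]
    if (is.na(e1) || is.na(e2)) return(labelset$negative)
    feats <- kg_pair_features(kg, e1, e2)
    row <- match(paste(feats$interact, feats$shared_category), rulekey)
    labelset$labels[which.max(as.numeric(rule[row, labelset$labels]))]
  }, "")
}
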