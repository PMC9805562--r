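# Ranking-based link-prediction evaluation with same-type candidate
# replacement: per-triple rank, MRR, Hits@k, and the closed-form
# random-ranking baseline.

#' Rank a true triple against same-type corruptions
#'
#' Candidates are all entities of the same type as the replaced endpoint,
#' excluding the true endpoint. The rank is `1 + (# candidates scoring
#' strictly higher) + 0.5 * (# candidates scoring equal)`, so ties average.
#' The raw setting ranks against every created corruption; the filtered
#' setting drops candidates that form a known positive triple anywhere in
#' the graph.
#'
#' @param model a `kge_model`.
#' @param kg a `kg` object.
#' @param h,r,t the true triple.
#' @param side which endpoint to replace, `"head"` or `"tail"`.
#' @param filtered drop known-positive corruptions from the candidate set.
#' @return A list with `rank` (1 <= rank <= n_candidates + 1),
#'   `n_candidates`, `side` and the triple.
#' @export
rank_triple <- function(model, kg, h, r, t, side = c("tail", "head"),
                        filtered = FALSE) {
  side <- match.arg(side)
  true_ep <- if (side == "head") h else t
  cands <- setdiff(candidates_of_type(kg, kg_entity_type(kg, true_ep)),
                   true_ep)
  if (filtered && length(cands)) {
    tr <- kg$triples
    known <- triple_key(tr$h, tr$r, tr$t)
    keys <- if (side == "head") triple_key(cands, r, t)
            else triple_key(h, r, cands)
    cands <- cands[!(keys %in% known)]
  }
  if (!length(cands))
    stopf("no same-type candidate to corrupt the %s of (%s, %s, %s)",
          side, h, r, t)
  s_true <- kge_score(model, h, r, t)
  s_cand <- if (side == "head") kge_score(model, cands, r, t)
            else kge_score(model, h, r, cands)
  rank <- 1 + sum(s_cand > s_true) + 0.5 * sum(s_cand == s_true)
  list(h = h, r = r, t = t, side = side, rank = rank,
       n_candidates = length(cands))
}

#' Evaluate link prediction on a split
#'
#' Every triple of the split contributes one head-replacement rank and one
#' tail-replacement rank. MRR is the mean reciprocal rank; Hits@k the
#' fraction of ranks at most k.
#'
#' @param model a `kge_model`.
#' @param kg a `kg` object.
#' @param split `"valid"` or `"test"` (or `"train"`).
#' @param filtered see [rank_triple()].
#' @param ks cutoffs for Hits@k.
#' @return A list of class `lp_eval` with `mrr`, `hits` (named vector),
#'   `ranks`, `n_candidates` and `n` (number of ranks).
#' @export
lp_evaluate <- function(model, kg, split = "test", filtered = FALSE,
                        ks = c(1, 3, 10)) {
  tr <- kg$triples[kg$triples$split == split, , drop = FALSE]
  if (nrow(tr) == 0) stopf("split '%s' is empty", split)
  ranks <- numeric(2 * nrow(tr))
  ncand <- integer(2 * nrow(tr))
  for (i in seq_len(nrow(tr))) {
    for (s in c("head", "tail")) {
      rr <- rank_triple(model, kg, tr$h[i], tr$r[i], tr$t[i], side = s,
                        filtered = filtered)
      j <- 2 * (i - 1) + (s == "tail") + 1
      ranks[j] <- rr$rank
      ncand[j] <- rr$n_candidates
    }
  }
  hits <- vapply(ks, function(k) mean(ranks <= k), 1.0)
  names(hits) <- paste0("hits@", ks)
  structure(list(mrr = mean(1 / ranks), hits = hits, ranks = ranks,
                 n_candidates = ncand, n = length(ranks), split = split,
                 filtered = filtered),
            class = "lp_eval")
}

#' @export
print.lp_eval <- function(x, ...) {
  cat(sprintf("<lp_eval> split=%s%s n=%d  MRR=%.4f  %s\n", x$split,
              if (x$filtered) " (filtered)" else "", x$n, x$mrr,
              paste(sprintf("%s=%.4f", names(x$hits), x$hits),
                    collapse = "  ")))
  invisible(x)
}

#' Closed-form random-ranking MRR baseline
#'
#' Under uniformly random scores the rank of the true entity among
#' `n_candidates + 1` scored triples is uniform, so the expected reciprocal
#' rank is `H(N) / N` with `N = n_candidates + 1`. The baseline averages
#' this over both replacement sides of every triple in the split.
#'
#' @param kg a `kg` object.
#' @param split evaluated split.
#' @param filtered match the filtered evaluation protocol: known-positive
#'   corruptions are excluded from the candidate pool, so the uniform rank
#'   runs over the filtered pool size.
#' @return Scalar expected MRR of a random model.
#' @export
lp_random_baseline <- function(kg, split = "test", filtered = FALSE) {
  tr <- kg$triples[kg$triples$split == split, , drop = FALSE]
  if (nrow(tr) == 0) stopf("split '%s' is empty", split)
  counts <- table(factor(kg$entities$type, levels = KG_ENTITY_TYPES))
  known <- triple_key(kg$triples$h, kg$triples$r, kg$triples$t)
  vals <- numeric(2 * nrow(tr))
  for (i in seq_len(nrow(tr))) {
    for (s in 1:2) {
      ep <- if (s == 1) tr$h[i] else tr$t[i]
      n_cand <- as.integer(counts[[kg_entity_type(kg, ep)]]) - 1L
      if (filtered) {
        cands <- setdiff(candidates_of_type(kg, kg_entity_type(kg, ep)), ep)
        keys <- if (s == 1) triple_key(cands, tr$r[i], tr$t[i])
                else triple_key(tr$h[i], tr$r[i], cands)
        n_cand <- sum(!(keys %in% known))
      }
      N <- n_cand + 1L
      vals[2 * (i - 1) + s] <- harmonic(N) / N
    }
  }
  mean(vals)
}
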