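# Shared fixtures, built in code.

# A small hand-made graph: three drugs, one protein, one category.
toy_kg <- function() {
  ent <- data.frame(
    id = c("d1", "d2", "d3", "p1", "c1"),
    type = c("drug", "drug", "drug", "protein", "category"),
    names = c("aspirin|asa|acetylsalicylic acid", "warfarin|coumadin",
              "heparin", "CYP3A4", "anticoagulants"),
    smiles = c("CC(=O)OC", "CC(=O)OC", NA, NA, NA),
    description = c("a pain reliever", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  tri <- data.frame(
    h = c("d1", "d2", "d1", "d2", "d1"),
    r = c("interact", "interact", "target", "category", "category"),
    t = c("d2", "d1", "p1", "c1", "c1"),
    split = c("train", "test", "train", "train", "train"),
    stringsAsFactors = FALSE)
  kg_new(ent, tri)
}

# A 10-entity graph with 3 relations for ranking-oracle tests.
rank_kg <- function() {
  ent <- data.frame(
    id = c(paste0("d", 1:6), paste0("p", 1:3), "c1", "c2"),
    type = c(rep("drug", 6), rep("protein", 3), "category", "category"),
    names = c(paste0("drug-", 1:6), paste0("prot-", 1:3), "cat-1", "cat-2"),
    stringsAsFactors = FALSE)
  tri <- data.frame(
    h = c("d1", "d2", "d2", "d3", "d1", "d4", "d5", "d1"),
    r = c("interact", "interact", "interact", "interact", "target",
          "target", "enzyme", "category"),
    t = c("d2", "d1", "d3", "d2", "p1", "p2", "p3", "c1"),
    split = c("train", "test", "train", "test", "test", "train", "test",
              "test"),
    stringsAsFactors = FALSE)
  kg_new(ent, tri)
}

# The preprocessing example sentence with its three drug mentions; spans
# are recovered from the raw string, not hard-coded.
example_sentence <- function() {
  text <- paste0("Exposure to oral S-ketamine is unaffected by ",
                 "itraconazole but greatly increased by ticlopidine.")
  drugs <- c("S-ketamine", "itraconazole", "ticlopidine")
  starts <- vapply(drugs, function(x)
    as.integer(regexpr(x, text, fixed = TRUE)) - 1L, 1L)
  mentions <- data.frame(id = paste0("m", 1:3), start = starts,
                         end = starts + nchar(drugs), text = drugs,
                         type = "DRUG", stringsAsFactors = FALSE)
  list(text = text, mentions = mentions)
}

# DDIExtraction-2013-style XML for the example sentence.
example_ddi_xml <- function(path) {
  ex <- example_sentence()
  m <- ex$mentions
  ents <- paste0(sprintf(
    '<entity id="%s" charOffset="%d-%d" type="drug" text="%s"/>',
    m$id, m$start, m$end - 1L, m$text), collapse = "")
  xml <- paste0(
    '<corpus><document id="doc1"><sentence id="s1" text="', ex$text, '">',
    ents,
    '<pair id="p1" e1="m1" e2="m2" ddi="true" type="effect"/>',
    '<pair id="p2" e1="m1" e2="m3" ddi="false"/>',
    '<pair id="p3" e1="m2" e2="m3" ddi="true" type="advise"/>',
    "</sentence></document></corpus>")
  writeLines(xml, path)
  path
}

# Brute-force micro P/R/F: explicit loop over classes and instances.
brute_micro_prf <- function(gold, pred, labelset = ddi_labelset()) {
  tp <- fp <- fn <- 0
  for (cl in labelset$positives) {
    for (i in seq_along(gold)) {
      if (gold[i] == cl && pred[i] == cl) tp <- tp + 1
      if (pred[i] == cl && gold[i] != cl) fp <- fp + 1
      if (gold[i] == cl && pred[i] != cl) fn <- fn + 1
    }
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F = f)
}

# Brute-force rank of a true triple: score every candidate one at a time.
brute_rank <- function(model, kg, h, r, t, side, filtered = FALSE) {
  true_ep <- if (side == "head") h else t
  type <- kg$entities$type[kg$entities$id == true_ep]
  cands <- setdiff(sort(kg$entities$id[kg$entities$type == type]), true_ep)
  if (filtered) {
    known <- paste(kg$triples$h, kg$triples$r, kg$triples$t)
    keep <- logical(length(cands))
    for (i in seq_along(cands)) {
      key <- if (side == "head") paste(cands[i], r, t)
             else paste(h, r, cands[i])
      keep[i] <- !(key %in% known)
    }
    cands <- cands[keep]
  }
  s_true <- kge_score(model, h, r, t)
  higher <- equal <- 0
  for (cand in cands) {
    s <- if (side == "head") kge_score(model, cand, r, t)
         else kge_score(model, h, r, cand)
    if (s > s_true) higher <- higher + 1
    if (s == s_true) equal <- equal + 1
  }
  1 + higher + 0.5 * equal
}
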