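# Whitespace + punctuation tokenizer with atomic reserved tokens, and the
# vocabulary for the relation classifier.

RESERVED_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[KG1]", "[KG2]",
                     "DRUG1", "DRUG2", "DRUGOTHER")

#' Tokenize text for the relation classifier
#'
#' Punctuation is split off as separate tokens, tokens are lowercased, and
#' the reserved tokens (`DRUG1`, `DRUG2`, `DRUGOTHER`, the special BERT
#' markers) stay atomic and case-preserved. Any tokenizer with the same
#' reserved-token contract can replace this one.
#'
#' @param text character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(text) {
  spaced <- gsub("([[:punct:]])", " \\1 ", text)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  ifelse(toks %in% RESERVED_TOKENS, toks, tolower(toks))
}

#' Build a vocabulary from training texts
#'
#' Reserved tokens occupy the first ids; the remaining tokens are sorted
#' for determinism. Tokens seen fewer than `min_count` times map to
#' `[UNK]` at encoding time.
#'
#' @param texts character vector of (masked) sentences.
#' @param min_count minimum frequency to enter the vocabulary.
#' @return An object of class `ddie_vocab` with `tokens` and the
#'   token-to-id `index` (1-based).
#' @export
build_vocab <- function(texts, min_count = 1) {
  counts <- table(unlist(lapply(texts, tokenize_text)))
  keep <- names(counts)[counts >= min_count]
  keep <- sort(setdiff(keep, RESERVED_TOKENS), method = "radix")
  tokens <- c(RESERVED_TOKENS, keep)
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "ddie_vocab")
}

vocab_id <- function(vocab, toks) {
  i <- vocab$index[toks]
  i[is.na(i)] <- vocab$index[["[UNK]"]]
  unname(i)
}

#' @export
print.ddie_vocab <- function(x, ...) {
  cat(sprintf("<ddie_vocab> %d tokens (%d reserved)\n", length(x$tokens),
              length(RESERVED_TOKENS)))
  invisible(x)
}
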