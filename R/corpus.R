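# Relation-extraction corpus ingestion: the DDIExtraction-2013 XML dialect
# and an equivalent normalized JSON dialect, candidate-pair enumeration and
# DRUG1/DRUG2/DRUGOTHER masking, plus instance (JSON-lines) I/O.
#
# Internal corpus representation: list of documents; each document is
# list(id, sentences); each sentence is list(id, text,
# mentions = data.frame(id, start, end, text, type),   # 0-based half-open
# pairs = data.frame(e1, e2, label)).

#' The DDI label set
#'
#' Four positive interaction classes in fixed order plus the negative
#' class (c = 5 total).
#'
#' @param positives ordered positive class labels.
#' @param negative the no-interaction label.
#' @return A list of class `labelset` with `positives`, `negative` and
#'   `labels` (positives first, negative last).
#' @export
ddi_labelset <- function(positives = c("Mechanism", "Effect", "Advice", "Int"),
                         negative = "negative") {
  if (negative %in% positives)
    stopf("negative label '%s' must not be a positive class", negative)
  structure(list(positives = positives, negative = negative,
                 labels = c(positives, negative)), class = "labelset")
}

# Canonicalize corpus label spellings (DDIExtraction-2013 uses lowercase
# attribute values and 'advise' for the Advice class).
canonical_label <- function(x, labelset = ddi_labelset()) {
  lx <- tolower(trimws(x))
  map <- c(mechanism = "Mechanism", effect = "Effect", advise = "Advice",
           advice = "Advice", int = "Int", "int." = "Int",
           negative = "negative", none = "negative", false = "negative")
  out <- unname(map[lx])
  known <- tolower(labelset$labels)
  out[is.na(out) & lx %in% known] <-
    labelset$labels[match(lx[is.na(out) & lx %in% known], known)]
  if (anyNA(out)) stopf("unknown label: %s", x[is.na(out)][1])
  out
}

.mention_df <- function(id = character(), start = integer(),
                        end = integer(), text = character(),
                        type = character()) {
  data.frame(id = id, start = as.integer(start), end = as.integer(end),
             text = text, type = type, stringsAsFactors = FALSE)
}

validate_mentions <- function(text, mentions, where = "") {
  n <- nchar(text)
  for (i in seq_len(nrow(mentions))) {
    s <- mentions$start[i]; e <- mentions$end[i]
    if (is.na(s) || is.na(e) || s < 0 || e > n || s >= e)
      stopf("mention %s%s has offsets [%s, %s) outside sentence of length %d",
            mentions$id[i], where, s, e, n)
    sub <- substr(text, s + 1, e)
    if (!identical(sub, mentions$text[i]))
      stopf("mention %s%s: span text '%s' != annotated text '%s'",
            mentions$id[i], where, sub, mentions$text[i])
  }
  invisible(TRUE)
}

# Drop duplicate spans (keep first) and later mentions overlapping an
# earlier one; masking needs non-overlapping spans.
resolve_overlaps <- function(mentions) {
  if (nrow(mentions) < 2) return(mentions)
  keep <- rep(TRUE, nrow(mentions))
  for (i in 2:nrow(mentions)) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if (mentions$start[i] < mentions$end[j] &&
          mentions$end[i] > mentions$start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  mentions[keep, , drop = FALSE]
}

#' Read a DDIExtraction-2013 XML corpus
#'
#' Character offsets in the XML are inclusive (`start-end`); they are
#' converted to 0-based half-open intervals. Discontinuous mentions
#' (semicolon-separated offset lists) are truncated to their first
#' contiguous segment. Pair annotations with `ddi="false"` get the
#' negative label; `ddi="true"` pairs take their `type` attribute
#' (canonicalized, e.g. `advise` to `Advice`).
#'
#' @param xml_path path to the XML file.
#' @param labelset a [ddi_labelset()].
#' @return A corpus (list of documents).
#' @export
read_ddi_xml <- function(xml_path, labelset = ddi_labelset()) {
  doc <- xml2::read_xml(xml_path)
  docs <- lapply(xml2::xml_find_all(doc, ".//document"), function(dnode) {
    sents <- lapply(xml2::xml_find_all(dnode, ".//sentence"), function(snode) {
      text <- xml2::xml_attr(snode, "text")
      ents <- xml2::xml_find_all(snode, ".//entity")
      mention_rows <- lapply(ents, function(e) {
        off <- xml2::xml_attr(e, "charOffset")
        seg <- strsplit(off, ";", fixed = TRUE)[[1]][1]
        se <- as.integer(strsplit(seg, "-", fixed = TRUE)[[1]])
        start <- se[1]; end <- se[2] + 1L  # inclusive -> half-open
        if (is.na(start) || is.na(end) || end > nchar(text) || start < 0)
          stopf("entity %s: charOffset '%s' outside sentence %s",
                xml2::xml_attr(e, "id"), off, xml2::xml_attr(snode, "id"))
        .mention_df(xml2::xml_attr(e, "id"), start, end,
                    substr(text, start + 1, end),
                    toupper(xml2::xml_attr(e, "type")))
      })
      mentions <- if (length(mention_rows)) do.call(rbind, mention_rows)
                  else .mention_df()
      mentions <- resolve_overlaps(mentions)
      validate_mentions(text, mentions,
                        sprintf(" (sentence %s)", xml2::xml_attr(snode, "id")))
      prs <- xml2::xml_find_all(snode, ".//pair")
      pairs <- if (length(prs)) {
        data.frame(
          e1 = vapply(prs, xml2::xml_attr, "", attr = "e1"),
          e2 = vapply(prs, xml2::xml_attr, "", attr = "e2"),
          label = vapply(prs, function(p) {
            if (identical(xml2::xml_attr(p, "ddi"), "true"))
              canonical_label(xml2::xml_attr(p, "type"), labelset)
            else labelset$negative
          }, ""),
          stringsAsFactors = FALSE)
      } else {
        data.frame(e1 = character(), e2 = character(), label = character(),
                   stringsAsFactors = FALSE)
      }
      list(id = xml2::xml_attr(snode, "id"), text = text,
           mentions = mentions, pairs = pairs)
    })
    list(id = xml2::xml_attr(dnode, "id"), sentences = sents)
  })
  structure(docs, class = "kgrex_corpus")
}

#' Read / write the normalized JSON corpus dialect
#'
#' The JSON schema mirrors the internal representation: an object with a
#' `documents` array; each document has `id` and `sentences`; each sentence
#' has `id`, `text`, `mentions` (objects with `id`, `start`, `end`, `text`,
#' `type`; 0-based half-open offsets) and `pairs` (objects with `e1`, `e2`,
#' `label`). Synthetic corpora and non-DDI tasks use this dialect to bypass
#' XML.
#'
#' @param path JSON file path.
#' @param corpus a corpus object (for writing).
#' @param labelset a [ddi_labelset()].
#' @return A corpus (read) or `path` invisibly (write).
#' @export
read_corpus_json <- function(path, labelset = ddi_labelset()) {
  x <- jsonlite::read_json(path)
  docs <- lapply(x$documents, function(d) {
    sents <- lapply(d$sentences, function(s) {
      mentions <- if (length(s$mentions)) {
        do.call(rbind, lapply(s$mentions, function(m)
          .mention_df(m$id, m$start, m$end, m$text, m$type)))
      } else .mention_df()
      mentions <- resolve_overlaps(mentions)
      validate_mentions(s$text, mentions, sprintf(" (sentence %s)", s$id))
      pairs <- if (length(s$pairs)) {
        data.frame(e1 = vapply(s$pairs, function(p) p$e1, ""),
                   e2 = vapply(s$pairs, function(p) p$e2, ""),
                   label = canonical_label(
                     vapply(s$pairs, function(p) p$label, ""), labelset),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(e1 = character(), e2 = character(), label = character(),
                   stringsAsFactors = FALSE)
      }
      list(id = s$id, text = s$text, mentions = mentions, pairs = pairs)
    })
    list(id = d$id, sentences = sents)
  })
  structure(docs, class = "kgrex_corpus")
}

#' @rdname read_corpus_json
#' @export
write_corpus_json <- function(corpus, path) {
  docs <- lapply(corpus, function(d) {
    list(id = d$id, sentences = lapply(d$sentences, function(s) {
      list(id = s$id, text = s$text,
           mentions = lapply(seq_len(nrow(s$mentions)), function(i)
             as.list(s$mentions[i, , drop = FALSE])),
           pairs = lapply(seq_len(nrow(s$pairs)), function(i)
             as.list(s$pairs[i, , drop = FALSE])))
    }))
  })
  jsonlite::write_json(list(documents = docs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Enumerate candidate mention pairs of a sentence
#'
#' A sentence with n drug mentions yields choose(n, 2) pairs, each ordered
#' by position (the first-by-start mention is m1).
#'
#' @param mentions mention data.frame of a sentence.
#' @return data.frame with columns `i1`, `i2` (row indices into
#'   `mentions`), m1 before m2 in the sentence.
#' @export
enumerate_pairs <- function(mentions) {
  n <- nrow(mentions)
  if (n < 2)
    return(data.frame(i1 = integer(), i2 = integer()))
  ord <- order(mentions$start, mentions$end)
  out <- list()
  for (a in 1:(n - 1)) for (b in (a + 1):n)
    out[[length(out) + 1]] <- c(ord[a], ord[b])
  m <- do.call(rbind, out)
  data.frame(i1 = m[, 1], i2 = m[, 2])
}

#' Mask a sentence for one target mention pair
#'
#' The two target mentions become `DRUG1` and `DRUG2` in sentence order;
#' every other mention becomes `DRUGOTHER`. Replacement proceeds
#' right-to-left so earlier spans stay valid; all non-mention text is
#' byte-identical to the input.
#'
#' @param text the raw sentence.
#' @param mentions mention data.frame (non-overlapping).
#' @param i1,i2 row indices of the target pair.
#' @return The masked sentence string.
#' @export
mask_sentence <- function(text, mentions, i1, i2) {
  if (i1 == i2) stopf("target pair must be two distinct mentions")
  if (mentions$start[i1] > mentions$start[i2]) { tmp <- i1; i1 <- i2; i2 <- tmp }
  if (mentions$end[i1] > mentions$start[i2])
    stopf("target mentions %s and %s overlap", mentions$id[i1],
          mentions$id[i2])
  repl <- rep("DRUGOTHER", nrow(mentions))
  repl[i1] <- "DRUG1"; repl[i2] <- "DRUG2"
  ord <- order(mentions$start, decreasing = TRUE)
  out <- text
  for (i in ord) {
    out <- paste0(substr(out, 1, mentions$start[i]), repl[i],
                  substring(out, mentions$end[i] + 1))
  }
  out
}

#' Build relation instances from a corpus
#'
#' Enumerates every mention pair of every sentence, masks the sentence per
#' pair, attaches the gold label (pairs absent from the annotation get the
#' negative label) and, when a linking table is given, the linked
#' knowledge-graph entries of both mentions.
#'
#' @param corpus a corpus from [read_ddi_xml()], [read_corpus_json()] or
#'   [generate_corpus()].
#' @param linking optional [build_linking_table()] result.
#' @param labelset a [ddi_labelset()].
#' @return data.frame of instances with provenance columns (`doc_id`,
#'   `sent_id`, mention ids/texts/types), `sentence_masked`, `label`,
#'   `kg1`, `kg2`.
#' @export
build_instances <- function(corpus, linking = NULL,
                            labelset = ddi_labelset()) {
  rows <- list()
  for (d in corpus) {
    for (s in d$sentences) {
      prs <- enumerate_pairs(s$mentions)
      if (!nrow(prs)) next
      gold <- s$pairs
      gkey <- c(paste(gold$e1, gold$e2), paste(gold$e2, gold$e1))
      glab <- c(gold$label, gold$label)
      for (p in seq_len(nrow(prs))) {
        i1 <- prs$i1[p]; i2 <- prs$i2[p]
        m1 <- s$mentions[i1, ]; m2 <- s$mentions[i2, ]
        key <- paste(m1$id, m2$id)
        lab <- if (key %in% gkey) glab[match(key, gkey)] else labelset$negative
        kg1 <- kg2 <- NA_character_
        if (!is.null(linking)) {
          kg1 <- link_mention(linking, m1$text, m1$type)
          kg2 <- link_mention(linking, m2$text, m2$type)
        }
        rows[[length(rows) + 1]] <- data.frame(
          doc_id = d$id, sent_id = s$id,
          m1_id = m1$id, m2_id = m2$id,
          m1_text = m1$text, m2_text = m2$text,
          m1_type = m1$type, m2_type = m2$type,
          sentence_masked = mask_sentence(s$text, s$mentions, i1, i2),
          label = lab, kg1 = kg1, kg2 = kg2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(doc_id = character(), sent_id = character(),
                      m1_id = character(), m2_id = character(),
                      m1_text = character(), m2_text = character(),
                      m1_type = character(), m2_type = character(),
                      sentence_masked = character(), label = character(),
                      kg1 = character(), kg2 = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write instances as JSON-lines
#'
#' One JSON object per line with the fields of [build_instances()].
#'
#' @param instances instance data.frame.
#' @param path file path.
#' @return The instance data.frame (read) or `path` invisibly (write).
#' @export
write_instances <- function(instances, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(instances))) {
    writeLines(jsonlite::toJSON(as.list(instances[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, TRUE)] <- NA_character_
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
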