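# Typed heterogeneous knowledge graph: data model, I/O, pseudo-node
# augmentation, node-type filtering.

KG_ENTITY_TYPES <- c("drug", "protein", "pathway", "category", "atc",
                     "textual", "structural")
KG_ACTUAL_TYPES <- c("drug", "protein", "pathway", "category", "atc")
KG_PSEUDO_TYPES <- c("textual", "structural")
KG_SPLITS <- c("train", "valid", "test")

#' Relation schema of the pharmaceutical knowledge graph
#'
#' Declares the relation vocabulary: the eight relations among actual nodes
#' (category, atc, pathway, interact, target, enzyme, carrier, transporter)
#' plus the three relations that attach pseudo-nodes (structure, synonym,
#' description). `interact` is the only symmetric relation. Domains and
#' ranges are pipe-separated entity-type sets validated at load time.
#'
#' @return A data.frame with columns `name`, `symmetric`, `domain`, `range`.
#' @export
kg_relation_schema <- function() {
  actual <- paste(KG_ACTUAL_TYPES, collapse = "|")
  data.frame(
    name = c("category", "atc", "pathway", "interact", "target", "enzyme",
             "carrier", "transporter", "structure", "synonym", "description"),
    symmetric = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE),
    domain = c("drug", "drug", "drug|protein", "drug", "drug", "drug",
               "drug", "drug", "drug", actual, actual),
    range = c("category", "atc", "pathway", "drug", "protein", "protein",
              "protein", "protein", "structural", "textual", "textual"),
    stringsAsFactors = FALSE
  )
}

.split_types <- function(x) strsplit(x, "|", fixed = TRUE)[[1]]

#' Construct a knowledge graph
#'
#' @param entities data.frame with columns `id`, `type`, and optionally
#'   `names` (pipe-separated primary name + synonyms), `smiles`,
#'   `description`.
#' @param triples data.frame with columns `h`, `r`, `t` and optionally
#'   `split` (one of train/valid/test; default train). `NULL` for an
#'   edgeless graph.
#' @param relations relation schema, see [kg_relation_schema()].
#' @return An object of class `kg`.
#' @export
kg_new <- function(entities, triples = NULL, relations = kg_relation_schema()) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(entities)))
    stopf("entity metadata needs columns 'id' and 'type'")
  for (col in c("names", "smiles", "description"))
    if (is.null(entities[[col]])) entities[[col]] <- NA_character_
  entities <- entities[, c("id", "type", "names", "smiles", "description")]
  entities$id <- as.character(entities$id)

  if (is.null(triples) || nrow(as.data.frame(triples)) == 0) {
    triples <- data.frame(h = character(), r = character(), t = character(),
                          split = character(), stringsAsFactors = FALSE)
  } else {
    triples <- as.data.frame(triples, stringsAsFactors = FALSE)
    if (is.null(triples$split)) triples$split <- "train"
    triples <- triples[, c("h", "r", "t", "split")]
  }
  kg <- structure(list(entities = entities, relations = relations,
                       triples = triples), class = "kg")
  kg_validate(kg)
  kg
}

kg_validate <- function(kg) {
  ent <- kg$entities
  if (anyDuplicated(ent$id))
    stopf("duplicate entity id: %s", ent$id[duplicated(ent$id)][1])
  bad <- setdiff(unique(ent$type), KG_ENTITY_TYPES)
  if (length(bad)) stopf("unknown entity type: %s", bad[1])
  actual <- ent$type %in% KG_ACTUAL_TYPES
  noname <- actual & (is.na(ent$names) | !nzchar(ent$names))
  if (any(noname))
    stopf("actual entity without a name: %s", ent$id[noname][1])

  tr <- kg$triples
  if (nrow(tr)) {
    type_of <- stats::setNames(ent$type, ent$id)
    for (col in c("h", "t")) {
      miss <- is.na(type_of[tr[[col]]])
      if (any(miss))
        stopf("triple references unregistered entity id: %s",
              tr[[col]][miss][1])
    }
    rel <- kg$relations
    unk <- !(tr$r %in% rel$name)
    if (any(unk)) stopf("unknown relation: %s", tr$r[unk][1])
    if (!all(tr$split %in% KG_SPLITS))
      stopf("unknown split label: %s", setdiff(tr$split, KG_SPLITS)[1])
    for (i in seq_len(nrow(rel))) {
      sel <- tr$r == rel$name[i]
      if (!any(sel)) next
      dom <- .split_types(rel$domain[i]); rng <- .split_types(rel$range[i])
      badh <- sel & !(type_of[tr$h] %in% dom)
      badt <- sel & !(type_of[tr$t] %in% rng)
      if (any(badh))
        stopf("relation '%s' does not accept head of type '%s' (%s)",
              rel$name[i], type_of[tr$h[badh][1]], tr$h[badh][1])
      if (any(badt))
        stopf("relation '%s' does not accept tail of type '%s' (%s)",
              rel$name[i], type_of[tr$t[badt][1]], tr$t[badt][1])
    }
  }
  invisible(kg)
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<kg> %d entities, %d triples (train %d / valid %d / test %d)\n",
              nrow(x$entities), nrow(x$triples),
              sum(x$triples$split == "train"),
              sum(x$triples$split == "valid"),
              sum(x$triples$split == "test")))
  tab <- table(factor(x$entities$type, levels = KG_ENTITY_TYPES))
  cat("  entities:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

kg_entity_type <- function(kg, ids) {
  out <- stats::setNames(kg$entities$type, kg$entities$id)[ids]
  if (anyNA(out)) stopf("unknown entity id: %s", ids[is.na(out)][1])
  unname(out)
}

triple_key <- function(h, r, t) paste(h, r, t, sep = "\r")

#' Load a knowledge graph from triple and metadata tables
#'
#' @param tsv_path path to a tab-separated triple file with columns
#'   head / relation / tail and an optional 4th split column; a header row
#'   `h r t` (or `head relation tail`) is detected and skipped.
#' @param metadata_path path to a tab-separated entity table with header
#'   `id type names smiles description` (`names` pipe-separated).
#' @param relations relation schema.
#' @return A validated [kg_new()] object; metadata rows never referenced by
#'   a triple become isolated entities.
#' @export
load_triples <- function(tsv_path, metadata_path,
                         relations = kg_relation_schema()) {
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            quote = "", na.strings = c("NA", ""))
  raw <- tryCatch(
    utils::read.delim(tsv_path, header = FALSE, stringsAsFactors = FALSE,
                      quote = ""),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    triples <- NULL
  } else {
    if (ncol(raw) < 3) stopf("triple file needs >= 3 tab-separated columns")
    first <- tolower(as.character(raw[1, 1:3]))
    if (identical(first, c("h", "r", "t")) ||
        identical(first, c("head", "relation", "tail")))
      raw <- raw[-1, , drop = FALSE]
    triples <- data.frame(h = as.character(raw[[1]]),
                          r = as.character(raw[[2]]),
                          t = as.character(raw[[3]]),
                          stringsAsFactors = FALSE)
    if (ncol(raw) >= 4) triples$split <- as.character(raw[[4]])
    if (nrow(triples) == 0) triples <- NULL
  }
  kg_new(meta, triples, relations)
}

#' Serialize a knowledge graph to a directory
#'
#' Writes `entities.tsv`, `relations.tsv`, `triples.tsv` and a
#' `manifest.json`; [kg_read()] round-trips the archive.
#'
#' @param kg a `kg` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
kg_write <- function(kg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(kg$entities, file.path(dir, "entities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(kg$relations, file.path(dir, "relations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(kg$triples, file.path(dir, "triples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(format = "kgrex-kg", version = 1L,
                   n_entities = nrow(kg$entities),
                   n_triples = nrow(kg$triples))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a knowledge graph archive written by [kg_write()]
#'
#' @param dir archive directory.
#' @return A `kg` object.
#' @export
kg_read <- function(dir) {
  ent <- utils::read.delim(file.path(dir, "entities.tsv"),
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""))
  rel <- utils::read.delim(file.path(dir, "relations.tsv"),
                           stringsAsFactors = FALSE, quote = "")
  tr <- utils::read.delim(file.path(dir, "triples.tsv"),
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (nrow(tr) == 0) tr <- NULL
  kg_new(ent, tr, rel)
}

#' Entity identifiers of one type, in stable sorted order
#'
#' @param kg a `kg` object.
#' @param kind an entity type.
#' @return Character vector of ids, sorted; empty when no entity has the
#'   type.
#' @export
candidates_of_type <- function(kg, kind) {
  if (!kind %in% KG_ENTITY_TYPES) stopf("unknown entity type: %s", kind)
  sort(kg$entities$id[kg$entities$type == kind], method = "radix")
}

#' Remove all nodes of one type (node-type ablation)
#'
#' Drops every entity of `kind` and every triple touching one; the split
#' membership of surviving triples is preserved. Drugs are the subjects of
#' the extraction task and cannot be removed.
#'
#' @param kg a `kg` object.
#' @param kind entity type to remove (not `"drug"`).
#' @return The filtered `kg`.
#' @export
remove_node_type <- function(kg, kind) {
  if (!kind %in% KG_ENTITY_TYPES) stopf("unknown entity type: %s", kind)
  if (kind == "drug")
    stopf("refusing to remove drug nodes: drugs are the task subjects")
  drop_ids <- kg$entities$id[kg$entities$type == kind]
  kg$entities <- kg$entities[!(kg$entities$id %in% drop_ids), , drop = FALSE]
  keep <- !(kg$triples$h %in% drop_ids) & !(kg$triples$t %in% drop_ids)
  kg$triples <- kg$triples[keep, , drop = FALSE]
  rownames(kg$entities) <- NULL
  rownames(kg$triples) <- NULL
  kg_validate(kg)
  kg
}

entity_names <- function(names_field) {
  if (is.na(names_field) || !nzchar(names_field)) return(character())
  strsplit(names_field, "|", fixed = TRUE)[[1]]
}

#' Augment a graph with textual pseudo-nodes
#'
#' For every actual entity, each synonym (the entries of `names` after the
#' primary name) and each description becomes one textual pseudo-node,
#' linked by the `synonym` / `description` relation. Added triples go to
#' the train split only; applying the augmentation twice adds nothing the
#' second time.
#'
#' @param kg a `kg` object.
#' @return The augmented `kg`.
#' @export
add_textual_nodes <- function(kg) {
  ent <- kg$entities
  have <- ent$id
  new_ent <- list(); new_tri <- list()
  for (i in which(ent$type %in% KG_ACTUAL_TYPES)) {
    id <- ent$id[i]
    syns <- entity_names(ent$names[i])
    syns <- if (length(syns) > 1) syns[-1] else character()
    for (j in seq_along(syns)) {
      nid <- sprintf("TXT:%s:syn%d", id, j)
      if (nid %in% have) next
      new_ent[[nid]] <- data.frame(id = nid, type = "textual",
                                   names = syns[j], smiles = NA_character_,
                                   description = NA_character_,
                                   stringsAsFactors = FALSE)
      new_tri[[nid]] <- data.frame(h = id, r = "synonym", t = nid,
                                   split = "train", stringsAsFactors = FALSE)
    }
    if (!is.na(ent$description[i]) && nzchar(ent$description[i])) {
      nid <- sprintf("TXT:%s:desc", id)
      if (!(nid %in% have)) {
        new_ent[[nid]] <- data.frame(id = nid, type = "textual",
                                     names = ent$description[i],
                                     smiles = NA_character_,
                                     description = NA_character_,
                                     stringsAsFactors = FALSE)
        new_tri[[nid]] <- data.frame(h = id, r = "description", t = nid,
                                     split = "train",
                                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(new_ent)) {
    kg$entities <- rbind(kg$entities, do.call(rbind, new_ent))
    kg$triples <- rbind(kg$triples, do.call(rbind, new_tri))
    rownames(kg$entities) <- NULL
    rownames(kg$triples) <- NULL
    kg_validate(kg)
  }
  kg
}

#' Augment a graph with molecular-structure pseudo-nodes
#'
#' Every drug with a SMILES string is linked via the `structure` relation
#' to a structural pseudo-node keyed by the SMILES string itself, so drugs
#' with identical structures share one node. Added triples go to the train
#' split only; idempotent.
#'
#' @param kg a `kg` object.
#' @return The augmented `kg`.
#' @export
add_structural_nodes <- function(kg) {
  ent <- kg$entities
  drugs <- which(ent$type == "drug" & !is.na(ent$smiles) & nzchar(ent$smiles))
  if (!length(drugs)) return(kg)
  have_ent <- ent$id
  have_tri <- triple_key(kg$triples$h, kg$triples$r, kg$triples$t)
  new_ent <- list(); new_tri <- list()
  for (i in drugs) {
    smi <- ent$smiles[i]
    nid <- paste0("SMILES:", smi)
    if (!(nid %in% have_ent) && is.null(new_ent[[nid]])) {
      new_ent[[nid]] <- data.frame(id = nid, type = "structural",
                                   names = smi, smiles = smi,
                                   description = NA_character_,
                                   stringsAsFactors = FALSE)
    }
    key <- triple_key(ent$id[i], "structure", nid)
    if (!(key %in% have_tri)) {
      new_tri[[key]] <- data.frame(h = ent$id[i], r = "structure", t = nid,
                                   split = "train", stringsAsFactors = FALSE)
    }
  }
  if (length(new_ent)) kg$entities <- rbind(kg$entities, do.call(rbind, new_ent))
  if (length(new_tri)) kg$triples <- rbind(kg$triples, do.call(rbind, new_tri))
  rownames(kg$entities) <- NULL
  rownames(kg$triples) <- NULL
  kg_validate(kg)
  kg
}
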