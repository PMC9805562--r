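# Mention-to-knowledge-graph linking by normalized exact string matching
# over entity names and synonyms.

#' Build a linking table from a knowledge graph
#'
#' Two lookup spaces are built from normalized (lowercased,
#' whitespace-collapsed) surfaces: the drug space from drug names and
#' synonyms (GROUP-type mentions do not use it) and the group space from
#' category and ATC names. On surface collisions the first entity in
#' registry order wins.
#'
#' @param kg a `kg` object.
#' @return An object of class `linking_table` with named character vectors
#'   `drug` and `group` (normalized surface -> entity id).
#' @export
build_linking_table <- function(kg) {
  ent <- kg$entities
  space <- function(types) {
    out <- character(0)
    for (i in which(ent$type %in% types)) {
      for (nm in entity_names(ent$names[i])) {
        key <- normalize_surface(nm)
        if (!nzchar(key) || key %in% names(out)) next
        out[key] <- ent$id[i]
      }
    }
    out
  }
  structure(list(drug = space("drug"), group = space(c("category", "atc"))),
            class = "linking_table")
}

#' Link one mention surface to a knowledge-graph entry
#'
#' GROUP-type mentions match against the category/ATC space, all other
#' mention types against the drug space; matching is normalized exact.
#'
#' @param table a [build_linking_table()] result.
#' @param text mention surface string.
#' @param mention_type corpus mention type (e.g. DRUG, BRAND, GROUP,
#'   DRUG_N).
#' @return The linked entity id, or `NA_character_` on a miss (downstream
#'   a learned unknown-entity vector stands in).
#' @export
link_mention <- function(table, text, mention_type = "DRUG") {
  space <- if (identical(toupper(mention_type), "GROUP")) table$group
           else table$drug
  hit <- space[normalize_surface(text)]
  if (is.na(hit)) NA_character_ else unname(hit)
}

#' Write / read a linking table as TSV
#'
#' Three columns: normalized surface, entity id, space (drug/group).
#'
#' @param table a `linking_table`.
#' @param path TSV path.
#' @return `path` invisibly (write) or the `linking_table` (read).
#' @export
write_linking_table <- function(table, path) {
  df <- rbind(
    data.frame(key = names(table$drug), id = unname(table$drug),
               space = "drug", stringsAsFactors = FALSE),
    data.frame(key = names(table$group), id = unname(table$group),
               space = "group", stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_linking_table
#' @export
read_linking_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  structure(list(
    drug = stats::setNames(df$id[df$space == "drug"],
                           df$key[df$space == "drug"]),
    group = stats::setNames(df$id[df$space == "group"],
                            df$key[df$space == "group"])),
    class = "linking_table")
}

#' Linking coverage of an instance set
#'
#' @param instances instance data.frame from [build_instances()] with
#'   `kg1` / `kg2` columns.
#' @return A list with `instance` (fraction of instances where both
#'   mentions linked) and `mention` (fraction of unique normalized mention
#'   surfaces that linked).
#' @export
coverage <- function(instances) {
  if (nrow(instances) == 0) stopf("no instances")
  inst <- mean(!is.na(instances$kg1) & !is.na(instances$kg2))
  surf <- data.frame(
    key = normalize_surface(c(instances$m1_text, instances$m2_text)),
    linked = !is.na(c(instances$kg1, instances$kg2)),
    stringsAsFactors = FALSE)
  agg <- tapply(surf$linked, surf$key, any)
  list(instance = inst, mention = mean(agg))
}
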