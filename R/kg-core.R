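#' Closed vocabulary of entity types
#'
#' The fifteen entity types a cross-medicine knowledge graph may contain.
#' Traditional-medicine entities (Herb, Ingredient, SymptomTCM, Syndrome)
#' and modern-medicine entities (Compound, DiseaseMM, SymptomMM, Pathway,
#' ontology terms, SideEffect, Anatomy, PharmacologicalClassification) are
#' bridged through shared Gene nodes.
#'
#' @export
kg_entity_types <- c(
  "DiseaseMM", "SymptomMM", "SymptomTCM", "Herb", "Ingredient", "Compound",
  "Gene", "Pathway", "MolecularFunction", "CellularComponent",
  "BiologicalProcess", "SideEffect", "Anatomy",
  "PharmacologicalClassification", "Syndrome"
)

entity_columns <- c("entity_id", "name", "entity_type", "source_db")
triple_columns <- c("head_id", "relation", "tail_id", "source_db")

validate_entities <- function(entities) {
  missing <- setdiff(entity_columns, names(entities))
  if (length(missing) > 0L)
    format_error(sprintf("entity table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  entities <- as.data.frame(entities)[entity_columns]
  for (col in entity_columns) entities[[col]] <- as.character(entities[[col]])
  bad_type <- setdiff(unique(entities$entity_type), kg_entity_types)
  if (length(bad_type) > 0L)
    format_error(sprintf("unknown entity_type value(s): %s",
                         paste(bad_type, collapse = ", ")))
  if (any(!nzchar(entities$name)))
    format_error("entity names must be non-empty")
  dup <- unique(entities$entity_id[duplicated(entities$entity_id)])
  if (length(dup) > 0L)
    integrity_error(sprintf("duplicate entity_id value(s): %s",
                            paste(dup, collapse = ", ")))
  rownames(entities) <- NULL
  entities
}

#' Read a tab-separated entity table
#'
#' Expects a UTF-8 TSV with header row and columns `entity_id`, `name`,
#' `entity_type`, `source_db`. Entity types must come from the closed
#' vocabulary [kg_entity_types]; duplicated ids are an integrity error.
#'
#' @param path Path to the entity TSV.
#' @return A data frame with one row per entity.
#' @export
read_entity_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  validate_entities(df)
}

#' Write an entity table as TSV
#'
#' @param entities Entity data frame.
#' @param path Output path.
#' @export
write_entity_table <- function(entities, path) {
  utils::write.table(entities[entity_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a triple table as TSV
#'
#' @param store A `kg_store` or a triple data frame.
#' @param path Output path.
#' @export
write_triple_table <- function(store, path) {
  triples <- if (inherits(store, "kg_store")) store$triples else store
  utils::write.table(triples[triple_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a knowledge-graph store
#'
#' Deduplicates triples on (head, relation, tail), checks that every triple
#' endpoint resolves to a known entity, and builds out/in adjacency indices.
#'
#' @param entities Entity data frame (see [read_entity_table]).
#' @param triples Data frame with columns `head_id`, `relation`, `tail_id`,
#'   `source_db`.
#' @param lenient If `TRUE`, triples referencing unknown entities are dropped
#'   (with their count recorded in `$dropped`) instead of raising an
#'   integrity error.
#' @return An object of class `kg_store` with components `entities`,
#'   `triples`, `out_index`, `in_index`, `relations` and `dropped`.
#' @export
kg_store <- function(entities, triples, lenient = FALSE) {
  entities <- validate_entities(entities)
  missing <- setdiff(triple_columns, names(triples))
  if (length(missing) > 0L)
    format_error(sprintf("triple table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  triples <- as.data.frame(triples)[triple_columns]
  for (col in triple_columns) triples[[col]] <- as.character(triples[[col]])

  known <- triples$head_id %in% entities$entity_id &
    triples$tail_id %in% entities$entity_id
  dropped <- sum(!known)
  if (dropped > 0L) {
    if (!lenient) {
      bad <- unique(c(setdiff(triples$head_id, entities$entity_id),
                      setdiff(triples$tail_id, entities$entity_id)))
      integrity_error(sprintf(
        "%d triple(s) reference unknown entit%s: %s",
        dropped, if (length(bad) == 1L) "y" else "ies",
        paste(utils::head(bad, 10L), collapse = ", ")))
    }
    triples <- triples[known, , drop = FALSE]
  }

  key <- paste(triples$head_id, triples$relation, triples$tail_id, sep = "\r")
  triples <- triples[!duplicated(key), , drop = FALSE]
  rownames(triples) <- NULL

  structure(list(
    entities  = entities,
    triples   = triples,
    out_index = split(seq_len(nrow(triples)), triples$head_id),
    in_index  = split(seq_len(nrow(triples)), triples$tail_id),
    relations = sort(unique(triples$relation)),
    dropped   = dropped
  ), class = "kg_store")
}

#' Read a triple table and assemble a store
#'
#' @inheritParams kg_store
#' @param path Path to the triple TSV (columns `head_id`, `relation`,
#'   `tail_id`, `source_db`, header row).
#' @return A [kg_store].
#' @export
read_triples <- function(path, entities, lenient = FALSE) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  kg_store(entities, df, lenient = lenient)
}

#' @export
print.kg_store <- function(x, ...) {
  cat(sprintf("<kg_store> %d entities (%d types), %d triples (%d relations)\n",
              nrow(x$entities), length(unique(x$entities$entity_type)),
              nrow(x$triples), length(x$relations)))
  if (x$dropped > 0L)
    cat(sprintf("  %d dangling triple(s) dropped (lenient mode)\n", x$dropped))
  invisible(x)
}

entity_type_of <- function(store, ids) {
  store$entities$entity_type[match(ids, store$entities$entity_id)]
}

has_entity <- function(store, id) id %in% store$entities$entity_id

#' Incident edges of an entity
#'
#' @param store A [kg_store].
#' @param entity_id Entity identifier.
#' @param direction `"out"`, `"in"`, or `"both"`.
#' @return Data frame with columns `relation` and `neighbor_id`, ordered by
#'   (relation, neighbor_id); for `"both"` an extra `direction` column.
#' @export
kg_neighbors <- function(store, entity_id, direction = c("out", "in", "both")) {
  direction <- match.arg(direction)
  if (!has_entity(store, entity_id))
    lookup_error(sprintf("unknown entity: %s", entity_id))
  take <- function(idx, nb_col, dir) {
    idx <- store[[if (dir == "out") "out_index" else "in_index"]][[entity_id]]
    if (is.null(idx)) idx <- integer(0)
    data.frame(relation = store$triples$relation[idx],
               neighbor_id = store$triples[[nb_col]][idx],
               direction = rep(dir, length(idx)),
               stringsAsFactors = FALSE)
  }
  res <- switch(direction,
    out  = take(NULL, "tail_id", "out"),
    "in" = take(NULL, "head_id", "in"),
    both = rbind(take(NULL, "tail_id", "out"), take(NULL, "head_id", "in")))
  res <- res[order(res$relation, res$neighbor_id), , drop = FALSE]
  rownames(res) <- NULL
  if (direction != "both") res$direction <- NULL
  res
}

#' Default custom-ID scheme
#'
#' Per-type prefixes and zero-pad widths mirroring the published ID naming
#' table (e.g. herbs HEB0001..., compounds DCP00001...). Ontology-term types
#' (MolecularFunction, CellularComponent, BiologicalProcess, SideEffect,
#' Anatomy, PharmacologicalClassification) retain their source-database IDs.
#'
#' @return Named list mapping entity type to `list(prefix, width)` or the
#'   string `"retain"`.
#' @export
default_id_scheme <- function() {
  list(
    DiseaseMM  = list(prefix = "DIMM", width = 5L),
    SymptomMM  = list(prefix = "MS", width = 4L),
    SymptomTCM = list(prefix = "TS", width = 4L),
    Herb       = list(prefix = "HEB", width = 4L),
    Ingredient = list(prefix = "INT", width = 5L),
    Compound   = list(prefix = "DCP", width = 5L),
    Gene       = list(prefix = "GEE", width = 5L),
    Pathway    = list(prefix = "PW", width = 4L),
    Syndrome   = list(prefix = "ZH", width = 3L),
    MolecularFunction = "retain",
    CellularComponent = "retain",
    BiologicalProcess = "retain",
    SideEffect = "retain",
    Anatomy = "retain",
    PharmacologicalClassification = "retain"
  )
}

#' Assign custom entity identifiers
#'
#' Reassigns per-type sequential identifiers (prefix + zero-padded ordinal)
#' to entities, the standard remedy for inconsistent source-database IDs.
#' Within a type, entities are ordered case-insensitively by name, with ties
#' broken by `source_db` then original id, so the assignment is deterministic.
#' Types whose scheme entry is the string `"retain"` keep their source IDs.
#'
#' @param entities Entity data frame.
#' @param scheme Named list, per entity type: `list(prefix=, width=)` or
#'   `"retain"`. Defaults to [default_id_scheme()].
#' @return Named character vector mapping old id to new id (injective).
#' @export
assign_custom_ids <- function(entities, scheme = default_id_scheme()) {
  entities <- validate_entities(entities)
  if (nrow(entities) == 0L) return(stats::setNames(character(0), character(0)))
  types <- unique(entities$entity_type)
  uncovered <- setdiff(types, names(scheme))
  if (length(uncovered) > 0L)
    config_error(sprintf("scheme does not cover entity type(s): %s",
                         paste(uncovered, collapse = ", ")))
  prefixes <- vapply(scheme, function(s)
    if (identical(s, "retain")) NA_character_ else s$prefix, character(1))
  pf <- prefixes[!is.na(prefixes)]
  if (anyDuplicated(pf))
    config_error(sprintf("prefix collision across types: %s",
                         paste(unique(pf[duplicated(pf)]), collapse = ", ")))
  mapping <- stats::setNames(entities$entity_id, entities$entity_id)
  for (ty in types) {
    s <- scheme[[ty]]
    if (identical(s, "retain")) next
    rows <- which(entities$entity_type == ty)
    e <- entities[rows, , drop = FALSE]
    ord <- order(tolower(e$name), e$source_db, e$entity_id, method = "radix")
    new_ids <- sprintf(paste0(s$prefix, "%0", s$width, "d"), seq_along(rows))
    mapping[e$entity_id[ord]] <- new_ids
  }
  if (anyDuplicated(mapping))
    integrity_error("custom ID assignment produced duplicate ids")
  mapping
}

#' Apply an id mapping to a store
#'
#' @param store A [kg_store].
#' @param mapping Named character vector, old id -> new id.
#' @return A new [kg_store] with remapped identifiers.
#' @export
remap_ids <- function(store, mapping) {
  remap <- function(ids) {
    hit <- ids %in% names(mapping)
    ids[hit] <- unname(mapping[ids[hit]])
    ids
  }
  ent <- store$entities
  ent$entity_id <- remap(ent$entity_id)
  tri <- store$triples
  tri$head_id <- remap(tri$head_id)
  tri$tail_id <- remap(tri$tail_id)
  kg_store(ent, tri)
}
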