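## Entity alignment, set-similarity relation fusion, and graph-level audit
## statistics (source contributions, cross-system shared gene targets).

pair_key <- function(heads, tails) paste(heads, tails, sep = "\r")

#' Jaccard similarity of two pair sets
#'
#' `|A ∩ B| / |A ∪ B|` over sets of (head, tail) entity pairs.
#'
#' @param a,b Character vectors of pair keys (see [relation_profile]) or any
#'   vectors treated as sets.
#' @return Value in \[0, 1\].
#' @export
kg_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    argument_error("jaccard undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap coefficient of two pair sets
#'
#' `|A ∩ B| / min(|A|, |B|)`: high when the smaller relation's pairs are
#' mostly contained in the larger one's, even if Jaccard is low.
#'
#' @inheritParams kg_jaccard
#' @return Value in \[0, 1\].
#' @export
kg_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    argument_error("overlap undefined for an empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pair-set profile of a relation
#'
#' @param store A [kg_store].
#' @param relation Relation name.
#' @return List with `relation` and `pairs` (keys of (head, tail) pairs).
#' @export
relation_profile <- function(store, relation) {
  sel <- store$triples$relation == relation
  list(relation = relation,
       pairs = unique(pair_key(store$triples$head_id[sel],
                               store$triples$tail_id[sel])))
}

#' Fusion decision for a relation pair
#'
#' Two relations are merged when their pair sets are highly similar
#' (Jaccard >= `j_hi`) or when a small relation is largely contained in a
#' big one (Jaccard <= `j_lo` and Overlap >= `o_hi`); otherwise both are
#' kept. The survivor is the relation with the larger pair set, ties broken
#' lexicographically.
#'
#' @param pa,pb Profiles from [relation_profile].
#' @param j_hi,j_lo,o_hi Threshold values (defaults 0.8, 0.2, 0.6).
#' @return One-row data frame: relation_a, relation_b, jaccard, overlap,
#'   action ("merge"/"keep"), survivor.
#' @export
fusion_decision <- function(pa, pb, j_hi = 0.8, j_lo = 0.2, o_hi = 0.6) {
  j <- kg_jaccard(pa$pairs, pb$pairs)
  o <- kg_overlap(pa$pairs, pb$pairs)
  merge <- (j >= j_hi) || (j <= j_lo && o >= o_hi)
  survivor <- if (!merge) NA_character_
    else if (length(pa$pairs) > length(pb$pairs)) pa$relation
    else if (length(pb$pairs) > length(pa$pairs)) pb$relation
    else min(pa$relation, pb$relation)
  data.frame(relation_a = pa$relation, relation_b = pb$relation,
             jaccard = j, overlap = o,
             action = if (merge) "merge" else "keep",
             survivor = survivor, stringsAsFactors = FALSE)
}

#' Propose fusion decisions for all comparable relation pairs
#'
#' Only relations sharing the same (head type, tail type) signature are
#' compared; similarity across different type signatures is meaningless.
#'
#' @param store A [kg_store].
#' @inheritParams fusion_decision
#' @return Data frame of decisions (possibly zero rows).
#' @export
propose_fusions <- function(store, j_hi = 0.8, j_lo = 0.2, o_hi = 0.6) {
  tri <- store$triples
  sig <- paste(entity_type_of(store, tri$head_id),
               entity_type_of(store, tri$tail_id), sep = "->")
  rel_sig <- unique(data.frame(relation = tri$relation, sig = sig,
                               stringsAsFactors = FALSE))
  out <- list()
  for (s in unique(rel_sig$sig)) {
    rels <- sort(rel_sig$relation[rel_sig$sig == s])
    if (length(rels) < 2L) next
    profs <- lapply(rels, relation_profile, store = store)
    for (i in seq_len(length(rels) - 1L))
      for (k in seq(i + 1L, length(rels)))
        out[[length(out) + 1L]] <- fusion_decision(profs[[i]], profs[[k]],
                                                   j_hi, j_lo, o_hi)
  }
  if (length(out) == 0L)
    return(data.frame(relation_a = character(0), relation_b = character(0),
                      jaccard = numeric(0), overlap = numeric(0),
                      action = character(0), survivor = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Apply fusion decisions to a store
#'
#' Merged relations are renamed to their survivor (merge chains are resolved
#' by union-find; conflicting chains raise a consistency error), and
#' duplicate triples created by the renaming are removed.
#'
#' @param store A [kg_store].
#' @param decisions Data frame from [fusion_decision]/[propose_fusions].
#' @return List with `store` (fused) and `report` (removed relations and
#'   triple-count delta).
#' @export
fuse_relations <- function(store, decisions) {
  merges <- decisions[decisions$action == "merge", , drop = FALSE]
  rename <- stats::setNames(store$relations, store$relations)
  find <- function(r) { while (rename[[r]] != r) r <- rename[[r]]; r }
  if (nrow(merges) > 0L) {
    for (i in seq_len(nrow(merges))) {
      a <- find(merges$relation_a[i]); b <- find(merges$relation_b[i])
      s <- merges$survivor[i]
      if (!(s %in% c(merges$relation_a[i], merges$relation_b[i])))
        config_error(sprintf("survivor %s is neither member of the pair", s))
      s <- find(s)
      loser <- setdiff(c(a, b), s)
      if (length(loser) > 1L)
        integrity_error(sprintf(
          "conflicting survivors in merge chain involving %s / %s", a, b))
      if (length(loser) == 1L) rename[[loser]] <- s
    }
  }
  resolved <- vapply(store$relations, find, character(1))
  tri <- store$triples
  tri$relation <- unname(resolved[tri$relation])
  fused <- kg_store(store$entities, tri)
  removed <- names(resolved)[resolved != names(resolved)]
  list(store = fused,
       report = list(removed_relations = removed,
                     triples_before = nrow(store$triples),
                     triples_after = nrow(fused$triples),
                     delta = nrow(store$triples) - nrow(fused$triples)))
}

normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x
}

#' Align entities across sources by normalized name and type
#'
#' Records with equal normalized name (case-folded, whitespace-collapsed,
#' end punctuation stripped) and equal entity type merge into one entity
#' that keeps all source provenance (semicolon-joined `source_db`). No fuzzy
#' matching is attempted.
#'
#' @param tables A list of entity data frames (one per source) or a single
#'   combined data frame.
#' @return List with `entities` (aligned data frame; the first-seen id wins)
#'   and `report` (merge counts per entity type).
#' @export
align_entities <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  all <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[entity_columns]))
  if (is.null(all) || nrow(all) == 0L)
    return(list(entities = data.frame(entity_id = character(0),
                                      name = character(0),
                                      entity_type = character(0),
                                      source_db = character(0),
                                      stringsAsFactors = FALSE),
                report = list(merges_per_type = integer(0),
                              id_map = stats::setNames(character(0),
                                                       character(0)))))
  key <- paste(normalize_name(all$name), all$entity_type, sep = "\r")
  grp <- match(key, unique(key))
  keep <- !duplicated(grp)
  merged <- all[keep, , drop = FALSE]
  merged$source_db <- vapply(split(all$source_db, grp), function(s)
    paste(unique(s), collapse = ";"), character(1))[as.character(unique(grp))]
  id_map <- stats::setNames(merged$entity_id[grp], all$entity_id)
  merges <- table(all$entity_type[!keep])
  rownames(merged) <- NULL
  list(entities = merged,
       report = list(merges_per_type = merges, id_map = id_map))
}

#' Per-source triple counts and contribution percentages
#'
#' @param x A [kg_store] (tabulated by `source_db`) or a named numeric vector
#'   of per-source triple counts.
#' @param total Optional total to use as the percentage denominator; defaults
#'   to `sum(counts)`.
#' @return Data frame (source, triples, percentage) with percentages rounded
#'   to two decimals; they sum to 100 within rounding.
#' @export
source_contribution <- function(x, total = NULL) {
  counts <- if (inherits(x, "kg_store")) {
    tab <- table(x$triples$source_db)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    if (is.null(names(x))) argument_error("counts must be named by source")
    x
  }
  if (is.null(total)) total <- sum(counts)
  data.frame(source = names(counts),
             triples = as.numeric(counts),
             percentage = round(100 * as.numeric(counts) / total, 2),
             stringsAsFactors = FALSE)
}

#' Shared gene targets between two medical systems
#'
#' A gene is "shared" when it is adjacent (either direction, any relation)
#' to at least one entity of a traditional-medicine type and at least one of
#' a modern-medicine type. Per-system intersection counts are reported as
#' percentages of the shared-gene count, one decimal.
#'
#' @param store A [kg_store].
#' @param tcm_types,mm_types Disjoint character vectors of entity types
#'   defining the two systems.
#' @return List with `shared_genes`, `n_shared`, and a per-system data frame
#'   of intersection counts/percentages.
#' @export
shared_target_stats <- function(store,
                                tcm_types = c("Herb", "Ingredient",
                                              "SymptomTCM", "Syndrome"),
                                mm_types = c("Compound", "DiseaseMM",
                                             "SymptomMM", "Pathway")) {
  if (length(tcm_types) == 0L || length(mm_types) == 0L)
    config_error("both system type sets must be non-empty")
  if (length(intersect(tcm_types, mm_types)) > 0L)
    config_error("system type sets must be disjoint")
  tri <- store$triples
  ht <- entity_type_of(store, tri$head_id)
  tt <- entity_type_of(store, tri$tail_id)
  gene_touching <- function(types) {
    unique(c(tri$tail_id[ht %in% types & tt == "Gene"],
             tri$head_id[tt %in% types & ht == "Gene"]))
  }
  tcm_genes <- gene_touching(tcm_types)
  mm_genes <- gene_touching(mm_types)
  shared <- intersect(tcm_genes, mm_genes)
  n <- length(shared)
  ## Venn-style statistic: shared genes adjacent to every type of a system.
  all_types_hit <- function(types) {
    hit <- shared
    for (ty in types) hit <- intersect(hit, gene_touching(ty))
    hit
  }
  per_system <- data.frame(
    system = c("TCM", "MM"),
    intersection = c(length(all_types_hit(tcm_types)),
                     length(all_types_hit(mm_types))),
    stringsAsFactors = FALSE)
  per_system$percentage <- if (n > 0)
    round(100 * per_system$intersection / n, 1) else NA_real_
  list(shared_genes = sort(shared), n_shared = n, per_system = per_system)
}

#' Percentage of a shared-target subset, one decimal
#'
#' Audit arithmetic used when quoting system intersections: `100 * count /
#' shared`, rounded to one decimal place.
#'
#' @param count Intersection count.
#' @param shared Shared-gene total.
#' @return Percentage rounded to one decimal.
#' @export
system_share <- function(count, shared) round(100 * count / shared, 1)
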