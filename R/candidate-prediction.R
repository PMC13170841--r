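## Gene-bridged, meta-path-constrained candidate ranking: drugs are scored
## against a disease through the genes the disease is known to touch, under
## a fixed set of bridging relations.

#' Default bridge relations
#'
#' The six drug-gene relations used as meta-path constraints. Relations
#' whose head slot is the Gene (here `Gene:is_associated_with:Compound`)
#' are scored with the candidate in the tail slot.
#'
#' @return Data frame with `relation` and `candidate_slot` ("head"/"tail").
#' @export
default_bridge_relations <- function() {
  data.frame(
    relation = c("bind", "downregulate", "upregulate", "act_on",
                 "is_associated_with", "is_associated_with"),
    candidate_slot = c("head", "head", "head", "head", "tail", "head"),
    stringsAsFactors = FALSE)
}

#' Genes adjacent to a disease
#'
#' All Gene entities adjacent to the disease in either direction under any
#' relation; these act as the semantic bridge for candidate scoring.
#'
#' @param store A [kg_store].
#' @param disease_id Disease entity id.
#' @return Sorted character vector of gene ids.
#' @export
disease_gene_bridge <- function(store, disease_id) {
  if (!has_entity(store, disease_id))
    lookup_error(sprintf("unknown disease: %s", disease_id))
  nb <- kg_neighbors(store, disease_id, "both")
  genes <- nb$neighbor_id[entity_type_of(store, nb$neighbor_id) == "Gene"]
  sort(unique(genes))
}

#' Rank drug candidates against a disease
#'
#' Each candidate of an allowed type is scored over the grid of (bridge
#' relation, bridge gene) embedding scores; the candidate's score is the
#' mean of its top `m` grid values (rewarding multi-target support while
#' resisting single-pair outliers; `m = Inf` gives the plain mean,
#' `aggregate = "max"` the maximum). Candidates are sorted by score
#' descending, ties broken by entity id; the top `top_k` per type are kept.
#'
#' @param object A `kg_embedding`.
#' @param store A [kg_store].
#' @param disease_id Disease entity id.
#' @param bridge_relations Data frame as [default_bridge_relations()];
#'   relations absent from the embedding vocabulary are ignored.
#' @param candidate_types Subset of `c("Herb", "Compound")`.
#' @param top_k Retained candidates per type (default 100).
#' @param m Top grid values averaged per candidate (default 5).
#' @param aggregate `"topm"`, `"mean"` or `"max"`.
#' @param exclude_known Drop (candidate, relation, gene) grid cells already
#'   present as store triples.
#' @return Data frame (rank, entity_id, name, type, score), per-type blocks.
#' @export
rank_candidates <- function(object, store, disease_id,
                            bridge_relations = default_bridge_relations(),
                            candidate_types = c("Herb", "Compound"),
                            top_k = 100L, m = 5L,
                            aggregate = c("topm", "mean", "max"),
                            exclude_known = FALSE) {
  aggregate <- match.arg(aggregate)
  genes <- disease_gene_bridge(store, disease_id)
  if (length(genes) == 0L)
    argument_error(sprintf("disease %s has no gene neighbors", disease_id))
  bridge_relations <- bridge_relations[
    bridge_relations$relation %in% object$relation_ids, , drop = FALSE]
  if (nrow(bridge_relations) == 0L)
    argument_error("no bridge relation present in the embedding vocabulary")
  gi <- match(genes, object$entity_ids)
  tab <- object[c("E_re", "E_im", "R_re", "R_im")]
  tn <- object$config$transe_norm
  known_keys <- paste(store$triples$head_id, store$triples$relation,
                      store$triples$tail_id)
  out <- list()
  for (ty in candidate_types) {
    cand <- store$entities[store$entities$entity_type == ty, , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning(sprintf("no entities of candidate type %s in the store", ty))
      next
    }
    scores <- numeric(nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      ce <- match(cand$entity_id[ci], object$entity_ids)
      grid <- numeric(0)
      for (bi in seq_len(nrow(bridge_relations))) {
        r <- match(bridge_relations$relation[bi], object$relation_ids)
        slot <- bridge_relations$candidate_slot[bi]
        s <- if (slot == "head")
          batch_scores(tab, object$model, rep(ce, length(gi)),
                       rep(r, length(gi)), gi, tn)
        else
          batch_scores(tab, object$model, gi, rep(r, length(gi)),
                       rep(ce, length(gi)), tn)
        if (exclude_known) {
          keys <- if (slot == "head")
            paste(cand$entity_id[ci], bridge_relations$relation[bi], genes)
          else
            paste(genes, bridge_relations$relation[bi], cand$entity_id[ci])
          s <- s[!(keys %in% known_keys)]
        }
        grid <- c(grid, s)
      }
      scores[ci] <- if (length(grid) == 0L) -Inf
        else switch(aggregate,
          topm = mean(sort(grid, decreasing = TRUE)[
            seq_len(min(m, length(grid)))]),
          mean = mean(grid),
          max = max(grid))
    }
    ord <- order(-scores, cand$entity_id, method = "radix")
    keep <- ord[seq_len(min(top_k, length(ord)))]
    out[[ty]] <- data.frame(rank = seq_along(keep),
                            entity_id = cand$entity_id[keep],
                            name = cand$name[keep],
                            type = ty,
                            score = scores[keep],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
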