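## DFS path enumeration and the unified path scoring system:
##   score = BaseScore x Decay(L) x C_effective x Bonus
## BaseScore is the geometric mean of relation and entity weights along the
## path; ingredients are down-weighted by a TF-IDF-style specificity index;
## rule-derived and search-derived paths are put on one confidence scale by
## the calibration factor lambda_dfs.

#' Construct a mechanistic path
#'
#' @param nodes Entity id sequence e0..eL.
#' @param relations Relation sequence r1..rL (length one less than nodes).
#' @param node_types Entity types of `nodes`.
#' @param origin `"DFS"` or `"Rule"`.
#' @param c_rule Rule confidence, required when `origin = "Rule"`.
#' @return Object of class `kg_path`.
#' @export
kg_path <- function(nodes, relations, node_types, origin = c("DFS", "Rule"),
                    c_rule = NA_real_) {
  origin <- match.arg(origin)
  if (length(nodes) != length(relations) + 1L)
    argument_error("node count must be relation count + 1")
  if (length(node_types) != length(nodes))
    argument_error("node_types must match nodes")
  structure(list(nodes = as.character(nodes),
                 relations = as.character(relations),
                 node_types = as.character(node_types),
                 length = length(relations),
                 origin = origin, c_rule = c_rule),
            class = "kg_path")
}

path_key <- function(path)
  paste(paste(path$nodes, collapse = "|"),
        paste(path$relations, collapse = "|"), sep = "#")

#' @export
format.kg_path <- function(x, ...) {
  out <- x$nodes[1]
  for (i in seq_len(x$length))
    out <- paste0(out, "→", x$relations[i], "→", x$nodes[i + 1])
  out
}

#' @export
print.kg_path <- function(x, ...) {
  cat(sprintf("<kg_path %s L=%d> %s\n", x$origin, x$length, format(x)))
  invisible(x)
}

#' Enumerate simple paths between two entities by bounded DFS
#'
#' All simple (no repeated node) paths of length at most `config$max_hops`
#' from `source` to `target`, traversing edges forward and, for relations
#' listed in `config$symmetric_relations`, also backward. Enumeration order
#' is deterministic (neighbors visited in (relation, neighbor) order).
#'
#' @param store A [kg_store].
#' @param source,target Entity ids (must differ).
#' @param config A [scoring_config].
#' @return List of [kg_path] objects with origin `"DFS"`.
#' @export
dfs_paths <- function(store, source, target, config = scoring_config()) {
  if (!has_entity(store, source)) lookup_error(paste("unknown entity:", source))
  if (!has_entity(store, target)) lookup_error(paste("unknown entity:", target))
  if (identical(source, target)) argument_error("source must differ from target")
  max_hops <- config$max_hops
  sym <- config$symmetric_relations
  tri <- store$triples
  expand <- function(node) {
    oi <- store$out_index[[node]]
    ii <- store$in_index[[node]]
    nb <- data.frame(relation = c(tri$relation[oi], tri$relation[ii]),
                     neighbor = c(tri$tail_id[oi], tri$head_id[ii]),
                     forward = c(rep(TRUE, length(oi)), rep(FALSE, length(ii))),
                     stringsAsFactors = FALSE)
    nb <- nb[nb$forward | nb$relation %in% sym, , drop = FALSE]
    nb <- nb[!duplicated(paste(nb$relation, nb$neighbor)), , drop = FALSE]
    nb[order(nb$relation, nb$neighbor), , drop = FALSE]
  }
  results <- list()
  walk <- function(node, nodes, rels) {
    depth <- length(rels)
    if (depth >= max_hops) return()
    nb <- expand(node)
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$neighbor[i]
      if (nxt %in% nodes) next
      if (identical(nxt, target)) {
        results[[length(results) + 1L]] <<-
          kg_path(c(nodes, nxt), c(rels, nb$relation[i]),
                  entity_type_of(store, c(nodes, nxt)), origin = "DFS")
      } else {
        walk(nxt, c(nodes, nxt), c(rels, nb$relation[i]))
      }
    }
  }
  walk(source, source, character(0))
  results
}

#' Weight of a relation given its endpoint types
#'
#' Gene-gene relations with experimental evidence get 1.0, other gene-gene
#' relations 0.9, everything else the baseline weight.
#'
#' @param relation Relation name.
#' @param endpoint_types Length-2 character vector of endpoint entity types.
#' @param config A [scoring_config].
#' @return Numeric weight.
#' @export
relation_weight <- function(relation, endpoint_types,
                            config = scoring_config()) {
  if (all(endpoint_types == "Gene")) {
    if (relation %in% config$evidence_relations) 1.0
    else config$other_gene_gene_weight
  } else config$w_base
}

#' Ingredient specificity factor and weight
#'
#' `isi_factor` is `max(isi_floor, ln(N / (df + 1)) / ln N)`; the weight is
#' the ingredient's pre-ISI weight times this factor. Ubiquitous ingredients
#' (df near N) are floored at `isi_floor`; unseen ingredients (df = 0) keep
#' almost full weight.
#'
#' @param df Document frequency of the ingredient (herbs containing it).
#' @param index A `kg_ifi` (used for N when `df` is not given directly).
#' @param config A [scoring_config].
#' @return The specificity factor in \[isi_floor, 1\].
#' @export
isi_factor <- function(df, index, config = scoring_config()) {
  n <- index$n_herbs
  if (n < 2) config_error("ISI needs at least 2 herbs (ln N > 0)")
  max(config$isi_floor, log(n / (df + 1)) / log(n))
}

#' @rdname isi_factor
#' @param weight Pre-ISI weight of the ingredient.
#' @param ingredient Ingredient entity id (df looked up in `index`, 0 when
#'   unseen).
#' @export
isi_weight <- function(weight, index, ingredient,
                       config = scoring_config()) {
  df <- unname(index$df[ingredient])
  if (length(df) != 1L || is.na(df)) df <- 0
  weight * isi_factor(df, index, config)
}

#' Weight of an entity given its type
#'
#' Mechanism-associated types (Herb, Gene, Compound) carry full weight 1.0;
#' Ingredients carry 1.0 scaled by the specificity factor; all other types
#' get the baseline weight.
#'
#' @param entity Entity id (used for the ingredient df lookup).
#' @param entity_type Entity type string.
#' @param config A [scoring_config].
#' @param index A `kg_ifi`.
#' @return Numeric weight.
#' @export
entity_weight <- function(entity, entity_type, config = scoring_config(),
                          index = frequency_index(2)) {
  if (entity_type == "Ingredient")
    isi_weight(1.0, index, entity, config)
  else if (entity_type %in% config$mech_entity_types) 1.0
  else config$w_base
}

#' Geometric-mean base score of a path
#'
#' `(prod_{i=1..L} w_{r_i} * w_{e_i})^(1/L)`: the product runs over the L
#' edges and the entities e_1..e_L they lead to; the head entity e_0 is not
#' part of the mean. Computed in log domain for numerical stability.
#'
#' @param path A [kg_path].
#' @param config A [scoring_config].
#' @param index A `kg_ifi`.
#' @return Base score in (0, 1].
#' @export
base_score <- function(path, config = scoring_config(),
                       index = frequency_index(2)) {
  L <- path$length
  logs <- 0
  for (i in seq_len(L)) {
    wr <- relation_weight(path$relations[i],
                          path$node_types[c(i, i + 1L)], config)
    we <- entity_weight(path$nodes[i + 1L], path$node_types[i + 1L],
                        config, index)
    logs <- logs + log(wr) + log(we)
  }
  exp(logs / L)
}

#' Length decay factor
#'
#' 1.0 for paths of at most two hops, `decay_base^(L - 2)` beyond.
#'
#' @param L Path length in hops (1..max_hops).
#' @param config A [scoring_config].
#' @return Decay factor in (0, 1].
#' @export
path_decay <- function(L, config = scoring_config()) {
  if (L < 1 || L > config$max_hops)
    argument_error(sprintf("path length %d outside 1..%d", L, config$max_hops))
  if (L <= 2) 1.0 else config$decay_base^(L - 2)
}

#' Hybrid effective confidence
#'
#' Rule-derived paths keep their rule confidence (clamped at 1); DFS paths
#' take `base * lambda_dfs` (clamped at 1) so deterministic search shares a
#' scale with probabilistic rules.
#'
#' @param path A [kg_path].
#' @param base The path's base score.
#' @param config A [scoring_config].
#' @return Effective confidence in (0, 1].
#' @export
effective_confidence <- function(path, base, config = scoring_config()) {
  if (path$origin == "Rule") {
    if (is.na(path$c_rule))
      integrity_error("rule-derived path lacks a rule confidence")
    min(1.0, path$c_rule)
  } else {
    min(1.0, base * config$lambda_dfs)
  }
}

#' Mechanism bonus
#'
#' Starts at 1.0; multiplied by `bonus_structural` when the path contains a
#' Gene node or a specific Ingredient (specificity factor at least the
#' configured fraction), by `bonus_evidence` when any relation is an
#' evidence relation or `includes`; the product is capped at `bonus_cap`.
#'
#' @param path A [kg_path].
#' @param config A [scoring_config].
#' @param index A `kg_ifi`.
#' @return Bonus factor in \[1, bonus_cap\].
#' @export
path_bonus <- function(path, config = scoring_config(),
                       index = frequency_index(2)) {
  b <- 1.0
  structural <- "Gene" %in% path$node_types
  if (!structural) {
    ing <- which(path$node_types == "Ingredient")
    for (i in ing) {
      f <- isi_weight(1.0, index, path$nodes[i], config)
      if (f >= config$specific_ingredient_threshold * 1.0) {
        structural <- TRUE
        break
      }
    }
  }
  if (structural) b <- b * config$bonus_structural
  if (any(path$relations %in% config$bonus_trigger_relations))
    b <- b * config$bonus_evidence
  min(b, config$bonus_cap)
}

#' Unified path score with component breakdown
#'
#' @param path A [kg_path].
#' @param config A [scoring_config].
#' @param index A `kg_ifi`.
#' @return Object of class `kg_path_score`: list with `base`, `decay`,
#'   `c_effective`, `bonus` and `score` (their exact product, full
#'   precision; printed to 4 decimals).
#' @export
score_path <- function(path, config = scoring_config(),
                       index = frequency_index(2)) {
  base <- base_score(path, config, index)
  dec <- path_decay(path$length, config)
  ce <- effective_confidence(path, base, config)
  bo <- path_bonus(path, config, index)
  structure(list(base = base, decay = dec, c_effective = ce, bonus = bo,
                 score = base * dec * ce * bo),
            class = "kg_path_score")
}

#' @export
print.kg_path_score <- function(x, ...) {
  cat(sprintf("base %.4f x decay %.4f x c_eff %.4f x bonus %.4f = %.4f\n",
              x$base, x$decay, x$c_effective, x$bonus, x$score))
  invisible(x)
}

#' Merge, score and rank rule- and DFS-derived paths
#'
#' Paths with identical node/relation sequences appearing in both inputs
#' are kept once with rule provenance (rules carry explicit confidence and
#' must not be drowned out by duplicate search paths). Sorted by score
#' descending; ties broken by shorter length, then lexicographic node ids.
#'
#' @param rule_paths,dfs_paths Lists of [kg_path] objects.
#' @param config A [scoring_config].
#' @param index A `kg_ifi`.
#' @param k Number of top paths to keep.
#' @return Object of class `kg_ranked_paths`: list of entries, each with
#'   `path` and `breakdown`, plus a `table` attribute.
#' @export
rank_paths <- function(rule_paths, dfs_paths, config = scoring_config(),
                       index = frequency_index(2), k = 10L) {
  if (k <= 0) argument_error("k must be positive")
  all <- c(rule_paths, dfs_paths)
  if (length(all) == 0L)
    return(structure(list(), class = "kg_ranked_paths"))
  keys <- vapply(all, path_key, character(1))
  is_rule <- vapply(all, function(p) p$origin == "Rule", logical(1))
  ## rule provenance preferred on duplicates
  ord0 <- order(!is_rule)
  all <- all[ord0][!duplicated(keys[ord0])]
  scored <- lapply(all, score_path, config = config, index = index)
  score <- vapply(scored, function(s) s$score, numeric(1))
  len <- vapply(all, function(p) p$length, numeric(1))
  firstnode <- vapply(all, function(p) paste(p$nodes, collapse = "|"),
                      character(1))
  ord <- order(-score, len, firstnode, method = "radix")
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- lapply(keep, function(i) list(path = all[[i]],
                                       breakdown = scored[[i]]))
  structure(out, class = "kg_ranked_paths")
}

#' @export
print.kg_ranked_paths <- function(x, ...) {
  if (length(x) == 0L) { cat("<kg_ranked_paths> empty\n"); return(invisible(x)) }
  cat(sprintf("<kg_ranked_paths> top %d\n", length(x)))
  for (i in seq_along(x)) {
    e <- x[[i]]
    cat(sprintf("%2d. [%s] %.4f  %s\n", i, e$path$origin,
                e$breakdown$score, format(e$path)))
  }
  invisible(x)
}

#' @export
as.data.frame.kg_ranked_paths <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(rank = integer(0), path = character(0),
                      origin = character(0), base = numeric(0),
                      decay = numeric(0), c_eff = numeric(0),
                      bonus = numeric(0), score = numeric(0)))
  data.frame(
    rank = seq_along(x),
    path = vapply(x, function(e) format(e$path), character(1)),
    origin = vapply(x, function(e) e$path$origin, character(1)),
    base = vapply(x, function(e) e$breakdown$base, numeric(1)),
    decay = vapply(x, function(e) e$breakdown$decay, numeric(1)),
    c_eff = vapply(x, function(e) e$breakdown$c_effective, numeric(1)),
    bonus = vapply(x, function(e) e$breakdown$bonus, numeric(1)),
    score = vapply(x, function(e) e$breakdown$score, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Explain a drug-disease link by ranked mechanistic paths
#'
#' Convenience wrapper: enumerate DFS paths, ground the given rules between
#' source and target, and rank the merged set.
#'
#' @param store A [kg_store].
#' @param source,target Entity ids.
#' @param rules Optional list of `kg_rule` objects to ground.
#' @param config A [scoring_config].
#' @param index A `kg_ifi`; computed from the store when `NULL`.
#' @param k Top paths to keep.
#' @return A `kg_ranked_paths`.
#' @export
kg_explain <- function(store, source, target, rules = list(),
                       config = scoring_config(), index = NULL, k = 10L) {
  if (is.null(index)) index <- ingredient_frequency_index(store)
  dfs <- dfs_paths(store, source, target, config)
  rp <- list()
  for (r in rules)
    rp <- c(rp, ground_rule(r, store, source, target))
  rank_paths(rp, dfs, config, index, k)
}
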