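#' Scoring configuration for the unified path score
#'
#' Collects every tunable of the path scoring system. Defaults are the
#' baseline configuration: baseline weight 0.7, non-evidence gene-gene
#' weight 0.9, calibration factor 0.2, decay base 0.9, bonus tiers 1.2
#' (structural) and 1.5 (evidence) capped at 1.8, ISI floor 0.01, at most
#' 4 hops.
#'
#' @param w_base Baseline weight for entity and relation types without a
#'   mechanistic role (default 0.7).
#' @param mech_entity_types Entity types carrying full weight 1.0.
#' @param evidence_relations Gene-gene relations with direct or transferred
#'   experimental support; weighted 1.0 and bonus triggers.
#' @param other_gene_gene_weight Weight of gene-gene relations without
#'   evidence labels (default 0.9).
#' @param lambda_dfs Calibration factor scaling DFS path confidences onto
#'   the rule-confidence scale (default 0.2).
#' @param decay_base Per-extra-hop decay beyond two hops (default 0.9).
#' @param max_hops Maximum path length in edges (default 4).
#' @param isi_floor Lower bound of the ingredient specificity factor
#'   (default 0.01). Setting it to 1.0 disables the ISI.
#' @param bonus_structural Bonus tier for paths containing a Gene node or a
#'   specific Ingredient (default 1.2).
#' @param bonus_evidence Bonus tier for paths containing an evidence or
#'   `includes` relation (default 1.5).
#' @param bonus_cap Cap on the combined bonus (default 1.8).
#' @param specific_ingredient_threshold An Ingredient counts as "specific"
#'   when its ISI factor is at least this fraction of its full weight
#'   (default 0.5).
#' @param bonus_trigger_relations Relations triggering the evidence bonus;
#'   defaults to the evidence relations plus `includes`.
#' @param symmetric_relations Relations traversable against edge direction
#'   during DFS (undirected gene-gene interaction sources).
#' @return Object of class `kg_scoring_config`.
#' @export
scoring_config <- function(w_base = 0.7,
                           mech_entity_types = c("Herb", "Ingredient",
                                                 "Gene", "Compound"),
                           evidence_relations = c("experiments",
                                                  "experiments_transferred"),
                           other_gene_gene_weight = 0.9,
                           lambda_dfs = 0.2,
                           decay_base = 0.9,
                           max_hops = 4L,
                           isi_floor = 0.01,
                           bonus_structural = 1.2,
                           bonus_evidence = 1.5,
                           bonus_cap = 1.8,
                           specific_ingredient_threshold = 0.5,
                           bonus_trigger_relations = NULL,
                           symmetric_relations = c("experiments",
                                                   "experiments_transferred",
                                                   "synergizewith")) {
  if (is.null(bonus_trigger_relations))
    bonus_trigger_relations <- c(evidence_relations, "includes")
  cfg <- list(w_base = w_base, mech_entity_types = mech_entity_types,
              evidence_relations = evidence_relations,
              other_gene_gene_weight = other_gene_gene_weight,
              lambda_dfs = lambda_dfs, decay_base = decay_base,
              max_hops = as.integer(max_hops), isi_floor = isi_floor,
              bonus_structural = bonus_structural,
              bonus_evidence = bonus_evidence, bonus_cap = bonus_cap,
              specific_ingredient_threshold = specific_ingredient_threshold,
              bonus_trigger_relations = bonus_trigger_relations,
              symmetric_relations = symmetric_relations)
  stopifnot(cfg$w_base > 0, cfg$w_base <= 1,
            cfg$lambda_dfs > 0, cfg$lambda_dfs <= 1,
            cfg$decay_base > 0, cfg$decay_base <= 1,
            cfg$max_hops >= 1)
  class(cfg) <- "kg_scoring_config"
  cfg
}

#' Ingredient document-frequency index
#'
#' For the specificity index: `n_herbs` is the total number of herb
#' entities N and `df[i]` the number of distinct herbs containing
#' ingredient i (counted over all Herb -> Ingredient edges, regardless of
#' relation name). Ingredients never seen in a herb have df 0.
#'
#' @param store A [kg_store].
#' @return Object of class `kg_ifi`: list with `n_herbs` and named numeric
#'   `df`.
#' @export
ingredient_frequency_index <- function(store) {
  types_h <- entity_type_of(store, store$triples$head_id)
  types_t <- entity_type_of(store, store$triples$tail_id)
  hi <- types_h == "Herb" & types_t == "Ingredient"
  ih <- types_h == "Ingredient" & types_t == "Herb"
  pairs <- unique(rbind(
    data.frame(herb = store$triples$head_id[hi],
               ing = store$triples$tail_id[hi], stringsAsFactors = FALSE),
    data.frame(herb = store$triples$tail_id[ih],
               ing = store$triples$head_id[ih], stringsAsFactors = FALSE)))
  df <- if (nrow(pairs) > 0) table(pairs$ing) else table(character(0))
  structure(list(
    n_herbs = sum(store$entities$entity_type == "Herb"),
    df = stats::setNames(as.numeric(df), names(df))
  ), class = "kg_ifi")
}

#' Manually built document-frequency index
#'
#' @param n_herbs Total herb count N.
#' @param df Named numeric vector of per-ingredient document frequencies.
#' @return Object of class `kg_ifi`.
#' @export
frequency_index <- function(n_herbs, df = numeric(0)) {
  structure(list(n_herbs = n_herbs, df = df), class = "kg_ifi")
}
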