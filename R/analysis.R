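## Sensitivity and ablation harnesses for the path scoring system: the
## lambda_dfs sweep, IoU rank-consistency across configuration variants,
## and the ablation metrics (average ISI, evidence ratio, rule contribution).

#' Fraction of rule-derived paths in a ranked list
#'
#' @param topk A `kg_ranked_paths` or list of entries with `$path`.
#' @return Fraction in \[0, 1\].
#' @export
rule_ratio <- function(topk) {
  if (length(topk) == 0L) argument_error("ranked path list is empty")
  mean(vapply(topk, function(e) e$path$origin == "Rule", logical(1)))
}

#' Sweep the DFS calibration factor
#'
#' Re-ranks the merged rule/DFS path pool at each lambda value and reports
#' the rule ratio and mean score of the top-k list. Because lambda scales
#' only DFS confidences, the rule ratio is non-increasing in lambda.
#'
#' @param rule_paths,dfs_paths Lists of [kg_path] objects.
#' @param config A [scoring_config] (its `lambda_dfs` is overridden).
#' @param index A `kg_ifi`.
#' @param grid Lambda values (default covers \[0.05, 1\]).
#' @param k Top-list size.
#' @return Data frame (lambda, rule_ratio, mean_score).
#' @export
lambda_sweep <- function(rule_paths, dfs_paths, config = scoring_config(),
                         index = frequency_index(2),
                         grid = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                         k = 10L) {
  if (length(grid) == 0L) argument_error("lambda grid is empty")
  rows <- lapply(grid, function(lam) {
    cfg <- config
    cfg$lambda_dfs <- lam
    top <- rank_paths(rule_paths, dfs_paths, cfg, index, k)
    data.frame(lambda = lam,
               rule_ratio = if (length(top) > 0) rule_ratio(top) else NA_real_,
               mean_score = if (length(top) > 0)
                 mean(vapply(top, function(e) e$breakdown$score, numeric(1)))
               else NA_real_)
  })
  do.call(rbind, rows)
}

#' Intersection-over-union of two top-k path lists
#'
#' Paths are compared by node/relation sequence identity; list order is
#' irrelevant.
#'
#' @param list_a,list_b `kg_ranked_paths` objects or lists of [kg_path].
#' @return Value in \[0, 1\].
#' @export
path_iou <- function(list_a, list_b) {
  keys <- function(l) unique(vapply(l, function(e) {
    p <- if (!is.null(e$path)) e$path else e
    path_key(p)
  }, character(1)))
  a <- keys(list_a); b <- keys(list_b)
  if (length(a) == 0L && length(b) == 0L)
    argument_error("IoU undefined for two empty lists")
  length(intersect(a, b)) / length(union(a, b))
}

#' Ablation metrics of a ranked path list
#'
#' `avg_isi`: mean specificity factor over all Ingredient node occurrences
#' across the paths (0 when no path contains an ingredient); `evidence_ratio`:
#' fraction of edges whose relation carries experimental evidence;
#' `rule_contribution`: fraction of rule-derived paths.
#'
#' @param topk A `kg_ranked_paths`.
#' @param config A [scoring_config].
#' @param index A `kg_ifi`.
#' @return List with `avg_isi`, `evidence_ratio`, `rule_contribution`.
#' @export
ablation_metrics <- function(topk, config = scoring_config(),
                             index = frequency_index(2)) {
  if (length(topk) == 0L) argument_error("ranked path list is empty")
  isis <- numeric(0)
  n_edges <- 0L
  n_evid <- 0L
  for (e in topk) {
    p <- e$path
    ing <- which(p$node_types == "Ingredient")
    for (i in ing)
      isis <- c(isis, isi_weight(1.0, index, p$nodes[i], config))
    n_edges <- n_edges + p$length
    n_evid <- n_evid + sum(p$relations %in% config$evidence_relations)
  }
  list(avg_isi = if (length(isis) > 0) mean(isis) else 0,
       evidence_ratio = if (n_edges > 0) n_evid / n_edges else 0,
       rule_contribution = rule_ratio(topk))
}

#' Table of standard sensitivity variants
#'
#' The baseline plus single-dimension perturbations: weight flattening /
#' sharpening, decay removal / strengthening, bonus removal / inflation,
#' and ISI removal (floor raised to 1).
#'
#' @return Named list of override lists.
#' @export
standard_variants <- function() {
  list(
    baseline = list(),
    no_weight_distinction = list(w_base = 1.0, other_gene_gene_weight = 1.0),
    strong_weight_distinction = list(w_base = 0.2),
    no_decay = list(decay_base = 1.0),
    strong_decay = list(decay_base = 0.5),
    no_bonus = list(bonus_structural = 1.0, bonus_evidence = 1.0,
                    bonus_cap = 1.0),
    high_bonus = list(bonus_cap = 5.0),
    no_isi = list(isi_floor = 1.0)
  )
}

apply_overrides <- function(config, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(config))
      config_error(sprintf("unknown scoring-config field: %s", nm))
    config[[nm]] <- overrides[[nm]]
  }
  config
}

#' Rank-consistency of configuration variants
#'
#' For each drug, builds the baseline top-k path list, re-ranks the same
#' path pool under each variant, and reports the mean IoU with the baseline
#' across drugs plus the variant's ablation metrics. Drugs without paths
#' are skipped (their count is reported).
#'
#' @param store A [kg_store].
#' @param drugs Character vector of drug entity ids.
#' @param target Target disease entity id.
#' @param rules List of [kg_rule] objects grounded per drug.
#' @param base_config A [scoring_config].
#' @param variants Named list of override lists (see [standard_variants]).
#' @param index A `kg_ifi`; computed from the store when `NULL`.
#' @param k Top-list size.
#' @return List with `iou` (data frame: variant, mean_iou, n_drugs) and
#'   `metrics` (per-variant ablation metrics), plus `n_skipped`.
#' @export
run_variants <- function(store, drugs, target, rules = list(),
                         base_config = scoring_config(),
                         variants = standard_variants(),
                         index = NULL, k = 10L) {
  if (is.null(index)) index <- ingredient_frequency_index(store)
  pools <- list()
  skipped <- 0L
  for (d in drugs) {
    dfs <- dfs_paths(store, d, target, base_config)
    rp <- list()
    for (r in rules) rp <- c(rp, ground_rule(r, store, d, target))
    if (length(dfs) + length(rp) == 0L) { skipped <- skipped + 1L; next }
    pools[[d]] <- list(rule = rp, dfs = dfs)
  }
  baseline_tops <- lapply(pools, function(p)
    rank_paths(p$rule, p$dfs, base_config, index, k))
  rows <- list()
  metrics <- list()
  for (vn in names(variants)) {
    cfg <- apply_overrides(base_config, variants[[vn]])
    ious <- numeric(0)
    all_tops <- list()
    for (d in names(pools)) {
      top <- rank_paths(pools[[d]]$rule, pools[[d]]$dfs, cfg, index, k)
      ious <- c(ious, path_iou(top, baseline_tops[[d]]))
      all_tops <- c(all_tops, top)
    }
    rows[[vn]] <- data.frame(variant = vn,
                             mean_iou = if (length(ious)) mean(ious) else NA,
                             n_drugs = length(ious),
                             stringsAsFactors = FALSE)
    metrics[[vn]] <- if (length(all_tops) > 0)
      ablation_metrics(all_tops, cfg, index) else NULL
  }
  list(iou = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       metrics = metrics, n_skipped = skipped)
}
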