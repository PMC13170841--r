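cfg <- scoring_config()

test_that("relation weights follow the domain-aware scheme", {
  expect_equal(relation_weight("experiments", c("Gene", "Gene"), cfg), 1.0)
  expect_equal(relation_weight("experiments_transferred", c("Gene", "Gene"),
                               cfg), 1.0)
  expect_equal(relation_weight("synergizewith", c("Gene", "Gene"), cfg), 0.9)
  expect_equal(relation_weight("act_on", c("Herb", "Gene"), cfg), 0.7)
  # an evidence-named relation outside gene-gene context stays baseline
  expect_equal(relation_weight("experiments", c("Herb", "Gene"), cfg), 0.7)
})

test_that("ingredient specificity follows ln(N/(df+1))/ln N with floor", {
  idx <- frequency_index(100, c(ubiq = 99, mid = 9, rare = 0))
  # df = 0: full weight
  expect_equal(isi_weight(1.0, idx, "rare", cfg), log(100) / log(100))
  # df = 9, N = 100: exactly half weight
  expect_equal(isi_weight(1.0, idx, "mid", cfg), 0.5)
  expect_equal(isi_weight(0.7, idx, "mid", cfg), 0.35)
  # df = N - 1: ln(1) = 0 -> floor
  expect_equal(isi_weight(1.0, idx, "ubiq", cfg), 0.01)
  # unseen ingredient treated as df = 0
  expect_equal(isi_weight(1.0, idx, "unheard_of", cfg), 1.0)
  expect_error(isi_factor(0, frequency_index(1), cfg),
               class = "cmkg_config_error")
})

test_that("isi is non-increasing in df and bounded", {
  idx100 <- frequency_index(100)
  f <- vapply(0:99, function(d) isi_factor(d, idx100, cfg), numeric(1))
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= cfg$isi_floor & f <= 1))
})

test_that("entity weights distinguish mechanism types and ingredients", {
  idx <- frequency_index(100, c(I1 = 9))
  expect_equal(entity_weight("G1", "Gene", cfg, idx), 1.0)
  expect_equal(entity_weight("H1", "Herb", cfg, idx), 1.0)
  expect_equal(entity_weight("C1", "Compound", cfg, idx), 1.0)
  expect_equal(entity_weight("D1", "DiseaseMM", cfg, idx), 0.7)
  expect_equal(entity_weight("S1", "SymptomTCM", cfg, idx), 0.7)
  expect_equal(entity_weight("I1", "Ingredient", cfg, idx), 0.5)
})

test_that("base score is the geometric mean excluding the head entity", {
  idx <- frequency_index(100)
  # all weights 1: gene-gene evidence chain
  p1 <- make_path(c("Gene", "Gene", "Gene"),
                  c("experiments", "experiments_transferred"))
  expect_equal(base_score(p1, cfg, idx), 1.0)
  # worked 4-hop chain: (0.7*1 x 0.9*1 x 0.9*1 x 0.7*0.7)^(1/4)
  p2 <- chain_4hop()
  expect_equal(base_score(p2, cfg, idx), (0.7 * 0.9 * 0.9 * 0.49)^0.25,
               tolerance = 1e-12)
  expect_equal(round(base_score(p2, cfg, idx), 4), 0.7260)
  # the head entity's weight does not enter the mean: an ubiquitous
  # ingredient head scores like any other head of the same adjacency
  idx_ub <- frequency_index(100, c(UB = 99))
  p3a <- kg_path(c("UB", "G2", "G3"), p1$relations,
                 c("Ingredient", "Gene", "Gene"))
  # relation endpoints differ (Ingredient-Gene vs Gene-Gene), so compare two
  # heads of identical type but wildly different ISI weight
  idx_ra <- frequency_index(100, c(UB = 0))
  expect_equal(base_score(p3a, cfg, idx_ub), base_score(p3a, cfg, idx_ra))
})

test_that("length decay is 1 through two hops then decay_base^(L-2)", {
  expect_equal(path_decay(1, cfg), 1.0)
  expect_equal(path_decay(2, cfg), 1.0)
  expect_equal(path_decay(3, cfg), 0.9)
  expect_equal(path_decay(4, cfg), 0.81)
  expect_error(path_decay(5, cfg), class = "cmkg_argument_error")
  d <- vapply(1:4, path_decay, numeric(1), config = cfg)
  expect_true(all(diff(d) <= 0))
})

test_that("effective confidence calibrates DFS paths and clamps rules", {
  idx <- frequency_index(100)
  rule_p <- make_path(c("Herb", "Gene", "DiseaseMM"), c("act_on", "dysregulate"),
                      origin = "Rule", c_rule = 0.75)
  expect_equal(effective_confidence(rule_p, 0.9, cfg), 0.75)
  rule_hi <- make_path(c("Herb", "Gene", "DiseaseMM"),
                       c("act_on", "dysregulate"),
                       origin = "Rule", c_rule = 1.3)
  expect_equal(effective_confidence(rule_hi, 0.9, cfg), 1.0)
  dfs_p <- chain_4hop()
  base <- base_score(dfs_p, cfg, idx)
  expect_equal(round(effective_confidence(dfs_p, base, cfg), 4), 0.1452)
  missing <- make_path(c("Herb", "Gene", "DiseaseMM"),
                       c("act_on", "dysregulate"), origin = "Rule")
  expect_error(effective_confidence(missing, 0.9, cfg),
               class = "cmkg_integrity_error")
})

test_that("bonus tiers fire on genes, specific ingredients and evidence", {
  idx <- frequency_index(100, c(ubiq = 99, rare = 0))
  none <- make_path(c("Herb", "SymptomTCM", "DiseaseMM"),
                    c("is_associated_with", "is_associated_with"))
  expect_equal(path_bonus(none, cfg, idx), 1.0)
  gene_only <- make_path(c("Herb", "Gene", "DiseaseMM"),
                         c("act_on", "dysregulate"))
  expect_equal(path_bonus(gene_only, cfg, idx), 1.2)
  both <- make_path(c("Herb", "Gene", "Gene", "DiseaseMM"),
                    c("act_on", "experiments", "dysregulate"))
  expect_equal(path_bonus(both, cfg, idx), 1.8)  # min(1.8, 1.2 * 1.5)
  # ubiquitous ingredient does not trigger the structural tier...
  ub <- kg_path(c("H", "ubiq", "D"), c("includes", "is_associated_with"),
                c("Herb", "Ingredient", "DiseaseMM"))
  # ...but its includes edge still fires the evidence tier
  expect_equal(path_bonus(ub, cfg, idx), 1.5)
  rare <- kg_path(c("H", "rare", "D"), c("includes", "is_associated_with"),
                  c("Herb", "Ingredient", "DiseaseMM"))
  expect_equal(path_bonus(rare, cfg, idx), min(1.8, 1.2 * 1.5))
})

test_that("the worked 4-hop chain reproduces its hand-computed breakdown", {
  idx <- frequency_index(100)
  s <- score_path(chain_4hop(), cfg, idx)
  expect_equal(round(s$base, 4), 0.7260)
  expect_equal(s$decay, 0.81)
  expect_equal(round(s$c_effective, 4), 0.1452)
  expect_equal(s$bonus, 1.2)
  expect_equal(round(s$score, 4), 0.1025)
  expect_equal(s$score, s$base * s$decay * s$c_effective * s$bonus)
})

test_that("neutral two-hop path scores exactly one", {
  idx <- frequency_index(100)
  cfg1 <- scoring_config(lambda_dfs = 1.0)
  p <- make_path(c("Gene", "Gene", "Gene"),
                 c("synergizewith", "synergizewith"))
  # gene-gene non-evidence edges weigh 0.9; use evidence for neutrality
  p2 <- make_path(c("Gene", "Gene", "Gene"),
                  c("experiments", "experiments"))
  cfg_nb <- scoring_config(lambda_dfs = 1.0, bonus_structural = 1.0,
                           bonus_evidence = 1.0, bonus_cap = 1.0)
  s <- score_path(p2, cfg_nb, idx)
  expect_equal(s$base, 1); expect_equal(s$decay, 1)
  expect_equal(s$c_effective, 1); expect_equal(s$bonus, 1)
  expect_equal(s$score, 1)
})

test_that("score_path equals an independent single-expression oracle", {
  idx <- frequency_index(50, stats::setNames(sample(0:49, 20, replace = TRUE),
                                             paste0("I", 1:20)))
  set.seed(99)
  types_pool <- c("Herb", "Gene", "Compound", "Ingredient", "DiseaseMM",
                  "SymptomTCM", "Pathway")
  rel_pool <- c("act_on", "synergizewith", "experiments", "includes",
                "dysregulate", "bind", "is_associated_with")
  oracle <- function(p, cfg, idx) {
    L <- p$length
    w <- 1
    for (i in seq_len(L)) {
      tt <- p$node_types[c(i, i + 1)]
      wr <- if (all(tt == "Gene"))
        (if (p$relations[i] %in% cfg$evidence_relations) 1 else 0.9)
      else cfg$w_base
      ty <- p$node_types[i + 1]
      we <- if (ty == "Ingredient") {
        d <- idx$df[[p$nodes[i + 1]]]; if (is.null(d)) d <- 0
        1 * max(cfg$isi_floor, log(idx$n_herbs / (d + 1)) / log(idx$n_herbs))
      } else if (ty %in% cfg$mech_entity_types) 1 else cfg$w_base
      w <- w * wr * we
    }
    base <- w^(1 / L)
    decay <- if (L <= 2) 1 else cfg$decay_base^(L - 2)
    ce <- if (p$origin == "Rule") min(1, p$c_rule)
      else min(1, base * cfg$lambda_dfs)
    spec_ing <- any(vapply(seq_along(p$nodes), function(i) {
      if (p$node_types[i] != "Ingredient") return(FALSE)
      d <- idx$df[[p$nodes[i]]]; if (is.null(d)) d <- 0
      max(cfg$isi_floor, log(idx$n_herbs / (d + 1)) / log(idx$n_herbs)) >=
        cfg$specific_ingredient_threshold
    }, logical(1)))
    b <- 1
    if ("Gene" %in% p$node_types || spec_ing) b <- b * cfg$bonus_structural
    if (any(p$relations %in% cfg$bonus_trigger_relations))
      b <- b * cfg$bonus_evidence
    b <- min(b, cfg$bonus_cap)
    base * decay * ce * b
  }
  for (i in 1:1000) {
    L <- sample(1:4, 1)
    types <- sample(types_pool, L + 1, replace = TRUE)
    ids <- ifelse(types == "Ingredient",
                  sample(paste0("I", 1:20), L + 1, replace = TRUE),
                  paste0("N", seq_len(L + 1)))
    origin <- sample(c("DFS", "Rule"), 1)
    p <- kg_path(ids, sample(rel_pool, L, replace = TRUE), types,
                 origin = origin,
                 c_rule = if (origin == "Rule") stats::runif(1, 0.05, 1.2)
                 else NA_real_)
    expect_equal(score_path(p, cfg, idx)$score, oracle(p, cfg, idx),
                 tolerance = 1e-12)
  }
})

test_that("dfs enumeration matches brute force on a random graph", {
  store <- random_store(n_entities = 12L, n_triples = 40L, seed = 5L)
  src <- store$entities$entity_id[1]
  tgt <- store$entities$entity_id[12]
  cfg0 <- scoring_config(symmetric_relations = character(0))
  got <- dfs_paths(store, src, tgt, cfg0)
  # brute force: forward-only simple paths up to 4 hops over all sequences
  adj <- split(seq_len(nrow(store$triples)), store$triples$head_id)
  brute <- list()
  recur <- function(node, nodes, rels) {
    if (length(rels) >= 4) return()
    for (i in adj[[node]]) {
      nb <- store$triples$tail_id[i]
      if (nb %in% nodes) next
      if (nb == tgt)
        brute[[length(brute) + 1]] <<- paste(
          paste(c(nodes, nb), collapse = "|"),
          paste(c(rels, store$triples$relation[i]), collapse = "|"))
      else recur(nb, c(nodes, nb), c(rels, store$triples$relation[i]))
    }
  }
  recur(src, src, character(0))
  got_keys <- vapply(got, function(p)
    paste(paste(p$nodes, collapse = "|"),
          paste(p$relations, collapse = "|")), character(1))
  expect_setequal(got_keys, unlist(brute))
  expect_false(any(duplicated(got_keys)))
})

test_that("dfs handles direct edges, disconnection, and input errors", {
  store <- tiny_store()
  cfg0 <- scoring_config(symmetric_relations = character(0))
  p <- dfs_paths(store, "GEE00002", "DM01", cfg0)
  expect_equal(length(p), 1L)
  expect_equal(p[[1]]$relations, "dysregulate")
  expect_equal(length(dfs_paths(store, "TS0001", "DM01", cfg0)), 0L)
  expect_error(dfs_paths(store, "NOPE", "DM01", cfg0),
               class = "cmkg_lookup_error")
  expect_error(dfs_paths(store, "DM01", "DM01", cfg0),
               class = "cmkg_argument_error")
})

test_that("ranking dedupes toward rule provenance and sorts by score", {
  idx <- frequency_index(100)
  rule_p <- make_path(c("Herb", "Gene", "DiseaseMM"),
                      c("act_on", "dysregulate"), origin = "Rule",
                      c_rule = 0.9, ids = c("H", "G", "D"))
  dfs_same <- make_path(c("Herb", "Gene", "DiseaseMM"),
                        c("act_on", "dysregulate"), origin = "DFS",
                        ids = c("H", "G", "D"))
  dfs_other <- make_path(c("Herb", "SymptomTCM", "DiseaseMM"),
                         c("is_associated_with", "is_associated_with"),
                         ids = c("H", "S", "D"))
  top <- rank_paths(list(rule_p), list(dfs_same, dfs_other), cfg, idx, k = 10)
  expect_equal(length(top), 2L)
  expect_equal(top[[1]]$path$origin, "Rule")
  scores <- vapply(top, function(e) e$breakdown$score, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_error(rank_paths(list(), list(), cfg, idx, k = 0),
               class = "cmkg_argument_error")
  # sort oracle on a random pool
  set.seed(7)
  pool <- lapply(1:20, function(i)
    make_path(sample(c("Gene", "Herb", "DiseaseMM"), 3, replace = TRUE),
              sample(c("act_on", "synergizewith"), 2, replace = TRUE),
              ids = paste0("n", i, "_", 1:3)))
  top_all <- rank_paths(list(), pool, cfg, idx, k = 20)
  s_all <- vapply(top_all, function(e) e$breakdown$score, numeric(1))
  brute <- sort(vapply(pool, function(p) score_path(p, cfg, idx)$score,
                       numeric(1)), decreasing = TRUE)
  expect_equal(s_all, brute)
})

test_that("scores are invariant under entity renaming", {
  idx <- frequency_index(100, c(I_a = 9))
  p <- kg_path(c("H", "I_a", "G", "D"), c("includes", "act_on", "dysregulate"),
               c("Herb", "Ingredient", "Gene", "DiseaseMM"))
  idx2 <- frequency_index(100, c(ZZZ = 9))
  p2 <- kg_path(c("Q", "ZZZ", "W", "E"),
                c("includes", "act_on", "dysregulate"),
                c("Herb", "Ingredient", "Gene", "DiseaseMM"))
  expect_equal(score_path(p, cfg, idx)$score, score_path(p2, cfg, idx2)$score)
})

test_that("dfs score grows with lambda and isi_floor=1 erases df sensitivity", {
  idx <- frequency_index(100, c(ub = 90, ra = 1))
  p <- chain_4hop()
  lams <- c(0.05, 0.2, 0.5, 1.0)
  sc <- vapply(lams, function(l)
    score_path(p, scoring_config(lambda_dfs = l), idx)$score, numeric(1))
  expect_true(all(diff(sc) >= 0))
  cfg_noisi <- scoring_config(isi_floor = 1.0)
  ub_p <- kg_path(c("H", "ub", "G", "D"), c("includes", "act_on", "dysregulate"),
                  c("Herb", "Ingredient", "Gene", "DiseaseMM"))
  ra_p <- kg_path(c("H", "ra", "G", "D"), c("includes", "act_on", "dysregulate"),
                  c("Herb", "Ingredient", "Gene", "DiseaseMM"))
  expect_equal(score_path(ub_p, cfg_noisi, idx)$score,
               score_path(ra_p, cfg_noisi, idx)$score)
  expect_lt(score_path(ub_p, cfg, idx)$score, score_path(ra_p, cfg, idx)$score)
})
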