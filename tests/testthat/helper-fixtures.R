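# Shared in-code fixtures: a tiny hand-built store and path constructors.

tiny_entities <- function() {
  data.frame(
    entity_id = c("HEB0001", "HEB0002", "INT00001", "INT00002",
                  "GEE00001", "GEE00002", "GEE00003", "DM01", "TS0001"),
    name = c("astragalus", "ginseng", "quercetin", "rareoside",
             "INSR", "GRB14", "TP53", "type 2 diabetes", "thirst"),
    entity_type = c("Herb", "Herb", "Ingredient", "Ingredient",
                    "Gene", "Gene", "Gene", "DiseaseMM", "SymptomTCM"),
    source_db = "test",
    stringsAsFactors = FALSE)
}

tiny_triples <- function() {
  data.frame(
    head_id = c("HEB0001", "HEB0001", "HEB0002", "INT00001", "GEE00001",
                "GEE00002", "GEE00001", "HEB0001"),
    relation = c("includes", "act_on", "includes", "act_on", "synergizewith",
                 "dysregulate", "experiments", "is_associated_with"),
    tail_id = c("INT00001", "GEE00001", "INT00001", "GEE00002", "GEE00002",
                "DM01", "GEE00003", "TS0001"),
    source_db = "test",
    stringsAsFactors = FALSE)
}

tiny_store <- function() kg_store(tiny_entities(), tiny_triples())

make_path <- function(types, relations, origin = "DFS", c_rule = NA_real_,
                      ids = NULL) {
  if (is.null(ids)) ids <- paste0("N", seq_along(types))
  kg_path(ids, relations, types, origin = origin, c_rule = c_rule)
}

# The worked 4-hop herb-gene chain under the baseline configuration.
chain_4hop <- function() {
  kg_path(c("HEB1435", "G1", "G2", "G3", "DM06"),
          c("act_on", "synergizewith", "synergizewith", "dysregulate"),
          c("Herb", "Gene", "Gene", "Gene", "DiseaseMM"), origin = "DFS")
}

normalize_name_for_test <- function(x) tolower(gsub("\\s+", " ", x))

random_store <- function(n_entities = 20L, n_triples = 50L, seed = 1L,
                         types = NULL) {
  set.seed(seed)
  ids <- sprintf("E%03d", seq_len(n_entities))
  if (is.null(types))
    types <- sample(c("Gene", "Herb", "Compound", "DiseaseMM"),
                    n_entities, replace = TRUE)
  ent <- data.frame(entity_id = ids, name = paste("e", seq_len(n_entities)),
                    entity_type = types, source_db = "rand",
                    stringsAsFactors = FALSE)
  tri <- data.frame(head_id = sample(ids, n_triples, replace = TRUE),
                    relation = sample(c("r1", "r2", "r3"), n_triples,
                                      replace = TRUE),
                    tail_id = sample(ids, n_triples, replace = TRUE),
                    source_db = "rand", stringsAsFactors = FALSE)
  tri <- tri[tri$head_id != tri$tail_id, , drop = FALSE]
  kg_store(ent, tri)
}
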