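## Seeded generator of schema-faithful toy cross-medicine graphs:
## Herb -> Ingredient -> Gene -> Disease chains, gene-gene edges with and
## without experimental-evidence labels, controllable ingredient ubiquity,
## planted drug -> ... -> disease mechanisms and planted Horn rules with
## exact confidences. Everything the other modules need for end-to-end
## testing without external downloads.

## Relations reserved for planted rules; the noise generator never emits
## them, so rule grounding counts are exact by construction.
RULE_RELATION_POOL <- list(
  c(head = "alleviate", b1 = "inhibit", b2 = "affect"),
  c(head = "regulate", b1 = "induce", b2 = "elevate")
)

#' Parameters of the synthetic graph generator
#'
#' @param n_herbs,n_ingredients,n_compounds,n_genes,n_diseases Entity
#'   counts.
#' @param n_symptoms_tcm,n_symptoms_mm Symptom counts per system.
#' @param edges_per_herb Mean act_on edges from each herb to genes.
#' @param edges_per_compound Mean bind/up/downregulate edges per compound.
#' @param gene_gene_edges Total gene-gene interaction edges.
#' @param evidence_fraction Fraction of gene-gene edges labeled with the
#'   evidence relations (`experiments` / `experiments_transferred`); the
#'   rest are `synergizewith`.
#' @param ubiquitous_fraction Fraction of ingredients that are near-
#'   ubiquitous (document frequency close to the herb count); the rest are
#'   rare (df 1-3).
#' @param genes_per_disease Gene -> disease edges per disease.
#' @param mechanism_lengths Integer vector: one planted drug-to-disease
#'   mechanism chain per element, of that length in hops (2-4).
#' @param rule_confidences Target confidences of planted Horn rules (at
#'   most `length(RULE_RELATION_POOL)`); each rule gets `rule_groundings`
#'   body groundings.
#' @param rule_groundings Body groundings per planted rule.
#' @param seed RNG seed.
#' @return Object of class `kg_synthesis_params`.
#' @export
synthesis_params <- function(n_herbs = 10L, n_ingredients = 20L,
                             n_compounds = 10L, n_genes = 30L,
                             n_diseases = 2L, n_symptoms_tcm = 3L,
                             n_symptoms_mm = 3L,
                             edges_per_herb = 3, edges_per_compound = 3,
                             gene_gene_edges = 40L,
                             evidence_fraction = 0.3,
                             ubiquitous_fraction = 0.2,
                             genes_per_disease = 8L,
                             mechanism_lengths = c(3L, 4L),
                             rule_confidences = c(0.5),
                             rule_groundings = 4L,
                             seed = 42L) {
  if (length(rule_confidences) > length(RULE_RELATION_POOL))
    argument_error(sprintf("at most %d planted rules supported",
                           length(RULE_RELATION_POOL)))
  if (any(mechanism_lengths < 2 | mechanism_lengths > 4))
    argument_error("mechanism lengths must be within 2..4 hops")
  if (any(rule_confidences <= 0 | rule_confidences > 1))
    argument_error("rule confidences must lie in (0, 1]")
  structure(as.list(environment()), class = "kg_synthesis_params")
}

make_ids <- function(prefix, n, width)
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))

#' Generate a synthetic cross-medicine knowledge graph
#'
#' Builds a typed store honouring all store invariants, together with a
#' ground-truth manifest: each ingredient's true document frequency, the
#' planted mechanism paths, and the planted rules with their exact support
#' and body-grounding counts. Byte-identical output for equal seeds.
#'
#' @param params A [synthesis_params].
#' @return List with `store` (a [kg_store]) and `manifest`.
#' @export
generate_cmkg <- function(params = synthesis_params()) {
  p <- params
  set.seed(p$seed)
  herbs <- make_ids("HEB", p$n_herbs, 4L)
  ings <- make_ids("INT", p$n_ingredients, 5L)
  comps <- make_ids("DCP", p$n_compounds, 5L)
  genes <- make_ids("GEE", p$n_genes, 5L)
  dis <- make_ids("DM", p$n_diseases, 2L)
  ts <- make_ids("TS", p$n_symptoms_tcm, 4L)
  ms <- make_ids("MS", p$n_symptoms_mm, 4L)

  ent <- function(ids, type, label) data.frame(
    entity_id = ids, name = paste(label, seq_along(ids)),
    entity_type = type, source_db = "synthetic", stringsAsFactors = FALSE)
  entities <- rbind(ent(herbs, "Herb", "herb"),
                    ent(ings, "Ingredient", "ingredient"),
                    ent(comps, "Compound", "compound"),
                    ent(genes, "Gene", "gene"),
                    ent(dis, "DiseaseMM", "disease"),
                    ent(ts, "SymptomTCM", "tcm symptom"),
                    ent(ms, "SymptomMM", "mm symptom"))

  tri <- function(h, r, t) data.frame(head_id = h, relation = r, tail_id = t,
                                      source_db = "synthetic",
                                      stringsAsFactors = FALSE)
  triples <- list()

  ## Herb -> includes -> Ingredient with controlled document frequency
  n_ubiq <- round(p$ubiquitous_fraction * p$n_ingredients)
  df <- integer(p$n_ingredients)
  if (p$n_herbs >= 1) {
    for (i in seq_len(p$n_ingredients)) {
      df[i] <- if (i <= n_ubiq) max(1L, p$n_herbs - sample.int(2L, 1L) + 1L)
      else sample.int(min(3L, p$n_herbs), 1L)
      in_herbs <- sample(herbs, df[i])
      triples[[length(triples) + 1L]] <- tri(in_herbs, "includes", ings[i])
    }
  }
  names(df) <- ings

  ## drug -> gene edges
  for (h in herbs)
    triples[[length(triples) + 1L]] <-
      tri(h, "act_on", sample(genes, min(p$edges_per_herb, p$n_genes)))
  for (ing in sample(ings, ceiling(p$n_ingredients / 2)))
    triples[[length(triples) + 1L]] <-
      tri(ing, "act_on", sample(genes, min(2L, p$n_genes)))
  for (cm in comps) {
    rels <- sample(c("bind", "upregulate", "downregulate"),
                   min(p$edges_per_compound, p$n_genes), replace = TRUE)
    triples[[length(triples) + 1L]] <-
      tri(cm, rels, sample(genes, length(rels)))
  }

  ## gene-gene interactions, a fraction carrying evidence labels
  if (p$gene_gene_edges > 0 && p$n_genes >= 2) {
    g1 <- sample(genes, p$gene_gene_edges, replace = TRUE)
    g2 <- sample(genes, p$gene_gene_edges, replace = TRUE)
    keep <- g1 != g2
    g1 <- g1[keep]; g2 <- g2[keep]
    ev <- stats::runif(length(g1)) < p$evidence_fraction
    rel <- ifelse(ev, sample(c("experiments", "experiments_transferred"),
                             length(g1), replace = TRUE), "synergizewith")
    triples[[length(triples) + 1L]] <- tri(g1, rel, g2)
  }

  ## gene -> disease and symptom attachments
  for (d in dis)
    triples[[length(triples) + 1L]] <-
      tri(sample(genes, min(p$genes_per_disease, p$n_genes)),
          sample(c("dysregulate", "act in pathway"),
                 min(p$genes_per_disease, p$n_genes), replace = TRUE), d)
  if (p$n_symptoms_tcm > 0)
    triples[[length(triples) + 1L]] <-
      tri(ts, "is_associated_with", sample(genes, p$n_symptoms_tcm,
                                           replace = TRUE))
  if (p$n_symptoms_mm > 0)
    triples[[length(triples) + 1L]] <-
      tri(ms, "is_associated_with", sample(genes, p$n_symptoms_mm,
                                           replace = TRUE))
  triples[[length(triples) + 1L]] <-
    tri(sample(genes, min(3L, p$n_genes)), "is_associated_with",
        sample(comps, min(3L, p$n_genes), replace = TRUE))

  ## planted drug -> ... -> disease mechanism chains
  mechanisms <- list()
  for (L in p$mechanism_lengths) {
    drug <- sample(c(herbs, comps), 1L)
    drug_rel <- if (drug %in% herbs) "act_on" else "bind"
    mid <- sample(genes, L - 1L)
    nodes <- c(drug, mid, sample(dis, 1L))
    rels <- c(drug_rel, rep("synergizewith", L - 2L), "dysregulate")
    for (i in seq_len(L))
      triples[[length(triples) + 1L]] <- tri(nodes[i], rels[i], nodes[i + 1L])
    mechanisms[[length(mechanisms) + 1L]] <- list(nodes = nodes,
                                                  relations = rels)
  }

  ## planted Horn rules over reserved relations, exact confidences
  rules <- list()
  if (length(p$rule_confidences) > 0) {
    for (k in seq_along(p$rule_confidences)) {
      rr <- RULE_RELATION_POOL[[k]]
      m <- p$rule_groundings
      s <- round(p$rule_confidences[k] * m)
      xs <- sample(comps, m)
      as_ <- sample(genes, m)
      y <- sample(dis, 1L)
      triples[[length(triples) + 1L]] <- tri(xs, rr[["b1"]], as_)
      triples[[length(triples) + 1L]] <- tri(as_, rr[["b2"]], y)
      if (s > 0)
        triples[[length(triples) + 1L]] <- tri(xs[seq_len(s)], rr[["head"]], y)
      rules[[length(rules) + 1L]] <-
        kg_rule(rr[["head"]], c(rr[["b1"]], rr[["b2"]]), s, m)
    }
  }

  all_triples <- do.call(rbind, triples)
  store <- kg_store(entities, all_triples)
  manifest <- list(params = p, df = df, mechanisms = mechanisms,
                   rules = rules)
  list(store = store, manifest = manifest)
}

#' Write a synthetic fixture to plain-text files
#'
#' Emits `entities.tsv`, `triples.tsv`, `rules.tsv` (4-field rule dialect)
#' and `manifest.tsv` (tagged key-value rows) into `dir`.
#'
#' @param store A [kg_store].
#' @param manifest Manifest from [generate_cmkg].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(store, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_entity_table(store$entities, file.path(dir, "entities.tsv"))
  write_triple_table(store, file.path(dir, "triples.tsv"))
  write_rules(manifest$rules, file.path(dir, "rules.tsv"))
  lines <- c(sprintf("n_herbs\t%d", manifest$params$n_herbs),
             sprintf("df\t%s\t%d", names(manifest$df), manifest$df))
  for (m in manifest$mechanisms)
    lines <- c(lines, sprintf("mechanism\t%s\t%s",
                              paste(m$nodes, collapse = "|"),
                              paste(m$relations, collapse = "|")))
  writeLines(lines, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Read a synthetic fixture back
#'
#' @param dir Fixture directory written by [write_fixture].
#' @return List with `store`, `rules`, `df`, `n_herbs`, `mechanisms`.
#' @export
read_fixture <- function(dir) {
  entities <- read_entity_table(file.path(dir, "entities.tsv"))
  store <- read_triples(file.path(dir, "triples.tsv"), entities)
  rules <- parse_rules(file.path(dir, "rules.tsv"))
  lines <- strsplit(readLines(file.path(dir, "manifest.tsv")), "\t",
                    fixed = TRUE)
  tag <- vapply(lines, `[`, character(1), 1)
  df_rows <- lines[tag == "df"]
  df <- stats::setNames(as.integer(vapply(df_rows, `[`, character(1), 3)),
                        vapply(df_rows, `[`, character(1), 2))
  mech <- lapply(lines[tag == "mechanism"], function(l)
    list(nodes = strsplit(l[2], "|", fixed = TRUE)[[1]],
         relations = strsplit(l[3], "|", fixed = TRUE)[[1]]))
  list(store = store, rules = rules, df = df,
       n_herbs = as.integer(lines[tag == "n_herbs"][[1]][2]),
       mechanisms = mech)
}
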