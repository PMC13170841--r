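## Horn chain rules: an AnyBURL-compatible 4-field rule dialect, a minimal
## path-sampling miner, and grounding of rule bodies into concrete paths.
## Body atoms may traverse an edge against its direction; such atoms carry
## the relation-name suffix "::inv".

INV_SUFFIX <- "::inv"

is_inverse <- function(rel) endsWith(rel, INV_SUFFIX)
strip_inverse <- function(rel) sub("::inv$", "", rel)

#' Construct a Horn chain rule
#'
#' A rule `head(X, Y) <= b1(X, A), b2(A, Y)` whose body forms a connected
#' variable chain from X to Y. Confidence is `support / body_count`, where
#' `body_count` counts distinct (X, Y) pairs satisfying the body and
#' `support` those among them also satisfying the head.
#'
#' @param head_relation Relation of the head atom (over X, Y).
#' @param body_relations Character vector of body relations in chain order;
#'   a `::inv` suffix marks traversal against edge direction.
#' @param support,body_count Grounding counts.
#' @param confidence Defaults to `support / body_count`.
#' @return Object of class `kg_rule`.
#' @export
kg_rule <- function(head_relation, body_relations, support, body_count,
                    confidence = support / body_count) {
  if (length(body_relations) < 1L)
    argument_error("rule body must have at least one atom")
  structure(list(head_relation = head_relation,
                 body_relations = as.character(body_relations),
                 support = as.numeric(support),
                 body_count = as.numeric(body_count),
                 confidence = as.numeric(confidence)),
            class = "kg_rule")
}

rule_variables <- function(n_body) {
  ## X, A, B, ..., Y for a body of n_body atoms
  if (n_body == 1L) return(c("X", "Y"))
  c("X", LETTERS[seq_len(n_body - 1L)], "Y")
}

#' @export
format.kg_rule <- function(x, ...) {
  vars <- rule_variables(length(x$body_relations))
  atoms <- vapply(seq_along(x$body_relations), function(i)
    sprintf("%s(%s,%s)", x$body_relations[i], vars[i], vars[i + 1L]),
    character(1))
  sprintf("%s(X,Y) <= %s", x$head_relation, paste(atoms, collapse = ", "))
}

#' @export
print.kg_rule <- function(x, ...) {
  cat(sprintf("<kg_rule conf=%.4f support=%g body=%g> %s\n",
              x$confidence, x$support, x$body_count, format(x)))
  invisible(x)
}

rule_signature <- function(rule)
  paste(rule$head_relation, paste(rule$body_relations, collapse = "|"),
        sep = "#")

parse_atom <- function(s, line_no) {
  m <- regmatches(s, regexec("^\\s*(.+)\\(([^,()]+),\\s*([^,()]+)\\)\\s*$", s))[[1]]
  if (length(m) != 4L)
    format_error(sprintf("line %d: malformed atom '%s'", line_no, s))
  list(relation = trimws(m[2]), arg1 = trimws(m[3]), arg2 = trimws(m[4]))
}

#' Parse a rule file
#'
#' Each line is `support<TAB>body_count<TAB>confidence<TAB>head(X,Y) <=
#' atom1(..), atom2(..)`. The stored confidence is cross-checked against
#' `support / body_count` (tolerance 1e-4, warning beyond). Rules whose
#' bodies are not X-to-Y variable chains (e.g. constant-bound rule classes)
#' are skipped with a count reported via attribute `n_skipped`; bodies
#' longer than `max_len` raise an error.
#'
#' @param path Rule file path.
#' @param max_len Maximum body length (default 4).
#' @return List of [kg_rule] objects, attribute `n_skipped`.
#' @export
parse_rules <- function(path, max_len = 4L) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rules <- list()
  n_skipped <- 0L
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 4L)
      format_error(sprintf("line %d: expected 4 tab-separated fields, got %d",
                           ln, length(parts)))
    support <- suppressWarnings(as.numeric(parts[1]))
    body_count <- suppressWarnings(as.numeric(parts[2]))
    conf <- suppressWarnings(as.numeric(parts[3]))
    if (anyNA(c(support, body_count, conf)))
      format_error(sprintf("line %d: non-numeric count/confidence field", ln))
    halves <- strsplit(parts[4], "<=", fixed = TRUE)[[1]]
    if (length(halves) != 2L)
      format_error(sprintf("line %d: missing '<=' in rule", ln))
    head_atom <- parse_atom(halves[1], ln)
    body_strs <- strsplit(trimws(halves[2]), "\\)\\s*,\\s*")[[1]]
    body_strs <- ifelse(endsWith(body_strs, ")"), body_strs,
                        paste0(body_strs, ")"))
    body <- lapply(body_strs, parse_atom, line_no = ln)
    if (length(body) > max_len)
      format_error(sprintf("line %d: body length %d exceeds max %d",
                           ln, length(body), max_len))
    vars <- rule_variables(length(body))
    is_chain <- identical(c(head_atom$arg1, head_atom$arg2), c("X", "Y")) &&
      all(vapply(seq_along(body), function(i)
        identical(c(body[[i]]$arg1, body[[i]]$arg2), vars[c(i, i + 1L)]),
        logical(1)))
    if (!is_chain) { n_skipped <- n_skipped + 1L; next }
    if (body_count > 0 && abs(conf - support / body_count) > 1e-4)
      warning(sprintf(
        "line %d: confidence %.6f disagrees with support/body_count %.6f",
        ln, conf, support / body_count))
    rules[[length(rules) + 1L]] <-
      kg_rule(head_atom$relation,
              vapply(body, function(a) a$relation, character(1)),
              support, body_count, conf)
  }
  attr(rules, "n_skipped") <- n_skipped
  rules
}

#' Write rules in the 4-field dialect
#'
#' Emits the same dialect [parse_rules] reads, so mined rules round-trip.
#'
#' @param rules List of [kg_rule] objects.
#' @param path Output path.
#' @export
write_rules <- function(rules, path) {
  lines <- vapply(rules, function(r)
    sprintf("%g\t%g\t%s\t%s", r$support, r$body_count,
            format(r$confidence, digits = 12), format(r)), character(1))
  writeLines(lines, path)
  invisible(path)
}

## Edge table for one body atom: columns `from`, `to` bind chain variables.
atom_edges <- function(store, relation) {
  if (is_inverse(relation)) {
    sel <- store$triples$relation == strip_inverse(relation)
    data.frame(from = store$triples$tail_id[sel],
               to = store$triples$head_id[sel], stringsAsFactors = FALSE)
  } else {
    sel <- store$triples$relation == relation
    data.frame(from = store$triples$head_id[sel],
               to = store$triples$tail_id[sel], stringsAsFactors = FALSE)
  }
}

## Relational join of a body chain. Returns a data frame with one column per
## chain variable (X, A, ..., Y); zero rows when nothing grounds.
join_body <- function(store, body_relations, x = NULL, y = NULL) {
  vars <- rule_variables(length(body_relations))
  bind <- atom_edges(store, body_relations[1])
  names(bind) <- vars[1:2]
  if (!is.null(x)) bind <- bind[bind[[1]] == x, , drop = FALSE]
  for (i in seq_along(body_relations)[-1]) {
    e <- atom_edges(store, body_relations[i])
    names(e) <- vars[c(i, i + 1L)]
    bind <- merge(bind, e, by = vars[i], sort = FALSE)
  }
  if (!is.null(y)) bind <- bind[bind[[vars[length(vars)]]] == y, , drop = FALSE]
  bind <- bind[!duplicated(bind), , drop = FALSE]
  bind[, vars, drop = FALSE]
}

## Exact support / body_count of a candidate rule by brute-force grounding.
ground_counts <- function(store, head_relation, body_relations) {
  bind <- join_body(store, body_relations)
  if (nrow(bind) == 0L) return(c(support = 0, body_count = 0))
  pairs <- unique(bind[, c("X", "Y")])
  heads <- atom_edges(store, head_relation)
  hk <- paste(heads$from, heads$to, sep = "\r")
  pk <- paste(pairs$X, pairs$Y, sep = "\r")
  c(support = sum(pk %in% hk), body_count = nrow(pairs))
}

#' Mine chain rules by random path sampling
#'
#' Each sample draws a random triple as the head grounding `r(x, y)` and
#' enumerates the simple paths (forward and inverse edges) from x to y of
#' bounded length; every such path is generalized into a chain rule by
#' replacing entities with variables. Support and body-grounding counts are
#' then computed exactly by brute-force grounding. Reproducible given
#' `seed`; the rule set grows monotonically with `n_samples` under the
#' same seed.
#'
#' @param store A [kg_store].
#' @param n_samples Number of head-triple samples.
#' @param max_len Maximum body length in hops (default 4).
#' @param seed RNG seed.
#' @param min_confidence Drop mined rules below this confidence (default 0).
#' @return List of [kg_rule] objects, deduplicated, in discovery order.
#' @export
mine_rules <- function(store, n_samples, max_len = 4L, seed = 42L,
                       min_confidence = 0) {
  if (n_samples <= 0) argument_error("n_samples must be positive")
  if (nrow(store$triples) == 0L) return(list())
  tri <- store$triples
  moves <- function(node) {
    oi <- store$out_index[[node]]; ii <- store$in_index[[node]]
    inv <- tri$relation[ii]
    if (length(inv) > 0L) inv <- paste0(inv, INV_SUFFIX)
    data.frame(relation = c(tri$relation[oi], inv),
               neighbor = c(tri$tail_id[oi], tri$head_id[ii]),
               stringsAsFactors = FALSE)
  }
  ## all relation sequences of simple paths x -> y, bounded length
  body_walks <- function(x, y) {
    out <- list()
    recur <- function(node, visited, body) {
      if (length(body) >= max_len) return()
      mv <- moves(node)
      for (i in seq_len(nrow(mv))) {
        nb <- mv$neighbor[i]
        if (nb %in% visited) next
        if (identical(nb, y))
          out[[length(out) + 1L]] <<- c(body, mv$relation[i])
        else recur(nb, c(visited, nb), c(body, mv$relation[i]))
      }
    }
    recur(x, x, character(0))
    out
  }
  seen_triples <- logical(nrow(tri))
  seen <- character(0)
  rules <- list()
  set.seed(seed)
  for (s in seq_len(n_samples)) {
    ti <- sample.int(nrow(tri), 1L)
    if (seen_triples[ti]) next
    seen_triples[ti] <- TRUE
    x <- tri$head_id[ti]; y <- tri$tail_id[ti]; h <- tri$relation[ti]
    for (body in body_walks(x, y)) {
      if (length(body) == 1L && identical(body, h)) next
      sig <- paste(h, paste(body, collapse = "|"), sep = "#")
      if (sig %in% seen) next
      seen <- c(seen, sig)
      cnt <- ground_counts(store, h, body)
      if (cnt["body_count"] == 0) next
      r <- kg_rule(h, body, cnt["support"], cnt["body_count"])
      if (r$confidence >= min_confidence && r$support > 0)
        rules[[length(rules) + 1L]] <- r
    }
  }
  rules
}

#' Ground a rule between two entities
#'
#' Instantiates the rule body with X = `source`, Y = `target`; every
#' grounding becomes a mechanistic path with origin `"Rule"` carrying the
#' rule's confidence. Relation names on the returned paths have the
#' inverse marker stripped (weights and bonuses key on the plain name).
#'
#' @param rule A [kg_rule].
#' @param store A [kg_store].
#' @param source,target Entity ids.
#' @return List of [kg_path] objects (deduplicated; possibly empty).
#' @export
ground_rule <- function(rule, store, source, target) {
  if (!has_entity(store, source)) lookup_error(paste("unknown entity:", source))
  if (!has_entity(store, target)) lookup_error(paste("unknown entity:", target))
  bind <- join_body(store, rule$body_relations, x = source, y = target)
  if (nrow(bind) == 0L) return(list())
  rels <- strip_inverse(rule$body_relations)
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(bind))) {
    nodes <- as.character(unlist(bind[i, ], use.names = FALSE))
    p <- kg_path(nodes, rels, entity_type_of(store, nodes),
                 origin = "Rule", c_rule = rule$confidence)
    k <- path_key(p)
    if (k %in% seen) next
    seen <- c(seen, k)
    out[[length(out) + 1L]] <- p
  }
  out
}
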