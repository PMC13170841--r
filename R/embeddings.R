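## Knowledge-graph embedding models: TransE, DistMult, ComplEx, RotatE.
## Margin-ranking training with uniform negative sampling and filtered
## MRR/Hits@K evaluation. Pure R, vectorized over mini-batches.

MODEL_KINDS <- c("transe", "distmult", "complex", "rotate")

#' Training configuration for embedding models
#'
#' Defaults follow the published protocol (dimension 400, batch 1024, 200
#' negatives per positive, penalty 1e-9); tests and examples use much
#' smaller desk-scale values.
#'
#' @param dimension Embedding dimension d.
#' @param batch_size Mini-batch size.
#' @param negatives Negative samples per positive triple.
#' @param margin Margin gamma of the ranking loss.
#' @param learning_rate SGD step size.
#' @param l2_penalty Weight decay on embedding parameters.
#' @param epochs Training epochs.
#' @param seed RNG seed (recorded in the fitted object).
#' @param transe_norm `"L2"` or `"L1"` for the TransE distance.
#' @return Object of class `kg_train_config`.
#' @export
train_config <- function(dimension = 400L, batch_size = 1024L,
                         negatives = 200L, margin = 6.0,
                         learning_rate = 1e-3, l2_penalty = 1e-9,
                         epochs = 30L, seed = 42L, transe_norm = "L2") {
  stopifnot(dimension > 0, batch_size > 0, negatives > 0, margin > 0,
            learning_rate > 0, l2_penalty >= 0, epochs >= 0)
  structure(list(dimension = as.integer(dimension),
                 batch_size = as.integer(batch_size),
                 negatives = as.integer(negatives), margin = margin,
                 learning_rate = learning_rate, l2_penalty = l2_penalty,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 transe_norm = match.arg(transe_norm, c("L2", "L1"))),
            class = "kg_train_config")
}

check_dims <- function(...) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1L)
    argument_error(sprintf("dimension mismatch: %s",
                           paste(lens, collapse = " vs ")))
}

#' TransE score
#'
#' `f(h, r, t) = -||h + r - t||`; zero (the maximum) when the relation
#' translates the head exactly onto the tail.
#'
#' @param h,r,t Real vectors of equal length.
#' @param norm `"L2"` (default) or `"L1"`.
#' @return Scalar score (higher is better).
#' @export
score_transe <- function(h, r, t, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  check_dims(h, r, t)
  d <- h + r - t
  if (norm == "L2") -sqrt(sum(d^2)) else -sum(abs(d))
}

#' DistMult score
#'
#' Bilinear-diagonal score `sum_i h_i r_i t_i`. Symmetric in head and tail
#' by commutativity, hence unable to model directional relations.
#'
#' @param h,r,t Real vectors of equal length.
#' @return Scalar score.
#' @export
score_distmult <- function(h, r, t) {
  check_dims(h, r, t)
  ## h*t first: elementwise products commute exactly in IEEE arithmetic,
  ## making the head-tail symmetry bit-exact
  sum(r * (h * t))
}

#' ComplEx score
#'
#' `Re(sum_i h_i r_i conj(t_i))` over complex vectors; the conjugate breaks
#' the symmetry of the bilinear form.
#'
#' @param h,r,t Complex (or real) vectors of equal length.
#' @return Scalar real score.
#' @export
score_complex <- function(h, r, t) {
  check_dims(h, r, t)
  Re(sum(as.complex(h) * as.complex(r) * Conj(as.complex(t))))
}

#' RotatE score
#'
#' `-||h o r - t||` with element-wise complex multiplication; relation
#' coordinates must have unit modulus (rotations in the complex plane).
#'
#' @param h,r,t Complex vectors of equal length.
#' @param tol Tolerance on the unit-modulus constraint.
#' @return Scalar score (0 when t is exactly the rotated head).
#' @export
score_rotate <- function(h, r, t, tol = 1e-6) {
  check_dims(h, r, t)
  r <- as.complex(r)
  if (any(abs(Mod(r) - 1) > tol))
    argument_error("rotate relation coordinates must have unit modulus")
  -sqrt(sum(Mod(as.complex(h) * r - as.complex(t))^2))
}

#' Sample corrupted triples
#'
#' Each negative corrupts the head or the tail (uniform choice) of the
#' positive triple with a uniformly drawn replacement entity.
#'
#' @param triple One-row data frame or list with `head_id`, `relation`,
#'   `tail_id`.
#' @param n Number of negatives.
#' @param store A [kg_store].
#' @param seed Optional seed for reproducibility.
#' @return Data frame of `n` corrupted triples.
#' @export
sample_negatives <- function(triple, n, store, seed = NULL) {
  if (n <= 0) argument_error("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  ids <- store$entities$entity_id
  corrupt_head <- sample(c(TRUE, FALSE), n, replace = TRUE)
  repl <- character(n)
  for (i in seq_len(n)) {
    avoid <- if (corrupt_head[i]) triple$head_id else triple$tail_id
    repl[i] <- sample(setdiff(ids, avoid), 1L)
  }
  data.frame(
    head_id = ifelse(corrupt_head, repl, triple$head_id),
    relation = triple$relation,
    tail_id = ifelse(corrupt_head, triple$tail_id, repl),
    stringsAsFactors = FALSE)
}

#' Random triple split
#'
#' @param store A [kg_store].
#' @param fractions Train/validation/test fractions (default 0.9/0.05/0.05).
#' @param seed RNG seed.
#' @return List of triple data frames `train`, `valid`, `test`.
#' @export
kg_split <- function(store, fractions = c(0.9, 0.05, 0.05), seed = 42L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(store$triples)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(fractions[1] * n)
  n_valid <- floor(fractions[2] * n)
  list(train = store$triples[idx[seq_len(n_train)], , drop = FALSE],
       valid = store$triples[idx[n_train + seq_len(n_valid)], , drop = FALSE],
       test = store$triples[idx[(n_train + n_valid + 1):n], , drop = FALSE])
}

init_tables <- function(model, n_ent, n_rel, d) {
  bound <- 6 / sqrt(d)
  runifm <- function(n) matrix(stats::runif(n * d, -bound, bound), n, d)
  tab <- list(E_re = runifm(n_ent), E_im = NULL,
              R_re = runifm(n_rel), R_im = NULL)
  if (model %in% c("complex", "rotate")) {
    tab$E_im <- runifm(n_ent)
    tab$R_im <- runifm(n_rel)
  }
  if (model == "rotate") {
    phase <- matrix(stats::runif(n_rel * d, -pi, pi), n_rel, d)
    tab$R_re <- cos(phase)
    tab$R_im <- sin(phase)
  }
  tab
}

## Row-wise scores for index vectors ih, ir, it against a table.
batch_scores <- function(tab, model, ih, ir, it, transe_norm = "L2") {
  Hr <- tab$E_re[ih, , drop = FALSE]
  Rr <- tab$R_re[ir, , drop = FALSE]
  Tr <- tab$E_re[it, , drop = FALSE]
  switch(model,
    transe = {
      D <- Hr + Rr - Tr
      if (transe_norm == "L2") -sqrt(rowSums(D^2)) else -rowSums(abs(D))
    },
    distmult = rowSums(Rr * (Hr * Tr)),
    complex = {
      Hi <- tab$E_im[ih, , drop = FALSE]
      Ri <- tab$R_im[ir, , drop = FALSE]
      Ti <- tab$E_im[it, , drop = FALSE]
      ## Re(h r conj(t)) expanded over channels
      rowSums(Hr * Rr * Tr - Hi * Ri * Tr + Hr * Ri * Ti + Hi * Rr * Ti)
    },
    rotate = {
      Hi <- tab$E_im[ih, , drop = FALSE]
      Ri <- tab$R_im[ir, , drop = FALSE]
      Ti <- tab$E_im[it, , drop = FALSE]
      Ure <- Hr * Rr - Hi * Ri - Tr
      Uim <- Hr * Ri + Hi * Rr - Ti
      -sqrt(rowSums(Ure^2 + Uim^2))
    })
}

## Scores of (h, r, e) for every entity e (or (e, r, t) when side = "head").
all_entity_scores <- function(tab, model, h, r, t, side = c("tail", "head"),
                              transe_norm = "L2") {
  side <- match.arg(side)
  n <- nrow(tab$E_re)
  if (side == "tail")
    batch_scores(tab, model, rep(h, n), rep(r, n), seq_len(n), transe_norm)
  else
    batch_scores(tab, model, seq_len(n), rep(r, n), rep(t, n), transe_norm)
}

## Accumulate per-row gradient matrices into a parameter matrix.
apply_grad <- function(M, idx, G, lr, l2) {
  agg <- rowsum(G, group = idx)
  rows <- as.integer(rownames(agg))
  M[rows, ] <- M[rows, , drop = FALSE] * (1 - lr * l2) - lr * agg
  M
}

#' Fit a knowledge-graph embedding model
#'
#' Trains entity and relation embeddings with pairwise margin-ranking loss
#' `max(0, margin - f(pos) + f(neg))` averaged over uniformly sampled
#' corruptions, by mini-batch SGD with analytic gradients. RotatE relation
#' coordinates are renormalized to unit modulus after every update. Fully
#' deterministic given the seed.
#'
#' @param store A [kg_store] (provides the entity/relation vocabulary).
#' @param model `"transe"`, `"distmult"`, `"complex"` or `"rotate"`.
#' @param config A [train_config].
#' @param triples Training triples (default: all triples in the store).
#' @return Object of class `kg_embedding` with the embedding tables, the
#'   per-epoch loss trace, and the configuration.
#' @export
kg_embed <- function(store, model = c("complex", "transe", "distmult",
                                      "rotate"),
                     config = train_config(), triples = store$triples) {
  model <- match.arg(model)
  if (nrow(triples) == 0L) argument_error("training split is empty")
  d <- config$dimension
  ids <- store$entities$entity_id
  rels <- store$relations
  set.seed(config$seed)
  tab <- init_tables(model, length(ids), length(rels), d)
  ih_all <- match(triples$head_id, ids)
  ir_all <- match(triples$relation, rels)
  it_all <- match(triples$tail_id, ids)
  n <- nrow(triples)
  n_ent <- length(ids)
  lr <- config$learning_rate
  l2 <- config$l2_penalty
  loss_trace <- numeric(config$epochs)
  nn <- config$negatives

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    total_loss <- 0
    n_terms <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      bi <- perm[b0:min(b0 + config$batch_size - 1L, n)]
      B <- length(bi)
      ih <- ih_all[bi]; ir <- ir_all[bi]; it <- it_all[bi]
      ## replicate positives once per negative
      rep_idx <- rep(seq_len(B), each = nn)
      ihn <- ih[rep_idx]; irn <- ir[rep_idx]; itn <- it[rep_idx]
      corrupt_head <- sample(c(TRUE, FALSE), B * nn, replace = TRUE)
      repl <- sample.int(n_ent, B * nn, replace = TRUE)
      ihn[corrupt_head] <- repl[corrupt_head]
      itn[!corrupt_head] <- repl[!corrupt_head]
      f_pos <- batch_scores(tab, model, ih, ir, it, config$transe_norm)
      f_neg <- batch_scores(tab, model, ihn, irn, itn, config$transe_norm)
      viol <- config$margin - f_pos[rep_idx] + f_neg
      active <- viol > 0
      total_loss <- total_loss + sum(viol[active])
      n_terms <- n_terms + length(viol)
      if (!any(active)) next
      scale <- 1 / length(viol)
      ## d(loss)/d f_pos = -scale, d(loss)/d f_neg = +scale on active terms
      upd <- grad_step(tab, model, config,
                       ih[rep_idx][active], irn[active], it[rep_idx][active],
                       rep(-scale, sum(active)),
                       ihn[active], itn[active], rep(scale, sum(active)),
                       lr, l2)
      tab <- upd
      if (model == "rotate") {
        mod <- sqrt(tab$R_re^2 + tab$R_im^2)
        tab$R_re <- tab$R_re / mod
        tab$R_im <- tab$R_im / mod
      }
    }
    loss_trace[epoch] <- total_loss / max(n_terms, 1L)
    if (!is.finite(loss_trace[epoch]))
      stop_cmkg(sprintf("training diverged at epoch %d", epoch),
                "cmkg_training_error")
  }

  structure(list(model = model, dimension = d,
                 entity_ids = ids, relation_ids = rels,
                 E_re = tab$E_re, E_im = tab$E_im,
                 R_re = tab$R_re, R_im = tab$R_im,
                 config = config, loss_trace = loss_trace),
            class = "kg_embedding")
}

## One SGD step: gradients of sum(w_pos * f(pos) + w_neg * f(neg)) flow into
## the embedding tables. Positive and negative triples share relation rows.
grad_step <- function(tab, model, config, ih, ir, it, w_pos,
                      ihn, itn, w_neg, lr, l2) {
  ## combine positive and negative contributions into one row list
  rows_h <- c(ih, ihn)
  rows_r <- c(ir, ir)
  rows_t <- c(it, itn)
  w <- c(w_pos, w_neg)  # signed loss gradient wrt f, per row
  Hr <- tab$E_re[rows_h, , drop = FALSE]
  Rr <- tab$R_re[rows_r, , drop = FALSE]
  Tr <- tab$E_re[rows_t, , drop = FALSE]
  if (model == "transe") {
    D <- Hr + Rr - Tr
    if (config$transe_norm == "L2") {
      nrm <- sqrt(rowSums(D^2))
      nrm[nrm == 0] <- Inf
      G <- -D / nrm    # d f / d h
    } else {
      G <- -sign(D)
    }
    gH <- w * G; gR <- w * G; gT <- -w * G
    tab$E_re <- apply_grad(tab$E_re, rows_h, gH, lr, l2)
    tab$R_re <- apply_grad(tab$R_re, rows_r, gR, lr, l2)
    tab$E_re <- apply_grad(tab$E_re, rows_t, gT, lr, l2)
  } else if (model == "distmult") {
    gH <- w * (Rr * Tr); gR <- w * (Hr * Tr); gT <- w * (Hr * Rr)
    tab$E_re <- apply_grad(tab$E_re, rows_h, gH, lr, l2)
    tab$R_re <- apply_grad(tab$R_re, rows_r, gR, lr, l2)
    tab$E_re <- apply_grad(tab$E_re, rows_t, gT, lr, l2)
  } else {
    Hi <- tab$E_im[rows_h, , drop = FALSE]
    Ri <- tab$R_im[rows_r, , drop = FALSE]
    Ti <- tab$E_im[rows_t, , drop = FALSE]
    if (model == "complex") {
      gHr <- w * (Rr * Tr + Ri * Ti)
      gHi <- w * (Rr * Ti - Ri * Tr)
      gRr <- w * (Hr * Tr + Hi * Ti)
      gRi <- w * (Hr * Ti - Hi * Tr)
      gTr <- w * (Hr * Rr - Hi * Ri)
      gTi <- w * (Hr * Ri + Hi * Rr)
    } else { # rotate
      Ure <- Hr * Rr - Hi * Ri - Tr
      Uim <- Hr * Ri + Hi * Rr - Ti
      nrm <- sqrt(rowSums(Ure^2 + Uim^2))
      nrm[nrm == 0] <- Inf
      A <- Ure / nrm; Bm <- Uim / nrm
      gHr <- -w * (A * Rr + Bm * Ri)
      gHi <- -w * (-A * Ri + Bm * Rr)
      gRr <- -w * (A * Hr + Bm * Hi)
      gRi <- -w * (-A * Hi + Bm * Hr)
      gTr <- w * A
      gTi <- w * Bm
    }
    tab$E_re <- apply_grad(tab$E_re, rows_h, gHr, lr, l2)
    tab$E_im <- apply_grad(tab$E_im, rows_h, gHi, lr, l2)
    tab$R_re <- apply_grad(tab$R_re, rows_r, gRr, lr, l2)
    tab$R_im <- apply_grad(tab$R_im, rows_r, gRi, lr, l2)
    tab$E_re <- apply_grad(tab$E_re, rows_t, gTr, lr, l2)
    tab$E_im <- apply_grad(tab$E_im, rows_t, gTi, lr, l2)
  }
  tab
}

#' @export
print.kg_embedding <- function(x, ...) {
  cat(sprintf("<kg_embedding %s> d=%d, %d entities, %d relations, %d epochs\n",
              x$model, x$dimension, length(x$entity_ids),
              length(x$relation_ids), length(x$loss_trace)))
  if (length(x$loss_trace) > 0)
    cat(sprintf("  final mean margin loss: %.5f\n",
                x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Score triples under a fitted embedding
#'
#' @param object A `kg_embedding`.
#' @param triples Data frame with `head_id`, `relation`, `tail_id`.
#' @param ... Unused.
#' @return Numeric vector of scores (higher is more plausible).
#' @export
predict.kg_embedding <- function(object, triples, ...) {
  ih <- match(triples$head_id, object$entity_ids)
  ir <- match(triples$relation, object$relation_ids)
  it <- match(triples$tail_id, object$entity_ids)
  if (anyNA(ih) || anyNA(it)) lookup_error("triple references unknown entity")
  if (anyNA(ir)) lookup_error("triple references unknown relation")
  tab <- object[c("E_re", "E_im", "R_re", "R_im")]
  batch_scores(tab, object$model, ih, ir, it, object$config$transe_norm)
}

## Average-tie rank of the true candidate among scores, after filtering.
filtered_rank <- function(scores, true_idx, filter_idx) {
  keep <- rep(TRUE, length(scores))
  keep[filter_idx] <- FALSE
  keep[true_idx] <- TRUE
  s <- scores[keep]
  st <- scores[true_idx]
  sum(s > st) + (sum(s == st) + 1) / 2
}

#' Filtered link-prediction evaluation
#'
#' For every test triple, ranks the true head among all head corruptions
#' and the true tail among all tail corruptions, removing candidates that
#' form other known true triples (the test triple itself is kept). Ties get
#' average ranks. MRR and Hits@K are averaged over both directions and all
#' test triples.
#'
#' @param object A `kg_embedding`.
#' @param test Triple data frame.
#' @param store The full [kg_store] supplying known true triples.
#' @param ks Cutoffs for Hits@K.
#' @param raw Also report unfiltered metrics.
#' @return Object of class `kg_eval`: list with `mrr`, `hits` (named by K),
#'   `ranks`, and optionally `raw_mrr`/`raw_ranks`.
#' @export
evaluate_filtered <- function(object, test, store, ks = c(1, 3, 10),
                              raw = FALSE) {
  if (nrow(test) == 0L) argument_error("test set is empty")
  ids <- object$entity_ids
  rels <- object$relation_ids
  tab <- object[c("E_re", "E_im", "R_re", "R_im")]
  tn <- object$config$transe_norm
  known <- store$triples
  kh <- match(known$head_id, ids)
  kr <- match(known$relation, rels)
  kt <- match(known$tail_id, ids)
  ## known-true lookup by (head, relation) -> tails and (relation, tail) -> heads
  tail_map <- split(kt, paste(kh, kr))
  head_map <- split(kh, paste(kr, kt))
  ranks <- numeric(0)
  raw_ranks <- numeric(0)
  for (i in seq_len(nrow(test))) {
    h <- match(test$head_id[i], ids)
    r <- match(test$relation[i], rels)
    t <- match(test$tail_id[i], ids)
    if (anyNA(c(h, r, t))) lookup_error("test triple references unknown id")
    s_tail <- all_entity_scores(tab, object$model, h, r, t, "tail", tn)
    s_head <- all_entity_scores(tab, object$model, h, r, t, "head", tn)
    filt_t <- tail_map[[paste(h, r)]]
    filt_h <- head_map[[paste(r, t)]]
    ranks <- c(ranks,
               filtered_rank(s_tail, t, filt_t),
               filtered_rank(s_head, h, filt_h))
    if (raw)
      raw_ranks <- c(raw_ranks,
                     filtered_rank(s_tail, t, integer(0)),
                     filtered_rank(s_head, h, integer(0)))
  }
  res <- list(mrr = mean(1 / ranks),
              hits = stats::setNames(
                vapply(ks, function(k) mean(ranks <= k), numeric(1)),
                paste0("hits@", ks)),
              ranks = ranks)
  if (raw) {
    res$raw_mrr <- mean(1 / raw_ranks)
    res$raw_ranks <- raw_ranks
  }
  structure(res, class = "kg_eval")
}

#' @export
print.kg_eval <- function(x, ...) {
  cat(sprintf("MRR %.4f | %s\n", x$mrr,
              paste(sprintf("%s %.4f", names(x$hits), x$hits),
                    collapse = " | ")))
  invisible(x)
}

#' Save / load an embedding checkpoint as plain text
#'
#' Writes a metadata file plus per-table TSV arrays so checkpoints are
#' portable and diffable.
#'
#' @param object A `kg_embedding`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_embedding <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(model = object$model, dimension = object$dimension,
            seed = object$config$seed)
  writeLines(paste(names(meta), meta, sep = "="), file.path(dir, "meta.txt"))
  writeLines(object$entity_ids, file.path(dir, "entities.txt"))
  writeLines(object$relation_ids, file.path(dir, "relations.txt"))
  wm <- function(M, f) if (!is.null(M))
    utils::write.table(M, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  wm(object$E_re, "E_re.tsv"); wm(object$E_im, "E_im.tsv")
  wm(object$R_re, "R_re.tsv"); wm(object$R_im, "R_im.tsv")
  writeLines(format(object$loss_trace, digits = 17),
             file.path(dir, "loss_trace.txt"))
  invisible(dir)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(dir) {
  meta <- strsplit(readLines(file.path(dir, "meta.txt")), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(meta, `[`, character(1), 2),
                          vapply(meta, `[`, character(1), 1))
  rm <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    as.matrix(utils::read.table(p, sep = "\t"))
  }
  E_re <- rm("E_re.tsv")
  dimnames(E_re) <- NULL
  strip <- function(M) { if (!is.null(M)) dimnames(M) <- NULL; M }
  structure(list(model = meta[["model"]],
                 dimension = as.integer(meta[["dimension"]]),
                 entity_ids = readLines(file.path(dir, "entities.txt")),
                 relation_ids = readLines(file.path(dir, "relations.txt")),
                 E_re = E_re, E_im = strip(rm("E_im.tsv")),
                 R_re = strip(rm("R_re.tsv")), R_im = strip(rm("R_im.tsv")),
                 config = train_config(dimension = as.integer(meta[["dimension"]]),
                                       seed = as.integer(meta[["seed"]])),
                 loss_trace = as.numeric(
                   readLines(file.path(dir, "loss_trace.txt")))),
            class = "kg_embedding")
}
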