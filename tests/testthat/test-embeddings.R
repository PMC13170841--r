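test_that("scoring functions match hand-computed values", {
  # TransE
  expect_equal(score_transe(c(1, 2), c(3, 4), c(4, 6)), 0)
  expect_equal(score_transe(c(1, 0), c(0, 1), c(0, 0)), -sqrt(2))
  expect_equal(score_transe(c(1, 0), c(0, 1), c(0, 0), norm = "L1"), -2)
  # translation invariance: adding c to both h and t leaves the score
  h <- c(0.3, -1); r <- c(2, 0.5); t <- c(1, 1); cc <- c(5, -7)
  expect_equal(score_transe(h, r, t), score_transe(h + cc, r, t + cc))
  expect_error(score_transe(c(1, 2), c(1, 2, 3), c(1, 2)),
               class = "cmkg_argument_error")
  # DistMult
  expect_equal(score_distmult(c(1, 2), c(1, 1), c(3, 1)), 5)
  expect_equal(score_distmult(h, r, t), score_distmult(t, r, h))
  expect_equal(score_distmult(h, c(0, 0), t), 0)
  # ComplEx
  expect_equal(score_complex(1 + 0i, 0 + 1i, 0 + 1i), 1)
  expect_equal(score_complex(h, r, t), score_distmult(h, r, t))
  ri <- complex(real = 0, imaginary = c(1, -2))
  hc <- complex(real = c(1, 2), imaginary = c(-1, 0.5))
  tc <- complex(real = c(0.2, 1), imaginary = c(2, -1))
  expect_equal(score_complex(hc, ri, tc), -score_complex(tc, ri, hc))
  # RotatE
  expect_equal(score_rotate(1 + 0i, 0 + 1i, 0 + 1i), 0)
  expect_equal(score_rotate(hc, c(1 + 0i, 1 + 0i), tc),
               -sqrt(sum(Mod(hc - tc)^2)))
  expect_error(score_rotate(hc, c(2 + 0i, 1 + 0i), tc),
               class = "cmkg_argument_error")
})

test_that("distmult symmetry and complex reduction hold on random vectors", {
  set.seed(1)
  for (i in 1:25) {
    d <- sample(2:8, 1)
    h <- stats::rnorm(d); r <- stats::rnorm(d); t <- stats::rnorm(d)
    expect_identical(score_distmult(h, r, t), score_distmult(t, r, h))
    expect_equal(score_complex(complex(real = h), complex(real = r),
                               complex(real = t)),
                 score_distmult(h, r, t), tolerance = 1e-14)
  }
})

test_that("negative sampling corrupts exactly one slot reproducibly", {
  store <- random_store(n_entities = 10L, n_triples = 30L, seed = 2L)
  pos <- store$triples[1, ]
  neg <- sample_negatives(pos, 200, store, seed = 4)
  expect_equal(nrow(neg), 200L)
  one_slot <- (neg$head_id == pos$head_id) != (neg$tail_id == pos$tail_id)
  expect_true(all(one_slot))
  expect_true(all(neg$relation == pos$relation))
  expect_identical(neg, sample_negatives(pos, 200, store, seed = 4))
  expect_error(sample_negatives(pos, 0, store), class = "cmkg_argument_error")
  # two-entity store: the corrupted slot must take the other entity
  ent2 <- data.frame(entity_id = c("A", "B"), name = c("a", "b"),
                     entity_type = "Gene", source_db = "s",
                     stringsAsFactors = FALSE)
  st2 <- kg_store(ent2, data.frame(head_id = "A", relation = "r",
                                   tail_id = "B", source_db = "s"))
  n2 <- sample_negatives(st2$triples[1, ], 50, st2, seed = 1)
  expect_true(all((n2$head_id == "B" & n2$tail_id == "B") |
                    (n2$head_id == "A" & n2$tail_id == "A")))
})

test_that("training is deterministic and epochs=0 returns the seeded init", {
  store <- random_store(n_entities = 15L, n_triples = 60L, seed = 3L)
  cfg <- train_config(dimension = 8L, batch_size = 16L, negatives = 4L,
                      epochs = 3L, seed = 11L, learning_rate = 0.05)
  f1 <- kg_embed(store, "transe", cfg)
  f2 <- kg_embed(store, "transe", cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$E_re, f2$E_re)
  cfg0 <- train_config(dimension = 8L, epochs = 0L, seed = 11L)
  init <- kg_embed(store, "transe", cfg0)
  set.seed(11L)
  expect_equal(init$E_re,
               matrix(stats::runif(15 * 8, -6 / sqrt(8), 6 / sqrt(8)), 15, 8))
})

test_that("rotate relation coordinates stay unit-modulus through training", {
  store <- random_store(n_entities = 12L, n_triples = 50L, seed = 6L)
  cfg <- train_config(dimension = 6L, batch_size = 16L, negatives = 4L,
                      epochs = 3L, seed = 2L, learning_rate = 0.05)
  fit <- kg_embed(store, "rotate", cfg)
  expect_true(all(abs(sqrt(fit$R_re^2 + fit$R_im^2) - 1) < 1e-6))
})

test_that("training a planted bijection beats the random initialization", {
  # relation p maps entity i deterministically to entity i+10
  n <- 20L
  ids <- sprintf("E%02d", 1:n)
  ent <- data.frame(entity_id = ids, name = ids, entity_type = "Gene",
                    source_db = "s", stringsAsFactors = FALSE)
  tri <- data.frame(head_id = ids[1:10], relation = "p",
                    tail_id = ids[11:20], source_db = "s",
                    stringsAsFactors = FALSE)
  store <- kg_store(ent, tri)
  cfg <- train_config(dimension = 16L, batch_size = 10L, negatives = 8L,
                      epochs = 60L, seed = 5L, learning_rate = 0.05,
                      margin = 2)
  fit <- kg_embed(store, "transe", cfg)
  init <- kg_embed(store, "transe",
                   train_config(dimension = 16L, epochs = 0L, seed = 5L))
  ev_fit <- evaluate_filtered(fit, store$triples, store)
  ev_init <- evaluate_filtered(init, store$triples, store)
  expect_lt(mean(ev_fit$ranks), mean(ev_init$ranks))
})

test_that("filtered evaluation matches a brute-force oracle with ties", {
  store <- random_store(n_entities = 12L, n_triples = 45L, seed = 8L)
  cfg <- train_config(dimension = 4L, epochs = 0L, seed = 3L)
  fit <- kg_embed(store, "distmult", cfg)
  test <- store$triples[1:10, ]
  ev <- evaluate_filtered(fit, test, store, raw = TRUE)
  # oracle: directly rescore every candidate and rank with average ties
  ids <- fit$entity_ids
  oracle_ranks <- c()
  for (i in seq_len(nrow(test))) {
    h <- test$head_id[i]; r <- test$relation[i]; t <- test$tail_id[i]
    hv <- fit$E_re[match(h, ids), ]; rv <- fit$R_re[match(r, fit$relation_ids), ]
    s_tail <- vapply(ids, function(e)
      score_distmult(hv, rv, fit$E_re[match(e, ids), ]), numeric(1))
    s_head <- vapply(ids, function(e)
      score_distmult(fit$E_re[match(e, ids), ], rv,
                     fit$E_re[match(t, ids), ]), numeric(1))
    known_t <- store$triples$tail_id[store$triples$head_id == h &
                                       store$triples$relation == r]
    known_h <- store$triples$head_id[store$triples$tail_id == t &
                                       store$triples$relation == r]
    rk <- function(s, true_id, known) {
      keep <- !(ids %in% setdiff(known, true_id))
      sv <- s[keep]; st <- s[ids == true_id]
      sum(sv > st) + (sum(sv == st) + 1) / 2
    }
    oracle_ranks <- c(oracle_ranks, rk(s_tail, t, known_t),
                      rk(s_head, h, known_h))
  }
  expect_equal(ev$ranks, oracle_ranks)
  # filtered rank never exceeds raw rank; metric sanity
  expect_true(all(ev$ranks <= ev$raw_ranks))
  expect_gte(ev$mrr, ev$raw_mrr)
  hits <- ev$hits
  expect_true(all(diff(hits) >= 0))
  expect_gte(ev$mrr, hits[["hits@1"]])
  expect_lte(ev$mrr, 1)
  expect_error(evaluate_filtered(fit, test[0, ], store),
               class = "cmkg_argument_error")
})

test_that("an oracle-perfect model attains MRR 1 under filtering", {
  # embed a tiny bijective graph so the true triple scores strictly highest
  ids <- c("A", "B", "C", "D")
  ent <- data.frame(entity_id = ids, name = ids, entity_type = "Gene",
                    source_db = "s", stringsAsFactors = FALSE)
  tri <- data.frame(head_id = c("A", "C"), relation = "p",
                    tail_id = c("B", "D"), source_db = "s",
                    stringsAsFactors = FALSE)
  store <- kg_store(ent, tri)
  fit <- kg_embed(store, "transe", train_config(dimension = 2L, epochs = 0L,
                                                seed = 1L))
  # hand-set embeddings realizing the translation exactly
  fit$E_re <- rbind(c(0, 0), c(1, 0), c(5, 5), c(6, 5))
  fit$R_re <- matrix(c(1, 0), 1, 2)
  ev <- evaluate_filtered(fit, store$triples, store)
  expect_equal(ev$mrr, 1.0)
  expect_equal(unname(ev$hits[["hits@1"]]), 1.0)
})

test_that("checkpoints round-trip through plain-text files", {
  store <- random_store(n_entities = 10L, n_triples = 30L, seed = 4L)
  cfg <- train_config(dimension = 5L, batch_size = 8L, negatives = 2L,
                      epochs = 2L, seed = 9L, learning_rate = 0.05)
  fit <- kg_embed(store, "complex", cfg)
  dir <- withr::local_tempdir()
  save_embedding(fit, dir)
  back <- load_embedding(dir)
  expect_equal(back$model, "complex")
  expect_equal(back$E_re, fit$E_re, tolerance = 1e-12)
  expect_equal(back$E_im, fit$E_im, tolerance = 1e-12)
  expect_equal(predict(back, store$triples[1:5, ]),
               predict(fit, store$triples[1:5, ]), tolerance = 1e-10)
})

test_that("split fractions partition the triples", {
  store <- random_store(n_entities = 30L, n_triples = 200L, seed = 5L)
  sp <- kg_split(store, seed = 3L)
  n <- nrow(store$triples)
  expect_equal(nrow(sp$train) + nrow(sp$valid) + nrow(sp$test), n)
  key <- function(df) paste(df$head_id, df$relation, df$tail_id)
  expect_equal(length(intersect(key(sp$train), key(sp$test))), 0L)
  expect_equal(nrow(sp$train), floor(0.9 * n))
})
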