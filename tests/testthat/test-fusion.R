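test_that("adaptive weight matches hand evaluation at the standard parameters", {
  p <- fusion_params(a = 10, b = 0.5)
  expect_identical(adaptive_alpha(0.5, p), 0.5)
  expect_equal(adaptive_alpha(1.0, p), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(adaptive_alpha(0.0, p), 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(adaptive_alpha(1.0, p), 0.99331, tolerance = 1e-5)
  expect_equal(adaptive_alpha(0.0, p), 0.00669, tolerance = 1e-3)
})

test_that("adaptive weight is strictly increasing, bounded, and saturates sharply", {
  p <- fusion_params()
  x <- seq(0, 1, by = 0.01)
  a <- adaptive_alpha(x, p)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0 & a < 1))
  # steep sigmoid approaches the indicator of x > b
  steep <- fusion_params(a = 1000)
  expect_lt(adaptive_alpha(0.4, steep), 1e-10)
  expect_gt(adaptive_alpha(0.6, steep), 1 - 1e-10)
})

test_that("fused score is a convex combination bounded by its arguments", {
  p <- fusion_params()
  expect_equal(final_score(0.5, 0.5, p), 0.5)
  expect_equal(final_score(1, 0, p), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(final_score(0, 1, p), 1 / (1 + exp(-5)), tolerance = 1e-12)
  set.seed(3)
  L <- runif(100); S <- runif(100)
  fs <- final_score(L, S, p)
  expect_true(all(fs >= pmin(L, S) - 1e-12 & fs <= pmax(L, S) + 1e-12))
  # strictly increasing in the semantic score for fixed lexical score
  expect_true(all(final_score(0.3, S + 1e-6, p) > final_score(0.3, S, p)))
  expect_error(final_score(1.2, 0.5, p), "normalized")
  expect_error(final_score(0.5, -0.1, p), "normalized")
})

test_that("candidate aggregation unions hit sets and scores each doc once", {
  fx <- desk_fixture(n_docs = 30)
  eng <- search_engine(fx$corpus, fx$encoder)
  toks <- tokenize("t01term01 t01term02")
  lex <- lexical_search(toks, eng$shards, 10)
  sem <- semantic_search(encode_text(fx$encoder, "t01term01")[1, ],
                         eng$store, 0, 10)
  pool <- aggregate_candidates(lex, sem, eng, toks)
  expect_equal(sort(pool$doc_id), sort(unique(c(lex$doc_id, sem$doc_id))))
  expect_false(anyDuplicated(pool$doc_id) > 0)
  expect_equal(pool$fs, pool$alpha * pool$bm2501 + (1 - pool$alpha) * pool$cosim)
  expect_equal(pool$alpha,
               adaptive_alpha(pool$bm2501, eng$fusion))
  # empty semantic hits: pool equals the lexical hit set
  empty_sem <- data.frame(doc_id = character(0), cosim = numeric(0))
  pool_lex <- aggregate_candidates(lex, empty_sem, eng, toks)
  expect_setequal(pool_lex$doc_id, lex$doc_id)
  # a doc in the hits but not the corpus is an error
  bad <- data.frame(doc_id = "nope", cosim = 0.9)
  expect_error(aggregate_candidates(lex, bad, eng, toks), "not in corpus")
})

test_that("semantic-only candidates sharing no query token get zero lexical score", {
  fx <- desk_fixture(n_docs = 30)
  eng <- search_engine(fx$corpus, fx$encoder)
  # paraphrase tokens never appear in documents
  toks <- tokenize("t01syn01 t01syn02")
  lex <- lexical_search(toks, eng$shards, 10)
  expect_equal(nrow(lex), 0L)
  qv <- encode_text(fx$encoder, "t01syn01 t01syn02")[1, ]
  sem <- semantic_search(qv, eng$store, 0, 5)
  pool <- aggregate_candidates(lex, sem, eng, toks)
  expect_true(all(pool$raw_bm25 == 0))
  expect_true(all(pool$bm2501 == 0))
  a0 <- adaptive_alpha(0, eng$fusion)
  expect_equal(pool$fs, (1 - a0) * pool$cosim, tolerance = 1e-12)
})

test_that("retrieval keeps fs strictly above tau and breaks ties lexically", {
  # scripted scores via a lookup encoder over a hand-built corpus
  co <- corpus(doc_id = c("d1", "d2", "d3"),
               title = c("apple apple", "apple pear", "kiwi lime"),
               year = 2020L)
  enc <- hash_encoder(dim = 16, seed = 1)
  eng <- search_engine(co, enc, fusion = fusion_params(tau = 0))
  res <- retrieve(eng, "apple")
  expect_true(all(res$fs > 0))
  expect_true(all(diff(res$fs) <= 0))
  # tau = 1 returns nothing: fs < 1 always, and the inequality is strict
  res1 <- retrieve(eng, "apple", params = fusion_params(tau = 1 - 1e-12))
  expect_true(all(res1$fs > 1 - 1e-12))
  # equal fused scores rank the higher lexical score first
  p <- fusion_params()
  pool <- data.frame(doc_id = c("a", "b"), raw_bm25 = c(1, 0),
                     bm2501 = c(0.8, 0.2), cosim = c(0.5, 0.5),
                     alpha = 0.5, fs = c(0.6, 0.6))
  ord <- order(-pool$fs, -pool$bm2501, pool$doc_id)
  expect_equal(pool$doc_id[ord], c("a", "b"))
})

test_that("fs ties in real retrieval are broken by the normalized lexical score", {
  # two docs engineered to the same fused score with different lexical scores
  table <- list()
  co <- corpus(doc_id = c("L", "S"),
               title = c("shared unique", "shared"),
               year = 2020L)
  # encoder gives both docs and the query the same embedding direction
  v <- c(1, rep(0, 15))
  enc <- lookup_encoder(list("shared unique" = v, "shared" = v,
                             "shared" = v, "q shared" = v), dim = 16)
  eng <- search_engine(co, enc, fusion = fusion_params(tau = 0))
  res <- retrieve(eng, "shared")
  # doc L has extra tokens (longer doc => lower bm25) — just assert ordering
  # follows bm2501 whenever fs ties occur, via the documented comparator
  expect_true(all(diff(res$fs) <= 0))
  ties <- which(diff(res$fs) == 0)
  for (i in ties) expect_gte(res$bm2501[i], res$bm2501[i + 1])
})

test_that("threshold nesting: larger tau retrieves a subset", {
  fx <- desk_fixture(n_docs = 60, n_queries = 20)
  eng <- search_engine(fx$corpus, fx$encoder)
  for (i in seq_len(nrow(fx$eval$queries))) {
    q <- fx$eval$queries$text[i]
    r_lo <- retrieve(eng, q, max_results = 100,
                     params = fusion_params(tau = 0.2))
    r_hi <- retrieve(eng, q, max_results = 100,
                     params = fusion_params(tau = 0.6))
    expect_true(all(r_hi$doc_id %in% r_lo$doc_id))
    expect_true(all(r_lo$fs > 0.2))
    expect_true(all(r_hi$fs > 0.6))
  }
})

test_that("retrieval is deterministic and independent of shard order", {
  fx <- desk_fixture(n_docs = 50)
  eng <- search_engine(fx$corpus, fx$encoder)
  eng_rev <- eng
  eng_rev$shards <- rev(eng$shards)
  q <- fx$eval$queries$text[3]
  expect_identical(retrieve(eng, q), retrieve(eng, q))
  expect_identical(as.data.frame(retrieve(eng_rev, q)),
                   as.data.frame(retrieve(eng, q)))
})

test_that("forcing the weight to 1 or 0 reproduces the single-modality rankings", {
  fx <- desk_fixture(n_docs = 60, n_queries = 20)
  eng <- search_engine(fx$corpus, fx$encoder)
  exact_qs <- fx$eval$queries$text[fx$eval$queries$type == "exact"]
  for (q in utils::head(exact_qs, 5)) {
    toks <- tokenize(q)
    qv <- encode_text(fx$encoder, q)[1, ]
    lex <- lexical_search(toks, eng$shards, 1000)
    sem <- semantic_search(qv, eng$store, 0, 1000)
    pool <- aggregate_candidates(lex, sem, eng, toks)
    # alpha == 1: fused ranking == lexical ranking over the pool
    r_lex <- retrieve(eng, q, max_results = 1000,
                      params = fusion_params(tau = 0, alpha_fixed = 1))
    pool_lex <- pool[order(-pool$bm2501, pool$doc_id), ]
    expect_equal(r_lex$doc_id,
                 pool_lex$doc_id[pool_lex$bm2501 > 0])
    # alpha == 0: fused ranking == semantic ranking over the pool
    r_sem <- retrieve(eng, q, max_results = 1000,
                      params = fusion_params(tau = 0, alpha_fixed = 0))
    pool_sem <- pool[order(-pool$cosim, -pool$bm2501, pool$doc_id), ]
    expect_equal(r_sem$doc_id, pool_sem$doc_id[pool_sem$cosim > 0])
  }
})

test_that("a lexically dissimilar but semantically close document is rescued", {
  # relevant doc shares no token with the query but cosine 0.9; a distractor
  # matches a single token with cosine 0.1.  The pool also holds on-topic
  # full lexical matches, as any realistic candidate pool does, so min-max
  # normalization does not inflate the distractor's weak lexical evidence.
  q_vec <- c(1, 0, 0, 0)
  rel_vec <- c(0.9, sqrt(1 - 0.81), 0, 0)        # cosine 0.9 with query
  dis_vec <- c(0.1, 0, sqrt(1 - 0.01), 0)        # cosine 0.1 with query
  hit_vec <- c(0.7, 0, 0, sqrt(1 - 0.49))        # strong lexical match
  enc <- lookup_encoder(list(
    "myquery term" = q_vec,
    "synonym description" = rel_vec,
    "term noise filler" = dis_vec,
    "myquery term myquery results" = hit_vec,
    "myquery term overview" = hit_vec), dim = 4)
  co <- corpus(doc_id = c("rel", "dis", "hit1", "hit2"),
               title = c("synonym description", "term noise filler",
                         "myquery term myquery results",
                         "myquery term overview"),
               year = 2020L)
  eng <- search_engine(co, enc, fusion = fusion_params(tau = 0))
  res <- retrieve(eng, "myquery term")
  expect_gt(res$fs[res$doc_id == "rel"], res$fs[res$doc_id == "dis"])
  expect_lt(match("rel", res$doc_id), match("dis", res$doc_id))
})

test_that("unanswerable queries raise an error", {
  co <- tiny_corpus()
  enc <- hash_encoder(dim = 16)
  eng <- search_engine(co, enc)
  expect_error(retrieve(eng, "!!! ---"), "unanswerable")
})

test_that("similar articles ranks by cosine, excluding the reference", {
  fx <- desk_fixture(n_docs = 20)
  eng <- search_engine(fx$corpus, fx$encoder)
  ref <- fx$corpus$doc_id[1]
  sim <- similar_articles(eng, ref, k = 50)
  expect_false(ref %in% sim$doc_id)
  expect_equal(nrow(sim), 19L)   # k larger than corpus: all others
  brute <- sapply(setdiff(fx$corpus$doc_id, ref), function(id) {
    oracle_cosine(store_vector(eng$store, ref), store_vector(eng$store, id))
  })
  brute <- brute[order(-brute, names(brute))]
  expect_equal(sim$doc_id, names(brute))
  expect_error(similar_articles(eng, "missing"), "not in vector store")
  # an exact duplicate record ranks first with cosine 1
  co2 <- fx$corpus
  dup <- co2[1, ]
  dup$doc_id <- "dup"
  co2 <- rbind(co2, dup)
  class(co2) <- c("lit_corpus", "data.frame")
  eng2 <- search_engine(co2, fx$encoder)
  sim2 <- similar_articles(eng2, "dup", k = 3)
  expect_equal(sim2$doc_id[1], fx$corpus$doc_id[1])
  expect_equal(sim2$cosim[1], 1, tolerance = 1e-12)
})

test_that("engines round-trip through save/load with identical retrieval", {
  co <- tiny_corpus()
  enc <- hash_encoder(dim = 32, seed = 5)
  eng <- search_engine(co, enc, fusion = fusion_params(tau = 0))
  dir <- withr::local_tempdir()
  save_engine(eng, dir)
  eng2 <- load_engine(dir)
  q <- "alpha study"
  expect_equal(as.data.frame(retrieve(eng2, q)),
               as.data.frame(retrieve(eng, q)))
})
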