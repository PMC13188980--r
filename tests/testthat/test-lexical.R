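test_that("tokenizer lowercases, splits on non-alphanumerics, and is deterministic", {
  expect_equal(tokenize("BM25-based Search!"), c("bm25", "based", "search"))
  expect_equal(tokenize(""), character(0))
  expect_identical(tokenize("Héllo,  world_2"), tokenize("Héllo,  world_2"))
  expect_equal(tokenize("the quick fox", stopwords = c("the")),
               c("quick", "fox"))
})

test_that("shards partition the corpus by year with correct statistics", {
  co <- corpus(doc_id = c("a", "b", "c"),
               title = c("x y", "y z", "w"),
               year = c(2020L, 2020L, 2021L))
  sh <- build_shards(co)
  expect_named(sh, c("2020", "2021"))
  expect_equal(sh[["2020"]]$N, 2L)
  expect_equal(sh[["2021"]]$N, 1L)
  expect_equal(sh[["2020"]]$avgdl, 2)
  expect_equal(sh[["2020"]]$doc_freq[["y"]], 2L)
  expect_equal(sh[["2020"]]$postings[["y"]], c(a = 1L, b = 1L))
})

test_that("shard term statistics equal a brute-force recount", {
  docs <- random_token_corpus(25, seed = 3)
  co <- token_corpus_to_lit(docs)
  sh <- build_shards(co)[[1]]
  expect_equal(sh$N, length(docs))
  expect_equal(sh$avgdl, mean(sapply(docs, length)))
  for (term in names(sh$postings)) {
    n_brute <- sum(sapply(docs, function(d) term %in% d))
    expect_equal(unname(sh$doc_freq[term]), n_brute)
    for (id in names(sh$postings[[term]])) {
      expect_equal(unname(sh$postings[[term]][id]), sum(docs[[id]] == term))
    }
  }
})

test_that("idf matches hand evaluation of the formula", {
  sh <- structure(list(N = 4L, doc_freq = c(w = 2L)), class = "lexical_shard")
  expect_equal(idf("w", sh), log(2), tolerance = 1e-12)
  sh1 <- structure(list(N = 1L, doc_freq = c(w = 1L)), class = "lexical_shard")
  expect_equal(idf("w", sh1), log(4 / 3), tolerance = 1e-12)
  # absent term uses n = 0 and stays positive for any N >= 1
  for (N in c(1L, 5L, 1000L)) {
    shN <- structure(list(N = N, doc_freq = integer(0)),
                     class = "lexical_shard")
    expect_gt(idf("absent", shN), 0)
  }
})

test_that("bm25 collapses to IDF when tf = 1 and |d| = avgdl", {
  # all docs the same length, query term once in the target doc
  co <- corpus(doc_id = c("a", "b", "c"),
               title = c("apple pear plum", "kiwi lime pear", "fig date plum"),
               year = 2020L)
  sh <- build_shards(co)[["2020"]]
  expect_equal(bm25_score("apple", "a", sh), idf("apple", sh),
               tolerance = 1e-12)
  expect_equal(bm25_score(c("missing", "tokens"), "a", sh), 0)
  expect_error(bm25_score("apple", "nope", sh), "unknown doc_id")
})

test_that("bm25 matches the brute-force oracle on random corpora", {
  params <- lexical_params()
  for (rep in 1:12) {
    docs <- random_token_corpus(20, seed = 100 + rep)
    co <- token_corpus_to_lit(docs)
    sh <- build_shards(co, params)[[1]]
    set.seed(200 + rep)
    for (qi in 1:5) {
      q <- sample(sprintf("w%02d", 1:12), sample(1:4, 1), replace = TRUE)
      id <- sample(names(docs), 1)
      expect_equal(bm25_score(q, id, sh, params),
                   oracle_bm25(q, docs, id, params$k1, params$b),
                   tolerance = 1e-9)
    }
  }
})

test_that("single-shard lexical search equals global brute-force ranking", {
  docs <- random_token_corpus(30, seed = 9)
  co <- token_corpus_to_lit(docs)
  sh <- build_shards(co)
  q <- c("w01", "w05", "w05")
  hits <- lexical_search(q, sh, top_m = 100)
  ora <- oracle_bm25_ranking(q, docs, 1.5, 0.75)
  expect_equal(hits$doc_id, names(ora))
  expect_equal(hits$score, unname(ora), tolerance = 1e-9)
  expect_equal(nrow(lexical_search("zzz", sh, 10)), 0L)
})

test_that("pooled ranking is independent of shard evaluation order", {
  fx <- desk_fixture(n_docs = 60)
  sh <- build_shards(fx$corpus)
  q <- tokenize("t01term01 t02term03")
  r1 <- lexical_search(q, sh, 50)
  r2 <- lexical_search(q, rev(sh), 50)
  expect_identical(r1, r2)
})

test_that("adding a document changes only corpus-level shard statistics", {
  docs <- random_token_corpus(10, seed = 4)
  co_small <- token_corpus_to_lit(docs)
  extra <- c(docs, list(dnew = c("w01", "w01", "w07")))
  co_big <- token_corpus_to_lit(extra)
  sh_small <- build_shards(co_small)[[1]]
  sh_big <- build_shards(co_big)[[1]]
  expect_equal(sh_big$N, sh_small$N + 1L)
  for (term in names(sh_small$postings)) {
    old <- sh_small$postings[[term]]
    new <- sh_big$postings[[term]][names(old)]
    expect_equal(new, old)   # existing docs' term frequencies untouched
  }
})

test_that("bm2501 maps to [0,1) preserving order, all-equal input to zeros", {
  out <- bm2501(c(2, 4, 6), epsilon = 1e-9)
  expect_equal(out, c(0, 0.5, 1), tolerance = 1e-8)
  expect_true(all(out >= 0 & out < 1))
  expect_equal(bm2501(c(3, 3, 3)), c(0, 0, 0))
  expect_false(anyNA(bm2501(c(3, 3, 3))))
  expect_equal(bm2501(7), 0)
  expect_equal(bm2501(numeric(0)), numeric(0))
  # order preservation and shift invariance on random input
  set.seed(1)
  x <- rnorm(50)
  expect_equal(order(bm2501(x)), order(x))
  expect_equal(bm2501(x + 100), bm2501(x), tolerance = 1e-6)
})

test_that("shards serialize and reload with identical scoring behaviour", {
  docs <- random_token_corpus(15, seed = 5)
  co <- token_corpus_to_lit(docs)
  sh <- build_shards(co)
  path <- withr::local_tempfile(fileext = ".json")
  save_shards(sh, path)
  sh2 <- load_shards(path)
  q <- c("w02", "w11")
  expect_equal(lexical_search(q, sh2, 50), lexical_search(q, sh, 50))
  expect_error(load_shards(withr::local_tempfile()), "no such shard")
})
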