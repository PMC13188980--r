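# Independent brute-force oracles, written directly from the defining
# formulas and kept separate from the package's implementation paths.

# BM25 by direct counting: tokenizes every document itself, counts term
# frequencies with explicit loops, and evaluates the scoring formula
# term by term.
oracle_bm25 <- function(query_tokens, doc_tokens_list, doc_id, k1, b) {
  N <- length(doc_tokens_list)
  lens <- sapply(doc_tokens_list, length)
  avgdl <- sum(lens) / N
  d <- doc_tokens_list[[doc_id]]
  total <- 0
  for (q in query_tokens) {
    n_q <- 0
    for (toks in doc_tokens_list) if (q %in% toks) n_q <- n_q + 1
    f <- sum(d == q)
    idf_q <- log((N - n_q + 0.5) / (n_q + 0.5) + 1)
    total <- total + idf_q * (f * (k1 + 1)) /
      (f + k1 * (1 - b + b * length(d) / avgdl))
  }
  total
}

# Full-ranking brute force over one tokenized corpus.
oracle_bm25_ranking <- function(query_tokens, doc_tokens_list, k1, b) {
  scores <- sapply(names(doc_tokens_list), function(id) {
    oracle_bm25(query_tokens, doc_tokens_list, id, k1, b)
  })
  scores <- scores[scores > 0]
  scores[order(-scores, names(scores))]
}

oracle_cosine <- function(q, d) {
  num <- 0; sq <- 0; sd_ <- 0
  for (i in seq_along(q)) {
    num <- num + q[i] * d[i]
    sq <- sq + q[i]^2
    sd_ <- sd_ + d[i]^2
  }
  num / (sqrt(sq) * sqrt(sd_))
}

# Reference ranked metrics, each evaluated by explicit position loops.
oracle_ndcg <- function(ranking, relevant, k) {
  dcg <- 0
  for (i in seq_len(min(k, length(ranking)))) {
    if (ranking[i] %in% relevant) dcg <- dcg + 1 / (log(i + 1) / log(2))
  }
  idcg <- 0
  for (i in seq_len(min(k, length(relevant)))) {
    idcg <- idcg + 1 / (log(i + 1) / log(2))
  }
  dcg / idcg
}

oracle_ap <- function(ranking, relevant, k) {
  hits <- 0
  s <- 0
  for (i in seq_len(min(k, length(ranking)))) {
    if (ranking[i] %in% relevant) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / min(length(relevant), k)
}

oracle_rr <- function(ranking, relevant, k) {
  for (i in seq_len(min(k, length(ranking)))) {
    if (ranking[i] %in% relevant) return(1 / i)
  }
  0
}

# Random tokenized corpus for the lexical oracle checks.
random_token_corpus <- function(n_docs, vocab_size = 12, seed = 1) {
  set.seed(seed)
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  docs <- lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(3:25, 1), replace = TRUE)
  })
  names(docs) <- sprintf("d%03d", seq_len(n_docs))
  docs
}

# Wraps a tokenized corpus into a lit_corpus (single year so one shard).
token_corpus_to_lit <- function(docs, year = 2020L) {
  corpus(doc_id = names(docs),
         title = vapply(docs, function(t) paste(t, collapse = " "),
                        character(1)),
         year = year)
}
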