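# Per-year BM25 lexical index: tokenization, shard construction, scoring,
# and min-max score normalization.

SHARD_SCHEMA_VERSION <- "1"

#' BM25 parameters
#'
#' `k1` controls term-frequency saturation and `b` the strength of document
#' length normalization.  Defaults are the standard Okapi settings.  Note
#' `b` here is the BM25 length-normalization exponent, unrelated to the
#' sigmoid midpoint of [fusion_params()].
#'
#' @param k1 positive real, term-frequency saturation (default 1.5).
#' @param b real in `[0, 1]`, length-normalization strength (default 0.75).
#' @return an object of class `lexical_params`.
#' @export
lexical_params <- function(k1 = 1.5, b = 0.75) {
  stopifnot(is.numeric(k1), length(k1) == 1L, k1 > 0,
            is.numeric(b), length(b) == 1L, b >= 0, b <= 1)
  structure(list(k1 = k1, b = b), class = "lexical_params")
}

#' Tokenize text
#'
#' Lowercases and splits on runs of non-alphanumeric characters.  No stemming.
#' Deterministic: the same input always yields the same token sequence.
#'
#' @param text character vector.
#' @param stopwords optional character vector of tokens to remove (default
#'   none).
#' @return for a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @export
tokenize <- function(text, stopwords = NULL) {
  toks <- strsplit(tolower(normalize_text(text)), "[^[:alnum:]]+", perl = TRUE)
  toks <- lapply(toks, function(t) {
    t <- t[nzchar(t)]
    if (!is.null(stopwords)) t <- t[!t %in% stopwords]
    t
  })
  if (length(toks) == 1L) toks[[1]] else toks
}

# Builds one shard's statistics from token lists.
.build_shard <- function(key, doc_ids, token_lists, params) {
  doc_len <- vapply(token_lists, length, integer(1))
  names(doc_len) <- doc_ids
  postings <- new.env(parent = emptyenv())
  for (i in seq_along(doc_ids)) {
    tab <- table(token_lists[[i]])
    for (j in seq_along(tab)) {
      term <- names(tab)[j]
      cur <- postings[[term]]
      if (is.null(cur)) cur <- integer(0)
      cur[doc_ids[i]] <- as.integer(tab[j])
      postings[[term]] <- cur
    }
  }
  terms <- sort(ls(postings))
  postings_list <- lapply(terms, function(t) postings[[t]])
  names(postings_list) <- terms
  structure(list(
    shard_key = key,
    N = length(doc_ids),
    avgdl = mean(doc_len),
    doc_len = doc_len,
    postings = postings_list,
    doc_freq = vapply(postings_list, length, integer(1)),
    params = params
  ), class = "lexical_shard")
}

#' @export
print.lexical_shard <- function(x, ...) {
  cat(sprintf("<lexical_shard '%s'> N=%d, avgdl=%.1f, vocabulary=%d terms\n",
              x$shard_key, x$N, x$avgdl, length(x$postings)))
  invisible(x)
}

#' Build per-year BM25 shards
#'
#' Partitions the corpus by publication year (sentinel shard `"unknown"` for
#' records without a resolvable year) and builds one inverted index per
#' shard with shard-local statistics: document count `N`, average document
#' length `avgdl`, per-document token counts, term postings `f(term, d)` and
#' document frequencies `n(term)`.  Every record lands in exactly one shard.
#'
#' @param corpus a [corpus()].
#' @param params [lexical_params()].
#' @param stopwords optional stopword list forwarded to [tokenize()].
#' @return named list of `lexical_shard` objects, keyed by year.
#' @export
build_shards <- function(corpus, params = lexical_params(), stopwords = NULL) {
  stopifnot(inherits(corpus, "lit_corpus"), nrow(corpus) >= 1L)
  txt <- index_text(corpus)
  toks <- lapply(txt, tokenize, stopwords = stopwords)
  keys <- shard_key(corpus)
  shards <- lapply(split(seq_len(nrow(corpus)), keys), function(idx) {
    .build_shard(keys[idx[1]], corpus$doc_id[idx], toks[idx], params)
  })
  shards[order(names(shards))]
}

#' Inverse document frequency of a term within a shard
#'
#' `IDF(q) = log((N - n(q) + 0.5) / (n(q) + 0.5) + 1)` with the natural
#' logarithm, where `N` is the shard's document count and `n(q)` the number
#' of documents containing the term.  The `+1` inside the log keeps the
#' weight non-negative even for terms present in more than half the shard.
#' A term absent from the shard uses `n = 0`.
#'
#' @param term a single token.
#' @param shard a `lexical_shard`.
#' @return non-negative real.
#' @export
idf <- function(term, shard) {
  n <- unname(shard$doc_freq[term])
  if (length(n) == 0L || is.na(n)) n <- 0L
  log((shard$N - n + 0.5) / (n + 0.5) + 1)
}

#' BM25 score of one document for a query
#'
#' Sums, over the query tokens, `IDF(q) * f(q,d) * (k1 + 1) /
#' (f(q,d) + k1 * (1 - b + b * |d| / avgdl))` with shard-local statistics.
#' Tokens that do not occur in the document contribute zero; repeated query
#' tokens contribute once per occurrence in the query.
#'
#' @param query_tokens character vector of query tokens.
#' @param doc_id a document id present in `shard`.
#' @param shard a `lexical_shard`.
#' @param params [lexical_params()]; defaults to the shard's own.
#' @return non-negative real.
#' @export
bm25_score <- function(query_tokens, doc_id, shard, params = shard$params) {
  if (!doc_id %in% names(shard$doc_len)) {
    stop("unknown doc_id in shard '", shard$shard_key, "': ", doc_id)
  }
  dl <- unname(shard$doc_len[doc_id])
  k1 <- params$k1
  norm <- k1 * (1 - params$b + params$b * dl / shard$avgdl)
  s <- 0
  for (q in query_tokens) {
    post <- shard$postings[[q]]
    f <- if (is.null(post)) 0 else unname(post[doc_id])
    if (length(f) && !is.na(f) && f > 0) {
      s <- s + idf(q, shard) * f * (k1 + 1) / (f + norm)
    }
  }
  s
}

# Scores every document in a shard that contains at least one query token.
.shard_candidates <- function(query_tokens, shard, params = shard$params) {
  hit_ids <- unique(unlist(lapply(unique(query_tokens),
                                  function(q) names(shard$postings[[q]]))))
  if (is.null(hit_ids) || !length(hit_ids)) {
    return(data.frame(doc_id = character(0), score = numeric(0)))
  }
  hit_ids <- sort(hit_ids)
  data.frame(doc_id = hit_ids,
             score = vapply(hit_ids, bm25_score, numeric(1),
                            query_tokens = query_tokens, shard = shard,
                            params = params),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Search all shards lexically
#'
#' Scores each shard independently with its own statistics, pools the
#' per-shard candidates, and returns the `top_m` documents by raw BM25 score
#' (ties broken by lexicographic `doc_id`).  Only documents sharing at least
#' one query token are returned; the result is independent of shard
#' evaluation order.
#'
#' @param query_tokens character vector of query tokens.
#' @param shards named list from [build_shards()].
#' @param top_m maximum number of hits (>= 1).
#' @return data frame with columns `doc_id`, `score`, sorted by descending
#'   score.
#' @export
lexical_search <- function(query_tokens, shards, top_m = 1000L) {
  stopifnot(top_m >= 1L)
  pooled <- do.call(rbind, lapply(shards, .shard_candidates,
                                  query_tokens = query_tokens))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(data.frame(doc_id = character(0), score = numeric(0)))
  }
  ord <- order(-pooled$score, pooled$doc_id)
  pooled <- pooled[ord, , drop = FALSE]
  rownames(pooled) <- NULL
  utils::head(pooled, top_m)
}

#' Min-max normalize raw BM25 scores to `[0, 1)`
#'
#' Each score `s` maps to `(s - min) / (max - min + epsilon)`.  The small
#' positive `epsilon` in the denominator prevents division by zero: when all
#' scores are equal the output is all zeros rather than `NaN`.  The mapping
#' is monotone, so ranking order is preserved, and the best score normalizes
#' to just under 1.
#'
#' @param raw_scores numeric vector of raw BM25 scores.
#' @param epsilon small positive constant (default `1e-9`).
#' @return numeric vector in `[0, 1)`, same length and order.
#' @export
bm2501 <- function(raw_scores, epsilon = 1e-9) {
  stopifnot(epsilon > 0)
  if (length(raw_scores) == 0L) return(numeric(0))
  lo <- min(raw_scores)
  hi <- max(raw_scores)
  (raw_scores - lo) / (hi - lo + epsilon)
}

#' Save / load lexical shards
#'
#' Single-file JSON layout with a version tag; the term dictionary is stored
#' sorted so the byte output is reproducible for a fixed corpus.
#'
#' @param shards named list from [build_shards()].
#' @param path file path.
#' @return `save_shards()` returns `path` invisibly; `load_shards()` the
#'   shard list.
#' @export
save_shards <- function(shards, path) {
  payload <- list(
    schema = "litfuse-shards", schema_version = SHARD_SCHEMA_VERSION,
    shards = lapply(shards, function(s) {
      list(shard_key = s$shard_key, N = s$N, avgdl = s$avgdl,
           doc_len = as.list(s$doc_len),
           postings = lapply(s$postings, as.list),
           params = unclass(s$params))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_shards
#' @export
load_shards <- function(path) {
  if (!file.exists(path)) stop("no such shard file: ", path)
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "litfuse-shards") ||
      !identical(as.character(payload$schema_version), SHARD_SCHEMA_VERSION)) {
    stop("not a litfuse shard store (or version mismatch): ", path)
  }
  lapply(payload$shards, function(s) {
    postings <- lapply(s$postings, function(p) {
      v <- vapply(p, as.integer, integer(1))
      v
    })
    structure(list(
      shard_key = s$shard_key, N = as.integer(s$N), avgdl = as.numeric(s$avgdl),
      doc_len = vapply(s$doc_len, as.integer, integer(1)),
      postings = postings,
      doc_freq = vapply(postings, length, integer(1)),
      params = lexical_params(k1 = s$params$k1, b = s$params$b)
    ), class = "lexical_shard")
  })
}
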