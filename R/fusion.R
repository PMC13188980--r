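# Sigmoid-adaptive fusion of normalized lexical and semantic scores, and the
# thresholded ranked retrieval built on it.

#' Fusion parameters
#'
#' `a` sets the sharpness of the sigmoid transition between the semantic- and
#' lexical-dominated regimes and `b` its midpoint on the normalized lexical
#' score axis; the defaults `a = 10`, `b = 0.5` give a balanced hand-off
#' across query types.  `tau` is the retrieval threshold: only documents with
#' fused score strictly above `tau` are returned.  `epsilon` guards the
#' min-max denominator of [bm2501()], and `t_cutoff` is the cosine retention
#' threshold of [semantic_search()].
#'
#' @param a positive real, sigmoid sharpness (default 10).
#' @param b real in `[0, 1]`, sigmoid midpoint (default 0.5).
#' @param tau retrieval threshold in `[0, 1)` (default 0.35).
#' @param epsilon small positive constant for score normalization.
#' @param t_cutoff semantic retention threshold, `>= 0`.
#' @param top_m per-modality candidate pool size before fusion.
#' @param alpha_fixed optional constant in `[0, 1]` overriding the adaptive
#'   weight; `alpha_fixed = 1` gives a pure-lexical ranking of the candidate
#'   pool and `alpha_fixed = 0` a pure-semantic one (ablation modes).
#' @return an object of class `fusion_params`.
#' @export
fusion_params <- function(a = 10, b = 0.5, tau = 0.35, epsilon = 1e-9,
                          t_cutoff = 0, top_m = 1000L, alpha_fixed = NULL) {
  stopifnot(a > 0, b >= 0, b <= 1, tau >= 0, tau < 1, epsilon > 0,
            t_cutoff >= 0, top_m >= 1L)
  if (!is.null(alpha_fixed)) {
    stopifnot(alpha_fixed >= 0, alpha_fixed <= 1)
  }
  structure(list(a = a, b = b, tau = tau, epsilon = epsilon,
                 t_cutoff = t_cutoff, top_m = as.integer(top_m),
                 alpha_fixed = alpha_fixed),
            class = "fusion_params")
}

#' Adaptive lexical weight
#'
#' The fusion weight is a sigmoid of the normalized lexical score:
#' `alpha(x) = 1 / (1 + exp(-a (x - b)))`.  Queries with strong exact-term
#' evidence (`x` near 1) are weighted towards the lexical score; queries with
#' weak lexical evidence lean on the semantic score.  Strictly increasing in
#' `x` and bounded in `(0, 1)`.
#'
#' @param x normalized lexical score(s) in `[0, 1]`.
#' @param params [fusion_params()].
#' @return value(s) in `(0, 1)`.
#' @export
adaptive_alpha <- function(x, params = fusion_params()) {
  if (!is.null(params$alpha_fixed)) return(rep(params$alpha_fixed, length(x)))
  1 / (1 + exp(-params$a * (x - params$b)))
}

#' Fused final score
#'
#' `FS = alpha * L + (1 - alpha) * S` where `L` is the normalized lexical
#' score, `S` the cosine similarity, and `alpha = adaptive_alpha(L)`.  A
#' convex combination, so the result always lies between `min(L, S)` and
#' `max(L, S)`.
#'
#' @param bm2501_score normalized lexical score(s) in `[0, 1]`.
#' @param cosim_score semantic score(s) in `[0, 1]`.
#' @param params [fusion_params()].
#' @return fused score(s) in `[0, 1]`.
#' @export
final_score <- function(bm2501_score, cosim_score, params = fusion_params()) {
  if (any(bm2501_score < 0 | bm2501_score > 1, na.rm = TRUE) ||
      any(cosim_score < 0 | cosim_score > 1, na.rm = TRUE)) {
    stop("final_score() expects both scores normalized to [0, 1]")
  }
  alpha <- adaptive_alpha(bm2501_score, params)
  alpha * bm2501_score + (1 - alpha) * cosim_score
}

#' Build a hybrid search engine
#'
#' Bundles everything query-time retrieval needs: the corpus, its per-year
#' BM25 shards, the vector store, the encoder (used to embed queries), and
#' the scoring parameters.
#'
#' @param corpus a [corpus()].
#' @param encoder a [text_encoder()].
#' @param lexical [lexical_params()].
#' @param fusion [fusion_params()].
#' @param precision vector-store precision, `"full"` or `"half"`.
#' @param stopwords optional stopword list for tokenization.
#' @return an object of class `search_engine`.
#' @export
search_engine <- function(corpus, encoder, lexical = lexical_params(),
                          fusion = fusion_params(),
                          precision = c("full", "half"), stopwords = NULL) {
  precision <- match.arg(precision)
  shards <- build_shards(corpus, lexical, stopwords = stopwords)
  store <- build_vector_store(corpus, encoder, precision)
  structure(list(corpus = corpus, shards = shards, store = store,
                 encoder = encoder, lexical = lexical, fusion = fusion,
                 stopwords = stopwords),
            class = "search_engine")
}

#' @export
print.search_engine <- function(x, ...) {
  cat(sprintf(
    "<search_engine> %d docs, %d year shard(s), encoder '%s' (dim %d, %s)\n",
    nrow(x$corpus), length(x$shards), x$encoder$name, x$encoder$dim,
    x$store$precision))
  cat(sprintf("  k1=%.2f b=%.2f | a=%g b=%g tau=%g t=%g\n",
              x$lexical$k1, x$lexical$b, x$fusion$a, x$fusion$b,
              x$fusion$tau, x$fusion$t_cutoff))
  invisible(x)
}

#' @export
summary.search_engine <- function(object, ...) {
  print(object)
  for (s in object$shards) print(s)
  invisible(object)
}

#' Aggregate lexical and semantic hits into one scored candidate pool
#'
#' The candidate pool is the union of the two hit sets.  Every pool member
#' gets a raw BM25 score against its year shard (0 when it shares no query
#' token), and a cosine score from the vector store (similarities below the
#' cutoff `t` count as 0).  Min-max normalization ([bm2501()]) is applied
#' over the pooled raw scores, so the best lexical hit in the pool
#' normalizes to just under 1; then each candidate receives exactly one
#' fused score.
#'
#' @param lexical_hits data frame from [lexical_search()].
#' @param semantic_hits data frame from [semantic_search()].
#' @param engine a [search_engine()].
#' @param query_tokens tokenized query.
#' @param params [fusion_params()].
#' @return data frame with columns `doc_id`, `raw_bm25`, `bm2501`, `cosim`,
#'   `alpha`, `fs`, one row per pool member (unordered).
#' @export
aggregate_candidates <- function(lexical_hits, semantic_hits, engine,
                                 query_tokens, params = engine$fusion) {
  ids <- sort(unique(c(lexical_hits$doc_id, semantic_hits$doc_id)))
  if (!length(ids)) {
    return(data.frame(doc_id = character(0), raw_bm25 = numeric(0),
                      bm2501 = numeric(0), cosim = numeric(0),
                      alpha = numeric(0), fs = numeric(0)))
  }
  missing <- setdiff(ids, engine$corpus$doc_id)
  if (length(missing)) {
    stop("candidate doc_id(s) not in corpus: ", paste(missing, collapse = ", "))
  }
  keys <- shard_key(engine$corpus)
  raw <- numeric(length(ids))
  lex_idx <- match(ids, lexical_hits$doc_id)
  for (i in seq_along(ids)) {
    if (!is.na(lex_idx[i])) {
      raw[i] <- lexical_hits$score[lex_idx[i]]
    } else if (length(query_tokens)) {
      # semantic-only candidate: evaluate BM25 in its own shard (0 when it
      # shares no query token)
      raw[i] <- bm25_score(query_tokens, ids[i],
                           engine$shards[[keys[[ids[i]]]]], engine$lexical)
    }
  }
  cs <- numeric(length(ids))
  sem_idx <- match(ids, semantic_hits$doc_id)
  cs[!is.na(sem_idx)] <- semantic_hits$cosim[sem_idx[!is.na(sem_idx)]]
  cs[cs < params$t_cutoff] <- 0   # below-cutoff similarity contributes nothing
  cs <- pmax(cs, 0)
  norm <- bm2501(raw, params$epsilon)
  alpha <- adaptive_alpha(norm, params)
  data.frame(doc_id = ids, raw_bm25 = raw, bm2501 = norm, cosim = cs,
             alpha = alpha, fs = alpha * norm + (1 - alpha) * cs,
             stringsAsFactors = FALSE)
}

#' Retrieve documents for a free-text query
#'
#' Runs the full hybrid pipeline: tokenize and embed the query, search the
#' BM25 shards and the vector store in parallel (each capped at
#' `params$top_m` candidates), aggregate the union into one scored pool
#' ([aggregate_candidates()]), keep documents with fused score strictly
#' above `tau`, and sort by fused score.  Ties on the fused score are
#' resolved in favour of the higher normalized lexical score (preserving
#' precision for exact term matches), then lexicographic `doc_id`.
#'
#' @param engine a [search_engine()].
#' @param query query text.
#' @param max_results maximum rows returned (default 20).
#' @param params [fusion_params()]; defaults to the engine's.
#' @return data frame of scored candidates (class `lit_results`), best
#'   first, with the query string as attribute `query`.
#' @export
retrieve <- function(engine, query, max_results = 20L,
                     params = engine$fusion) {
  stopifnot(inherits(engine, "search_engine"), max_results >= 1L)
  toks <- tokenize(query, stopwords = engine$stopwords)
  qvec <- encode_text(engine$encoder, query)[1L, ]
  lex <- if (length(toks)) {
    lexical_search(toks, engine$shards, params$top_m)
  } else data.frame(doc_id = character(0), score = numeric(0))
  sem <- if (sum(qvec^2) > 0) {
    semantic_search(qvec, engine$store, params$t_cutoff, params$top_m)
  } else data.frame(doc_id = character(0), cosim = numeric(0))
  if (!length(toks) && sum(qvec^2) == 0) {
    stop("unanswerable query: no tokens and zero-vector embedding")
  }
  pool <- aggregate_candidates(lex, sem, engine, toks, params)
  pool <- pool[pool$fs > params$tau, , drop = FALSE]
  pool <- pool[order(-pool$fs, -pool$bm2501, pool$doc_id), , drop = FALSE]
  rownames(pool) <- NULL
  out <- utils::head(pool, max_results)
  attr(out, "query") <- query
  class(out) <- c("lit_results", "data.frame")
  out
}

#' @export
print.lit_results <- function(x, ...) {
  q <- attr(x, "query")
  cat(sprintf("<lit_results> %d hit(s)%s\n", nrow(x),
              if (!is.null(q)) paste0(" for query: \"", q, "\"") else ""))
  if (nrow(x)) {
    print.data.frame(utils::head(
      transform(as.data.frame(x), fs = round(fs, 4), bm2501 = round(bm2501, 4),
                cosim = round(cosim, 4), alpha = round(alpha, 4),
                raw_bm25 = round(raw_bm25, 4)), 10L))
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Find articles semantically similar to a reference article
#'
#' Cosine-only ranking of every other stored vector against the reference
#' document's embedding; the reference itself is excluded.
#'
#' @param engine a [search_engine()].
#' @param doc_id reference document id (must be indexed).
#' @param k number of neighbours to return.
#' @return data frame with columns `doc_id`, `cosim`, best first.
#' @export
similar_articles <- function(engine, doc_id, k = 10L) {
  ref <- store_vector(engine$store, doc_id)   # errors on unknown id
  vecs <- engine$store$vectors
  sims <- as.numeric(vecs %*% ref) /
    (sqrt(rowSums(vecs^2)) * sqrt(sum(ref^2)))
  res <- data.frame(doc_id = rownames(vecs), cosim = sims,
                    stringsAsFactors = FALSE)
  res <- res[res$doc_id != doc_id, , drop = FALSE]
  res <- res[order(-res$cosim, res$doc_id), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, k)
}

#' Save / load a search engine
#'
#' Writes the corpus, shards, and vector store as single-file stores in a
#' directory, plus a `manifest.json` tying the component schema versions and
#' the encoder identity together.  The encoder itself is code, not data:
#' `load_engine()` rebuilds hash-mode test encoders from the manifest and
#' otherwise requires the encoder to be passed back in.
#'
#' @param engine a [search_engine()].
#' @param dir directory path (created if needed).
#' @param encoder optional [text_encoder()] for `load_engine()`.
#' @return `save_engine()` returns `dir` invisibly; `load_engine()` a
#'   `search_engine`.
#' @export
save_engine <- function(engine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_corpus(engine$corpus, file.path(dir, "corpus.json"))
  save_shards(engine$shards, file.path(dir, "shards.json"))
  save_vector_store(engine$store, file.path(dir, "vectors.json"))
  manifest <- list(
    schema = "litfuse-engine", schema_version = "1",
    corpus_version = CORPUS_SCHEMA_VERSION,
    shard_version = SHARD_SCHEMA_VERSION,
    store_version = STORE_SCHEMA_VERSION,
    encoder = engine$encoder$name, dim = engine$encoder$dim,
    lexical = unclass(engine$lexical),
    fusion = unclass(engine$fusion))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_engine
#' @export
load_engine <- function(dir, encoder = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$schema, "litfuse-engine")) {
    stop("not a litfuse engine directory: ", dir)
  }
  if (is.null(encoder)) {
    if (grepl("^hash-", manifest$encoder)) {
      seed <- as.integer(sub("^hash-d[0-9]+-s", "", manifest$encoder))
      encoder <- hash_encoder(dim = as.integer(manifest$dim), seed = seed)
    } else {
      stop("engine was built with encoder '", manifest$encoder,
           "'; pass it to load_engine(encoder = )")
    }
  }
  fusion <- manifest$fusion
  structure(list(
    corpus = load_corpus(file.path(dir, "corpus.json")),
    shards = load_shards(file.path(dir, "shards.json")),
    store = load_vector_store(file.path(dir, "vectors.json")),
    encoder = encoder,
    lexical = lexical_params(manifest$lexical$k1, manifest$lexical$b),
    fusion = fusion_params(fusion$a, fusion$b, fusion$tau, fusion$epsilon,
                           fusion$t_cutoff, fusion$top_m),
    stopwords = NULL), class = "search_engine")
}
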