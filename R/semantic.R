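# Embedding-based semantic index: pluggable encoder contract, vector store
# (full or half precision), and exact cosine-similarity search.

STORE_SCHEMA_VERSION <- "1"

#' Construct a text encoder
#'
#' An encoder is the contract the semantic index builds on: a deterministic
#' function from text to a fixed-dimension real vector.  Any encoder (a
#' production sentence transformer, the deterministic test encoders of
#' [hash_encoder()] / [topic_encoder()], a lookup table) plugs in through
#' this constructor.  Encoders that need query prompts or other text
#' preprocessing implement it inside `fun`.
#'
#' @param fun function taking a single string and returning a numeric vector
#'   of length `dim`.
#' @param dim positive integer, the output dimension.
#' @param name short identifier used in store manifests.
#' @return an object of class `text_encoder`.
#' @export
text_encoder <- function(fun, dim, name = "custom") {
  stopifnot(is.function(fun), dim >= 1L)
  structure(list(fun = fun, dim = as.integer(dim), name = name),
            class = "text_encoder")
}

#' @export
print.text_encoder <- function(x, ...) {
  cat(sprintf("<text_encoder '%s'> dim=%d\n", x$name, x$dim))
  invisible(x)
}

#' Encode texts to embedding vectors
#'
#' @param encoder a [text_encoder()].
#' @param texts character vector.
#' @return numeric matrix with one row per text and `encoder$dim` columns.
#' @export
encode_text <- function(encoder, texts) {
  stopifnot(inherits(encoder, "text_encoder"))
  out <- matrix(0, nrow = length(texts), ncol = encoder$dim)
  for (i in seq_along(texts)) {
    v <- encoder$fun(texts[i])
    if (length(v) != encoder$dim || any(!is.finite(v))) {
      stop("encoder '", encoder$name, "' returned an invalid vector for text ",
           i, " (need ", encoder$dim, " finite values)")
    }
    out[i, ] <- v
  }
  rownames(out) <- names(texts)
  out
}

#' Cosine similarity between two vectors
#'
#' `q . d / (||q|| ||d||)`, the scale-invariant angular similarity in
#' `[-1, 1]`.  Both vectors must be non-zero.
#'
#' @param q,d numeric vectors of equal length.
#' @return a real in `[-1, 1]`.
#' @export
cosim <- function(q, d) {
  stopifnot(length(q) == length(d))
  nq <- sqrt(sum(q^2))
  nd <- sqrt(sum(d^2))
  if (nq == 0 || nd == 0) stop("cosine similarity is undefined for a zero vector")
  sum(q * d) / (nq * nd)
}

#' Round to IEEE 754 half precision (binary16)
#'
#' Quantizes each value to the nearest number representable with a 5-bit
#' exponent and 10-bit significand (subnormals handled; values are assumed
#' within half-precision range).  For inputs in `[-1, 1]` the per-coordinate
#' absolute error is below `5e-4`.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape, every entry binary16-representable.
#' @export
quantize_half <- function(x) {
  out <- x
  a <- abs(as.numeric(x))
  nz <- a > 0
  if (any(nz)) {
    e <- pmin(pmax(floor(log2(a[nz])), -14), 15)  # clamp at subnormal boundary
    m <- a[nz] / 2^e
    q <- round(m * 1024) / 1024                   # 10 fraction bits
    out[nz] <- sign(as.numeric(x)[nz]) * q * 2^e
  }
  out
}

#' Build a vector store over a corpus
#'
#' Encodes each record's [index_text()] (title + abstract) with the given
#' encoder.  With `precision = "half"` the stored vectors are quantized to
#' binary16-representable values (scalar quantization); similarity math is
#' always carried out in full double precision on the stored values.
#'
#' @param corpus a [corpus()].
#' @param encoder a [text_encoder()].
#' @param precision `"full"` or `"half"`.
#' @return an object of class `vector_store`: a doc_id-indexed matrix of
#'   embeddings plus encoder metadata.
#' @export
build_vector_store <- function(corpus, encoder,
                               precision = c("full", "half")) {
  precision <- match.arg(precision)
  txt <- index_text(corpus)
  vecs <- tryCatch(encode_text(encoder, txt), error = function(e) {
    stop("encoding failed: ", conditionMessage(e), call. = FALSE)
  })
  if (precision == "half") vecs <- quantize_half(vecs)
  structure(list(vectors = vecs, dim = encoder$dim, precision = precision,
                 encoder_name = encoder$name),
            class = "vector_store")
}

#' @export
print.vector_store <- function(x, ...) {
  cat(sprintf("<vector_store> %d vectors, dim=%d, precision=%s, encoder='%s'\n",
              nrow(x$vectors), x$dim, x$precision, x$encoder_name))
  invisible(x)
}

#' Look up a stored vector
#'
#' @param store a `vector_store`.
#' @param doc_id document id.
#' @return numeric vector.
#' @export
store_vector <- function(store, doc_id) {
  if (!doc_id %in% rownames(store$vectors)) {
    stop("doc_id not in vector store: ", doc_id)
  }
  store$vectors[doc_id, ]
}

#' Exact cosine search over a vector store
#'
#' Computes the cosine similarity of the query vector against every stored
#' vector, keeps documents with similarity at or above the cutoff `t` (others
#' are excluded, not clamped), and returns up to `top_m` hits sorted by
#' descending similarity with ties broken by lexicographic `doc_id`.  The
#' cutoff is applied before truncation.
#'
#' @param query_vec numeric vector of the store's dimension.
#' @param store a `vector_store`.
#' @param t_cutoff retention threshold in `[0, 1]` (default 0, keeping all
#'   non-negative similarities).
#' @param top_m maximum number of hits.
#' @return data frame with columns `doc_id`, `cosim`.
#' @export
semantic_search <- function(query_vec, store, t_cutoff = 0, top_m = 1000L) {
  stopifnot(t_cutoff >= 0, top_m >= 1L)
  if (nrow(store$vectors) == 0L) {
    return(data.frame(doc_id = character(0), cosim = numeric(0)))
  }
  nq <- sqrt(sum(query_vec^2))
  if (nq == 0) stop("cosine similarity is undefined for a zero query vector")
  norms <- sqrt(rowSums(store$vectors^2))
  sims <- as.numeric(store$vectors %*% query_vec) / (norms * nq)
  ids <- rownames(store$vectors)
  keep <- sims >= t_cutoff
  res <- data.frame(doc_id = ids[keep], cosim = sims[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(-res$cosim, res$doc_id), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_m)
}

#' Save / load a vector store
#'
#' Single-file JSON layout: a header (dimension, precision, count, version)
#' followed by the doc_id table and the vectors written at full decimal
#' precision, so the bytes are stable for fixed inputs and the values
#' round-trip exactly.
#'
#' @param store a `vector_store`.
#' @param path file path.
#' @return `save_vector_store()` returns `path` invisibly;
#'   `load_vector_store()` a `vector_store`.
#' @export
save_vector_store <- function(store, path) {
  payload <- list(schema = "litfuse-vectors",
                  schema_version = STORE_SCHEMA_VERSION,
                  dim = store$dim, precision = store$precision,
                  count = nrow(store$vectors),
                  encoder_name = store$encoder_name,
                  doc_ids = as.list(rownames(store$vectors)),
                  vectors = apply(store$vectors, 1L, as.list, simplify = FALSE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vector_store
#' @export
load_vector_store <- function(path) {
  if (!file.exists(path)) stop("no such vector store: ", path)
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "litfuse-vectors") ||
      !identical(as.character(payload$schema_version), STORE_SCHEMA_VERSION)) {
    stop("not a litfuse vector store (or version mismatch): ", path)
  }
  dim <- as.integer(payload$dim)
  vecs <- do.call(rbind, lapply(payload$vectors, function(v) {
    vapply(v, as.numeric, numeric(1))
  }))
  rownames(vecs) <- vapply(payload$doc_ids, as.character, character(1))
  structure(list(vectors = vecs, dim = dim,
                 precision = payload$precision,
                 encoder_name = payload$encoder_name),
            class = "vector_store")
}
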