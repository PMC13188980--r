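# Retrieval evaluation: ranked metrics (NDCG/MAP/MRR at rank cutoffs),
# query-result mean cosine with relevance bucketing, and TREC-style
# qrels/run file I/O.

#' NDCG at rank cutoff k
#'
#' Binary-gain normalized discounted cumulative gain:
#' `DCG@k = sum_{i<=k} rel_i / log2(i + 1)`, divided by the ideal DCG for
#' `min(|relevant|, k)` relevant documents at the top.
#'
#' @param ranking character vector of doc_ids, best first.
#' @param relevant_set character vector of relevant doc_ids (non-empty).
#' @param k rank cutoff, `>= 1`.
#' @return a real in `[0, 1]`.
#' @export
ndcg_at_k <- function(ranking, relevant_set, k) {
  stopifnot(k >= 1L)
  if (!length(relevant_set)) stop("NDCG is undefined for an empty relevant set")
  top <- utils::head(ranking, k)
  rel <- as.integer(top %in% relevant_set)
  dcg <- sum(rel / log2(seq_along(rel) + 1))
  ideal_n <- min(length(relevant_set), k)
  idcg <- sum(1 / log2(seq_len(ideal_n) + 1))
  dcg / idcg
}

#' Average precision at rank cutoff k
#'
#' `AP@k = (sum over relevant hits at ranks i <= k of Precision@i) /
#' min(|relevant|, k)` — the trec_eval convention, so a ranking placing all
#' reachable relevant documents first scores 1.
#'
#' @inheritParams ndcg_at_k
#' @return a real in `[0, 1]`.
#' @export
map_at_k <- function(ranking, relevant_set, k) {
  stopifnot(k >= 1L)
  if (!length(relevant_set)) stop("AP is undefined for an empty relevant set")
  top <- utils::head(ranking, k)
  rel <- top %in% relevant_set
  if (!any(rel)) return(0)
  ranks <- which(rel)
  prec <- cumsum(rel)[ranks] / ranks
  sum(prec) / min(length(relevant_set), k)
}

#' Reciprocal rank at cutoff k
#'
#' `1 / rank` of the first relevant document within the top `k`, or 0 when
#' none appears there.
#'
#' @inheritParams ndcg_at_k
#' @return a real in `[0, 1]`.
#' @export
mrr_at_k <- function(ranking, relevant_set, k) {
  stopifnot(k >= 1L)
  if (!length(relevant_set)) stop("RR is undefined for an empty relevant set")
  top <- utils::head(ranking, k)
  hit <- which(top %in% relevant_set)
  if (!length(hit)) 0 else 1 / hit[1]
}

#' Mean query-result cosine over the top K results
#'
#' Embeds the query and the abstracts of the top `min(K, n)` results with
#' the same encoder and averages the pairwise cosines — a proxy relevance
#' measure for judgment-free evaluation.  An empty result list yields `NA`
#' ("no results"), which is distinct from a similarity of 0.
#'
#' @param query query text.
#' @param results data frame with a `doc_id` column, best first.
#' @param corpus the [corpus()] the results refer to.
#' @param encoder a [text_encoder()].
#' @param K number of top results to average over (default 3).
#' @return mean cosine, or `NA_real_` when there are no results.
#' @export
mean_cosine_topk <- function(query, results, corpus, encoder, K = 3L) {
  stopifnot(K >= 1L)
  if (nrow(results) == 0L) return(NA_real_)
  top <- utils::head(results$doc_id, K)
  idx <- match(top, corpus$doc_id)
  if (anyNA(idx)) stop("result doc_id(s) not in corpus")
  qv <- encode_text(encoder, query)[1L, ]
  texts <- ifelse(nzchar(corpus$abstract[idx]), corpus$abstract[idx],
                  corpus$title[idx])
  dv <- encode_text(encoder, texts)
  mean(vapply(seq_len(nrow(dv)), function(i) cosim(qv, dv[i, ]), numeric(1)))
}

#' Bucket a cosine similarity into a relevance category
#'
#' `Relevant` at or above the upper threshold (default 0.5, the relevance
#' line), `Irrelevant` below the lower threshold (default 0.3), otherwise
#' `PartiallyRelevant`.
#'
#' @param cosine numeric vector of similarities.
#' @param lower,upper bucket boundaries, `lower <= upper`.
#' @return character vector of bucket labels.
#' @export
bucket_relevance <- function(cosine, lower = 0.3, upper = 0.5) {
  stopifnot(lower <= upper)
  ifelse(cosine >= upper, "Relevant",
         ifelse(cosine < lower, "Irrelevant", "PartiallyRelevant"))
}

#' Evaluate a run against relevance judgments
#'
#' Computes mean NDCG, MAP and MRR over queries at each rank cutoff.
#' Queries judged but absent from the run score 0; queries with empty
#' relevant sets are skipped with a warning.
#'
#' @param run named list: query_id -> ranked character vector of doc_ids
#'   (no duplicates within a query).
#' @param judgments named list: query_id -> character vector of relevant
#'   doc_ids.
#' @param cutoffs integer vector of rank cutoffs (default `c(5, 10, 15,
#'   100)`).
#' @return data frame with columns `metric`, `k`, `mean`, and attribute
#'   `n_queries`.
#' @export
evaluate_run <- function(run, judgments, cutoffs = c(5L, 10L, 15L, 100L)) {
  empty <- names(judgments)[lengths(judgments) == 0L]
  if (length(empty)) {
    warning("skipping ", length(empty),
            " query(ies) with empty relevant sets: ",
            paste(empty, collapse = ", "), call. = FALSE)
    judgments <- judgments[lengths(judgments) > 0L]
  }
  qids <- names(judgments)
  if (!length(qids)) stop("no scorable queries")
  if (!length(intersect(qids, names(run)))) {
    stop("run and judgments share no query ids")
  }
  for (q in intersect(qids, names(run))) {
    if (anyDuplicated(run[[q]])) {
      stop("duplicate doc_ids in run for query ", q)
    }
  }
  rows <- list()
  for (k in cutoffs) {
    per_q <- function(fun) {
      mean(vapply(qids, function(q) {
        ranking <- run[[q]]
        if (is.null(ranking)) return(0)   # judged query missing from run
        fun(ranking, judgments[[q]], k)
      }, numeric(1)))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("NDCG", "MAP", "MRR"), k = as.integer(k),
      mean = c(per_q(ndcg_at_k), per_q(map_at_k), per_q(mrr_at_k)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_queries") <- length(qids)
  out
}

#' Read / write TREC-style qrels
#'
#' Lines of `query_id 0 doc_id rel`; judgments with `rel > 0` count as
#' relevant.
#'
#' @param path file path.
#' @return `read_qrels()` a named list query_id -> relevant doc_ids.
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) stop("no such qrels file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) != 4L) stop("malformed qrels line: ", ln)
    if (as.numeric(f[4]) > 0) out[[f[1]]] <- c(out[[f[1]]], f[3])
  }
  out
}

#' @rdname read_qrels
#' @param judgments named list query_id -> relevant doc_ids.
#' @export
write_qrels <- function(judgments, path) {
  lines <- unlist(lapply(names(judgments), function(q) {
    sprintf("%s 0 %s 1", q, judgments[[q]])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write TREC-style run files
#'
#' Lines of `query_id Q0 doc_id rank score tag`; rankings are returned
#' sorted by rank.
#'
#' @param path file path.
#' @return `read_run()` a named list query_id -> ranked doc_ids.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such run file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) < 5L) stop("malformed run line: ", ln)
    list(qid = f[1], doc = f[3], rank = as.integer(f[4]))
  })
  qids <- vapply(parsed, `[[`, character(1), "qid")
  out <- lapply(split(parsed, qids), function(entries) {
    ranks <- vapply(entries, `[[`, integer(1), "rank")
    vapply(entries, `[[`, character(1), "doc")[order(ranks)]
  })
  out[unique(qids)]
}

#' @rdname read_run
#' @param run named list query_id -> ranked doc_ids.
#' @param tag run tag written in the last column.
#' @export
write_run <- function(run, path, tag = "litfuse") {
  lines <- unlist(lapply(names(run), function(q) {
    docs <- run[[q]]
    if (!length(docs)) return(character(0))
    sprintf("%s Q0 %s %d %.6f %s", q, docs, seq_along(docs),
            1 / seq_along(docs), tag)
  }))
  writeLines(lines, path)
  invisible(path)
}
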