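# Deterministic synthetic corpora, queries, judgments, and test encoders.
# Everything is reproducible from a single integer seed, so the full
# pipeline is testable without any download.

# Runs code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit string hash (polynomial rolling hash), platform
# independent: doubles hold exact integers well below 2^53.
.str_hash <- function(s, seed = 0L) {
  h <- 5381 + as.numeric(seed)
  for (c in utf8ToInt(enc2utf8(s))) h <- (h * 33 + c) %% 2147483647
  h
}

#' Deterministic hash encoder
#'
#' A test stand-in for a sentence encoder: each token is hashed to a
#' coordinate and a sign, the text's vector is the tf-weighted sum of its
#' token vectors, L2-normalized.  Deterministic for a fixed seed, and the
#' cosine between two texts grows with their token overlap — the behaviour
#' the lexical/semantic contrast tests rely on.  Empty text encodes to the
#' zero vector.
#'
#' @param dim embedding dimension (default 64).
#' @param seed integer mixed into the token hash.
#' @return a [text_encoder()].
#' @export
hash_encoder <- function(dim = 64L, seed = 0L) {
  dim <- as.integer(dim)
  force(seed)
  text_encoder(function(text) {
    toks <- tokenize(text)
    v <- numeric(dim)
    if (length(toks)) {
      tab <- table(toks)
      for (j in seq_along(tab)) {
        h <- .str_hash(names(tab)[j], seed)
        idx <- (h %% dim) + 1
        sgn <- if ((h %/% dim) %% 2 == 0) 1 else -1
        v[idx] <- v[idx] + sgn * as.numeric(tab[j])
      }
      n <- sqrt(sum(v^2))
      if (n > 0) v <- v / n
    }
    v
  }, dim = dim, name = sprintf("hash-d%d-s%d", dim, as.integer(seed)))
}

#' Topic specifications for synthetic corpora
#'
#' Each topic carries a surface vocabulary (used in documents and exact-term
#' queries), a disjoint paraphrase vocabulary expressing the same topic with
#' different words (used to construct queries with zero token overlap), and
#' a unit base direction in embedding space.  Base directions are mutually
#' orthogonal, so distinct topics have pairwise cosine 0.
#'
#' @param n_topics number of topics.
#' @param dim embedding dimension (default 64; must be `>= n_topics`).
#' @param vocab_size tokens per vocabulary (default 30).
#' @param seed integer seed for the base directions.
#' @return list of `topic_spec` objects with fields `topic_id`,
#'   `vocabulary`, `paraphrase`, `base_vector`.
#' @export
make_topics <- function(n_topics, dim = 64L, vocab_size = 30L, seed = 1L) {
  stopifnot(n_topics >= 1L, dim >= n_topics)
  with_seed(seed, {
    raw <- matrix(stats::rnorm(dim * n_topics), nrow = dim)
    base <- qr.Q(qr(raw))[, seq_len(n_topics), drop = FALSE]
  })
  lapply(seq_len(n_topics), function(k) {
    structure(list(
      topic_id = sprintf("topic%02d", k),
      vocabulary = sprintf("t%02dterm%02d", k, seq_len(vocab_size)),
      paraphrase = sprintf("t%02dsyn%02d", k, seq_len(vocab_size)),
      base_vector = base[, k]), class = "topic_spec")
  })
}

# Topic of a text: the topic whose combined vocabulary covers most of its
# tokens; 0 when no topic token occurs.
.topic_of <- function(tokens, topics) {
  hits <- vapply(topics, function(tp) {
    sum(tokens %in% c(tp$vocabulary, tp$paraphrase))
  }, numeric(1))
  if (max(hits) == 0) 0L else which.max(hits)
}

#' Deterministic topic encoder
#'
#' A test encoder that understands the synthetic topics: a text is mapped
#' near its topic's base direction (recognizing both the surface and the
#' paraphrase vocabulary), plus a small deterministic text-specific
#' perturbation.  Two texts on the same topic therefore have cosine around
#' 0.9 even with zero token overlap, while texts on different topics stay
#' well below 0.3 — emulating what a sentence transformer provides for
#' conceptually related but lexically dissimilar text.  Texts matching no
#' topic fall back to the hash encoding.
#'
#' @param topics list from [make_topics()].
#' @param noise perturbation weight in `[0, 1)` (default 0.3).
#' @param seed integer seed for the perturbation hash.
#' @return a [text_encoder()].
#' @export
topic_encoder <- function(topics, noise = 0.3, seed = 0L) {
  dim <- length(topics[[1]]$base_vector)
  fallback <- hash_encoder(dim, seed)
  text_encoder(function(text) {
    toks <- tokenize(text)
    k <- .topic_of(toks, topics)
    if (k == 0L) return(fallback$fun(text))
    base <- topics[[k]]$base_vector
    # deterministic pseudo-noise from the text hash, orthogonalized so the
    # cosine to the base direction is exactly sqrt(1 - noise^2)
    h <- .str_hash(paste(toks, collapse = " "), seed)
    u <- with_seed((h %% 2000000000) + 1, stats::rnorm(dim))
    u <- u - sum(u * base) * base
    n <- sqrt(sum(u^2))
    if (n > 0) u <- u / n
    sqrt(1 - noise^2) * base + noise * u
  }, dim = dim, name = sprintf("topic-k%d-d%d", length(topics), dim))
}

#' Generate a synthetic corpus
#'
#' Documents are assigned to topics round-robin.  Token sampling within a
#' topic's vocabulary follows Zipf-like weights (probability proportional to
#' 1/rank) and document lengths are uniform on 50-200 tokens, exercising
#' BM25 term-frequency saturation and length normalization.  Every
#' document's title opens with its topic's anchor token (the rank-1
#' vocabulary entry), so an exact-term query containing the anchor shares a
#' token with every document of the topic.  Journals, authors, and MeSH
#' terms are drawn from per-topic pools; the MeSH list always includes the
#' topic id, and years are uniform over `year_range`.  Fully reproducible
#' from `seed`.
#'
#' @param n_docs number of documents (>= 1).
#' @param topics list from [make_topics()].
#' @param year_range integer vector `c(first, last)` (default 2019-2021).
#' @param seed integer seed.
#' @param len_range token-count range per document (default `c(50, 200)`).
#' @return a [corpus()] with attribute `topic_id`, the per-record topic
#'   index.
#' @export
generate_corpus <- function(n_docs, topics, year_range = c(2019L, 2021L),
                            seed = 1L, len_range = c(50L, 200L)) {
  stopifnot(n_docs >= 1L, length(topics) >= 1L)
  n_topics <- length(topics)
  topic_idx <- rep(seq_len(n_topics), length.out = n_docs)
  with_seed(seed, {
    rows <- lapply(seq_len(n_docs), function(i) {
      tp <- topics[[topic_idx[i]]]
      vocab <- tp$vocabulary
      zipf <- (1 / seq_along(vocab))
      len <- sample(len_range[1]:len_range[2], 1L)
      toks <- sample(vocab, len, replace = TRUE, prob = zipf / sum(zipf))
      title_len <- sample(4:7, 1L)
      title <- paste(c(vocab[1], toks[seq_len(title_len)]), collapse = " ")
      abstract <- paste(toks[-seq_len(title_len)], collapse = " ")
      list(
        doc_id = sprintf("%d", 100000L + i),
        title = title, abstract = abstract,
        year = sample(year_range[1]:year_range[2], 1L),
        journal = sprintf("Journal of %s Studies %d", toupper(tp$topic_id),
                          sample(1:3, 1L)),
        authors = sprintf("%s%02d A", toupper(substr(tp$topic_id, 1, 1)),
                          sample(1:8, sample(1:3, 1L))),
        mesh = c(tp$topic_id, sprintf("%s mesh %d", tp$topic_id,
                                      sample(1:5, sample(1:2, 1L)))))
    })
    out <- corpus(
      doc_id = vapply(rows, `[[`, character(1), "doc_id"),
      title = vapply(rows, `[[`, character(1), "title"),
      abstract = vapply(rows, `[[`, character(1), "abstract"),
      year = vapply(rows, `[[`, integer(1), "year"),
      journal = vapply(rows, `[[`, character(1), "journal"),
      authors = lapply(rows, `[[`, "authors"),
      mesh_terms = lapply(rows, `[[`, "mesh"))
  })
  attr(out, "topic_id") <- topic_idx
  out
}

#' Generate evaluation queries and judgments for a synthetic corpus
#'
#' Each query targets one topic (cycling through them); its relevant set is
#' all documents of that topic.  Exact-term queries are drawn from the
#' topic's surface vocabulary and always include the anchor token, so they
#' share at least one token with every relevant document.  A
#' `paraphrase_fraction` of queries instead uses only the disjoint
#' paraphrase vocabulary and therefore shares zero tokens with every
#' relevant document — the "conceptually related but lexically dissimilar"
#' condition.
#'
#' @param corpus a corpus from [generate_corpus()] (carries `topic_id`).
#' @param topics the same topic list the corpus was generated from.
#' @param n_queries number of queries.
#' @param paraphrase_fraction fraction in `[0, 1]` of paraphrase queries.
#' @param seed integer seed.
#' @return list with `queries` (data frame: `query_id`, `text`, `type`,
#'   `topic`) and `judgments` (named list query_id -> relevant doc_ids).
#' @export
generate_eval_set <- function(corpus, topics, n_queries = 40L,
                              paraphrase_fraction = 0.5, seed = 1L) {
  topic_idx <- attr(corpus, "topic_id")
  stopifnot(!is.null(topic_idx), n_queries >= 1L,
            paraphrase_fraction >= 0, paraphrase_fraction <= 1)
  n_para <- round(paraphrase_fraction * n_queries)
  # deterministic interleaving of query types and topics
  type <- rep("exact", n_queries)
  if (n_para > 0) type[seq_len(n_para)] <- "paraphrase"
  topic_of_q <- rep(seq_along(topics), length.out = n_queries)
  with_seed(seed, {
    texts <- vapply(seq_len(n_queries), function(i) {
      tp <- topics[[topic_of_q[i]]]
      n_tok <- sample(3:6, 1L)
      if (type[i] == "paraphrase") {
        paste(sample(tp$paraphrase, n_tok), collapse = " ")
      } else {
        paste(c(tp$vocabulary[1], sample(tp$vocabulary[-1], n_tok - 1L)),
              collapse = " ")
      }
    }, character(1))
  })
  qids <- sprintf("q%03d", seq_len(n_queries))
  judgments <- lapply(topic_of_q, function(k) corpus$doc_id[topic_idx == k])
  names(judgments) <- qids
  list(queries = data.frame(query_id = qids, text = texts, type = type,
                            topic = topic_of_q, stringsAsFactors = FALSE),
       judgments = judgments)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a corpus as MEDLINE-dialect citation XML
#'
#' Emits a `PubmedArticleSet` document with the elements
#' [parse_pubmed_xml()] reads (PMID, ArticleTitle, AbstractText, journal
#' title, PubDate/Year, authors, MeSH descriptors, DOI), so generated
#' fixtures exercise the real ingestion path.
#'
#' @param corpus a [corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(corpus, path) {
  recs <- vapply(seq_len(nrow(corpus)), function(i) {
    authors <- paste(vapply(corpus$authors[[i]], function(a) {
      parts <- strsplit(trimws(a), "[[:space:]]+")[[1]]
      last <- paste(parts[-length(parts)], collapse = " ")
      init <- parts[length(parts)]
      if (length(parts) < 2L) { last <- a; init <- "" }
      paste0("          <Author><LastName>", .xml_escape(last),
             "</LastName><Initials>", .xml_escape(init),
             "</Initials></Author>")
    }, character(1)), collapse = "\n")
    mesh <- paste(vapply(corpus$mesh_terms[[i]], function(m) {
      paste0("          <MeshHeading><DescriptorName>", .xml_escape(m),
             "</DescriptorName></MeshHeading>")
    }, character(1)), collapse = "\n")
    paste0(
      "  <PubmedArticle>\n",
      "    <MedlineCitation>\n",
      "      <PMID>", .xml_escape(corpus$doc_id[i]), "</PMID>\n",
      "      <Article>\n",
      "        <Journal>\n",
      "          <JournalIssue><PubDate>",
      if (!is.na(corpus$year[i])) {
        paste0("<Year>", corpus$year[i], "</Year>")
      } else "",
      "</PubDate></JournalIssue>\n",
      "          <Title>", .xml_escape(corpus$journal[i]), "</Title>\n",
      "        </Journal>\n",
      "        <ArticleTitle>", .xml_escape(corpus$title[i]),
      "</ArticleTitle>\n",
      if (nzchar(corpus$abstract[i])) {
        paste0("        <Abstract><AbstractText>",
               .xml_escape(corpus$abstract[i]),
               "</AbstractText></Abstract>\n")
      } else "",
      if (nzchar(corpus$doi[i])) {
        paste0("        <ELocationID EIdType=\"doi\">",
               .xml_escape(corpus$doi[i]), "</ELocationID>\n")
      } else "",
      if (length(corpus$authors[[i]])) {
        paste0("        <AuthorList>\n", authors, "\n        </AuthorList>\n")
      } else "",
      "      </Article>\n",
      if (length(corpus$mesh_terms[[i]])) {
        paste0("      <MeshHeadingList>\n", mesh,
               "\n      </MeshHeadingList>\n")
      } else "",
      "    </MedlineCitation>\n",
      "  </PubmedArticle>")
  }, character(1))
  payload <- paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
                    "<PubmedArticleSet>\n",
                    paste(recs, collapse = "\n"),
                    "\n</PubmedArticleSet>\n")
  writeLines(payload, path, sep = "", useBytes = TRUE)
  invisible(path)
}
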