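# Corpus container and PubMed/MEDLINE XML ingestion.

CORPUS_SCHEMA_VERSION <- "1"

#' Normalize free text for storage
#'
#' Applies Unicode NFC normalization, collapses internal whitespace runs to a
#' single space, and trims leading/trailing whitespace.  All text stored in a
#' corpus goes through this, so tokenization downstream is reproducible across
#' input encodings.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(enc2utf8(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)
  trimws(x)
}

#' Construct a corpus of bibliographic records
#'
#' A corpus is a data frame with one row per article: `doc_id`, `title`,
#' `abstract`, `year` (integer, `NA` when unresolvable), `journal`, `doi`,
#' and list columns `authors` and `mesh_terms`.  `doc_id` must be unique and
#' non-empty, and every record must have a non-empty title after whitespace
#' normalization.  Iteration (row) order is stable.
#'
#' @param doc_id character vector of unique document ids (PMIDs or synthetic).
#' @param title,abstract character vectors; `abstract` may contain `""`.
#' @param year integer vector of 4-digit publication years; `NA` allowed.
#' @param journal,doi character vectors (`""` when absent).
#' @param authors,mesh_terms lists of character vectors.
#' @return an object of class `lit_corpus`.
#' @export
corpus <- function(doc_id, title, abstract = "", year = NA_integer_,
                   journal = "", authors = list(), mesh_terms = list(),
                   doi = "") {
  n <- length(doc_id)
  recycle <- function(x, default) {
    if (length(x) == 0L) x <- default
    rep_len(x, n)
  }
  doc_id <- as.character(doc_id)
  title <- normalize_text(recycle(title, ""))
  abstract <- normalize_text(recycle(abstract, ""))
  year <- suppressWarnings(as.integer(recycle(year, NA_integer_)))
  journal <- normalize_text(recycle(journal, ""))
  doi <- normalize_text(recycle(doi, ""))
  if (length(authors) == 0L) authors <- rep(list(character()), n)
  if (length(mesh_terms) == 0L) mesh_terms <- rep(list(character()), n)
  stopifnot(length(authors) == n, length(mesh_terms) == n)
  if (any(!nzchar(doc_id)) || anyNA(doc_id)) {
    stop("every record needs a non-empty doc_id")
  }
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "))
  }
  if (any(!nzchar(title))) {
    stop("every record needs a non-empty title after normalization")
  }
  bad_year <- !is.na(year) & (year < 1000L | year > 9999L)
  if (any(bad_year)) stop("year must be a 4-digit integer or NA")
  out <- data.frame(doc_id = doc_id, title = title, abstract = abstract,
                    year = year, journal = journal, doi = doi,
                    stringsAsFactors = FALSE)
  out$authors <- lapply(authors, as.character)
  out$mesh_terms <- lapply(mesh_terms, as.character)
  rownames(out) <- NULL
  class(out) <- c("lit_corpus", "data.frame")
  out
}

#' @export
print.lit_corpus <- function(x, ...) {
  yrs <- x$year[!is.na(x$year)]
  cat(sprintf("<lit_corpus> %d records", nrow(x)))
  if (length(yrs)) cat(sprintf(", years %d-%d", min(yrs), max(yrs)))
  cat("\n")
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  [%s] %s (%s)\n", show$doc_id[i],
                  substr(show$title[i], 1L, 60L),
                  ifelse(is.na(show$year[i]), "unknown", show$year[i])))
    }
    if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Indexing text of each record
#'
#' Both the lexical and the semantic pipeline index exactly this string:
#' `title` followed by a single space and the abstract (title alone when the
#' abstract is empty).
#'
#' @param corpus a `lit_corpus`.
#' @return character vector named by `doc_id`.
#' @export
index_text <- function(corpus) {
  stopifnot(inherits(corpus, "lit_corpus"))
  txt <- ifelse(nzchar(corpus$abstract),
                paste(corpus$title, corpus$abstract),
                corpus$title)
  names(txt) <- corpus$doc_id
  txt
}

#' Shard key of each record
#'
#' Publication year as a character key, with the sentinel `"unknown"` for
#' records whose year could not be resolved.
#'
#' @param corpus a `lit_corpus`.
#' @return character vector named by `doc_id`.
#' @export
shard_key <- function(corpus) {
  key <- ifelse(is.na(corpus$year), "unknown", as.character(corpus$year))
  names(key) <- corpus$doc_id
  key
}

# Year from a PubDate node: prefer <Year>; else the leading 4-digit run of
# <MedlineDate> (the MEDLINE dialect stores ranges like "1998 Dec-1999 Jan").
.extract_year <- function(article) {
  y <- xml2::xml_text(xml2::xml_find_first(
    article, ".//Journal/JournalIssue/PubDate/Year"))
  if (!is.na(y) && grepl("^[0-9]{4}$", y)) return(as.integer(y))
  md <- xml2::xml_text(xml2::xml_find_first(
    article, ".//Journal/JournalIssue/PubDate/MedlineDate"))
  if (!is.na(md)) {
    m <- regmatches(md, regexpr("[0-9]{4}", md))
    if (length(m)) return(as.integer(m))
  }
  NA_integer_
}

.parse_article <- function(article) {
  pmid <- xml2::xml_text(xml2::xml_find_first(article, ".//MedlineCitation/PMID"))
  if (is.na(pmid)) pmid <- xml2::xml_text(xml2::xml_find_first(article, ".//PMID"))
  title <- xml2::xml_text(xml2::xml_find_first(article, ".//ArticleTitle"))
  # multiple AbstractText sections (structured abstracts) are concatenated
  # with a single space in document order
  abs_nodes <- xml2::xml_find_all(article, ".//Abstract/AbstractText")
  abstract <- if (length(abs_nodes)) {
    paste(vapply(abs_nodes, xml2::xml_text, character(1)), collapse = " ")
  } else ""
  journal <- xml2::xml_text(xml2::xml_find_first(article, ".//Journal/Title"))
  author_nodes <- xml2::xml_find_all(article, ".//AuthorList/Author")
  authors <- character(0)
  for (a in author_nodes) {
    last <- xml2::xml_text(xml2::xml_find_first(a, "./LastName"))
    init <- xml2::xml_text(xml2::xml_find_first(a, "./Initials"))
    if (!is.na(last)) {
      authors <- c(authors, trimws(paste(last, if (!is.na(init)) init else "")))
    }
  }
  mesh <- vapply(xml2::xml_find_all(article, ".//MeshHeadingList/MeshHeading/DescriptorName"),
                 xml2::xml_text, character(1))
  doi <- xml2::xml_text(xml2::xml_find_first(
    article, ".//ELocationID[@EIdType='doi']"))
  list(doc_id = if (is.na(pmid)) "" else trimws(pmid),
       title = if (is.na(title)) "" else title,
       abstract = abstract,
       year = .extract_year(article),
       journal = if (is.na(journal)) "" else journal,
       authors = authors,
       mesh_terms = as.character(mesh),
       doi = if (is.na(doi)) "" else doi)
}

#' Parse PubMed/MEDLINE citation XML into a corpus
#'
#' Reads a `PubmedArticleSet` document and extracts one record per
#' `PubmedArticle`: PMID, title, abstract (structured sections joined with a
#' single space), publication year (`PubDate/Year`, falling back to the first
#' 4-digit run of `MedlineDate`), journal title, authors (LastName +
#' Initials), MeSH descriptor names, and DOI.  Records lacking both title and
#' abstract are dropped; when the same PMID appears twice the later record
#' wins and a warning is issued.  Parsing is deterministic: the same bytes
#' always yield the same corpus.
#'
#' @param x path to an XML file, or a single string / raw vector of XML.
#' @return a [corpus()] with attribute `parse_report`, a list with counts
#'   `n_articles`, `n_kept`, `n_dropped_empty`, `n_duplicates`.
#' @export
parse_pubmed_xml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop("malformed MEDLINE XML: ",
                                           conditionMessage(e), call. = FALSE))
  articles <- xml2::xml_find_all(doc, "//PubmedArticle")
  recs <- lapply(articles, .parse_article)
  n_articles <- length(recs)
  # drop records with neither title nor abstract (unindexable)
  keep <- vapply(recs, function(r) {
    nzchar(trimws(r$title)) || nzchar(trimws(r$abstract))
  }, logical(1))
  n_dropped <- sum(!keep)
  recs <- recs[keep]
  # title-only invariant: records with an abstract but no title get the
  # placeholder "[untitled]" so the corpus invariant holds
  recs <- lapply(recs, function(r) {
    if (!nzchar(trimws(r$title))) r$title <- "[untitled]"
    r
  })
  ids <- vapply(recs, `[[`, character(1), "doc_id")
  dup <- duplicated(ids, fromLast = TRUE)  # later record wins
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning("duplicate PMID(s): ",
            paste(unique(ids[dup]), collapse = ", "),
            "; keeping the later record", call. = FALSE)
    recs <- recs[!dup]
    ids <- ids[!dup]
  }
  out <- corpus(
    doc_id = ids,
    title = vapply(recs, `[[`, character(1), "title"),
    abstract = vapply(recs, `[[`, character(1), "abstract"),
    year = vapply(recs, `[[`, integer(1), "year"),
    journal = vapply(recs, `[[`, character(1), "journal"),
    authors = lapply(recs, `[[`, "authors"),
    mesh_terms = lapply(recs, `[[`, "mesh_terms"),
    doi = vapply(recs, `[[`, character(1), "doi"))
  attr(out, "parse_report") <- list(n_articles = n_articles,
                                    n_kept = nrow(out),
                                    n_dropped_empty = n_dropped,
                                    n_duplicates = n_dup)
  out
}

#' Save / load a corpus
#'
#' Single-file JSON record store with a schema version tag.  `load_corpus()`
#' of a saved corpus round-trips every field (including unicode text and
#' record order) exactly.
#'
#' @param corpus a `lit_corpus`.
#' @param path file path.
#' @return `save_corpus()` returns `path` invisibly; `load_corpus()` a
#'   `lit_corpus`.
#' @export
save_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "lit_corpus"))
  payload <- list(
    schema = "litfuse-corpus",
    schema_version = CORPUS_SCHEMA_VERSION,
    records = lapply(seq_len(nrow(corpus)), function(i) {
      list(doc_id = corpus$doc_id[i], title = corpus$title[i],
           abstract = corpus$abstract[i],
           year = corpus$year[i],
           journal = corpus$journal[i], doi = corpus$doi[i],
           authors = as.list(corpus$authors[[i]]),
           mesh_terms = as.list(corpus$mesh_terms[[i]]))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(path) {
  if (!file.exists(path)) stop("no such corpus file: ", path)
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "litfuse-corpus")) {
    stop("not a corpus store: ", path)
  }
  if (!identical(as.character(payload$schema_version), CORPUS_SCHEMA_VERSION)) {
    stop("corpus schema version mismatch: found ", payload$schema_version,
         ", expected ", CORPUS_SCHEMA_VERSION)
  }
  recs <- payload$records
  corpus(
    doc_id = vapply(recs, function(r) r$doc_id, character(1)),
    title = vapply(recs, function(r) r$title, character(1)),
    abstract = vapply(recs, function(r) r$abstract, character(1)),
    year = vapply(recs, function(r) {
      if (is.null(r$year)) NA_integer_ else as.integer(r$year)
    }, integer(1)),
    journal = vapply(recs, function(r) r$journal, character(1)),
    authors = lapply(recs, function(r) unlist(r$authors) %||% character()),
    mesh_terms = lapply(recs, function(r) unlist(r$mesh_terms) %||% character()),
    doi = vapply(recs, function(r) r$doi, character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
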