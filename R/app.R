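# Result filtering, facet aggregation, and CSV/BibTeX export over ranked
# retrieval results.

#' Construct a result filter
#'
#' All present constraints must hold for a record to pass (AND semantics);
#' within a set-valued constraint any membership suffices (OR).
#'
#' @param year_min,year_max optional integer bounds on publication year
#'   (inclusive).
#' @param journals,authors,mesh_terms optional character vectors; a record
#'   passes a set constraint when it matches at least one element.
#' @return an object of class `result_filter`.
#' @export
result_filter <- function(year_min = NULL, year_max = NULL, journals = NULL,
                          authors = NULL, mesh_terms = NULL) {
  if (!is.null(year_min) && !is.null(year_max) && year_min > year_max) {
    stop("year_min must not exceed year_max")
  }
  structure(list(year_min = year_min, year_max = year_max,
                 journals = journals, authors = authors,
                 mesh_terms = mesh_terms),
            class = "result_filter")
}

#' Filter ranked results by metadata
#'
#' Order-preserving subset of `results`: a row is kept iff its corpus record
#' satisfies every constraint present in the filter.  Records with unknown
#' year fail any year constraint.
#'
#' @param results data frame with a `doc_id` column (e.g. from
#'   [retrieve()]).
#' @param filter a [result_filter()].
#' @param corpus the [corpus()] the results refer to.
#' @return the filtered results, original order and columns preserved.
#' @export
apply_filter <- function(results, filter, corpus) {
  stopifnot(inherits(filter, "result_filter"))
  idx <- match(results$doc_id, corpus$doc_id)
  if (anyNA(idx)) {
    stop("result doc_id(s) not in corpus: ",
         paste(results$doc_id[is.na(idx)], collapse = ", "))
  }
  keep <- rep(TRUE, nrow(results))
  if (!is.null(filter$year_min)) {
    keep <- keep & !is.na(corpus$year[idx]) & corpus$year[idx] >= filter$year_min
  }
  if (!is.null(filter$year_max)) {
    keep <- keep & !is.na(corpus$year[idx]) & corpus$year[idx] <= filter$year_max
  }
  if (!is.null(filter$journals)) {
    keep <- keep & corpus$journal[idx] %in% filter$journals
  }
  if (!is.null(filter$authors)) {
    keep <- keep & vapply(corpus$authors[idx], function(a) {
      any(a %in% filter$authors)
    }, logical(1))
  }
  if (!is.null(filter$mesh_terms)) {
    keep <- keep & vapply(corpus$mesh_terms[idx], function(m) {
      any(m %in% filter$mesh_terms)
    }, logical(1))
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.top_counts <- function(values, n = 10L) {
  values <- values[nzchar(values)]
  if (!length(values)) {
    return(data.frame(term = character(0), count = integer(0)))
  }
  tab <- table(values)
  df <- data.frame(term = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$term), , drop = FALSE]  # ties alphabetical
  rownames(df) <- NULL
  utils::head(df, n)
}

#' Facet summary of a retrieved set
#'
#' Counts, over the retrieved records only, the top 10 MeSH terms, journals,
#' and authors by article count.  Ties are broken alphabetically.  The
#' summary depends on the result set, not its order.
#'
#' @param results data frame with a `doc_id` column.
#' @param corpus the [corpus()] the results refer to.
#' @param n how many entries per facet (default 10).
#' @return an object of class `facet_summary`: list of data frames
#'   `top_mesh`, `top_journals`, `top_authors`, each with columns `term`,
#'   `count`.
#' @export
compute_facets <- function(results, corpus, n = 10L) {
  idx <- match(results$doc_id, corpus$doc_id)
  idx <- idx[!is.na(idx)]
  structure(list(
    top_mesh = .top_counts(unlist(corpus$mesh_terms[idx]), n),
    top_journals = .top_counts(corpus$journal[idx], n),
    top_authors = .top_counts(unlist(corpus$authors[idx]), n)),
    class = "facet_summary")
}

#' @export
print.facet_summary <- function(x, ...) {
  for (f in c("top_mesh", "top_journals", "top_authors")) {
    cat(sprintf("%s:\n", f))
    if (nrow(x[[f]])) {
      print.data.frame(x[[f]])
    } else cat("  (none)\n")
  }
  invisible(x)
}

# RFC 4180: quote fields containing delimiter, quote or newline; escape
# embedded quotes by doubling.
.csv_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# "Smith JA" (MEDLINE LastName + Initials) -> "Smith, J. A."
.bibtex_author <- function(a) {
  parts <- strsplit(trimws(a), "[[:space:]]+")[[1]]
  if (length(parts) < 2L) return(a)
  initials <- strsplit(parts[length(parts)], "")[[1]]
  paste0(paste(parts[-length(parts)], collapse = " "), ", ",
         paste0(initials, ".", collapse = " "))
}

#' Export results as CSV or BibTeX
#'
#' CSV uses the fixed header
#' `doc_id,title,abstract,year,journal,authors,doi,fs,bm2501,cosim` with
#' UTF-8 text, comma delimiter and RFC 4180 quoting; list fields are joined
#' with `"; "`.  BibTeX emits one `@article` entry per record with citation
#' key `pmid<doc_id>` and authors formatted `Last, I. and Last, I.`.  Output
#' is byte-stable for fixed input.
#'
#' @param results data frame with a `doc_id` column; score columns `fs`,
#'   `bm2501`, `cosim` are included in CSV when present.
#' @param corpus the [corpus()] the results refer to.
#' @param format `"csv"` or `"bibtex"`.
#' @param ids optional character vector restricting the export to selected
#'   doc_ids (order follows `results`).
#' @param file optional path; when given, the text is also written there.
#' @return a single string, the export payload.
#' @export
export_results <- function(results, corpus, format = c("csv", "bibtex"),
                           ids = NULL, file = NULL) {
  format <- match.arg(format)
  if (!is.null(ids)) results <- results[results$doc_id %in% ids, , drop = FALSE]
  idx <- match(results$doc_id, corpus$doc_id)
  if (anyNA(idx)) {
    stop("result doc_id(s) not in corpus: ",
         paste(results$doc_id[is.na(idx)], collapse = ", "))
  }
  rec <- corpus[idx, , drop = FALSE]
  score_col <- function(col) {
    if (col %in% names(results)) results[[col]] else rep(NA_real_, nrow(results))
  }
  if (format == "csv") {
    header <- "doc_id,title,abstract,year,journal,authors,doi,fs,bm2501,cosim"
    rows <- vapply(seq_len(nrow(rec)), function(i) {
      paste(.csv_field(c(
        rec$doc_id[i], rec$title[i], rec$abstract[i],
        ifelse(is.na(rec$year[i]), "", rec$year[i]), rec$journal[i],
        paste(rec$authors[[i]], collapse = "; "), rec$doi[i],
        score_col("fs")[i], score_col("bm2501")[i], score_col("cosim")[i])),
        collapse = ",")
    }, character(1))
    payload <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
  } else {
    entries <- vapply(seq_len(nrow(rec)), function(i) {
      fields <- c(
        title = rec$title[i],
        author = paste(vapply(rec$authors[[i]], .bibtex_author, character(1)),
                       collapse = " and "),
        journal = rec$journal[i],
        year = ifelse(is.na(rec$year[i]), "", as.character(rec$year[i])),
        doi = rec$doi[i])
      fields <- fields[nzchar(fields)]
      paste0("@article{pmid", rec$doc_id[i], ",\n",
             paste(sprintf("  %s = {%s}", names(fields), fields),
                   collapse = ",\n"),
             "\n}\n")
    }, character(1))
    payload <- paste(entries, collapse = "\n")
  }
  if (!is.null(file)) writeLines(payload, file, sep = "", useBytes = TRUE)
  payload
}
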