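# Small in-code fixtures shared across test files.

medline_xml_one <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<PubmedArticleSet>\n',
    '<PubmedArticle><MedlineCitation><PMID>1</PMID><Article>',
    '<Journal><JournalIssue><PubDate><Year>2020</Year></PubDate>',
    '</JournalIssue><Title>J</Title></Journal>',
    '<ArticleTitle>T</ArticleTitle>',
    '<Abstract><AbstractText>A</AbstractText></Abstract>',
    '<ELocationID EIdType="doi">10.1000/x1</ELocationID>',
    '<AuthorList><Author><LastName>Smith</LastName>',
    '<Initials>JA</Initials></Author></AuthorList>',
    '</Article><MeshHeadingList><MeshHeading>',
    '<DescriptorName>Humans</DescriptorName></MeshHeading>',
    '</MeshHeadingList></MedlineCitation></PubmedArticle>\n',
    '</PubmedArticleSet>')
}

# Three-record corpus with varied metadata for filter/facet/export tests.
tiny_corpus <- function() {
  corpus(
    doc_id = c("10", "11", "12"),
    title = c("alpha study", "beta study", "gamma review"),
    abstract = c("first abstract", "second abstract", ""),
    year = c(2019L, 2020L, 2022L),
    journal = c("J1", "J1", "J2"),
    authors = list(c("Smith JA", "Doe B"), "Doe B", "Lee C"),
    mesh_terms = list(c("A", "B"), "A", "C"),
    doi = c("10.1/x", "", "10.2/y"))
}

# An encoder that looks texts up in a fixed table (used to construct exact
# score scenarios); unknown texts hash-encode.
lookup_encoder <- function(table, dim) {
  fallback <- hash_encoder(dim, seed = 99)
  text_encoder(function(text) {
    if (!is.null(table[[text]])) table[[text]] else fallback$fun(text)
  }, dim = dim, name = "lookup")
}

# Desk-scale topic fixture reused by fusion and acceptance tests.
desk_fixture <- function(n_docs = 200, n_queries = 40, seed = 42) {
  topics <- make_topics(2, dim = 64, seed = seed)
  co <- generate_corpus(n_docs, topics, seed = seed + 1)
  ev <- generate_eval_set(co, topics, n_queries = n_queries,
                          paraphrase_fraction = 0.5, seed = seed + 2)
  enc <- topic_encoder(topics, seed = seed + 3)
  list(topics = topics, corpus = co, eval = ev, encoder = enc)
}
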