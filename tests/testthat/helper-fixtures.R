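# in-code MEDLINE XML fixture: three citations — one structured, one with a
# plain abstract, one with no abstract at all
medline_fixture_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<PubmedArticleSet>\n",
    " <PubmedArticle><MedlineCitation>\n",
    "  <PMID>1001</PMID>\n",
    "  <Article>\n",
    "   <Journal><Title>Synthetic Medicine</Title>",
    "<JournalIssue><PubDate><Year>2019</Year></PubDate></JournalIssue></Journal>\n",
    "   <ArticleTitle>A structured prediction-model abstract</ArticleTitle>\n",
    "   <Abstract>\n",
    '    <AbstractText Label="BACKGROUND">Risk prediction is hard.</AbstractText>\n',
    '    <AbstractText Label="METHODS">We fitted a logistic model.</AbstractText>\n',
    '    <AbstractText Label="RESULTS">The AUC was 0.82 in validation data.</AbstractText>\n',
    "   </Abstract>\n",
    "   <PublicationTypeList><PublicationType>Journal Article</PublicationType></PublicationTypeList>\n",
    "  </Article>\n",
    "  <MeshHeadingList><MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading></MeshHeadingList>\n",
    " </MedlineCitation></PubmedArticle>\n",
    " <PubmedArticle><MedlineCitation>\n",
    "  <PMID>1002</PMID>\n",
    "  <Article>\n",
    "   <Journal><Title>PLoS One</Title>",
    "<JournalIssue><PubDate><Year>2021</Year></PubDate></JournalIssue></Journal>\n",
    "   <ArticleTitle>An unstructured abstract</ArticleTitle>\n",
    "   <Abstract><AbstractText>This plain abstract has more than ten words ",
    "but reports no discrimination statistic at all.</AbstractText></Abstract>\n",
    "  </Article>\n",
    " </MedlineCitation></PubmedArticle>\n",
    " <PubmedArticle><MedlineCitation>\n",
    "  <PMID>1003</PMID>\n",
    "  <Article>\n",
    "   <Journal><Title>Annals of Simulated Research</Title>",
    "<JournalIssue><PubDate><Year>2015</Year></PubDate></JournalIssue></Journal>\n",
    "   <ArticleTitle>A citation without any abstract</ArticleTitle>\n",
    "  </Article>\n",
    " </MedlineCitation></PubmedArticle>\n",
    "</PubmedArticleSet>\n"
  )
}

write_fixture <- function(gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".xml.gz" else ".xml")
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeLines(medline_fixture_xml(), con)
  close(con)
  path
}

results_record <- function(text, pmid = "1", label = "RESULTS") {
  abstract_record(pmid, title = "t",
                  sections = data.frame(label = label, text = text,
                                        stringsAsFactors = FALSE))
}

# multiset recall/precision of extraction against generator ground truth
fidelity <- function(corpus, matches, included_pmids) {
  truth <- corpus$truth
  expected <- truth[truth$should_be_extracted &
                      truth$pmid %in% included_pmids, ]
  key <- function(p, v, r) paste(p, sprintf("%.4f", v), r)
  et <- table(key(expected$pmid, expected$rendered_value, expected$role))
  at <- table(key(matches$pmid, matches$value, matches$role))
  common <- intersect(names(et), names(at))
  tp <- sum(pmin(et[common], at[common]))
  list(recall = tp / sum(et), precision = tp / sum(at),
       n_expected = sum(et), n_extracted = sum(at))
}
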