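test_that("MEDLINE fixture parses into records with labelled sections", {
  path <- write_fixture()
  recs <- parse_pubmed_xml(path)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, character(1), "pmid"),
               c("1001", "1002", "1003"))
  expect_equal(recs[[1]]$sections$label,
               c("BACKGROUND", "METHODS", "RESULTS"))
  expect_equal(recs[[2]]$sections$label, "")
  expect_equal(nrow(recs[[3]]$sections), 0)
  expect_equal(recs[[1]]$year, 2019L)
  expect_equal(recs[[1]]$mesh_terms, "Humans")
})

test_that("gzip-compressed XML parses identically", {
  plain <- parse_pubmed_xml(write_fixture(gz = FALSE))
  gz <- parse_pubmed_xml(write_fixture(gz = TRUE))
  expect_identical(plain, gz)
})

test_that("malformed XML is a hard error; missing PMID a warning", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><MedlineCitation>", bad)
  expect_error(parse_pubmed_xml(bad), "malformed")
  nopmid <- tempfile(fileext = ".xml")
  writeLines(paste0(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<Article><ArticleTitle>t</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>"), nopmid)
  expect_warning(recs <- parse_pubmed_xml(nopmid), "PMID")
  expect_length(recs, 0)
})

test_that("serialisation round-trips through the MEDLINE dialect", {
  set.seed(3)
  corp <- generate_corpus(synthetic_config(n_abstracts = 20L, seed = 3L))
  path <- tempfile(fileext = ".xml")
  write_medline_xml(corp$records, path)
  reparsed <- parse_pubmed_xml(path)
  expect_identical(reparsed, corp$records)
})

test_that("word_count tokenises on whitespace", {
  expect_equal(word_count(""), 0L)
  expect_equal(word_count("a b  c"), 3L)
  expect_equal(word_count(paste(rep("word", 10), collapse = " ")), 10L)
  expect_equal(word_count("state-of-the-art model"), 2L)
})

test_that("exclusion cascade applies first matching rule in fixed order", {
  ten <- results_record(paste(rep("w", 10), collapse = " "))
  eleven <- results_record(paste(rep("w", 11), collapse = " "))
  expect_equal(apply_exclusions(ten)$reason, "empty_or_short_abstract")
  expect_equal(apply_exclusions(eleven)$status, "included")

  pk <- abstract_record("2", sections = eleven$sections,
                        mesh_terms = c("Humans", "Pharmacokinetics"))
  expect_equal(apply_exclusions(pk)$reason, "pharmacokinetic")

  meta <- abstract_record("3", title = "A meta-analysis of models",
                          sections = eleven$sections)
  expect_equal(apply_exclusions(meta)$reason, "meta_analysis")
  meta_pt <- abstract_record("4", sections = eleven$sections,
                             publication_types = "Meta-Analysis")
  expect_equal(apply_exclusions(meta_pt)$reason, "meta_analysis")

  tut <- abstract_record("5", title = "A tutorial on ROC analysis",
                         sections = eleven$sections)
  expect_equal(apply_exclusions(tut)$reason, "tutorial")

  # rule order: a short pharmacokinetic abstract is excluded as short
  short_pk <- abstract_record("6", sections = ten$sections,
                              mesh_terms = "Pharmacokinetics")
  expect_equal(apply_exclusions(short_pk)$reason, "empty_or_short_abstract")

  # idempotence: the decision does not depend on having been made before
  expect_identical(apply_exclusions(pk), apply_exclusions(pk))
})

test_that("flow counts conserve the corpus and reject duplicate pmids", {
  mk <- function(pmid, status, reason) {
    structure(list(pmid = pmid, status = status, reason = reason),
              class = "filter_decision")
  }
  d <- list(mk("1", "included", "none"), mk("2", "included", "none"),
            mk("3", "excluded", "pharmacokinetic"),
            mk("4", "excluded", "no_auc_value"),
            mk("5", "excluded", "empty_or_short_abstract"))
  fc <- flow_counts(d)
  expect_equal(fc$total, 5)
  expect_equal(fc$included, 2)
  expect_equal(fc$included + sum(unlist(fc$excluded)), fc$total)

  expect_equal(flow_counts(list())$total, 0)
  d10 <- lapply(1:10, function(i) mk(as.character(i), "excluded",
                                     "no_auc_value"))
  fc10 <- flow_counts(d10)
  expect_equal(fc10$included, 0)
  expect_equal(fc10$excluded$no_auc_value, 10)

  expect_error(flow_counts(c(d, d[1])), "duplicate")
})

test_that("exclusion cascade conserves counts on a generated corpus", {
  corp <- generate_corpus(synthetic_config(n_abstracts = 150L, seed = 9L))
  decisions <- lapply(corp$records, apply_exclusions)
  fc <- flow_counts(decisions)
  expect_equal(fc$total, 150)
  expect_equal(fc$included + sum(unlist(fc$excluded)), 150)
})
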