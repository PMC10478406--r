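#' Construct an abstract record
#'
#' The unit of the corpus: one parsed abstract with its labelled sections
#' and the citation metadata used by the exclusion cascade.
#'
#' @param pmid PubMed identifier, a non-empty string of digits.
#' @param title Article title.
#' @param sections A data.frame with columns `label` (uppercase section
#'   label, `""` for unstructured abstracts) and `text`, in document order.
#'   May have zero rows (the record then fails inclusion).
#' @param year Publication year (integer, may be `NA`).
#' @param journal Journal title.
#' @param mesh_terms Character vector of MeSH descriptor names.
#' @param publication_types Character vector of publication types.
#' @return An object of class `abstract_record`.
#' @export
abstract_record <- function(pmid, title = "", sections = empty_sections(),
                            year = NA_integer_, journal = "",
                            mesh_terms = character(),
                            publication_types = character()) {
  pmid <- as.character(pmid)
  if (!nzchar(pmid) || is.na(pmid)) stop("pmid must be a non-empty string")
  stopifnot(is.data.frame(sections), all(c("label", "text") %in% names(sections)))
  sections$label <- toupper(as.character(sections$label))
  sections$text <- as.character(sections$text)
  structure(
    list(pmid = pmid, title = as.character(title), sections = sections,
         year = as.integer(year), journal = as.character(journal),
         mesh_terms = as.character(mesh_terms),
         publication_types = as.character(publication_types)),
    class = "abstract_record"
  )
}

empty_sections <- function() {
  data.frame(label = character(), text = character(), stringsAsFactors = FALSE)
}

#' @export
print.abstract_record <- function(x, ...) {
  cat("<abstract_record> PMID", x$pmid, "-", substr(x$title, 1, 60), "\n")
  cat("  ", nrow(x$sections), "section(s),", x$journal,
      if (!is.na(x$year)) paste0("(", x$year, ")") else "", "\n")
  invisible(x)
}

abstract_text <- function(record) {
  paste(record$sections$text, collapse = " ")
}

#' Parse MEDLINE-citation XML into abstract records
#'
#' Reads one file in the PubMed baseline dialect (a `PubmedArticleSet` of
#' `MedlineCitation` elements), optionally gzip-compressed, and returns one
#' [abstract_record()] per citation. Structured-abstract section labels are
#' preserved (uppercase-normalised); citations without any abstract text
#' yield a record with zero sections. Citations lacking a PMID are skipped
#' with a warning.
#'
#' @param path Path to a MEDLINE XML file (`.xml` or `.xml.gz`).
#' @return A list of `abstract_record` objects.
#' @export
parse_pubmed_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed MEDLINE XML in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
  records <- vector("list", length(cits))
  keep <- logical(length(cits))
  for (i in seq_along(cits)) {
    cit <- cits[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    if (is.na(pmid) || !nzchar(trimws(pmid))) {
      warning("citation #", i, " has no PMID; skipped")
      next
    }
    art <- xml2::xml_find_first(cit, "./Article")
    title <- xml2::xml_text(xml2::xml_find_first(art, "./ArticleTitle"))
    abst <- xml2::xml_find_all(art, "./Abstract/AbstractText")
    if (length(abst) > 0) {
      labels <- xml2::xml_attr(abst, "Label")
      labels[is.na(labels)] <- ""
      sections <- data.frame(label = toupper(labels),
                             text = xml2::xml_text(abst),
                             stringsAsFactors = FALSE)
    } else {
      sections <- empty_sections()
    }
    journal <- xml2::xml_text(xml2::xml_find_first(art, "./Journal/Title"))
    year <- xml2::xml_text(xml2::xml_find_first(
      art, "./Journal/JournalIssue/PubDate/Year"))
    if (is.na(year)) {
      md <- xml2::xml_text(xml2::xml_find_first(
        art, "./Journal/JournalIssue/PubDate/MedlineDate"))
      year <- if (!is.na(md)) regmatches(md, regexpr("[0-9]{4}", md)) else NA
      if (length(year) == 0) year <- NA
    }
    mesh <- xml2::xml_text(xml2::xml_find_all(
      cit, "./MeshHeadingList/MeshHeading/DescriptorName"))
    ptypes <- xml2::xml_text(xml2::xml_find_all(
      art, "./PublicationTypeList/PublicationType"))
    records[[i]] <- abstract_record(
      pmid = trimws(pmid),
      title = if (is.na(title)) "" else title,
      sections = sections,
      year = suppressWarnings(as.integer(year)),
      journal = if (is.na(journal)) "" else journal,
      mesh_terms = mesh,
      publication_types = ptypes
    )
    keep[i] <- TRUE
  }
  records[keep]
}

#' Count whitespace-delimited words
#'
#' Supports the short-abstract exclusion rule: tokens are maximal runs of
#' non-whitespace, so hyphenated words count once.
#'
#' @param text Character vector.
#' @return Integer vector of token counts (0 for empty strings).
#' @export
word_count <- function(text) {
  vapply(text, function(x) {
    x <- trimws(x)
    if (is.na(x) || !nzchar(x)) return(0L)
    length(strsplit(x, "\\s+")[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Apply the exclusion cascade to one abstract
#'
#' Rules are applied in a fixed order and the first match wins, so every
#' abstract gets exactly one reason: (1) empty abstract or 10 words or
#' fewer; (2) pharmacokinetic study (MeSH or publication-type indicator);
#' (3) meta-analysis / pooled analysis (publication type, then title
#' keyword); (4) tutorial. Anything else is a candidate for inclusion; the
#' final `no_auc_value` decision is made after extraction (see
#' [run_analysis()]).
#'
#' @param record An [abstract_record()].
#' @param config A configuration list from [auc_config()].
#' @return A `filter_decision`: list with `pmid`, `status`
#'   (`"included"`/`"excluded"`) and `reason`.
#' @export
apply_exclusions <- function(record, config = auc_config()) {
  ex <- config$exclusion
  body <- abstract_text(record)
  reason <- "none"
  if (word_count(body) <= ex$max_short_words) {
    reason <- "empty_or_short_abstract"
  } else if (matches_any(record$mesh_terms, ex$pk_mesh) ||
             matches_any(record$publication_types, ex$pk_pubtypes)) {
    reason <- "pharmacokinetic"
  } else if (matches_any(record$publication_types, ex$meta_pubtypes) ||
             matches_any(record$title, ex$meta_title)) {
    reason <- "meta_analysis"
  } else if (matches_any(record$publication_types, ex$tutorial_pubtypes) ||
             matches_any(record$title, ex$tutorial_title)) {
    reason <- "tutorial"
  }
  structure(
    list(pmid = record$pmid,
         status = if (reason == "none") "included" else "excluded",
         reason = reason),
    class = "filter_decision"
  )
}

matches_any <- function(fields, indicators) {
  if (length(fields) == 0 || length(indicators) == 0) return(FALSE)
  pattern <- paste(indicators, collapse = "|")
  any(grepl(pattern, fields, ignore.case = TRUE))
}

FILTER_REASONS <- c("empty_or_short_abstract", "pharmacokinetic",
                    "meta_analysis", "tutorial", "no_auc_value")

#' Tally filter decisions into flow-chart counts
#'
#' @param decisions A list of `filter_decision` objects, one per abstract.
#' @return A `flow_counts` list with `total`, `included` and one count per
#'   exclusion reason. Conservation (`included + sum(excluded) == total`)
#'   holds by construction and is asserted.
#' @export
flow_counts <- function(decisions) {
  pmids <- vapply(decisions, `[[`, character(1), "pmid")
  if (anyDuplicated(pmids)) {
    stop("duplicate pmid in decisions: ", pmids[duplicated(pmids)][1])
  }
  reasons <- vapply(decisions, `[[`, character(1), "reason")
  status <- vapply(decisions, `[[`, character(1), "status")
  excluded <- vapply(FILTER_REASONS, function(r) sum(reasons == r),
                     integer(1))
  out <- structure(
    list(total = length(decisions),
         included = sum(status == "included"),
         excluded = as.list(excluded)),
    class = "flow_counts"
  )
  stopifnot(out$included + sum(unlist(out$excluded)) == out$total)
  out
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("<flow_counts> total:", x$total, " included:", x$included, "\n")
  for (r in names(x$excluded)) cat("  excluded,", r, ":", x$excluded[[r]], "\n")
  invisible(x)
}

#' Summarise a corpus as a table
#'
#' @param records List of `abstract_record` objects.
#' @param decisions Optional list of `filter_decision` objects aligned with
#'   `records`.
#' @return A data.frame with one row per abstract: pmid, year, journal,
#'   n_sections and (when decisions are given) decision and reason.
#' @export
corpus_table <- function(records, decisions = NULL) {
  out <- data.frame(
    pmid = vapply(records, `[[`, character(1), "pmid"),
    year = vapply(records, `[[`, integer(1), "year"),
    journal = vapply(records, `[[`, character(1), "journal"),
    n_sections = vapply(records, function(r) nrow(r$sections), integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(decisions)) {
    stopifnot(length(decisions) == length(records))
    out$decision <- vapply(decisions, `[[`, character(1), "status")
    out$reason <- vapply(decisions, `[[`, character(1), "reason")
  }
  out
}
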