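#' Configuration for the synthetic abstract-corpus generator
#'
#' The generator emulates abstracts that report AUC values in the styles
#' seen in the literature, on top of a smooth base distribution of true
#' values, with an optional threshold "promotion" mechanism standing in for
#' hacking: a value landing just below a salient threshold is, with
#' probability `promotion_prob`, replaced by a value just above it. That
#' mechanism produces the predicted caliper signature (deficit just below,
#' excess just above) and nothing else; with `promotion_prob = 0` the
#' corpus is a smooth null.
#'
#' @param n_abstracts Number of abstracts.
#' @param values_prob Success probability of the geometric law for the
#'   number of AUC values per abstract (`1 + rgeom(values_prob)`); the
#'   default 0.35 gives median 2 and quartiles 1 to 4.
#' @param base Base distribution of true AUC values: a scaled Beta on
#'   `(lower, upper)`; the default Beta(4.5, 3.5) on (0.4, 1) is smooth,
#'   unimodal with mode near 0.75.
#' @param thresholds Salient thresholds, aligned to the 0.01 grid.
#' @param promotion_prob Probability `h` that an eligible value is
#'   promoted.
#' @param promotion_window Width `delta` of the eligibility window
#'   `(t - delta, t]` below each threshold.
#' @param landing_window Width `epsilon` of the landing window
#'   `(t, t + epsilon]` above each threshold.
#' @param style_mix Proportions of reporting styles (must sum to 1):
#'   `plain_point` ("The AUC was 0.731."), `point_with_ci`
#'   ("0.731 (95% CI 0.655 to 0.807)"), `percent` ("73.1%"),
#'   `one_decimal` ("0.7"), `exactly_one` ("an AUC of 1").
#' @param decoy_rate Fraction of abstracts that are pure decoys containing
#'   no true AUC value.
#' @param decoy_mix Proportions of decoy types (must sum to 1):
#'   `pharmacokinetic` (AUC with units), `sens_spec_list`,
#'   `scale_definition_sentence`, `no_auc_filler`.
#' @param sens_spec_rate Probability that an AUC-reporting abstract also
#'   carries a sensitivity/specificity list in its results section.
#' @param short_rate Fraction of abstracts with a 10-words-or-fewer body
#'   (exercises the exclusion cascade).
#' @param pk_mesh_rate Probability that a pharmacokinetic decoy abstract
#'   carries a pharmacokinetic MeSH heading (those are excluded upstream;
#'   the rest must be handled by the extraction guards).
#' @param seed Integer seed making the corpus fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_abstracts = 5000L,
                             values_prob = 0.35,
                             base = list(shape1 = 4.5, shape2 = 3.5,
                                         lower = 0.4, upper = 1),
                             thresholds = c(0.7, 0.8, 0.9),
                             promotion_prob = 0,
                             promotion_window = 0.03,
                             landing_window = 0.01,
                             style_mix = c(plain_point = 0.45,
                                           point_with_ci = 0.30,
                                           percent = 0.10,
                                           one_decimal = 0.10,
                                           exactly_one = 0.05),
                             decoy_rate = 0.25,
                             decoy_mix = c(pharmacokinetic = 0.3,
                                           sens_spec_list = 0.35,
                                           scale_definition_sentence = 0.15,
                                           no_auc_filler = 0.2),
                             sens_spec_rate = 0.3,
                             short_rate = 0.02,
                             pk_mesh_rate = 0.5,
                             seed = NULL) {
  stopifnot(abs(sum(style_mix) - 1) < 1e-9, abs(sum(decoy_mix) - 1) < 1e-9,
            promotion_window > 0, landing_window > 0,
            promotion_prob >= 0, promotion_prob <= 1,
            all(abs(thresholds * 100 - round(thresholds * 100)) < 1e-9))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Draw true AUC values from the smooth base distribution
#'
#' Two families are available through `config$base$family`:
#' * `"beta"` (default): a scaled Beta on `(lower, upper)` — smooth and
#'   realistic in shape, but its log-density is not inside the span of a
#'   4-df natural spline, so the smooth fit carries a small (about 1%)
#'   deterministic lack-of-fit at any given bin.
#' * `"smooth_null"`: the in-model counterpart — the log-density *is* a
#'   4-df natural spline of the value, calibrated once (deterministically)
#'   to match the Beta shape. Use this family for calibration studies of
#'   the residual diagnostic, where the null must carry no lack-of-fit of
#'   its own.
#'
#' Both densities are smooth: no atoms, no jumps.
#'
#' @param n Number of draws.
#' @param config A [synthetic_config()].
#' @return Numeric vector in `(base$lower, base$upper)`.
#' @export
sample_true_auc <- function(n, config = synthetic_config()) {
  b <- config$base
  family <- if (is.null(b$family)) "beta" else b$family
  if (family == "beta") {
    b$lower + (b$upper - b$lower) * stats::rbeta(n, b$shape1, b$shape2)
  } else if (family == "smooth_null") {
    sample_smooth_null(n, b)
  } else {
    stop("unknown base family: ", family)
  }
}

# inverse-CDF sampling from the log-spline density matched to the Beta
# shape; entirely deterministic apart from the uniform draws
sample_smooth_null <- function(n, b) {
  lo_bin <- ceiling(b$lower * 100)
  hi_bin <- floor(b$upper * 100)
  mids <- (seq(lo_bin, hi_bin - 1L) + 0.5) / 100
  edges <- seq(lo_bin, hi_bin) / 100
  pr <- stats::pbeta((edges - b$lower) / (b$upper - b$lower),
                     b$shape1, b$shape2)
  expected <- 1e4 * diff(pr)
  basis <- natural_spline_basis(mids, df = 4L, boundary = range(mids))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, basis), expected,
                                         family = stats::poisson()))
  # full support; the natural spline extrapolates linearly into the two
  # half-bins beyond the boundary knots
  grid <- seq(b$lower, b$upper, length.out = 6001L)
  gb <- cbind(1, stats::predict(basis, grid))
  loginten <- drop(gb %*% fit$coefficients)
  dens <- exp(loginten - max(loginten))
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, grid, xout = stats::runif(n), rule = 2)$y
}

#' Apply the threshold promotion mechanism
#'
#' Each value in `(t - delta, t]` for some threshold `t` is, with
#' probability `h = promotion_prob`, replaced by a uniform draw from
#' `(t, t + epsilon]`. Values outside every window are never changed.
#'
#' @param values Numeric vector in (0, 1).
#' @param config A [synthetic_config()].
#' @return List with `values` (after promotion) and `promoted` (logical).
#' @export
apply_promotion <- function(values, config = synthetic_config()) {
  promoted <- rep(FALSE, length(values))
  out <- values
  if (config$promotion_prob > 0) {
    for (t in config$thresholds) {
      eligible <- out > t - config$promotion_window & out <= t & !promoted
      fire <- eligible & stats::runif(length(out)) < config$promotion_prob
      out[fire] <- t + stats::runif(sum(fire)) * config$landing_window
      promoted <- promoted | fire
    }
  }
  list(values = out, promoted = promoted)
}

#' Simulate a vector of reported AUC values (no text)
#'
#' The value-level fast path used by the simulation studies: draws from the
#' base distribution and applies the promotion mechanism, skipping text
#' rendering and extraction.
#'
#' @param n Number of values.
#' @param config A [synthetic_config()]; `config$seed` is honoured when
#'   set.
#' @return List with `values`, `promoted` and `pre_promotion`.
#' @export
simulate_auc_values <- function(n, config = synthetic_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pre <- sample_true_auc(n, config)
  prom <- apply_promotion(pre, config)
  list(values = prom$values, promoted = prom$promoted, pre_promotion = pre)
}

# -- text rendering -----------------------------------------------------------

AUC_CUE_RENDERINGS <- c("The AUC was %s", "The AUROC was %s",
                        "The model achieved an AUC of %s",
                        "The area under the curve was %s",
                        "The c-statistic was %s",
                        "AUC = %s")

FILLER <- list(
  background = c(
    "Early identification of patients at risk remains difficult in routine care.",
    "Risk stratification tools are increasingly used to support clinical decisions.",
    "Accurate prognostic information is needed to guide treatment decisions."),
  methods = c(
    "We developed a multivariable prediction model using routinely collected data.",
    "A retrospective cohort was analysed with logistic regression models.",
    "Model discrimination was assessed in a held-out validation sample."),
  conclusions = c(
    "The model may support clinical decision making after external validation.",
    "Further validation in independent cohorts is warranted.",
    "These findings should be interpreted with caution."))

DECOY_SENTENCES <- list(
  pharmacokinetic = c(
    "The mean glucose AUC0-24 was %d ng·h/mL.",
    "The AUC(0-12) after dosing was %d mg·h/L.",
    "Mean AUCinf was %d µg·h/mL following a single oral dose."),
  scale_definition_sentence = c(
    "The AUC ranges between 0.5 and 1.",
    "AUC values between 0.7 and 0.8 were considered acceptable.",
    "An AUC above 0.9 is interpreted as outstanding discrimination."),
  no_auc_filler = c(
    "Treatment adherence improved over the study period.",
    "No serious adverse events were observed during follow-up."))

render_value_sentence <- function(value, style, rng_cue, rng_sep) {
  # returns list(sentence, tokens = data.frame(role, rendered_value,
  # raw_token, decimal_places))
  cue_fmt <- AUC_CUE_RENDERINGS[rng_cue]
  if (style == "plain_point") {
    tok <- sprintf("%.3f", value)
    body <- sprintf(cue_fmt, tok)
    tokens <- data.frame(role = "point", rendered_value = as.numeric(tok),
                         raw_token = tok, stringsAsFactors = FALSE)
  } else if (style == "point_with_ci") {
    hw <- 0.03 + 0.09 * stats::runif(1)
    lo <- max(value - hw, 0.001)
    hi <- min(value + hw, 0.999)
    toks <- sprintf("%.3f", c(value, lo, hi))
    sep <- c("to", "-", ",")[rng_sep]
    body <- sprintf("%s (95%% CI %s %s %s)",
                    sprintf(cue_fmt, toks[1]), toks[2], sep, toks[3])
    tokens <- data.frame(role = c("point", "ci_lower", "ci_upper"),
                         rendered_value = as.numeric(toks),
                         raw_token = toks, stringsAsFactors = FALSE)
  } else if (style == "percent") {
    tok <- sprintf("%.1f%%", value * 100)
    body <- sprintf(cue_fmt, tok)
    tokens <- data.frame(role = "point",
                         rendered_value = as.numeric(sub("%", "", tok)) / 100,
                         raw_token = tok, stringsAsFactors = FALSE)
  } else if (style == "one_decimal") {
    tok <- sprintf("%.1f", value)
    body <- sprintf(cue_fmt, tok)
    tokens <- data.frame(role = "point", rendered_value = as.numeric(tok),
                         raw_token = tok, stringsAsFactors = FALSE)
  } else if (style == "exactly_one") {
    tok <- "1"
    body <- sprintf(cue_fmt, tok)
    tokens <- data.frame(role = "point", rendered_value = 1,
                         raw_token = tok, stringsAsFactors = FALSE)
  } else stop("unknown style: ", style)
  tokens$decimal_places <- decimal_places(tokens$raw_token)
  list(sentence = paste0(body, "."), tokens = tokens)
}

#' Render one synthetic abstract
#'
#' Builds a structured abstract (BACKGROUND/METHODS/RESULTS/CONCLUSIONS)
#' with the AUC sentences in RESULTS, plus optional decoy sentences, and
#' the per-value ground truth: which rendered numbers are true AUC values
#' and whether each is extraction-eligible (a printed "1" is not) and
#' histogram-eligible (a one-decimal point value is not; confidence-interval
#' limits are not under the default histogram specification).
#'
#' @param pmid PMID for the record.
#' @param values True (post-promotion) AUC values to report; may be empty.
#' @param styles Reporting style per value (recycled names from
#'   `style_mix`).
#' @param decoy One of `names(decoy_mix)` or `NA` for none.
#' @param promoted Logical vector aligned with `values`.
#' @param pre_promotion Numeric vector aligned with `values`.
#' @param journal,year Citation metadata.
#' @param config A [synthetic_config()].
#' @return List with `record` (an [abstract_record()]) and `truth` (a
#'   data.frame: pmid, role, style, true_value, rendered_value, raw_token,
#'   promoted, pre_promotion, should_be_extracted, should_enter_histogram).
#' @export
render_abstract <- function(pmid, values, styles, decoy = NA,
                            promoted = rep(FALSE, length(values)),
                            pre_promotion = values,
                            journal = "Journal of Synthetic Examples",
                            year = 2018L,
                            config = synthetic_config()) {
  results <- character()
  truth <- list()
  mesh <- character()
  for (i in seq_along(values)) {
    r <- render_value_sentence(values[i], styles[i],
                               rng_cue = sample.int(length(AUC_CUE_RENDERINGS), 1),
                               rng_sep = sample.int(3, 1))
    results <- c(results, r$sentence)
    tk <- r$tokens
    tk$pmid <- pmid
    tk$style <- styles[i]
    tk$true_value <- values[i]
    tk$promoted <- promoted[i]
    tk$pre_promotion <- pre_promotion[i]
    tk$should_be_extracted <- tk$rendered_value < 1 & tk$rendered_value >= 0
    tk$should_enter_histogram <- tk$should_be_extracted &
      tk$role == "point" & tk$decimal_places != 1L
    truth[[length(truth) + 1]] <- tk
  }
  if (!is.na(decoy) && decoy != "none") {
    if (decoy == "sens_spec_list") {
      sn <- sprintf("The sensitivity was %.2f and the specificity was %.2f.",
                    stats::runif(1, 0.5, 0.99), stats::runif(1, 0.5, 0.99))
    } else if (decoy == "pharmacokinetic") {
      sn <- sprintf(sample(DECOY_SENTENCES$pharmacokinetic, 1),
                    sample(100:900, 1))
      if (stats::runif(1) < config$pk_mesh_rate && length(values) == 0) {
        mesh <- "Pharmacokinetics"
      }
    } else {
      sn <- sample(DECOY_SENTENCES[[decoy]], 1)
    }
    results <- c(results, sn)
  }
  if (length(results) == 0) {
    results <- "The intervention group showed modest improvement over usual care."
  }
  sections <- data.frame(
    label = c("BACKGROUND", "METHODS", "RESULTS", "CONCLUSIONS"),
    text = c(sample(FILLER$background, 1), sample(FILLER$methods, 1),
             paste(results, collapse = " "), sample(FILLER$conclusions, 1)),
    stringsAsFactors = FALSE)
  record <- abstract_record(
    pmid = pmid, title = "A synthetic prediction model abstract",
    sections = sections, year = year, journal = journal, mesh_terms = mesh,
    publication_types = "Journal Article")
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  list(record = record, truth = truth)
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws the per-abstract value counts, true values, promotion outcomes,
#' reporting styles and decoys, renders every abstract, and returns the
#' records together with the ground-truth table. Optionally serialises the
#' corpus to MEDLINE-dialect XML so that [parse_pubmed_xml()] can
#' round-trip it. Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param xml_path Optional path; when given, the corpus is also written as
#'   MEDLINE-style XML (gzip-compressed if the path ends in `.gz`).
#' @return List with `records` (list of `abstract_record`), `truth`
#'   (data.frame, one row per rendered number that is a true AUC value) and
#'   `xml_path` (or `NULL`).
#' @export
generate_corpus <- function(config = synthetic_config(), xml_path = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_abstracts
  journals <- sample(c("PLoS One", "Synthetic Medicine",
                       "Annals of Simulated Research"),
                     n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  years <- sample(2010:2022, n, replace = TRUE)
  is_short <- stats::runif(n) < config$short_rate
  is_decoy <- !is_short & stats::runif(n) < config$decoy_rate
  decoy_type <- rep(NA_character_, n)
  decoy_type[is_decoy] <- sample(names(config$decoy_mix), sum(is_decoy),
                                 replace = TRUE, prob = config$decoy_mix)
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pmid <- as.character(10000000L + i)
    if (is_short[i]) {
      records[[i]] <- abstract_record(
        pmid = pmid, title = "A very short synthetic abstract",
        sections = data.frame(label = "", text = "Too short to include.",
                              stringsAsFactors = FALSE),
        year = years[i], journal = journals[i],
        publication_types = "Journal Article")
      next
    }
    if (is_decoy[i]) {
      r <- render_abstract(pmid, numeric(0), character(0),
                           decoy = decoy_type[i], journal = journals[i],
                           year = years[i], config = config)
    } else {
      k <- 1L + stats::rgeom(1, config$values_prob)
      pre <- sample_true_auc(k, config)
      prom <- apply_promotion(pre, config)
      styles <- sample(names(config$style_mix), k, replace = TRUE,
                       prob = config$style_mix)
      decoy <- if (stats::runif(1) < config$sens_spec_rate) {
        "sens_spec_list"
      } else NA
      r <- render_abstract(pmid, prom$values, styles, decoy = decoy,
                           promoted = prom$promoted, pre_promotion = pre,
                           journal = journals[i], year = years[i],
                           config = config)
    }
    records[[i]] <- r$record
    truth[[i]] <- r$truth
  }
  truth <- do.call(rbind, Filter(Negate(is.null), truth))
  if (is.null(truth)) {
    truth <- data.frame(pmid = character(), role = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  if (!is.null(xml_path)) {
    write_medline_xml(records, xml_path)
  }
  list(records = records, truth = truth, xml_path = xml_path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialise abstract records as MEDLINE-dialect XML
#'
#' Writes a `PubmedArticleSet` in the PubMed baseline dialect that
#' [parse_pubmed_xml()] reads back identically. Gzip-compressed when
#' `path` ends in `.gz`.
#'
#' @param records List of `abstract_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(records, path) {
  chunks <- vapply(records, function(r) {
    secs <- if (nrow(r$sections) == 0) "" else paste(vapply(
      seq_len(nrow(r$sections)), function(i) {
        lab <- r$sections$label[i]
        attr_str <- if (nzchar(lab)) {
          sprintf(' Label="%s" NlmCategory="%s"', xml_escape(lab),
                  xml_escape(lab))
        } else ""
        sprintf("        <AbstractText%s>%s</AbstractText>", attr_str,
                xml_escape(r$sections$text[i]))
      }, character(1)), collapse = "\n")
    abstract_block <- if (nzchar(secs)) {
      sprintf("      <Abstract>\n%s\n      </Abstract>\n", secs)
    } else ""
    mesh_block <- if (length(r$mesh_terms)) {
      sprintf("    <MeshHeadingList>\n%s\n    </MeshHeadingList>\n",
              paste(sprintf(
                "      <MeshHeading><DescriptorName>%s</DescriptorName></MeshHeading>",
                xml_escape(r$mesh_terms)), collapse = "\n"))
    } else ""
    ptype_block <- if (length(r$publication_types)) {
      sprintf("      <PublicationTypeList>\n%s\n      </PublicationTypeList>\n",
              paste(sprintf("        <PublicationType>%s</PublicationType>",
                            xml_escape(r$publication_types)),
                    collapse = "\n"))
    } else ""
    paste0(
      " <PubmedArticle>\n  <MedlineCitation>\n   <PMID>", r$pmid,
      "</PMID>\n   <Article>\n",
      "    <Journal>\n     <Title>", xml_escape(r$journal),
      "</Title>\n     <JournalIssue><PubDate><Year>",
      ifelse(is.na(r$year), "", r$year),
      "</Year></PubDate></JournalIssue>\n    </Journal>\n",
      "    <ArticleTitle>", xml_escape(r$title), "</ArticleTitle>\n",
      abstract_block, ptype_block,
      "   </Article>\n", mesh_block,
      "  </MedlineCitation>\n </PubmedArticle>")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<PubmedArticleSet>", chunks, "</PubmedArticleSet>"),
             con, useBytes = FALSE)
  invisible(path)
}
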