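#' Default pipeline configuration
#'
#' Returns the declarative configuration that drives every stage of the
#' pipeline: the exclusion-cascade indicator lists, the text-extraction cue
#' and guard lists, the histogram convention and the smooth-fit settings.
#' All indicator lists are data, not code: they can be overridden here or
#' from a YAML file via [load_config()].
#'
#' @param ... Named overrides, merged recursively into the defaults. Use the
#'   same nesting as the returned list, e.g.
#'   `auc_config(extraction = list(window = 150))`.
#' @return A nested named list with components `exclusion`, `extraction`,
#'   `histogram`, `spline` and `thresholds`.
#' @export
#' @examples
#' cfg <- auc_config(spline = list(df = 4))
#' cfg$thresholds
auc_config <- function(...) {
  defaults <- list(
    exclusion = list(
      # abstracts with 10 words or fewer are excluded
      max_short_words = 10,
      # MeSH descriptors flagging pharmacokinetic studies (substring match,
      # case-insensitive)
      pk_mesh = c("Pharmacokinetics", "Biological Availability",
                  "Metabolic Clearance Rate", "Tissue Distribution",
                  "Drug Elimination"),
      pk_pubtypes = character(),
      meta_pubtypes = c("Meta-Analysis"),
      meta_title = c("meta-analysis", "meta analysis", "pooled analysis"),
      tutorial_pubtypes = character(),
      tutorial_title = c("tutorial")
    ),
    extraction = list(
      # numbers are associated with the nearest statistic cue to their left,
      # up to this many characters away
      window = 250L,
      # phrase cues, matched case-insensitively
      phrase_cues = c(
        roc_area_phrase = "area under the (?:receiver[- ]operating[- ]characteristic )?(?:\\(?ROC\\)? )?curve",
        roc_area_phrase = "receiver[- ]operating[- ]characteristic(?: curve)?",
        c_statistic = "c[- ]statistic",
        c_index = "c[- ]index",
        concordance = "concordance (?:index|statistic)"
      ),
      # bare acronyms, matched case-sensitively with word boundaries;
      # pharmacokinetic subscripted forms (AUC0-24, AUC(0-24), AUCinf) are
      # never matched because the subscript removes the word boundary or is
      # caught by the lookahead
      acronym_cues = c(
        auc = "AUC\\b(?!\\s*\\(?\\s*0\\s*-)",
        auroc = "AUROCC?\\b"
      ),
      # cues for neighbouring statistics that claim nearby numbers away from
      # the AUC (matched case-insensitively)
      competing_cues = c(
        "sensitivity", "specificity", "accuracy", "\\bbrier\\b",
        "positive predictive value", "negative predictive value",
        "\\bPPV\\b", "\\bNPV\\b", "\\bprecision\\b", "\\brecall\\b",
        "F1[- ]score", "odds ratio", "hazard ratio", "risk ratio",
        "\\bkappa\\b", "\\bp\\s*[=<>]", "R-?squared", "\\bR2\\b",
        "cut-?off", "\\bthreshold\\b", "youden", "likelihood ratio",
        "prevalence", "\\bincidence\\b", "correlation", "calibration slope"
      ),
      # a number followed by one of these is a measured quantity with units
      # (pharmacokinetic exposure etc.), never an AUC
      unit_pattern = "^\\s*(?:[·x×*]\\s*)?(?:ng|ug|µg|μg|mg|g|kg|nmol|pmol|mmol|mol|IU|U|h|hr|hrs|min|ms|s|mL|ml|L|dL|cm|mm|m)(?:\\b|[·/])|^\\s*/",
      # sentences that define or discuss the AUC scale rather than report a
      # value; all numbers in such sentences are ignored
      scale_patterns = c(
        "ranges? (?:between|from)", "can range", "varies (?:between|from)",
        "(?:was|were|is|are) considered", "interpreted as",
        "defined as (?:acceptable|good|excellent|poor)"
      )
    ),
    histogram = list(
      bin_width = 0.01,
      exclude_one_decimal = TRUE,
      roles = "point"
    ),
    spline = list(
      df = 4L,
      # fit domain in value units; NULL means all 100 bins
      fit_lower = NULL,
      fit_upper = NULL
    ),
    thresholds = c(0.7, 0.8, 0.9)
  )
  modifyList(defaults, list(...), keep.null = TRUE)
}

#' Load a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults from [auc_config()];
#' everything else keeps its default.
#'
#' @param path Path to a YAML file with the same nesting as [auc_config()].
#' @return A configuration list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  overrides <- yaml::read_yaml(path)
  do.call(auc_config, overrides)
}
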