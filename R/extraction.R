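# -- text utilities -----------------------------------------------------------

# length-preserving normalisation so character offsets stay valid
normalise_text <- function(x) {
  x <- gsub("[–—−]", "-", x)
  gsub(" ", " ", x)
}

# split text into sentences, keeping character offsets (1-based, inclusive)
split_sentences <- function(text) {
  if (!nzchar(text)) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("(?<=[.!?])\\s+(?=[A-Z0-9(\\[])", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    starts <- 1L
  } else {
    starts <- c(1L, as.integer(m) + attr(m, "match.length"))
  }
  ends <- c(starts[-1] - 1L, nchar(text))
  data.frame(start = starts, end = ends,
             text = substring(text, starts, ends), stringsAsFactors = FALSE)
}

sentence_of <- function(pos, sentences) {
  findInterval(pos, sentences$start)
}

# all matches of `pattern` in `text` as data.frame(start, end)
regex_spans <- function(pattern, text, ignore_case = FALSE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# -- cue detection ------------------------------------------------------------

#' Find AUC cue mentions in a text
#'
#' Locates every non-overlapping mention of an AUC-family cue: phrases like
#' "area under the receiver operating characteristic curve", "c-statistic",
#' "c-index" and "concordance index" (case-insensitive), and the bare
#' acronyms AUC / AUROC / AUROCC (case-sensitive, word-bounded, so that
#' pharmacokinetic subscripted forms such as "AUC0-24" are not cues).
#' Overlapping matches are resolved leftmost-longest, so the full phrase
#' "area under the receiver operating characteristic curve" yields one
#' mention, not one per sub-phrase.
#'
#' @param section_text Text of one abstract section.
#' @param section_label Label attached to the returned mentions.
#' @param config Configuration from [auc_config()].
#' @return A data.frame with columns `cue`, `canonical_cue`, `char_start`,
#'   `char_end`, `section_label`, in document order.
#' @export
#' @examples
#' find_cue_mentions("The AUC was 0.82.", "RESULTS")
find_cue_mentions <- function(section_text, section_label = "",
                              config = auc_config()) {
  text <- normalise_text(section_text)
  cues <- cue_mentions_all(text, config)
  cues <- cues[cues$type == "auc", , drop = FALSE]
  if (nrow(cues) == 0) {
    return(data.frame(cue = character(), canonical_cue = character(),
                      char_start = integer(), char_end = integer(),
                      section_label = character(), stringsAsFactors = FALSE))
  }
  data.frame(cue = substring(text, cues$start, cues$end),
             canonical_cue = cues$canonical,
             char_start = cues$start, char_end = cues$end,
             section_label = rep(section_label, nrow(cues)),
             stringsAsFactors = FALSE)
}

# all cues (AUC-family and competing) with leftmost-longest de-overlap
cue_mentions_all <- function(text, config) {
  ex <- config$extraction
  pieces <- list()
  for (i in seq_along(ex$phrase_cues)) {
    sp <- regex_spans(paste0("\\b", ex$phrase_cues[[i]], "\\b"), text,
                      ignore_case = TRUE)
    if (nrow(sp)) {
      sp$canonical <- names(ex$phrase_cues)[i]
      sp$type <- "auc"
      pieces[[length(pieces) + 1]] <- sp
    }
  }
  for (i in seq_along(ex$acronym_cues)) {
    sp <- regex_spans(paste0("\\b", ex$acronym_cues[[i]]), text,
                      ignore_case = FALSE)
    if (nrow(sp)) {
      sp$canonical <- names(ex$acronym_cues)[i]
      sp$type <- "auc"
      pieces[[length(pieces) + 1]] <- sp
    }
  }
  competing <- paste0("(?:", ex$competing_cues, ")", collapse = "|")
  sp <- regex_spans(competing, text, ignore_case = TRUE)
  if (nrow(sp)) {
    sp$canonical <- "competing"
    sp$type <- "competing"
    pieces[[length(pieces) + 1]] <- sp
  }
  if (length(pieces) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      canonical = character(), type = character(),
                      stringsAsFactors = FALSE))
  }
  cues <- do.call(rbind, pieces)
  cues <- cues[order(cues$start, -cues$end), , drop = FALSE]
  # leftmost-longest: drop any match overlapping an earlier-kept one
  keep <- logical(nrow(cues))
  last_end <- 0L
  for (i in seq_len(nrow(cues))) {
    if (cues$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cues$end[i]
    }
  }
  cues[keep, , drop = FALSE]
}

# -- numeric token handling ---------------------------------------------------

NUM_CORE <- "(?:[0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)"
NUM_TOKEN <- paste0("(?<![0-9.\\w])-?", NUM_CORE, "(?:\\s?%)?")

# point value followed by a bracketed or labelled confidence interval, e.g.
# "0.704 (95% CI 0.603 to 0.806)", "0.70 [0.60-0.80]", "0.70 (0.60, 0.80)",
# "0.70, 95% CI 0.60 to 0.80"
ci_triplet_pattern <- function() {
  num <- paste0("(-?", NUM_CORE, "(?:\\s?%)?)")
  label <- "95\\s?%\\s?(?:CI|confidence interval)\\s*[:,=]?\\s*"
  sep <- "\\s*(?:to|-|,|;)\\s*"
  paste0(
    num, "\\s*",
    "(?:",
    "[\\(\\[]\\s*(?:", label, ")?", num, sep, num, "\\s*[\\)\\]]",
    "|",
    ",?\\s*", label, num, sep, num,
    ")"
  )
}

#' Normalise a printed numeric token to an AUC value
#'
#' Applies the percent and range rules: a token with an explicit percent
#' sign, or a bare number in (1, 100] when the surrounding sentence
#' mentions percent, is divided by 100; afterwards values below 0 or
#' greater than or equal to 1 are rejected (so a printed "1" is dropped).
#'
#' @param raw_token The token as printed, e.g. `"0.704"`, `"85%"`.
#' @param percent_context Logical: does the surrounding sentence mention
#'   `%` or "percent"?
#' @return A list with `ok` (logical), and when `ok`: `value` in `[0, 1)`
#'   and `was_percent`; when not `ok`: a `reason` string.
#' @export
#' @examples
#' normalize_value("85%")$value
#' normalize_value("1.0")$ok
normalize_value <- function(raw_token, percent_context = FALSE) {
  tok <- gsub("\\s", "", raw_token)
  has_pct <- grepl("%$", tok)
  numstr <- sub("%$", "", tok)
  numstr <- gsub("(?<=[0-9]),(?=[0-9]{3})", "", numstr, perl = TRUE)
  val <- suppressWarnings(as.numeric(numstr))
  if (is.na(val)) {
    return(list(ok = FALSE, reason = "non_numeric"))
  }
  was_percent <- FALSE
  if (has_pct) {
    val <- val / 100
    was_percent <- TRUE
  } else if (val > 1 && val <= 100 && isTRUE(percent_context)) {
    val <- val / 100
    was_percent <- TRUE
  }
  if (val < 0) return(list(ok = FALSE, reason = "below_zero"))
  if (val >= 1) return(list(ok = FALSE, reason = "at_or_above_one"))
  list(ok = TRUE, value = val, was_percent = was_percent)
}

#' Count printed decimal places of a numeric token
#'
#' Digits after the decimal point as printed; percent tokens get two more
#' so that "80%" is comparable to "0.80" after conversion.
#'
#' @param raw_token Printed token, e.g. `"0.8"`, `"80%"`.
#' @return Integer count.
#' @export
#' @examples
#' decimal_places("0.8")   # 1
#' decimal_places("80%")   # 2
decimal_places <- function(raw_token) {
  vapply(raw_token, function(tok) {
    tok <- gsub("\\s", "", tok)
    has_pct <- grepl("%$", tok)
    numstr <- sub("%$", "", sub("^-", "", tok))
    dp <- if (grepl("\\.", numstr)) {
      nchar(sub("^[^.]*\\.", "", numstr))
    } else 0L
    as.integer(dp + if (has_pct) 2L else 0L)
  }, integer(1), USE.NAMES = FALSE)
}

# -- main extraction ----------------------------------------------------------

#' Extract AUC values from an abstract record
#'
#' For every AUC cue, numeric tokens within the association window after the
#' cue are captured. Interval patterns following a point value — e.g.
#' "0.704 (95% CI 0.603 to 0.806)" — are classified point / ci_lower /
#' ci_upper. Guards reject (i) numbers with trailing measurement units
#' (pharmacokinetic areas under the curve), (ii) numbers whose nearest
#' preceding statistic cue is sensitivity/specificity/accuracy/Brier etc.
#' rather than an AUC cue, (iii) sentences that define the AUC scale
#' ("The AUC ranges between 0.5 and 1"), and (iv) values below 0 or at or
#' above 1 after percent normalisation (so an AUC reported as exactly 1 is
#' dropped). Every rejected candidate is recorded with a machine-readable
#' reason in the `"rejections"` attribute of the result.
#'
#' @param record An [abstract_record()].
#' @param config Configuration from [auc_config()].
#' @return A data.frame with one row per retained value: `pmid`, `value`,
#'   `raw_token`, `role` (`point`/`ci_lower`/`ci_upper`), `decimal_places`,
#'   `was_percent`, `section_label`, `char_start`, `anomaly_flags`
#'   (comma-separated subset of `ci_reversed`, `out_of_range_partner`).
#'   Attribute `"rejections"`: data.frame of rejected candidates.
#' @export
extract_values <- function(record, config = auc_config()) {
  out <- list()
  rej <- list()
  for (i in seq_len(nrow(record$sections))) {
    res <- extract_from_section(record$sections$text[i],
                                record$sections$label[i], config)
    out[[i]] <- res$matches
    rej[[i]] <- res$rejections
  }
  matches <- rbind_or_empty(out, match_columns())
  rejections <- rbind_or_empty(rej, rejection_columns())
  if (nrow(matches)) matches$pmid <- record$pmid
  if (nrow(rejections)) rejections$pmid <- record$pmid
  matches <- matches[, c("pmid", setdiff(names(matches), "pmid"))]
  attr(matches, "rejections") <- rejections
  matches
}

match_columns <- function() {
  data.frame(value = numeric(), raw_token = character(), role = character(),
             decimal_places = integer(), was_percent = logical(),
             section_label = character(), char_start = integer(),
             anomaly_flags = character(), pmid = character(),
             stringsAsFactors = FALSE)
}

rejection_columns <- function() {
  data.frame(raw_token = character(), reason = character(),
             section_label = character(), char_start = integer(),
             pmid = character(), stringsAsFactors = FALSE)
}

rbind_or_empty <- function(pieces, template) {
  pieces <- Filter(function(x) !is.null(x) && nrow(x) > 0, pieces)
  if (length(pieces) == 0) return(template)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  for (col in setdiff(names(template), names(out))) out[[col]] <- template[[col]][0]
  out
}

extract_from_section <- function(text, label, config) {
  ex <- config$extraction
  text <- normalise_text(text)
  empty <- list(matches = NULL, rejections = NULL)
  if (!nzchar(trimws(text))) return(empty)
  if (!grepl("[0-9]", text)) return(empty)  # no numbers, nothing to extract

  sentences <- split_sentences(text)
  cues <- cue_mentions_all(text, config)
  if (!any(cues$type == "auc")) return(empty)
  cues$sentence <- sentence_of(cues$start, sentences)

  # sentences that define the AUC scale: ignore all their numbers
  guard_re <- paste(ex$scale_patterns, collapse = "|")
  guarded <- grepl(guard_re, sentences$text, perl = TRUE, ignore.case = TRUE)
  # the coverage level of a "95% CI" label must not put the sentence in
  # percent context
  pct_text <- gsub("[0-9]+\\s?%\\s?(CI\\b|confidence interval)", "",
                   sentences$text, ignore.case = TRUE)
  percent_ctx <- grepl("%|percent", pct_text, ignore.case = TRUE)
  competing_in <- vapply(seq_len(nrow(sentences)), function(s) {
    any(cues$type == "competing" & cues$sentence == s)
  }, logical(1))

  consumed <- rep(FALSE, nchar(text))
  candidates <- list()

  # confidence-interval triplets first; their spans are consumed
  tri <- gregexpr(ci_triplet_pattern(), text, perl = TRUE)[[1]]
  if (tri[1] != -1) {
    starts <- as.integer(tri)
    lens <- attr(tri, "match.length")
    cs <- attr(tri, "capture.start")
    cl <- attr(tri, "capture.length")
    for (k in seq_along(starts)) {
      grp_start <- cs[k, ]
      grp_len <- cl[k, ]
      present <- which(grp_start > 0 & grp_len > 0)
      # groups: 1 = point; 2,3 = bracketed lower/upper; 4,5 = labelled
      lower_g <- if (2 %in% present) 2L else 4L
      upper_g <- if (3 %in% present) 3L else 5L
      toks <- substring(text, grp_start[c(1, lower_g, upper_g)],
                        grp_start[c(1, lower_g, upper_g)] +
                          grp_len[c(1, lower_g, upper_g)] - 1L)
      candidates[[length(candidates) + 1]] <- list(
        kind = "triplet", tokens = toks,
        starts = grp_start[c(1, lower_g, upper_g)],
        anchor = grp_start[1]
      )
      consumed[starts[k]:(starts[k] + lens[k] - 1L)] <- TRUE
    }
  }

  # standalone numbers outside consumed spans
  nums <- regex_spans(NUM_TOKEN, text)
  if (nrow(nums)) {
    for (k in seq_len(nrow(nums))) {
      if (consumed[nums$start[k]]) next
      tok <- substring(text, nums$start[k], nums$end[k])
      # "95% CI": the coverage level is not a value
      trailing <- substring(text, nums$end[k] + 1L,
                            min(nchar(text), nums$end[k] + 25L))
      if (grepl("%$", gsub("\\s", "", tok)) &&
          grepl("^\\s*(?:CI\\b|confidence interval)", trailing,
                ignore.case = TRUE)) {
        next
      }
      candidates[[length(candidates) + 1]] <- list(
        kind = "point", tokens = tok, starts = nums$start[k],
        anchor = nums$start[k]
      )
    }
  }
  if (length(candidates) == 0) return(empty)
  # process in document order
  candidates <- candidates[order(vapply(candidates, `[[`, numeric(1), "anchor"))]

  matches <- list()
  rejections <- list()
  reject <- function(tok, reason, start) {
    rejections[[length(rejections) + 1]] <<- data.frame(
      raw_token = tok, reason = reason, section_label = label,
      char_start = start, pmid = "", stringsAsFactors = FALSE)
  }
  auc_cues <- cues[cues$type == "auc", , drop = FALSE]

  for (cand in candidates) {
    anchor <- cand$anchor
    s_id <- sentence_of(anchor, sentences)
    # claiming: nearest statistic cue ending before the number, within window
    left <- cues[cues$end < anchor, , drop = FALSE]
    if (nrow(left) == 0) next   # unclaimed, not a statistic at all
    nearest <- left[which.max(left$end), ]
    if (anchor - nearest$end > ex$window) next
    if (nearest$type == "competing") {
      reject(cand$tokens[1], "competing_cue", anchor)
      next
    }
    # crossing a sentence boundary into a sentence with a competing cue
    if (nearest$sentence != s_id && competing_in[s_id]) {
      reject(cand$tokens[1], "cross_sentence_competing", anchor)
      next
    }
    if (guarded[s_id]) {
      reject(cand$tokens[1], "scale_definition", anchor)
      next
    }
    pct_ctx <- percent_ctx[s_id]
    if (cand$kind == "point") {
      tok <- cand$tokens
      after <- substring(text, cand$starts + nchar(tok),
                         min(nchar(text), cand$starts + nchar(tok) + 15L))
      if (grepl(ex$unit_pattern, after, perl = TRUE)) {
        reject(tok, "pk_unit", anchor)
        next
      }
      nv <- normalize_value(tok, pct_ctx)
      if (!nv$ok) {
        reject(tok, nv$reason, anchor)
        next
      }
      matches[[length(matches) + 1]] <- data.frame(
        value = nv$value, raw_token = tok, role = "point",
        decimal_places = decimal_places(tok), was_percent = nv$was_percent,
        section_label = label, char_start = cand$starts,
        anomaly_flags = "", pmid = "", stringsAsFactors = FALSE)
    } else {
      roles <- c("point", "ci_lower", "ci_upper")
      nvs <- lapply(cand$tokens, normalize_value, percent_context = pct_ctx)
      ok <- vapply(nvs, `[[`, logical(1), "ok")
      flags <- c("", "", "")
      if (ok[2] && ok[3] && nvs[[2]]$value > nvs[[3]]$value) {
        flags[2:3] <- "ci_reversed"
      }
      if (xor(ok[2], ok[3])) {
        surv <- which(c(FALSE, ok[2], ok[3]))
        flags[surv] <- paste_flag(flags[surv], "out_of_range_partner")
      }
      for (j in 1:3) {
        if (!ok[j]) {
          reject(cand$tokens[j], nvs[[j]]$reason, cand$starts[j])
          next
        }
        matches[[length(matches) + 1]] <- data.frame(
          value = nvs[[j]]$value, raw_token = cand$tokens[j], role = roles[j],
          decimal_places = decimal_places(cand$tokens[j]),
          was_percent = nvs[[j]]$was_percent, section_label = label,
          char_start = cand$starts[j], anomaly_flags = flags[j],
          pmid = "", stringsAsFactors = FALSE)
      }
    }
  }
  list(matches = rbind_or_empty(matches, match_columns()),
       rejections = rbind_or_empty(rejections, rejection_columns()))
}

paste_flag <- function(existing, flag) {
  ifelse(nzchar(existing), paste(existing, flag, sep = ","), flag)
}

#' Extract AUC values from a whole corpus
#'
#' @param records List of `abstract_record` objects (typically the included
#'   candidates after [apply_exclusions()]).
#' @param config Configuration from [auc_config()].
#' @return A data.frame of matches as in [extract_values()], with a
#'   `"rejections"` attribute covering the whole corpus.
#' @export
extract_corpus <- function(records, config = auc_config()) {
  res <- lapply(records, extract_values, config = config)
  matches <- rbind_or_empty(res, match_columns())
  rejections <- rbind_or_empty(lapply(res, attr, "rejections"),
                               rejection_columns())
  matches <- matches[, c("pmid", setdiff(names(matches), "pmid"))]
  attr(matches, "rejections") <- rejections
  matches
}
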