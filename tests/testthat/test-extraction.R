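test_that("cue mentions are found, non-overlapping, in document order", {
  m <- find_cue_mentions("The AUC was 0.82.", "RESULTS")
  expect_equal(nrow(m), 1)
  expect_equal(m$canonical_cue, "auc")
  expect_equal(m$section_label, "RESULTS")

  m2 <- find_cue_mentions(
    "area under the receiver operating characteristic curve (AUROC)")
  expect_equal(nrow(m2), 2)
  expect_equal(m2$canonical_cue, c("roc_area_phrase", "auroc"))

  # pharmacokinetic subscripted acronyms are not cues
  m3 <- find_cue_mentions("glucose AUC0-24 was 412 ng·h/mL")
  expect_equal(nrow(m3), 0)
  m4 <- find_cue_mentions("the AUC(0-12) after dosing")
  expect_equal(nrow(m4), 0)

  # acronym matching is case-sensitive
  expect_equal(nrow(find_cue_mentions("the auc was high")), 0)
  expect_equal(nrow(find_cue_mentions("the c-statistic was 0.7"))
               , 1)
})

test_that("point + CI triplets get roles point/ci_lower/ci_upper", {
  m <- extract_values(results_record(
    "The AUC was 0.704 (95% CI 0.603 to 0.806)."))
  expect_equal(nrow(m), 3)
  expect_equal(m$role, c("point", "ci_lower", "ci_upper"))
  expect_equal(m$value, c(0.704, 0.603, 0.806))
  expect_equal(m$decimal_places, c(3L, 3L, 3L))

  # other separators and brackets
  for (s in c("The AUC was 0.70 [0.60-0.80].",
              "The AUC was 0.70 (0.60, 0.80).",
              "The AUC was 0.70, 95% CI 0.60 to 0.80.")) {
    mm <- extract_values(results_record(s))
    expect_equal(mm$role, c("point", "ci_lower", "ci_upper"), label = s)
  }
})

test_that("scale-definition sentences and values of 1 yield no matches", {
  expect_equal(nrow(extract_values(results_record(
    "The AUC ranges between 0.5 and 1."))), 0)
  expect_equal(nrow(extract_values(results_record(
    "AUC values between 0.7 and 0.8 were considered acceptable."))), 0)
  m <- extract_values(results_record("The model achieved an AUC of 1."))
  expect_equal(nrow(m), 0)
  rej <- attr(m, "rejections")
  expect_true("at_or_above_one" %in% rej$reason)
})

test_that("competing statistics claim their own numbers", {
  m <- extract_values(results_record(
    "sensitivity 0.91, specificity 0.66, AUC 0.83"))
  expect_equal(m$value, 0.83)
  rej <- attr(m, "rejections")
  expect_setequal(rej$raw_token, c("0.91", "0.66"))
  expect_true(all(rej$reason == "competing_cue"))

  # a number in a later sentence with a competing cue is not claimed across
  # the boundary
  m2 <- extract_values(results_record(
    "We report the AUC. The specificity was 0.66."))
  expect_equal(nrow(m2), 0)
})

test_that("pharmacokinetic unit guard rejects dose-exposure numbers", {
  m <- extract_values(results_record(
    "The AUC was 0.81. The glucose AUC0-24 was 412 ng·h/mL."))
  expect_equal(m$value, 0.81)
  m2 <- extract_values(results_record("The AUCinf was 38.5 mg·h/L."))
  expect_equal(nrow(m2), 0)
})

test_that("percent values are converted and flagged", {
  m <- extract_values(results_record("The AUC was 85.2%."))
  expect_equal(m$value, 0.852)
  expect_true(m$was_percent)
  expect_equal(m$decimal_places, 3L)

  nv <- normalize_value("85%")
  expect_equal(nv$value, 0.85)
  expect_true(nv$was_percent)
  expect_equal(normalize_value("0.5")$value, 0.5)
  expect_false(normalize_value("0.5")$was_percent)
  expect_false(normalize_value("1.0")$ok)
  expect_false(normalize_value("-0.2")$ok)
  # bare >1 number only rescaled in percent context
  expect_false(normalize_value("85", percent_context = FALSE)$ok)
  expect_equal(normalize_value("85", percent_context = TRUE)$value, 0.85)
})

test_that("decimal places count printed digits, +2 for percent tokens", {
  expect_equal(decimal_places(c("0.8", "0.704", "80%", "73.1%", "1")),
               c(1L, 3L, 2L, 3L, 0L))
})

test_that("reversed and range-filtered intervals are flagged, not swapped", {
  m <- extract_values(results_record(
    "The AUC was 0.70 (95% CI 0.80 to 0.60)."))
  expect_equal(m$value[m$role == "ci_lower"], 0.80)
  expect_true(all(grepl("ci_reversed",
                        m$anomaly_flags[m$role != "point"])))

  m2 <- extract_values(results_record(
    "The AUC was 0.95 (95% CI 0.88 to 1.02)."))
  expect_equal(m2$role, c("point", "ci_lower"))
  expect_true(grepl("out_of_range_partner",
                    m2$anomaly_flags[m2$role == "ci_lower"]))
})

test_that("every retained value is in [0,1) under fuzzing", {
  set.seed(21)
  for (i in 1:60) {
    vals <- round(runif(3, -0.5, 1.5), sample(1:3, 1))
    text <- paste0("The AUC was ", paste(vals, collapse = ", then "), ".")
    m <- extract_values(results_record(text))
    if (nrow(m)) {
      expect_true(all(m$value >= 0 & m$value < 1))
    }
  }
})

test_that("extraction is deterministic", {
  rec <- results_record(
    "The AUROC was 0.88 (95% CI 0.80-0.95) and the AUC was 77.5%.")
  expect_identical(extract_values(rec), extract_values(rec))
})
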