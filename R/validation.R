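#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval obtained by inverting the binomial tail
#' probabilities, computed through the binomial-beta relationship:
#' `lower = qbeta(alpha/2, s, n - s + 1)` and
#' `upper = qbeta(1 - alpha/2, s + 1, n - s)`, with `lower = 0` when
#' `s = 0` and `upper = 1` when `s = n`.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (at least 1).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' round(exact_binomial_ci(100, 100), 3)  # 0.964 to 1.000
#' round(exact_binomial_ci(99, 100), 3)   # 0.946 to 1.000
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (length(successes) != 1 || length(trials) != 1 ||
      is.na(successes) || is.na(trials) ||
      successes %% 1 != 0 || trials %% 1 != 0 ||
      trials < 1 || successes < 0 || successes > trials) {
    stop("need integer counts with 0 <= successes <= trials and trials >= 1")
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else {
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  }
  upper <- if (successes == trials) 1 else {
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  }
  c(lower = lower, upper = upper)
}

#' Bland-Altman limits of agreement
#'
#' Classic normal-quantile limits for paired differences:
#' `mean(d) +/- z * sd(d)` with `z` the standard-normal quantile at
#' `(1 + coverage)/2` (1.6449 for the default 90% coverage) and the sample
#' standard deviation on `n - 1` degrees of freedom.
#'
#' @param differences Numeric vector of paired differences (at least 2).
#' @param coverage Coverage of the limits, default 0.90.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' limits_of_agreement(c(-2, -1, -1, 0, 0, 0))
limits_of_agreement <- function(differences, coverage = 0.90) {
  if (length(differences) < 2) stop("need at least 2 differences")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  z <- stats::qnorm((1 + coverage) / 2)
  m <- mean(differences)
  s <- stats::sd(differences)
  c(lower = m - z * s, upper = m + z * s)
}

#' Build annotation pairs from extraction and manual tables
#'
#' @param algo A data.frame with columns `pmid` and `value`: the
#'   algorithm's extracted values.
#' @param manual A data.frame with columns `pmid` and `value`: manually
#'   entered values for the same abstracts.
#' @param pmids Optional full set of annotated pmids (an abstract where
#'   neither side found a value must still count as a both-absent
#'   agreement); defaults to the union of the two tables' pmids.
#' @return A list of `annotation_pair` lists (pmid, algo_values,
#'   manual_values).
#' @export
annotation_pairs <- function(algo, manual, pmids = NULL) {
  if (is.null(pmids)) pmids <- union(algo$pmid, manual$pmid)
  pmids <- as.character(pmids)
  if (anyDuplicated(pmids)) stop("duplicate pmid in annotation set")
  lapply(pmids, function(p) {
    list(pmid = p,
         algo_values = algo$value[algo$pmid == p],
         manual_values = manual$value[manual$pmid == p])
  })
}

#' Compare algorithmic extraction against manual annotation
#'
#' Tallies presence/absence agreement (an abstract "has an AUC" when its
#' value multiset is non-empty), computes algorithm-conditioned negative
#' and positive predictive values with exact binomial intervals, and the
#' Bland-Altman limits of agreement for the per-abstract difference in the
#' number of values extracted (algorithm minus manual), computed over
#' abstracts where either side found at least one value.
#'
#' @param pairs A list from [annotation_pairs()].
#' @param level Confidence level for the predictive-value intervals.
#' @param loa_coverage Coverage for the limits of agreement.
#' @return A `validation_result` list: `n_abstracts`, `confusion` (counts
#'   both_present / both_absent / algo_only / manual_only), `npv`, `ppv`
#'   (each a list with `estimate`, `lower`, `upper`), `count_differences`,
#'   `loa`, `loa_coverage`.
#' @export
compare_annotations <- function(pairs, level = 0.95, loa_coverage = 0.90) {
  pmids <- vapply(pairs, `[[`, character(1), "pmid")
  if (anyDuplicated(pmids)) {
    stop("duplicate pmid in annotation pairs: ", pmids[duplicated(pmids)][1])
  }
  a <- vapply(pairs, function(p) length(p$algo_values) > 0, logical(1))
  m <- vapply(pairs, function(p) length(p$manual_values) > 0, logical(1))
  confusion <- c(both_present = sum(a & m), both_absent = sum(!a & !m),
                 algo_only = sum(a & !m), manual_only = sum(!a & m))
  stopifnot(sum(confusion) == length(pairs))
  mk_pv <- function(agree, denom) {
    if (denom == 0) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    ci <- exact_binomial_ci(agree, denom, level)
    list(estimate = unname(agree / denom), lower = unname(ci["lower"]),
         upper = unname(ci["upper"]))
  }
  npv <- mk_pv(confusion["both_absent"], sum(!a))
  ppv <- mk_pv(confusion["both_present"], sum(a))
  either <- a | m
  diffs <- vapply(pairs[either], function(p) {
    length(p$algo_values) - length(p$manual_values)
  }, numeric(1))
  loa <- if (length(diffs) >= 2) {
    limits_of_agreement(diffs, loa_coverage)
  } else c(lower = NA_real_, upper = NA_real_)
  structure(
    list(n_abstracts = length(pairs), confusion = confusion,
         npv = npv, ppv = ppv, count_differences = diffs,
         loa = loa, loa_coverage = loa_coverage),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>", x$n_abstracts, "annotated abstracts\n")
  cat("  presence confusion:",
      paste(names(x$confusion), x$confusion, collapse = ", "), "\n")
  fmt <- function(pv) sprintf("%.3f (%.3f to %.3f)", pv$estimate, pv$lower,
                              pv$upper)
  cat("  NPV:", fmt(x$npv), " PPV:", fmt(x$ppv), "\n")
  cat(sprintf("  %.0f%% limits of agreement (algo - manual): %.3f to %.3f\n",
              100 * x$loa_coverage, x$loa["lower"], x$loa["upper"]))
  invisible(x)
}
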