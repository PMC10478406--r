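#' Histogram specification for AUC values
#'
#' The convention is 100 half-open bins `(lower, upper]` of width 0.01 on
#' `(0, 1]`, with lower edges 0, 0.01, ..., 0.99; the bin `(0.69, 0.70]`
#' contains every value greater than 0.69 and less than or equal to 0.70,
#' so that a printed "0.70" counts below the 0.7 threshold. Values printed
#' with a single decimal place ("0.8") are excluded by default because
#' rounding alone would spike the tenths bins, and confidence-interval
#' limits are excluded by default so the histogram describes point
#' estimates.
#'
#' @param bin_width Bin width; only 0.01 is supported.
#' @param exclude_one_decimal Drop values whose printed token has exactly
#'   one decimal place.
#' @param roles Which roles enter the histogram (subset of `"point"`,
#'   `"ci_lower"`, `"ci_upper"`).
#' @return A `histogram_spec` list.
#' @export
histogram_spec <- function(bin_width = 0.01, exclude_one_decimal = TRUE,
                           roles = "point") {
  stopifnot(isTRUE(all.equal(bin_width, 0.01)))
  stopifnot(all(roles %in% c("point", "ci_lower", "ci_upper")))
  structure(list(bin_width = bin_width,
                 lower_edges = (0:99) / 100,
                 upper_edges = (1:100) / 100,
                 exclude_one_decimal = isTRUE(exclude_one_decimal),
                 roles = roles),
            class = "histogram_spec")
}

#' Bin AUC values into the (lower, upper] histogram
#'
#' @param values Either a numeric vector of values in `[0, 1)` (all treated
#'   as point estimates with unknown decimal places) or a data.frame of
#'   matches from [extract_values()] with columns `value`, `role` and
#'   `decimal_places`.
#' @param spec A [histogram_spec()].
#' @return An `auc_histogram`: list with `spec`, `counts` (100 integers),
#'   `n_values` (number binned), `n_excluded_one_decimal`. Conservation
#'   `sum(counts) == n_values` always holds.
#' @export
#' @examples
#' h <- build_histogram(c(0.70, 0.701, 0.85))
#' h$counts[70:71]   # 0.70 in (0.69, 0.70], 0.701 in (0.70, 0.71]
build_histogram <- function(values, spec = histogram_spec()) {
  n_excl <- 0L
  if (is.data.frame(values)) {
    df <- values[values$role %in% spec$roles, , drop = FALSE]
    if (spec$exclude_one_decimal && nrow(df) > 0) {
      one_dp <- !is.na(df$decimal_places) & df$decimal_places == 1L
      n_excl <- sum(one_dp)
      df <- df[!one_dp, , drop = FALSE]
    }
    x <- df$value
  } else {
    x <- as.numeric(values)
  }
  if (any(is.na(x)) || any(x < 0 | x >= 1)) {
    stop("all values must lie in [0, 1); upstream filtering should have ",
         "removed the rest")
  }
  edges <- (0:100) / 100
  idx <- findInterval(x, edges, left.open = TRUE)
  idx[idx == 0L] <- 1L  # a value of exactly 0 is counted in (0, 0.01]
  counts <- tabulate(idx, nbins = 100L)
  out <- structure(list(spec = spec, counts = as.integer(counts),
                        n_values = length(x),
                        n_excluded_one_decimal = n_excl),
                   class = "auc_histogram")
  stopifnot(sum(out$counts) == out$n_values)
  out
}

#' @export
print.auc_histogram <- function(x, ...) {
  cat("<auc_histogram>", x$n_values, "values in 100 bins of width 0.01;",
      x$n_excluded_one_decimal, "one-decimal values excluded\n")
  invisible(x)
}

#' Natural cubic spline basis
#'
#' Basis for a natural cubic spline with the given degrees of freedom:
#' piecewise cubic with continuous second derivatives, constrained to be
#' linear beyond the boundary knots. For `df = 4` the interior knots sit at
#' the 25th/50th/75th percentiles of `x` (the conventional default for a
#' df-specified natural spline; knots can also be given explicitly).
#'
#' @param x Evaluation points (e.g. histogram bin midpoints).
#' @param df Degrees of freedom (number of basis columns, excluding the
#'   intercept); must be at least 2.
#' @param boundary Boundary knots; defaults to `range(x)`.
#' @param knots Optional explicit interior knots.
#' @return A numeric matrix with `length(x)` rows and `df` columns, with
#'   attributes `knots` and `Boundary.knots`.
#' @export
natural_spline_basis <- function(x, df = 4L, boundary = range(x),
                                 knots = NULL) {
  stopifnot(df >= 2)
  if (is.null(knots)) {
    probs <- seq(0, 1, length.out = df + 1L)[-c(1L, df + 1L)]
    knots <- unname(stats::quantile(x, probs = probs, type = 7))
  }
  if (anyDuplicated(c(boundary, knots))) {
    stop("duplicate knots: x has too few distinct values for df = ", df)
  }
  basis <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  stopifnot(ncol(basis) == df)
  basis
}

#' Fit the Poisson natural-spline smooth to a histogram
#'
#' Fits a log-linear Poisson regression of the bin counts on an intercept
#' plus a natural cubic spline (default 4 degrees of freedom) of the bin
#' midpoints, via iteratively reweighted least squares. The fitted curve is
#' the smooth null distribution; residuals are observed minus fitted, so an
#' excess of values in a bin gives a positive residual.
#'
#' @param hist An [build_histogram()] result.
#' @param df Spline degrees of freedom.
#' @param fit_lower,fit_upper Optional fit domain in value units: only bins
#'   whose interval lies inside `[fit_lower, fit_upper]` are fitted (use
#'   this when the data have bounded support and distant structural-zero
#'   bins should not influence the smooth). Default: all 100 bins.
#' @return An `auc_smoothfit`: list with `coefficients` (intercept + `df`
#'   spline terms), `fitted` and `residuals` (length-100 vectors, `NA`
#'   outside the fit domain), `deviance`, `converged`, `n_iterations`,
#'   `fit_bins` (indices of fitted bins), `knots`, `boundary`, `df`.
#' @export
fit_poisson_spline <- function(hist, df = 4L, fit_lower = NULL,
                               fit_upper = NULL) {
  stopifnot(inherits(hist, "auc_histogram"))
  mids <- hist$spec$lower_edges + hist$spec$bin_width / 2
  sel <- rep(TRUE, 100L)
  if (!is.null(fit_lower)) sel <- sel & hist$spec$lower_edges >= fit_lower - 1e-9
  if (!is.null(fit_upper)) sel <- sel & hist$spec$upper_edges <= fit_upper + 1e-9
  counts <- hist$counts[sel]
  if (sum(sel) < df + 2L) stop("too few bins in the fit domain for df = ", df)
  if (all(counts == 0L)) stop("all counts in the fit domain are zero")
  x <- mids[sel]
  basis <- natural_spline_basis(x, df = df, boundary = range(x))
  fit <- suppressWarnings(stats::glm.fit(
    x = cbind(`(Intercept)` = 1, basis), y = counts,
    family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)
  ))
  if (!fit$converged) {
    warning("Poisson spline fit did not converge in 100 iterations")
  }
  fitted <- residuals <- rep(NA_real_, 100L)
  fitted[sel] <- fit$fitted.values
  residuals[sel] <- counts - fit$fitted.values
  structure(
    list(coefficients = stats::coef(fit), fitted = fitted,
         residuals = residuals, deviance = fit$deviance,
         converged = fit$converged, n_iterations = fit$iter,
         fit_bins = which(sel), knots = attr(basis, "knots"),
         boundary = attr(basis, "Boundary.knots"), df = df),
    class = "auc_smoothfit"
  )
}

#' @export
print.auc_smoothfit <- function(x, ...) {
  cat("<auc_smoothfit> natural spline, df =", x$df,
      "| deviance =", format(x$deviance, digits = 5),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Histogram and smooth fit as a table
#'
#' @param hist An `auc_histogram`.
#' @param fit An `auc_smoothfit` for the same histogram.
#' @return data.frame with lower_edge, upper_edge, observed, fitted,
#'   residual.
#' @export
histogram_fit_table <- function(hist, fit = NULL) {
  out <- data.frame(lower_edge = hist$spec$lower_edges,
                    upper_edge = hist$spec$upper_edges,
                    observed = hist$counts)
  if (!is.null(fit)) {
    out$fitted <- fit$fitted
    out$residual <- fit$residuals
  }
  out
}

#' Summarise excesses at reporting thresholds
#'
#' For each threshold `t` (default 0.7, 0.8, 0.9) reports the observed
#' count, smooth-fit count and residual for the bin just below
#' (`(t-0.01, t]`) and just above (`(t, t+0.01]`) the threshold, plus the
#' observed/fitted ratio of the above-bin (`excess_ratio_above`, a
#' convenience summary on top of the residuals).
#'
#' @param hist An `auc_histogram`.
#' @param fit An `auc_smoothfit` for the same histogram.
#' @param thresholds Thresholds, each a multiple of 0.01 strictly inside
#'   (0.01, 0.99).
#' @return A `threshold_report` data.frame with one row per threshold:
#'   `threshold`, `observed_below`, `fitted_below`, `residual_below`,
#'   `observed_above`, `fitted_above`, `residual_above`,
#'   `excess_ratio_above`.
#' @export
threshold_report <- function(hist, fit, thresholds = c(0.7, 0.8, 0.9)) {
  idx <- thresholds * 100
  if (any(abs(idx - round(idx)) > 1e-9)) {
    stop("thresholds must be aligned to the 0.01 bin grid")
  }
  idx <- as.integer(round(idx))
  if (any(idx <= 1L | idx >= 99L)) {
    stop("thresholds must lie strictly inside (0.01, 0.99)")
  }
  below <- idx        # bin (t-0.01, t]
  above <- idx + 1L   # bin (t, t+0.01]
  out <- data.frame(
    threshold = thresholds,
    observed_below = hist$counts[below],
    fitted_below = fit$fitted[below],
    residual_below = fit$residuals[below],
    observed_above = hist$counts[above],
    fitted_above = fit$fitted[above],
    residual_above = fit$residuals[above]
  )
  out$excess_ratio_above <- out$observed_above / out$fitted_above
  class(out) <- c("threshold_report", "data.frame")
  out
}

#' Keep the highest point value per abstract
#'
#' Supports the best-model-per-abstract subgroup: abstracts often report
#' several competing models, and the question is whether the best one sits
#' just above a threshold.
#'
#' @param matches Match data.frame (rows with role other than "point" are
#'   dropped first).
#' @return One row per pmid: the maximum value, ties broken by first
#'   occurrence.
#' @export
max_per_abstract <- function(matches) {
  m <- matches[matches$role == "point", , drop = FALSE]
  if (nrow(m) == 0) return(m)
  ord <- order(m$pmid, -m$value)
  m <- m[ord, , drop = FALSE]
  out <- m[!duplicated(m$pmid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep values from the results section of structured abstracts
#'
#' @param matches Match data.frame.
#' @return Rows whose uppercase section label contains "RESULT";
#'   unstructured abstracts (empty label) are dropped.
#' @export
subset_results_section <- function(matches) {
  keep <- grepl("RESULT", toupper(matches$section_label), fixed = TRUE)
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep values published in a given journal
#'
#' @param matches Match data.frame.
#' @param corpus A data.frame with columns `pmid` and `journal` (e.g. from
#'   [corpus_table()]).
#' @param journal_name Journal title, matched case-insensitively and
#'   exactly.
#' @return The matching rows.
#' @export
subset_journal <- function(matches, corpus, journal_name) {
  jl <- tolower(trimws(corpus$journal))
  keep_pmids <- corpus$pmid[jl == tolower(trimws(journal_name))]
  out <- matches[matches$pmid %in% keep_pmids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
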