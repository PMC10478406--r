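# independent textbook construction of the natural cubic spline space:
# {x, d_k(x) - d_{K-1}(x)} with truncated-power functions
# d_k(x) = ((x - k_k)_+^3 - (x - k_K)_+^3) / (k_K - k_k)
truncated_power_natural_basis <- function(x, knots_all) {
  K <- length(knots_all)
  d <- function(k) {
    (pmax(x - knots_all[k], 0)^3 - pmax(x - knots_all[K], 0)^3) /
      (knots_all[K] - knots_all[k])
  }
  cols <- lapply(seq_len(K - 2), function(k) d(k) - d(K - 1))
  cbind(x, do.call(cbind, cols))
}

test_that("values land in the (lower, upper] bin; conservation under fuzz", {
  h <- build_histogram(c(0.70, 0.690001, 0.70001))
  expect_equal(h$counts[70], 2)   # (0.69, 0.70]
  expect_equal(h$counts[71], 1)   # (0.70, 0.71]
  expect_equal(sum(h$counts), 3)

  set.seed(4)
  for (i in 1:20) {
    x <- round(runif(500), sample(2:6, 1))
    x <- x[x < 1]
    h <- build_histogram(x)
    expect_equal(sum(h$counts), length(x))
    # single-bin membership: counts match a direct cut()
    direct <- table(cut(x, breaks = (0:100) / 100, right = TRUE,
                        include.lowest = TRUE))
    expect_equal(h$counts, as.integer(direct))
  }
  expect_error(build_histogram(c(0.5, 1.0)), "\\[0, 1\\)")
  expect_error(build_histogram(c(-0.1)), "\\[0, 1\\)")
})

test_that("one-decimal values and CI limits are excluded per the spec", {
  m <- data.frame(pmid = "1",
                  value = c(0.8, 0.812, 0.7, 0.65),
                  raw_token = c("0.8", "0.812", "0.70", "0.65"),
                  role = c("point", "point", "ci_lower", "ci_upper"),
                  decimal_places = c(1L, 3L, 2L, 2L),
                  stringsAsFactors = FALSE)
  h <- build_histogram(m)
  expect_equal(h$n_values, 1)             # only the 3-decimal point value
  expect_equal(h$n_excluded_one_decimal, 1)
  expect_equal(h$counts[82], 1)           # 0.812 in (0.81, 0.82]

  h2 <- build_histogram(m, histogram_spec(roles = c("ci_lower")))
  expect_equal(h2$counts[70], 1)          # the printed "0.70" counts below
})

test_that("natural spline basis spans the textbook truncated-power space", {
  x <- (0:99) / 100 + 0.005
  B <- natural_spline_basis(x, df = 4)
  expect_equal(dim(B), c(100L, 4L))
  knots_all <- sort(c(attr(B, "Boundary.knots"), attr(B, "knots")))
  O <- truncated_power_natural_basis(x, knots_all)
  # each basis lies in the span of the other (residual ~ 0)
  for (j in seq_len(ncol(O))) {
    r <- residuals(lm(O[, j] ~ B))
    expect_lt(max(abs(r)), 1e-10)
  }
  for (j in seq_len(ncol(B))) {
    r <- residuals(lm(B[, j] ~ O))
    expect_lt(max(abs(r)), 1e-10)
  }
})

test_that("spline basis is linear beyond the boundary knots", {
  B <- natural_spline_basis((40:99) / 100 + 0.005, df = 4,
                            boundary = c(0.405, 0.995))
  for (outside in list(seq(0.1, 0.4, by = 0.01), seq(1.0, 1.3, by = 0.01))) {
    P <- predict(B, outside)
    for (j in seq_len(ncol(P))) {
      expect_lt(max(abs(diff(diff(P[, j])))), 1e-10)
    }
  }
  expect_error(natural_spline_basis(rep(0.5, 10), df = 4), "duplicate")
})

test_that("Poisson spline fit matches direct likelihood maximisation", {
  # 20-bin toy: counts 1..20 in bins (0.40, 0.60]
  vals <- rep((40:59) / 100 + 0.005, times = 1:20)
  h <- build_histogram(vals)
  fit <- fit_poisson_spline(h, df = 4, fit_lower = 0.40, fit_upper = 0.60)
  expect_true(fit$converged)

  mids <- (40:59) / 100 + 0.005
  X <- cbind(1, natural_spline_basis(mids, df = 4, boundary = range(mids)))
  counts <- 1:20
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(exp(eta)) - sum(counts * eta)
  }
  gr <- function(beta) drop(crossprod(X, exp(drop(X %*% beta)) - counts))
  oracle <- optim(rep(0, ncol(X)), negll, gr, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(unname(fit$coefficients) - oracle$par)), 1e-6)

  # score equation: sum fitted = sum observed
  expect_lt(abs(sum(fit$fitted, na.rm = TRUE) - sum(counts)) / sum(counts),
            1e-6)
  expect_lt(abs(sum(fit$residuals, na.rm = TRUE)), 1e-6 * sum(counts))
})

test_that("constant counts are fitted exactly; conservation holds on fuzz", {
  h <- build_histogram(rep((0:99) / 100 + 0.005, each = 50))
  fit <- fit_poisson_spline(h)
  expect_true(all(abs(fit$fitted - 50) < 1e-6))
  expect_true(all(abs(fit$residuals) < 1e-6))

  set.seed(17)
  for (i in 1:10) {
    x <- rbeta(2000, 2, 2)
    fit <- fit_poisson_spline(build_histogram(x))
    expect_lt(abs(sum(fit$fitted) - 2000) / 2000, 1e-6)
    expect_true(all(fit$fitted > 0))
  }
  expect_error(fit_poisson_spline(build_histogram(numeric(0))), "zero")
})

test_that("threshold report picks the bins adjacent to each threshold", {
  set.seed(8)
  h <- build_histogram(rbeta(5000, 4, 2))
  fit <- fit_poisson_spline(h)
  tr <- threshold_report(h, fit, c(0.7, 0.8, 0.9))
  expect_equal(tr$observed_below, h$counts[c(70, 80, 90)])
  expect_equal(tr$observed_above, h$counts[c(71, 81, 91)])
  expect_equal(tr$residual_above,
               h$counts[c(71, 81, 91)] - fit$fitted[c(71, 81, 91)])
  expect_equal(tr$excess_ratio_above,
               tr$observed_above / tr$fitted_above)
  expect_error(threshold_report(h, fit, 0.705), "grid")
  expect_error(threshold_report(h, fit, 0.01), "strictly inside")

  # fitted == observed everywhere -> residual 0, ratio 1
  fake <- fit
  fake$fitted <- as.numeric(h$counts)
  fake$residuals <- rep(0, 100)
  tr0 <- threshold_report(h, fake)
  expect_true(all(tr0$residual_above == 0))
  expect_true(all(tr0$excess_ratio_above[tr0$observed_above > 0] == 1))
})

test_that("subgroup helpers: max per abstract, results-only, journal", {
  m <- data.frame(
    pmid = c("a", "a", "a", "b", "c"),
    value = c(0.71, 0.83, 0.80, 0.65, 0.83),
    role = c("point", "point", "ci_upper", "point", "point"),
    section_label = c("RESULTS", "RESULTS", "RESULTS", "METHODS", ""),
    stringsAsFactors = FALSE)
  top <- max_per_abstract(m)
  expect_equal(top$value[top$pmid == "a"], 0.83)
  expect_equal(nrow(top), 3)
  single <- max_per_abstract(m[m$pmid == "b", ])
  expect_equal(single$value, 0.65)

  rs <- subset_results_section(m)
  expect_setequal(rs$pmid, "a")   # METHODS and unlabelled dropped

  corpus <- data.frame(pmid = c("a", "b", "c"),
                       journal = c("PLoS One", "Other J", "plos one"),
                       stringsAsFactors = FALSE)
  pj <- subset_journal(m, corpus, "PLOS ONE")
  expect_setequal(pj$pmid, c("a", "c"))
  expect_equal(nrow(subset_journal(m, corpus[0, ], "PLOS ONE")), 0)
})
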