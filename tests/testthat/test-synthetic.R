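test_that("base draws are smooth, in range, and reproducible", {
  cfg <- synthetic_config(seed = 5L)
  set.seed(5)
  x <- sample_true_auc(10000, cfg)
  expect_true(all(x > cfg$base$lower & x < cfg$base$upper))
  # no atoms at bin-width scale: no single 0.001-wide cell dominates
  tab <- table(round(x, 3))
  expect_lt(max(tab) / length(x), 0.02)

  set.seed(5); a <- sample_true_auc(100, cfg)
  set.seed(5); b <- sample_true_auc(100, cfg)
  expect_identical(a, b)

  cfgs <- synthetic_config(base = list(family = "smooth_null", shape1 = 4.5,
                                       shape2 = 3.5, lower = 0.4, upper = 1))
  set.seed(5)
  y <- sample_true_auc(10000, cfgs)
  expect_true(all(y >= 0.4 & y <= 1))
})

test_that("promotion fires only in the window, lands just above threshold", {
  cfg1 <- synthetic_config(promotion_prob = 1)
  set.seed(1)
  p <- apply_promotion(0.69, cfg1)
  expect_true(p$promoted)
  expect_gt(p$values, 0.70)
  expect_lte(p$values, 0.71)

  p2 <- apply_promotion(0.50, cfg1)
  expect_false(p2$promoted)
  expect_equal(p2$values, 0.50)

  cfg0 <- synthetic_config(promotion_prob = 0)
  set.seed(2)
  x <- sample_true_auc(5000, cfg0)
  p3 <- apply_promotion(x, cfg0)
  expect_identical(p3$values, x)
  expect_false(any(p3$promoted))
})

test_that("promoted fraction among eligible values is close to h", {
  cfg <- synthetic_config(promotion_prob = 0.3)
  set.seed(12)
  pre <- sample_true_auc(50000, cfg)
  eligible <- rep(FALSE, length(pre))
  for (t in cfg$thresholds) {
    eligible <- eligible | (pre > t - cfg$promotion_window & pre <= t)
  }
  prom <- apply_promotion(pre, cfg)
  frac <- sum(prom$promoted) / sum(eligible)
  se <- sqrt(0.3 * 0.7 / sum(eligible))
  expect_lt(abs(frac - 0.3), 3 * se)
  # every promoted value sits in (t, t + eps] with its source in (t-delta, t]
  moved <- which(prom$promoted)
  for (i in moved[seq_len(min(200, length(moved)))]) {
    t <- cfg$thresholds[which.min(abs(cfg$thresholds - prom$values[i]))]
    expect_true(prom$values[i] > t && prom$values[i] <= t + cfg$landing_window)
    expect_true(pre[i] > t - cfg$promotion_window && pre[i] <= t)
  }
})

test_that("rendered styles carry correct ground-truth eligibility", {
  set.seed(6)
  r1 <- render_abstract("1", 0.5, "exactly_one")
  expect_false(r1$truth$should_be_extracted)

  r2 <- render_abstract("2", 0.73, "one_decimal")
  expect_true(r2$truth$should_be_extracted)
  expect_false(r2$truth$should_enter_histogram)

  r3 <- render_abstract("3", 0.731, "point_with_ci")
  expect_equal(r3$truth$role, c("point", "ci_lower", "ci_upper"))
  expect_true(all(r3$truth$should_be_extracted))
  expect_equal(sum(r3$truth$should_enter_histogram), 1)

  r4 <- render_abstract("4", numeric(0), character(0),
                        decoy = "pharmacokinetic")
  expect_null(r4$truth)

  # the rendered sentences are recovered by the extractor
  m <- extract_values(r3$record)
  expect_equal(sort(m$value), sort(r3$truth$rendered_value))
})

test_that("corpus generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_abstracts = 50L, promotion_prob = 0.2, seed = 77L)
  p1 <- tempfile(fileext = ".xml")
  p2 <- tempfile(fileext = ".xml")
  generate_corpus(cfg, xml_path = p1)
  generate_corpus(cfg, xml_path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an all-decoy corpus yields zero extracted values", {
  cfg <- synthetic_config(n_abstracts = 60L, decoy_rate = 1, short_rate = 0,
                          seed = 13L)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$truth), 0)
  dec <- lapply(corp$records, apply_exclusions)
  inc <- corp$records[vapply(dec, function(d) d$status == "included",
                             logical(1))]
  m <- extract_corpus(inc)
  expect_equal(nrow(m), 0)
})

test_that("extraction recovers planted values exactly on a small corpus", {
  cfg <- synthetic_config(n_abstracts = 300L, promotion_prob = 0.1,
                          seed = 101L)
  corp <- generate_corpus(cfg)
  dec <- lapply(corp$records, apply_exclusions)
  inc <- corp$records[vapply(dec, function(d) d$status == "included",
                             logical(1))]
  m <- extract_corpus(inc)
  f <- fidelity(corp, m, vapply(inc, `[[`, character(1), "pmid"))
  expect_gte(f$recall, 0.99)
  expect_gte(f$precision, 0.95)
})
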