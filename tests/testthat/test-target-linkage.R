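# Signal levels, one-tailed correlation tests, multiple-testing adjustment
# and association calling.

test_that("signal levels follow their definitions", {
  expect_equal(activity_level(500, 1e6), 500)
  expect_equal(activity_level(0, 1e6), 0)
  expect_equal(activity_level(250, 5e6), 50)
  expect_equal(methylation_level(cbind(m = c(2, 3), n = c(4, 6))), 0.5)
  expect_equal(methylation_level(cbind(m = 0, n = 10)), 0)
  expect_equal(methylation_level(cbind(m = c(4, 0), n = c(4, 6))), 0.4)
  expect_true(is.na(methylation_level(cbind(m = c(0, 0), n = c(0, 0)))))
  # invariant under CpG reordering, bounded in [0, 1]
  set.seed(3)
  n <- 5 + stats::rpois(10, 20)
  m <- stats::rbinom(10, n, 0.3)
  lvl <- methylation_level(cbind(m, n))
  expect_equal(methylation_level(cbind(m, n)[sample(10), ]), lvl)
  expect_true(lvl >= 0 && lvl <= 1)
  expect_equal(expression_level(100, 1e6), 100)
  expect_equal(expression_level(c(100, 300), c(1e6, 1e6)), 200)
  expect_equal(expression_level(c(100, 100), c(1e6, 2e6)), 75)
})

test_that("candidate targets use a closed 1 Mb boundary to the element edge", {
  el <- list(chrom = "chr1", start = 2e6, end = 2e6 + 1000)
  tss <- data.frame(
    id = c("near", "far", "edge", "inside", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(2e6 - 5e5, 2e6 - 1.5e6, 2e6 - 1e6, 2e6 + 500, 2e6),
    stringsAsFactors = FALSE
  )
  got <- candidate_targets(el, tss)
  expect_setequal(got, c("near", "edge", "inside"))
})

test_that("Pearson one-tailed p-values match the t closed form", {
  set.seed(11)
  for (n in c(5, 10, 20)) {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    ct <- correlation_test(x, y, "pearson", "right")
    r <- stats::cor(x, y)
    expect_equal(ct$r, r)
    expect_equal(ct$p, stats::pt(r * sqrt((n - 2) / (1 - r^2)), n - 2, lower.tail = FALSE),
      tolerance = 1e-12
    )
    # mirrored tails of the continuous t sum to 1
    left <- correlation_test(x, y, "pearson", "left")
    expect_equal(ct$p + left$p, 1, tolerance = 1e-12)
  }
  # an exactly zero correlation sits at p = 0.5
  x <- c(1, 2, 3, 4)
  y <- c(1, -1, -1, 1)
  expect_equal(correlation_test(x, y, "pearson", "right")$p, 0.5)
  # perfect concordance: p effectively 0
  expect_lt(correlation_test(1:6, (1:6) * 2, "pearson", "right")$p, 1e-10)
  # degenerate zero-variance input
  d <- correlation_test(rep(1, 5), stats::rnorm(5), "pearson", "right")
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
})

test_that("exact Spearman p-values equal permutation enumeration", {
  # perfect concordance at n = 5: exactly one of 5! orderings
  ct <- correlation_test(1:5, c(10, 20, 30, 40, 50), "spearman", "right")
  expect_true(ct$exact)
  expect_equal(ct$p, 1 / 120)
  # cross-check against the reference implementation on random data
  set.seed(4)
  for (rep in 1:5) {
    x <- stats::rnorm(6)
    y <- stats::rnorm(6)
    ours <- correlation_test(x, y, "spearman", "right")
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman", alternative = "greater"))
    expect_equal(ours$r, unname(ref$estimate))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # large n falls back to the t approximation
  big <- correlation_test(stats::rnorm(20), stats::rnorm(20), "spearman", "right")
  expect_false(big$exact)
})

test_that("Fisher-Z option approximates the t-based p-value", {
  set.seed(5)
  x <- stats::rnorm(30)
  y <- x + stats::rnorm(30)
  p_t <- correlation_test(x, y, "pearson", "right")$p
  p_z <- correlation_test(x, y, "pearson", "right", use_fisher_z = TRUE)$p
  expect_equal(log10(p_z), log10(p_t), tolerance = 0.2)
})

test_that("p-value adjustment reproduces hand-computed step procedures", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01) # single p unchanged
  expect_equal(adjust_pvalues(rep(0.01, 10), "bonferroni"), rep(0.1, 10))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.04, 0.3)
  # Holm step-down by hand: p_(i) * (m - i + 1), cumulative max
  expect_equal(adjust_pvalues(p, "holm"), cummax(p * c(4, 3, 2, 1)))
  # BY adds the harmonic-sum factor to BH
  cm <- sum(1 / (1:4))
  bh <- rev(cummin(rev(p * 4 / (1:4))))
  expect_equal(adjust_pvalues(p, "by"), pmin(bh * cm, 1))
  # elementwise ordering: bonferroni >= holm >= raw
  set.seed(6)
  q <- stats::runif(25)
  expect_true(all(adjust_pvalues(q, "bonferroni") >= adjust_pvalues(q, "holm") - 1e-12))
  expect_true(all(adjust_pvalues(q, "holm") >= q - 1e-12))
})

test_that("association calling recovers planted pairs with the right tails", {
  panel <- make_tissue_panel(fixture_spec(seed = 19))
  assoc <- call_associations(panel$panel, alpha = 0.05, adjust_method = "bh")
  truth <- panel$truth
  sig <- assoc[assoc$significant, ]
  # planted activity pairs: tracked expression, right tail
  act <- truth[truth$type == "activity", ]
  recalled <- mapply(function(el, tss) {
    any(sig$element == el & sig$tss == tss)
  }, act$element, act$tss)
  expect_gte(mean(recalled), 0.9)
  # planted methylation pairs recovered through the left tail only
  met <- truth[truth$type == "methylation", ]
  met_hits <- sig[sig$element %in% met$element &
    mapply(function(e, t) any(met$element == e & met$tss == t), sig$element, sig$tss), ]
  expect_gt(nrow(met_hits), 0)
  expect_true(all(met_hits$tail == "left"))
  expect_true(all(met_hits$signal == "methylation"))
  expect_true(all(met_hits$r < 0))
})
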