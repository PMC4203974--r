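# PWM scoring, exact tail p-values, and motif break/gain detection.

test_that("log-likelihood transform matches its closed form", {
  uni <- to_log_likelihood(
    list(name = "u", freqs = matrix(0.25, 2, 4)),
    pseudocount = 0.01
  )
  expect_equal(unname(uni$mat), matrix(0, 2, 4)) # uniform over uniform bg
  sharp <- to_log_likelihood(
    list(name = "s", freqs = matrix(c(1, 0, 0, 0), 1, 4)),
    pseudocount = 1e-9
  )
  expect_equal(unname(sharp$mat[1, "A"]), 2, tolerance = 1e-6) # log2(4) in the pc -> 0 limit
  # hand arithmetic: f = (.97,.01,.01,.01), pc = .01, uniform background
  m <- to_log_likelihood(
    list(name = "h", freqs = matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4)),
    pseudocount = 0.01
  )
  expect_equal(unname(m$mat[1, "A"]), log2((0.97 + 0.0025) / (1.01 * 0.25)), tolerance = 1e-12)
  expect_equal(unname(m$mat[1, "C"]), log2((0.01 + 0.0025) / (1.01 * 0.25)), tolerance = 1e-12)
})

test_that("sequence scores sum matrix entries and respect strand", {
  zero <- to_log_likelihood(list(name = "z", freqs = matrix(0.25, 3, 4)))
  expect_equal(sequence_score(zero, "ACG"), 0)
  ac <- to_log_likelihood(
    list(name = "ac", freqs = rbind(c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.97, 0.01, 0.01))),
    pseudocount = 0.01
  )
  expect_equal(
    sequence_score(ac, "AC", "+"),
    2 * log2((0.97 + 0.0025) / (1.01 * 0.25))
  )
  # reverse-complement symmetry: GT on minus equals AC on plus
  expect_equal(sequence_score(ac, "GT", "-"), sequence_score(ac, "AC", "+"))
  expect_true(is.na(sequence_score(ac, "AN", "+")))
})

test_that("tail p-value handles the closed-form cases", {
  m <- to_log_likelihood(
    list(name = "one", freqs = matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4)),
    pseudocount = 0.01
  )
  smax <- max(m$mat)
  expect_equal(score_pvalue(m, smax), 0.25) # only A attains the maximum
  expect_equal(score_pvalue(m, -Inf), 1)
  expect_equal(score_pvalue(m, smax + 10), 0)
})

test_that("tail p-value is monotone and within the discretization bound of enumeration", {
  set.seed(401)
  g <- 1e-3
  for (rep in 1:8) {
    L <- sample(3:5, 1)
    bg <- if (rep %% 2 == 0) rep(0.25, 4) else {
      b <- stats::rgamma(4, 4)
      b / sum(b)
    }
    m <- random_llm(L, background = bg)
    sc <- sort(brute_force_scores(m))
    for (q in c(0.1, 0.5, 0.9)) {
      s <- stats::quantile(sc, q, names = FALSE)
      p_dp <- score_pvalue(m, s, granularity = g)
      expect_gte(p_dp, brute_force_pvalue(m, s) - 1e-9)
      expect_lte(p_dp, brute_force_pvalue(m, s - L * g) + 1e-9)
    }
    # monotone non-increasing in s
    grid <- seq(min(sc), max(sc), length.out = 25)
    ps <- vapply(grid, function(s) score_pvalue(m, s, g), numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("motif-breaking deltas follow the matrix and strand", {
  m <- to_log_likelihood(
    list(name = "b", freqs = rbind(
      c(0.97, 0.01, 0.01, 0.01),
      c(0.01, 0.97, 0.01, 0.01),
      c(0.25, 0.25, 0.25, 0.25)
    )),
    pseudocount = 1e-12
  )
  hit <- list(chrom = "chr1", start = 100L, end = 103L, strand = "+")
  v <- variant_table("chr1", 100, "A", "C") # consensus -> rare at position 1
  br <- motif_break_score(v, hit, m)
  expect_equal(br$break_score, log2(0.97 / 0.01), tolerance = 1e-6)
  # equal-frequency change is conserving
  v2 <- variant_table("chr1", 102, "A", "G")
  expect_null(motif_break_score(v2, hit, m))
  # rare -> consensus improves the match: conserving
  v3 <- variant_table("chr1", 100, "C", "A")
  expect_null(motif_break_score(v3, hit, m))
  # strand consistency: complementary variant on the minus-strand hit
  hit_minus <- list(chrom = "chr1", start = 100L, end = 103L, strand = "-")
  v4 <- variant_table("chr1", 102, "T", "G") # complements A -> C at motif pos 1
  br4 <- motif_break_score(v4, hit_minus, m)
  expect_equal(br4$break_score, br$break_score)
  expect_error(motif_break_score(variant_table("chr1", 500, "A", "C"), hit, m), "overlap")
})

test_that("indel breaks report the maximum per-position score range", {
  m <- to_log_likelihood(
    list(name = "b", freqs = rbind(
      c(0.97, 0.01, 0.01, 0.01),
      c(0.25, 0.25, 0.25, 0.25)
    )),
    pseudocount = 1e-12
  )
  hit <- list(chrom = "chr1", start = 100L, end = 102L, strand = "+")
  v <- variant_table("chr1", 100, "AT", "") # deletion across both positions
  br <- motif_break_score(v, hit, m)
  expect_equal(br$kind, "indel")
  expect_equal(br$break_score, log2(0.97 / 0.01), tolerance = 1e-6)
})

test_that("gain scan detects the planted consensus-completing variant", {
  fx <- shared_fixture()
  g <- fx$truth$gain
  v <- variant_table(g$chrom, g$pos, g$ref, g$alt, "s")
  ev <- gain_scan(v, fx$ctx$genome_str, fx$ctx$llms)
  expect_gte(nrow(ev), 1)
  best <- ev[which.max(ev$gain_score), ]
  expect_equal(best$motif, g$motif)
  expect_lte(best$p_mutant, 4e-8)
  expect_gt(best$p_germline, 4e-8)
  expect_gt(best$score_mutant, best$score_germline)
  expect_equal(best$win_start, g$win_start)
  # an alt scoring no better than ref yields no event
  alt2 <- setdiff(c("A", "C", "G", "T"), c(g$ref, g$alt))[1]
  v_flat <- variant_table(g$chrom, g$pos, g$ref, alt2, "s")
  ev_flat <- gain_scan(v_flat, fx$ctx$genome_str, fx$ctx$llms)
  expect_equal(nrow(ev_flat[ev_flat$motif == g$motif, ]), 0)
  # a genome/allele disagreement is refused
  v_rev <- variant_table(g$chrom, g$pos, g$alt, g$ref, "s")
  expect_error(gain_scan(v_rev, fx$ctx$genome_str, fx$ctx$llms), "mismatch")
})

test_that("no re-gaining: windows already significant in germline emit nothing", {
  fx <- shared_fixture()
  site <- fx$truth$motif_sites[fx$truth$motif_sites$strand == "+", ][1, ]
  cons <- fx$truth$consensi[[site$motif]]
  # any SNV inside an exact consensus occurrence: germline p is already
  # below threshold, so no gain can be called for that motif
  pos <- site$start + 4L
  ref <- substr(cons, 5L, 5L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- variant_table(site$chrom, pos, ref, alt, "s")
  ev <- gain_scan(v, fx$ctx$genome_str, fx$ctx$llms)
  expect_equal(sum(ev$motif == site$motif), 0)
})

test_that("genome scanning recovers exactly the planted motif occurrences", {
  fx <- shared_fixture()
  mh <- fx$ctx$tracks$motif_hits
  planted <- fx$truth$motif_sites
  expect_equal(length(mh), nrow(planted))
  key <- function(chrom, start, motif, strand) paste(chrom, start, motif, strand)
  expect_setequal(
    key(
      as.character(GenomicRanges::seqnames(mh)), GenomicRanges::start(mh) - 1L,
      mh$name, as.character(GenomicRanges::strand(mh))
    ),
    key(planted$chrom, planted$start, planted$motif, planted$strand)
  )
})
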