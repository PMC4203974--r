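# Context assembly, interval queries, DRM definition and the recurrence DB.

test_that("the context loads every configured resource", {
  fx <- shared_fixture()
  ctx <- fx$ctx
  expect_s3_class(ctx, "data_context")
  expect_setequal(
    names(ctx$tracks),
    c("tfp", "dhs", "enhancer", "hot", "sensitive", "ultra_sensitive", "ultra_conserved", "motif_hits")
  )
  expect_equal(length(ctx$genome), 2)
  expect_named(ctx$networks, c("ppi", "regulatory"))
  expect_true(all(c("cancer_driver", "dna_repair", "actionable", "under_selection") %in%
    names(ctx$gene_lists)))
  expect_gt(nrow(ctx$recurrence_db), 0)
  expect_gt(nrow(ctx$polymorphisms), 0)
})

test_that("missing mandatory keys are reported by name; optional keys default", {
  fx <- shared_fixture()
  cfg <- regvar:::read_context_config(fx$config)
  broken <- cfg[setdiff(names(cfg), "track.dhs")]
  expect_error(build_context(broken), "track.dhs")
  no_db <- cfg[setdiff(names(cfg), "recurrence_db")]
  ctx2 <- build_context(no_db)
  expect_equal(nrow(ctx2$recurrence_db), 0)
})

test_that("point queries against tracks agree with a naive scan", {
  fx <- shared_fixture()
  gr <- fx$ctx$tracks$dhs
  starts <- GenomicRanges::start(gr) - 1L
  ends <- GenomicRanges::end(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  set.seed(9)
  pts_pos <- c(starts[1], ends[3] - 1L, sample(0:199999, 300))
  pts_chrom <- c(chroms[1], chroms[3], sample(c("chr1", "chr2"), 300, replace = TRUE))
  q <- GenomicRanges::GRanges(pts_chrom, IRanges::IRanges(pts_pos + 1L, width = 1L))
  fast <- IRanges::overlapsAny(q, gr)
  naive <- vapply(seq_along(pts_pos), function(i) {
    any(chroms == pts_chrom[i] & starts <= pts_pos[i] & pts_pos[i] < ends)
  }, logical(1))
  expect_equal(fast, naive)
})

test_that("DRM definition enforces the gene-distance threshold and is monotone", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 3, panel_size = 200L)
  res <- make_context(spec, dir)
  ctx <- build_context(res$config)
  drms <- define_drms(ctx)
  regs <- c(ctx$tracks$tfp, ctx$tracks$dhs, ctx$tracks$enhancer)
  d <- GenomicRanges::distanceToNearest(regs, ctx$gene_bodies, ignore.strand = TRUE)
  dist <- rep(Inf, length(regs))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  # exactly the far-enough regions survive
  expect_equal(length(drms), sum(dist >= 1000))
  # monotone: a larger threshold yields a subset
  larger <- define_drms(ctx, min_distance = 50000)
  expect_true(all(names(larger) %in% names(drms)))
  expect_lte(length(larger), length(drms))
})

test_that("DRM distance semantics: overlap and near genes excluded, far included", {
  # one gene body at [5000, 8000); regions at distance 0, 500 and 5000
  dir <- withr::local_tempdir()
  gm <- data.frame(
    gene_id = "g1", chrom = "chrA", strand = "+", txstart = 5000L, txend = 8000L,
    tss = 5000L, cds_starts = "", cds_ends = "", stringsAsFactors = FALSE
  )
  ctx <- list(
    gene_models = gm,
    gene_bodies = regvar:::gene_body_granges(gm),
    tracks = list(
      tfp = GenomicRanges::GRanges(
        "chrA",
        IRanges::IRanges(c(6001, 8501, 13001), width = 100),
        name = c("overlap", "near", "far")
      ),
      dhs = GenomicRanges::GRanges(), enhancer = GenomicRanges::GRanges()
    )
  )
  names(ctx$tracks$tfp) <- ctx$tracks$tfp$name
  drms <- define_drms(ctx)
  expect_equal(names(drms), "far")
})

test_that("recurrence entries count distinct samples only", {
  fx <- shared_fixture()
  v <- variant_table(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1"),
    pos = c(500, 500, 500, 140100, 140250, 90000),
    ref = c("A", "A", "A", "C", "G", "T"),
    alt = c("G", "G", "G", "T", "A", "C"),
    sample_id = c("s1", "s2", "s2", "s1", "s2", "s1")
  )
  db <- build_recurrence_db(list(Liver = v), fx$ctx)
  site <- db[db$kind == "site", ]
  # same site in s1+s2 counts 2; the duplicate within s2 does not inflate it
  expect_equal(nrow(site), 1)
  expect_equal(site$n_samples, 2)
  expect_equal(site$key, "chr1:500:G")
  # one DHS tile overlapped at different positions by two samples
  el <- db[db$kind == "element", ]
  expect_true(any(el$n_samples == 2))
  # a site seen twice in the same sample yields no entry
  v2 <- variant_table("chr2", c(100, 100), "A", "G", c("sX", "sX"))
  db2 <- build_recurrence_db(list(T2 = v2), fx$ctx)
  expect_equal(nrow(db2[db2$kind == "site", ]), 0)
})

test_that("sample aliasing collapses duplicate ids before counting", {
  fx <- shared_fixture()
  v <- variant_table("chr1", c(700, 700), "A", "G", c("study1_s1", "study2_s1"))
  db_plain <- build_recurrence_db(list(X = v), fx$ctx)
  expect_equal(db_plain$n_samples[db_plain$kind == "site"], 2)
  alias <- c(study1_s1 = "s1", study2_s1 = "s1")
  db_alias <- build_recurrence_db(list(X = v), fx$ctx, sample_alias = alias)
  expect_equal(nrow(db_alias[db_alias$kind == "site", ]), 0)
})
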