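# Feature extraction, scoring semantics, the coding tally, recurrence flags
# and the ranked pipeline.

# a small hand-built weight model for semantics tests
toy_model <- function() {
  feats <- default_feature_config()
  disc <- setdiff(feats$discrete, "gerp_gt2")
  w <- stats::setNames(rep(0.3, length(disc)), disc)
  w["in_functional_annotation"] <- 0.2
  w["in_sensitive"] <- 0.5
  w["recurrent"] <- 0.7
  structure(
    list(
      discrete = data.frame(
        feature = disc, p = 0.1, w = unname(w),
        low_confidence = FALSE, stringsAsFactors = FALSE
      ),
      curves = list(),
      gerp = list(p = 0.05, w_d = 0.6, k = 10, midpoint = 2),
      tree = feats$tree,
      features = list(
        discrete = feats$discrete, continuous = character(),
        tree = feats$tree, gerp = feats$gerp
      ),
      meta = list()
    ),
    class = "weight_model"
  )
}

fv_with <- function(...) {
  flags <- list(...)
  base <- as.list(stats::setNames(
    rep(FALSE, length(default_feature_config()$discrete)),
    default_feature_config()$discrete
  ))
  base$gerp <- NA_real_
  base[names(flags)] <- flags
  base
}

test_that("MAF filtering is allele-aware and threshold-driven", {
  poly <- variant_table("chr1", c(10, 20, 30), c("A", "C", "G"), c("G", "T", "A"))
  poly$af <- c(0.02, 0.001, 0.2)
  v <- variant_table("chr1", c(10, 20, 30, 40), c("A", "C", "G", "T"), c("G", "T", "C", "A"))
  expect_message(kept <- maf_filter(v, poly, threshold = 0.01), "removed 1")
  # AF 0.02 >= 0.01 removed; AF 0.001 kept; different alt at pos 30 kept
  expect_equal(kept$pos, c(20, 30, 40))
  expect_equal(attr(kept, "n_removed"), 1L)
  all_matches <- maf_filter(v, poly, threshold = 0)
  expect_equal(all_matches$pos, c(30, 40)) # pos 30 has a different alt allele
})

test_that("parent features are suppressed when children are observed", {
  m <- toy_model()
  s1 <- noncoding_score(fv_with(in_functional_annotation = TRUE), m)
  expect_equal(s1$core, 0.2)
  s2 <- noncoding_score(fv_with(in_functional_annotation = TRUE, in_sensitive = TRUE), m)
  expect_equal(s2$core, 0.5) # the root's 0.2 is not summed
  expect_false("in_functional_annotation" %in% names(s2$contributions))
  s3 <- noncoding_score(fv_with(), m)
  expect_equal(s3$core, 0)
  # ultra-sensitive suppresses sensitive in turn
  s4 <- noncoding_score(
    fv_with(
      in_functional_annotation = TRUE, in_sensitive = TRUE,
      in_ultra_sensitive = TRUE
    ), m
  )
  expect_equal(s4$core, 0.3) # only the deepest leaf
})

test_that("recurrence contributes to the final score only", {
  m <- toy_model()
  s <- noncoding_score(fv_with(in_dhs = TRUE, recurrent = TRUE), m)
  expect_equal(s$core, 0.3)
  expect_equal(s$final, 0.3 + 0.7)
  expect_gte(s$final, s$core)
})

test_that("adding a non-parent feature never lowers the core score", {
  m <- toy_model()
  base_flags <- list(in_dhs = TRUE)
  s0 <- noncoding_score(do.call(fv_with, base_flags), m)
  for (extra in c("in_hot", "in_ultra_conserved", "has_target_gene", "target_is_cancer_gene")) {
    flags <- base_flags
    flags[[extra]] <- TRUE
    s1 <- noncoding_score(do.call(fv_with, flags), m)
    expect_gte(s1$core, s0$core)
  }
})

test_that("an observed feature missing from the model is a named scoring error", {
  m <- toy_model()
  m$features$continuous <- "motif_gain_score"
  fv <- fv_with()
  fv$motif_gain_score <- 3.2
  expect_error(noncoding_score(fv, m), "motif_gain_score")
})

test_that("coding consequences are translated codon by codon", {
  ctx <- codon_context()
  # TAC (Tyr) -> TAA (stop): premature stop
  stop_gain <- coding_consequence(variant_table("chrT", 12, "C", "A"), ctx)
  expect_equal(stop_gain$consequence, "premature_stop")
  expect_equal(stop_gain$gene, "gT")
  # GAA (Glu) -> GAC (Asp): nonsynonymous
  nonsyn <- coding_consequence(variant_table("chrT", 15, "A", "C"), ctx)
  expect_equal(nonsyn$consequence, "nonsynonymous")
  # CTA (Leu) -> CTG (Leu): synonymous
  syn <- coding_consequence(variant_table("chrT", 18, "A", "G"), ctx)
  expect_equal(syn$consequence, "synonymous")
  # indels in CDS are 'other', flagged by frame
  fs <- coding_consequence(variant_table("chrT", 12, "CG", ""), ctx)
  expect_equal(fs$consequence, "other")
  expect_equal(fs$detail, "frameshift")
})

test_that("minus-strand CDS translation complements and reverses", {
  # chrM carries the reverse complement of TACGAACTA, so the minus-strand
  # transcript reads Tyr-Glu-Leu again
  seq <- paste0(strrep("A", 10), "TAGTTCGTA", strrep("G", 10))
  gm <- data.frame(
    gene_id = "gM", chrom = "chrM", strand = "-", txstart = 5L, txend = 25L,
    tss = 24L, cds_starts = "10", cds_ends = "19", stringsAsFactors = FALSE
  )
  cds <- GenomicRanges::GRanges("chrM", IRanges::IRanges(11, 19), strand = "-")
  cds$gene_id <- "gM"
  ctx <- structure(
    list(genome_str = c(chrM = seq), gene_models = gm, cds = cds),
    class = "data_context"
  )
  # genomic G->T at 0-based 16 hits codon TAC -> TAA on the transcript
  got <- coding_consequence(variant_table("chrM", 16, "G", "T"), ctx)
  expect_equal(got$consequence, "premature_stop")
})

test_that("the coding tally awards one point per criterion", {
  expect_equal(coding_score("premature_stop", TRUE, TRUE, TRUE, gerp = 3), 5L)
  expect_equal(coding_score("synonymous", FALSE, FALSE, FALSE, gerp = 1), 0L)
  expect_equal(coding_score("nonsynonymous"), 1L)
  # stop gain counts once, never also as nonsynonymous
  expect_equal(coding_score("premature_stop"), 1L)
  expect_equal(coding_score("nonsynonymous", gerp = NA), 1L)
})

test_that("within-cohort recurrence needs two distinct samples", {
  fx <- shared_fixture()
  v <- variant_table("chr2", c(171234, 171234, 180001), c("A", "A", "C"), c("G", "G", "T"),
    sample_id = c("s1", "s2", "s3")
  )
  rec <- detect_recurrence(v, fx$ctx)
  expect_true(all(rec$recurrent[1:2]))
  expect_false(rec$recurrent[3])
  # a single sample with the database disabled can never be recurrent
  single <- v[1, , drop = FALSE]
  rec1 <- detect_recurrence(single, fx$ctx, use_db = FALSE)
  expect_false(any(rec1$recurrent))
})

test_that("recurrence database matches report per-cancer-type counts", {
  fx <- shared_fixture()
  g <- fx$truth$gain
  v <- variant_table(g$chrom, g$pos, g$ref, g$alt, "only_sample")
  rec <- detect_recurrence(v, fx$ctx, use_db = TRUE)
  expect_true(rec$recurrent[1])
  expect_match(rec$db_match[1], "5/88 Liver samples")
  expect_match(rec$db_match[1], "54/570 COSMIC samples")
  rec_off <- detect_recurrence(v, fx$ctx, use_db = FALSE)
  expect_false(rec_off$recurrent[1])
})

test_that("feature extraction flags the archetypal promoter driver", {
  fx <- shared_fixture()
  g <- fx$truth$gain
  fv <- extract_features(variant_table(g$chrom, g$pos, g$ref, g$alt, "s"), fx$ctx)
  expect_true(fv$in_dhs && fv$in_enhancer && fv$in_tfp && fv$in_functional_annotation)
  expect_true(fv$has_target_gene && fv$target_is_cancer_gene)
  expect_match(fv$target_genes, fx$truth$hub_gene)
  expect_match(fv$gene_highlights, "cancer_driver")
  expect_equal(fv$network_centrality, 1.0)
  expect_false(is.na(fv$motif_gain_score))
  expect_match(fv$motif_gain, g$motif)
  # a variant outside every annotation has an empty feature vector
  bare <- extract_features(variant_table("chr1", 198000, "A", "C", "s"), fx$ctx)
  flags <- unlist(bare[c(
    "in_tfp", "in_dhs", "in_enhancer", "in_hot", "in_sensitive",
    "in_ultra_sensitive", "in_ultra_conserved", "in_functional_annotation",
    "has_target_gene", "target_is_cancer_gene"
  )])
  expect_false(any(flags))
  expect_equal(bare$annotations, "")
})

test_that("pipeline output is deterministic and decomposes exactly", {
  fx <- shared_fixture()
  pr <- shared_pipeline()
  # determinism: identical rerun
  pr2 <- run_pipeline(fx$cohort$variants, fx$ctx, fx$model)
  expect_identical(pr$noncoding, pr2$noncoding)
  expect_identical(pr$coding, pr2$coding)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_report(pr$noncoding, f1, fmt = "bed")
  write_report(pr2$noncoding, f2, fmt = "bed")
  expect_identical(readLines(f1), readLines(f2))
  # ranking is by descending final score with coordinate tie-breaks
  expect_true(all(diff(pr$noncoding$score) <= 1e-12))
  # per-variant contributions sum exactly to the reported score
  fm <- extract_feature_matrix(fx$cohort$variants, fx$ctx)
  rec <- detect_recurrence(fx$cohort$variants, fx$ctx)
  fm$recurrent <- rec$recurrent
  for (i in sample(seq_len(nrow(fm)), 40)) {
    sc <- noncoding_score(lapply(fm, `[[`, i), fx$model)
    expect_equal(sum(sc$contributions), sc$final, tolerance = 1e-9)
  }
})

test_that("scores match an independent straight-line reimplementation", {
  fx <- shared_fixture()
  model <- fx$model
  v <- fx$cohort$variants[seq_len(50), ]
  fm <- extract_feature_matrix(v, fx$ctx)
  rec <- detect_recurrence(v, fx$ctx)
  fm$recurrent <- rec$recurrent
  got <- predict(model, fm)
  w <- stats::setNames(model$discrete$w, model$discrete$feature)
  tree <- model$tree
  for (i in seq_len(nrow(fm))) {
    # observed feature set, written out longhand
    obs <- character()
    for (f in model$discrete$feature) if (isTRUE(fm[[f]][i])) obs <- c(obs, f)
    for (f in names(model$curves)) if (!is.na(fm[[f]][i])) obs <- c(obs, f)
    total <- 0
    for (f in obs) {
      kids <- tree[[f]]
      if (!is.null(kids) && any(kids %in% obs)) next # parent suppressed
      total <- total + if (f %in% names(model$curves)) {
        predict(model$curves[[f]], fm[[f]][i])
      } else {
        w[[f]]
      }
    }
    if (!is.na(fm$gerp[i])) {
      total <- total + model$gerp$w_d / (1 + exp(-model$gerp$k * (fm$gerp[i] - model$gerp$midpoint)))
    }
    expect_equal(got$final_score[i], total, tolerance = 1e-9)
  }
})

test_that("core scores are invariant to recurrence settings", {
  fx <- shared_fixture()
  pr_off <- shared_pipeline()
  pr_on <- run_pipeline(fx$cohort$variants, fx$ctx, fx$model, use_recurrence_db = TRUE)
  key <- function(df) paste(df$chrom, df$pos, df$alt)
  m <- match(key(pr_off$noncoding), key(pr_on$noncoding))
  expect_equal(pr_off$noncoding$core_score, pr_on$noncoding$core_score[m])
  # the flagged driver gains an additional recurrence score on top of core
  g <- fx$truth$gain
  row_on <- pr_on$noncoding[pr_on$noncoding$pos == g$pos & pr_on$noncoding$chrom == g$chrom, ]
  expect_gte(row_on$score, row_on$core_score)
})

test_that("empty input produces an empty, well-formed report", {
  fx <- shared_fixture()
  pr <- run_pipeline(fx$cohort$variants[0, ], fx$ctx, fx$model)
  expect_equal(nrow(pr$noncoding), 0)
  expect_equal(nrow(pr$coding), 0)
  path <- withr::local_tempfile()
  write_report(pr$noncoding, path, fmt = "bed")
  expect_length(readLines(path), 1)
})
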