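# Shared toy fixtures (built once per test run) and independent oracles.

fixture_env <- new.env()

shared_fixture <- function() {
  if (is.null(fixture_env$ctx)) {
    dir <- file.path(tempdir(), "regvar-shared-ctx")
    spec <- fixture_spec(seed = 42)
    res <- make_context(spec, dir)
    ctx <- build_context(res$config)
    cohort <- make_cohort(spec, ctx, res$truth)
    model <- train_weights(ctx$polymorphisms, ctx, sample_fraction = 1, seed = 11)
    fixture_env$spec <- spec
    fixture_env$truth <- res$truth
    fixture_env$config <- res$config
    fixture_env$ctx <- ctx
    fixture_env$cohort <- cohort
    fixture_env$model <- model
  }
  as.list(fixture_env)
}

shared_pipeline <- function() {
  if (is.null(fixture_env$pr)) {
    fx <- shared_fixture()
    fixture_env$pr <- run_pipeline(fx$cohort$variants, fx$ctx, fx$model)
  }
  fixture_env$pr
}

# Exhaustive enumeration over all 4^L background sequences: the independent
# oracle for the DP tail p-value.
brute_force_pvalue <- function(m, s) {
  L <- nrow(m$mat)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(L)) {
    scores <- scores + unname(m$mat[j, ])[grid[, j]]
    probs <- probs * m$background[grid[, j]]
  }
  sum(probs[scores >= s])
}

brute_force_scores <- function(m) {
  L <- nrow(m$mat)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  for (j in seq_len(L)) scores <- scores + unname(m$mat[j, ])[grid[, j]]
  scores
}

random_llm <- function(L, background = rep(0.25, 4)) {
  f <- matrix(stats::rgamma(L * 4, shape = 0.6), L, 4)
  f <- f / rowSums(f)
  colnames(f) <- c("A", "C", "G", "T")
  to_log_likelihood(list(name = "random", freqs = f), background = background)
}

# tiny hand-built data context for codon-level tests
codon_context <- function() {
  # chrT: CDS 9 bp starting at 0-based 10 encoding Tyr-Glu-Leu (TAC GAA CTA)
  seq <- paste0(strrep("A", 10), "TACGAACTA", strrep("G", 10))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chrT"
  gm <- data.frame(
    gene_id = "gT", chrom = "chrT", strand = "+", txstart = 5L, txend = 25L,
    tss = 5L, cds_starts = "10", cds_ends = "19", stringsAsFactors = FALSE
  )
  cds <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 19), strand = "+")
  cds$gene_id <- "gT"
  structure(
    list(
      genome = genome, genome_str = c(chrT = seq), gene_models = gm, cds = cds,
      tracks = list(), networks = list(), gene_lists = list(),
      recurrence_db = data.frame()
    ),
    class = "data_context"
  )
}
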