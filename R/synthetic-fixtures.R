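# Deterministic toy data contexts, cohorts and tissue panels with planted,
# known structure, so every pipeline stage is testable offline. All
# generators are pure functions of (spec, seed).
#
# The toy genome reserves disjoint zones per annotation so that the
# polymorphism panel can plant each feature at an exact configured rate
# (trained weights then have closed-form expectations), and plants motif
# consensus occurrences so the motif-hit track contains true matches found
# by scanning the generated genome.

#' Fixture specification
#'
#' Defaults define the toy study conditions: a 2 x 200 kb genome, 12 genes
#' (one a network hub and known cancer gene), sharp 14-bp PWMs, a
#' polymorphism panel planting the enhancer/DHS/sensitive features at rates
#' 0.5 / 0.1 / 0.01, a 3-sample cohort with one planted gain-of-motif
#' driver variant, one motif-breaking variant and one recurrent site, and a
#' 20-tissue panel with planted element-gene correlations of 0.9.
#'
#' @param seed master seed; every derived generator offsets it
#'   deterministically.
#' @param ... overrides for any default field.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, ...) {
  spec <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 200000L, chr2 = 200000L),
    n_genes_per_chrom = 6L,
    pwm_length = 14L,
    pwm_sharpness = 0.97,
    n_pwms = 3L,
    panel_size = 5000L,
    panel_rates = c(
      enhancer = 0.5, dhs = 0.1, tfp = 0.05, hot = 0.03,
      sens_only = 0.008, ultra_sensitive = 0.002, ultra_conserved = 0.005,
      gerp = 0.05
    ),
    maf_max = 0.5,
    n_samples = 3L,
    n_background_variants = 2200L,
    n_null_promoter = 30L,
    recurrent_site_samples = 2L,
    n_tissues = 20L,
    n_activity_pairs = 20L,
    n_methylation_pairs = 10L,
    n_null_pairs = 20L,
    target_r = 0.9
  )
  over <- list(...)
  spec[names(over)] <- over
  structure(spec, class = "fixture_spec")
}

# fixed zone layout, identical on every chromosome (0-based half-open)
.fixture_zones <- function() {
  list(
    enhancer = c(100000L, 140000L),
    dhs = c(140000L, 148000L),
    tfp = c(148000L, 152000L),
    hot = c(152000L, 155000L),
    sens_only = c(155000L, 155800L),
    ultra_sensitive = c(155800L, 156000L),
    ultra_conserved = c(156200L, 156700L),
    gerp = c(157000L, 167000L),
    background = c(170000L, 195000L)
  )
}

.tile <- function(chroms, lo, hi, width, prefix) {
  starts <- seq.int(lo, hi - width, by = width)
  gr <- GenomicRanges::GRanges(
    rep(chroms, each = length(starts)),
    IRanges::IRanges(rep(starts, length(chroms)) + 1L, width = width)
  )
  names(gr) <- paste0(prefix, "_", rep(chroms, each = length(starts)), "_", rep(seq_along(starts), length(chroms)))
  gr$name <- names(gr)
  gr
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

.sharp_pwm <- function(name, consensus, sharpness) {
  L <- nchar(consensus)
  f <- matrix((1 - sharpness) / 3, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- seq_to_idx(consensus)
  f[cbind(seq_len(L), idx)] <- sharpness
  list(name = name, freqs = f)
}

#' Generate a toy data context on disk
#'
#' Writes a complete context — FASTA genome, the eight BED tracks, PWMs,
#' GERP table, gene models, networks, gene lists, element-gene association
#' table, recurrence database and polymorphism panel VCF — plus a
#' `context.config` file loadable by [build_context()]. Deterministic given
#' `spec$seed`.
#'
#' Planted structure (returned as `$truth`): a hub cancer gene whose
#' promoter carries a one-mismatch motif site (so a single substitution
#' completes the consensus: the gain-of-motif archetype), exact consensus
#' motif occurrences under TFP peaks (the motif-breaking substrate), and
#' panel variants placed so each discrete feature is observed at its
#' configured rate.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, `list(config, truth)` where `config` is the config
#'   file path.
#' @export
make_context <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, .make_context_impl(spec, dir))
}

.make_context_impl <- function(spec, dir) {
  zones <- .fixture_zones()
  chroms <- names(spec$chrom_lengths)
  path <- function(...) file.path(dir, ...)

  # --- genes ---
  gene_rows <- list()
  g <- 0L
  for (chrom in chroms) {
    for (k in seq_len(spec$n_genes_per_chrom)) {
      g <- g + 1L
      base <- 10000L + (k - 1L) * 14000L
      strand <- if (k %% 2L == 1L) "+" else "-"
      tss <- if (strand == "+") base else base + 2999L
      coding <- g %% 2L == 1L
      gene_rows[[g]] <- data.frame(
        gene_id = sprintf("gene%02d", g), chrom = chrom, strand = strand,
        txstart = base, txend = base + 3000L, tss = tss,
        cds_starts = if (coding) as.character(base + 600L) else "",
        cds_ends = if (coding) as.character(base + 900L) else "",
        stringsAsFactors = FALSE
      )
    }
  }
  gm <- do.call(rbind, gene_rows)
  hub_gene <- "gene01"

  # --- PWMs ---
  consensi <- vapply(seq_len(spec$n_pwms), function(i) .random_dna(spec$pwm_length), character(1))
  # an ETS-like GGAA core in the first motif's consensus
  substr(consensi[1], 6, 9) <- "GGAA"
  pwm_names <- c("ETS_like", paste0("motif_", seq_len(spec$n_pwms))[-1])
  pwms <- Map(.sharp_pwm, pwm_names, consensi, spec$pwm_sharpness)
  llms <- lapply(pwms, to_log_likelihood)

  # --- genome with planted motif occurrences ---
  seqs <- lapply(spec$chrom_lengths, .random_dna)
  motif_sites <- list()
  L <- spec$pwm_length
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    for (mi in seq_along(pwms)) {
      # two forward and one reverse occurrence per motif, under TFP peaks
      starts <- zones$tfp[1] + 20L + ((mi - 1L) * 3L + 0:2) * 120L
      strands <- c("+", "+", "-")
      for (k in 1:3) {
        planted <- if (strands[k] == "+") consensi[mi] else reverse_complement(consensi[mi])
        substr(seqs[[ci]], starts[k] + 1L, starts[k] + L) <- planted
        motif_sites[[length(motif_sites) + 1L]] <- data.frame(
          chrom = chrom, start = starts[k], end = starts[k] + L,
          motif = pwm_names[mi], strand = strands[k], stringsAsFactors = FALSE
        )
      }
    }
  }
  motif_sites <- do.call(rbind, motif_sites)

  # planted gain site: one-mismatch motif in the hub gene promoter
  gain_start <- 8800L
  mm_off <- 6L # 0-based offset of the mismatch within the motif
  cons1 <- consensi[1]
  cons_base <- substr(cons1, mm_off + 1L, mm_off + 1L)
  mm_base <- setdiff(c("A", "C", "G", "T"), cons_base)[1]
  germ_site <- cons1
  substr(germ_site, mm_off + 1L, mm_off + 1L) <- mm_base
  substr(seqs[[1]], gain_start + 1L, gain_start + L) <- germ_site
  gain <- list(
    chrom = "chr1", pos = gain_start + mm_off, ref = mm_base, alt = cons_base,
    motif = pwm_names[1], win_start = gain_start, win_end = gain_start + L,
    gene = hub_gene
  )

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms
  Biostrings::writeXStringSet(genome, path("genome.fa"), width = 80L)

  # --- tracks ---
  tr <- list(
    tfp = .tile(chroms, zones$tfp[1], zones$tfp[2], 400L, "tfp"),
    dhs = .tile(chroms, zones$dhs[1], zones$dhs[2], 400L, "dhs"),
    enhancer = .tile(chroms, zones$enhancer[1], zones$enhancer[2], 500L, "enh"),
    hot = .tile(chroms, zones$hot[1], zones$hot[2], 500L, "hot")
  )
  # promoter elements over the planted gain site (the archetype is flagged
  # DHS + Enhancer + TFP)
  prom_el <- function(prefix, lo, hi) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(lo + 1L, hi))
    names(gr) <- paste0(prefix, "_prom")
    gr$name <- names(gr)
    gr
  }
  tr$dhs <- suppressWarnings(c(tr$dhs, prom_el("dhs", 8750L, 8950L)))
  tr$enhancer <- suppressWarnings(c(tr$enhancer, prom_el("enh", 8700L, 9000L)))
  tr$tfp <- suppressWarnings(c(tr$tfp, prom_el("tfp", 8780L, 8900L)))

  span <- function(lo, hi) {
    GenomicRanges::GRanges(chroms, IRanges::IRanges(rep(lo + 1L, length(chroms)), rep(hi, length(chroms))))
  }
  sens <- span(zones$sens_only[1], zones$ultra_sensitive[2])
  usens <- span(zones$ultra_sensitive[1], zones$ultra_sensitive[2])
  ucons <- span(zones$ultra_conserved[1], zones$ultra_conserved[2])
  mh <- scan_motifs(genome, llms)
  tracks <- c(tr, list(
    sensitive = sens, ultra_sensitive = usens,
    ultra_conserved = ucons, motif_hits = mh
  ))
  for (nm in names(tracks)) write_track(tracks[[nm]], path(paste0(nm, ".bed")))

  # --- GERP: conserved blocks plus mildly scored background blocks ---
  gerp_rows <- list()
  for (chrom in chroms) {
    starts <- seq.int(zones$gerp[1], zones$gerp[2] - 500L, by = 500L)
    gerp_rows[[length(gerp_rows) + 1L]] <- data.frame(
      chrom = chrom, start = starts, end = starts + 500L,
      score = round(stats::runif(length(starts), 2.5, 5), 3)
    )
    bg_starts <- seq.int(170000L, 179500L, by = 500L)
    gerp_rows[[length(gerp_rows) + 1L]] <- data.frame(
      chrom = chrom, start = bg_starts, end = bg_starts + 500L,
      score = round(stats::runif(length(bg_starts), -2, 2), 3)
    )
    gerp_rows[[length(gerp_rows) + 1L]] <- data.frame(
      chrom = chrom, start = zones$ultra_conserved[1], end = zones$ultra_conserved[2],
      score = 4.5
    )
  }
  utils::write.table(do.call(rbind, gerp_rows), path("gerp.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  write_pwms(pwms, path("pwms.txt"))
  write_gene_models(gm, path("gene_models.tsv"))

  # --- networks: hub-and-spoke PPI plus a sparse regulatory net ---
  others <- setdiff(gm$gene_id, hub_gene)
  ppi <- rbind(
    data.frame(a = hub_gene, b = others),
    data.frame(a = others[-length(others)], b = others[-1])
  )
  utils::write.table(ppi, path("ppi.tsv"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  reg <- data.frame(a = sample(gm$gene_id, 8, replace = TRUE), b = sample(gm$gene_id, 8, replace = TRUE))
  reg <- reg[reg$a != reg$b, ]
  utils::write.table(reg, path("regulatory.tsv"),
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )

  lists <- list(
    cancer_driver = c(hub_gene, "gene05"), dna_repair = "gene03",
    actionable = "gene04", under_selection = c(hub_gene, "gene02")
  )
  for (nm in names(lists)) writeLines(lists[[nm]], path(paste0(nm, ".txt")))

  # --- planted element-gene associations (distal enhancer tiles) ---
  assoc_el <- paste0("enh_chr1_", 1:5)
  assoc <- data.frame(
    element = c(assoc_el, "enh_chr1_6"),
    tss = paste0("tss_", c(2:6, 7)),
    gene = sprintf("gene%02d", c(2:6, 7)),
    signal = "H3K4me1", method = "pearson", tail = "right",
    r = c(rep(0.95, 5), 0.1), p_raw = c(rep(1e-8, 5), 0.4),
    n_tissues = 20L, degenerate = FALSE,
    p_adj = c(rep(1e-6, 5), 0.9),
    significant = c(rep(TRUE, 5), FALSE), stringsAsFactors = FALSE
  )
  utils::write.table(assoc, path("associations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- recurrence database (synthetic stand-in for public cohorts) ---
  recdb <- data.frame(
    cancer_type = c("Liver", "COSMIC", "Liver"),
    kind = c("site", "site", "element"),
    key = c(
      paste("chr1", gain$pos, gain$alt, sep = ":"),
      paste("chr1", gain$pos, gain$alt, sep = ":"),
      "enh_chr1_1"
    ),
    n_samples = c(5L, 54L, 3L),
    n_cohort = c(88L, 570L, 88L),
    stringsAsFactors = FALSE
  )
  utils::write.table(recdb, path("recurrence_db.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- polymorphism panel with planted feature rates ---
  rates <- spec$panel_rates
  cat_names <- c(names(rates), "background")
  probs <- c(unname(rates), 1 - sum(rates))
  stopifnot(probs[length(probs)] > 0)
  n <- spec$panel_size
  cat_draw <- sample.int(length(cat_names), n, replace = TRUE, prob = probs)
  chrom_draw <- sample(chroms, n, replace = TRUE)
  lo <- vapply(cat_names, function(z) zones[[z]][1], integer(1))[cat_draw]
  hi <- vapply(cat_names, function(z) zones[[z]][2], integer(1))[cat_draw]
  pos <- lo + floor(stats::runif(n) * (hi - lo))
  ref <- vapply(seq_len(n), function(i) {
    substr(seqs[[chrom_draw[i]]], pos[i] + 1L, pos[i] + 1L)
  }, character(1))
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  poly <- variant_table(chrom_draw, pos, ref, alt, "panel")
  poly$af <- round(stats::runif(n, 0, spec$maf_max), 4)
  write_polymorphisms(poly, path("polymorphisms.vcf"))

  # --- config ---
  cfg <- c(
    paste0("genome = ", "genome.fa"),
    paste0("gene_models = ", "gene_models.tsv"),
    paste0("pwms = ", "pwms.txt"),
    paste0("gerp = ", "gerp.tsv"),
    paste0("associations = ", "associations.tsv"),
    paste0("recurrence_db = ", "recurrence_db.tsv"),
    paste0("polymorphisms = ", "polymorphisms.vcf"),
    vapply(names(tracks), function(nm) paste0("track.", nm, " = ", nm, ".bed"), character(1)),
    "network.ppi = ppi.tsv",
    "network.regulatory = regulatory.tsv",
    vapply(names(lists), function(nm) paste0("gene_list.", nm, " = ", nm, ".txt"), character(1))
  )
  writeLines(cfg, path("context.config"))

  truth <- list(
    gain = gain,
    motif_sites = motif_sites,
    consensi = stats::setNames(consensi, pwm_names),
    hub_gene = hub_gene,
    zones = zones,
    panel_rates = rates,
    gene_models = gm,
    panel_keys = site_key(poly)
  )
  invisible(list(config = path("context.config"), truth = truth))
}

#' Generate a toy tumor cohort with a truth table
#'
#' Planted events: one gain-of-motif driver variant in the hub-gene
#' promoter (completing the planted one-mismatch consensus), one
#' motif-breaking variant at a consensus occurrence, one site mutated
#' identically in several samples, a set of promoter SNVs that create no
#' motif (alpha-matched nulls for the gain scan), and uniform background
#' variants. Panel collisions are avoided so the MAF filter leaves planted
#' events untouched.
#'
#' @param spec the [fixture_spec()] used for [make_context()].
#' @param context the built [build_context()] context.
#' @param truth the `$truth` element returned by [make_context()].
#' @param dir optional directory; when given, per-sample VCFs and a
#'   `truth.tsv` table are written there.
#' @return `list(variants, truth_table)`.
#' @export
make_cohort <- function(spec, context, truth, dir = NULL) {
  with_seed(spec$seed + 1L, .make_cohort_impl(spec, context, truth, dir))
}

.make_cohort_impl <- function(spec, context, truth, dir) {
  samples <- paste0("S", seq_len(spec$n_samples))
  chroms <- names(spec$chrom_lengths)
  genome_chr <- function(chrom) as.character(context$genome[[chrom]])
  seqs <- stats::setNames(lapply(chroms, genome_chr), chroms)
  taken <- truth$panel_keys
  rows <- list()
  add <- function(kind, chrom, pos, ref, alt, sample_id, motif = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, chrom = chrom, pos = pos, ref = ref, alt = alt,
      sample_id = sample_id, motif = motif, stringsAsFactors = FALSE
    )
    taken <<- c(taken, paste(chrom, pos, alt, sep = ":"))
  }
  # 1. the gain-of-motif driver
  g <- truth$gain
  add("gain", g$chrom, g$pos, g$ref, g$alt, samples[1], g$motif)
  # 2. a motif-breaking variant: consensus base -> rare base at a planted site
  site <- truth$motif_sites[truth$motif_sites$strand == "+", ][1, ]
  cons <- truth$consensi[[site$motif]]
  bpos <- site$start + 2L
  bref <- substr(cons, 3L, 3L)
  balt <- setdiff(c("A", "C", "G", "T"), bref)[1]
  add("break", site$chrom, bpos, bref, balt, samples[min(2, length(samples))], site$motif)
  # 3. a recurrent site shared by several samples
  rchrom <- chroms[length(chroms)]
  rpos <- truth$zones$background[1] + 1234L
  rref <- substr(seqs[[rchrom]], rpos + 1L, rpos + 1L)
  ralt <- setdiff(c("A", "C", "G", "T"), rref)[1]
  for (s in samples[seq_len(min(spec$recurrent_site_samples, length(samples)))]) {
    add("recurrent_site", rchrom, rpos, rref, ralt, s)
  }
  # 4. promoter SNVs creating no motif (nulls for the gain scan)
  gm <- truth$gene_models
  null_genes <- gm[gm$gene_id != truth$hub_gene, ]
  for (k in seq_len(spec$n_null_promoter)) {
    repeat {
      row <- null_genes[sample.int(nrow(null_genes), 1), ]
      off <- sample.int(2400L, 1)
      pos <- if (row$strand == "+") row$tss - off else row$tss + off
      ref <- substr(seqs[[row$chrom]], pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      key <- paste(row$chrom, pos, alt, sep = ":")
      if (!key %in% taken) break
    }
    add("null_promoter", row$chrom, pos, ref, alt, sample(samples, 1))
  }
  # 5. uniform background variants
  n_bg <- spec$n_background_variants
  k <- 0L
  while (k < n_bg) {
    chrom <- sample(chroms, 1)
    pos <- sample.int(spec$chrom_lengths[[chrom]] - 1L, 1) - 1L
    ref <- substr(seqs[[chrom]], pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    key <- paste(chrom, pos, alt, sep = ":")
    if (key %in% taken) next
    add("background", chrom, pos, ref, alt, sample(samples, 1))
    k <- k + 1L
  }
  truth_table <- do.call(rbind, rows)
  variants <- variant_table(
    truth_table$chrom, truth_table$pos, truth_table$ref,
    truth_table$alt, truth_table$sample_id
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in samples) {
      write_cohort_vcf(
        variants[variants$sample_id == s, , drop = FALSE],
        file.path(dir, paste0(s, ".vcf")), s
      )
    }
    utils::write.table(truth_table, file.path(dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  list(variants = variants, truth_table = truth_table)
}

# minimal single-sample VCF with a genotype column carrying the sample name
write_cohort_vcf <- function(v, path, sample_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  ), con)
  if (nrow(v)) {
    writeLines(paste(v$chrom, v$pos + 1L, ".", v$ref, v$alt, ".", ".", ".",
      "GT", "0/1",
      sep = "\t"
    ), con)
  }
  invisible(path)
}

#' Generate a toy tissue panel with planted correlations
#'
#' Planted activity pairs: expression tracks element activity with a target
#' correlation (`spec$target_r`) across tissues, for both enhancer marks.
#' Planted methylation pairs: the element methylation level is generated
#' anti-correlated with expression through binomial sampling of per-CpG
#' `(m_i, n_i)` counts. Null elements and tssEUs are mutually independent.
#'
#' @param spec a [fixture_spec()] (needs `n_tissues >= 5`).
#' @return `list(panel, truth)` where `truth` lists every planted pair.
#' @export
make_tissue_panel <- function(spec) {
  stopifnot(spec$n_tissues >= 5)
  with_seed(spec$seed + 2L, .make_tissue_panel_impl(spec))
}

.make_tissue_panel_impl <- function(spec) {
  nt <- spec$n_tissues
  tissues <- paste0("T", seq_len(nt))
  marks <- c("H3K4me1", "H3K27ac")
  n_act <- spec$n_activity_pairs
  n_met <- spec$n_methylation_pairs
  n_nul <- spec$n_null_pairs
  el_names <- c(
    paste0("el_act_", seq_len(n_act)),
    paste0("el_meth_", seq_len(n_met)),
    paste0("el_null_", seq_len(n_nul))
  )
  n_el <- length(el_names)
  elements <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(100001L + (seq_len(n_el) - 1L) * 500L, width = 300L)
  )
  names(elements) <- el_names
  tss_table <- data.frame(
    id = paste0("tss_", seq_len(n_el)), chrom = "chr1",
    pos = 120000L + (seq_len(n_el) - 1L) * 700L,
    gene = paste0("g", seq_len(n_el)), stringsAsFactors = FALSE
  )
  act_libs <- lapply(marks, function(m) {
    stats::setNames(round(1e6 * stats::runif(nt, 0.9, 1.1)), tissues)
  })
  names(act_libs) <- marks
  expr_libs <- stats::setNames(
    lapply(tissues, function(t) round(1e6 * stats::runif(2, 0.9, 1.1))),
    tissues
  )
  activity <- lapply(marks, function(m) {
    matrix(0, n_el, nt, dimnames = list(el_names, tissues))
  })
  names(activity) <- marks
  methylation <- list()
  expression <- list()
  truth <- list()
  r <- spec$target_r
  level_to_counts <- function(level, libs) pmax(0L, round(level * libs / 1e6))
  for (i in seq_len(n_el)) {
    el <- el_names[i]
    tssid <- tss_table$id[i]
    kind <- if (i <= n_act) "activity" else if (i <= n_act + n_met) "methylation" else "null"
    z <- stats::rnorm(nt)
    ze <- if (kind == "activity") {
      r * z + sqrt(1 - r^2) * stats::rnorm(nt)
    } else {
      stats::rnorm(nt)
    }
    act_level <- pmax(1, 200 + 50 * z)
    expr_level <- pmax(1, 300 + 60 * ze)
    for (m in marks) {
      noise <- stats::rnorm(nt, sd = 4)
      activity[[m]][el, ] <- level_to_counts(act_level + noise, act_libs[[m]])
    }
    if (kind %in% c("methylation", "null")) {
      meth_target <- if (kind == "methylation") {
        stats::plogis(-1.2 * scale(ze)[, 1] + stats::rnorm(nt, sd = 0.3))
      } else {
        stats::plogis(stats::rnorm(nt, sd = 1))
      }
      methylation[[el]] <- stats::setNames(lapply(seq_len(nt), function(t) {
        ncov <- 25L + stats::rpois(8, 10)
        cbind(m = stats::rbinom(8, ncov, meth_target[t]), n = ncov)
      }), tissues)
    }
    expression[[tssid]] <- stats::setNames(lapply(seq_len(nt), function(t) {
      base <- expr_level[t] * c(0.98, 1.02)
      level_to_counts(base, expr_libs[[tissues[t]]])
    }), tissues)
    truth[[i]] <- data.frame(
      element = el, tss = tssid, gene = tss_table$gene[i],
      type = kind, stringsAsFactors = FALSE
    )
  }
  panel <- tissue_panel(
    tissues, elements, tss_table, activity, act_libs,
    methylation, expression, expr_libs
  )
  list(panel = panel, truth = do.call(rbind, truth))
}

#' Serialize a tissue panel to a directory of TSV files
#'
#' @param panel a [tissue_panel()].
#' @param dir output directory.
#' @export
write_tissue_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(panel$tissues, file.path(dir, "tissues.txt"))
  write_track(panel$elements, file.path(dir, "elements.bed"))
  utils::write.table(panel$tss_table, file.path(dir, "tss.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (m in names(panel$activity)) {
    utils::write.table(
      data.frame(element = rownames(panel$activity[[m]]), panel$activity[[m]], check.names = FALSE),
      file.path(dir, paste0("activity_", m, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(
      data.frame(tissue = panel$tissues, lib = unname(panel$activity_libs[[m]][panel$tissues])),
      file.path(dir, paste0("activity_libs_", m, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  meth <- list()
  for (el in names(panel$methylation)) {
    for (t in names(panel$methylation[[el]])) {
      pairs <- panel$methylation[[el]][[t]]
      meth[[length(meth) + 1L]] <- data.frame(
        element = el, tissue = t, cpg = seq_len(nrow(pairs)),
        m = pairs[, 1], n = pairs[, 2]
      )
    }
  }
  utils::write.table(do.call(rbind, meth), file.path(dir, "methylation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  expr <- list()
  for (id in names(panel$expression)) {
    for (t in names(panel$expression[[id]])) {
      counts <- panel$expression[[id]][[t]]
      expr[[length(expr) + 1L]] <- data.frame(
        tss = id, tissue = t, replicate = seq_along(counts),
        count = counts, lib = panel$expression_libs[[t]][seq_along(counts)]
      )
    }
  }
  utils::write.table(do.call(rbind, expr), file.path(dir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a tissue panel from a directory written by [write_tissue_panel()]
#'
#' @param dir panel directory.
#' @return a [tissue_panel()].
#' @export
read_tissue_panel <- function(dir) {
  tissues <- readLines(file.path(dir, "tissues.txt"))
  elements <- read_track(file.path(dir, "elements.bed"))
  tss_table <- utils::read.table(file.path(dir, "tss.tsv"),
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  act_files <- list.files(dir, "^activity_", full.names = TRUE)
  act_files <- act_files[!grepl("^activity_libs_", basename(act_files))]
  marks <- sub("^activity_(.*)\\.tsv$", "\\1", basename(act_files))
  activity <- list()
  activity_libs <- list()
  for (k in seq_along(marks)) {
    df <- utils::read.table(act_files[k],
      sep = "\t", header = TRUE, check.names = FALSE,
      stringsAsFactors = FALSE
    )
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$element
    activity[[marks[k]]] <- mat
    libs <- utils::read.table(file.path(dir, paste0("activity_libs_", marks[k], ".tsv")),
      sep = "\t", header = TRUE, stringsAsFactors = FALSE
    )
    activity_libs[[marks[k]]] <- stats::setNames(libs$lib, libs$tissue)
  }
  meth_df <- utils::read.table(file.path(dir, "methylation.tsv"),
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  methylation <- list()
  for (el in unique(meth_df$element)) {
    sub <- meth_df[meth_df$element == el, ]
    methylation[[el]] <- lapply(split(sub, sub$tissue), function(d) {
      cbind(m = d$m, n = d$n)
    })
  }
  expr_df <- utils::read.table(file.path(dir, "expression.tsv"),
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  expression <- list()
  for (id in unique(expr_df$tss)) {
    sub <- expr_df[expr_df$tss == id, ]
    expression[[id]] <- lapply(split(sub, sub$tissue), function(d) d$count[order(d$replicate)])
  }
  expression_libs <- list()
  for (t in unique(expr_df$tissue)) {
    sub <- expr_df[expr_df$tissue == t, ]
    sub <- sub[sub$tss == sub$tss[1], ]
    expression_libs[[t]] <- sub$lib[order(sub$replicate)]
  }
  tissue_panel(
    tissues, elements, tss_table, activity, activity_libs,
    methylation, expression, expression_libs
  )
}
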