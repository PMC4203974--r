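# Per-variant feature extraction, weighted scoring and ranked reporting.
#
# Coding variants (SNVs/indels in annotated CDS) are ranked on the 0-6
# criterion tally; everything else goes through the entropy-weighted
# noncoding scheme. The two scales are reported separately.

#' Filter somatic calls against a polymorphism panel
#'
#' Variants matching a known polymorphism — same chromosome, position and
#' alternate allele — whose allele frequency is at least `threshold` are
#' removed as unlikely somatic. `threshold = 0` removes every matching
#' polymorphism.
#'
#' @param variants a variant table.
#' @param polymorphisms a polymorphism table with an `af` column (see
#'   [read_polymorphisms()]).
#' @param threshold minor-allele-frequency threshold (default 0).
#' @return the retained variants, with attribute `n_removed`.
#' @export
maf_filter <- function(variants, polymorphisms, threshold = 0) {
  hit_af <- polymorphisms$af[match(site_key(variants), site_key(polymorphisms))]
  drop <- !is.na(hit_af) & hit_af >= threshold
  if (any(drop)) {
    message("MAF filter removed ", sum(drop), " variant(s) matching panel polymorphisms")
  }
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

# gene ids per variant, resolved through promoters, gene bodies (introns /
# UTRs of the toy models) and the significant-association table
.target_genes <- function(vgr, context) {
  n <- length(vgr)
  genes <- vector("list", n)
  add <- function(q_idx, gene_ids) {
    for (k in seq_along(q_idx)) {
      i <- q_idx[k]
      genes[[i]] <<- union(genes[[i]], gene_ids[k])
    }
  }
  ov <- GenomicRanges::findOverlaps(vgr, context$promoters, ignore.strand = TRUE)
  add(S4Vectors::queryHits(ov), names(context$promoters)[S4Vectors::subjectHits(ov)])
  ov <- GenomicRanges::findOverlaps(vgr, context$gene_bodies, ignore.strand = TRUE)
  add(S4Vectors::queryHits(ov), names(context$gene_bodies)[S4Vectors::subjectHits(ov)])
  if (!is.null(context$associations) && length(context$element_index) > 0) {
    sig <- context$associations[context$associations$significant, , drop = FALSE]
    if (nrow(sig)) {
      ov <- GenomicRanges::findOverlaps(vgr, context$element_index)
      el <- names(context$element_index)[S4Vectors::subjectHits(ov)]
      qi <- S4Vectors::queryHits(ov)
      for (k in seq_along(qi)) {
        g <- unique(sig$gene[sig$element == el[k]])
        if (length(g)) genes[[qi[k]]] <- union(genes[[qi[k]]], g)
      }
    }
  }
  genes
}

#' Extract the feature matrix for a set of variants
#'
#' Overlap queries against the context tracks set the discrete flags; the
#' motif engine supplies breaking/gaining values (the largest value is kept
#' when a variant hits several motifs); target genes are resolved through
#' promoters, gene bodies and the significant element-gene associations;
#' network centrality is the maximum percentile over associated genes and
#' networks; GERP is looked up per position. Gain-of-motif scanning is
#' restricted to variants in promoters or in elements with a significant
#' gene association.
#'
#' @param variants a variant table.
#' @param context a [build_context()] data context.
#' @param features feature configuration.
#' @param alpha_gain,granularity gain-scan parameters (see [gain_scan()]).
#' @return `data.frame`, one row per variant: discrete flags, continuous
#'   values (`NA` when unobserved), and provenance strings.
#' @export
extract_feature_matrix <- function(variants, context,
                                   features = default_feature_config(),
                                   alpha_gain = 4e-8, granularity = 1e-3) {
  n <- nrow(variants)
  vgr <- variant_granges(variants)
  ov_any <- function(gr) {
    if (is.null(gr) || length(gr) == 0) rep(FALSE, n) else IRanges::overlapsAny(vgr, gr, ignore.strand = TRUE)
  }
  fm <- data.frame(
    in_tfp = ov_any(context$tracks$tfp),
    in_dhs = ov_any(context$tracks$dhs),
    in_enhancer = ov_any(context$tracks$enhancer),
    in_hot = ov_any(context$tracks$hot),
    in_sensitive = ov_any(context$tracks$sensitive),
    in_ultra_sensitive = ov_any(context$tracks$ultra_sensitive),
    in_ultra_conserved = ov_any(context$tracks$ultra_conserved),
    stringsAsFactors = FALSE
  )
  fm$in_functional_annotation <- fm$in_tfp | fm$in_dhs | fm$in_enhancer | fm$in_hot
  fm$in_promoter <- ov_any(context$promoters)
  fm$in_cds <- ov_any(context$cds)
  fm$gerp <- if (length(context$gerp)) {
    gerp_lookup(context$gerp, variants$chrom, variants$pos)
  } else {
    rep(NA_real_, n)
  }
  fm$gerp_gt2 <- !is.na(fm$gerp) & fm$gerp > 2

  genes <- .target_genes(vgr, context)
  fm$has_target_gene <- lengths(genes) > 0
  cancer <- context$gene_lists$cancer_driver %||% character()
  fm$target_is_cancer_gene <- vapply(genes, function(g) any(g %in% cancer), logical(1))
  fm$target_genes <- vapply(genes, paste, character(1), collapse = ",")
  fm$gene_highlights <- vapply(genes, function(g) {
    hits <- character()
    for (nm in names(context$gene_lists)) {
      hh <- intersect(g, context$gene_lists[[nm]])
      if (length(hh)) hits <- c(hits, paste0(nm, ":", hh))
    }
    paste(hits, collapse = ",")
  }, character(1))

  fm$network_centrality <- vapply(
    genes,
    function(g) variant_network_score(g, context$networks), numeric(1)
  )

  # motif breaking: variants inside motif-hit instances
  fm$motif_break_score <- NA_real_
  fm$motif_break <- ""
  mh <- context$tracks$motif_hits
  if (!is.null(mh) && length(mh)) {
    ov <- GenomicRanges::findOverlaps(vgr, mh, ignore.strand = TRUE)
    for (k in seq_along(S4Vectors::queryHits(ov))) {
      i <- S4Vectors::queryHits(ov)[k]
      j <- S4Vectors::subjectHits(ov)[k]
      motif <- mh$name[j]
      m <- context$llms[[motif]]
      if (is.null(m)) next
      hit <- list(
        chrom = as.character(GenomicRanges::seqnames(mh)[j]),
        start = GenomicRanges::start(mh)[j] - 1L,
        end = GenomicRanges::end(mh)[j],
        strand = as.character(GenomicRanges::strand(mh)[j])
      )
      br <- tryCatch(motif_break_score(variants[i, , drop = FALSE], hit, m),
        error = function(e) NULL
      )
      if (is.null(br)) next
      if (is.na(fm$motif_break_score[i]) || br$break_score > fm$motif_break_score[i]) {
        fm$motif_break_score[i] <- br$break_score
        fm$motif_break[i] <- sprintf(
          "%s:%.3f%s", motif, br$break_score,
          if (br$kind == "indel") ":indel" else ""
        )
      }
    }
  }

  # motif gaining: promoters or elements with a significant association
  fm$motif_gain_score <- NA_real_
  fm$motif_gain <- ""
  in_assoc_element <- rep(FALSE, n)
  if (!is.null(context$associations) && length(context$element_index)) {
    sig_el <- unique(context$associations$element[context$associations$significant])
    idx <- context$element_index[names(context$element_index) %in% sig_el]
    in_assoc_element <- ov_any(idx)
  }
  eligible <- which(fm$in_promoter | in_assoc_element)
  genome_seq <- context$genome_str %||% context$genome
  for (i in eligible) {
    ev <- gain_scan(variants[i, , drop = FALSE], genome_seq, context$llms,
      alpha_gain = alpha_gain, granularity = granularity
    )
    if (nrow(ev) == 0) next
    best <- ev[which.max(ev$gain_score), ]
    fm$motif_gain_score[i] <- best$gain_score
    fm$motif_gain[i] <- sprintf(
      "%s:%s:%d-%d:%.3f->%.3f", best$motif, best$strand,
      best$win_start, best$win_end, best$score_germline, best$score_mutant
    )
  }

  track_cols <- c(
    "in_tfp" = "TFP", "in_dhs" = "DHS", "in_enhancer" = "Enhancer",
    "in_hot" = "HOT", "in_sensitive" = "Sensitive",
    "in_ultra_sensitive" = "UltraSensitive", "in_ultra_conserved" = "UltraConserved"
  )
  fm$annotations <- apply(fm[, names(track_cols)], 1, function(fl) {
    paste(track_cols[fl], collapse = ",")
  })
  fm$recurrent <- FALSE
  fm
}

#' Feature vector of a single variant
#'
#' Convenience wrapper over [extract_feature_matrix()] for one variant.
#'
#' @inheritParams extract_feature_matrix
#' @param v one-row variant table.
#' @return one-row feature `data.frame`.
#' @export
extract_features <- function(v, context, features = default_feature_config(), ...) {
  extract_feature_matrix(v[1, , drop = FALSE], context, features, ...)
}

#' Entropy-weighted score of one feature vector
#'
#' Sums the discrete weights of observed flags and the curve evaluations of
#' observed continuous values, plus the sigmoid-scaled GERP contribution.
#' A parent feature's weight is excluded whenever any of its child features
#' is observed (so nested annotations are not double-counted); unobserved
#' features contribute nothing. The recurrence weight is added to the final
#' score only — the core score is independent of cohort size and
#' recurrence-database settings.
#'
#' @param fv one-row feature `data.frame` (see [extract_feature_matrix()]).
#' @param model a trained [train_weights()] model.
#' @return `list(core, final, contributions)`; the named `contributions`
#'   vector sums exactly to the reported scores.
#' @export
noncoding_score <- function(fv, model) {
  disc <- setdiff(model$features$discrete, "gerp_gt2")
  observed <- disc[vapply(disc, function(f) isTRUE(fv[[f]]), logical(1))]
  cont <- model$features$continuous
  observed <- c(observed, cont[vapply(cont, function(f) {
    !is.null(fv[[f]]) && !is.na(fv[[f]])
  }, logical(1))])
  suppressed <- names(model$tree)[vapply(
    model$tree,
    function(kids) any(kids %in% observed), logical(1)
  )]
  use <- setdiff(observed, suppressed)
  contributions <- numeric(0)
  for (f in use) {
    contributions[[f]] <- if (f %in% cont) {
      cv <- model$curves[[f]]
      if (is.null(cv)) stop("observed feature '", f, "' is not covered by the weight model")
      predict(cv, fv[[f]])
    } else {
      discrete_weight(model, f)
    }
  }
  if (!is.null(fv$gerp) && !is.na(fv$gerp)) {
    contributions[["gerp"]] <- gerp_weighted_value(
      fv$gerp, model$gerp$w_d,
      model$gerp$k, model$gerp$midpoint
    )
  }
  core <- sum(contributions[setdiff(names(contributions), "recurrent")])
  final <- core + sum(contributions[intersect(names(contributions), "recurrent")])
  list(core = core, final = final, contributions = contributions)
}

#' Coding consequence of a variant
#'
#' Strand-aware codon-level translation of the reference versus alternate
#' allele for SNVs in annotated CDS: stop gain is a premature stop, an
#' amino-acid change is nonsynonymous, otherwise synonymous. Indels in CDS
#' are classed `other` and flagged frameshift/inframe.
#'
#' @param v one-row variant table (must overlap an annotated CDS).
#' @param context a data context.
#' @return `list(consequence, gene, detail)`.
#' @export
coding_consequence <- function(v, context) {
  ov <- GenomicRanges::findOverlaps(variant_granges(v), context$cds,
    ignore.strand = TRUE, select = "first"
  )
  if (is.na(ov)) stop("variant does not overlap an annotated CDS")
  gene <- context$cds$gene_id[ov]
  if (v$vclass != "SNV") {
    shift <- abs(nchar(v$ref) - nchar(v$alt)) %% 3L
    return(list(
      consequence = "other", gene = gene,
      detail = if (shift == 0) "inframe" else "frameshift"
    ))
  }
  gm_row <- context$gene_models[match(gene, context$gene_models$gene_id), ]
  segs <- cds_segments(gm_row)
  segs <- segs[order(segs[, "start"]), , drop = FALSE]
  total <- sum(segs[, "end"] - segs[, "start"])
  if (total %% 3L != 0L) stop("CDS length of gene '", gene, "' is not divisible by 3")
  # genomic positions of the CDS in transcription order
  gpos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    seq.int(segs[i, "start"], segs[i, "end"] - 1L)
  }))
  minus <- gm_row$strand == "-"
  if (minus) gpos <- rev(gpos)
  off <- match(v$pos, gpos)
  if (is.na(off)) stop("variant position not inside the CDS of gene '", gene, "'")
  codon_i <- (off - 1L) %/% 3L
  within <- (off - 1L) %% 3L
  cpos <- gpos[codon_i * 3L + 1:3]
  chrom_seq <- if (is.null(context$genome_str)) {
    as.character(context$genome[[v$chrom]])
  } else {
    context$genome_str[[v$chrom]]
  }
  bases <- substring(chrom_seq, cpos + 1L, cpos + 1L)
  if (minus) bases <- vapply(bases, reverse_complement, character(1))
  ref_base <- if (minus) reverse_complement(v$ref) else v$ref
  alt_base <- if (minus) reverse_complement(v$alt) else v$alt
  if (bases[within + 1L] != ref_base) {
    stop("reference allele mismatch in CDS of '", gene, "'")
  }
  alt_codon <- ref_codon <- paste(bases, collapse = "")
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  consequence <- if (aa_alt == "*" && aa_ref != "*") {
    "premature_stop"
  } else if (aa_alt != aa_ref) "nonsynonymous" else "synonymous"
  list(consequence = consequence, gene = gene, detail = paste0(ref_codon, ">", alt_codon))
}

#' Coding criterion tally
#'
#' One point per satisfied criterion: nonsynonymous; premature stop (the
#' two are mutually exclusive — a stop gain counts only as premature stop);
#' gene under strong selection; gene a network hub; recurrent; GERP > 2.
#'
#' @param consequence consequence string from [coding_consequence()].
#' @param under_selection,network_hub,recurrent logical gene/variant flags.
#' @param gerp GERP score at the site (`NA` counts as not conserved).
#' @return integer score 0..6 (in practice 0..5, criteria 1 and 2 being
#'   exclusive).
#' @export
coding_score <- function(consequence, under_selection = FALSE, network_hub = FALSE,
                         recurrent = FALSE, gerp = NA) {
  as.integer(
    (consequence == "nonsynonymous") + (consequence == "premature_stop") +
      isTRUE(under_selection) + isTRUE(network_hub) + isTRUE(recurrent) +
      isTRUE(!is.na(gerp) && gerp > 2)
  )
}

#' Detect recurrence within a cohort and against the recurrence database
#'
#' A variant is recurrent when its exact site, an overlapped regulatory
#' element, or (for coding variants) its gene is mutated in at least
#' `min_samples` distinct input samples. When `use_db` is set, variants are
#' additionally matched against the context's recurrence database and the
#' per-cancer-type counts are reported (e.g. `"5/88 Liver samples"`); DB
#' matches also set the recurrence flag.
#'
#' @param variants a variant table (with `sample_id`).
#' @param context a data context.
#' @param use_db match against the recurrence database (default `FALSE`).
#' @param element_tracks tracks whose intervals define recurrent elements.
#' @param min_samples minimum distinct samples (default 2).
#' @return `list(recurrent, detail, db_match)`: a logical flag and two
#'   character vectors per variant.
#' @export
detect_recurrence <- function(variants, context, use_db = FALSE,
                              element_tracks = c("tfp", "dhs", "enhancer"),
                              min_samples = 2) {
  n <- nrow(variants)
  recurrent <- rep(FALSE, n)
  detail <- character(n)
  keys <- site_key(variants)
  vgr <- variant_granges(variants)
  rec_sites <- .count_distinct(keys, variants$sample_id, min_samples)
  hit <- match(keys, rec_sites$key)
  got <- !is.na(hit)
  recurrent[got] <- TRUE
  detail[got] <- paste0("site:", rec_sites$n_samples[hit[got]], "/",
    length(unique(variants$sample_id)), " samples")
  for (tr in element_tracks) {
    gr <- context$tracks[[tr]]
    if (is.null(gr) || length(gr) == 0) next
    ov <- GenomicRanges::findOverlaps(vgr, gr, ignore.strand = TRUE)
    ids <- names(gr)[S4Vectors::subjectHits(ov)]
    if (is.null(ids)) ids <- paste0(tr, "_", S4Vectors::subjectHits(ov))
    qi <- S4Vectors::queryHits(ov)
    rec_el <- .count_distinct(ids, variants$sample_id[qi], min_samples)
    in_rec <- qi[ids %in% rec_el$key]
    newly <- setdiff(in_rec, which(recurrent))
    recurrent[in_rec] <- TRUE
    detail[newly] <- paste0("element:", tr)
  }
  if (length(context$cds) > 0) {
    ov <- GenomicRanges::findOverlaps(vgr, context$cds, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov)
    gid <- context$cds$gene_id[S4Vectors::subjectHits(ov)]
    rec_g <- .count_distinct(gid, variants$sample_id[qi], min_samples)
    in_rec <- qi[gid %in% rec_g$key]
    newly <- setdiff(in_rec, which(recurrent))
    recurrent[in_rec] <- TRUE
    detail[newly] <- "gene"
  }
  db_match <- character(n)
  if (use_db && nrow(context$recurrence_db)) {
    db <- context$recurrence_db
    fmt <- function(rows) {
      paste(sprintf(
        "%d/%d %s samples", db$n_samples[rows], db$n_cohort[rows],
        db$cancer_type[rows]
      ), collapse = ",")
    }
    site_rows <- which(db$kind == "site")
    if (length(site_rows)) {
      for (i in seq_len(n)) {
        rows <- site_rows[db$key[site_rows] == keys[i]]
        if (length(rows)) db_match[i] <- fmt(rows)
      }
    }
    el_rows <- which(db$kind == "element")
    if (length(el_rows) && length(context$element_index)) {
      ov <- GenomicRanges::findOverlaps(vgr, context$element_index)
      el <- names(context$element_index)[S4Vectors::subjectHits(ov)]
      qi <- S4Vectors::queryHits(ov)
      for (k in seq_along(qi)) {
        rows <- el_rows[db$key[el_rows] == el[k]]
        if (length(rows)) {
          add <- fmt(rows)
          db_match[qi[k]] <- if (nzchar(db_match[qi[k]])) paste(db_match[qi[k]], add, sep = ",") else add
        }
      }
    }
    recurrent <- recurrent | nzchar(db_match)
  }
  list(recurrent = recurrent, detail = detail, db_match = db_match)
}

#' Run the prioritization pipeline
#'
#' Filters input variants against the polymorphism panel, splits coding
#' from noncoding, extracts features, scores (entropy-weighted for
#' noncoding; the 0-6 tally for coding), detects recurrence, and returns
#' the two ranked tables. Ranking is by descending final score with ties
#' broken by genomic coordinate, so repeated runs are byte-identical.
#'
#' @param variants a variant table (e.g. from [read_variants()]).
#' @param context a [build_context()] data context.
#' @param model a [train_weights()] weight model.
#' @param maf_threshold MAF threshold for the polymorphism filter; `NULL`
#'   disables filtering (default 0: any panel match is removed).
#' @param use_recurrence_db match against the recurrence database.
#' @param hub_percentile centrality percentile at or above which a coding
#'   gene counts as a network hub (default 0.75).
#' @param alpha_gain,granularity gain-scan parameters.
#' @return an object of class `"prioritization"` with ranked `$noncoding`
#'   and `$coding` data frames.
#' @export
run_pipeline <- function(variants, context, model, maf_threshold = 0,
                         use_recurrence_db = FALSE, hub_percentile = 0.75,
                         alpha_gain = 4e-8, granularity = 1e-3) {
  n_input <- nrow(variants)
  n_removed <- 0L
  if (!is.null(maf_threshold) && !is.null(context$polymorphisms)) {
    variants <- maf_filter(variants, context$polymorphisms, maf_threshold)
    n_removed <- attr(variants, "n_removed")
  }
  empty <- function() {
    data.frame(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      sample = character(), vclass = character(), score = numeric(),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(variants) == 0) {
    return(structure(
      list(
        noncoding = empty(), coding = empty(), n_input = n_input,
        n_removed_maf = n_removed, use_recurrence_db = use_recurrence_db
      ),
      class = "prioritization"
    ))
  }
  fm <- extract_feature_matrix(variants, context,
    features = model$features,
    alpha_gain = alpha_gain, granularity = granularity
  )
  rec <- detect_recurrence(variants, context, use_db = use_recurrence_db)
  fm$recurrent <- rec$recurrent
  base_cols <- function(idx) {
    data.frame(
      chrom = variants$chrom[idx], pos = variants$pos[idx],
      ref = variants$ref[idx], alt = variants$alt[idx],
      sample = variants$sample_id[idx], vclass = variants$vclass[idx],
      stringsAsFactors = FALSE
    )
  }
  is_coding <- fm$in_cds
  # --- noncoding ---
  nc_idx <- which(!is_coding)
  noncoding <- empty()
  if (length(nc_idx)) {
    fml <- lapply(nc_idx, function(i) lapply(fm, `[[`, i))
    scores <- lapply(fml, noncoding_score, model = model)
    noncoding <- cbind(
      base_cols(nc_idx),
      fm[nc_idx, c(
        "annotations", "gerp", "motif_break", "motif_gain", "target_genes",
        "gene_highlights", "network_centrality"
      ), drop = FALSE],
      data.frame(
        recurrence = ifelse(rec$recurrent[nc_idx], ifelse(
          nzchar(rec$detail[nc_idx]), rec$detail[nc_idx], "db"
        ), ""),
        recurrence_db = rec$db_match[nc_idx],
        core_score = vapply(scores, `[[`, numeric(1), "core"),
        score = vapply(scores, `[[`, numeric(1), "final"),
        stringsAsFactors = FALSE
      )
    )
    ord <- order(-noncoding$score, noncoding$chrom, noncoding$pos)
    noncoding <- noncoding[ord, , drop = FALSE]
    noncoding$rank <- seq_len(nrow(noncoding))
    rownames(noncoding) <- NULL
  }
  # --- coding ---
  cd_idx <- which(is_coding)
  coding <- empty()
  if (length(cd_idx)) {
    anns <- lapply(cd_idx, function(i) coding_consequence(variants[i, , drop = FALSE], context))
    under_sel <- context$gene_lists$under_selection %||% character()
    rows <- lapply(seq_along(cd_idx), function(k) {
      i <- cd_idx[k]
      ann <- anns[[k]]
      hub <- variant_network_score(ann$gene, context$networks)
      sc <- coding_score(
        ann$consequence,
        under_selection = ann$gene %in% under_sel,
        network_hub = !is.na(hub) && hub >= hub_percentile,
        recurrent = rec$recurrent[i], gerp = fm$gerp[i]
      )
      cbind(base_cols(i), data.frame(
        coding_consequence = ann$consequence, target_genes = ann$gene,
        gerp = fm$gerp[i],
        recurrence = ifelse(rec$recurrent[i], "yes", ""),
        recurrence_db = rec$db_match[i],
        score = sc, stringsAsFactors = FALSE
      ))
    })
    coding <- do.call(rbind, rows)
    ord <- order(-coding$score, coding$chrom, coding$pos)
    coding <- coding[ord, , drop = FALSE]
    coding$rank <- seq_len(nrow(coding))
    rownames(coding) <- NULL
  }
  structure(
    list(
      noncoding = noncoding, coding = coding, n_input = n_input,
      n_removed_maf = n_removed, use_recurrence_db = use_recurrence_db
    ),
    class = "prioritization"
  )
}

#' @export
print.prioritization <- function(x, ...) {
  cat("Variant prioritization\n")
  cat(
    "  input variants: ", x$n_input, " (", x$n_removed_maf, " removed by MAF filter)\n",
    sep = ""
  )
  cat(
    "  noncoding scored: ", nrow(x$noncoding), "  coding scored: ", nrow(x$coding),
    "  recurrence DB: ", if (x$use_recurrence_db) "on" else "off", "\n",
    sep = ""
  )
  if (nrow(x$noncoding)) {
    cat("  top noncoding variants:\n")
    top <- utils::head(x$noncoding[, c("chrom", "pos", "ref", "alt", "annotations", "score")], 5)
    print.data.frame(top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.prioritization <- function(object, ...) {
  print(object)
  if (nrow(object$noncoding)) {
    cat("  noncoding score quantiles:\n")
    print(stats::quantile(object$noncoding$score, c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1)))
  }
  invisible(object)
}
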