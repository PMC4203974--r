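# The data context: an immutable bundle of every annotation resource the
# prioritization pipeline queries — interval tracks, the reference genome,
# PWMs, conservation scores, element-gene associations, gene networks, gene
# lists, the recurrence database and the polymorphism panel.

.track_names <- c(
  "tfp", "dhs", "enhancer", "hot", "sensitive",
  "ultra_sensitive", "ultra_conserved", "motif_hits"
)

# key = path file, one entry per line; '#' comments allowed. Keys:
#   genome, gene_models, pwms, gerp, associations, recurrence_db,
#   polymorphisms, track.<name> (the 8 mandatory tracks),
#   network.<label>, gene_list.<label>
read_context_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2)) stop("malformed config line(s) in ", path)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  # relative paths resolve against the config file's directory
  abs <- grepl("^/", vals)
  vals[!abs] <- file.path(dirname(path), vals[!abs])
  stats::setNames(as.list(vals), keys)
}

#' Build the data context
#'
#' Loads every referenced resource, builds interval indexes per track, and
#' returns a read-only bundle. `config` is either a named list (keys as in
#' the documented config dialect) or the path of a `key = path` file.
#'
#' Mandatory keys: `genome`, `gene_models`, `pwms`, and the eight
#' `track.*` entries (`tfp`, `dhs`, `enhancer`, `hot`, `sensitive`,
#' `ultra_sensitive`, `ultra_conserved`, `motif_hits`). Optional: `gerp`,
#' `associations`, `recurrence_db`, `polymorphisms`, any number of
#' `network.*` and `gene_list.*` entries.
#'
#' @param config named list or config-file path.
#' @param background,pseudocount,log_base log-likelihood convention passed
#'   to [to_log_likelihood()] for the PWM library.
#' @param network_centrality centrality measure for loaded networks.
#' @return an object of class `"data_context"`.
#' @export
build_context <- function(config, background = rep(0.25, 4), pseudocount = 0.01,
                          log_base = 2, network_centrality = "degree") {
  if (is.character(config) && length(config) == 1) config <- read_context_config(config)
  need <- c("genome", "gene_models", "pwms", paste0("track.", .track_names))
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys)) {
    stop("data context config is missing mandatory key(s): ", paste(missing_keys, collapse = ", "))
  }
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  tracks <- stats::setNames(
    lapply(.track_names, function(t) read_track(config[[paste0("track.", t)]])),
    .track_names
  )
  gm <- read_gene_models(config$gene_models)
  pwms <- read_pwms(config$pwms)
  llms <- lapply(pwms, to_log_likelihood,
    background = background,
    pseudocount = pseudocount, base = log_base
  )
  gerp <- if (!is.null(config$gerp)) read_gerp(config$gerp) else GenomicRanges::GRanges()
  assoc <- if (!is.null(config$associations)) {
    read_associations(config$associations)
  } else {
    NULL
  }
  recdb <- if (!is.null(config$recurrence_db)) {
    utils::read.table(config$recurrence_db, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(
      cancer_type = character(), kind = character(), key = character(),
      n_samples = integer(), n_cohort = integer(), stringsAsFactors = FALSE
    )
  }
  poly <- if (!is.null(config$polymorphisms)) read_polymorphisms(config$polymorphisms) else NULL
  net_keys <- grep("^network\\.", names(config), value = TRUE)
  networks <- stats::setNames(
    lapply(net_keys, function(k) {
      build_network(config[[k]], name = sub("^network\\.", "", k), centrality = network_centrality)
    }),
    sub("^network\\.", "", net_keys)
  )
  gl_keys <- grep("^gene_list\\.", names(config), value = TRUE)
  gene_lists <- stats::setNames(
    lapply(gl_keys, function(k) readLines(config[[k]])),
    sub("^gene_list\\.", "", gl_keys)
  )
  # index of named element intervals for association lookups
  named_tracks <- c("tfp", "dhs", "enhancer")
  element_index <- do.call(c, unname(lapply(named_tracks, function(t) {
    gr <- tracks[[t]]
    gr[!is.na(names(gr)) & nzchar(names(gr))]
  })))
  # CDS segments with gene ids, for the coding path
  cds_list <- lapply(seq_len(nrow(gm)), function(i) {
    segs <- cds_segments(gm[i, ])
    if (nrow(segs) == 0) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(
      gm$chrom[i], IRanges::IRanges(segs[, "start"] + 1L, segs[, "end"]),
      strand = gm$strand[i]
    )
    gr$gene_id <- gm$gene_id[i]
    gr
  })
  cds_keep <- cds_list[vapply(cds_list, length, integer(1)) > 0]
  cds_gr <- if (length(cds_keep)) suppressWarnings(do.call(c, cds_keep)) else GenomicRanges::GRanges()
  genome_str <- stats::setNames(as.character(genome), names(genome))
  ctx <- structure(
    list(
      genome = genome, genome_str = genome_str, seqlens = seqlens, tracks = tracks,
      gene_models = gm,
      promoters = promoter_granges(gm, seqlens = seqlens),
      gene_bodies = gene_body_granges(gm),
      cds = cds_gr,
      pwms = pwms, llms = llms,
      gerp = gerp,
      associations = assoc,
      element_index = element_index,
      networks = networks,
      gene_lists = gene_lists,
      recurrence_db = recdb,
      polymorphisms = poly,
      config = config
    ),
    class = "data_context"
  )
  ctx
}

#' @export
print.data_context <- function(x, ...) {
  cat("Data context\n")
  cat(
    "  genome: ", length(x$genome), " chromosome(s), ",
    sum(x$seqlens), " bp\n",
    sep = ""
  )
  cat("  tracks:", paste(sprintf("%s(%d)", names(x$tracks), lengths(x$tracks)), collapse = " "), "\n")
  cat(
    "  genes: ", nrow(x$gene_models), "  PWMs: ", length(x$pwms),
    "  networks: ", length(x$networks),
    "  gene lists: ", length(x$gene_lists), "\n",
    sep = ""
  )
  cat(
    "  associations: ", if (is.null(x$associations)) 0 else nrow(x$associations),
    "  recurrence DB entries: ", nrow(x$recurrence_db),
    "  polymorphisms: ", if (is.null(x$polymorphisms)) 0 else nrow(x$polymorphisms), "\n",
    sep = ""
  )
  invisible(x)
}

#' Define distal regulatory modules
#'
#' Regulatory regions (by default the TFP, DHS and enhancer tracks) whose
#' distance to the nearest annotated gene body is at least `min_distance`
#' (regions overlapping or within the gap are excluded; regions on
#' chromosomes without genes are kept).
#'
#' @param context a [build_context()] data context.
#' @param tracks track names pooled as regulatory regions.
#' @param min_distance minimum gap to the closest gene body in bp
#'   (default 1000).
#' @return a `GRanges` of DRMs.
#' @export
define_drms <- function(context, tracks = c("tfp", "dhs", "enhancer"),
                        min_distance = 1000) {
  if (nrow(context$gene_models) == 0) stop("no gene models in context")
  regs <- do.call(c, unname(lapply(tracks, function(t) context$tracks[[t]])))
  genes <- context$gene_bodies
  hits <- GenomicRanges::distanceToNearest(regs, genes, ignore.strand = TRUE)
  dist <- rep(Inf, length(regs))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  regs[dist >= min_distance]
}

# distinct-sample counts per key; helper for recurrence
.count_distinct <- function(keys, samples, min_samples) {
  if (length(keys) == 0) {
    return(data.frame(key = character(), n_samples = integer(), stringsAsFactors = FALSE))
  }
  tab <- tapply(samples, keys, function(s) length(unique(s)))
  out <- data.frame(key = names(tab), n_samples = as.integer(tab), stringsAsFactors = FALSE)
  out[out$n_samples >= min_samples, , drop = FALSE]
}

site_key <- function(v) paste(v$chrom, v$pos, v$alt, sep = ":")

#' Build a recurrence database from per-cancer variant sets
#'
#' For each cancer type, stores (a) sites — identical `(chrom, pos, alt)`
#' mutated in at least `min_samples` distinct samples; (b) elements —
#' intervals of the given tracks overlapped by variants from at least
#' `min_samples` distinct samples; (c) genes — hit by coding variants (in
#' annotated CDS) from at least `min_samples` distinct samples. Counts are
#' of distinct samples, never variants. An optional `sample_alias` map
#' collapses duplicate sample ids across studies before counting.
#'
#' @param variant_sets named list: cancer type -> variant table.
#' @param context a data context (for element tracks and CDS annotation).
#' @param element_tracks track names whose intervals define recurrent
#'   elements.
#' @param min_samples minimum distinct samples (default 2).
#' @param sample_alias optional named character vector mapping sample ids
#'   to canonical ids.
#' @return `data.frame`: `cancer_type`, `kind` (site|element|gene), `key`,
#'   `n_samples`, `n_cohort` (samples in that cancer set).
#' @export
build_recurrence_db <- function(variant_sets, context,
                                element_tracks = c("tfp", "dhs", "enhancer"),
                                min_samples = 2, sample_alias = NULL) {
  out <- list()
  for (ct in names(variant_sets)) {
    v <- variant_sets[[ct]]
    samples <- v$sample_id
    if (!is.null(sample_alias)) {
      mapped <- sample_alias[samples]
      samples <- ifelse(is.na(mapped), samples, mapped)
    }
    n_cohort <- length(unique(samples))
    add <- function(df, kind) {
      if (nrow(df) == 0) return(NULL)
      df$cancer_type <- ct
      df$kind <- kind
      df$n_cohort <- n_cohort
      out[[length(out) + 1L]] <<- df
    }
    add(.count_distinct(site_key(v), samples, min_samples), "site")
    vgr <- variant_granges(v)
    for (tr in element_tracks) {
      gr <- context$tracks[[tr]]
      ov <- GenomicRanges::findOverlaps(vgr, gr)
      ids <- names(gr)[S4Vectors::subjectHits(ov)]
      if (is.null(ids)) ids <- paste0(tr, "_", S4Vectors::subjectHits(ov))
      add(
        .count_distinct(ids, samples[S4Vectors::queryHits(ov)], min_samples),
        "element"
      )
    }
    if (length(context$cds) > 0) {
      ov <- GenomicRanges::findOverlaps(vgr, context$cds)
      add(
        .count_distinct(
          context$cds$gene_id[S4Vectors::subjectHits(ov)],
          samples[S4Vectors::queryHits(ov)], min_samples
        ),
        "gene"
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      cancer_type = character(), kind = character(), key = character(),
      n_samples = integer(), n_cohort = integer(), stringsAsFactors = FALSE
    ))
  }
  db <- do.call(rbind, out)
  rownames(db) <- NULL
  db[, c("cancer_type", "kind", "key", "n_samples", "n_cohort")]
}
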