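# Readers and writers for the external formats the pipeline touches.
#
# A single coordinate convention is used internally: 0-based half-open,
# everywhere. Conversions happen only here, at the I/O boundary. VCF is
# 1-based (pos = POS - 1 on the way in); BED is already 0-based half-open
# and passes through unchanged.

#' Read somatic variants from VCF or BED
#'
#' VCF 4.x records are converted to 0-based coordinates, multi-allelic
#' records are split into one variant per alternate allele, and alleles are
#' left-normalized (shared suffix then prefix trimmed, position advanced).
#' Indels with a net length change above `max_indel` are dropped with a
#' message reporting the count.
#'
#' The BED dialect is `chrom start end sample_id ref alt` (0-based half-open,
#' already normalized or normalized on read).
#'
#' @param path path to the variant file.
#' @param fmt `"vcf"`, `"bed"`, or `"auto"` (by file extension).
#' @param sample_id sample of origin; defaults to the VCF genotype sample
#'   name when present, else the file base name. Ignored for BED, which
#'   carries the sample in column 4.
#' @param max_indel maximum net indel length retained (default 20 bp).
#' @return a variant `data.frame` (see [variant_table()]).
#' @export
read_variants <- function(path, fmt = c("auto", "vcf", "bed"),
                          sample_id = NULL, max_indel = 20L) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "vcf"
  }
  if (fmt == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      return(variant_table(character(), integer(), character(), character())[0, ])
    }
    if (is.null(sample_id)) {
      gt_samples <- colnames(vcf@gt)
      sample_id <- if (!is.null(gt_samples) && length(gt_samples) > 1) {
        gt_samples[2]
      } else {
        sub("\\.vcf(\\.gz)?$", "", basename(path), ignore.case = TRUE)
      }
    }
    bad <- is.na(fix$REF) | is.na(fix$ALT) | !grepl("^[0-9]+$", fix$POS)
    if (any(bad)) {
      stop(
        "malformed VCF record(s) at line offset(s): ",
        paste(which(bad), collapse = ", ")
      )
    }
    # split multi-allelic records: one variant per alt
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(fix)), lengths(alts))
    raw <- data.frame(
      chrom = fix$CHROM[idx],
      pos = as.integer(fix$POS[idx]) - 1L, # VCF is 1-based
      ref = toupper(fix$REF[idx]),
      alt = toupper(unlist(alts)),
      stringsAsFactors = FALSE
    )
    raw$sample_id <- sample_id
  } else {
    raw <- utils::read.table(path,
      sep = "\t", header = FALSE, stringsAsFactors = FALSE,
      col.names = c("chrom", "start", "end", "sample_id", "ref", "alt"),
      colClasses = c("character", "integer", "integer", "character", "character", "character")
    )
    raw <- data.frame(
      chrom = raw$chrom, pos = raw$start, ref = toupper(raw$ref),
      alt = toupper(raw$alt), sample_id = raw$sample_id,
      stringsAsFactors = FALSE
    )
  }
  norm <- Map(normalize_allele, raw$pos, raw$ref, raw$alt)
  raw$pos <- vapply(norm, `[[`, integer(1), "pos")
  raw$ref <- vapply(norm, `[[`, character(1), "ref")
  raw$alt <- vapply(norm, `[[`, character(1), "alt")
  if (any(raw$ref == raw$alt)) {
    stop("record(s) with identical ref and alt after normalization: line(s) ",
         paste(which(raw$ref == raw$alt), collapse = ", "))
  }
  too_long <- abs(nchar(raw$ref) - nchar(raw$alt)) > max_indel
  if (any(too_long)) {
    message("dropped ", sum(too_long), " indel(s) with net length > ", max_indel, " bp")
    raw <- raw[!too_long, , drop = FALSE]
  }
  v <- variant_table(raw$chrom, raw$pos, raw$ref, raw$alt, raw$sample_id)
  rownames(v) <- NULL
  v
}

#' Read a position weight matrix library
#'
#' File dialect: a header line `>name` followed by L whitespace-separated
#' rows of 4 base frequencies in A, C, G, T order. Rows are renormalized
#' when their sum is within 1e-3 of 1; a larger deviation is a format error
#' naming the motif.
#'
#' @param path path to the PWM text file.
#' @return a named list of PWM records, each `list(name, freqs)` with
#'   `freqs` an L x 4 matrix (columns A, C, G, T) whose rows sum to 1.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no PWM header ('>name') found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  pwms <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) == 0) stop("PWM '", name, "' has no frequency rows")
    rows <- lapply(strsplit(body, "\\s+"), as.numeric)
    if (any(lengths(rows) != 4) || anyNA(unlist(rows))) {
      stop("PWM '", name, "': each row must be 4 numeric frequencies")
    }
    freqs <- do.call(rbind, rows)
    sums <- rowSums(freqs)
    if (any(abs(sums - 1) > 1e-3)) {
      stop("PWM '", name, "': row sum deviates from 1 by more than 1e-3")
    }
    if (any(freqs < 0 | freqs > 1)) stop("PWM '", name, "': frequencies outside [0,1]")
    freqs <- freqs / sums
    colnames(freqs) <- c("A", "C", "G", "T")
    pwms[[i]] <- list(name = name, freqs = freqs)
  }
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  pwms
}

write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    utils::write.table(format(p$freqs, digits = 6, trim = TRUE),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(NULL)
}

#' Read BED interval tracks
#'
#' @param path BED3/BED4/BED6 file, 0-based half-open.
#' @return a `GRanges`; interval names (column 4) become `names()`.
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

write_track <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(NULL)
}

# Gene model table: TSV with columns
#   gene_id chrom strand txstart txend tss cds_starts cds_ends
# (0-based; cds_starts/cds_ends comma-separated, empty for noncoding genes).
read_gene_models <- function(path) {
  gm <- utils::read.table(path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = c(
      gene_id = "character", chrom = "character", strand = "character",
      txstart = "integer", txend = "integer", tss = "integer",
      cds_starts = "character", cds_ends = "character"
    )
  )
  stopifnot(all(gm$strand %in% c("+", "-")))
  gm
}

write_gene_models <- function(gm, path) {
  utils::write.table(gm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# Promoters: 2.5 kb upstream of the TSS, strand-aware, clipped at the
# chromosome start (lengths come from `seqlens` when given).
promoter_granges <- function(gm, upstream = 2500L, seqlens = NULL) {
  start0 <- ifelse(gm$strand == "+", gm$tss - upstream, gm$tss + 1L)
  end0 <- ifelse(gm$strand == "+", gm$tss, gm$tss + 1L + upstream)
  start0 <- pmax(start0, 0L)
  if (!is.null(seqlens)) end0 <- pmin(end0, as.integer(seqlens[gm$chrom]))
  gr <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = gm$strand
  )
  names(gr) <- gm$gene_id
  gr
}

gene_body_granges <- function(gm) {
  gr <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(start = gm$txstart + 1L, end = gm$txend),
    strand = gm$strand
  )
  names(gr) <- gm$gene_id
  gr
}

# CDS segments of one gene, in genomic order, as a 0-based start/end matrix.
cds_segments <- function(gm_row) {
  if (!nzchar(gm_row$cds_starts)) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(
    start = as.integer(strsplit(gm_row$cds_starts, ",")[[1]]),
    end = as.integer(strsplit(gm_row$cds_ends, ",")[[1]])
  )
}

# GERP constraint scores as scored intervals: TSV chrom/start/end/score,
# 0-based half-open. Point lookup returns the covering interval's score, or
# `default` outside all intervals.
read_gerp <- function(path) {
  g <- utils::read.table(path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = c(chrom = "character", start = "integer", end = "integer", score = "numeric")
  )
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  gr$score <- g$score
  gr
}

gerp_lookup <- function(gerp, chrom, pos, default = 0) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, gerp, select = "first")
  out <- rep(default, length(q))
  got <- !is.na(hits)
  out[got] <- gerp$score[hits[got]]
  out
}

# Polymorphism panel: VCF whose INFO field carries AF=. Returns a variant
# table with an `af` column (multi-allelic records split; AF split with
# them when comma-separated).
read_polymorphisms <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  af_str <- sub(".*AF=([^;]+).*", "\\1", fix$INFO)
  af_str[!grepl("AF=", fix$INFO)] <- NA_character_
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  afs <- strsplit(af_str, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  af_flat <- unlist(Map(function(a, f) {
    if (length(f) == length(a)) f else rep(f[1], length(a))
  }, alts, afs))
  v <- variant_table(fix$CHROM[idx], as.integer(fix$POS[idx]) - 1L,
    fix$REF[idx], unlist(alts),
    sample_id = "panel"
  )
  v$af <- as.numeric(af_flat)
  v
}

write_polymorphisms <- function(poly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(poly)) {
    writeLines(paste(poly$chrom, poly$pos + 1L, ".", poly$ref, poly$alt, ".", ".",
      paste0("AF=", format(poly$af, scientific = FALSE, trim = TRUE)),
      sep = "\t"
    ), con)
  }
  invisible(NULL)
}

# Fixed annotation key order for reports; kept stable so output is
# bit-exact across runs.
.report_keys <- c(
  "sample", "vclass", "gerp", "annotations", "motif_break", "motif_gain",
  "target_genes", "gene_highlights", "network_centrality", "recurrence",
  "recurrence_db", "coding_consequence", "core_score", "score"
)

#' Write a ranked variant report
#'
#' BED output: `chrom start end annotation score`, one row per variant,
#' sorted by descending score (ties by chrom, pos); the annotation column is
#' a semicolon-delimited `key=value` string with a fixed, documented key
#' order. VCF output: the same keys as INFO fields.
#'
#' @param scored a scored variant `data.frame` as produced by
#'   [run_pipeline()] (`$noncoding` or `$coding` component).
#' @param path output file.
#' @param fmt `"bed"` or `"vcf"`.
#' @export
write_report <- function(scored, path, fmt = c("bed", "vcf")) {
  fmt <- match.arg(fmt)
  con <- file(path, "w")
  on.exit(close(con))
  keys <- intersect(.report_keys, names(scored))
  fmt_val <- function(x) {
    out <- vapply(x, function(el) {
      if (is.na(el)) return(".")
      if (is.numeric(el)) return(format(el, digits = 6, scientific = FALSE, trim = TRUE))
      if (!nzchar(as.character(el))) "." else as.character(el)
    }, character(1))
    gsub("[;=\t ]", "_", out, perl = TRUE)
  }
  if (fmt == "bed") {
    writeLines(paste0("#chrom\tstart\tend\t", paste(keys, collapse = ";"), "\tscore"), con)
    if (nrow(scored)) {
      ann <- do.call(paste, c(lapply(keys, function(k) paste0(k, "=", fmt_val(scored[[k]]))),
        sep = ";"
      ))
      writeLines(paste(scored$chrom, scored$pos,
        scored$pos + pmax(nchar(scored$ref), 1L),
        ann, fmt_val(scored$score),
        sep = "\t"
      ), con)
    }
  } else {
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0(
        "##INFO=<ID=", toupper(keys),
        ",Number=1,Type=String,Description=\"", keys, "\">"
      ),
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    ), con)
    if (nrow(scored)) {
      info <- do.call(paste, c(
        lapply(keys, function(k) paste0(toupper(k), "=", fmt_val(scored[[k]]))),
        sep = ";"
      ))
      # empty-allele indels re-anchored on the previous base for VCF
      ref <- scored$ref
      alt <- scored$alt
      pos1 <- scored$pos + 1L
      bare <- !nzchar(ref) | !nzchar(alt)
      if (any(bare)) {
        ref[bare] <- paste0("N", ref[bare])
        alt[bare] <- paste0("N", alt[bare])
        pos1[bare] <- pos1[bare] - 1L
      }
      writeLines(paste(scored$chrom, pos1, ".", ref, alt, ".", ".", info, sep = "\t"), con)
    }
  }
  invisible(path)
}
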