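# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All generators in the package are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a validated variant table
#'
#' Variants are kept internally as a plain `data.frame` in 0-based half-open
#' coordinates: `pos` is the 0-based position of the first altered base.
#' `ref`/`alt` are allele strings after left-normalization; either may be the
#' empty string for a pure insertion/deletion.
#'
#' @param chrom,pos,ref,alt,sample_id vectors of equal length (recycled where
#'   length 1); `pos` 0-based.
#' @return `data.frame` with columns `chrom, pos, ref, alt, sample_id, vclass`.
#' @export
variant_table <- function(chrom, pos, ref, alt, sample_id = "sample") {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 0)) stop("variant positions must be >= 0")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  df$vclass <- variant_class(df$ref, df$alt)
  df
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
    ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")
  )
}

# GRanges spanning the reference footprint of each variant (width >= 1 so
# pure insertions still anchor at the insertion point).
variant_granges <- function(v) {
  GenomicRanges::GRanges(
    v$chrom,
    IRanges::IRanges(start = v$pos + 1L, width = pmax(nchar(v$ref), 1L))
  )
}

# Left-normalize one allele pair: trim shared suffix, then shared prefix,
# advancing pos past the trimmed prefix.
normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  k <- 0L
  while (length(r) > k && length(a) > k && r[k + 1L] == a[k + 1L]) k <- k + 1L
  list(
    pos = pos + k,
    ref = paste(r[seq_len(length(r) - k) + k], collapse = ""),
    alt = paste(a[seq_len(length(a) - k) + k], collapse = "")
  )
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
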