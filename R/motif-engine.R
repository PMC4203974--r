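# Nucleotide-level motif analysis: PWM scoring in log-likelihood space,
# motif-breaking deltas, gain-of-motif scanning, and exact tail p-values for
# match scores computed by dynamic programming over a discretized score
# distribution.

.base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.base_comp <- c(4L, 3L, 2L, 1L) # A<->T, C<->G in index space

seq_to_idx <- function(seq) {
  unname(.base_idx[strsplit(toupper(seq), "")[[1]]])
}

#' Transform a PWM to a log-likelihood matrix
#'
#' Each entry is `log2((f + pc * bg) / ((1 + pc) * bg))`: the base-2
#' log-likelihood ratio of the motif model over an i.i.d. background, with an
#' additive pseudocount proportional to the background so all entries are
#' finite. Base, background and pseudocount are parameterized so alternative
#' published conventions can be matched by configuration.
#'
#' @param pwm a PWM record from [read_pwms()] (`list(name, freqs)`).
#' @param background base probabilities (A, C, G, T), summing to 1, all > 0.
#' @param pseudocount small positive pseudocount (default 0.01).
#' @param base logarithm base (default 2; scores are then in bits).
#' @return an object of class `"llm"`: `name`, `mat` (L x 4), `background`,
#'   `pseudocount`, `base`, plus a cache for score distributions.
#' @export
to_log_likelihood <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01,
                              base = 2) {
  stopifnot(abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  if (any(background <= 0)) stop("background probabilities must be positive")
  mat <- log(sweep(pwm$freqs + pseudocount * rep(background, each = nrow(pwm$freqs)),
    2, (1 + pseudocount) * background, "/"
  ), base = base)
  dimnames(mat) <- list(NULL, c("A", "C", "G", "T"))
  structure(
    list(
      name = pwm$name, mat = mat, background = background,
      pseudocount = pseudocount, base = base, cache = new.env(parent = emptyenv())
    ),
    class = "llm"
  )
}

#' @export
print.llm <- function(x, ...) {
  cat("Log-likelihood matrix '", x$name, "': length ", nrow(x$mat),
    ", pseudocount ", x$pseudocount, ", log base ", x$base, "\n",
    sep = ""
  )
  invisible(x)
}

# Matrix for the reverse-complement strand: reversed positions, complemented
# bases. Scoring a sequence against it equals scoring the sequence's reverse
# complement against the forward matrix.
revcomp_llm <- function(m) {
  out <- m
  out$mat <- m$mat[rev(seq_len(nrow(m$mat))), .base_comp, drop = FALSE]
  dimnames(out$mat) <- dimnames(m$mat)
  out$cache <- new.env(parent = emptyenv()) # distribution is identical, but keep caches separate
  out
}

#' Score a sequence against a log-likelihood matrix
#'
#' The match score is the sum of the matrix entries at each position. On the
#' minus strand the reverse complement of the sequence is scored.
#'
#' @param m an `"llm"` object.
#' @param seq a string over A/C/G/T of length `nrow(m$mat)`.
#' @param strand `"+"` or `"-"`.
#' @return score in log-base units (bits for base 2), or `NA` if the
#'   sequence contains an ambiguous base.
#' @export
sequence_score <- function(m, seq, strand = "+") {
  idx <- seq_to_idx(seq)
  if (length(idx) != nrow(m$mat)) stop("sequence length does not match the matrix")
  if (anyNA(idx)) return(NA_real_)
  if (strand == "-") idx <- .base_comp[rev(idx)]
  sum(m$mat[cbind(seq_len(nrow(m$mat)), idx)])
}

# Discretized distribution of the match score of an i.i.d. background
# sequence. Entries are floored onto a grid of width `granularity`; the
# distribution of the integer sum is built by convolving the per-position
# mass functions. Cached per (matrix, granularity).
score_distribution <- function(m, granularity = 1e-3) {
  key <- sprintf("g%.12g", granularity)
  hit <- get0(key, envir = m$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  ints <- matrix(as.integer(floor(m$mat / granularity)), nrow = nrow(m$mat))
  lo <- 0L
  v <- 1
  for (i in seq_len(nrow(ints))) {
    ri <- ints[i, ]
    rlo <- min(ri)
    new <- numeric(length(v) + max(ri) - rlo)
    for (b in 1:4) {
      sh <- ri[b] - rlo
      span <- seq_along(v) + sh
      new[span] <- new[span] + v * m$background[b]
    }
    v <- new
    lo <- lo + rlo
  }
  res <- list(
    lo = lo, probs = v,
    tail = rev(cumsum(rev(v))), # tail[k] = P(int_sum >= lo + k - 1)
    granularity = granularity, L = nrow(ints)
  )
  assign(key, res, envir = m$cache)
  res
}

#' Exact tail p-value of a motif match score
#'
#' Returns `P(score(X) >= s)` for an i.i.d. background sequence `X` of the
#' matrix length, computed by dynamic programming over the discretized score
#' distribution. Entries are floored to a grid of width `granularity`; the
#' returned value is guaranteed to lie between the exact `P(score >= s)` and
#' `P(score >= s - L * granularity)`, i.e. within the probability mass of
#' scores in `[s - L * granularity, s)` of the exact answer.
#'
#' @param m an `"llm"` object.
#' @param s score threshold (same units as [sequence_score()]).
#' @param granularity discretization grid in score units (default 1e-3).
#' @return a probability in `[0, 1]`.
#' @export
score_pvalue <- function(m, s, granularity = 1e-3) {
  if (!is.finite(s)) {
    return(if (s == -Inf) 1 else 0)
  }
  d <- score_distribution(m, granularity)
  thr <- as.integer(ceiling(s / granularity - 1e-9)) - d$L
  k <- thr - d$lo + 1L
  if (k <= 1L) return(1)
  if (k > length(d$tail)) return(0)
  d$tail[k]
}

#' Motif-breaking score of a variant inside a motif hit
#'
#' For an SNV, the break score is the log-likelihood difference between the
#' germline and mutant base at the motif position the variant hits
#' (strand-adjusted). Only score *decreases* are breaking events; a
#' conserving or improving change returns `NULL`. For an indel overlapping
#' the hit, the maximum per-position score range over the disrupted motif
#' positions is returned, flagged as an indel break.
#'
#' @param v one-row variant `data.frame`.
#' @param hit the motif hit: `list(chrom, start, end, strand)`, 0-based
#'   half-open, spanning the motif instance.
#' @param m the `"llm"` for the hit's motif.
#' @return `NULL`, or `list(break_score, kind)` with `kind` `"snv"` or
#'   `"indel"`.
#' @export
motif_break_score <- function(v, hit, m) {
  L <- nrow(m$mat)
  if (hit$end - hit$start != L) stop("hit width does not match the matrix length")
  ref_end <- v$pos + max(nchar(v$ref), 1L)
  if (v$pos >= hit$end || ref_end <= hit$start) {
    stop("variant does not overlap the motif hit")
  }
  if (v$vclass == "SNV") {
    j <- if (hit$strand == "-") hit$end - 1L - v$pos else v$pos - hit$start
    gb <- .base_idx[[v$ref]]
    mb <- .base_idx[[v$alt]]
    if (hit$strand == "-") {
      gb <- .base_comp[gb]
      mb <- .base_comp[mb]
    }
    delta <- m$mat[j + 1L, gb] - m$mat[j + 1L, mb]
    if (delta <= 0) return(NULL)
    return(list(break_score = unname(delta), kind = "snv"))
  }
  # indel: all motif positions touched by the reference footprint (or the
  # insertion point) are considered disrupted
  lo <- max(v$pos, hit$start)
  hi <- min(max(ref_end, v$pos + 1L), hit$end)
  js <- seq.int(lo - hit$start, hi - 1L - hit$start) + 1L
  if (hit$strand == "-") js <- L + 1L - js
  ranges <- apply(m$mat[js, , drop = FALSE], 1, function(r) max(r) - min(r))
  best <- max(ranges)
  if (best <= 0) return(NULL)
  list(break_score = unname(best), kind = "indel")
}

#' Scan a variant for gain-of-motif events
#'
#' Builds the germline window (reference allele plus `flank` bases each
#' side) and the mutant window (alternate allele substituted), and for every
#' matrix, strand and offset whose motif window covers the altered base(s),
#' evaluates the match score tail p-value of the mutant window and of the
#' germline-aligned window. A gain event requires
#' `p_mutant <= alpha_gain`, `p_germline > alpha_gain`, and a score
#' increase.
#'
#' @param v one-row variant `data.frame`.
#' @param genome a `DNAStringSet`, or a named character vector of
#'   chromosome sequences, containing the variant's chromosome.
#' @param llms list of `"llm"` matrices.
#' @param flank flank width in bp (default 29, i.e. 59-bp windows for SNVs).
#' @param alpha_gain significance threshold on the tail p-value
#'   (default 4e-8).
#' @param granularity p-value discretization grid (default 1e-3).
#' @return `data.frame` of events (possibly empty): motif, strand, genomic
#'   window start/end (0-based half-open, germline coordinates),
#'   score_germline, score_mutant, p_germline, p_mutant, gain_score.
#' @export
gain_scan <- function(v, genome, llms, flank = 29L, alpha_gain = 4e-8,
                      granularity = 1e-3) {
  chrom_seq <- if (is.character(genome)) genome[[v$chrom]] else as.character(genome[[v$chrom]])
  clen <- nchar(chrom_seq)
  reflen <- nchar(v$ref)
  altlen <- nchar(v$alt)
  win_lo <- max(0L, v$pos - flank) # window clipped at chromosome edges
  win_hi <- min(clen, v$pos + reflen + flank)
  germ <- substr(chrom_seq, win_lo + 1L, win_hi)
  var_off <- v$pos - win_lo
  obs_ref <- substr(germ, var_off + 1L, var_off + reflen)
  if (reflen > 0 && obs_ref != v$ref) {
    stop("reference allele mismatch at ", v$chrom, ":", v$pos, " (genome has ", obs_ref, ")")
  }
  mut <- paste0(
    substr(germ, 1L, var_off), v$alt,
    substr(germ, var_off + reflen + 1L, nchar(germ))
  )
  cover_end <- var_off + max(altlen, 1L)
  out <- list()
  for (m in llms) {
    L <- nrow(m$mat)
    if (nchar(mut) < L) next
    o_lo <- max(0L, var_off - L + 1L)
    o_hi <- min(cover_end - 1L, nchar(mut) - L)
    if (o_hi < o_lo) next
    offs <- seq.int(o_lo, o_hi)
    for (o in offs) {
      mutseq <- substr(mut, o + 1L, o + L)
      # germline-aligned window: same left genomic coordinate; offsets past
      # the allele are remapped through the length change
      og <- if (o + L <= var_off) o else if (o >= var_off + altlen) o + reflen - altlen else o
      og <- max(0L, min(og, nchar(germ) - L))
      germseq <- substr(germ, og + 1L, og + L)
      for (strand in c("+", "-")) {
        s_mut <- sequence_score(m, mutseq, strand)
        s_germ <- sequence_score(m, germseq, strand)
        if (is.na(s_mut) || is.na(s_germ) || s_mut <= s_germ) next
        p_mut <- score_pvalue(m, s_mut, granularity)
        if (p_mut > alpha_gain) next
        p_germ <- score_pvalue(m, s_germ, granularity)
        if (p_germ <= alpha_gain) next
        out[[length(out) + 1L]] <- data.frame(
          motif = m$name, strand = strand,
          win_start = win_lo + og, win_end = win_lo + og + L,
          score_germline = s_germ, score_mutant = s_mut,
          p_germline = p_germ, p_mutant = p_mut,
          gain_score = s_mut - s_germ,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      motif = character(), strand = character(), win_start = integer(),
      win_end = integer(), score_germline = numeric(), score_mutant = numeric(),
      p_germline = numeric(), p_mutant = numeric(), gain_score = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

# Sliding-window match scores of a whole chromosome against one matrix, on
# one strand; used to derive the motif-hit track of synthetic genomes.
sliding_scores <- function(idx, mat) {
  L <- nrow(mat)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + unname(mat[j, ])[idx[j:(j + n - 1L)]]
  s
}

#' Scan a genome for motif matches
#'
#' Both strands are scanned; windows scoring at least `min_score` (in
#' log-likelihood units) are reported. Used to build motif-hit tracks for
#' synthetic genomes.
#'
#' @param genome a `DNAStringSet`.
#' @param llms list of `"llm"` matrices.
#' @param min_score either a single score threshold or a function of one
#'   `"llm"` returning its threshold (default: maximum achievable score
#'   minus 3).
#' @return a `GRanges` with `name` = motif and the match strand.
#' @export
scan_motifs <- function(genome, llms, min_score = NULL) {
  hits <- list()
  for (chrom in names(genome)) {
    idx <- seq_to_idx(as.character(genome[[chrom]]))
    for (m in llms) {
      thr <- if (is.null(min_score)) {
        sum(apply(m$mat, 1, max)) - 3
      } else if (is.function(min_score)) min_score(m) else min_score
      for (strand in c("+", "-")) {
        mm <- if (strand == "+") m else revcomp_llm(m)
        sc <- sliding_scores(idx, mm$mat)
        at <- which(sc >= thr)
        if (length(at)) {
          hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(at, width = nrow(m$mat)),
            strand = strand, name = m$name
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- suppressWarnings(do.call(c, hits))
  names(gr) <- paste0(gr$name, "_", seq_along(gr))
  gr
}
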