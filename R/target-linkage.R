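# Associating regulatory elements with likely target genes by correlating
# element activity/inactivity signals with expression across tissues.
#
# Activity signals are the enhancer marks H3K4me1 and H3K27ac (right-tailed
# tests: looking for positive correlation with expression); the inactivity
# signal is DNA methylation (left-tailed: looking for anti-correlation).

#' Normalized activity level of an element in one experiment
#'
#' Reads-per-million: `raw_count / library_size * 1e6`.
#'
#' @param raw_count aligned reads in the element.
#' @param library_size total reads of the experiment (> 0).
#' @return normalized level (vectorized).
#' @export
activity_level <- function(raw_count, library_size) {
  if (any(library_size <= 0)) stop("library size must be positive")
  raw_count / library_size * 1e6
}

#' Methylation level of an element
#'
#' The ratio of summed methylated-read counts to summed coverage over all
#' CpG sites in the element: `sum(m_i) / sum(n_i)`.
#'
#' @param cpg_pairs two-column matrix (or data.frame) with columns `m`
#'   (reads supporting methylation) and `n` (total reads covering the CpG).
#' @return ratio in `[0, 1]`, or `NA` when no CpG has coverage (the
#'   element-tissue cell is missing).
#' @export
methylation_level <- function(cpg_pairs) {
  cpg_pairs <- as.matrix(cpg_pairs)
  m <- cpg_pairs[, 1]
  n <- cpg_pairs[, 2]
  if (any(m < 0 | n < 0 | m > n)) stop("need 0 <= m_i <= n_i for every CpG")
  if (sum(n) == 0) return(NA_real_)
  sum(m) / sum(n)
}

#' Normalized expression level of a TSS expression unit
#'
#' Per-replicate reads-per-million in the TSS +/- 50 bp window, averaged
#' across replicates.
#'
#' @param reads_in_window per-replicate read counts.
#' @param library_sizes per-replicate total reads.
#' @return mean normalized level.
#' @export
expression_level <- function(reads_in_window, library_sizes) {
  stopifnot(length(reads_in_window) >= 1, length(reads_in_window) == length(library_sizes))
  mean(activity_level(reads_in_window, library_sizes))
}

#' Candidate target tssEUs of a regulatory element
#'
#' All TSS expression units on the element's chromosome whose TSS lies
#' within `max_distance` of the element boundary (closed boundary: a TSS at
#' exactly `max_distance` is included; a TSS inside the element is at
#' distance 0).
#'
#' @param element `list(chrom, start, end)`, 0-based half-open.
#' @param tss_table `data.frame` with columns `id`, `chrom`, `pos` (0-based
#'   TSS position).
#' @param max_distance candidate window in bp (default 1e6).
#' @return character vector of candidate tssEU ids.
#' @export
candidate_targets <- function(element, tss_table, max_distance = 1e6) {
  same <- tss_table$chrom == element$chrom
  pos <- tss_table$pos[same]
  d <- ifelse(pos < element$start, element$start - pos,
    ifelse(pos >= element$end, pos - (element$end - 1L), 0L)
  )
  tss_table$id[same][d <= max_distance]
}

# all permutations of 1..n, memoised; used for exact Spearman p-values
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  hit <- get0(key, envir = .perm_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- if (n == 1) matrix(1L) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  assign(key, res, envir = .perm_cache)
  res
}

#' One-tailed correlation test between signal and expression levels
#'
#' Pearson: the one-tailed p-value comes from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (right tail: `P(T >= t)`; left tail: `P(T <= t)`); optionally from the
#' Fisher Z transformation instead. Spearman: the rank correlation; the
#' p-value is exact by full enumeration of rank permutations when `n <= 7`,
#' otherwise from the large-sample t approximation on the rank correlation.
#'
#' Pairs with a missing value in either vector are dropped first. A
#' zero-variance input yields `p = 1` and is flagged degenerate.
#'
#' @param x signal levels across tissues.
#' @param y expression levels across the same tissues.
#' @param method `"pearson"` or `"spearman"`.
#' @param tail `"right"` (activity signals) or `"left"` (methylation).
#' @param use_fisher_z use the Fisher Z approximation for the Pearson
#'   p-value instead of the t distribution.
#' @return `list(r, p, n, method, tail, degenerate, exact)`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman"),
                             tail = c("right", "left"), use_fisher_z = FALSE) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete tissue pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(
      r = NA_real_, p = 1, n = n, method = method, tail = tail,
      degenerate = TRUE, exact = FALSE
    ))
  }
  if (method == "pearson") {
    r <- stats::cor(x, y)
    if (use_fisher_z) {
      z <- atanh(max(min(r, 1 - 1e-15), -1 + 1e-15)) * sqrt(n - 3)
      p <- stats::pnorm(z, lower.tail = (tail == "left"))
    } else {
      tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      p <- stats::pt(tstat, df = n - 2, lower.tail = (tail == "left"))
    }
    return(list(
      r = r, p = p, n = n, method = method, tail = tail,
      degenerate = FALSE, exact = FALSE
    ))
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= 7) {
    perms <- all_perms(n)
    rp <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- if (tail == "right") mean(rp >= r - 1e-12) else mean(rp <= r + 1e-12)
    exact <- TRUE
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    p <- stats::pt(tstat, df = n - 2, lower.tail = (tail == "left"))
    exact <- FALSE
  }
  list(r = r, p = p, n = n, method = method, tail = tail, degenerate = FALSE, exact = exact)
}

#' Adjust p-values for multiple testing
#'
#' Thin, order-preserving wrapper over [stats::p.adjust()] for the four
#' supported procedures.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"holm"`, `"bh"`, or `"by"`.
#' @return adjusted p-values, capped at 1, in input order.
#' @export
adjust_pvalues <- function(p, method = c("bh", "by", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bh = "BH", by = "BY", holm = "holm", bonferroni = "bonferroni")[method])
}

#' Construct a tissue panel
#'
#' Bundles the cross-tissue signal and expression measurements used by
#' [call_associations()].
#'
#' @param tissues ordered tissue names (>= 2).
#' @param elements named `GRanges` of regulatory elements.
#' @param tss_table `data.frame` with `id`, `chrom`, `pos` (0-based TSS),
#'   `gene` (target gene id; defaults to `id`).
#' @param activity named list, one entry per mark (e.g. `H3K4me1`,
#'   `H3K27ac`), each an element x tissue matrix of raw read counts.
#' @param activity_libs named list parallel to `activity`: per-tissue
#'   library sizes.
#' @param methylation nested list `methylation[[element]][[tissue]]`: a
#'   two-column (`m`, `n`) CpG count matrix, or `NULL` when missing.
#' @param expression nested list `expression[[tss_id]][[tissue]]`:
#'   per-replicate read counts in the TSS window.
#' @param expression_libs list `expression_libs[[tissue]]`: per-replicate
#'   library sizes.
#' @return an object of class `"tissue_panel"`.
#' @export
tissue_panel <- function(tissues, elements, tss_table, activity, activity_libs,
                         methylation, expression, expression_libs) {
  stopifnot(length(tissues) >= 2)
  if (is.null(tss_table$gene)) tss_table$gene <- tss_table$id
  structure(
    list(
      tissues = tissues, elements = elements, tss_table = tss_table,
      activity = activity, activity_libs = activity_libs,
      methylation = methylation, expression = expression,
      expression_libs = expression_libs
    ),
    class = "tissue_panel"
  )
}

#' @export
print.tissue_panel <- function(x, ...) {
  cat(
    "Tissue panel: ", length(x$tissues), " tissues, ", length(x$elements),
    " elements, ", nrow(x$tss_table), " tssEUs; marks: ",
    paste(names(x$activity), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

# element x tissue matrices of normalized levels
panel_activity_levels <- function(panel, mark) {
  act <- panel$activity[[mark]]
  libs <- panel$activity_libs[[mark]]
  sweep(act, 2, libs, function(a, l) activity_level(a, l))
}

panel_methylation_levels <- function(panel) {
  el <- names(panel$methylation)
  out <- matrix(NA_real_, length(el), length(panel$tissues),
    dimnames = list(el, panel$tissues)
  )
  for (e in el) {
    for (t in panel$tissues) {
      pairs <- panel$methylation[[e]][[t]]
      if (!is.null(pairs)) out[e, t] <- methylation_level(pairs)
    }
  }
  out
}

panel_expression_levels <- function(panel) {
  ids <- names(panel$expression)
  out <- matrix(NA_real_, length(ids), length(panel$tissues),
    dimnames = list(ids, panel$tissues)
  )
  for (id in ids) {
    for (t in panel$tissues) {
      counts <- panel$expression[[id]][[t]]
      if (!is.null(counts)) out[id, t] <- expression_level(counts, panel$expression_libs[[t]])
    }
  }
  out
}

#' Call element-target gene associations across a tissue panel
#'
#' For every element, every candidate tssEU within `max_distance`, every
#' signal and every correlation method, runs the one-tailed
#' [correlation_test()] (right tail for the activity marks, left tail for
#' methylation), adjusts all raw p-values jointly, and flags records with
#' `p_adj <= alpha` significant.
#'
#' @param panel a [tissue_panel()].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param adjust_method multiple-testing procedure (see
#'   [adjust_pvalues()]).
#' @param methods correlation methods to run.
#' @param max_distance candidate window in bp (default 1e6).
#' @param min_n minimum complete tissue pairs per test (default 3).
#' @param use_fisher_z see [correlation_test()].
#' @return `data.frame` of association records: `element`, `tss`, `gene`,
#'   `signal`, `method`, `tail`, `r`, `p_raw`, `p_adj`, `n_tissues`,
#'   `significant`; `adjust_method` and `alpha` as attributes.
#' @export
call_associations <- function(panel, alpha = 0.05, adjust_method = "bh",
                              methods = c("pearson", "spearman"),
                              max_distance = 1e6, min_n = 3, use_fisher_z = FALSE) {
  levels_by_signal <- list()
  for (mark in names(panel$activity)) {
    levels_by_signal[[mark]] <- list(x = panel_activity_levels(panel, mark), tail = "right")
  }
  if (length(panel$methylation)) {
    levels_by_signal[["methylation"]] <- list(x = panel_methylation_levels(panel), tail = "left")
  }
  expr <- panel_expression_levels(panel)
  rows <- list()
  for (ei in seq_along(panel$elements)) {
    el_name <- names(panel$elements)[ei]
    el <- list(
      chrom = as.character(GenomicRanges::seqnames(panel$elements)[ei]),
      start = GenomicRanges::start(panel$elements)[ei] - 1L,
      end = GenomicRanges::end(panel$elements)[ei]
    )
    cand <- candidate_targets(el, panel$tss_table, max_distance)
    for (signal in names(levels_by_signal)) {
      sig <- levels_by_signal[[signal]]
      if (!el_name %in% rownames(sig$x)) next
      x <- sig$x[el_name, ]
      for (tssid in cand) {
        if (!tssid %in% rownames(expr)) next
        y <- expr[tssid, ]
        if (sum(!(is.na(x) | is.na(y))) < min_n) next
        for (method in methods) {
          ct <- correlation_test(x, y, method, sig$tail, use_fisher_z)
          rows[[length(rows) + 1L]] <- data.frame(
            element = el_name, tss = tssid,
            gene = panel$tss_table$gene[match(tssid, panel$tss_table$id)],
            signal = signal, method = method, tail = sig$tail,
            r = ct$r, p_raw = ct$p, n_tissues = ct$n,
            degenerate = ct$degenerate, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(
      element = character(), tss = character(), gene = character(),
      signal = character(), method = character(), tail = character(),
      r = numeric(), p_raw = numeric(), n_tissues = integer(),
      degenerate = logical(), p_adj = numeric(), significant = logical(),
      stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, rows)
    out$p_adj <- adjust_pvalues(out$p_raw, adjust_method)
    out$significant <- out$p_adj <= alpha
  }
  attr(out, "alpha") <- alpha
  attr(out, "adjust_method") <- adjust_method
  class(out) <- c("association_set", "data.frame")
  out
}

#' @export
print.association_set <- function(x, ...) {
  cat(
    "Association set: ", nrow(x), " tests, ", sum(x$significant),
    " significant at alpha=", attr(x, "alpha"),
    " (", attr(x, "adjust_method"), "-adjusted)\n",
    sep = ""
  )
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

write_associations <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_associations <- function(path) {
  a <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(a) <- c("association_set", "data.frame")
  a
}
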