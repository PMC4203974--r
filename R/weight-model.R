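# Entropy-based feature weighting trained on a natural-polymorphism panel.
#
# Features frequently observed among polymorphisms arise in regions tolerant
# of variation and are weighted down; the weight of a feature observed with
# probability p is one minus its Shannon entropy,
#   w = 1 + p log2 p + (1 - p) log2 (1 - p),
# which is 1 for p in {0, 1}, 0 at p = 0.5, and strictly decreasing on
# (0, 0.5]. Continuous features get a weight *curve*: at each observed value
# v the tail probability P(value >= v) among polymorphisms is converted to a
# weight by the same formula, and a monotone smooth curve is fitted through
# the points.

#' One minus the Shannon entropy of a Bernoulli probability
#'
#' `w(p) = 1 + p log2(p) + (1 - p) log2(1 - p)`, with `0 log2 0 := 0`.
#' Symmetric about 0.5; `w(0) = w(1) = 1`, `w(0.5) = 0`.
#'
#' @param p probability (vectorized), in `[0, 1]`.
#' @return weights in `[0, 1]`.
#' @export
shannon_weight <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  term <- function(q) ifelse(q == 0, 0, q * log2(q))
  w <- 1 + term(p) + term(1 - p)
  pmin(pmax(w, 0), 1)
}

#' Fit an entropy weight curve for a continuous feature
#'
#' At each distinct observed value `v`, the tail probability
#' `p = #(values >= v) / n_total` is converted to a weight by
#' [shannon_weight()]. A monotone fit (isotonic regression over the grid
#' where `p <= 0.5`, followed by a shape-preserving monotone spline) yields
#' a weight for any query value; queries outside the observed range clamp to
#' the boundary weights.
#'
#' @param values feature values observed among polymorphisms carrying the
#'   feature (at least 1; at least 10 for a non-degenerate curve).
#' @param n_total total number of polymorphisms in the panel (the tail
#'   probability denominator). Defaults to `length(values)`.
#' @param feature feature name carried along for reporting.
#' @return an object of class `"weight_curve"` with the grid (`v`, raw
#'   tail probabilities `p`, raw weights `w`, fitted weights `w_fit`).
#' @export
fit_weight_curve <- function(values, n_total = length(values), feature = "feature") {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no observed values for feature '", feature, "'")
  v <- sort(unique(values))
  nv <- length(values)
  # tail counts: number of observations >= each grid value
  tail_n <- nv - findInterval(v - 1e-12, sort(values))
  p <- tail_n / n_total
  w <- shannon_weight(pmin(p, 1))
  keep <- p <= 0.5
  if (!any(keep)) keep <- p == min(p) # degenerate: feature more common than rare
  v2 <- v[keep]
  w2 <- w[keep]
  if (length(v2) >= 2) {
    w_fit <- stats::isoreg(v2, w2)$yf
  } else {
    w_fit <- w2
  }
  structure(
    list(
      feature = feature, v = v, p = p, w = w,
      grid_v = v2, grid_w = w_fit, n_total = n_total, n_observed = nv,
      degenerate = length(v2) < 2
    ),
    class = "weight_curve"
  )
}

#' @export
predict.weight_curve <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$grid_v[1]), object$grid_v[length(object$grid_v)])
  if (object$degenerate) {
    out <- rep(object$grid_w[1], length(x))
  } else {
    f <- tryCatch(
      stats::splinefun(object$grid_v, object$grid_w, method = "hyman"),
      error = function(e) stats::approxfun(object$grid_v, object$grid_w, rule = 2)
    )
    out <- f(x)
  }
  out[is.na(newdata)] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' @export
print.weight_curve <- function(x, ...) {
  cat(
    "Entropy weight curve for '", x$feature, "': ", x$n_observed,
    " observed values of ", x$n_total, " polymorphisms; grid of ",
    length(x$grid_v), " points\n",
    sep = ""
  )
  invisible(x)
}

#' Weighted value of a GERP constraint score
#'
#' GERP is handled as a discrete feature (`GERP > 2`) whose entropy weight
#' scales a sigmoid transform of the raw score, sharp at the conventional
#' conservation cutoff of 2: `w_d / (1 + exp(-k (g - midpoint)))`. The
#' transform keeps the `GERP > 2` semantics while making the contribution
#' continuous in the score.
#'
#' @param g GERP score(s).
#' @param w_d entropy weight of the `GERP > 2` discrete feature.
#' @param k sigmoid steepness per GERP unit (default 10).
#' @param midpoint sigmoid midpoint (default 2).
#' @return weighted values in `[0, w_d]`.
#' @export
gerp_weighted_value <- function(g, w_d, k = 10, midpoint = 2) {
  stopifnot(k > 0)
  w_d * stats::plogis(k * (g - midpoint))
}

#' Default feature configuration
#'
#' Names the discrete and continuous features the scorer understands and
#' their dependency graph (acyclic; a child may refine several parents): a
#' parent feature's weight is dropped from the
#' sum whenever any of its children is observed, so that nested annotations
#' are not double-counted (e.g. a variant in a polymorphism-depleted
#' "sensitive" region does not also collect the generic
#' "in functional annotation" weight). The tree is configuration, not code,
#' and can be overridden.
#'
#' @return a list with elements `discrete`, `continuous`, `tree`, `gerp`.
#' @export
default_feature_config <- function() {
  list(
    discrete = c(
      "in_functional_annotation", "in_tfp", "in_dhs", "in_enhancer", "in_hot",
      "in_sensitive", "in_ultra_sensitive", "in_ultra_conserved",
      "has_target_gene", "target_is_cancer_gene", "recurrent", "gerp_gt2"
    ),
    continuous = c("motif_break_score", "motif_gain_score", "network_centrality"),
    tree = list(
      in_functional_annotation = c(
        "in_tfp", "in_dhs", "in_enhancer", "in_hot", "in_sensitive",
        "in_ultra_sensitive", "in_ultra_conserved",
        "motif_break_score", "motif_gain_score"
      ),
      in_sensitive = "in_ultra_sensitive"
    ),
    gerp = list(k = 10, midpoint = 2)
  )
}

validate_feature_config <- function(features) {
  kids <- unlist(features$tree, use.names = FALSE)
  all_feats <- c(features$discrete, features$continuous)
  unknown <- setdiff(c(names(features$tree), kids), all_feats)
  if (length(unknown)) stop("dependency tree names unknown features: ", paste(unknown, collapse = ", "))
  # no cycles: parents may not also be descendants
  for (p in names(features$tree)) {
    seen <- character()
    stack <- features$tree[[p]]
    while (length(stack)) {
      f <- stack[[1]]
      stack <- stack[-1]
      if (f == p) stop("dependency tree has a cycle through '", p, "'")
      if (f %in% seen) next
      seen <- c(seen, f)
      stack <- c(stack, features$tree[[f]])
    }
  }
  invisible(features)
}

#' Train the entropy weight model on a polymorphism panel
#'
#' Runs feature extraction on a (seeded) random sample of the panel, then
#' computes one entropy weight per discrete feature from the fraction of
#' polymorphisms carrying it, one weight curve per continuous feature from
#' the observed value distribution, and the GERP sigmoid scaling from the
#' `GERP > 2` fraction. This is the model-fitting step of the package; the
#' result is used by [predict.weight_model()] / [run_pipeline()] to score
#' somatic variants.
#'
#' @param polymorphisms a variant table of natural polymorphisms (see
#'   [read_polymorphisms()]); allele frequencies are not needed for
#'   training.
#' @param context a [build_context()] data context.
#' @param features feature configuration (see [default_feature_config()]).
#' @param sample_fraction fraction of the panel to run through feature
#'   extraction (default 0.1).
#' @param seed RNG seed for the panel sample.
#' @return an object of class `"weight_model"`.
#' @seealso [write_weight_model()], [read_weight_model()]
#' @export
train_weights <- function(polymorphisms, context, features = default_feature_config(),
                          sample_fraction = 0.1, seed = 1) {
  stopifnot(nrow(polymorphisms) > 0, sample_fraction > 0, sample_fraction <= 1)
  validate_feature_config(features)
  n_take <- max(1L, round(nrow(polymorphisms) * sample_fraction))
  panel <- with_seed(seed, polymorphisms[sample.int(nrow(polymorphisms), n_take), , drop = FALSE])
  fm <- extract_feature_matrix(panel, context, features)
  disc <- setdiff(features$discrete, "gerp_gt2")
  p_d <- vapply(disc, function(f) mean(fm[[f]] %in% TRUE), numeric(1))
  discrete <- data.frame(
    feature = disc, p = unname(p_d), w = unname(shannon_weight(p_d)),
    low_confidence = unname(p_d == 0), stringsAsFactors = FALSE
  )
  p_gerp <- mean(fm$gerp > 2, na.rm = TRUE)
  curves <- list()
  for (f in features$continuous) {
    vals <- fm[[f]]
    obs <- !is.na(vals)
    if (sum(obs) >= 10) {
      curves[[f]] <- fit_weight_curve(vals[obs], n_total = nrow(fm), feature = f)
    } else {
      # too few observations for a curve: constant weight at the observation
      # rate, flagged low-confidence
      p_obs <- max(sum(obs), 1) / nrow(fm)
      curves[[f]] <- structure(
        list(
          feature = f, v = numeric(), p = numeric(), w = numeric(),
          grid_v = 0, grid_w = shannon_weight(min(p_obs, 0.5)),
          n_total = nrow(fm), n_observed = sum(obs), degenerate = TRUE
        ),
        class = "weight_curve"
      )
    }
  }
  structure(
    list(
      discrete = discrete,
      curves = curves,
      gerp = list(
        p = p_gerp, w_d = shannon_weight(p_gerp),
        k = features$gerp$k, midpoint = features$gerp$midpoint
      ),
      tree = features$tree,
      features = features,
      meta = list(
        panel_size = nrow(polymorphisms), sampled = n_take,
        sample_fraction = sample_fraction, seed = seed
      )
    ),
    class = "weight_model"
  )
}

discrete_weight <- function(model, feature) {
  i <- match(feature, model$discrete$feature)
  if (is.na(i)) stop("feature '", feature, "' is not covered by the weight model")
  model$discrete$w[i]
}

#' @export
print.weight_model <- function(x, ...) {
  cat("Entropy weight model\n")
  cat(
    "  trained on ", x$meta$sampled, " of ", x$meta$panel_size,
    " polymorphisms (fraction ", x$meta$sample_fraction, ", seed ", x$meta$seed, ")\n",
    sep = ""
  )
  cat("  discrete features:", nrow(x$discrete), " continuous curves:", length(x$curves), "\n")
  cat(
    "  GERP>2 fraction ", signif(x$gerp$p, 3), " -> weight ", signif(x$gerp$w_d, 3),
    " (sigmoid k=", x$gerp$k, " at ", x$gerp$midpoint, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
summary.weight_model <- function(object, ...) {
  cat("Discrete feature weights (fraction of polymorphism panel -> weight):\n")
  d <- object$discrete
  for (i in seq_len(nrow(d))) {
    cat(sprintf(
      "  %-26s p=%-8.4g w=%.4f%s\n", d$feature[i], d$p[i], d$w[i],
      if (d$low_confidence[i]) " (never observed; low confidence)" else ""
    ))
  }
  cat(sprintf("  %-26s p=%-8.4g w=%.4f (sigmoid-scaled)\n", "gerp_gt2", object$gerp$p, object$gerp$w_d))
  cat("Continuous weight curves:\n")
  for (f in names(object$curves)) {
    cv <- object$curves[[f]]
    cat(sprintf(
      "  %-26s observed %d/%d%s\n", f, cv$n_observed, cv$n_total,
      if (cv$degenerate) " (degenerate: constant weight)" else ""
    ))
  }
  invisible(object)
}

#' @export
coef.weight_model <- function(object, ...) {
  out <- stats::setNames(object$discrete$w, object$discrete$feature)
  c(out, gerp_gt2 = object$gerp$w_d)
}

#' @export
plot.weight_model <- function(x, features = names(x$curves), ...) {
  old <- graphics::par(mfrow = c(1, max(length(features), 1)))
  on.exit(graphics::par(old))
  for (f in features) {
    cv <- x$curves[[f]]
    if (is.null(cv) || cv$degenerate) next
    grid <- seq(cv$grid_v[1], cv$grid_v[length(cv$grid_v)], length.out = 200)
    plot(cv$v, cv$w,
      pch = 16, cex = 0.6, xlab = f, ylab = "weight",
      main = paste("weight curve:", f), ylim = c(0, 1), ...
    )
    graphics::lines(grid, predict(cv, grid), col = "red", lty = 2)
  }
  invisible(x)
}

#' Score feature observations with a trained weight model
#'
#' @param object a `"weight_model"`.
#' @param newdata a feature matrix as returned by
#'   [extract_feature_matrix()] (or any data.frame with the same columns).
#' @param ... unused.
#' @return `data.frame` with `core_score` and `final_score` per row.
#' @export
predict.weight_model <- function(object, newdata, ...) {
  fml <- lapply(seq_len(nrow(newdata)), function(i) lapply(newdata, `[[`, i))
  out <- lapply(fml, function(fv) {
    sc <- noncoding_score(fv, object)
    data.frame(core_score = sc$core, final_score = sc$final)
  })
  do.call(rbind, out)
}

#' Serialize a weight model to JSON
#'
#' The on-disk schema is versioned and text-only; [read_weight_model()]
#' restores a model that serializes back bit-identically and produces
#' identical predictions.
#'
#' @param model a `"weight_model"`.
#' @param path output file.
#' @export
write_weight_model <- function(model, path) {
  payload <- list(
    schema = "regvar-weight-model/1",
    discrete = model$discrete,
    curves = lapply(model$curves, function(cv) cv[setdiff(names(cv), "class")]),
    gerp = model$gerp,
    tree = model$tree,
    features = model$features[c("discrete", "continuous")],
    gerp_config = model$features$gerp,
    meta = model$meta
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a serialized weight model
#'
#' @param path file written by [write_weight_model()].
#' @return a `"weight_model"`.
#' @export
read_weight_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "regvar-weight-model/1")) {
    stop("unrecognized weight model schema in ", path)
  }
  curves <- lapply(payload$curves, function(cv) {
    cv <- as.list(cv)
    structure(cv, class = "weight_curve")
  })
  tree <- lapply(payload$tree, unlist)
  structure(
    list(
      discrete = as.data.frame(payload$discrete, stringsAsFactors = FALSE),
      curves = curves,
      gerp = as.list(payload$gerp),
      tree = tree,
      features = list(
        discrete = unlist(payload$features$discrete),
        continuous = unlist(payload$features$continuous),
        tree = tree, gerp = as.list(payload$gerp_config)
      ),
      meta = as.list(payload$meta)
    ),
    class = "weight_model"
  )
}
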