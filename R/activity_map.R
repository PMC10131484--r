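#' Fit a variant activity map from selection-screen counts
#'
#' The central estimator of the package. From per-tile pre/post/control
#' counts it computes background-adjusted frequencies, per-replicate log2
#' enrichments, rescales them per normalization group (region x replicate)
#' so that synonymous variants have median score 1 and nonsense variants
#' median score 0, combines replicates, fits the regression prior for
#' per-variant standard deviations and applies Bayesian regularization, and
#' (optionally) attaches percentile-bootstrap confidence intervals over
#' replicate scores.
#'
#' @param counts count table (`variant`, `tile`, `condition`, `replicate`,
#'   `count`, `depth`), e.g. from [simulate_screen()] or [read_counts()].
#' @param layout region/tile layout from [region_layout()]; taken from the
#'   counts' `layout` attribute when present, else a single normalization
#'   group is used.
#' @param pseudocount frequency pseudocount (default 0.5).
#' @param min_count low-count flag threshold on raw pre-selection reads
#'   (default 10).
#' @param v0 prior degrees of freedom for the variance regularization
#'   (default 3).
#' @param n_boot bootstrap resamples for per-variant CIs (default 1000; 0
#'   disables CIs).
#' @param level CI level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `activity_map`: list with `scores` (one row per
#'   variant: position, consequence, score, `s`, `sigma0`, `sigma`, `n`,
#'   `ci_low`, `ci_high`, flags), `anchors` (per-group rescaling medians),
#'   `prior_fit` (the `lm`), `params`, `call`.
#' @examples
#' truth <- generate_truth(protein_length = 30, mutable_range = c(2, 30))
#' cfg <- screen_config(depth_per_tile = 2e5, n_clones = 2e4, seed = 7)
#' fit <- activity_map(simulate_screen(truth, cfg))
#' fit
#' @export
activity_map <- function(counts, layout = attr(counts, "layout"),
                         pseudocount = 0.5, min_count = 10, v0 = 3,
                         n_boot = 1000L, level = 0.95, seed = 1L) {
  cl <- match.call()
  freq <- compute_frequencies(counts, pseudocount = pseudocount,
                              min_count = min_count)
  freq$phi <- enrichment(freq$f_pre, freq$f_post)
  vf <- variant_fields(freq$variant)
  region <- if (!is.null(layout)) position_tile(vf$position, layout)$region
            else rep(1L, nrow(freq))
  group <- paste(region, freq$replicate, sep = ".")
  flagged <- freq$background_dominated | freq$low_count
  rs <- rescale_scores(freq$phi, vf$consequence, group = group,
                       flagged = flagged)
  freq$score <- as.vector(rs)
  anchors <- attr(rs, "anchors")

  comb <- combine_replicates(freq)
  cvf <- variant_fields(comb$variant)
  comb <- cbind(comb[, setdiff(names(comb), "replicate_scores")], cvf,
                replicate_scores = I(comb$replicate_scores))
  comb$region <- if (!is.null(layout))
    position_tile(comb$position, layout)$region else 1L
  pre_mean <- tapply(freq$pre_count, freq$variant, mean)
  comb$pre_count <- as.vector(pre_mean[comb$variant])

  prior <- fit_prior_sd(comb$score, comb$s, comb$pre_count)
  comb$sigma0 <- prior$sigma0
  comb$sigma <- regularize_variance(comb$s, comb$sigma0, comb$n, v0 = v0)

  if (n_boot > 0) {
    reps <- sort(unique(freq$replicate))
    mat <- matrix(NA_real_, nrow = nrow(comb), ncol = length(reps))
    for (j in seq_along(reps))
      mat[, j] <- vapply(comb$replicate_scores, function(v)
        if (as.character(reps[j]) %in% names(v))
          v[[as.character(reps[j])]] else NA_real_, numeric(1))
    ci <- bootstrap_ci_rows(mat, n_boot = n_boot, level = level,
                            seed = seed)
    comb$ci_low <- ci[, 1]; comb$ci_high <- ci[, 2]
  } else {
    comb$ci_low <- NA_real_; comb$ci_high <- NA_real_
  }
  rownames(comb) <- NULL
  structure(list(scores = comb, anchors = anchors, prior_fit = prior$fit,
                 params = list(pseudocount = pseudocount,
                               min_count = min_count, v0 = v0,
                               n_boot = n_boot, level = level, seed = seed),
                 layout = layout, call = cl),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  s <- x$scores
  cat("Variant activity map\n")
  cat("  variants scored:", nrow(s), "(",
      sum(s$consequence == "missense"), "missense,",
      sum(s$consequence == "nonsense"), "nonsense,",
      sum(s$consequence == "synonymous"), "synonymous )\n")
  cat("  replicates:", max(s$n), " v0 =", x$params$v0, "\n")
  cat("  score range:",
      paste(format(range(s$score, na.rm = TRUE), digits = 3),
            collapse = " .. "), "\n")
  invisible(x)
}

#' @export
summary.activity_map <- function(object, thresholds = c(0.66, 1.18), ...) {
  s <- object$scores
  med <- function(k) stats::median(s$score[s$consequence == k],
                                   na.rm = TRUE)
  cls <- table(assign_class(s$score[s$consequence == "missense" &
                                      is.finite(s$score)], thresholds))
  out <- list(n = nrow(s),
              median_synonymous = med("synonymous"),
              median_nonsense = med("nonsense"),
              median_missense = med("missense"),
              class_counts = cls,
              flagged = sum(s$background_dominated | s$low_count),
              sigma_quartiles = stats::quantile(s$sigma, c(.25, .5, .75),
                                                na.rm = TRUE))
  class(out) <- "summary.activity_map"
  out
}

#' @export
print.summary.activity_map <- function(x, ...) {
  cat("Activity-map summary (", x$n, "variants )\n")
  cat(sprintf("  anchor medians: synonymous %.3f, nonsense %.3f\n",
              x$median_synonymous, x$median_nonsense))
  cat(sprintf("  missense median: %.3f;  flagged variants: %d\n",
              x$median_missense, x$flagged))
  cat("  missense classes:",
      paste(names(x$class_counts), x$class_counts, collapse = ", "), "\n")
  cat("  regularized sd quartiles:",
      paste(format(x$sigma_quartiles, digits = 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.activity_map <- function(object, ...) {
  stats::setNames(object$scores$score, object$scores$variant)
}

#' @export
fitted.activity_map <- function(object, ...) object$scores

#' Heatmap of an activity map
#'
#' Positions on the y axis, the 20 substitutions plus stop and the
#' per-position missense median on the x axis; white = 1 (wild-type-like),
#' dark = 0 (null), blue = above wild type.
#'
#' @param x an `activity_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.activity_map <- function(x, ...) {
  m <- export_heatmap(x$scores)
  pal <- grDevices::colorRampPalette(c("#67001f", "#d6604d", "#ffffff",
                                       "#4393c3"))(64)
  zlim <- c(min(0, min(m, na.rm = TRUE)),
            max(1.5, max(m, na.rm = TRUE)))
  graphics::image(x = seq_len(ncol(m)), y = as.integer(rownames(m)),
                  z = t(m), col = pal, zlim = zlim, xaxt = "n",
                  xlab = "substitution", ylab = "position", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                 cex.axis = 0.6, las = 2)
  invisible(m)
}
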