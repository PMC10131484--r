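#' ROC curve and AUC for a binary variant classification
#'
#' The curve is built over all distinct score cutoffs; the AUC is the
#' trapezoidal area, which for a step curve equals the all-pairs concordance
#' probability (ties counted 1/2). `direction` states which tail carries the
#' positive class: loss-of-function calls use `"lower-is-positive"`,
#' hyperactivity calls `"higher-is-positive"`.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1): `TRUE` = positive class.
#' @param direction `"lower-is-positive"` or `"higher-is-positive"`.
#' @return list of class `roc_result`: `auc`, `curve` (data.frame `cutoff`,
#'   `fpr`, `tpr`), `direction`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels,
                    direction = c("lower-is-positive",
                                  "higher-is-positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need >= 1 positive and 1 negative")
  # orient so that LARGE oriented scores indicate the positive class
  x <- if (direction == "lower-is-positive") -scores else scores

  cuts <- sort(unique(x), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) mean(x[labels] >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(x[!labels] >= c), numeric(1))
  curve <- data.frame(cutoff = c(Inf, cuts), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(cutoff = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve, direction = direction,
                 n_pos = n_pos, n_neg = n_neg, scores = scores,
                 labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC analysis (", x$direction, "): ", x$n_pos, " positives, ",
      x$n_neg, " negatives\n  AUC = ", format(x$auc, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Select a classification threshold from a ROC analysis
#'
#' Candidate cutoffs are the midpoints between adjacent distinct scores
#' (plus open-ended extremes). The default criterion maximizes Youden's
#' J = sensitivity + specificity - 1; `"closest"` minimizes the Euclidean
#' distance to the (0,1) corner. Ties are broken toward higher specificity.
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @param method `"youden"` or `"closest"`.
#' @return list: `threshold` (on the original score scale), `sensitivity`,
#'   `specificity`, `j`, `degenerate` (TRUE when no cutoff beats J = 0).
#' @export
select_threshold <- function(roc, method = c("youden", "closest")) {
  method <- match.arg(method)
  scores <- roc$scores; labels <- roc$labels
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores identical: no threshold exists")
  cand <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  lower_pos <- roc$direction == "lower-is-positive"
  eval_cut <- function(t) {
    call_pos <- if (lower_pos) scores < t else scores > t
    sens <- mean(call_pos[labels])
    spec <- mean(!call_pos[!labels])
    c(sens = sens, spec = spec)
  }
  m <- t(vapply(cand, eval_cut, numeric(2)))
  crit <- if (method == "youden") m[, "sens"] + m[, "spec"] - 1
          else -sqrt((1 - m[, "sens"])^2 + (1 - m[, "spec"])^2)
  best <- which(crit == max(crit))
  best <- best[which.max(m[best, "spec"])]
  list(threshold = unname(cand[best]),
       sensitivity = unname(m[best, "sens"]),
       specificity = unname(m[best, "spec"]),
       j = unname(m[best, "sens"] + m[best, "spec"] - 1),
       degenerate = method == "youden" && max(crit) <= 0)
}

#' Three-way classification of an activity score
#'
#' Scores below `t_low` are called loss-of-function-like (GCK-MODY-like),
#' scores above `t_high` hyperactive-like (HH-like), and everything between
#' (boundaries inclusive) wild-type-like. Both inequalities are strict.
#'
#' @param score numeric scores.
#' @param thresholds `c(t_low, t_high)` with `t_low < t_high`; defaults to
#'   the published clinical thresholds 0.66 and 1.18.
#' @return factor with levels `MODY-like`, `WT-like`, `HH-like`.
#' @examples
#' assign_class(c(0.5, 1.0, 1.3))
#' @export
assign_class <- function(score, thresholds = c(0.66, 1.18)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  if (any(!is.finite(score))) stop("scores must be finite")
  cls <- ifelse(score < thresholds[1], "MODY-like",
         ifelse(score > thresholds[2], "HH-like", "WT-like"))
  factor(cls, levels = c("MODY-like", "WT-like", "HH-like"))
}

#' Allele-frequency consistency check
#'
#' Variants common in the population are expected to be functionally
#' wild-type-like; a common variant with a non-WT-like score is flagged as a
#' quality-control discordance.
#'
#' @param variant variant ids.
#' @param score activity scores.
#' @param allele_frequency population allele frequencies (NA = unknown,
#'   never flagged).
#' @param af_cut frequency above which WT-like function is expected
#'   (default 1e-4).
#' @param thresholds classification thresholds, see [assign_class()].
#' @return data.frame: `variant`, `score`, `allele_frequency`, `class`,
#'   `discordant`.
#' @export
af_consistency <- function(variant, score, allele_frequency,
                           af_cut = 1e-4, thresholds = c(0.66, 1.18)) {
  cls <- assign_class(score, thresholds)
  disc <- !is.na(allele_frequency) & allele_frequency > af_cut &
    cls != "WT-like"
  data.frame(variant = variant, score = score,
             allele_frequency = allele_frequency, class = cls,
             discordant = disc, stringsAsFactors = FALSE)
}
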