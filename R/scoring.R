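# variant-id helpers: ids look like "p.W99R", "p.G261*" or "p.L55=" (synonymous)
variant_fields <- function(id) {
  re <- "^p\\.([A-Z])([0-9]+)([A-Z\\*=])$"
  if (!all(grepl(re, id))) stop("unparseable variant id: ",
                                paste(utils::head(id[!grepl(re, id)], 5),
                                      collapse = ", "))
  wt <- sub(re, "\\1", id)
  alt <- sub(re, "\\3", id)
  data.frame(position = as.integer(sub(re, "\\2", id)), wt_aa = wt,
             alt_aa = ifelse(alt == "=", wt, alt),
             consequence = ifelse(alt == "=", "synonymous",
                           ifelse(alt == "*", "nonsense", "missense")),
             stringsAsFactors = FALSE)
}

#' Background-adjusted variant frequencies
#'
#' Converts per-tile counts into pseudocounted relative frequencies, averages
#' the wild-type-control frequencies across control replicates, and subtracts
#' that background from each pre- and post-selection replicate (floored at
#' `pseudocount / depth`). Variants whose raw pre-selection frequency is
#' within twofold of the control background are flagged
#' `background_dominated` (post-selection depletion to background is real
#' loss-of-function signal and is not flagged); variants with
#' fewer than `min_count` raw pre-selection reads are flagged `low_count`.
#'
#' @param counts count table (`variant`, `tile`, `condition`, `replicate`,
#'   `count`, `depth`), e.g. from [simulate_screen()] or [read_counts()].
#' @param pseudocount added to every count (default 0.5).
#' @param min_count minimum raw pre-selection reads (default 10).
#' @return data.frame with one row per (variant, replicate): adjusted
#'   `f_pre`, `f_post`, raw `pre_count`, `tile`, and logical flag columns.
#' @export
compute_frequencies <- function(counts, pseudocount = 0.5, min_count = 10) {
  stopifnot(all(c("variant", "tile", "condition", "replicate",
                  "count", "depth") %in% names(counts)))
  if (any(counts$depth <= 0)) stop("tile_depth must be positive")
  key <- function(d) paste(d$variant, d$replicate, sep = "\r")

  # pseudocounted frequency, normalized within tile (k = variants per tile)
  k_tile <- tapply(counts$variant, counts$tile,
                   function(v) length(unique(v)))
  k <- as.vector(k_tile[as.character(counts$tile)])
  counts$f <- (counts$count + pseudocount) / (counts$depth + pseudocount * k)

  ctrl <- counts[counts$condition == "control", , drop = FALSE]
  f_ctrl <- if (nrow(ctrl))
    tapply(ctrl$f, ctrl$variant, mean)
  else stats::setNames(numeric(0), character(0))

  pre  <- counts[counts$condition == "pre", , drop = FALSE]
  post <- counts[counts$condition == "post", , drop = FALSE]
  if (!nrow(pre)) stop("no pre-selection counts present")
  m <- match(key(pre), key(post))
  if (anyNA(m)) stop("variants missing a post-selection entry: ",
                     paste(utils::head(pre$variant[is.na(m)], 5),
                           collapse = ", "))
  post <- post[m, , drop = FALSE]

  fc <- as.vector(f_ctrl[pre$variant])
  fc[is.na(fc)] <- 0
  floor_pre  <- pseudocount / pre$depth
  floor_post <- pseudocount / post$depth
  out <- data.frame(
    variant = pre$variant, tile = pre$tile, replicate = pre$replicate,
    pre_count = pre$count,
    f_pre  = pmax(pre$f - fc, floor_pre),
    f_post = pmax(post$f - fc, floor_post),
    background_dominated = pre$f <= 2 * fc,
    low_count = pre$count < min_count,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Log2 enrichment of a variant across selection
#'
#' @param f_pre,f_post background-adjusted frequencies (positive).
#' @return `phi = log2(f_post / f_pre)`; nonpositive inputs give `NA` (the
#'   caller's flags mark these), never silent infinities.
#' @export
enrichment <- function(f_pre, f_post) {
  phi <- ifelse(f_pre > 0 & f_post > 0, log2(f_post / f_pre), NA_real_)
  phi[!is.finite(phi)] <- NA_real_
  phi
}

#' Rescale enrichments to the synonymous/nonsense activity scale
#'
#' Applies the linear map `(phi - median_nonsense) / (median_synonymous -
#' median_nonsense)` so that, within each normalization group, synonymous
#' variants have median score exactly 1 and nonsense variants exactly 0.
#' Medians use unflagged records only.
#'
#' @param phi enrichment values.
#' @param consequence parallel vector (`synonymous`/`missense`/`nonsense`).
#' @param group normalization group (e.g. region x replicate); a single group
#'   when omitted.
#' @param flagged logical; flagged records are excluded from the anchor
#'   medians (but still rescaled).
#' @param min_anchors minimum unflagged synonymous and nonsense records per
#'   group (default 5).
#' @return numeric vector of activity scores; anchor medians are attached as
#'   attribute `anchors`.
#' @export
rescale_scores <- function(phi, consequence, group = NULL, flagged = NULL,
                           min_anchors = 5L) {
  n <- length(phi)
  if (is.null(group)) group <- rep(1L, n)
  if (is.null(flagged)) flagged <- rep(FALSE, n)
  stopifnot(length(consequence) == n, length(group) == n)
  score <- rep(NA_real_, n)
  anchors <- list()
  for (g in unique(group)) {
    i <- group == g
    use <- i & !flagged & !is.na(phi)
    med_syn <- stats::median(phi[use & consequence == "synonymous"])
    med_non <- stats::median(phi[use & consequence == "nonsense"])
    n_syn <- sum(use & consequence == "synonymous")
    n_non <- sum(use & consequence == "nonsense")
    if (n_syn < min_anchors || n_non < min_anchors)
      stop("group ", g, ": need >= ", min_anchors,
           " unflagged synonymous and nonsense records (have ",
           n_syn, "/", n_non, ")")
    if (!(med_syn > med_non))
      stop("group ", g, ": degenerate anchors (synonymous median <= ",
           "nonsense median); selection failed")
    score[i] <- (phi[i] - med_non) / (med_syn - med_non)
    anchors[[as.character(g)]] <- c(median_syn = med_syn,
                                    median_nonsense = med_non)
  }
  structure(score, anchors = anchors)
}

#' Combine per-replicate activity scores
#'
#' @param scores data.frame with columns `variant`, `replicate`, `score`
#'   (plus any flag columns, which are OR-combined).
#' @return one row per variant: `score` (mean), `s` (unbiased sample sd,
#'   `NA` with flag `single_replicate` when n = 1), `n`, replicate scores as
#'   a list column `replicate_scores`.
#' @export
combine_replicates <- function(scores) {
  stopifnot(all(c("variant", "replicate", "score") %in% names(scores)))
  sp <- split(scores, scores$variant)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d$score[!is.na(d$score)]
    n <- length(v)
    data.frame(variant = d$variant[1],
               score = if (n) mean(v) else NA_real_,
               s = if (n >= 2) stats::sd(v) else NA_real_,
               n = n, single_replicate = n < 2,
               background_dominated =
                 if ("background_dominated" %in% names(d))
                   any(d$background_dominated) else FALSE,
               low_count = if ("low_count" %in% names(d))
                   any(d$low_count) else FALSE,
               stringsAsFactors = FALSE)
  }))
  out$replicate_scores <- lapply(sp, function(d)
    stats::setNames(d$score, d$replicate))
  rownames(out) <- NULL
  out
}
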