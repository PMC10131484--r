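#' Construct an MSA object from a character matrix or sequence vector
#'
#' @param seqs character matrix (rows = aligned sequences, cells = residue
#'   or `-`) or a character vector of equal-length aligned strings.
#' @param wt_row row index of the reference (wild-type) sequence.
#' @return list of class `msa`.
#' @export
msa <- function(seqs, wt_row = 1L) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (length(unique(nchar(seqs))) != 1L) stop("unequal row lengths")
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  stopifnot(is.matrix(seqs), wt_row >= 1L, wt_row <= nrow(seqs))
  structure(list(seqs = seqs, wt_row = as.integer(wt_row)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", nrow(x$seqs), "sequences x", ncol(x$seqs),
      "columns (wt_row =", x$wt_row, ")\n")
  invisible(x)
}

#' Filter an alignment to reference columns and low-gap sequences
#'
#' Columns where the reference (wild-type) sequence has a gap are removed
#' first; then sequences whose gap fraction over the remaining columns
#' exceeds 0.5 are removed. The reference row is always retained, and the
#' operation is idempotent.
#'
#' @param x an `msa`.
#' @param max_gap_frac sequence gap-fraction cutoff (default 0.5, strict
#'   inequality removes above it).
#' @return filtered `msa`.
#' @export
filter_msa <- function(x, max_gap_frac = 0.5) {
  stopifnot(inherits(x, "msa"))
  wt <- x$seqs[x$wt_row, ]
  if (all(wt == "-")) stop("reference row is all gaps")
  keep_col <- wt != "-"
  s <- x$seqs[, keep_col, drop = FALSE]
  gap_frac <- rowMeans(s == "-")
  keep_row <- gap_frac <= max_gap_frac
  keep_row[x$wt_row] <- TRUE
  msa(s[keep_row, , drop = FALSE],
      wt_row = match(x$wt_row, which(keep_row)))
}

#' Naive conservation score from amino-acid frequencies
#'
#' A deliberately simple stand-in for tree-aware conservation predictors,
#' intended for testing and synthetic-data work only: for each alignment
#' column, the log ratio of the substitution's frequency to the wild-type
#' residue's frequency, clipped at 0 (wild type scores 0 by definition; a
#' substitution as common as wild type also scores 0; rarer substitutions
#' score increasingly negative).
#'
#' @param x a filtered `msa`.
#' @param pseudocount frequency pseudocount (default 1e-3).
#' @return data.frame `position`, `wt_aa`, `alt_aa`, `deltaE` (<= 0) over
#'   the 19 non-wild-type residues per position.
#' @export
naive_deltaE <- function(x, pseudocount = 1e-3) {
  stopifnot(inherits(x, "msa"))
  if (nrow(x$seqs) == 0L || ncol(x$seqs) == 0L) stop("empty MSA")
  wt <- x$seqs[x$wt_row, ]
  out <- lapply(seq_len(ncol(x$seqs)), function(j) {
    col <- x$seqs[, j]
    col <- col[col != "-"]
    freq <- vapply(AA_ONE, function(a) mean(col == a), numeric(1))
    alt <- setdiff(AA_ONE, wt[j])
    dE <- log((freq[alt] + pseudocount) / (freq[wt[j]] + pseudocount))
    data.frame(position = j, wt_aa = wt[j], alt_aa = alt,
               deltaE = pmin(dE, 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between two paired profiles with bootstrap CI
#'
#' Pearson or Spearman correlation (Spearman via average ranks) with a
#' percentile-bootstrap confidence interval obtained by resampling pairs.
#' Missing values are dropped pairwise; an optional subset rule (logical
#' vector or predicate on the data) restricts the pairs first.
#'
#' @param x,y paired numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param subset optional logical vector selecting pairs.
#' @param n_boot bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list of class `correlation_result`: `method`, `r`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
correlate_profiles <- function(x, y, method = c("pearson", "spearman"),
                               subset = NULL, n_boot = 10000L,
                               level = 0.95, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (!is.null(subset)) { x <- x[subset]; y <- y[subset] }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a profile")
  r <- stats::cor(x, y, method = method)
  set.seed(seed)
  idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                nrow = n_boot)
  rb <- apply(idx, 1L, function(i)
    suppressWarnings(stats::cor(x[i], y[i], method = method)))
  a <- (1 - level) / 2
  q <- stats::quantile(rb, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  structure(list(method = method, r = r, ci_low = q[1], ci_high = q[2],
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
              x$method, x$r, x$ci_low, x$ci_high, x$n))
  invisible(x)
}
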