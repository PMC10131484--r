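#' Convert internal energy units to kcal/mol
#'
#' Structure-based stability predictions arrive in the predictor's internal
#' energy units; dividing by 2.9 converts them to kcal/mol.
#'
#' @param value numeric, internal energy units.
#' @return numeric, kcal/mol.
#' @examples
#' reu_to_kcal(2.9)  # 1
#' @export
reu_to_kcal <- function(value) {
  if (any(!is.finite(value))) stop("non-finite input")
  value / 2.9
}

# normalize one ddg table (variant, conformation, ddg, unit) to kcal/mol
normalize_ddg <- function(tab) {
  stopifnot(all(c("variant", "conformation", "ddg", "unit") %in% names(tab)))
  bad <- !(tab$unit %in% c("kcal_per_mol", "internal_energy_units"))
  if (any(bad)) stop("undeclared ddg unit: ",
                     paste(unique(tab$unit[bad]), collapse = ", "))
  reu <- tab$unit == "internal_energy_units"
  tab$ddg[reu] <- reu_to_kcal(tab$ddg[reu])
  tab$unit <- "kcal_per_mol"
  tab
}

#' Conformational equilibrium-shift score from paired stability tables
#'
#' Joins the closed- and super-open-conformation stability tables on variant
#' and computes `delta_ddg = ddg_superopen - ddg_closed` (kcal/mol). A
#' positive value means the super-open (inactive) conformation is
#' destabilized relative to the closed (active) one, predicting a shift of
#' the conformational equilibrium toward the active state. Variants missing
#' from the super-open table (e.g. the disordered 157-179 loop) receive the
#' verdict `no-data`.
#'
#' Verdicts: `destabilized` when both conformations are destabilized beyond
#' `stable_cut`; `shift-to-closed-candidate` / `shift-to-open` when
#' `|delta_ddg|` exceeds `shift_cut`; otherwise `neutral`.
#'
#' @param closed,superopen data.frames with columns `variant`,
#'   `conformation`, `ddg`, `unit` (units converted internally; must be
#'   declared per table).
#' @param stable_cut kcal/mol bound of the stable band (default 2).
#' @param shift_cut kcal/mol magnitude for a shift verdict (default 0.25).
#' @return data.frame: `variant`, `ddg_closed`, `ddg_superopen`,
#'   `delta_ddg`, `verdict`.
#' @export
delta_ddg <- function(closed, superopen, stable_cut = 2, shift_cut = 0.25) {
  closed <- normalize_ddg(closed); superopen <- normalize_ddg(superopen)
  if (nrow(closed) && nrow(superopen) &&
      any(closed$conformation == superopen$conformation[1]))
    stop("the two tables carry the same conformation label")
  m <- match(closed$variant, superopen$variant)
  out <- data.frame(variant = closed$variant,
                    ddg_closed = closed$ddg,
                    ddg_superopen = superopen$ddg[m],
                    stringsAsFactors = FALSE)
  out$delta_ddg <- out$ddg_superopen - out$ddg_closed
  out$verdict <- ifelse(is.na(out$ddg_superopen), "no-data",
    ifelse(pmin(out$ddg_closed, out$ddg_superopen) >= stable_cut,
           "destabilized",
    ifelse(out$delta_ddg > shift_cut, "shift-to-closed-candidate",
    ifelse(out$delta_ddg < -shift_cut, "shift-to-open", "neutral"))))
  out
}

#' Filter for hyperactive variants shifting the equilibrium toward closed
#'
#' Reproduces the candidate logic for mechanistically interpretable
#' hyperactive variants: activity score above `score_cut`, stable closed
#' conformation (`ddg_closed < stable_cut`), and preferential
#' destabilization of the super-open conformation
#' (`delta_ddg > shift_cut`). All inequalities are strict; variants without
#' super-open data are excluded.
#'
#' @param scores data.frame with `variant`, `score`.
#' @param calls data.frame from [delta_ddg()].
#' @param score_cut,stable_cut,shift_cut thresholds; defaults 1.18, 2 and
#'   0.25 (score units, kcal/mol, kcal/mol).
#' @return data.frame of candidates: `variant`, `score`, `ddg_closed`,
#'   `ddg_superopen`, `delta_ddg`.
#' @export
hyperactive_shift_filter <- function(scores, calls, score_cut = 1.18,
                                     stable_cut = 2, shift_cut = 0.25) {
  stopifnot(all(c("variant", "score") %in% names(scores)))
  m <- match(calls$variant, scores$variant)
  d <- cbind(calls, score = scores$score[m])
  keep <- !is.na(d$score) & !is.na(d$delta_ddg) &
    d$score > score_cut & d$ddg_closed < stable_cut &
    d$delta_ddg > shift_cut
  out <- d[keep, c("variant", "score", "ddg_closed", "ddg_superopen",
                   "delta_ddg")]
  rownames(out) <- NULL
  out
}

#' Per-position medians over missense substitutions
#'
#' Median of each position's available missense values (up to 19
#' substitutions); positions with no values are `NA` and flagged.
#'
#' @param position integer positions.
#' @param value numeric values (activity scores, ddg, ...).
#' @param consequence optional; when given, only `missense` rows enter the
#'   median.
#' @param positions positions to report (default: those observed).
#' @return data.frame `position`, `median`, `n`, `all_missing`.
#' @export
position_median <- function(position, value, consequence = NULL,
                            positions = NULL) {
  if (!is.null(consequence)) {
    keep <- consequence == "missense"
    position <- position[keep]; value <- value[keep]
  }
  if (is.null(positions)) positions <- sort(unique(position))
  med <- vapply(positions, function(p) {
    v <- value[position == p & !is.na(value)]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  n <- vapply(positions, function(p)
    sum(position == p & !is.na(value)), integer(1))
  data.frame(position = positions, median = med, n = n,
             all_missing = n == 0L)
}
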