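CONDITIONS <- c("pre", "post", "control")

#' Read / write a variant count table
#'
#' Tab-separated with header `variant, tile, condition, replicate, count,
#' depth`. Reading validates conditions, count ranges and key uniqueness and
#' reports every offending row.
#'
#' @param path file path.
#' @param counts count table (for the writer).
#' @return the count table (reader) or `path` invisibly (writer).
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("variant", "tile", "condition", "replicate", "count", "depth")
  if (!all(need %in% names(d)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  bad_cond <- !(d$condition %in% CONDITIONS)
  if (any(bad_cond))
    stop("unknown condition in rows: ",
         paste(utils::head(which(bad_cond), 10), collapse = ", "))
  bad_cnt <- d$count < 0 | d$count > d$depth
  if (any(bad_cnt))
    stop("count out of [0, depth] in rows: ",
         paste(utils::head(which(bad_cnt), 10), collapse = ", "))
  key <- paste(d$variant, d$condition, d$replicate)
  if (anyDuplicated(key))
    stop("duplicate (variant, condition, replicate) keys: ",
         paste(utils::head(unique(key[duplicated(key)]), 5),
               collapse = "; "))
  d
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  need <- c("variant", "tile", "condition", "replicate", "count", "depth")
  stopifnot(all(need %in% names(counts)))
  utils::write.table(counts[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a scoreset file
#'
#' CSV in the deposition dialect: variants in three-letter protein notation
#' with `Ter` for stop (`p.Trp99Arg`), fixed column order `hgvs_pro, score,
#' sd, se, ci_low, ci_high, n, flags`, floats at 6 significant digits. The
#' in-memory canonical form stays one-letter; conversion is centralized
#' here.
#'
#' @param scores finalized score table: needs `variant`, `score`, `s`,
#'   `sigma`, `n` (plus optional `ci_low`, `ci_high` and flag columns).
#' @param path file path.
#' @return `path` invisibly (writer); a score data.frame with one-letter
#'   `variant` column (reader).
#' @export
write_scoreset <- function(scores, path) {
  need <- c("variant", "score", "s", "sigma", "n")
  if (!all(need %in% names(scores)))
    stop("scores not finalized: need columns ", paste(need, collapse = ", "))
  vf <- variant_fields(scores$variant)
  syn <- vf$consequence == "synonymous"
  hgvs <- ifelse(syn, paste0("p.", aa_three(vf$wt_aa), vf$position, "="),
                 format_variant(vf$position, vf$wt_aa, vf$alt_aa,
                                three = TRUE))
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6),
                                                    format = "g",
                                                    digits = 6))
  flags <- character(nrow(scores))
  for (fc in intersect(c("single_replicate", "background_dominated",
                         "low_count"), names(scores))) {
    on <- !is.na(scores[[fc]]) & scores[[fc]]
    flags[on] <- ifelse(nchar(flags[on]), paste(flags[on], fc, sep = ";"),
                        fc)
  }
  out <- data.frame(hgvs_pro = hgvs, score = fmt(scores$score),
                    sd = fmt(scores$sigma), se = fmt(scores$sigma /
                                                       sqrt(scores$n)),
                    ci_low = fmt(scores$ci_low %||% rep(NA_real_,
                                                        nrow(scores))),
                    ci_high = fmt(scores$ci_high %||% rep(NA_real_,
                                                          nrow(scores))),
                    n = scores$n, flags = flags,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_scoreset
#' @export
read_scoreset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  pv <- parse_variant(d$hgvs_pro)
  d$variant <- ifelse(pv$consequence == "synonymous",
                      paste0("p.", pv$wt_aa, pv$position, "="),
                      format_variant(pv$position, pv$wt_aa, pv$alt_aa))
  for (col in c("score", "sd", "se", "ci_low", "ci_high"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  d
}

#' Score heatmap matrix (positions x substitutions)
#'
#' Rows are positions 2..L, columns the 20 amino acids, stop (`*`) and a
#' per-position missense median (`MED`). Unobserved cells are `NA`; the
#' wild-type cell of each row is marked in the attached logical attribute
#' `wt_mask`.
#'
#' @param scores table with `variant` and `score` columns (missense,
#'   nonsense; synonymous records are ignored for the matrix).
#' @param protein_length protein length (default: max observed position).
#' @param reference optional reference protein sequence for wild-type
#'   marking at unobserved positions.
#' @return numeric matrix `(L-1) x 22` with attribute `wt_mask`.
#' @export
export_heatmap <- function(scores, protein_length = NULL, reference = NULL) {
  vf <- variant_fields(scores$variant)
  keep <- vf$consequence != "synonymous"
  vf <- vf[keep, , drop = FALSE]
  sc <- scores$score[keep]
  if (is.null(protein_length)) protein_length <- max(vf$position)
  if (any(vf$position < 2 | vf$position > protein_length))
    stop("position outside 2..protein_length")
  pos <- seq.int(2L, protein_length)
  cols <- c(AA_ONE, "*", "MED")
  m <- matrix(NA_real_, nrow = length(pos), ncol = length(cols),
              dimnames = list(pos, cols))
  m[cbind(match(vf$position, pos), match(vf$alt_aa, cols))] <- sc
  med <- position_median(vf$position, sc,
                         consequence = vf$consequence, positions = pos)
  m[, "MED"] <- med$median
  wt_mask <- matrix(FALSE, nrow = length(pos), ncol = length(cols),
                    dimnames = dimnames(m))
  wt_by_pos <- tapply(vf$wt_aa, vf$position, function(x) x[1])
  if (!is.null(reference)) {
    ref <- strsplit(reference, "")[[1]]
    wt_by_pos <- stats::setNames(ref[pos], pos)
  }
  have <- names(wt_by_pos)[!is.na(wt_by_pos)]
  wt_mask[cbind(match(as.integer(have), pos),
                match(wt_by_pos[have], cols))] <- TRUE
  attr(m, "wt_mask") <- wt_mask
  m
}

#' Write per-residue values into a PDB B-factor column
#'
#' Every atom of a residue receives that residue's value, rendered with two
#' decimals per fixed-width PDB rules; residues without a value get 0.00 and
#' are reported in a message. Residue numbering in the coordinate file must
#' match the protein positions.
#'
#' @param pdb_in input PDB path.
#' @param values named numeric vector (names = residue numbers) or
#'   data.frame with `position` and `value`.
#' @param pdb_out output path.
#' @param chain optional chain id; required when the file has several
#'   chains.
#' @return `pdb_out` invisibly.
#' @export
annotate_structure <- function(pdb_in, values, pdb_out, chain = NULL) {
  if (is.data.frame(values))
    values <- stats::setNames(values$value, values$position)
  if (any(!is.finite(values))) stop("values must be finite")
  pdb <- bio3d::read.pdb(pdb_in)
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (length(chains) > 1L) {
    if (is.null(chain)) stop("several chains present (",
                             paste(chains, collapse = ", "),
                             "): specify `chain`")
    sel <- atoms$chain == chain
  } else sel <- rep(TRUE, nrow(atoms))
  resno <- atoms$resno
  matched <- sel & as.character(resno) %in% names(values)
  if (!any(matched)) stop("no residues matched the value table")
  b <- atoms$b
  b[sel] <- 0
  b[matched] <- unname(values[as.character(resno[matched])])
  b <- round(b, 2)
  missing_res <- setdiff(unique(resno[sel]),
                         as.integer(names(values)))
  if (length(missing_res))
    message("residues without values (B = 0.00): ",
            paste(missing_res, collapse = ", "))
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = pdb_out)
  invisible(pdb_out)
}

#' Read / write an aligned FASTA multiple sequence alignment
#'
#' @param x an `msa` (writer).
#' @param path file path.
#' @param wt_row reference row after reading (default 1, the first record).
#' @return an `msa` (reader) or `path` invisibly (writer).
#' @export
read_msa <- function(path, wt_row = 1L) {
  aln <- Biostrings::readAAStringSet(path)
  msa(as.character(aln), wt_row = wt_row)
}

#' @rdname read_msa
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  seqs <- apply(x$seqs, 1L, paste, collapse = "")
  names(seqs) <- if (!is.null(rownames(x$seqs))) rownames(x$seqs)
                 else sprintf("seq%04d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a per-conformation stability table
#'
#' CSV with columns `variant, conformation, value, unit`; values are
#' converted to kcal/mol on read when declared in internal energy units.
#'
#' @param path file path.
#' @return data.frame `variant`, `conformation`, `ddg`, `unit`
#'   (kcal/mol).
#' @export
read_ddg <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant", "conformation", "value", "unit")
  if (!all(need %in% names(d)))
    stop("ddg table must have columns: ", paste(need, collapse = ", "))
  names(d)[names(d) == "value"] <- "ddg"
  normalize_ddg(d)
}
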