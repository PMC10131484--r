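# Canonical amino-acid alphabet: 20 standard residues, '*' for stop.
AA_ONE <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
            "P","S","T","W","Y","V")

# one-letter -> three-letter map (stop rendered "Ter" on output, per MaveDB usage)
aa_three <- function(one) {
  out <- ifelse(one == "*", "Ter", unname(Biostrings::AMINO_ACID_CODE[one]))
  if (anyNA(out)) stop("unknown amino-acid code: ",
                       paste(one[is.na(out)], collapse = ", "))
  out
}

aa_one <- function(three) {
  map <- c(stats::setNames(names(Biostrings::AMINO_ACID_CODE),
                           Biostrings::AMINO_ACID_CODE),
           Ter = "*", `*` = "*")
  out <- unname(map[three])
  if (anyNA(out)) stop("unknown amino-acid code: ",
                       paste(three[is.na(out)], collapse = ", "))
  out
}

#' Parse a protein-variant string
#'
#' Accepts `p.`-prefixed substitution strings in one-letter (`p.W99R`) or
#' three-letter (`p.Trp99Arg`) form; the stop residue may be written `*` or
#' `Ter`. Returns the normalized one-letter representation used throughout
#' the package.
#'
#' @param text character vector of variant strings.
#' @param reference optional reference protein sequence (single string); when
#'   supplied the wild-type residue of each variant is checked against it.
#' @return A data.frame with columns `position`, `wt_aa`, `alt_aa`,
#'   `consequence` (one of `synonymous`, `missense`, `nonsense`).
#' @examples
#' parse_variant("p.W99R")
#' parse_variant("p.Asp205His")
#' @export
parse_variant <- function(text, reference = NULL) {
  stopifnot(is.character(text), length(text) >= 1L)
  re <- "^p\\.([A-Za-z\\*]{1,3})([0-9]+)([A-Za-z\\*=]{1,3})$"
  ok <- grepl(re, text)
  if (!all(ok)) stop("malformed variant string: ",
                     paste(text[!ok], collapse = ", "))
  wt  <- sub(re, "\\1", text)
  pos <- as.integer(sub(re, "\\2", text))
  alt <- sub(re, "\\3", text)
  norm <- function(x, wt1 = NULL) {
    vapply(seq_along(x), function(i) {
      xi <- x[i]
      if (xi == "=") return(wt1[i])            # synonymous shorthand p.Trp99=
      if (nchar(xi) == 1L) {
        xi <- toupper(xi)
        if (!(xi %in% c(AA_ONE, "*"))) stop("unknown amino acid: ", xi)
        xi
      } else aa_one(paste0(toupper(substr(xi, 1, 1)),
                           tolower(substr(xi, 2, nchar(xi)))))
    }, character(1))
  }
  wt1  <- norm(wt)
  alt1 <- norm(alt, wt1)
  if (any(wt1 == "*")) stop("wild-type residue cannot be a stop")
  if (!is.null(reference)) {
    ref <- strsplit(reference, "")[[1]]
    bad <- pos > length(ref) | ref[pmin(pos, length(ref))] != wt1
    if (any(bad)) stop("reference mismatch at: ",
                       paste(text[bad], collapse = ", "))
  }
  cons <- ifelse(alt1 == "*", "nonsense",
                 ifelse(alt1 == wt1, "synonymous", "missense"))
  data.frame(position = pos, wt_aa = wt1, alt_aa = alt1,
             consequence = cons, stringsAsFactors = FALSE)
}

#' Format a variant in one-letter or three-letter protein notation
#'
#' @param position,wt_aa,alt_aa parallel vectors describing substitutions.
#' @param three use three-letter codes with `Ter` for stop (the on-disk
#'   scoreset dialect); default `FALSE` gives the canonical one-letter form.
#' @return character vector of `p.`-prefixed variant strings.
#' @export
format_variant <- function(position, wt_aa, alt_aa, three = FALSE) {
  if (three) paste0("p.", aa_three(wt_aa), position, aa_three(alt_aa))
  else       paste0("p.", wt_aa, position, alt_aa)
}

#' Enumerate the complete single-substitution variant space
#'
#' Every mutable position contributes the 19 missense substitutions plus one
#' nonsense variant: 20 per position. Position 1 (the initiator methionine)
#' is immutable.
#'
#' @param protein_length total residue count of the protein.
#' @param mutable_range integer vector `c(first, last)` of mutable positions;
#'   default positions 2 to `protein_length`.
#' @param reference optional reference sequence used to fill `wt_aa`; when
#'   absent a poly-alanine placeholder is used beyond sequence information.
#' @return data.frame of variants (`position`, `wt_aa`, `alt_aa`,
#'   `consequence`).
#' @examples
#' nrow(enumerate_variant_space(465))  # 9280
#' @export
enumerate_variant_space <- function(protein_length,
                                    mutable_range = c(2L, protein_length),
                                    reference = NULL) {
  stopifnot(protein_length >= 2)
  if (length(mutable_range) != 2L || mutable_range[1] > mutable_range[2]) {
    if (length(mutable_range) == 2L && mutable_range[1] > mutable_range[2])
      return(data.frame(position = integer(), wt_aa = character(),
                        alt_aa = character(), consequence = character()))
    stop("mutable_range must be c(first, last)")
  }
  if (mutable_range[1] < 2) stop("position 1 (initiator Met) is immutable")
  if (mutable_range[2] > protein_length) stop("range exceeds protein length")
  pos <- seq.int(mutable_range[1], mutable_range[2])
  ref <- if (is.null(reference)) rep("A", protein_length)
         else strsplit(reference, "")[[1]]
  out <- do.call(rbind, lapply(pos, function(p) {
    wt <- ref[p]
    alt <- c(setdiff(AA_ONE, wt), "*")
    data.frame(position = p, wt_aa = wt, alt_aa = alt,
               consequence = ifelse(alt == "*", "nonsense", "missense"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify a codon change as synonymous, missense or nonsense
#'
#' @param ref_codon,alt_codon 3-letter DNA codons over A/C/G/T.
#' @return character vector of consequences.
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  stopifnot(length(ref_codon) == length(alt_codon))
  tr <- function(x) unname(Biostrings::GENETIC_CODE[toupper(x)])
  ra <- tr(ref_codon); aa <- tr(alt_codon)
  if (anyNA(ra) || anyNA(aa)) stop("invalid codon")
  if (any(ra == "*")) stop("reference codon is a stop codon")
  if (any(ref_codon == alt_codon)) stop("ref and alt codons are identical")
  ifelse(aa == "*", "nonsense", ifelse(aa == ra, "synonymous", "missense"))
}

# The 32 NNK codons: N = A/C/G/T at positions 1-2, K = G/T at position 3.
nnk_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), c("G", "T"), paste0))
}

#' Consequence spectrum of NNK codon randomization at one codon
#'
#' An NNK degenerate codon draws uniformly over the 32 codons with G or T in
#' the third position (all 20 amino acids reachable; TAG the single stop).
#'
#' @param ref_codon the wild-type codon being randomized (non-stop).
#' @return list with `consequences` (probabilities over wt-codon /
#'   synonymous / missense / nonsense, summing to 1) and `alt_aa`
#'   (probability of each resulting residue, stop as `*`).
#' @export
nnk_spectrum <- function(ref_codon) {
  stopifnot(length(ref_codon) == 1L)
  ref_aa <- unname(Biostrings::GENETIC_CODE[toupper(ref_codon)])
  if (is.na(ref_aa)) stop("invalid codon")
  if (ref_aa == "*") stop("reference codon is a stop codon")
  cods <- nnk_codons()
  aas  <- unname(Biostrings::GENETIC_CODE[cods])
  cls  <- ifelse(cods == toupper(ref_codon), "wt-codon",
          ifelse(aas == "*", "nonsense",
          ifelse(aas == ref_aa, "synonymous", "missense")))
  p <- rep(1 / length(cods), length(cods))
  cons <- vapply(c("wt-codon", "synonymous", "missense", "nonsense"),
                 function(k) sum(p[cls == k]), numeric(1))
  list(consequences = cons,
       alt_aa = vapply(split(p, aas), sum, numeric(1)),
       codons = stats::setNames(aas, cods))
}

#' Default region and tile layout for a three-region mutagenesis design
#'
#' Regions partition positions 2..L (defaults 2-171 / 172-337 / 338-465);
#' each region's codons are split into contiguous tiles (defaults 5/5/4,
#' fourteen tiles in total). Tile coordinates are ORF-nucleotide intervals.
#'
#' @param protein_length protein length in residues (default 465).
#' @param region_bounds integer matrix or list of `c(aa_start, aa_end)`.
#' @param tiles_per_region integer vector, tiles per region.
#' @return list with `regions` (data.frame region_id, aa_start, aa_end) and
#'   `tiles` (data.frame tile_id, region_id, aa_start, aa_end, nt_start,
#'   nt_end).
#' @export
region_layout <- function(protein_length = 465L,
                          region_bounds = NULL,
                          tiles_per_region = NULL) {
  if (is.null(region_bounds)) {
    if (protein_length == 465L) {
      region_bounds <- list(c(2L, 171L), c(172L, 337L), c(338L, 465L))
    } else if (protein_length >= 7L) {
      # three near-equal regions for non-canonical lengths
      cuts <- round(seq(2L, protein_length + 1L, length.out = 4L))
      region_bounds <- lapply(1:3, function(i)
        c(cuts[i], cuts[i + 1L] - 1L))
    } else region_bounds <- list(c(2L, protein_length))
  }
  if (is.null(tiles_per_region)) {
    if (protein_length == 465L && length(region_bounds) == 3L)
      tiles_per_region <- c(5L, 5L, 4L)
    else   # aim at tiles of <= ~35 codons (~105 nt)
      tiles_per_region <- vapply(region_bounds, function(b)
        as.integer(max(1, ceiling((b[2] - b[1] + 1) / 35))), integer(1))
  }
  stopifnot(length(region_bounds) == length(tiles_per_region))
  regions <- do.call(rbind, lapply(seq_along(region_bounds), function(i)
    data.frame(region_id = i, aa_start = region_bounds[[i]][1],
               aa_end = region_bounds[[i]][2])))
  if (regions$aa_start[1] != 2 ||
      any(regions$aa_start[-1] != utils::head(regions$aa_end, -1) + 1) ||
      regions$aa_end[nrow(regions)] != protein_length)
    stop("regions must partition positions 2..protein_length")
  tid <- 0L
  tiles <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    aa <- seq.int(regions$aa_start[i], regions$aa_end[i])
    grp <- ceiling(seq_along(aa) / (length(aa) / tiles_per_region[i]))
    cut <- split(aa, pmin(grp, tiles_per_region[i]))
    do.call(rbind, lapply(cut, function(p) {
      tid <<- tid + 1L
      data.frame(tile_id = tid, region_id = i,
                 aa_start = min(p), aa_end = max(p),
                 nt_start = (min(p) - 1L) * 3L + 1L, nt_end = max(p) * 3L)
    }))
  }))
  rownames(tiles) <- NULL
  list(regions = regions, tiles = tiles)
}

# map residue positions to tile / region ids under a layout
position_tile <- function(position, layout) {
  t <- layout$tiles
  idx <- vapply(position, function(p) {
    w <- which(t$aa_start <= p & p <= t$aa_end)
    if (length(w) != 1L) NA_integer_ else w
  }, integer(1))
  if (anyNA(idx)) stop("position outside tile layout: ",
                       paste(position[is.na(idx)], collapse = ", "))
  data.frame(tile = t$tile_id[idx], region = t$region_id[idx])
}

#' Convert a weight/volume percentage to millimolar concentration
#'
#' Used for the selection medium: 0.2% (w/v) glucose with molar mass
#' 180.16 g/mol is 11.1 mM.
#'
#' @param percent_wv concentration in percent weight/volume (g per 100 mL).
#' @param molar_mass molar mass in g/mol (default anhydrous D-glucose).
#' @return concentration in mM.
#' @examples
#' round(percent_wv_to_mM(0.2), 1)  # 11.1
#' @export
percent_wv_to_mM <- function(percent_wv, molar_mass = 180.16) {
  stopifnot(percent_wv >= 0, molar_mass > 0)
  percent_wv * 10 / molar_mass * 1000
}
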