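# Thermodynamic constants of the two-state-plus-unfolded occupancy model.
# Free energies are relative to the unfolded reference state at 0 kcal/mol;
# RT at 25 C in kcal/mol.
DEFAULT_TRUTH_PARAMS <- list(
  dG_closed_wt    = -2.0,
  dG_superopen_wt = -3.0,
  RT              = 0.593,
  # mixture over mechanistic effect classes for missense variants
  class_probs = c(neutral = 0.30, destabilizing = 0.35,
                  shift_to_open = 0.10, shift_to_closed = 0.10,
                  catalytic = 0.15)
)

# closed-state occupancy: P_closed = exp(-G_C/RT) / (1 + exp(-G_C/RT) + exp(-G_SO/RT))
p_closed <- function(dG_closed, dG_superopen, RT = 0.593) {
  ec <- exp(-dG_closed / RT)
  eo <- exp(-dG_superopen / RT)
  ec / (1 + ec + eo)
}

#' Closed-conformation occupancy ratio under free-energy perturbations
#'
#' Evaluates the Boltzmann occupancy model linking per-conformation stability
#' changes to enzymatic activity: the enzyme is active only in the closed
#' conformation, and a variant's activity relative to wild type is the ratio
#' of closed-state occupancies (times any catalytic-efficiency factor).
#'
#' @param ddg_closed,ddg_superopen perturbations in kcal/mol (positive =
#'   destabilizing) applied to the wild-type conformational free energies.
#' @param params list with `dG_closed_wt`, `dG_superopen_wt`, `RT`.
#' @return occupancy ratio `P_closed(mut) / P_closed(wt)`.
#' @export
occupancy_ratio <- function(ddg_closed, ddg_superopen,
                            params = DEFAULT_TRUTH_PARAMS) {
  if (!all(is.finite(c(ddg_closed, ddg_superopen,
                       params$dG_closed_wt, params$dG_superopen_wt,
                       params$RT))))
    stop("non-finite thermodynamic parameters")
  p_closed(params$dG_closed_wt + ddg_closed,
           params$dG_superopen_wt + ddg_superopen, params$RT) /
    p_closed(params$dG_closed_wt, params$dG_superopen_wt, params$RT)
}

# deterministic synthetic ORF: random sense codons (no internal stops),
# ATG initiator; returns vector of codons with attr "protein"
synthetic_orf <- function(protein_length, seed = 1L) {
  set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- c("ATG", sample(setdiff(sense, "ATG"), protein_length - 1L,
                            replace = TRUE))
  structure(codons,
            protein = paste(unname(Biostrings::GENETIC_CODE[codons]),
                            collapse = ""))
}

#' Generate ground-truth variant activities under the occupancy model
#'
#' Assigns every missense variant a mechanistic effect class (neutral,
#' globally destabilizing, shift-to-open, shift-to-closed, catalytically
#' impaired), draws per-conformation stability perturbations accordingly, and
#' derives the true activity as
#' `cat_factor * P_closed(mut) / P_closed(wt)` under the Boltzmann occupancy
#' model. Nonsense variants have activity 0; synonymous variants are defined
#' to have activity exactly 1 and are not enumerated here.
#'
#' @param protein_length residues (default 465).
#' @param mutable_range `c(first, last)` mutable positions (default 2..L).
#' @param model_params thermodynamic and mixture parameters; see
#'   `DEFAULT_TRUTH_PARAMS`.
#' @param seed integer RNG seed.
#' @param orf_seed seed for the deterministic synthetic ORF backbone.
#' @return data.frame (one row per missense/nonsense variant) with columns
#'   `variant`, `position`, `wt_aa`, `alt_aa`, `consequence`, `class_label`,
#'   `ddg_closed`, `ddg_superopen`, `cat_factor`, `true_activity`; the ORF
#'   codons and reference protein are attached as attributes `orf` and
#'   `protein`.
#' @export
generate_truth <- function(protein_length = 465L,
                           mutable_range = c(2L, protein_length),
                           model_params = DEFAULT_TRUTH_PARAMS,
                           seed = 1L, orf_seed = 1L) {
  params <- utils::modifyList(DEFAULT_TRUTH_PARAMS, model_params)
  orf <- synthetic_orf(protein_length, orf_seed)
  prot <- attr(orf, "protein")
  vs <- enumerate_variant_space(protein_length, mutable_range, reference = prot)
  set.seed(seed)
  n <- nrow(vs)
  mis <- vs$consequence == "missense"
  cls <- rep("nonsense", n)
  cls[mis] <- sample(names(params$class_probs), sum(mis), replace = TRUE,
                     prob = params$class_probs)

  ddg_c <- numeric(n); ddg_o <- numeric(n); cat_f <- rep(1, n)
  # effect scales are deliberately modest: the occupancy model amplifies
  # free-energy changes (0.3 kcal/mol already shifts occupancy ~2-fold), and
  # the measured map spans scores ~0..1.5 with little mass beyond
  draw <- function(k, what) {
    switch(what,
      neutral = list(c = stats::rnorm(k, 0, 0.15),
                     o = stats::rnorm(k, 0, 0.15), f = rep(1, k)),
      destabilizing = {
        base <- 0.25 + stats::rgamma(k, shape = 2, scale = 1.25)
        list(c = base + stats::rnorm(k, 0, 0.2),
             o = base + stats::rnorm(k, 0, 0.2), f = rep(1, k))
      },
      shift_to_open = list(c = 0.25 + stats::rgamma(k, shape = 2,
                                                    scale = 0.6),
                           o = stats::rnorm(k, 0, 0.15), f = rep(1, k)),
      shift_to_closed = list(c = stats::rnorm(k, 0, 0.15),
                             o = 0.1 + stats::rgamma(k, shape = 2,
                                                     scale = 0.3),
                             f = rep(1, k)),
      catalytic = list(c = stats::rnorm(k, 0, 0.15),
                       o = stats::rnorm(k, 0, 0.15),
                       f = stats::runif(k, 0, 0.05)))
  }
  for (what in names(params$class_probs)) {
    idx <- which(cls == what)
    if (!length(idx)) next
    d <- draw(length(idx), what)
    ddg_c[idx] <- d$c; ddg_o[idx] <- d$o; cat_f[idx] <- d$f
  }
  act <- cat_f * occupancy_ratio(ddg_c, ddg_o, params)
  act[!mis] <- 0                       # nonsense: no functional protein
  ddg_c[!mis] <- NA_real_; ddg_o[!mis] <- NA_real_; cat_f[!mis] <- NA_real_

  label <- rep(NA_character_, n)
  label[mis] <- c(neutral = "benign-like", destabilizing = "MODY-like",
                  shift_to_open = "MODY-like", shift_to_closed = "HH-like",
                  catalytic = "MODY-like")[cls[mis]]

  out <- data.frame(
    variant = format_variant(vs$position, vs$wt_aa, vs$alt_aa),
    vs, class_label = label,
    ddg_closed = ddg_c, ddg_superopen = ddg_o,
    cat_factor = cat_f, true_activity = act,
    stringsAsFactors = FALSE)
  attr(out, "orf") <- as.character(orf)
  attr(out, "protein") <- prot
  attr(out, "params") <- params
  out
}

#' Screen-simulation configuration
#'
#' Defaults mirror the experimental design: Poisson mutational load of 0.35
#' per mutagenized region, two biological replicates, two million reads per
#' tile and condition, ten wild-type doublings during the glucose selection,
#' a flat 1e-3 per-base miscall background, and growth response capped at
#' 1.5x wild-type activity.
#'
#' @param lambda_mut mean mutations per clone per region.
#' @param depth_per_tile reads per tile per condition and replicate.
#' @param n_replicates biological replicates (>= 2).
#' @param generations_wt doublings of a wild-type clone during selection.
#' @param base_error_rate per-base miscall probability.
#' @param a_cap activity value above which growth no longer increases.
#' @param n_clones clones per regional library.
#' @param seed integer RNG seed.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(lambda_mut = 0.35, depth_per_tile = 2e6,
                          n_replicates = 2L, generations_wt = 10,
                          base_error_rate = 1e-3, a_cap = 1.5,
                          n_clones = 2e5, seed = 1L) {
  if (lambda_mut < 0) stop("lambda_mut must be nonnegative")
  if (base_error_rate < 0 || base_error_rate > 0.1)
    stop("base_error_rate out of range")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  structure(list(lambda_mut = lambda_mut, depth_per_tile = depth_per_tile,
                 n_replicates = as.integer(n_replicates),
                 generations_wt = generations_wt,
                 base_error_rate = base_error_rate, a_cap = a_cap,
                 n_clones = as.integer(n_clones), seed = as.integer(seed)),
            class = "screen_config")
}

# single-nucleotide neighbours of a codon, with aa-level variant ids;
# used for the sequencing-error background
snv_neighbours <- function(position, ref_codon) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  for (i in 1:3) for (b in setdiff(bases, substr(ref_codon, i, i))) {
    alt <- ref_codon
    substr(alt, i, i) <- b
    aa <- unname(Biostrings::GENETIC_CODE[alt])
    id <- if (aa == ref_aa) paste0("p.", ref_aa, position, "=")
          else paste0("p.", ref_aa, position, aa)
    out[[length(out) + 1L]] <- id
  }
  unlist(out)
}

#' Simulate a growth-selection screen from ground truth
#'
#' Builds per-region clone libraries (Poisson mutational load, NNK alternate
#' codons), grows them deterministically for `generations_wt` wild-type
#' doublings with growth rate proportional to `min(activity, a_cap)`, and
#' samples pre-selection, post-selection and wild-type-control sequencing
#' counts per tile by multinomial draws at the configured depth. A flat
#' per-base miscall background is overlaid on every condition; the control
#' condition contains only that background. Reads whose tile carries two or
#' more amino-acid changes are tallied separately and excluded from
#' per-variant counts, as a tile-based caller would do.
#'
#' @param truth ground-truth table from [generate_truth()].
#' @param cfg a [screen_config()].
#' @return data.frame with columns `variant`, `tile`, `condition`
#'   (`pre`/`post`/`control`), `replicate`, `count`, `depth`. Per-tile read
#'   accounting (wild-type-like and excluded multi-mutant reads) is attached
#'   as attribute `accounting`; the tile layout as attribute `layout`.
#' @export
simulate_screen <- function(truth, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  orf <- attr(truth, "orf")
  if (is.null(orf)) stop("truth must carry its ORF (generate_truth output)")
  protein_length <- length(orf)
  layout <- region_layout(protein_length)
  set.seed(cfg$seed)
  if (cfg$depth_per_tile == 0)
    return(structure(data.frame(variant = character(), tile = integer(),
                                condition = character(), replicate = integer(),
                                count = integer(), depth = integer()),
                     layout = layout))

  act_lookup <- stats::setNames(truth$true_activity, truth$variant)
  nnk <- nnk_codons()

  # --- clone libraries, one per region --------------------------------------
  mut_tables <- lapply(seq_len(nrow(layout$regions)), function(r) {
    aa_lo <- layout$regions$aa_start[r]; aa_hi <- layout$regions$aa_end[r]
    m <- stats::rpois(cfg$n_clones, cfg$lambda_mut)
    M <- sum(m)
    if (M == 0L)
      return(structure(data.frame(region = integer(), clone = integer(),
                                  position = integer(),
                                  var_id = character(),
                                  activity = numeric(),
                                  stringsAsFactors = FALSE),
                       frac_mutation_free = 1))
    clone <- rep.int(seq_len(cfg$n_clones), m)
    pos <- sample(seq.int(aa_lo, aa_hi), M, replace = TRUE)
    ref <- orf[pos]
    # uniform over NNK codons other than the reference codon
    alt <- vapply(ref, function(rc) sample(setdiff(nnk, rc), 1L), character(1))
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt])
    id <- ifelse(alt_aa == ref_aa, paste0("p.", ref_aa, pos, "="),
                 paste0("p.", ref_aa, pos, alt_aa))
    act <- ifelse(alt_aa == ref_aa, 1, unname(act_lookup[id]))
    structure(data.frame(region = r, clone = clone, position = pos,
                         var_id = id, activity = act,
                         stringsAsFactors = FALSE),
              frac_mutation_free = mean(m == 0L))
  })

  # --- per-tile sequencing-error background ---------------------------------
  # tiles are read on both strands and a variant is called only when the two
  # reads agree, so a false call of a specific single-base change needs the
  # same miscall twice: probability (e/3)^2 per base position
  err_call <- (cfg$base_error_rate / 3)^2
  err_bg <- lapply(seq_len(nrow(layout$tiles)), function(t) {
    aa <- seq.int(layout$tiles$aa_start[t], layout$tiles$aa_end[t])
    ids <- unlist(lapply(aa, function(p) snv_neighbours(p, orf[p])))
    p <- rep(err_call, length(ids))
    tapply(p, ids, sum)
  })

  rows <- list()
  accounting <- list()
  tiles <- layout$tiles
  for (t in seq_len(nrow(tiles))) {
    r <- tiles$region_id[t]
    muts <- mut_tables[[r]]
    in_tile <- muts[muts$position >= tiles$aa_start[t] &
                    muts$position <= tiles$aa_end[t], , drop = FALSE]
    n_in_tile <- table(factor(in_tile$clone, levels = unique(in_tile$clone)))
    multi_clones <- as.integer(names(n_in_tile)[n_in_tile >= 2L])
    single <- in_tile[!(in_tile$clone %in% multi_clones), , drop = FALSE]

    # clone growth weights (whole-region library; deterministic growth)
    fit <- rep(1, cfg$n_clones)
    if (nrow(muts)) {
      prod_act <- tapply(muts$activity, muts$clone, prod)
      fit[as.integer(names(prod_act))] <- unname(prod_act)
    }
    w_post <- 2 ^ (cfg$generations_wt * pmin(fit, cfg$a_cap))

    cat_of_clone <- rep("wt", cfg$n_clones)
    cat_of_clone[single$clone] <- single$var_id
    cat_of_clone[multi_clones] <- "multi"
    pre_mass  <- tapply(rep(1, cfg$n_clones), cat_of_clone, sum)
    post_mass <- tapply(w_post, cat_of_clone, sum)

    cats <- sort(unique(c(names(pre_mass), names(err_bg[[t]]))))
    p_of <- function(mass) {
      p <- stats::setNames(rep(0, length(cats)), cats)
      p[names(mass)] <- mass / sum(mass)
      pe <- stats::setNames(rep(0, length(cats)), cats)
      pe[names(err_bg[[t]])] <- err_bg[[t]]
      (1 - sum(pe)) * p + pe
    }
    p_ctrl <- stats::setNames(rep(0, length(cats)), cats)
    p_ctrl["wt"] <- 1
    pe <- stats::setNames(rep(0, length(cats)), cats)
    pe[names(err_bg[[t]])] <- err_bg[[t]]
    p_ctrl <- (1 - sum(pe)) * p_ctrl + pe

    probs <- list(pre = p_of(pre_mass), post = p_of(post_mass),
                  control = p_ctrl)
    for (cond in names(probs)) for (rep_i in seq_len(cfg$n_replicates)) {
      cnt <- as.vector(stats::rmultinom(1, cfg$depth_per_tile, probs[[cond]]))
      names(cnt) <- cats
      keep <- !(cats %in% c("wt", "multi"))
      accounting[[length(accounting) + 1L]] <- data.frame(
        tile = t, condition = cond, replicate = rep_i,
        wt_reads = sum(cnt[cats == "wt"]),
        multi_reads = sum(cnt[cats == "multi"]),
        variant_reads = sum(cnt[keep]), depth = cfg$depth_per_tile)
      k <- cnt[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = names(k), tile = t, condition = cond, replicate = rep_i,
        count = as.integer(k), depth = as.integer(cfg$depth_per_tile),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, accounting = do.call(rbind, accounting), layout = layout,
            config = cfg,
            library_stats = data.frame(
              region = seq_along(mut_tables),
              frac_mutation_free = vapply(mut_tables,
                                          attr, numeric(1),
                                          which = "frac_mutation_free")))
}

#' Simulate paired per-conformation stability tables
#'
#' Adds Gaussian observation noise to the true per-conformation stability
#' perturbations and formats them as the two tables a structure-based
#' stability predictor would emit. The super-open table omits positions
#' 157-179, which are disordered in that conformation. Optionally values are
#' emitted in the predictor's internal energy units (kcal/mol times 2.9) to
#' exercise the unit converter.
#'
#' @param truth table from [generate_truth()].
#' @param noise_sd observation noise, kcal/mol.
#' @param seed RNG seed.
#' @param unit `"kcal_per_mol"` or `"internal_energy_units"`.
#' @param missing_superopen positions absent from the super-open structure.
#' @return list of two data.frames (`closed`, `superopen`) with columns
#'   `variant`, `position`, `wt_aa`, `alt_aa`, `conformation`, `ddg`, `unit`.
#' @export
simulate_ddg_tables <- function(truth, noise_sd = 0.25, seed = 1L,
                                unit = c("kcal_per_mol",
                                         "internal_energy_units"),
                                missing_superopen = 157:179) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  unit <- match.arg(unit)
  set.seed(seed)
  mis <- truth[truth$consequence == "missense", , drop = FALSE]
  scale <- if (unit == "internal_energy_units") 2.9 else 1
  mk <- function(conf, true_vals, drop_pos = integer()) {
    keep <- !(mis$position %in% drop_pos)
    data.frame(variant = mis$variant[keep], position = mis$position[keep],
               wt_aa = mis$wt_aa[keep], alt_aa = mis$alt_aa[keep],
               conformation = conf,
               ddg = (true_vals[keep] +
                        stats::rnorm(sum(keep), 0, noise_sd)) * scale,
               unit = unit, stringsAsFactors = FALSE)
  }
  list(closed = mk("closed", mis$ddg_closed),
       superopen = mk("super-open", mis$ddg_superopen,
                      drop_pos = missing_superopen))
}

#' Simulate a toy multiple sequence alignment from per-column preferences
#'
#' Sequences are drawn column-independently from the supplied amino-acid
#' preference weights, gaps are inserted at a flat rate, and a designated
#' wild-type row (gap-free) is placed first.
#'
#' @param preferences numeric matrix, rows = alignment columns, columns = the
#'   20 amino acids; rows are normalized internally.
#' @param n_sequences homolog rows to draw (the wild-type row is added on
#'   top).
#' @param gap_rate per-cell gap probability in homolog rows.
#' @param seed RNG seed.
#' @param wt optional explicit wild-type sequence; default: per-column
#'   preference argmax.
#' @return list of class `msa`: `seqs` (character matrix, rows = sequences)
#'   and `wt_row` (= 1).
#' @export
simulate_msa <- function(preferences, n_sequences, gap_rate = 0.05,
                         seed = 1L, wt = NULL) {
  stopifnot(is.matrix(preferences), ncol(preferences) == 20L)
  if (any(preferences < 0) || any(rowSums(preferences) <= 0))
    stop("preference weights must be nonnegative with positive row sums")
  if (is.null(colnames(preferences))) colnames(preferences) <- AA_ONE
  set.seed(seed)
  L <- nrow(preferences)
  if (is.null(wt))
    wt <- colnames(preferences)[max.col(preferences, ties.method = "first")]
  else wt <- strsplit(wt, "")[[1]]
  stopifnot(length(wt) == L)
  seqs <- matrix("-", nrow = n_sequences + 1L, ncol = L)
  seqs[1L, ] <- wt
  if (n_sequences > 0) {
    for (j in seq_len(L)) {
      p <- preferences[j, ] / sum(preferences[j, ])
      seqs[-1L, j] <- sample(colnames(preferences), n_sequences,
                             replace = TRUE, prob = p)
    }
    gaps <- matrix(stats::runif(n_sequences * L) < gap_rate,
                   nrow = n_sequences)
    seqs[-1L, ][gaps] <- "-"
  }
  structure(list(seqs = seqs, wt_row = 1L), class = "msa")
}

#' Per-position amino-acid preferences coupled to true activity
#'
#' Builds the preference matrix fed to [simulate_msa()] so that evolutionary
#' tolerance mirrors the simulated activity landscape: each substitution's
#' weight is `exp(beta * (activity - 1))`, the wild-type residue having
#' activity 1.
#'
#' @param truth table from [generate_truth()].
#' @param beta coupling strength.
#' @return preference matrix (rows = positions in `truth`, named).
#' @export
activity_preferences <- function(truth, beta = 3) {
  mis <- truth[truth$consequence == "missense", ]
  positions <- sort(unique(mis$position))
  pref <- matrix(0, nrow = length(positions), ncol = 20L,
                 dimnames = list(positions, AA_ONE))
  for (i in seq_along(positions)) {
    rows <- mis[mis$position == positions[i], ]
    pref[i, rows$alt_aa] <- exp(beta * (pmin(rows$true_activity, 1.5) - 1))
    pref[i, rows$wt_aa[1]] <- 1            # wild type: activity 1
  }
  pref
}
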