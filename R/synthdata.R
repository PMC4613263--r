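# Synthetic 2DE experiments and synthetic peptide-mass-fingerprint inputs.
#
# The raw gels behind a typical ontogeny study are rarely deposited, so this
# module simulates the statistical structure the downstream analysis assumes:
# three developmental stages with six replicate gels each, multiplicative
# lognormal replicate noise, stage-specific fold changes outside the
# unchanged band, occasional multi-spot and mixed spots, and stage-specific
# absences. Every generated spot carries a stable identifier so matching and
# calling can be validated against ground truth.

#' Configuration for a synthetic 2DE experiment
#'
#' @param n_replicates Gels per stage (default 6, one per animal).
#' @param stages Ordered stage labels; default `c("P7", "P90", "P637")`.
#' @param baseline_stage Baseline stage (default `"P90"`, the adult stage).
#' @param n_proteins Number of simulated proteins.
#' @param frac_regulated_per_stage Fraction of proteins truly regulated at
#'   each non-baseline stage, in `[0, 1)`.
#' @param fold_change_range Magnitude range for true stage/baseline ratios of
#'   regulated proteins; drawn log-uniformly and inverted with probability
#'   1/2 (down-regulation). Both ends must exceed 1.67 so true changes fall
#'   outside the unchanged SVQ band `[0.6, 1.67]`.
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise (2DE spot volumes are positive and right-skewed).
#' @param frac_multispot Fraction of proteins represented by 2-3 spots
#'   (isoforms / post-translational modification trains).
#' @param frac_mixed Fraction of spots that co-migrate with a spot of a
#'   second protein and are reported as a single merged spot.
#' @param frac_absent Fraction of regulated proteins that are completely
#'   undetectable in one stage (all gels), split evenly between absence in
#'   the compared stage and absence in the baseline.
#' @param pi_range Isoelectric-point range of the strips, within `[3, 10]`.
#' @param mw_range_kda Molecular-weight range in kDa (default 10-100, the
#'   separable window of a 12% gel).
#' @param position_jitter Per-gel standard deviation of spot displacement as
#'   `c(pI, log10 MW)`; a scalar is recycled to both axes.
#' @param min_separation Optional `c(pI, log10 MW)` minimum separation
#'   between distinct spots, enforced by rejection sampling (a pair is
#'   acceptable when it differs by at least the minimum on either axis).
#'   `NULL` (default) places spots uniformly, allowing chance coincidences
#'   as on a real crowded gel.
#' @param detection_floor Raw volume below which a spot goes unreported.
#' @param volume_range Range of per-protein baseline raw volumes, sampled
#'   log-uniformly (three decades by default: faint to near-saturated).
#' @param seed Integer seed; identical configs produce identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_replicates = 6L,
                             stages = c("P7", "P90", "P637"),
                             baseline_stage = "P90",
                             n_proteins = 100L,
                             frac_regulated_per_stage = 0.2,
                             fold_change_range = c(2, 5),
                             cv = 0.2,
                             frac_multispot = 0.1,
                             frac_mixed = 0.05,
                             frac_absent = 0.05,
                             pi_range = c(3, 10),
                             mw_range_kda = c(10, 100),
                             position_jitter = c(0.02, 0.005),
                             min_separation = NULL,
                             detection_floor = 0,
                             volume_range = c(1e3, 1e6),
                             seed = 1L) {
  if (!is_count(n_replicates, min = 2L)) stopf("n_replicates must be an integer >= 2")
  if (length(stages) < 2L || anyDuplicated(stages)) stopf("stages must be >= 2 distinct labels")
  if (!baseline_stage %in% stages) stopf("baseline_stage '%s' is not in stages", baseline_stage)
  if (!is_count(n_proteins, min = 1L)) stopf("n_proteins must be a positive integer")
  for (f in c(frac_regulated_per_stage, frac_multispot, frac_mixed, frac_absent))
    if (!is_fraction(f) || f >= 1) stopf("fractions must lie in [0, 1)")
  if (length(fold_change_range) != 2L || any(fold_change_range <= 1.67))
    stopf("fold_change_range must be two magnitudes > 1.67 (outside the unchanged band [0.6, 1.67])")
  if (!is_number(cv) || cv < 0) stopf("cv must be >= 0")
  if (length(pi_range) != 2L || pi_range[1] < 3 || pi_range[2] > 10 || diff(pi_range) <= 0)
    stopf("pi_range must be an increasing interval within [3, 10]")
  if (length(mw_range_kda) != 2L || mw_range_kda[1] <= 0 || diff(mw_range_kda) <= 0)
    stopf("mw_range_kda must be an increasing positive interval")
  if (length(position_jitter) == 1L) position_jitter <- rep(position_jitter, 2L)
  if (length(position_jitter) != 2L || any(position_jitter < 0))
    stopf("position_jitter must be 1 or 2 non-negative sds (pI, log10 MW)")
  if (length(min_separation) == 0L) min_separation <- NULL # incl. {} from JSON
  if (!is.null(min_separation) &&
      (length(min_separation) != 2L || any(min_separation < 0)))
    stopf("min_separation must be NULL or two non-negative distances (pI, log10 MW)")
  if (!is_number(detection_floor) || detection_floor < 0) stopf("detection_floor must be >= 0")
  if (length(volume_range) != 2L || volume_range[1] <= 0 || diff(volume_range) <= 0)
    stopf("volume_range must be an increasing positive interval")
  structure(list(
    n_replicates = as.integer(n_replicates), stages = stages,
    baseline_stage = baseline_stage, n_proteins = as.integer(n_proteins),
    frac_regulated_per_stage = frac_regulated_per_stage,
    fold_change_range = sort(as.numeric(fold_change_range)), cv = cv,
    frac_multispot = frac_multispot, frac_mixed = frac_mixed,
    frac_absent = frac_absent, pi_range = pi_range,
    mw_range_kda = mw_range_kda, position_jitter = position_jitter,
    min_separation = min_separation,
    detection_floor = detection_floor, volume_range = volume_range,
    seed = as.integer(seed)), class = "synthetic_config")
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic 2DE experiment
#'
#' Simulates one gel table per (stage, replicate) plus a ground-truth record
#' per (protein, non-baseline stage). Per-protein baseline volumes are drawn
#' log-uniformly over `volume_range`; a replicate's raw spot volume is
#' baseline volume x stage fold change x lognormal(1, cv) noise. The number
#' of regulated proteins per stage is exactly
#' `round(frac_regulated_per_stage * n_proteins)`, drawn with
#' `sample()`; fold-change magnitudes are log-uniform over
#' `fold_change_range` with a fair up/down coin. A fraction `frac_absent` of
#' regulated (protein, stage) pairs instead becomes a complete absence, in
#' the compared stage or in the baseline with equal probability. Spots below
#' `detection_floor` or in an absent stage are omitted from that gel's table.
#'
#' @param config A [synthetic_config()].
#' @return A list with `gels` (list of [gel_table()]) and `truth` (tibble
#'   with `protein_id`, `stage`, `true_fold_change`, `true_direction`,
#'   `n_spots`, `spot_ids`).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  np <- cfg$n_proteins
  stages <- cfg$stages
  other <- setdiff(stages, cfg$baseline_stage)
  protein_id <- sprintf("PROT%04d", seq_len(np))

  # multiplicity: 1 spot, or 2-3 for a multispot fraction
  n_spots_of <- rep(1L, np)
  n_multi <- round(cfg$frac_multispot * np)
  if (n_multi > 0L) {
    which_multi <- sample.int(np, n_multi)
    n_spots_of[which_multi] <- sample(2:3, n_multi, replace = TRUE)
  }
  spot_protein <- rep(seq_len(np), n_spots_of)
  spot_rank <- sequence(n_spots_of)
  n_slots <- length(spot_protein)

  # protein-level geometry and abundance; isoform spots are offset along pI,
  # well beyond the matching tolerances (offsets kept inside the strip range)
  iso_step <- 0.35
  draw_base <- function() {
    pi0 <- stats::runif(np, cfg$pi_range[1], cfg$pi_range[2])
    pmin(pi0, cfg$pi_range[2] - iso_step * (n_spots_of - 1L))
  }
  if (is.null(cfg$min_separation)) {
    base_pi <- draw_base()
    base_lmw <- stats::runif(np, log10(cfg$mw_range_kda[1]),
                             log10(cfg$mw_range_kda[2]))
  } else {
    # sequential rejection sampling against every previously placed slot
    base_pi <- numeric(np); base_lmw <- numeric(np)
    acc_pi <- numeric(0); acc_lmw <- numeric(0)
    lmw_lo <- log10(cfg$mw_range_kda[1]); lmw_hi <- log10(cfg$mw_range_kda[2])
    for (p in seq_len(np)) {
      for (try in seq_len(500L)) {
        cpi <- min(stats::runif(1, cfg$pi_range[1], cfg$pi_range[2]),
                   cfg$pi_range[2] - iso_step * (n_spots_of[p] - 1L))
        clmw <- stats::runif(1, lmw_lo, lmw_hi)
        spis <- cpi + iso_step * (seq_len(n_spots_of[p]) - 1L)
        clash <- length(acc_pi) > 0L && any(
          outer(acc_pi, spis, function(a, b) abs(a - b)) < cfg$min_separation[1] &
            abs(acc_lmw - clmw) < cfg$min_separation[2])
        if (!clash) break
      }
      if (clash) stopf("min_separation too large for %d proteins in the given ranges", np)
      base_pi[p] <- cpi; base_lmw[p] <- clmw
      acc_pi <- c(acc_pi, spis); acc_lmw <- c(acc_lmw, rep(clmw, length(spis)))
    }
  }
  base_vol <- 10^stats::runif(np, log10(cfg$volume_range[1]),
                              log10(cfg$volume_range[2]))
  slot_pi <- base_pi[spot_protein] + iso_step * (spot_rank - 1L)
  slot_lmw <- base_lmw[spot_protein]
  share <- stats::runif(n_slots, 0.5, 1)
  share <- share / unname(vapply(split(share, spot_protein), sum,
                                 numeric(1))[as.character(spot_protein)])
  slot_vol <- base_vol[spot_protein] * share

  # mixed spots: a slot of protein B co-migrates with a slot of protein A
  slot_alias <- seq_len(n_slots)
  n_mixed <- round(cfg$frac_mixed * n_slots)
  if (n_mixed > 0L && np >= 2L) {
    hosts <- which(spot_rank == 1L)
    guests <- sample(seq_len(n_slots), n_mixed)
    for (s in guests) {
      host <- sample(hosts[spot_protein[hosts] != spot_protein[s]], 1L)
      slot_alias[s] <- slot_alias[host]
      slot_pi[s] <- slot_pi[host]
      slot_lmw[s] <- slot_lmw[host]
    }
  }
  slot_id <- sprintf("S%05d", slot_alias)

  # per-stage regulation: documented sampling procedure
  fc <- matrix(1, nrow = np, ncol = length(stages), dimnames = list(NULL, stages))
  present <- matrix(TRUE, nrow = np, ncol = length(stages), dimnames = list(NULL, stages))
  regulated <- matrix(FALSE, nrow = np, ncol = length(stages), dimnames = list(NULL, stages))
  for (s in other) {
    n_reg <- round(cfg$frac_regulated_per_stage * np)
    if (n_reg == 0L) next
    idx <- sample.int(np, n_reg)
    regulated[idx, s] <- TRUE
    mag <- exp(stats::runif(n_reg, log(cfg$fold_change_range[1]),
                            log(cfg$fold_change_range[2])))
    up <- stats::runif(n_reg) < 0.5
    fc[idx, s] <- ifelse(up, mag, 1 / mag)
    n_abs <- round(cfg$frac_absent * n_reg)
    if (n_abs > 0L) {
      abs_idx <- idx[sample.int(n_reg, n_abs)]
      in_baseline <- stats::runif(n_abs) < 0.5
      present[abs_idx[!in_baseline], s] <- FALSE
      present[abs_idx[in_baseline], cfg$baseline_stage] <- FALSE
    }
  }

  # gel tables
  gels <- list()
  for (s in stages) {
    for (r in seq_len(cfg$n_replicates)) {
      vol <- slot_vol * fc[spot_protein, s] *
        rlnorm_cv(n_slots, cfg$cv) * present[spot_protein, s]
      pi_g <- slot_pi + stats::rnorm(n_slots, 0, cfg$position_jitter[1])
      lmw_g <- slot_lmw + stats::rnorm(n_slots, 0, cfg$position_jitter[2])
      keep <- vol > cfg$detection_floor
      df <- tibble::tibble(spot_id = slot_id, pi = pmin(pmax(pi_g, 0), 14),
                           mw_kda = 10^lmw_g, raw_volume = vol)[keep, ]
      # merge co-migrating (mixed) slots into one reported spot
      if (anyDuplicated(df$spot_id)) {
        agg <- split(seq_len(nrow(df)), df$spot_id)
        df <- tibble::tibble(
          spot_id = names(agg),
          pi = vapply(agg, function(i) df$pi[i][1], numeric(1)),
          mw_kda = vapply(agg, function(i) df$mw_kda[i][1], numeric(1)),
          raw_volume = vapply(agg, function(i) sum(df$raw_volume[i]), numeric(1)))
      }
      df <- df[order(df$spot_id), ]
      gels[[length(gels) + 1L]] <- gel_table(s, r, df)
    }
  }

  # truth records, one per (protein, non-baseline stage)
  spot_ids_of <- vapply(split(slot_id, spot_protein), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  truth <- do.call(rbind, lapply(other, function(s) {
    dir <- ifelse(!present[, cfg$baseline_stage], "absent_in_baseline",
           ifelse(!present[, s], "absent_in_stage",
           ifelse(regulated[, s] & fc[, s] > 1, "up",
           ifelse(regulated[, s] & fc[, s] < 1, "down", "unchanged"))))
    tibble::tibble(protein_id = protein_id, stage = s,
                   true_fold_change = fc[, s], true_direction = dir,
                   n_spots = n_spots_of,
                   spot_ids = unname(spot_ids_of[as.character(seq_len(np))]))
  }))
  list(gels = gels, truth = truth)
}

#' Write / read ground-truth tables
#'
#' Truth is stored as a TSV with columns `protein_id`, `stage`,
#' `true_fold_change`, `true_direction`, `spot_ids` (comma-joined).
#'
#' @param truth Truth tibble from [generate_experiment()].
#' @param path File path.
#' @return `path` (write) or the truth tibble (read).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Map synthetic spot identifiers to protein accessions
#'
#' Expands the comma-joined `spot_ids` column of a truth table into a long
#' (spot_id, accession) map; mixed spots map to more than one protein.
#'
#' @param truth Truth tibble from [generate_experiment()].
#' @return A tibble with columns `spot_id` and `accession`.
#' @export
truth_spot_map <- function(truth) {
  one_stage <- truth[truth$stage == truth$stage[1], ]
  ids <- strsplit(one_stage$spot_ids, ",", fixed = TRUE)
  out <- tibble::tibble(spot_id = unlist(ids),
                        accession = rep(one_stage$protein_id, lengths(ids)))
  unique(out)
}

# average amino-acid composition of vertebrate proteins (rounded, renormalised)
aa_background_freqs <- c(
  A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, E = 0.058, Q = 0.037,
  G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072, M = 0.018, F = 0.040,
  P = 0.050, S = 0.081, T = 0.062, W = 0.013, Y = 0.033, V = 0.068)

#' Configuration for a synthetic peptide-mass-fingerprint case
#'
#' @param n_proteins Database size (>= 2; a search needs decoys).
#' @param length_range Protein length range (residues).
#' @param residue_frequencies Named composition over the 20 standard amino
#'   acids; defaults to an average vertebrate composition.
#' @param mass_jitter_ppm Standard deviation of the gaussian relative mass
#'   error applied to each observed peak (ppm).
#' @param frac_peak_dropout Fraction of theoretical peptide masses missing
#'   from the peak list, in `[0, 1)`.
#' @param n_contaminant_peaks Number of uniform-random extra peaks appended.
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_sequence_config`.
#' @export
synthetic_sequence_config <- function(n_proteins = 500L,
                                      length_range = c(150L, 600L),
                                      residue_frequencies = aa_background_freqs,
                                      mass_jitter_ppm = 20,
                                      frac_peak_dropout = 0.3,
                                      n_contaminant_peaks = 5L,
                                      seed = 1L) {
  if (!is_count(n_proteins, min = 2L))
    stopf("n_proteins must be an integer >= 2 (a search needs decoys)")
  if (length(length_range) != 2L || length_range[1] < 10 || diff(length_range) < 0)
    stopf("length_range must be an increasing interval of lengths >= 10")
  if (!setequal(names(residue_frequencies), names(aa_background_freqs)) ||
      any(residue_frequencies < 0))
    stopf("residue_frequencies must cover the 20 standard amino acids")
  if (!is_number(mass_jitter_ppm) || mass_jitter_ppm < 0)
    stopf("mass_jitter_ppm must be >= 0")
  if (!is_fraction(frac_peak_dropout) || frac_peak_dropout >= 1)
    stopf("frac_peak_dropout must lie in [0, 1)")
  if (!is_count(n_contaminant_peaks)) stopf("n_contaminant_peaks must be a count")
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    residue_frequencies = residue_frequencies / sum(residue_frequencies),
    mass_jitter_ppm = mass_jitter_ppm, frac_peak_dropout = frac_peak_dropout,
    n_contaminant_peaks = as.integer(n_contaminant_peaks),
    seed = as.integer(seed)), class = "synthetic_sequence_config")
}

#' Generate a synthetic PMF search case
#'
#' Draws a random protein database, picks one "spotted" protein, digests it
#' in silico (trypsin, fixed carbamidomethyl-C) and emits its monoisotopic
#' peptide masses as the peak list after applying gaussian ppm error, peak
#' dropout and uniform-random contaminant peaks. Peaks are neutral
#' monoisotopic masses, not protonated m/z.
#'
#' @param config A [synthetic_sequence_config()].
#' @param pmf_config A [pmf_config()] controlling the theoretical digest.
#' @return A list with `database` (a named `AAStringSet`), `peaks` (sorted
#'   numeric masses) and `true_protein_id`.
#' @export
generate_pmf_case <- function(config, pmf_config = spotdiff::pmf_config()) {
  stopifnot(inherits(config, "synthetic_sequence_config"))
  with_seed(config$seed, {
    aa <- names(config$residue_frequencies)
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   config$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(aa, L, replace = TRUE, prob = config$residue_frequencies),
            collapse = ""), character(1))
    names(seqs) <- sprintf("SYN%04d", seq_len(config$n_proteins))
    db <- Biostrings::AAStringSet(seqs)
    true_id <- names(seqs)[sample.int(config$n_proteins, 1L)]
    theo <- theoretical_peak_list(seqs[[true_id]], pmf_config)
    keep <- stats::runif(length(theo)) >= config$frac_peak_dropout
    if (!any(keep)) keep[sample.int(length(theo), 1L)] <- TRUE
    peaks <- theo[keep]
    if (config$mass_jitter_ppm > 0)
      peaks <- peaks * (1 + stats::rnorm(length(peaks), 0, config$mass_jitter_ppm * 1e-6))
    if (config$n_contaminant_peaks > 0L)
      peaks <- c(peaks, stats::runif(config$n_contaminant_peaks,
                                     min(theo), max(theo)))
    list(database = db, peaks = sort(peaks), true_protein_id = true_id)
  })
}

#' Write a peak list (one neutral mass per line)
#'
#' @param peaks Numeric vector of masses.
#' @param path File path.
#' @return `path` (write) or the numeric peaks (read).
#' @export
write_peak_list <- function(peaks, path) {
  writeLines(sprintf("%.15g", peaks), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("%s: empty peak list", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stopf("%s: line %d: non-numeric mass '%s'", path,
                         which(is.na(vals))[1], lines[which(is.na(vals))[1]])
  vals
}
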