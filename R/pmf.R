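# Peptide-mass-fingerprint identification: in-silico tryptic digestion,
# monoisotopic peptide masses with fixed and variable modifications, ppm
# peak matching, a probability-based MOWSE-style score and a Mascot-style
# significance threshold.
#
# The score is -10*log10 of the binomial upper-tail probability of matching
# at least the observed number of peaks by chance, with the per-peak random
# match probability estimated from the candidate protein's theoretical
# peptide masses over the observed mass range. Mascot's exact scoring is
# unpublished; this is a documented variant of the same frequency logic.

# standard monoisotopic residue masses (Da)
residue_mono_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

water_mono <- 18.010565
proton_mass <- 1.007276

#' Configuration for peptide-mass-fingerprint searching
#'
#' Defaults follow common MALDI-TOF reflector-mode practice: trypsin
#' digestion (cleavage after K/R, not before P), one missed cleavage, fixed
#' carbamidomethylation of cysteine (+57.021464 Da), variable oxidation of
#' methionine (+15.994915 Da) and a 60 ppm mass tolerance.
#'
#' @param tolerance_ppm Mass-match window in parts per million (> 0).
#' @param max_missed_cleavages Maximum internal missed cleavage sites.
#' @param fixed_mods Named numeric: mass delta applied to every occurrence
#'   of a residue.
#' @param variable_mods Named numeric: mass delta optionally applied per
#'   occurrence of a residue; all 0..k combinations up to
#'   `max_variable_sites` sites per peptide are enumerated.
#' @param enzyme Cleavage rule; only `"trypsin"` is implemented.
#' @param alpha Significance level for the identification threshold.
#' @param min_peptide_length Shortest peptide retained from the digest.
#' @param max_variable_sites Combinatorial cap on variable-modification
#'   sites per peptide (default 5, i.e. at most 2^5 states).
#' @param peaks_are_mz If `TRUE`, observed peaks are singly protonated m/z
#'   values and 1.007276 Da is subtracted; by default peaks are neutral
#'   monoisotopic masses, as emitted by [generate_pmf_case()].
#' @param exclusion_masses Masses (e.g. trypsin autolysis or matrix peaks)
#'   removed from the peak list before searching, at `tolerance_ppm`.
#' @param score_cap Upper bound on reported scores (default 350).
#' @return A validated list of class `pmf_config`.
#' @export
pmf_config <- function(tolerance_ppm = 60, max_missed_cleavages = 1L,
                       fixed_mods = c(C = 57.021464),
                       variable_mods = c(M = 15.994915),
                       enzyme = "trypsin", alpha = 0.05,
                       min_peptide_length = 4L, max_variable_sites = 5L,
                       peaks_are_mz = FALSE, exclusion_masses = numeric(0),
                       score_cap = 350) {
  if (!is_number(tolerance_ppm) || tolerance_ppm <= 0)
    stopf("tolerance_ppm must be > 0")
  if (!is_count(max_missed_cleavages)) stopf("max_missed_cleavages must be >= 0")
  if (!identical(enzyme, "trypsin")) stopf("only trypsin cleavage is implemented")
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (!is_count(min_peptide_length, min = 1L)) stopf("min_peptide_length must be >= 1")
  structure(list(tolerance_ppm = tolerance_ppm,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 fixed_mods = fixed_mods, variable_mods = variable_mods,
                 enzyme = enzyme, alpha = alpha,
                 min_peptide_length = as.integer(min_peptide_length),
                 max_variable_sites = as.integer(max_variable_sites),
                 peaks_are_mz = isTRUE(peaks_are_mz),
                 exclusion_masses = as.numeric(exclusion_masses),
                 score_cap = score_cap), class = "pmf_config")
}

#' In-silico tryptic digestion
#'
#' Cleaves after every K or R not followed by P and emits all peptides with
#' 0 to `max_missed_cleavages` internal missed sites, dropping peptides
#' shorter than `min_peptide_length`.
#'
#' @param sequence Protein sequence over the 20 standard amino acids.
#' @param config A [pmf_config()].
#' @return A tibble with `sequence`, `missed_cleavages`, `start`, `end`.
#' @examples
#' digest("MKAR", pmf_config(min_peptide_length = 1))
#' @export
digest <- function(sequence, config = pmf_config()) {
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(residue_mono_mass))
  if (length(bad) > 0L)
    stopf("non-standard residue '%s' at position %d", chars[bad[1]], bad[1])
  L <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < L & chars[pmin(cut_after + 1L, L)] != "P"]
  bounds <- c(0L, cut_after, L) # fragment i spans (bounds[i], bounds[i+1]]
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (mc in 0:config$max_missed_cleavages) {
      j <- i + mc
      if (j > nfrag) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      if (e - s + 1L < config$min_peptide_length) next
      rows[[length(rows) + 1L]] <- list(
        sequence = substr(sequence, s, e), missed_cleavages = mc,
        start = s, end = e)
    }
  }
  if (length(rows) == 0L)
    return(tibble::tibble(sequence = character(0), missed_cleavages = integer(0),
                          start = integer(0), end = integer(0)))
  tibble::tibble(sequence = vapply(rows, `[[`, character(1), "sequence"),
                 missed_cleavages = vapply(rows, function(r) as.integer(r$missed_cleavages), integer(1)),
                 start = vapply(rows, function(r) as.integer(r$start), integer(1)),
                 end = vapply(rows, function(r) as.integer(r$end), integer(1)))
}

residue_counts <- function(sequences, residue) {
  vapply(gregexpr(residue, sequences, fixed = TRUE), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1))
}

#' Monoisotopic peptide masses with modifications
#'
#' The base mass is the sum of standard monoisotopic residue masses plus one
#' water (18.010565 Da) plus fixed-modification deltas for every matching
#' residue. Variable modifications enumerate all 0..k modified-site counts,
#' with the number of considered sites per peptide capped at
#' `max_variable_sites`.
#'
#' @param peptides A tibble from [digest()] (or a character vector of
#'   peptide sequences).
#' @param config A [pmf_config()].
#' @return A tibble with `sequence`, `missed_cleavages`, `n_var_mods`,
#'   `mono_mass`, one row per modification state.
#' @export
peptide_masses <- function(peptides, config = pmf_config()) {
  if (is.character(peptides))
    peptides <- tibble::tibble(sequence = peptides,
                               missed_cleavages = NA_integer_)
  seqs <- peptides$sequence
  base <- vapply(strsplit(seqs, "", fixed = TRUE), function(ch)
    sum(residue_mono_mass[ch]), numeric(1)) + water_mono
  for (res in names(config$fixed_mods))
    base <- base + config$fixed_mods[[res]] * residue_counts(seqs, res)
  nv <- length(config$variable_mods)
  if (nv == 0L) {
    return(tibble::tibble(sequence = seqs,
                          missed_cleavages = peptides$missed_cleavages,
                          n_var_mods = 0L, mono_mass = base))
  }
  if (nv == 1L) {
    # fast path for the common single variable mod (oxidation-M)
    n_sites <- pmin(residue_counts(seqs, names(config$variable_mods)),
                    config$max_variable_sites)
    delta <- config$variable_mods[[1]]
    reps <- n_sites + 1L
    k <- sequence(reps) - 1L
    idx <- rep(seq_along(seqs), reps)
    return(tibble::tibble(sequence = seqs[idx],
                          missed_cleavages = peptides$missed_cleavages[idx],
                          n_var_mods = k,
                          mono_mass = base[idx] + k * delta))
  }
  # general case: cross product of per-residue modified-site counts, each
  # residue's considered sites capped at max_variable_sites
  counts <- lapply(names(config$variable_mods), function(res)
    pmin(residue_counts(seqs, res), config$max_variable_sites))
  rows <- lapply(seq_along(seqs), function(i) {
    grid <- expand.grid(lapply(counts, function(cc) 0:cc[i]))
    dm <- as.matrix(grid) %*% unlist(config$variable_mods)
    tibble::tibble(sequence = seqs[i],
                   missed_cleavages = peptides$missed_cleavages[i],
                   n_var_mods = as.integer(rowSums(grid)),
                   mono_mass = base[i] + as.numeric(dm))
  })
  do.call(rbind, rows)
}

#' Theoretical peak list of one protein
#'
#' The sorted unique base (unmodified variable state) monoisotopic masses of
#' the protein's digest, fixed modifications applied — what an ideal MALDI
#' spectrum of the digest would contain.
#'
#' @param sequence Protein sequence.
#' @param config A [pmf_config()].
#' @return Sorted numeric vector of masses.
#' @export
theoretical_peak_list <- function(sequence, config = pmf_config()) {
  pep <- digest(sequence, config)
  m <- peptide_masses(pep, config)
  sort(unique(m$mono_mass[m$n_var_mods == 0L]))
}

#' Match observed peaks to candidate peptide masses
#'
#' A peak matches a candidate iff the relative deviation is within
#' `tolerance_ppm`. Each peak is assigned to at most one candidate (smallest
#' ppm error wins; exact ties go to the lower candidate mass).
#'
#' @param peaks Observed masses (sorted internally; converted from m/z when
#'   `config$peaks_are_mz`).
#' @param candidate_masses Numeric vector of theoretical masses.
#' @param config A [pmf_config()].
#' @return A tibble with `peak`, `candidate_mass`, `ppm_error`, one row per
#'   matched peak.
#' @export
match_peaks <- function(peaks, candidate_masses, config = pmf_config()) {
  if (length(candidate_masses) == 0L)
    return(tibble::tibble(peak = numeric(0), candidate_mass = numeric(0),
                          ppm_error = numeric(0)))
  peaks <- sort(as.numeric(peaks))
  if (config$peaks_are_mz) peaks <- peaks - proton_mass
  cm <- sort(as.numeric(candidate_masses))
  ppm <- abs(outer(peaks, cm, "-")) / rep(cm, each = length(peaks)) * 1e6
  best <- apply(ppm, 1L, which.min) # ties -> first = lower mass
  err <- ppm[cbind(seq_along(peaks), best)]
  hit <- err <= config$tolerance_ppm
  tibble::tibble(peak = peaks[hit], candidate_mass = cm[best[hit]],
                 ppm_error = err[hit])
}

#' Per-peak random-match probability for a candidate protein
#'
#' The measure of the union of the +-tolerance windows around the
#' candidate's theoretical peptide masses, clipped to the observed mass
#' range, divided by the width of that range: the probability that a
#' uniformly placed peak matches the candidate by chance.
#'
#' @param candidate_masses Theoretical masses of one candidate protein.
#' @param peak_range Numeric length-2: range of the observed peak list.
#' @param tolerance_ppm Match window in ppm.
#' @return Probability in `[0, 1]`.
#' @export
random_match_prob <- function(candidate_masses, peak_range, tolerance_ppm) {
  lo <- min(peak_range); hi <- max(peak_range)
  width <- hi - lo
  if (width <= 0) return(0)
  tol <- tolerance_ppm * 1e-6
  m <- sort(unique(candidate_masses))
  a <- pmax(m * (1 - tol), lo); b <- pmin(m * (1 + tol), hi)
  keep <- b > a
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(0)
  covered <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cur_b) cur_b <- max(cur_b, b[i])
    else { covered <- covered + cur_b - cur_a; cur_a <- a[i]; cur_b <- b[i] }
  }
  covered <- covered + cur_b - cur_a
  min(1, covered / width)
}

#' MOWSE-style score from a binomial tail
#'
#' `score = -10 * log10 P(X >= qm)` with `X ~ Binomial(n_peaks, q)`. A score
#' of 0 is returned for `qm = 0` (no evidence); scores are capped at
#' `cap` (also used when the tail underflows or `q = 0` with matches).
#'
#' @param qm Number of matched peaks.
#' @param n_peaks Number of observed peaks.
#' @param q Per-peak random-match probability.
#' @param cap Score cap.
#' @return Non-negative score.
#' @export
mowse_score <- function(qm, n_peaks, q, cap = 350) {
  stopifnot(qm >= 0, qm <= n_peaks)
  if (qm == 0L) return(0)
  if (q <= 0) return(cap)
  p <- stats::pbinom(qm - 1, n_peaks, q, lower.tail = FALSE)
  if (p <= 0) return(cap)
  min(-10 * log10(p), cap)
}

#' Mascot-style significance threshold
#'
#' `floor(-10 * log10(alpha / n_sequences))`: an identification is
#' significant at level `alpha` against a database of `n_sequences` entries
#' iff its score exceeds this integer bound. For `alpha = 0.05` and the
#' 42,755-sequence rat subset of UniProtKB this gives 59.
#'
#' @param alpha Significance level in (0, 1).
#' @param n_sequences Database size (>= 1).
#' @return Integer score bound.
#' @export
significance_threshold <- function(alpha, n_sequences) {
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (!is_count(n_sequences, min = 1L)) stopf("n_sequences must be >= 1")
  as.integer(floor(-10 * log10(alpha / n_sequences)))
}

#' Digest a protein database
#'
#' Precomputes, per protein, the sorted unique candidate masses (all
#' modification states) for reuse across searches.
#'
#' @param database A named `AAStringSet` or named character vector.
#' @param config A [pmf_config()].
#' @return A list of class `pmf_database` with `accessions` and `masses`
#'   (list of numeric vectors).
#' @export
digest_database <- function(database, config = pmf_config()) {
  if (methods::is(database, "AAStringSet")) database <- as.character(database)
  if (length(database) == 0L) stopf("empty protein database")
  if (is.null(names(database)) || any(!nzchar(names(database))))
    stopf("database sequences must be named by accession")
  masses <- lapply(database, function(s)
    sort(unique(peptide_masses(digest(s, config), config)$mono_mass)))
  structure(list(accessions = names(database), masses = masses,
                 n_sequences = length(database)), class = "pmf_database")
}

#' Peptide-mass-fingerprint search
#'
#' Digests every database protein, matches the observed peaks at the
#' configured ppm tolerance, scores each candidate with [mowse_score()] and
#' flags significance against [significance_threshold()]. Results are
#' sorted by score (descending), ties broken by matched-peak count then
#' accession.
#'
#' @param peaks Observed peak list (neutral masses, or m/z when
#'   `config$peaks_are_mz`).
#' @param database A named `AAStringSet`, named character vector, or a
#'   prepared [digest_database()] object.
#' @param config A [pmf_config()].
#' @return A tibble with `accession`, `score`, `qm`, `n_peaks`, `q`,
#'   `significant`, `matched` (list of matched-pair tibbles), sorted by
#'   rank.
#' @export
pmf_search <- function(peaks, database, config = pmf_config()) {
  peaks <- as.numeric(peaks)
  if (length(peaks) == 0L) stopf("empty peak list")
  if (!inherits(database, "pmf_database"))
    database <- digest_database(database, config)
  if (config$peaks_are_mz) peaks <- peaks - proton_mass
  if (length(config$exclusion_masses) > 0L) {
    tol <- config$tolerance_ppm * 1e-6
    excl <- vapply(peaks, function(p)
      any(abs(p - config$exclusion_masses) <= tol * config$exclusion_masses),
      logical(1))
    peaks <- peaks[!excl]
    if (length(peaks) == 0L) stopf("all peaks excluded as contaminant masses")
  }
  peaks <- sort(peaks)
  cfg_neutral <- config; cfg_neutral$peaks_are_mz <- FALSE # already converted
  pr <- range(peaks)
  n_peaks <- length(peaks)
  thr <- significance_threshold(config$alpha, database$n_sequences)
  n_db <- database$n_sequences
  score <- numeric(n_db); qm <- integer(n_db); qq <- numeric(n_db)
  matched <- vector("list", n_db)
  for (i in seq_len(n_db)) {
    mp <- match_peaks(peaks, database$masses[[i]], cfg_neutral)
    matched[[i]] <- mp
    qm[i] <- length(unique(mp$peak))
    qq[i] <- random_match_prob(database$masses[[i]], pr, config$tolerance_ppm)
    score[i] <- mowse_score(qm[i], n_peaks, qq[i], config$score_cap)
  }
  out <- tibble::tibble(accession = database$accessions, score = score,
                        qm = qm, n_peaks = n_peaks, q = qq,
                        significant = score > thr, matched = matched)
  out[order(-out$score, -out$qm, out$accession), ]
}

#' Read / write a protein FASTA database
#'
#' Thin wrappers over Biostrings' FASTA IO.
#'
#' @param path FASTA file path.
#' @param database A named `AAStringSet` (or named character vector).
#' @return An `AAStringSet` (read) or `path` (write).
#' @export
read_fasta_db <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  Biostrings::readAAStringSet(path)
}

#' @rdname read_fasta_db
#' @export
write_fasta_db <- function(database, path) {
  if (!methods::is(database, "AAStringSet"))
    database <- Biostrings::AAStringSet(database)
  Biostrings::writeXStringSet(database, path)
  invisible(path)
}
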