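test_that("tryptic digestion honours the K/R-not-before-P rule and missed cleavages", {
  cfg <- pmf_config(min_peptide_length = 1)
  d <- digest("MKAR", cfg)
  expect_setequal(d$sequence, c("MK", "AR", "MKAR"))
  expect_equal(sort(d$missed_cleavages), c(0L, 0L, 1L))

  # proline blocks cleavage
  dp <- digest("MKPR", cfg)
  expect_equal(dp$sequence, "MKPR")

  # combinatorial identity for proline-free sequences: (k+1) + k candidates
  set.seed(5)
  for (k in 0:8) {
    frags <- replicate(k + 1, paste(sample(c("A", "G", "V", "L"),
                                           sample(2:5, 1), replace = TRUE),
                                    collapse = ""))
    seqv <- paste(frags, collapse = "K") # k internal cleavage sites
    expect_equal(nrow(digest(seqv, cfg)), oracle_tryptic_count(k, 1))
  }

  expect_error(digest("MKXZR"), "non-standard residue 'X' at position 3")
  # peptides below the length floor are dropped
  d4 <- digest("MKAR", pmf_config(min_peptide_length = 4))
  expect_equal(d4$sequence, "MKAR")
})

test_that("monoisotopic masses sum the residue table plus water and fixed mods", {
  cfg <- pmf_config(min_peptide_length = 1)
  m_ar <- peptide_masses("AR", cfg)
  expect_equal(m_ar$mono_mass, 71.03711 + 156.10111 + 18.010565)
  m_c <- peptide_masses("C", cfg)
  expect_equal(m_c$mono_mass, 103.00919 + 57.021464 + 18.010565)

  # additivity up to one water on random peptides
  set.seed(8)
  for (i in 1:10) {
    p1 <- random_protein(sample(3:8, 1)); p2 <- random_protein(sample(3:8, 1))
    base <- function(s) {
      mm <- peptide_masses(s, cfg)
      mm$mono_mass[mm$n_var_mods == 0]
    }
    expect_equal(base(paste0(p1, p2)), base(p1) + base(p2) - 18.010565,
                 tolerance = 1e-9)
    expect_equal(base(p1), oracle_peptide_mass(p1), tolerance = 1e-9)
  }

  # variable oxidation enumerates 0..k modified states
  mm <- peptide_masses("AMMR", cfg)
  expect_equal(sort(mm$n_var_mods), 0:2)
  expect_equal(diff(sort(mm$mono_mass)), rep(15.994915, 2), tolerance = 1e-9)
  # combinatorial cap
  many_m <- paste(rep("M", 10), collapse = "")
  capped <- peptide_masses(many_m, pmf_config(min_peptide_length = 1,
                                              max_variable_sites = 3))
  expect_equal(max(capped$n_var_mods), 3L)
})

test_that("peak matching applies the ppm window with closest-then-lower-mass tie-breaks", {
  cfg <- pmf_config(tolerance_ppm = 60)
  hit <- match_peaks(1000.05, 1000.0, cfg)   # 50 ppm
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ppm_error, 50, tolerance = 1e-6)
  miss <- match_peaks(1000.07, 1000.0, cfg)  # 70 ppm
  expect_equal(nrow(miss), 0L)
  # exactly equidistant in ppm from two candidates: the lower mass wins
  # (peak 1600 is 600000 ppm from both 1000 and 4000, exactly, in doubles)
  both <- match_peaks(1600, c(1000, 4000), pmf_config(tolerance_ppm = 7e5))
  expect_equal(nrow(both), 1L)
  expect_equal(both$candidate_mass, 1000)
  # each peak matches at most one candidate
  mp <- match_peaks(c(999.99, 1000.01), c(1000, 2000), cfg)
  expect_true(all(table(mp$peak) == 1))
})

test_that("the MOWSE-style score is the binomial upper tail and is monotone in evidence", {
  # direct binomial-tail oracle
  p <- sum(dbinom(5:10, 10, 0.01))
  expect_equal(mowse_score(5, 10, 0.01), -10 * log10(p))
  expect_equal(mowse_score(0, 10, 0.01), 0)
  expect_equal(mowse_score(3, 10, 0), 350)
  # monotone nondecreasing in qm
  scores <- vapply(0:10, mowse_score, numeric(1), n_peaks = 10, q = 0.02)
  expect_true(all(diff(scores) >= 0))
  # random-match probability: union of windows over the observed range
  q <- random_match_prob(c(1000, 2000), c(500, 2500), 60)
  expect_equal(q, (2 * 60e-6 * 1000 + 2 * 60e-6 * 2000) / 2000, tolerance = 1e-9)
  # overlapping windows are not double counted
  q2 <- random_match_prob(c(1000, 1000.01), c(500, 2500), 60)
  expect_lt(q2, 2 * (2 * 60e-6 * 1000) / 2000)
})

test_that("the significance threshold reproduces the Mascot-style bound", {
  expect_equal(significance_threshold(0.05, 42755), 59L)
  expect_equal(significance_threshold(0.05, 1), 13L)
  expect_equal(significance_threshold(1, 1), 0L)
  # monotone in database size, decreasing in alpha
  ns <- c(1, 10, 1000, 42755, 1e6)
  thr <- vapply(ns, function(n) significance_threshold(0.05, n), integer(1))
  expect_true(all(diff(thr) >= 0))
  expect_gte(significance_threshold(0.01, 1000), significance_threshold(0.05, 1000))
})

test_that("a noise-free self-search matches every peak and ranks the true protein first", {
  cfg <- synthetic_sequence_config(n_proteins = 30, mass_jitter_ppm = 0,
                                   frac_peak_dropout = 0, n_contaminant_peaks = 0,
                                   seed = 12)
  case <- generate_pmf_case(cfg)
  res <- pmf_search(case$peaks, case$database)
  expect_equal(res$accession[1], case$true_protein_id)
  top <- res[res$accession == case$true_protein_id, ]
  expect_equal(top$qm, top$n_peaks)
  expect_equal(top$score, max(res$score))
  expect_true(top$significant)

  # single-protein database whose exact digest is the peak list
  one <- case$database[case$true_protein_id]
  # (threshold needs n>=1; a 1-protein db is allowed at search time)
  r1 <- pmf_search(case$peaks, one)
  expect_equal(r1$qm, r1$n_peaks)
  expect_error(pmf_search(numeric(0), case$database), "empty peak list")
})

test_that("exclusion masses and m/z peak lists are handled", {
  cfg <- synthetic_sequence_config(n_proteins = 15, mass_jitter_ppm = 0,
                                   frac_peak_dropout = 0, n_contaminant_peaks = 0,
                                   seed = 6)
  case <- generate_pmf_case(cfg)
  # protonated peaks with peaks_are_mz give the same result
  res_mz <- pmf_search(case$peaks + 1.007276, case$database,
                       pmf_config(peaks_are_mz = TRUE))
  res <- pmf_search(case$peaks, case$database)
  expect_equal(res_mz$score, res$score)
  # excluding one peak drops it from the search
  excl <- pmf_config(exclusion_masses = case$peaks[1])
  res_ex <- pmf_search(case$peaks, case$database, excl)
  expect_equal(res_ex$n_peaks[1], length(case$peaks) - 1L)
})
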