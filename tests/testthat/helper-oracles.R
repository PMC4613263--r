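# Independent oracles, deliberately implemented differently from the
# package internals they check.

# Two-sided exact Mann-Whitney p-value by bitmask enumeration: every subset
# of size n of the pooled positions, counted via binary representations.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask)[1:N])
    if (sum(bits) != n) next
    total <- total + 1L
    U <- sum(r[bits == 1L]) - n * (n + 1) / 2
    if (abs(U - mu) >= abs(U_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Brute-force count of tryptic peptides at <= max_mc missed cleavages for a
# proline-free sequence with k internal cleavage sites.
oracle_tryptic_count <- function(k, max_mc) {
  nfrag <- k + 1L
  sum(vapply(0:max_mc, function(mc) max(0L, nfrag - mc), integer(1)))
}

# Sum-of-residues peptide mass from an independent copy of the standard
# monoisotopic table.
oracle_peptide_mass <- function(seq, fixed_c = TRUE) {
  tab <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
           V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
           I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
           K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
           F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  ch <- strsplit(seq, "")[[1]]
  m <- sum(tab[ch]) + 18.010565
  if (fixed_c) m <- m + 57.021464 * sum(ch == "C")
  m
}

random_protein <- function(len, seed = NULL) {
  aa <- c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E","M","H","F","R","Y","W")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
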