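# Small builders shared across test files.

tiny_gel <- function(stage = "P90", rep = 1L,
                     pi = c(5.2, 6.1, 7.0),
                     mw = c(47.4, 30.0, 60.0),
                     vol = c(1200, 800, 500),
                     ids = paste0("s", seq_along(pi))) {
  gel_table(stage, rep, tibble::tibble(
    spot_id = ids, pi = pi, mw_kda = mw, raw_volume = vol))
}

# an experiment with a single protein per spot and no structural noise
clean_synth_config <- function(...) {
  synthetic_config(frac_multispot = 0, frac_mixed = 0, frac_absent = 0, ...)
}

table1_fixture <- function() {
  path <- system.file("extdata", "table1_svq.tsv", package = "spotdiff")
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
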