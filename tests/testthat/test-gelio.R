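test_that("spot tables parse, round-trip and reject malformed rows with line numbers", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "P7_rep1.tsv")
  writeLines(c("spot_id\tpi\tmw_kda\traw_volume", "s1\t5.20\t47.4\t1200.0"), p)
  g <- read_spot_table(p)
  expect_s3_class(g, "gel_table")
  expect_equal(g$stage, "P7")
  expect_equal(g$replicate, 1L)
  expect_equal(g$spots$pi, 5.20)
  expect_equal(g$spots$raw_volume, 1200)

  # round trip of a generated gel
  exp <- generate_experiment(clean_synth_config(n_proteins = 20, seed = 4))
  g0 <- exp$gels[[1]]
  p2 <- file.path(dir, sprintf("%s_rep%d.tsv", g0$stage, g0$replicate))
  write_spot_table(g0, p2)
  g1 <- read_spot_table(p2)
  expect_equal(g1$spots, g0$spots)
  expect_equal(g1$stage, g0$stage)

  # validation errors cite the offending line
  writeLines(c("spot_id\tpi\tmw_kda\traw_volume", "s1\t5.0\t40\t-3"), p)
  expect_error(read_spot_table(p), "line 2.*negative raw_volume")
  writeLines(c("spot_id\tpi\tmw_kda\traw_volume", "s1\t15.0\t40\t3"), p)
  expect_error(read_spot_table(p), "line 2.*pI")
  writeLines(c("spot_id\tpi\tmw_kda\traw_volume", "s1\t5\t40\t3", "s1\t6\t30\t2"), p)
  expect_error(read_spot_table(p), "line 3.*duplicate spot_id")
  writeLines(c("spot_id\tpi\tmw_kda\traw_volume", "s1\t5\t40"), p)
  expect_error(read_spot_table(p), "line 2.*expected 4 fields")
})

test_that("normalisation scales to ppm of total, preserves ratios, is idempotent and scale-invariant", {
  g <- normalize_volumes(tiny_gel(vol = c(2, 3, 5)))
  expect_equal(g$spots$norm_volume, c(200000, 300000, 500000))
  expect_equal(sum(g$spots$norm_volume), 1e6, tolerance = 1e-6)

  # ratios preserved exactly
  g2 <- normalize_volumes(tiny_gel(vol = c(123.4, 7.7, 991)))
  expect_equal(g2$spots$norm_volume[1] / g2$spots$norm_volume[2],
               g2$spots$raw_volume[1] / g2$spots$raw_volume[2])

  # scale invariance: [1,1] and [10,10] normalise identically
  a <- normalize_volumes(tiny_gel(pi = c(5, 6), mw = c(40, 50), vol = c(1, 1), ids = c("a", "b")))
  b <- normalize_volumes(tiny_gel(pi = c(5, 6), mw = c(40, 50), vol = c(10, 10), ids = c("a", "b")))
  expect_equal(a$spots$norm_volume, b$spots$norm_volume)

  # idempotence: renormalising the normalised volumes changes nothing
  g3 <- g
  g3$spots$raw_volume <- g3$spots$norm_volume
  expect_equal(normalize_volumes(g3)$spots$norm_volume, g$spots$norm_volume)

  expect_error(normalize_volumes(tiny_gel(vol = c(0, 0, 0))), "all spot volumes are zero")
})

test_that("reference gel is the one with most spots, ties to the lowest index", {
  mk <- function(n, rep) tiny_gel("P7", rep, pi = seq(4, 8, length.out = n),
                                  mw = rep(40, n), vol = rep(10, n),
                                  ids = paste0("s", 1:n))
  # stage-mean-like counts: the 901-spot gel wins
  gels <- list(mk(901, 1), mk(637, 2), mk(775, 3))
  expect_equal(select_reference_gel(gels), 1L)
  expect_equal(select_reference_gel(list(mk(5, 1), mk(5, 2))), 1L)
  expect_equal(select_reference_gel(list(mk(3, 1), mk(9, 2), mk(6, 3))), 2L)
  expect_error(select_reference_gel(list()), "non-empty")
})

test_that("spots with identical coordinates across 18 gels form one group per position", {
  gels <- unlist(lapply(c("P7", "P90", "P637"), function(s)
    lapply(1:6, function(r)
      normalize_volumes(tiny_gel(s, r)))), recursive = FALSE)
  m <- match_spots(gels)
  expect_equal(length(unique(m$group_id)), 3L)
  expect_true(all(table(m$group_id) == 18L))
})

test_that("matching is injective per gel and recovers truth under small jitter", {
  # jitter well below the tolerances and spots separated by > 2x tolerance,
  # the regime in which position-based matching can succeed at all
  cfg <- clean_synth_config(n_proteins = 200, position_jitter = c(0.02, 0.004),
                            min_separation = c(0.2, 0.04), seed = 11)
  exp <- generate_experiment(cfg)
  gels <- lapply(exp$gels, normalize_volumes)
  m <- match_spots(gels, tol_pi = 0.1, tol_logmw = 0.02)
  # injectivity: one spot per gel per group
  expect_false(any(duplicated(m[, c("group_id", "gel")])))
  # each spot in exactly one group
  expect_equal(nrow(m), sum(vapply(gels, n_spots, integer(1))))
  # >= 99% of true groups recovered intact (all members, nothing foreign)
  truth_groups <- split(paste(m$gel), m$spot_id)
  found <- split(paste(m$gel, m$spot_id), m$group_id)
  truth_sets <- split(paste(m$gel, m$spot_id), m$spot_id)
  intact <- vapply(truth_sets, function(ts) any(vapply(found, identical, logical(1), ts)),
                   logical(1))
  expect_gte(mean(intact), 0.99)
})

test_that("well-separated spots are never merged and tie-break favours the higher volume", {
  # two spots separated by > 2x tolerance on each gel: no merges
  gels <- lapply(1:4, function(r) normalize_volumes(
    tiny_gel("P90", r, pi = c(5, 5.3), mw = c(40, 40), vol = c(10, 20),
             ids = c("a", "b"))))
  m <- match_spots(gels, tol_pi = 0.1, tol_logmw = 0.02)
  expect_equal(length(unique(m$group_id)), 2L)
  for (gid in unique(m$group_id))
    expect_equal(length(unique(m$spot_id[m$group_id == gid])), 1L)

  # equidistant pair: higher raw volume wins the link, the other is a singleton.
  # the reference gel (most spots) seeds the groups; the second gel offers two
  # spots at the same distance from the contested group's centroid
  ref <- normalize_volumes(tiny_gel("P90", 1, pi = c(5, 8), mw = c(40, 40),
                                    vol = c(100, 100), ids = c("ref", "far")))
  two <- normalize_volumes(tiny_gel("P90", 2, pi = c(4.95, 5.05), mw = c(40, 40),
                                    vol = c(5, 50), ids = c("weak", "strong")))
  m2 <- match_spots(list(ref, two), tol_pi = 0.1, tol_logmw = 0.02)
  linked <- m2$spot_id[m2$group_id == m2$group_id[m2$spot_id == "ref"]]
  expect_setequal(linked, c("ref", "strong"))
  weak_group <- m2$group_id[m2$spot_id == "weak"]
  expect_equal(sum(m2$group_id == weak_group), 1L) # the loser stays a singleton
  expect_error(match_spots(list(ref, two), tol_pi = 0), "positive")
})

test_that("experiment directories round-trip through write_experiment/read_experiment", {
  exp <- generate_experiment(clean_synth_config(n_proteins = 10, seed = 2))
  dir <- withr::local_tempdir()
  write_experiment(exp$gels, dir)
  gels2 <- read_experiment(dir)
  expect_equal(length(gels2), 18L)
  key <- function(g) paste(g$stage, g$replicate)
  reread <- gels2[[match(key(exp$gels[[1]]), vapply(gels2, key, character(1)))]]
  expect_equal(reread$spots, exp$gels[[1]]$spots)
})
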