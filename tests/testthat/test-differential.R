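test_that("SVQ is the ratio of detected means with one per-gel quotient per stage gel", {
  r <- compute_svq(rep(10, 6), rep(5, 6))
  expect_equal(r$svq, 2.0)
  eq <- compute_svq(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$svq, 1.0)
  expect_equal(eq$per_gel_svq, c(2, 1, 2/3))
  hand <- compute_svq(c(4, 6), c(1, 3))
  expect_equal(hand$svq, 2.5)
  expect_equal(hand$per_gel_svq, c(5, 5/3))
  expect_error(compute_svq(c(0, 0), c(1, 2)), "detect_absence")
})

test_that("direction classification uses inclusive 0.6 / 1.67 cut-offs", {
  expect_equal(classify_direction(3.09), "down")
  expect_equal(classify_direction(0.52), "up")
  expect_equal(classify_direction(1.0), "unchanged")
  expect_equal(classify_direction(1.67), "down")
  expect_equal(classify_direction(0.6), "up")
  expect_equal(classify_direction(c(0.61, 1.66)), c("unchanged", "unchanged"))
  expect_error(classify_direction(-1), "positive")
  # near-antisymmetry at the default cut-off pair: 1/1.67 <= 0.6
  for (s in c(1.67, 2, 3.5, 10))
    expect_equal(classify_direction(1 / s), "up")
})

test_that("the coverage rule counts per-gel passes on the consensus side", {
  cfg <- diff_config()
  # four of six per-gel quotients past the down cut-off: H = 4, passes
  r <- coverage_filter(c(2.1, 1.9, 1.8, 1.7, 1.5, 1.2), "down", cfg)
  expect_equal(r$h_count, 4L)
  expect_true(r$passes)
  r3 <- coverage_filter(c(2.1, 1.9, 1.8, 1.1, 1.5, 1.2), "down", cfg)
  expect_equal(r3$h_count, 3L)
  expect_false(r3$passes)
  up <- coverage_filter(c(0.5, 0.55, 0.6, 0.2, 0.9, 0.7), "up", cfg)
  expect_equal(up$h_count, 4L)
  expect_true(up$passes)
  na <- coverage_filter(c(1, 1, 1), "unchanged", cfg)
  expect_equal(na$h_count, 0L)
  expect_false(na$passes)
})

test_that("absence needs zero detections on one side and min_gels on the other", {
  cfg <- diff_config()
  expect_equal(detect_absence(6, 0, cfg), "absent_in_stage")
  expect_equal(detect_absence(0, 5, cfg), "absent_in_baseline")
  expect_true(is.na(detect_absence(2, 0, cfg)))
  expect_true(is.na(detect_absence(0, 3, cfg)))
  expect_true(is.na(detect_absence(5, 3, cfg)))
})

test_that("multi-spot aggregation means the member SVQs and flags conflicts", {
  cfg <- diff_config()
  mk <- function(svq, dir, stage = "P7") tibble::tibble(
    group_id = paste0("G", seq_along(svq)), stage = stage,
    n_baseline_detected = 6L, n_stage_detected = 6L, svq = svq,
    per_gel_svq = replicate(length(svq), rep(svq, 6), simplify = FALSE),
    h_count = 6L, direction = dir, p_value = 0.01,
    passes_coverage = dir %in% c("up", "down"),
    regulated = dir %in% c("up", "down"))
  two <- aggregate_protein(mk(c(2, 3), c("down", "down")), "ACC1", cfg)
  expect_equal(two$mean_svq, 2.5)
  expect_equal(two$direction, "down")
  expect_false(two$conflict)
  one <- aggregate_protein(mk(2.2, "down"), "ACC2", cfg)
  expect_equal(one$mean_svq, 2.2)
  expect_equal(one$direction, "down")
  confl <- aggregate_protein(mk(c(0.5, 2.2), c("up", "down")), "ACC3", cfg)
  expect_equal(confl$mean_svq, 1.35)
  expect_equal(confl$direction, "unchanged")
  expect_true(confl$conflict)
  expect_error(aggregate_protein(rbind(mk(2, "down", "P7"), mk(2, "down", "P637")),
                                 "ACC4", cfg), "mixed stages")
})

make_matches <- function(base_vols, stage_vols, stage = "P7", gid = "G00001") {
  # minimal long-format matches table for one group
  rows <- rbind(
    tibble::tibble(stage = "P90", replicate = seq_along(base_vols),
                   norm_volume = base_vols),
    tibble::tibble(stage = stage, replicate = seq_along(stage_vols),
                   norm_volume = stage_vols))
  rows$group_id <- gid
  rows$gel <- seq_len(nrow(rows))
  rows$spot_id <- "s1"; rows$pi <- 5; rows$mw_kda <- 40; rows$raw_volume <- rows$norm_volume
  rows
}

test_that("compare_stage routes zero-detection groups to the absence path", {
  # absent group: present in baseline gels only, but the stage exists in the data
  m2 <- rbind(make_matches(rep(100, 6), numeric(0)),
              make_matches(rep(50, 6), rep(60, 6), gid = "G00002"))
  cmp2 <- compare_stage(m2, "P7", diff_config())
  row <- cmp2[cmp2$group_id == "G00001", ]
  expect_equal(row$direction, "absent_in_stage")
  expect_true(is.na(row$svq))
  expect_false(row$regulated)
  # insufficient baseline evidence stays uncalled
  m3 <- rbind(make_matches(rep(100, 2), numeric(0)),
              make_matches(rep(50, 6), rep(60, 6), gid = "G00002"))
  cmp3 <- compare_stage(m3, "P7", diff_config())
  expect_true(is.na(cmp3$direction[cmp3$group_id == "G00001"]))
})

test_that("compare_stage calls a clean 3x depression down with full coverage", {
  m <- rbind(make_matches(rep(90, 6), rep(30, 6)),
             make_matches(rep(50, 6), rep(50, 6), gid = "G00002"))
  cmp <- compare_stage(m, "P7", diff_config())
  down <- cmp[cmp$group_id == "G00001", ]
  expect_equal(down$svq, 3)
  expect_equal(down$direction, "down")
  expect_equal(down$h_count, 6L)
  expect_true(down$regulated)
  expect_equal(down$p_value, 2 / 924)
  flat <- cmp[cmp$group_id == "G00002", ]
  expect_equal(flat$direction, "unchanged")
  expect_false(flat$regulated)
  expect_error(compare_stage(m, "P42"), "unknown stage")
})

test_that("regulated records always have H >= min_gels and SVQ outside the unchanged band", {
  cfg <- diff_config()
  for (seed in 1:20) {
    exp <- generate_experiment(synthetic_config(n_proteins = 40, seed = seed))
    res <- analyze_experiment(exp$gels, cfg, match_by = "spot_id")
    reg <- res$comparisons[res$comparisons$regulated, ]
    if (nrow(reg) > 0) {
      expect_true(all(reg$h_count >= cfg$min_gels))
      expect_true(all(reg$svq <= cfg$svq_up_max | reg$svq >= cfg$svq_down_min))
    }
    # reciprocity of the quotient itself on a random group
    cmp <- res$comparisons
    ok <- which(!is.na(cmp$svq))
    if (length(ok) > 0) {
      i <- ok[1]
      gid <- cmp$group_id[i]
      rows <- res$matches[res$matches$group_id == gid, ]
      b <- rows$norm_volume[rows$stage == "P90"]
      s <- rows$norm_volume[rows$stage == cmp$stage[i]]
      expect_equal(compute_svq(b, s)$svq * compute_svq(s, b)$svq, 1)
    }
  }
})

test_that("scaling all stage volumes up never flips a call from down towards up", {
  set.seed(99)
  for (i in 1:50) {
    b <- runif(6, 10, 100); s <- runif(6, 5, 60)
    q1 <- compute_svq(b, s)$svq
    for (f in c(1.5, 3, 10)) {
      q2 <- compute_svq(b, s * f)$svq
      d1 <- classify_direction(q1); d2 <- classify_direction(q2)
      # raising stage volumes lowers the quotient monotonically
      expect_lte(q2, q1)
      expect_false(d1 == "down" && d2 == "down" && q2 > q1)
    }
  }
})

test_that("the pairwise coverage variant is available behind a flag", {
  cfg <- diff_config(pairwise_coverage = TRUE)
  m <- make_matches(rep(90, 6), rep(30, 6))
  cmp <- compare_stage(m, "P7", cfg)
  expect_equal(cmp$direction, "down")
  expect_equal(cmp$h_count, 6L)
  expect_true(cmp$regulated)
})
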