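# Differential calling on matched spot groups: spot volume quotients (SVQ),
# direction classification, the multi-gel coverage rule, absence detection,
# exact Mann-Whitney testing and multi-spot protein aggregation.
#
# The SVQ convention is baseline/stage (e.g. P90/P7): a LOW quotient means
# the compared stage is UP-regulated relative to the adult baseline. A spot
# is called regulated only if its SVQ passes the cut-off AND does so in at
# least `min_gels` of the stage's replicate gels (the coverage rule); the
# Mann-Whitney p-value is reported alongside but is not used as a gate,
# mirroring the coverage method's role as the primary criterion.

#' Configuration for differential calling
#'
#' @param svq_up_max SVQ at or below which a spot is up-regulated in the
#'   compared stage (default 0.6).
#' @param svq_down_min SVQ at or above which a spot is down-regulated
#'   (default 1.67). Both cut-offs are inclusive.
#' @param min_gels Minimum number of stage gels whose per-gel quotient must
#'   pass the cut-off on the consensus side (default 4 of 6).
#' @param alpha Significance level for the reported Mann-Whitney test.
#' @param detection_floor Normalised volume at or below which a spot counts
#'   as undetected (default 0: presence in the table is detection).
#' @param baseline_stage Baseline stage label (default `"P90"`).
#' @param pairwise_coverage If `TRUE`, the per-gel "change" for the coverage
#'   rule is assessed pairwise against every baseline gel (a stage gel counts
#'   when at least half its pairwise quotients pass) instead of against the
#'   baseline mean. Off by default.
#' @param compute_p Compute Mann-Whitney p-values in [compare_stage()]
#'   (default `TRUE`).
#' @return A validated list of class `diff_config`.
#' @export
diff_config <- function(svq_up_max = 0.6, svq_down_min = 1.67, min_gels = 4L,
                        alpha = 0.05, detection_floor = 0,
                        baseline_stage = "P90", pairwise_coverage = FALSE,
                        compute_p = TRUE) {
  if (!is_number(svq_up_max) || !is_number(svq_down_min) ||
      !(0 < svq_up_max && svq_up_max < 1 && 1 < svq_down_min))
    stopf("cut-offs must satisfy 0 < svq_up_max < 1 < svq_down_min")
  if (!is_count(min_gels, min = 1L)) stopf("min_gels must be a positive integer")
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (!is_number(detection_floor) || detection_floor < 0)
    stopf("detection_floor must be >= 0")
  structure(list(svq_up_max = svq_up_max, svq_down_min = svq_down_min,
                 min_gels = as.integer(min_gels), alpha = alpha,
                 detection_floor = detection_floor,
                 baseline_stage = baseline_stage,
                 pairwise_coverage = isTRUE(pairwise_coverage),
                 compute_p = isTRUE(compute_p)),
            class = "diff_config")
}

#' Spot volume quotient
#'
#' `svq = mean(baseline) / mean(stage)` over detected volumes, plus one
#' per-gel quotient `mean(baseline) / stage_volume[i]` for each detected
#' stage gel (the inputs to the coverage rule).
#'
#' @param baseline_volumes,stage_volumes Detected normalised volumes (both
#'   must contain at least one value above `detection_floor`).
#' @param detection_floor Volumes at or below this are dropped first.
#' @return A list with `svq` and `per_gel_svq`.
#' @examples
#' compute_svq(c(4, 6), c(1, 3))  # svq 2.5, per-gel 5 and 5/3
#' @export
compute_svq <- function(baseline_volumes, stage_volumes, detection_floor = 0) {
  b <- baseline_volumes[baseline_volumes > detection_floor]
  s <- stage_volumes[stage_volumes > detection_floor]
  if (length(b) == 0L || length(s) == 0L)
    stopf("compute_svq needs >= 1 detected volume on each side; use detect_absence for zero-detection groups")
  mb <- mean(b)
  list(svq = mb / mean(s), per_gel_svq = mb / s)
}

#' Classify an SVQ into a regulation direction
#'
#' Up-regulated (in the compared stage) iff `svq <= svq_up_max`;
#' down-regulated iff `svq >= svq_down_min`; otherwise unchanged. Both
#' boundaries are inclusive. Vectorised over `svq`.
#'
#' @param svq Positive spot volume quotient(s), baseline/stage.
#' @param config A [diff_config()].
#' @return Character vector in `c("up", "down", "unchanged")`.
#' @export
classify_direction <- function(svq, config = diff_config()) {
  if (any(!is.na(svq) & svq <= 0)) stopf("svq must be positive")
  ifelse(svq <= config$svq_up_max, "up",
         ifelse(svq >= config$svq_down_min, "down", "unchanged"))
}

#' Multi-gel coverage rule
#'
#' Counts the per-gel quotients that pass the cut-off on the consensus side
#' (the H statistic) and tests it against `min_gels`. Not applicable when
#' the consensus direction is `"unchanged"`: then `h_count = 0` and the
#' filter fails.
#'
#' @param per_gel_svq Per-gel quotients from [compute_svq()].
#' @param consensus_direction `"up"` or `"down"`.
#' @param config A [diff_config()].
#' @return A list with `h_count` and `passes`.
#' @export
coverage_filter <- function(per_gel_svq, consensus_direction, config = diff_config()) {
  if (!consensus_direction %in% c("up", "down"))
    return(list(h_count = 0L, passes = FALSE))
  h <- if (consensus_direction == "up") sum(per_gel_svq <= config$svq_up_max)
       else sum(per_gel_svq >= config$svq_down_min)
  list(h_count = as.integer(h), passes = h >= config$min_gels)
}

#' Absence detection
#'
#' A spot absent from every gel of one side is called
#' `"absent_in_stage"` / `"absent_in_baseline"` when the other side detects
#' it in at least `min_gels` gels; with fewer detections the evidence is
#' considered insufficient and `NA` is returned (no quotient exists either
#' way).
#'
#' @param baseline_detections,stage_detections Detection counts.
#' @param config A [diff_config()].
#' @return `"absent_in_stage"`, `"absent_in_baseline"`, or `NA_character_`.
#' @export
detect_absence <- function(baseline_detections, stage_detections,
                           config = diff_config()) {
  if (stage_detections == 0L && baseline_detections >= config$min_gels)
    return("absent_in_stage")
  if (baseline_detections == 0L && stage_detections >= config$min_gels)
    return("absent_in_baseline")
  NA_character_
}

pairwise_h_count <- function(b, s, direction, config) {
  # a stage gel counts as changed when >= half its per-baseline-gel
  # quotients pass the cut-off on the consensus side
  q <- outer(b, s, function(bb, ss) bb / ss) # baseline x stage
  pass <- if (direction == "up") q <= config$svq_up_max else q >= config$svq_down_min
  sum(colMeans(pass) >= 0.5)
}

#' Stage-versus-baseline comparison of all matched groups
#'
#' Emits one row per matched group detected in the baseline or compared
#' stage: the SVQ, the coverage H count, the classified direction (including
#' absence calls), the exact Mann-Whitney p-value (reported, not gating) and
#' the final `regulated` flag, which requires a non-`unchanged` direction
#' AND a passing coverage filter. Groups detected on only one side with
#' fewer than `min_gels` detections are kept but left uncalled
#' (`direction = NA`).
#'
#' @param matches Long tibble from [match_spots()] or [group_by_spot_id()]
#'   over normalised gels.
#' @param stage Compared stage label (must differ from the baseline).
#' @param config A [diff_config()].
#' @return A tibble with columns `group_id`, `stage`, `n_baseline_detected`,
#'   `n_stage_detected`, `svq`, `per_gel_svq` (list), `h_count`,
#'   `direction`, `p_value`, `passes_coverage`, `regulated`.
#' @export
compare_stage <- function(matches, stage, config = diff_config()) {
  stages_present <- unique(matches$stage)
  if (!stage %in% stages_present) stopf("unknown stage label '%s'", stage)
  if (!config$baseline_stage %in% stages_present)
    stopf("baseline stage '%s' not present in matches", config$baseline_stage)
  if (stage == config$baseline_stage) stopf("stage must differ from the baseline")
  floor <- config$detection_floor
  rows <- matches[matches$stage %in% c(stage, config$baseline_stage) &
                    matches$norm_volume > floor, ]
  is_base <- rows$stage == config$baseline_stage
  b_split <- split(rows$norm_volume[is_base], rows$group_id[is_base])
  s_split <- split(rows$norm_volume[!is_base], rows$group_id[!is_base])
  groups <- sort(union(names(b_split), names(s_split)))
  n <- length(groups)
  res <- list(svq = rep(NA_real_, n), h = rep(NA_integer_, n),
              dir = rep(NA_character_, n), p = rep(NA_real_, n),
              pass = rep(FALSE, n), reg = rep(FALSE, n),
              nb = integer(n), ns = integer(n), pg = vector("list", n))
  for (i in seq_len(n)) {
    b <- b_split[[groups[i]]] %||% numeric(0)
    s <- s_split[[groups[i]]] %||% numeric(0)
    res$nb[i] <- length(b); res$ns[i] <- length(s)
    if (length(b) == 0L || length(s) == 0L) {
      res$dir[i] <- detect_absence(length(b), length(s), config)
      next
    }
    q <- compute_svq(b, s, floor)
    res$svq[i] <- q$svq
    res$pg[[i]] <- q$per_gel_svq
    d <- classify_direction(q$svq, config)
    res$dir[i] <- d
    if (d %in% c("up", "down")) {
      h <- if (config$pairwise_coverage)
        list(h_count = pairwise_h_count(b, s, d, config),
             passes = NA) # filled below
      else coverage_filter(q$per_gel_svq, d, config)
      if (config$pairwise_coverage) h$passes <- h$h_count >= config$min_gels
      res$h[i] <- h$h_count
      res$pass[i] <- h$passes
      res$reg[i] <- h$passes
    }
    if (config$compute_p && length(b) >= 2L && length(s) >= 2L)
      res$p[i] <- mann_whitney_exact(b, s)$p_value
  }
  tibble::tibble(group_id = groups, stage = stage,
                 n_baseline_detected = res$nb, n_stage_detected = res$ns,
                 svq = res$svq, per_gel_svq = res$pg, h_count = res$h,
                 direction = res$dir, p_value = res$p,
                 passes_coverage = res$pass, regulated = res$reg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate spot-level comparisons to one protein
#'
#' When one protein is resolved in several spots, its differential
#' expression is the arithmetic mean of the member-spot SVQs, re-classified
#' with the same cut-offs. Absence calls propagate only when every member
#' spot agrees; members regulated in opposite directions raise a `conflict`
#' flag (such proteins are conventionally marked with an asterisk).
#'
#' @param spot_comparisons Rows of a [compare_stage()] result belonging to
#'   one protein (all at the same stage).
#' @param accession Protein accession to report.
#' @param config A [diff_config()].
#' @return One-row tibble: `accession`, `stage`, `spot_group_ids` (list),
#'   `n_spots`, `mean_svq`, `direction`, `h_count`, `p_value`,
#'   `conflict`.
#' @export
aggregate_protein <- function(spot_comparisons, accession, config = diff_config()) {
  sc <- spot_comparisons
  if (nrow(sc) == 0L) stopf("no spot comparisons for %s", accession)
  if (length(unique(sc$stage)) != 1L)
    stopf("aggregate_protein: mixed stages for %s", accession)
  svqs <- sc$svq[!is.na(sc$svq)]
  member_dirs <- sc$direction
  conflict <- any(member_dirs == "up", na.rm = TRUE) &&
    any(member_dirs == "down", na.rm = TRUE)
  if (length(svqs) == 0L) {
    # all members on the absence (or uncalled) path
    abs_dirs <- unique(member_dirs[!is.na(member_dirs)])
    direction <- if (length(abs_dirs) == 1L) abs_dirs else NA_character_
    mean_svq <- NA_real_
  } else {
    mean_svq <- mean(svqs)
    direction <- classify_direction(mean_svq, config)
    # an absence call on one member but a quotient on another is a conflict
    if (any(member_dirs %in% c("absent_in_stage", "absent_in_baseline"), na.rm = TRUE))
      conflict <- TRUE
  }
  # representative coverage/p: the member with the most extreme quotient
  rep_i <- if (length(svqs) > 0L)
    which.max(abs(log(ifelse(is.na(sc$svq), 1, sc$svq)))) else 1L
  tibble::tibble(accession = accession, stage = sc$stage[1],
                 spot_group_ids = list(sc$group_id), n_spots = nrow(sc),
                 mean_svq = mean_svq, direction = direction,
                 h_count = sc$h_count[rep_i], p_value = sc$p_value[rep_i],
                 conflict = conflict)
}

#' Aggregate all proteins of one stage comparison
#'
#' @param comparisons A [compare_stage()] result.
#' @param group_map Tibble mapping `group_id` to `accession` (e.g. from PMF
#'   identifications or [truth_spot_map()] joined on spot ids). Groups
#'   without an accession are skipped.
#' @param config A [diff_config()].
#' @return A tibble with one row per accession (see [aggregate_protein()]).
#' @export
aggregate_proteins <- function(comparisons, group_map, config = diff_config()) {
  gm <- group_map[group_map$group_id %in% comparisons$group_id, ]
  accs <- sort(unique(gm$accession))
  rows <- lapply(accs, function(a) {
    gids <- gm$group_id[gm$accession == a]
    aggregate_protein(comparisons[comparisons$group_id %in% gids, ], a, config)
  })
  do.call(rbind, rows)
}
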