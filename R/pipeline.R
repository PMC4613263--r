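# End-to-end convenience drivers: simulate -> analyze -> report.

#' Simulate an experiment to disk
#'
#' Generates a synthetic experiment and writes the spot tables
#' (`{stage}_rep{k}.tsv`), the ground truth (`truth.tsv`) and a run
#' manifest (`manifest.json`) into `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @return The generated experiment (list with `gels`, `truth`), invisibly.
#' @export
simulate_experiment <- function(config, dir) {
  exp <- generate_experiment(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_experiment(exp$gels, dir)
  write_truth(exp$truth, file.path(dir, "truth.tsv"))
  write_manifest(file.path(dir, "manifest.json"), config$seed,
                 list(synthetic = config))
  invisible(exp)
}

#' Analyze a set of gels
#'
#' Normalises every gel, matches spots across gels (or groups them by their
#' shared identifiers for synthetic data), and runs the stage-versus-
#' baseline comparison for every non-baseline stage.
#'
#' @param gels List of [gel_table()] objects (raw volumes are fine; they are
#'   normalised here).
#' @param config A [diff_config()].
#' @param tol_pi,tol_logmw Matching tolerances, see [match_spots()].
#' @param match_by `"position"` (default; [match_spots()]) or `"spot_id"`
#'   ([group_by_spot_id()], for synthetic data with shared identifiers).
#' @return A list with `matches` (long tibble) and `comparisons` (tibble of
#'   [compare_stage()] rows over all non-baseline stages).
#' @export
analyze_experiment <- function(gels, config = diff_config(), tol_pi = 0.1,
                               tol_logmw = 0.02,
                               match_by = c("position", "spot_id")) {
  match_by <- match.arg(match_by)
  gels <- lapply(gels, normalize_volumes)
  matches <- if (match_by == "position") match_spots(gels, tol_pi, tol_logmw)
             else group_by_spot_id(gels)
  stages <- setdiff(unique(matches$stage), config$baseline_stage)
  comparisons <- do.call(rbind, lapply(stages, function(s)
    compare_stage(matches, s, config)))
  list(matches = matches, comparisons = comparisons)
}

#' Report protein-level results for every stage contrast
#'
#' Aggregates spot comparisons to proteins, attaches functional groups and
#' writes per-stage results and summary TSVs. No multiple-testing
#' correction is applied to the reported Mann-Whitney p-values; the
#' coverage rule, not the test, is the calling criterion.
#'
#' @param comparisons Tibble from [analyze_experiment()].
#' @param group_map Tibble mapping `group_id` to `accession`.
#' @param annotation Optional named vector from [read_annotation()].
#' @param dir Optional output directory for TSV artifacts.
#' @param config A [diff_config()].
#' @return A list with `proteins` (tibble over all stages) and `summaries`
#'   (named list per stage with `regulation` and `categories` tibbles).
#' @export
report_experiment <- function(comparisons, group_map, annotation = NULL,
                              dir = NULL, config = diff_config()) {
  stages <- unique(comparisons$stage)
  proteins <- do.call(rbind, lapply(stages, function(s)
    aggregate_proteins(comparisons[comparisons$stage == s, ], group_map, config)))
  if (!is.null(annotation)) proteins <- assign_groups(proteins, annotation)
  summaries <- lapply(stages, function(s) {
    ps <- proteins[proteins$stage == s, ]
    list(regulation = summarize_regulation(ps),
         categories = if (!is.null(annotation)) summarize_categories(ps) else NULL)
  })
  names(summaries) <- stages
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in stages) {
      write_results_table(proteins[proteins$stage == s, ],
                          file.path(dir, sprintf("results_%s.tsv", s)))
      write_summary_table(summaries[[s]]$regulation,
                          file.path(dir, sprintf("summary_%s.tsv", s)))
      if (!is.null(summaries[[s]]$categories))
        write_summary_table(summaries[[s]]$categories,
                            file.path(dir, sprintf("categories_%s.tsv", s)))
    }
  }
  list(proteins = proteins, summaries = summaries)
}
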