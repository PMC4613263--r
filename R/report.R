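# Functional-category assignment, regulation summaries and result tables.

#' Read an annotation map
#'
#' A two-column TSV `accession<TAB>group` (an optional header line with
#' those names is skipped) mapping accessions to functional categories,
#' e.g. carbohydrate metabolism, biosynthesis, chaperones, structural or
#' transport proteins.
#'
#' @param path File path.
#' @return A named character vector (accession -> group).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  start <- 1L
  if (length(lines) > 0L &&
      identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]], c("accession", "group")))
    start <- 2L
  acc <- character(0); grp <- character(0)
  for (i in seq_along(lines)) {
    if (i < start) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L)
      stopf("%s: line %d: expected 2 tab-separated fields, got %d",
            path, i, length(fields))
    acc <- c(acc, fields[1]); grp <- c(grp, fields[2])
  }
  if (anyDuplicated(acc)) {
    dup <- which(duplicated(acc))[1]
    stopf("%s: line %d: duplicate accession '%s'", path, dup + start - 1L, acc[dup])
  }
  stats::setNames(grp, acc)
}

#' Assign functional groups to protein results
#'
#' @param protein_results Tibble with an `accession` column (e.g. from
#'   [aggregate_proteins()]).
#' @param annotation Named character vector from [read_annotation()].
#' @return The results with a `functional_group` column; accessions missing
#'   from the map become `"unclassified"`.
#' @export
assign_groups <- function(protein_results, annotation) {
  if (length(annotation) == 0L)
    warnf("empty annotation map: all proteins will be unclassified")
  grp <- unname(annotation[protein_results$accession])
  grp[is.na(grp)] <- "unclassified"
  protein_results$functional_group <- grp
  protein_results
}

regulated_directions <- c("up", "down", "absent_in_stage", "absent_in_baseline")

#' Regulation overview for one stage contrast
#'
#' Counts differentially expressed proteins the way a study overview table
#' does: Total, Up-regulated, Down-regulated, Absent (in the compared
#' stage), Absent baseline. The total equals the sum of the four categories.
#'
#' @param protein_results Results for one stage contrast, with a
#'   `direction` column.
#' @return A tibble with `category` and `count`.
#' @export
summarize_regulation <- function(protein_results) {
  if (length(unique(protein_results$stage)) > 1L)
    stopf("summarize_regulation expects results for a single stage contrast")
  d <- protein_results$direction
  counts <- c(
    "Up-regulated" = sum(d == "up", na.rm = TRUE),
    "Down-regulated" = sum(d == "down", na.rm = TRUE),
    "Absent" = sum(d == "absent_in_stage", na.rm = TRUE),
    "Absent baseline" = sum(d == "absent_in_baseline", na.rm = TRUE))
  tibble::tibble(category = c("Total", names(counts)),
                 count = unname(as.integer(c(sum(counts), counts))))
}

#' Per-functional-group counts and relative frequencies
#'
#' Counts differentially expressed proteins (up, down or absent) per
#' functional group; relative frequencies sum to 1. With no regulated
#' proteins an empty table is returned with a message.
#'
#' @param annotated_results Output of [assign_groups()] for one stage.
#' @return A tibble with `functional_group`, `n_up`, `n_down`, `n_absent`,
#'   `n_total`, `rel_freq`.
#' @export
summarize_categories <- function(annotated_results) {
  reg <- annotated_results[!is.na(annotated_results$direction) &
                             annotated_results$direction %in% regulated_directions, ]
  if (nrow(reg) == 0L) {
    message("no differentially expressed proteins; empty category summary")
    return(tibble::tibble(functional_group = character(0), n_up = integer(0),
                          n_down = integer(0), n_absent = integer(0),
                          n_total = integer(0), rel_freq = numeric(0)))
  }
  sp <- split(reg$direction, reg$functional_group)
  out <- tibble::tibble(
    functional_group = names(sp),
    n_up = unname(vapply(sp, function(d) sum(d == "up"), integer(1))),
    n_down = unname(vapply(sp, function(d) sum(d == "down"), integer(1))),
    n_absent = unname(vapply(sp, function(d) sum(d %in% c("absent_in_stage",
                                                          "absent_in_baseline")),
                             integer(1))))
  out$n_total <- out$n_up + out$n_down + out$n_absent
  out$rel_freq <- out$n_total / sum(out$n_total)
  out[order(-out$n_total, out$functional_group), ]
}

#' Write a protein-level results table
#'
#' TSV mirroring the usual published layout: accession, stage, regulation,
#' p-value, SVQ (labelled `Control/PD`), coverage count (labelled `H`) and
#' the number of member spots.
#'
#' @param protein_results Tibble from [aggregate_proteins()] (optionally
#'   after [assign_groups()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(protein_results, path) {
  df <- data.frame(
    accession = protein_results$accession,
    stage = protein_results$stage,
    regulation = protein_results$direction,
    p_value = protein_results$p_value,
    `Control/PD` = protein_results$mean_svq,
    H = protein_results$h_count,
    n_spots = protein_results$n_spots,
    check.names = FALSE)
  if ("functional_group" %in% names(protein_results))
    df$functional_group <- protein_results$functional_group
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a regulation summary table
#'
#' @param summary Tibble from [summarize_regulation()] or
#'   [summarize_categories()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the package version, seed and flattened configuration of a run as
#' JSON so any output can be reproduced exactly. Deliberately excludes
#' timestamps: re-running from a manifest must be byte-identical.
#'
#' @param path Output path.
#' @param seed Integer seed of the run.
#' @param configs Named list of configuration objects (coerced to plain
#'   lists).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, configs = list()) {
  manifest <- list(
    package = "spotdiff",
    version = as.character(utils::packageVersion("spotdiff")),
    seed = seed,
    configs = lapply(configs, unclass))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest path written by [write_manifest()].
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) jsonlite::fromJSON(path, simplifyVector = TRUE)
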