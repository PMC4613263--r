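# Spot-table IO, volume normalisation, reference-gel selection and
# cross-gel spot matching.
#
# A "gel table" is the spot-level digest of one 2DE gel image: one row per
# detected spot with its isoelectric point (pI), molecular weight (kDa) and
# integrated stain volume. All image-level processing (warping, segmentation)
# is out of scope; the pipeline starts from these tables.

#' Construct a gel table
#'
#' @param stage Stage label (e.g. `"P7"`).
#' @param replicate Replicate index (1-based).
#' @param spots A data frame with columns `spot_id`, `pi`, `mw_kda`,
#'   `raw_volume` and optionally `norm_volume`.
#' @return An object of class `gel_table`: a list with elements `stage`,
#'   `replicate` and `spots` (a tibble).
#' @export
gel_table <- function(stage, replicate, spots) {
  if (!is.character(stage) || length(stage) != 1L) stopf("stage must be a single label")
  if (!is_count(replicate, min = 1L)) stopf("replicate must be a positive integer")
  spots <- tibble::as_tibble(spots)
  required <- c("spot_id", "pi", "mw_kda", "raw_volume")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0L)
    stopf("spots is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (!"norm_volume" %in% names(spots)) spots$norm_volume <- NA_real_
  spots <- spots[, c(required, "norm_volume")]
  spots$spot_id <- as.character(spots$spot_id)
  if (anyDuplicated(spots$spot_id))
    stopf("duplicate spot_id within gel %s_rep%d: %s", stage, replicate,
          paste(unique(spots$spot_id[duplicated(spots$spot_id)]), collapse = ", "))
  if (any(!is.finite(spots$raw_volume)) || any(spots$raw_volume < 0))
    stopf("raw_volume must be finite and >= 0")
  if (any(spots$pi < 0 | spots$pi > 14)) stopf("pI outside [0, 14]")
  if (any(spots$mw_kda <= 0)) stopf("mw_kda must be > 0")
  structure(list(stage = stage, replicate = as.integer(replicate), spots = spots),
            class = "gel_table")
}

#' @export
print.gel_table <- function(x, ...) {
  cat(sprintf("<gel_table> stage %s, replicate %d: %d spots\n",
              x$stage, x$replicate, nrow(x$spots)))
  print(x$spots, ...)
  invisible(x)
}

#' Number of spots on a gel
#' @param gel A `gel_table`.
#' @return Integer spot count.
#' @export
n_spots <- function(gel) nrow(gel$spots)

spot_table_header <- c("spot_id", "pi", "mw_kda", "raw_volume", "norm_volume")

#' Read a spot table from a TSV file
#'
#' The dialect is a UTF-8 tab-separated file with header
#' `spot_id<TAB>pi<TAB>mw_kda<TAB>raw_volume[<TAB>norm_volume]` and `.` as
#' decimal separator. Malformed rows are rejected with their line number.
#'
#' @param path File path. If `stage`/`replicate` are not supplied they are
#'   parsed from a file name of the form `{stage}_rep{k}.tsv`.
#' @param stage,replicate Optional stage label and replicate index.
#' @return A [gel_table()].
#' @export
read_spot_table <- function(path, stage = NULL, replicate = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (is.null(stage) || is.null(replicate)) {
    base <- sub("\\.tsv$", "", basename(path))
    m <- regmatches(base, regexec("^(.+)_rep([0-9]+)$", base))[[1]]
    if (length(m) != 3L)
      stopf("cannot parse stage/replicate from file name '%s'; pass them explicitly",
            basename(path))
    if (is.null(stage)) stage <- m[2]
    if (is.null(replicate)) replicate <- as.integer(m[3])
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stopf("%s: empty file", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, spot_table_header[seq_along(header)]) ||
      length(header) < 4L || length(header) > 5L)
    stopf("%s: line 1: bad header '%s'", path, lines[1])
  has_norm <- length(header) == 5L
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  ids <- character(n); num <- matrix(NA_real_, n, 4L)
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    lineno <- i + 1L
    if (length(fields) != length(header))
      stopf("%s: line %d: expected %d fields, got %d", path, lineno,
            length(header), length(fields))
    ids[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals))
      stopf("%s: line %d: non-numeric value '%s'", path, lineno,
            fields[-1][which(is.na(vals))[1]])
    num[i, seq_along(vals)] <- vals
    if (vals[3] < 0)
      stopf("%s: line %d: negative raw_volume (%s)", path, lineno, fields[4])
    if (vals[1] < 0 || vals[1] > 14)
      stopf("%s: line %d: pI %s outside [0, 14]", path, lineno, fields[2])
    if (vals[2] <= 0)
      stopf("%s: line %d: non-positive mw_kda (%s)", path, lineno, fields[3])
  }
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[1]
    stopf("%s: line %d: duplicate spot_id '%s'", path, dup + 1L, ids[dup])
  }
  spots <- tibble::tibble(spot_id = ids, pi = num[, 1], mw_kda = num[, 2],
                          raw_volume = num[, 3],
                          norm_volume = if (has_norm) num[, 4] else NA_real_)
  gel_table(stage, replicate, spots)
}

#' Write a spot table to a TSV file
#'
#' @param gel A [gel_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(gel, path) {
  stopifnot(inherits(gel, "gel_table"))
  sp <- gel$spots
  has_norm <- any(is.finite(sp$norm_volume))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))
  cols <- cbind(sp$spot_id, fmt(sp$pi), fmt(sp$mw_kda), fmt(sp$raw_volume),
                if (has_norm) fmt(sp$norm_volume))
  header <- spot_table_header[seq_len(4L + has_norm)]
  lines <- c(paste(header, collapse = "\t"),
             apply(cols, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Normalise spot volumes to parts-per-million of total gel volume
#'
#' Each spot's normalised volume is its raw volume divided by the summed raw
#' volume of the gel, times 1e6. Within-gel volume ratios are preserved
#' exactly and the normalised volumes sum to 1e6.
#'
#' @param gel A [gel_table()] with at least one positive raw volume.
#' @return The gel with `norm_volume` filled in.
#' @export
normalize_volumes <- function(gel) {
  stopifnot(inherits(gel, "gel_table"))
  total <- sum(gel$spots$raw_volume)
  if (total <= 0)
    stopf("gel %s_rep%d: all spot volumes are zero; cannot normalise",
          gel$stage, gel$replicate)
  gel$spots$norm_volume <- gel$spots$raw_volume / total * 1e6
  gel
}

#' Select the reference gel
#'
#' Picks the gel with the largest spot count; ties are broken by the lowest
#' list position. Image-quality criteria (separation, staining, artifacts)
#' are not computable from spot tables and are deliberately not modelled.
#'
#' @param gels A non-empty list of [gel_table()] objects.
#' @return The index of the reference gel within `gels`.
#' @export
select_reference_gel <- function(gels) {
  if (!is.list(gels) || length(gels) == 0L) stopf("gels must be a non-empty list")
  counts <- vapply(gels, n_spots, integer(1))
  which.max(counts) # first maximum = lowest index on ties
}

#' Match spots across gels
#'
#' Greedy mutual-nearest-neighbour linkage in (pI, log10 MW) space, seeded
#' from the reference gel. Gels are visited reference-first; within each gel,
#' candidate (group, spot) links inside the tolerance box
#' (`|dpI| <= tol_pi`, `|dlog10 MW| <= tol_logmw`) are accepted in order of
#' increasing normalised distance, ties broken in favour of the
#' higher-volume spot, so each gel contributes at most one spot per group.
#' Spots left over start new groups, which later gels may join; spots never
#' matched at all end up as singleton groups.
#'
#' @param gels List of normalised [gel_table()] objects.
#' @param tol_pi Matching tolerance on pI (pH units, default 0.1).
#' @param tol_logmw Matching tolerance on log10 molecular weight
#'   (dimensionless, default 0.02).
#' @return A tibble with one row per (group, gel member): columns
#'   `group_id`, `gel`, `stage`, `replicate`, `spot_id`, `pi`, `mw_kda`,
#'   `raw_volume`, `norm_volume`. Group centroids are obtainable with
#'   [group_centroids()].
#' @export
match_spots <- function(gels, tol_pi = 0.1, tol_logmw = 0.02) {
  if (!is.list(gels) || length(gels) == 0L) stopf("gels must be a non-empty list")
  if (!is_number(tol_pi) || tol_pi <= 0 || !is_number(tol_logmw) || tol_logmw <= 0)
    stopf("matching tolerances must be positive")
  ref <- select_reference_gel(gels)
  visit <- c(ref, setdiff(seq_along(gels), ref))

  # growing group state
  cent_pi <- numeric(0); cent_lmw <- numeric(0); cent_n <- integer(0)
  assign_rows <- vector("list", length(gels))

  for (g in visit) {
    sp <- gels[[g]]$spots
    ns <- nrow(sp)
    group_of <- rep(NA_integer_, ns)
    if (length(cent_pi) > 0L && ns > 0L) {
      lmw <- log10(sp$mw_kda)
      dpi <- outer(cent_pi, sp$pi, "-")
      dlm <- outer(cent_lmw, lmw, "-")
      ok <- abs(dpi) <= tol_pi & abs(dlm) <= tol_logmw
      if (any(ok)) {
        cand <- which(ok, arr.ind = TRUE)
        d <- sqrt((dpi[ok] / tol_pi)^2 + (dlm[ok] / tol_logmw)^2)
        ord <- order(d, -sp$raw_volume[cand[, 2]], cand[, 2])
        used_group <- rep(FALSE, length(cent_pi))
        for (k in ord) {
          gi <- cand[k, 1]; si <- cand[k, 2]
          if (used_group[gi] || !is.na(group_of[si])) next
          used_group[gi] <- TRUE
          group_of[si] <- gi
        }
      }
    }
    new <- which(is.na(group_of))
    if (length(new) > 0L) {
      group_of[new] <- length(cent_pi) + seq_along(new)
      cent_pi <- c(cent_pi, sp$pi[new])
      cent_lmw <- c(cent_lmw, log10(sp$mw_kda[new]))
      cent_n <- c(cent_n, rep(0L, length(new)))
    }
    # running centroid update
    upd <- group_of
    cent_pi[upd] <- (cent_pi[upd] * cent_n[upd] + sp$pi) / (cent_n[upd] + 1L)
    cent_lmw[upd] <- (cent_lmw[upd] * cent_n[upd] + log10(sp$mw_kda)) / (cent_n[upd] + 1L)
    cent_n[upd] <- cent_n[upd] + 1L
    assign_rows[[g]] <- tibble::tibble(
      group = group_of, gel = g,
      stage = gels[[g]]$stage, replicate = gels[[g]]$replicate,
      spot_id = sp$spot_id, pi = sp$pi, mw_kda = sp$mw_kda,
      raw_volume = sp$raw_volume, norm_volume = sp$norm_volume)
  }
  out <- do.call(rbind, assign_rows)
  out$group_id <- sprintf("G%05d", out$group)
  out$group <- NULL
  out[order(out$group_id, out$gel), c("group_id", "gel", "stage", "replicate",
                                      "spot_id", "pi", "mw_kda",
                                      "raw_volume", "norm_volume")]
}

#' Group spots across gels by shared spot identifier
#'
#' Synthetic gel tables carry the same spot identifier for the same physical
#' spot on every gel, so grouping by id recovers the ground-truth matching.
#' Useful both as an oracle against [match_spots()] and to run the
#' differential stage on simulated data without matching noise.
#'
#' @param gels List of [gel_table()] objects.
#' @return A tibble in the same layout as [match_spots()].
#' @export
group_by_spot_id <- function(gels) {
  rows <- lapply(seq_along(gels), function(g) {
    sp <- gels[[g]]$spots
    tibble::tibble(spot_id = sp$spot_id, gel = g, stage = gels[[g]]$stage,
                   replicate = gels[[g]]$replicate, pi = sp$pi,
                   mw_kda = sp$mw_kda, raw_volume = sp$raw_volume,
                   norm_volume = sp$norm_volume)
  })
  out <- do.call(rbind, rows)
  ids <- sort(unique(out$spot_id))
  out$group_id <- sprintf("G%05d", match(out$spot_id, ids))
  out[order(out$group_id, out$gel), c("group_id", "gel", "stage", "replicate",
                                      "spot_id", "pi", "mw_kda",
                                      "raw_volume", "norm_volume")]
}

#' Centroids of matched groups
#'
#' @param matches Output of [match_spots()] or [group_by_spot_id()].
#' @return A tibble with `group_id`, `pi`, `mw_kda` (geometric mean on the
#'   MW axis) and `n_members`.
#' @export
group_centroids <- function(matches) {
  sp <- split(seq_len(nrow(matches)), matches$group_id)
  tibble::tibble(
    group_id = names(sp),
    pi = unname(vapply(sp, function(i) mean(matches$pi[i]), numeric(1))),
    mw_kda = unname(vapply(sp, function(i) 10^mean(log10(matches$mw_kda[i])),
                           numeric(1))),
    n_members = unname(lengths(sp)))
}

#' Read a directory of spot tables
#'
#' Reads every `{stage}_rep{k}.tsv` file in `dir`.
#'
#' @param dir Directory containing spot tables.
#' @return A list of [gel_table()] objects, ordered by stage then replicate.
#' @export
read_experiment <- function(dir) {
  files <- list.files(dir, pattern = "_rep[0-9]+\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stopf("no spot tables (*_rep*.tsv) found in %s", dir)
  gels <- lapply(sort(files), read_spot_table)
  ord <- order(vapply(gels, function(g) g$stage, character(1)),
               vapply(gels, function(g) g$replicate, integer(1)))
  gels[ord]
}

#' Write an experiment's spot tables
#'
#' @param gels List of [gel_table()] objects.
#' @param dir Output directory (created if needed).
#' @return The file paths written, invisibly.
#' @export
write_experiment <- function(gels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(gels, function(g) {
    file.path(dir, sprintf("%s_rep%d.tsv", g$stage, g$replicate))
  }, character(1))
  for (i in seq_along(gels)) write_spot_table(gels[[i]], paths[i])
  invisible(paths)
}
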