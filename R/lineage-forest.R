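#' Build a lineage forest from tracked-cell tables
#'
#' A lineage forest holds the complete division history of a tracked cell
#' population: one row per cell, with its parent, birth and end times (hours
#' after puparium formation, hAPF), and its end fate. Optional long-format
#' companion tables carry per-frame apical areas (\eqn{\mu m^2}), centroids
#' (\eqn{\mu m}; x = anterior-posterior axis, y = dorsal-ventral axis) and
#' elongation magnitudes.
#'
#' @param cells Data frame with columns `cell_id`, `parent_id` (`NA` for
#'   founders), `birth_time`, `end_time` (hAPF), `end_fate` (one of
#'   `"divided"`, `"extruded"`, `"censored"`) and optionally `is_sop`
#'   (logical, default `FALSE`) and `arrested` (logical).
#' @param areas,centroids,elongations Optional long-format data frames keyed
#'   by `cell_id` and `t`: `areas` has an `area` column, `centroids` have
#'   `x`, `y`, `elongations` an `elongation` column.
#' @param movie_end End of observation (hAPF). Defaults to the latest
#'   `end_time` in `cells`.
#' @param roi_label Free-text label of the region of interest the cells were
#'   taken from (e.g. `"noborder"`).
#'
#' @details Validation enforces the forest invariants: every non-founder's
#' parent exists; parent links are acyclic; `birth_time < end_time` for every
#' cell; a divided cell has exactly two children, each born at the mother's
#' end time (within `frame_tol` hours); `movie_end` is not earlier than any
#' `end_time`. Violations raise an error naming the offending `cell_id`.
#'
#' @param frame_tol Tolerance (hours) for the match between a mother's end
#'   time and her daughters' birth times; defaults to 1e-6.
#' @return An object of class `lineage_forest`: a list with elements
#'   `cells` (tibble), `areas`, `centroids`, `elongations` (tibbles or
#'   `NULL`), `movie_end` and `roi_label`.
#' @seealso [read_tracks()], [cycle_times()], [division_rate()]
#' @export
#' @examples
#' cells <- data.frame(
#'   cell_id = c("a", "a1", "a2"), parent_id = c(NA, "a", "a"),
#'   birth_time = c(0, 2.7, 2.7), end_time = c(2.7, 8, 8),
#'   end_fate = c("divided", "censored", "censored")
#' )
#' lineage_forest(cells, movie_end = 8)
lineage_forest <- function(cells, areas = NULL, centroids = NULL,
                           elongations = NULL, movie_end = NULL,
                           roi_label = "noborder", frame_tol = 1e-6) {
  cells <- tibble::as_tibble(cells)
  required <- c("cell_id", "parent_id", "birth_time", "end_time", "end_fate")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("`cells` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells$parent_id <- as.character(cells$parent_id)
  if (!"is_sop" %in% names(cells)) cells$is_sop <- FALSE
  cells$is_sop[is.na(cells$is_sop)] <- FALSE
  if (!"arrested" %in% names(cells)) cells$arrested <- NA
  movie_end <- movie_end %||% max(cells$end_time)

  forest <- structure(
    list(cells = cells,
         areas = if (!is.null(areas)) tibble::as_tibble(areas) else NULL,
         centroids = if (!is.null(centroids)) tibble::as_tibble(centroids) else NULL,
         elongations = if (!is.null(elongations)) tibble::as_tibble(elongations) else NULL,
         movie_end = movie_end,
         roi_label = roi_label),
    class = "lineage_forest"
  )
  validate_forest(forest, frame_tol = frame_tol)
  forest
}

#' Validate lineage forest invariants
#'
#' Checks the structural invariants of a [lineage_forest()] and raises an
#' informative error naming the first offending cell. Called automatically by
#' the constructor and by [read_tracks()].
#'
#' @param forest A `lineage_forest`.
#' @param frame_tol Tolerance (hours) for mother-end/daughter-birth matching.
#' @return `forest`, invisibly, if all invariants hold.
#' @export
validate_forest <- function(forest, frame_tol = 1e-6) {
  cells <- forest$cells
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1]
    abort(paste0("duplicated cell_id: ", dup))
  }
  bad_fate <- !cells$end_fate %in% c("divided", "extruded", "censored")
  if (any(bad_fate)) {
    abort(paste0("cell ", cells$cell_id[bad_fate][1],
                 ": unknown end_fate '", cells$end_fate[bad_fate][1], "'"))
  }
  bad_dur <- !(cells$birth_time < cells$end_time)
  if (any(bad_dur)) {
    abort(paste0("cell ", cells$cell_id[bad_dur][1],
                 ": birth_time must precede end_time"))
  }
  is_founder <- is.na(cells$parent_id)
  orphan <- !is_founder & !(cells$parent_id %in% cells$cell_id)
  if (any(orphan)) {
    abort(paste0("cell ", cells$cell_id[orphan][1],
                 ": parent '", cells$parent_id[orphan][1],
                 "' absent from the table"))
  }
  # acyclicity: walk each cell to its root; depth can never exceed n
  idx <- match(cells$parent_id, cells$cell_id)
  n <- nrow(cells)
  depth <- integer(n)
  cur <- idx
  for (step in seq_len(n)) {
    alive <- !is.na(cur)
    if (!any(alive)) break
    depth[alive] <- depth[alive] + 1L
    if (step == n && any(alive)) {
      abort(paste0("cell ", cells$cell_id[which(alive)[1]],
                   ": parent links contain a cycle"))
    }
    cur[alive] <- idx[cur[alive]]
  }
  # division arity and daughter birth times
  kids <- cells[!is_founder, ]
  n_children <- table(kids$parent_id)
  divided <- cells$cell_id[cells$end_fate == "divided"]
  for (id in divided) {
    k <- n_children[id]
    if (is.na(k) || k != 2) {
      abort(paste0("cell ", id, ": divided but has ",
                   ifelse(is.na(k), 0, k), " children (expected 2)"))
    }
  }
  with_kids <- names(n_children)
  not_div <- setdiff(with_kids, divided)
  if (length(not_div) > 0) {
    abort(paste0("cell ", not_div[1],
                 ": has children but end_fate is not 'divided'"))
  }
  if (nrow(kids) > 0) {
    mother_end <- cells$end_time[match(kids$parent_id, cells$cell_id)]
    off <- abs(kids$birth_time - mother_end) > frame_tol
    if (any(off)) {
      abort(paste0("cell ", kids$cell_id[off][1],
                   ": birth_time does not match mother's end_time"))
    }
  }
  if (forest$movie_end < max(cells$end_time) - frame_tol) {
    abort("movie_end is earlier than the latest end_time")
  }
  invisible(forest)
}

#' @export
print.lineage_forest <- function(x, ...) {
  cells <- x$cells
  cat("<lineage_forest> ", nrow(cells), " cells, ",
      sum(is.na(cells$parent_id)), " founders, ",
      sum(cells$end_fate == "divided"), " divisions, ",
      sum(cells$end_fate == "extruded"), " extrusions\n", sep = "")
  cat("  movie_end: ", x$movie_end, " hAPF; ROI: ", x$roi_label, "\n", sep = "")
  geom <- c(areas = !is.null(x$areas), centroids = !is.null(x$centroids),
            elongations = !is.null(x$elongations))
  if (any(geom)) {
    cat("  geometry: ", paste(names(geom)[geom], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read and write tracked-cell tables
#'
#' `read_tracks()` reads a tab-separated tracked-cell table with header
#' `cell_id, parent_id, birth_t, end_t, fate, is_sop` (times in hAPF) plus
#' optional long-format companion tables for per-frame geometry, and returns
#' a validated [lineage_forest()]. `write_tracks()` is its inverse; a forest
#' written and re-read is identical.
#'
#' @param path Path of the cell table (TSV).
#' @param areas_path,centroids_path Optional paths of companion TSVs:
#'   `cell_id, t, area` and `cell_id, t, x, y`.
#' @param movie_end,roi_label Passed to [lineage_forest()].
#' @return `read_tracks()` a `lineage_forest`; `write_tracks()` the input
#'   forest, invisibly.
#' @export
read_tracks <- function(path, areas_path = NULL, centroids_path = NULL,
                        movie_end = NULL, roi_label = "noborder") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "parent_id", "birth_t", "end_t", "fate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  cells <- tibble::tibble(
    cell_id = as.character(raw$cell_id),
    parent_id = as.character(raw$parent_id),
    birth_time = raw$birth_t,
    end_time = raw$end_t,
    end_fate = raw$fate,
    is_sop = if ("is_sop" %in% names(raw)) as.logical(raw$is_sop) else FALSE
  )
  if ("arrested" %in% names(raw)) cells$arrested <- as.logical(raw$arrested)
  areas <- if (!is.null(areas_path)) {
    readr::read_tsv(areas_path, show_col_types = FALSE, progress = FALSE)
  }
  centroids <- if (!is.null(centroids_path)) {
    readr::read_tsv(centroids_path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(areas)) areas$cell_id <- as.character(areas$cell_id)
  if (!is.null(centroids)) centroids$cell_id <- as.character(centroids$cell_id)
  lineage_forest(cells, areas = areas, centroids = centroids,
                 movie_end = movie_end, roi_label = roi_label)
}

#' @rdname read_tracks
#' @param forest A `lineage_forest` to write.
#' @export
write_tracks <- function(forest, path, areas_path = NULL,
                         centroids_path = NULL) {
  cells <- forest$cells
  out <- tibble::tibble(
    cell_id = cells$cell_id, parent_id = cells$parent_id,
    birth_t = cells$birth_time, end_t = cells$end_time,
    fate = cells$end_fate, is_sop = cells$is_sop
  )
  if (!all(is.na(cells$arrested))) out$arrested <- cells$arrested
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(areas_path) && !is.null(forest$areas)) {
    readr::write_tsv(forest$areas, areas_path, progress = FALSE)
  }
  if (!is.null(centroids_path) && !is.null(forest$centroids)) {
    readr::write_tsv(forest$centroids, centroids_path, progress = FALSE)
  }
  invisible(forest)
}
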