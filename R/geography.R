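# Nested census geography: blocks tiling block groups, nested in tracts and
# counties, with per-block demographic counts.

#' Construct a census geography
#'
#' Blocks are the atomic polygons; block groups, tracts and counties are
#' represented implicitly as the union of their member blocks (blocks tile
#' their parent unit). Coordinates must be planar meters (`crs_units = "m"`);
#' the package refuses geographic (degree) coordinates because error
#' distances are Euclidean meters.
#'
#' @param schema a [demographic_schema()].
#' @param blocks data.frame with columns `block_id`, `block_group_id`,
#'   `tract_id`, `county_id` (character).
#' @param polygons named list of n x 2 vertex matrices, names = `block_id`.
#' @param counts integer matrix, one row per block (rownames = `block_id`),
#'   `n_categories(schema)` columns; may be NULL before population assignment.
#' @param crs_units units tag; must be "m".
#' @param validate run [validate_geography()] (containment checks are
#'   sampling-based for non-rectangular blocks).
#' @return object of class `census_geography`.
#' @export
census_geography <- function(schema, blocks, polygons, counts = NULL,
                             crs_units = "m", validate = TRUE) {
  stopifnot(inherits(schema, "demographic_schema"))
  if (!identical(crs_units, "m"))
    stop("coordinate units must be planar meters (crs_units = \"m\"); ",
         "reproject before loading")
  need <- c("block_id", "block_group_id", "tract_id", "county_id")
  if (!all(need %in% names(blocks)))
    stop("blocks must have columns: ", paste(need, collapse = ", "))
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  for (cl in need) blocks[[cl]] <- as.character(blocks[[cl]])
  if (anyDuplicated(blocks$block_id)) stop("duplicate block_id")
  if (!setequal(names(polygons), blocks$block_id))
    stop("polygons must be named by block_id, one per block")
  polygons <- polygons[blocks$block_id]
  # precompute per-block geometry
  blocks$area_m2 <- vapply(polygons, polygon_area, numeric(1))
  cent <- t(vapply(polygons, polygon_centroid, numeric(2)))
  blocks$centroid_x <- cent[, 1]
  blocks$centroid_y <- cent[, 2]
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != nrow(blocks) || ncol(counts) != n_categories(schema))
      stop("counts must be n_blocks x n_categories")
    if (is.null(rownames(counts))) rownames(counts) <- blocks$block_id
    counts <- counts[blocks$block_id, , drop = FALSE]
    if (any(counts < 0)) stop("negative counts")
    storage.mode(counts) <- "integer"
  }
  g <- structure(
    list(schema = schema, blocks = blocks, polygons = polygons,
         counts = counts, crs_units = crs_units),
    class = "census_geography")
  if (validate) validate_geography(g)
  g
}

#' @export
print.census_geography <- function(x, ...) {
  cat("<census_geography>", nrow(x$blocks), "blocks,",
      length(unique(x$blocks$block_group_id)), "block groups,",
      length(unique(x$blocks$tract_id)), "tracts,",
      length(unique(x$blocks$county_id)), "counties;",
      if (is.null(x$counts)) "no counts" else
        paste0("population ", sum(x$counts)), "\n")
  invisible(x)
}

#' Validate nesting, polygon and count invariants of a geography
#'
#' Checks: positive block areas; consistent nesting (all blocks of a group
#' share the group's tract and county, all blocks of a tract share its
#' county); non-negative counts; pairwise non-overlap of sibling blocks
#' (exact bbox intersection for axis-aligned rectangular blocks, interior
#' point sampling otherwise, tolerance 1e-6 km^2).
#'
#' @param g a `census_geography`.
#' @param overlap_samples interior points per block for the sampling check.
#' @return invisibly TRUE; stops with a message naming the offending unit.
#' @export
validate_geography <- function(g, overlap_samples = 16L) {
  b <- g$blocks
  if (any(b$area_m2 <= 0))
    stop("zero-area block(s): ",
         paste(b$block_id[b$area_m2 <= 0], collapse = ", "))
  # nesting consistency
  chk <- function(child, parent, what) {
    tab <- unique(b[, c(child, parent)])
    dup <- tab[[child]][duplicated(tab[[child]])]
    if (length(dup))
      stop("inconsistent nesting: ", what, " for ",
           paste(unique(dup), collapse = ", "))
  }
  chk("block_group_id", "tract_id", "block group in multiple tracts")
  chk("block_group_id", "county_id", "block group in multiple counties")
  chk("tract_id", "county_id", "tract in multiple counties")
  # sibling overlap within each block group
  is_rect <- vapply(g$polygons, function(p) {
    bb <- polygon_bbox(p)
    isTRUE(all.equal(polygon_area(p),
                     (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]),
                     tolerance = 1e-9, check.attributes = FALSE))
  }, logical(1))
  tol_m2 <- 1e-6 * 1e6  # 1e-6 km^2
  for (grp in split(seq_len(nrow(b)), b$block_group_id)) {
    if (length(grp) < 2) next
    bbs <- t(vapply(g$polygons[grp], polygon_bbox, numeric(4)))
    for (i in seq_along(grp)[-1]) for (j in seq_len(i - 1)) {
      ox <- min(bbs[i, 2], bbs[j, 2]) - max(bbs[i, 1], bbs[j, 1])
      oy <- min(bbs[i, 4], bbs[j, 4]) - max(bbs[i, 3], bbs[j, 3])
      if (ox <= 0 || oy <= 0) next
      if (is_rect[grp[i]] && is_rect[grp[j]]) {
        if (ox * oy > tol_m2)
          stop("overlapping sibling blocks: ", b$block_id[grp[i]], ", ",
               b$block_id[grp[j]])
      } else {
        pts <- random_point_in_polygon(g$polygons[[grp[i]]], overlap_samples)
        if (any(point_in_polygon(g$polygons[[grp[j]]], pts[, 1], pts[, 2])))
          stop("overlapping sibling blocks: ", b$block_id[grp[i]], ", ",
               b$block_id[grp[j]])
      }
    }
  }
  if (!is.null(g$counts) && any(g$counts < 0)) stop("negative counts")
  invisible(TRUE)
}

# row indices of the blocks belonging to a coarse unit
unit_block_rows <- function(g, unit_id, level = c("block_group", "tract",
                                                  "county")) {
  level <- match.arg(level)
  col <- switch(level, block_group = "block_group_id",
                tract = "tract_id", county = "county_id")
  rows <- which(g$blocks[[col]] == unit_id)
  if (!length(rows))
    stop("unknown ", level, " id: ", unit_id, call. = FALSE)
  rows
}

#' Member block ids of a coarse unit
#' @param g a `census_geography`.
#' @param unit_id unit identifier.
#' @param level one of "block_group", "tract", "county".
#' @return character vector of block ids (ascending).
#' @export
unit_blocks <- function(g, unit_id, level = "block_group") {
  sort(g$blocks$block_id[unit_block_rows(g, unit_id, level)])
}

#' Demographic weight of a block within its block group
#'
#' The weight of a block for a demographic category is the block's count for
#' that category divided by the block-group total for the category, e.g. for
#' a 71-year-old white female: (white females 70-74 in block) /
#' (white females 70-74 in block group). Weights over a group's blocks sum
#' to 1 whenever the group total is positive.
#'
#' When the group total for the category is zero there is no matching
#' population to weight by: the function returns `NA_real_` as a value-level
#' no-match signal (not an error), which downstream strategies count as
#' unimputable.
#'
#' @param g a `census_geography` with counts.
#' @param block_id block identifier.
#' @param category 1-based category index (see [category_index()]).
#' @param level coarse level whose total forms the denominator; the default
#'   "block_group" is the primary analysis, tract/county support
#'   sensitivity analyses.
#' @return weight in `[0, 1]`, or `NA_real_` if the unit total is zero.
#' @export
block_weight <- function(g, block_id, category, level = "block_group") {
  w <- unit_weights(g, block_to_unit(g, block_id, level), category, level)
  if (all(is.na(w))) return(NA_real_)
  unname(w[block_id])
}

block_to_unit <- function(g, block_id, level) {
  i <- match(block_id, g$blocks$block_id)
  if (is.na(i)) stop("unknown block id: ", block_id, call. = FALSE)
  switch(level, block_group = g$blocks$block_group_id[i],
         tract = g$blocks$tract_id[i], county = g$blocks$county_id[i])
}

# named weight vector over all member blocks of a unit; all-NA on no match
unit_weights <- function(g, unit_id, category, level = "block_group") {
  if (is.null(g$counts)) stop("geography has no counts")
  stopifnot(length(category) == 1, category >= 1,
            category <= n_categories(g$schema))
  rows <- unit_block_rows(g, unit_id, level)
  cnt <- g$counts[rows, category]
  names(cnt) <- g$blocks$block_id[rows]
  tot <- sum(cnt)
  if (tot == 0) return(cnt * NA_real_)
  cnt / tot
}

#' Blocks of a unit with matching population for a category
#'
#' Exactly the member blocks whose count for the category is positive, in
#' ascending block id order (deterministic).
#'
#' @inheritParams block_weight
#' @param unit_id coarse unit identifier.
#' @return character vector of block ids; empty if none match.
#' @export
matching_blocks <- function(g, unit_id, category, level = "block_group") {
  if (is.null(g$counts)) stop("geography has no counts")
  rows <- unit_block_rows(g, unit_id, level)
  ids <- g$blocks$block_id[rows][g$counts[rows, category] > 0L]
  sort(ids)
}

#' Coarse-unit area, population and density table
#'
#' Density is unit population divided by unit area in km^2, the
#' stratification variable for accuracy-by-density analyses.
#'
#' @param g a `census_geography` with counts.
#' @param level "block_group", "tract" or "county".
#' @return data.frame: `unit_id`, `area_km2`, `population`,
#'   `density_per_km2`.
#' @export
unit_density_table <- function(g, level = "block_group") {
  col <- switch(level, block_group = "block_group_id", tract = "tract_id",
                county = "county_id", stop("unknown level: ", level))
  area <- tapply(g$blocks$area_m2, g$blocks[[col]], sum) / 1e6
  pop <- if (is.null(g$counts)) NA_real_ else {
    tot <- rowSums(g$counts)
    as.numeric(tapply(tot, g$blocks[[col]], sum))
  }
  data.frame(unit_id = names(area), area_km2 = as.numeric(area),
             population = pop,
             density_per_km2 = pop / as.numeric(area),
             row.names = NULL, stringsAsFactors = FALSE)
}
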