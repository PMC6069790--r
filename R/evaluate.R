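# Evaluation framework: coarsening, error distances, stratified summaries,
# density binning, multiple-imputation validation, spatial-unit sensitivity,
# tract-level aggregation and IDW error surfaces.

#' Locate the block containing each point
#'
#' @param g a `census_geography`.
#' @param x,y planar coordinates in meters.
#' @return character vector of block ids; errors if a point is outside every
#'   block.
#' @export
locate_block <- function(g, x, y) {
  out <- rep(NA_character_, length(x))
  bbs <- t(vapply(g$polygons, polygon_bbox, numeric(4)))
  for (k in seq_along(x)) {
    cand <- which(bbs[, 1] <= x[k] & bbs[, 2] >= x[k] &
                    bbs[, 3] <= y[k] & bbs[, 4] >= y[k])
    for (i in cand) {
      if (point_in_polygon(g$polygons[[i]], x[k], y[k])) {
        out[k] <- g$blocks$block_id[i]
        break
      }
    }
    if (is.na(out[k]))
      stop("point (", x[k], ", ", y[k], ") is outside every block")
  }
  out
}

#' Coarsen records to a spatial-unit level
#'
#' Replaces each record's coarse unit by the containing unit at the requested
#' level (the controlled information loss that the imputation strategies then
#' try to undo). The true location is retained for scoring only. Uses the
#' record's `block_id` column when present, otherwise locates the block by
#' point containment. Idempotent per level.
#'
#' @param records person records with true coordinates.
#' @param g a `census_geography`.
#' @param level one of "block_group", "tract", "county".
#' @return `records` with `coarse_unit_id` and `coarse_level` replaced.
#' @export
coarsen <- function(records, g, level = c("block_group", "tract", "county")) {
  level <- match.arg(level)
  bid <- if (!is.null(records$block_id)) records$block_id
         else locate_block(g, records$x, records$y)
  i <- match(bid, g$blocks$block_id)
  if (anyNA(i)) stop("unknown block id(s): ",
                     paste(utils::head(bid[is.na(i)]), collapse = ", "))
  records$coarse_unit_id <- switch(level,
    block_group = g$blocks$block_group_id[i],
    tract = g$blocks$tract_id[i],
    county = g$blocks$county_id[i])
  records$coarse_level <- level
  records
}

#' Default reporting age groups
#'
#' Five coarse age groups used for stratified accuracy reporting, distinct
#' from (and coarser than) the schema's tabulation age bins.
#' @param age_years integer ages.
#' @param breaks inner break points; default gives <20, 20-49, 50-64, 65-84,
#'   85+.
#' @return factor of age-group labels.
#' @export
age_group_label <- function(age_years, breaks = c(20, 50, 65, 85)) {
  lab <- c(paste0("<", breaks[1]),
           paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
           paste0(breaks[length(breaks)], "+"))
  cut(age_years, c(-Inf, breaks, Inf), labels = lab, right = FALSE)
}

#' Score an imputation table against true record locations
#'
#' Joins imputed points to their records, computes planar error distances and
#' attaches the stratification labels used throughout the evaluation: race,
#' sex, reporting age group, the coarse unit and its population density.
#' Rows with `status != "imputed"` keep `error_m = NA` and are excluded from
#' summaries downstream (but counted by [imputable_fraction()]).
#'
#' @param imputed output of [impute_batch()].
#' @param records the records that were imputed (with true `x`, `y`).
#' @param g the `census_geography`.
#' @param age_breaks passed to [age_group_label()].
#' @return data.frame of error records: `record_id`, `strategy`,
#'   `replicate`, `error_m`, `sex`, `race`, `age_group`, `coarse_unit_id`,
#'   `coarse_level`, `density_per_km2`, `status`, `fallback_used`.
#' @export
evaluate_errors <- function(imputed, records, g,
                            age_breaks = c(20, 50, 65, 85)) {
  i <- match(imputed$record_id, records$record_id)
  if (anyNA(i)) stop("imputed table references unknown record ids")
  if (anyNA(records$x[i]) || anyNA(records$y[i]))
    stop("records lack true coordinates; cannot score")
  err <- rep(NA_real_, nrow(imputed))
  ok <- imputed$status == "imputed"
  err[ok] <- error_distance(cbind(records$x[i][ok], records$y[i][ok]),
                            cbind(imputed$x[ok], imputed$y[ok]))
  lvl <- unique(records$coarse_level)
  if (length(lvl) != 1) stop("records mix coarse levels")
  dens <- unit_density_table(g, lvl)
  di <- match(records$coarse_unit_id[i], dens$unit_id)
  data.frame(
    record_id = imputed$record_id, strategy = imputed$strategy,
    replicate = imputed$replicate, error_m = err,
    sex = records$sex[i], race = records$race[i],
    age_group = as.character(age_group_label(records$age_years[i],
                                             age_breaks)),
    coarse_unit_id = records$coarse_unit_id[i], coarse_level = lvl,
    density_per_km2 = dens$density_per_km2[di],
    status = imputed$status, fallback_used = imputed$fallback_used,
    stringsAsFactors = FALSE)
}

#' Assign decade population-density bins
#'
#' Right-open logarithmic bins `[10^k, 10^(k+1))` of `density_per_km2`, the
#' binning used for accuracy-by-density analyses (densities in real census
#' geographies span many orders of magnitude).
#'
#' @param errors error table from [evaluate_errors()].
#' @return `errors` with `density_bin` (label) and `density_decade`
#'   (integer k) columns.
#' @export
assign_density_bins <- function(errors) {
  d <- errors$density_per_km2
  if (any(!is.finite(d) | d <= 0))
    stop("densities must be positive and finite")
  k <- floor(log10(d))
  errors$density_decade <- as.integer(k)
  errors$density_bin <- sprintf("[1e%+03d,1e%+03d)", k, k + 1)
  errors
}

summary_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(v), mean_m = mean(v), median_m = q[2],
             q1_m = q[1], q3_m = q[3], min_m = min(v), max_m = max(v),
             se_m = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_)
}

#' Stratified error-distance summary
#'
#' One row per observed combination of the stratification keys, with n,
#' mean, median, quartiles (linear interpolation, R type 7), min, max and
#' the standard error of the mean (NA when n = 1). Non-imputed rows are
#' excluded; empty strata are never emitted.
#'
#' @param errors error table (see [evaluate_errors()]; run
#'   [assign_density_bins()] first if `"density_bin"` is a key).
#' @param by character vector of key columns, subset of
#'   c("strategy", "race", "age_group", "sex", "density_bin", "level").
#' @return data.frame of summary rows ordered by the keys.
#' @export
stratified_summary <- function(errors, by = "strategy") {
  ok <- errors$status == "imputed" & !is.na(errors$error_m)
  e <- errors[ok, , drop = FALSE]
  if (!nrow(e)) stop("no imputed rows to summarise")
  miss <- setdiff(by, names(e))
  if (length(miss)) stop("unknown stratification key(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(e[by], drop = TRUE, sep = "\r")
  parts <- split(e, key)
  res <- do.call(rbind, lapply(parts, function(d)
    cbind(d[1, by, drop = FALSE], summary_stats(d$error_m))))
  rownames(res) <- NULL
  res[do.call(order, res[by]), , drop = FALSE]
}

#' Accuracy by population-density decade
#'
#' Convenience wrapper: assigns decade bins and summarises per strategy and
#' bin.
#'
#' @param errors error table from [evaluate_errors()].
#' @param scheme binning scheme; only "decade" is defined.
#' @param min_decade,max_decade optional truncation: rows outside are dropped.
#' @return summary rows keyed by strategy and density bin, in ascending
#'   density order.
#' @export
density_bins <- function(errors, scheme = "decade", min_decade = -Inf,
                         max_decade = Inf) {
  stopifnot(identical(scheme, "decade"))
  e <- assign_density_bins(errors)
  e <- e[e$density_decade >= min_decade & e$density_decade <= max_decade, ]
  out <- stratified_summary(e, by = c("strategy", "density_bin"))
  out <- out[order(out$strategy, bin_decade(out$density_bin)), ]
  rownames(out) <- NULL
  out
}

#' Decade exponent k of a density-bin label `[10^k, 10^(k+1))`
#' @param label density-bin label(s) from [assign_density_bins()].
#' @return integer vector of exponents.
#' @export
bin_decade <- function(label) {
  as.integer(sub("^\\[1e([+-][0-9]+),.*$", "\\1", label))
}

#' Multiple-imputation summary for stochastic strategies
#'
#' Averages each record's error over its replicates first, then summarises
#' per stratum (so every record contributes one observation regardless of
#' replicate count), and reports the between-replicate spread as the mean
#' within-record standard deviation. Refuses deterministic strategies, whose
#' replicates would be copies of the same point estimate.
#'
#' @param errors error table containing replicated stochastic rows.
#' @param by stratification keys (default strategy and density bin, which
#'   must be present -- see [assign_density_bins()]).
#' @return summary rows plus a `replicate_sd_m` column.
#' @export
multiple_imputation_summary <- function(errors,
                                        by = c("strategy", "density_bin")) {
  bad <- intersect(unique(errors$strategy), DETERMINISTIC)
  if (length(bad))
    stop("multiple imputation is undefined for deterministic strategies: ",
         paste(bad, collapse = ", "))
  ok <- errors$status == "imputed" & !is.na(errors$error_m)
  e <- errors[ok, , drop = FALSE]
  if (max(tapply(e$replicate, e$strategy, max)) < 2)
    stop("need >= 2 replicates for a multiple-imputation summary")
  keycols <- unique(c("record_id", "strategy", setdiff(by, "strategy")))
  key <- interaction(e[keycols], drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(e, key), function(d) {
    out <- d[1, c(keycols, setdiff(names(d), c("error_m", "replicate",
                                               keycols))), drop = FALSE]
    out$error_m <- mean(d$error_m)
    out$rep_sd <- if (nrow(d) > 1) stats::sd(d$error_m) else NA_real_
    out
  }))
  agg$status <- "imputed"
  res <- stratified_summary(agg, by = by)
  spread <- tapply(agg$rep_sd, interaction(agg[by], drop = TRUE, sep = "\r"),
                   mean, na.rm = TRUE)
  res$replicate_sd_m <- as.numeric(
    spread[match(interaction(res[by], drop = TRUE, sep = "\r"),
                 names(spread))])
  res
}

#' Sensitivity of accuracy to the coarsening level
#'
#' Re-runs the full pipeline (coarsen, impute with the same master seed,
#' score, density-bin summary) at each requested spatial-unit level.
#' Coarser units enlarge the search space, so error distances grow from
#' block group to tract to county.
#'
#' @param records person records with true coordinates and `block_id`.
#' @param g a `census_geography` with tract/county nesting.
#' @param levels levels to evaluate.
#' @param strategies,n_replicates,seed passed to [impute_batch()].
#' @return list with `overall` (per level x strategy summary) and
#'   `by_density` (per level x strategy x density bin), each with a `level`
#'   column.
#' @export
sensitivity_by_level <- function(records, g,
                                 levels = c("block_group", "tract",
                                            "county"),
                                 strategies = c("S1", "S2", "S3", "S4"),
                                 n_replicates = 1L, seed = 1L) {
  per_level <- lapply(levels, function(lvl) {
    rec <- coarsen(records, g, lvl)
    imp <- impute_batch(rec, g, strategies, n_replicates, seed)
    err <- evaluate_errors(imp, rec, g)
    ov <- stratified_summary(err, by = "strategy")
    ov <- cbind(level = lvl, ov)
    bd <- density_bins(err)
    bd <- cbind(level = lvl, bd)
    list(overall = ov, by_density = bd)
  })
  list(overall = do.call(rbind, lapply(per_level, `[[`, "overall")),
       by_density = do.call(rbind, lapply(per_level, `[[`, "by_density")))
}

#' Worst-case error per census tract
#'
#' Aggregates record-level errors to tracts (via the block-group membership
#' of each record's coarse unit) reporting the maximum error among member
#' records, and drops tracts with fewer imputed records per km^2 than the
#' threshold, whose surfaces would be unreliable.
#'
#' @param errors error table scored at block-group level (single strategy
#'   recommended).
#' @param g the `census_geography`.
#' @param min_records_per_km2 record-density threshold for keeping a tract.
#' @return list: `table` (tract_id, n, area_km2, records_per_km2,
#'   max_error_m) for kept tracts and `dropped` (tract ids removed).
#' @export
tract_accuracy_aggregation <- function(errors, g,
                                       min_records_per_km2 = 0.001) {
  if (!all(errors$coarse_level == "block_group"))
    stop("tract aggregation expects block-group-level errors")
  ok <- errors$status == "imputed" & !is.na(errors$error_m)
  e <- errors[ok, , drop = FALSE]
  tract <- g$blocks$tract_id[match(e$coarse_unit_id,
                                   g$blocks$block_group_id)]
  area <- unit_density_table(g, "tract")
  tab <- do.call(rbind, lapply(split(e$error_m, tract), function(v)
    data.frame(n = length(v), max_error_m = max(v))))
  tab$tract_id <- rownames(tab)
  tab$area_km2 <- area$area_km2[match(tab$tract_id, area$unit_id)]
  tab$records_per_km2 <- tab$n / tab$area_km2
  keep <- tab$records_per_km2 >= min_records_per_km2
  res <- tab[keep, c("tract_id", "n", "area_km2", "records_per_km2",
                     "max_error_m")]
  rownames(res) <- NULL
  list(table = res, dropped = sort(tab$tract_id[!keep]))
}

#' Inverse-distance-weighted interpolation of sample values onto a grid
#'
#' Each grid-cell value is the distance-decay weighted average of all sample
#' values, weights d^(-power); a cell within 1e-9 m of a sample takes that
#' sample's value exactly. Output is therefore bounded by the sample value
#' range.
#'
#' @param samples data.frame with columns `x`, `y`, `value`.
#' @param grid list with `xmin`, `xmax`, `ymin`, `ymax`, `nx`, `ny`: cell
#'   centers are an nx x ny lattice spanning the extent.
#' @param power positive distance-decay exponent (default 2).
#' @return data.frame `x`, `y`, `value`, one row per grid cell.
#' @export
idw_interpolate <- function(samples, grid, power = 2) {
  stopifnot(nrow(samples) >= 1, power > 0,
            all(c("x", "y", "value") %in% names(samples)))
  gx <- seq(grid$xmin, grid$xmax, length.out = grid$nx)
  gy <- seq(grid$ymin, grid$ymax, length.out = grid$ny)
  cells <- expand.grid(x = gx, y = gy)
  d <- sqrt(outer(cells$x, samples$x, "-")^2 +
              outer(cells$y, samples$y, "-")^2)
  w <- d^(-power)
  val <- as.vector((w %*% samples$value) / rowSums(w))
  hit <- d < 1e-9
  if (any(hit)) {
    hi <- which(hit, arr.ind = TRUE)
    val[hi[, 1]] <- samples$value[hi[, 2]]
  }
  cells$value <- val
  cells
}
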