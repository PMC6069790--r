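# File formats and end-to-end pipeline wiring.
#
# Canonical geography format: GeoJSON (one Polygon feature per block,
# properties carry the unit ids, a foreign "crs_units" member tags planar
# meters) plus a long-format counts CSV (block_id, sex, race, age_bin,
# count). Records travel as CSV.

#' Write a geography to GeoJSON + counts CSV
#'
#' @param g a `census_geography`.
#' @param geojson_path output GeoJSON path.
#' @param counts_path output counts CSV path (omitted if the geography has
#'   no counts). Only nonzero counts are written.
#' @return invisibly the paths written.
#' @export
write_geography <- function(g, geojson_path, counts_path = NULL) {
  feats <- lapply(seq_len(nrow(g$blocks)), function(i) {
    p <- g$polygons[[g$blocks$block_id[i]]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(block_id = g$blocks$block_id[i],
                           block_group_id = g$blocks$block_group_id[i],
                           tract_id = g$blocks$tract_id[i],
                           county_id = g$blocks$county_id[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(j) ring[j, ])))))
  })
  fc <- list(type = "FeatureCollection", crs_units = g$crs_units,
             features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA),
             geojson_path)
  if (!is.null(g$counts) && !is.null(counts_path)) {
    nz <- which(g$counts > 0L, arr.ind = TRUE)
    lab <- category_labels(g$schema, nz[, 2])
    df <- data.frame(block_id = rownames(g$counts)[nz[, 1]],
                     sex = lab$sex, race = lab$race, age_bin = lab$age_bin,
                     count = g$counts[nz], stringsAsFactors = FALSE)
    df <- df[order(df$block_id, df$sex, df$race, df$age_bin), ]
    utils::write.csv(df, counts_path, row.names = FALSE)
  }
  invisible(c(geojson_path, counts_path))
}

#' Read a geography from GeoJSON + counts CSV
#'
#' All type invariants are enforced on load: the units tag must be planar
#' meters, every feature needs the four unit ids and a valid simple polygon,
#' and every counts row must reference an existing block and schema labels.
#'
#' @param geojson_path GeoJSON of block polygons (see [write_geography()]).
#' @param counts_path optional long-format counts CSV.
#' @param schema the [demographic_schema()] the counts use.
#' @param validate run geometry/nesting validation.
#' @return a `census_geography`.
#' @export
read_geography <- function(geojson_path, counts_path = NULL,
                           schema = default_schema(), validate = TRUE) {
  fc <- jsonlite::fromJSON(geojson_path, simplifyVector = FALSE)
  if (is.null(fc$crs_units) || !identical(fc$crs_units, "m"))
    stop("geography file lacks crs_units = \"m\"; ",
         "only planar meter coordinates are supported")
  feats <- fc$features
  need <- c("block_id", "block_group_id", "tract_id", "county_id")
  rows <- vector("list", length(feats))
  polys <- vector("list", length(feats))
  ids <- character(length(feats))
  for (i in seq_along(feats)) {
    pr <- feats[[i]]$properties
    if (!all(need %in% names(pr)) || any(vapply(pr[need], is.null,
                                                logical(1))))
      stop("feature ", i, " missing block/group/tract/county ids")
    gm <- feats[[i]]$geometry
    if (is.null(gm) || !identical(gm$type, "Polygon"))
      stop("feature ", i, " (", pr$block_id, "): geometry must be Polygon")
    ring <- do.call(rbind, lapply(gm$coordinates[[1]], unlist))
    storage.mode(ring) <- "double"
    if (nrow(ring) < 4) stop("block ", pr$block_id, ": degenerate ring")
    if (all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    if (!ring_is_simple(ring))
      stop("block ", pr$block_id, ": polygon self-intersects")
    ids[i] <- pr$block_id
    rows[[i]] <- data.frame(block_id = pr$block_id,
                            block_group_id = pr$block_group_id,
                            tract_id = pr$tract_id,
                            county_id = pr$county_id,
                            stringsAsFactors = FALSE)
    polys[[i]] <- ring
  }
  names(polys) <- ids
  counts <- NULL
  if (!is.null(counts_path)) {
    cdf <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
    bad <- setdiff(cdf$block_id, ids)
    if (length(bad))
      stop("counts reference unknown block_id(s): ",
           paste(utils::head(bad), collapse = ", "))
    bins <- age_bin_labels(schema)
    bi <- match(cdf$age_bin, bins)
    if (anyNA(bi))
      stop("unknown age_bin label(s): ",
           paste(utils::head(unique(cdf$age_bin[is.na(bi)])), collapse = ", "))
    ci <- category_index(schema, cdf$sex, cdf$race,
                         schema$age_bin_edges[bi])
    counts <- matrix(0L, length(ids), n_categories(schema),
                     dimnames = list(ids, NULL))
    counts[cbind(match(cdf$block_id, ids), ci)] <- as.integer(cdf$count)
  }
  census_geography(schema, do.call(rbind, rows), polys, counts,
                   crs_units = "m", validate = validate)
}

# simple-polygon check: no two non-adjacent edges intersect
ring_is_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  inter <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next  # adjacent around the ring
    if (inter(seg[i, ], seg[j, ])) return(FALSE)
  }
  TRUE
}

#' Read person records from CSV
#'
#' Expected columns: record_id, sex, race, age_years, coarse_unit_id,
#' coarse_level; optional x, y (true location, required for evaluation) and
#' block_id (provenance from the generator).
#'
#' @param path CSV path.
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "sex", "race", "age_years", "coarse_unit_id",
            "coarse_level")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$record_id <- as.character(df$record_id)
  df
}

#' Write person records to CSV
#' @param records data.frame of records.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an imputation table as CSV
#' @param imputed output of [impute_batch()].
#' @param path CSV path.
#' @export
write_imputed <- function(imputed, path) {
  utils::write.csv(imputed, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imputed
#' @export
read_imputed <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$record_id <- as.character(df$record_id)
  df
}

#' Pipeline configuration
#'
#' @param geography,counts,records input file paths (validated to exist).
#' @param strategies strategy subset.
#' @param replicates replicates for stochastic strategies.
#' @param seed master seed; mandatory when a stochastic strategy is
#'   requested.
#' @param coarse_level coarsening level applied before imputation.
#' @param by stratification keys for the summary.
#' @param out_dir output directory (created if needed).
#' @param schema demographic schema for the counts.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(geography, counts, records,
                            strategies = c("S1", "S2", "S3", "S4"),
                            replicates = 1L, seed = NULL,
                            coarse_level = "block_group",
                            by = c("strategy", "race", "age_group"),
                            out_dir = ".", schema = default_schema()) {
  strategies <- match.arg(strategies, c("S1", "S2", "S3", "S4"),
                          several.ok = TRUE)
  if (any(strategies %in% STOCHASTIC) && is.null(seed))
    stop("config error: seed is mandatory with stochastic strategies")
  for (p in c(geography, counts, records))
    if (!file.exists(p)) stop("config error: file not found: ", p)
  structure(list(geography = geography, counts = counts, records = records,
                 strategies = strategies,
                 replicates = as.integer(replicates), seed = seed,
                 coarse_level = coarse_level, by = by, out_dir = out_dir,
                 schema = schema),
            class = "pipeline_config")
}

#' Run the full pipeline: coarsen, impute, score, summarise
#'
#' Reads the inputs, coarsens records to the configured level, runs
#' [impute_batch()], scores against the true coordinates, and writes
#' `imputed.csv`, `summary.csv`, `counts.json` (imputable accounting) and
#' `run_log.json` (seed, config hash, package version) to the output
#' directory. The same config always produces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly a list with the in-memory results (`imputed`, `errors`,
#'   `summary`, `counts`) and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  g <- read_geography(config$geography, config$counts, config$schema)
  rec <- read_records(config$records)
  if (is.null(rec$x) || is.null(rec$y))
    stop("stage coarsen: records lack true coordinates")
  rec <- coarsen(rec, g, config$coarse_level)
  imp <- impute_batch(rec, g, config$strategies, config$replicates,
                      config$seed)
  err <- evaluate_errors(imp, rec, g)
  err <- assign_density_bins(err)
  summ <- stratified_summary(err, by = config$by)
  frac <- imputable_fraction(imp)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("imputed.csv", "summary.csv", "counts.json",
                       "run_log.json"))
  write_imputed(imp, paths[1])
  utils::write.csv(summ, paths[2], row.names = FALSE)
  jsonlite::write_json(
    list(per_strategy = frac,
         n_records = length(unique(rec$record_id))),
    paths[3], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_json <- as.character(jsonlite::toJSON(
    cfg_for_hash[order(names(cfg_for_hash))], auto_unbox = TRUE,
    force = TRUE))
  jsonlite::write_json(
    list(seed = config$seed, config_hash = stable_hash(cfg_json),
         package_version = as.character(utils::packageVersion("geoimpute")),
         strategies = config$strategies, replicates = config$replicates,
         coarse_level = config$coarse_level),
    paths[4], auto_unbox = TRUE)
  invisible(list(imputed = imp, errors = err, summary = summ, counts = frac,
                 paths = paths))
}
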