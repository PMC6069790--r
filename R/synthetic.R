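# Synthetic census-like geography, block counts, and record populations with
# known true coordinates, so the full coarsen -> impute -> score pipeline is
# testable without restricted registry data.

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s == 0) {  # extreme underflow at tiny concentrations
    x[sample.int(length(alpha), 1)] <- 1
    s <- 1
  }
  x / s
}

#' Scenario configuration for the synthetic generator
#'
#' @param n_block_groups number of block groups, laid out on a near-square
#'   grid.
#' @param blocks_per_group blocks per group, subdivided on an integer grid
#'   (the most-square factor pair is used; primes give a 1 x n strip).
#' @param base_block_size_m side length in meters of a block in the
#'   lowest-density column.
#' @param density_gradient ratio of largest to smallest block area across the
#'   geography's x-axis (1 = no gradient). Population is spread evenly across
#'   blocks in expectation, so a gradient in block area is a gradient in
#'   population density, mimicking small urban blocks.
#' @param clustering_concentration Dirichlet concentration per race group for
#'   allocating that race's population over blocks: low values pile a race
#'   into few blocks (spatial clustering of minorities), high values spread
#'   it evenly. Scalar, or named vector over schema race labels.
#' @param total_population total people across all blocks (conserved
#'   exactly).
#' @param n_records number of person records to sample.
#' @param unmatchable_fraction fraction of records whose race is switched to
#'   one with no matching population in their block group (see
#'   [make_unmatchable()]).
#' @param seed master seed for all generator randomness.
#' @param groups_per_tract,tracts_per_county side length (in grid cells) of
#'   the tract and county super-grids.
#' @param race_shares named non-negative vector of expected population shares
#'   per race (normalised internally); default is a plausible mixed urban
#'   state profile.
#' @param schema a [demographic_schema()]; default [default_schema()].
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_block_groups = 25L,
                            blocks_per_group = 16L,
                            base_block_size_m = 1000,
                            density_gradient = 1,
                            clustering_concentration = 5,
                            total_population = 50000L,
                            n_records = 2000L,
                            unmatchable_fraction = 0,
                            seed = 1L,
                            groups_per_tract = 2L,
                            tracts_per_county = 2L,
                            race_shares = NULL,
                            schema = default_schema()) {
  stopifnot(n_block_groups >= 1, blocks_per_group >= 1,
            base_block_size_m > 0, density_gradient >= 1,
            total_population >= 1, n_records >= 0,
            unmatchable_fraction >= 0, unmatchable_fraction < 1,
            all(clustering_concentration > 0))
  if (blocks_per_group != round(blocks_per_group))
    stop("blocks_per_group must factor into an integer grid")
  races <- schema$race_labels
  if (length(clustering_concentration) == 1) {
    clustering_concentration <- stats::setNames(
      rep(clustering_concentration, length(races)), races)
  } else if (!setequal(names(clustering_concentration), races)) {
    stop("clustering_concentration must be scalar or named by schema races")
  }
  if (is.null(race_shares)) {
    race_shares <- c(White = 0.30, Black = 0.12, AIAN = 0.01,
                     Asian = 0.05, NHPI = 0.005, Other = 0.02,
                     TwoOrMore = 0.025, Hispanic = 0.38,
                     WhiteNonHispanic = 0.09)
    race_shares <- race_shares[races]
    names(race_shares) <- races
    race_shares[is.na(race_shares)] <- 0.01
  }
  if (!setequal(names(race_shares), races))
    stop("race_shares must be named by schema races")
  structure(
    list(n_block_groups = as.integer(n_block_groups),
         blocks_per_group = as.integer(blocks_per_group),
         base_block_size_m = base_block_size_m,
         density_gradient = density_gradient,
         clustering_concentration = clustering_concentration[races],
         total_population = as.integer(total_population),
         n_records = as.integer(n_records),
         unmatchable_fraction = unmatchable_fraction,
         seed = as.integer(seed),
         groups_per_tract = as.integer(groups_per_tract),
         tracts_per_county = as.integer(tracts_per_county),
         race_shares = race_shares[races] / sum(race_shares),
         schema = schema),
    class = "scenario_config")
}

#' Shipped scenario presets
#'
#' Three study conditions wired to the package's property checks:
#' \describe{
#'   \item{uniform}{flat density, evenly spread races; baseline sanity
#'     condition.}
#'   \item{clustered_minorities}{100 block groups, 200k people, 5k records;
#'     minority races drawn with low Dirichlet concentration so they
#'     concentrate in few blocks, the regime where demographically weighted
#'     strategies shine.}
#'   \item{density_gradient}{10^4-fold block-area gradient across the x-axis,
#'     producing a wide population-density range for accuracy-by-density
#'     analyses.}
#' }
#'
#' @param name preset name.
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = c("uniform", "clustered_minorities",
                                     "density_gradient"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    uniform = list(n_block_groups = 25L, blocks_per_group = 16L,
                   base_block_size_m = 1000, density_gradient = 1,
                   clustering_concentration = 5,
                   total_population = 50000L, n_records = 2000L),
    clustered_minorities = list(
      n_block_groups = 100L, blocks_per_group = 16L,
      base_block_size_m = 800, density_gradient = 1,
      clustering_concentration = c(
        White = 10, WhiteNonHispanic = 10, Hispanic = 0.3, Black = 0.2,
        Asian = 0.1, AIAN = 0.1, NHPI = 0.1, Other = 0.2, TwoOrMore = 0.5),
      total_population = 200000L, n_records = 5000L),
    density_gradient = list(
      n_block_groups = 100L, blocks_per_group = 16L,
      base_block_size_m = 3000, density_gradient = 1e4,
      clustering_concentration = 5,
      total_population = 100000L, n_records = 4000L))
  do.call(scenario_config, utils::modifyList(args, list(seed = seed, ...)))
}

# most-square factor pair (rows, cols) of n, rows <= cols
grid_factor <- function(n) {
  r <- floor(sqrt(n))
  while (n %% r != 0) r <- r - 1
  c(rows = as.integer(r), cols = as.integer(n / r))
}

#' Generate a nested rectangular census geography
#'
#' Block groups tile a rectangle on a near-square grid; each group is
#' subdivided into a grid of rectangular blocks. Column widths shrink
#' geometrically along the x-axis so the largest block area is exactly
#' `density_gradient` times the smallest. Tracts aggregate
#' `groups_per_tract^2` groups and counties `tracts_per_county^2` tracts on
#' super-grids. Deterministic given the config.
#'
#' @param config a [scenario_config()].
#' @return a `census_geography` without counts.
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  gg <- grid_factor(config$n_block_groups)  # group grid rows x cols
  bg <- grid_factor(config$blocks_per_group)
  nr <- gg["rows"]; nc <- gg["cols"]
  if (config$density_gradient > 1 && nc < 2)
    stop("density gradient needs at least two group columns")
  base_w <- config$base_block_size_m * bg["cols"]
  base_h <- config$base_block_size_m * bg["rows"]
  # isotropic shrink per column: dense areas have blocks that are smaller in
  # both dimensions, as small urban blocks are; area ratio across the x-axis
  # is exactly density_gradient
  shrink <- if (nc > 1) config$density_gradient^(-1 / (2 * (nc - 1))) else 1
  col_w <- base_w * shrink^(0:(nc - 1))
  col_h <- base_h * shrink^(0:(nc - 1))
  col_x <- c(0, cumsum(col_w))
  blocks <- vector("list", config$n_block_groups * config$blocks_per_group)
  polys <- vector("list", length(blocks))
  ids <- character(length(blocks))
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    gid <- sprintf("bg_r%02d_c%02d", r, cc)
    tid <- sprintf("tr_r%02d_c%02d",
                   (r - 1) %/% config$groups_per_tract + 1,
                   (cc - 1) %/% config$groups_per_tract + 1)
    cid <- sprintf("co_r%02d_c%02d",
                   (r - 1) %/% (config$groups_per_tract *
                                  config$tracts_per_county) + 1,
                   (cc - 1) %/% (config$groups_per_tract *
                                   config$tracts_per_county) + 1)
    x0 <- col_x[cc]; y0 <- (r - 1) * col_h[cc]
    bw <- col_w[cc] / bg["cols"]; bh <- col_h[cc] / bg["rows"]
    for (br in seq_len(bg["rows"])) for (bc in seq_len(bg["cols"])) {
      k <- k + 1L
      bid <- sprintf("%s_b%02d", gid, (br - 1L) * bg["cols"] + bc)
      ids[k] <- bid
      blocks[[k]] <- data.frame(block_id = bid, block_group_id = gid,
                                tract_id = tid, county_id = cid,
                                stringsAsFactors = FALSE)
      polys[[k]] <- rect_polygon(x0 + (bc - 1) * bw, y0 + (br - 1) * bh,
                                 x0 + bc * bw, y0 + br * bh)
    }
  }
  names(polys) <- ids
  census_geography(config$schema, do.call(rbind, blocks), polys,
                   validate = FALSE)
}

# global sex x age-bin cell probabilities: even sexes, smooth age pyramid
sex_age_profile <- function(schema) {
  e <- schema$age_bin_edges
  upper <- c(e[-1], 100)
  w <- (upper - e) * exp(-e / 60)  # bin width x gentle old-age decay
  q_age <- w / sum(w)
  q_sex <- rep(1 / length(schema$sex_labels), length(schema$sex_labels))
  outer(q_sex, q_age)  # sexes x bins
}

#' Assign demographic counts to a geography's blocks
#'
#' Population is split across races by the configured shares; each race's
#' people are then allocated over blocks by a single Dirichlet draw with the
#' race's clustering concentration (low concentration concentrates the race
#' in few blocks) crossed with a global sex-by-age profile, and realised by
#' one multinomial draw, so the total population is conserved exactly.
#' Expected population per block is flat across blocks, so block-area
#' gradients translate into density gradients.
#'
#' @param geography a `census_geography` (counts ignored if present).
#' @param config the [scenario_config()] used to build it.
#' @return the geography with an integer counts matrix filled in.
#' @export
assign_population <- function(geography, config) {
  stopifnot(inherits(geography, "census_geography"),
            inherits(config, "scenario_config"))
  schema <- config$schema
  nb <- nrow(geography$blocks)
  ncat <- n_categories(schema)
  counts <- matrix(0L, nb, ncat,
                   dimnames = list(geography$blocks$block_id, NULL))
  races <- schema$race_labels
  nbin <- length(schema$age_bin_edges)
  cellp <- sex_age_profile(schema)  # sexes x bins
  with_seed(config$seed * 7L + 101L, {
    n_race <- as.vector(stats::rmultinom(1, config$total_population,
                                         config$race_shares))
    for (ri in seq_along(races)) {
      if (n_race[ri] == 0) next
      alpha <- config$clustering_concentration[[races[ri]]]
      pb <- rdirichlet1(rep(alpha, nb))
      # joint cell probs: blocks x (sex x bin)
      pr <- as.vector(outer(pb, as.vector(t(cellp))))  # block-major
      draw <- stats::rmultinom(1, n_race[ri], pr)
      cells <- matrix(draw, nrow = nb)  # blocks x (sex*bin), block-fastest
      for (si in seq_along(schema$sex_labels)) {
        cols <- category_index(schema, schema$sex_labels[si], races[ri],
                               schema$age_bin_edges)
        counts[, cols] <- counts[, cols] +
          cells[, (si - 1L) * nbin + seq_len(nbin)]
      }
    }
  })
  geography$counts <- counts
  geography
}

#' Sample person records with known true coordinates
#'
#' Each record is drawn from the count table: a (block, category) cell with
#' probability proportional to its count, then a uniform true point inside
#' that block. The coarse unit is the block's group, so by construction every
#' pristine record has at least one matching block (its own) and the
#' deterministic strategies are always feasible.
#'
#' @param geography a `census_geography` with counts.
#' @param config the [scenario_config()].
#' @param n number of records (default `config$n_records`).
#' @return data.frame of person records: `record_id`, `sex`, `race`,
#'   `age_years`, `x`, `y` (true location), `block_id` (provenance),
#'   `coarse_unit_id`, `coarse_level`.
#' @export
sample_records <- function(geography, config, n = config$n_records) {
  stopifnot(!is.null(geography$counts))
  if (n == 0)
    return(data.frame(record_id = character(), sex = character(),
                      race = character(), age_years = integer(),
                      x = numeric(), y = numeric(), block_id = character(),
                      coarse_unit_id = character(),
                      coarse_level = character(),
                      stringsAsFactors = FALSE))
  cnt <- geography$counts
  if (sum(cnt) == 0) stop("cannot sample records: zero total population")
  schema <- config$schema
  nb <- nrow(cnt)
  edges <- schema$age_bin_edges
  upper <- c(edges[-1] - 1L, 99L)  # sampled age cap within last open bin
  with_seed(config$seed * 7L + 202L, {
    cell <- sample.int(length(cnt), n, replace = TRUE, prob = as.vector(cnt))
    bi <- (cell - 1L) %% nb + 1L
    ci <- (cell - 1L) %/% nb + 1L
    lab <- category_labels(schema, ci)
    bin <- (ci - 1L) %% length(edges) + 1L
    age <- edges[bin] +
      floor(stats::runif(n) * (upper[bin] - edges[bin] + 1L))
    pts <- matrix(NA_real_, n, 2)
    for (b in unique(bi)) {
      sel <- which(bi == b)
      pts[sel, ] <- random_point_in_polygon(
        geography$polygons[[geography$blocks$block_id[b]]], length(sel))
    }
    data.frame(
      record_id = sprintf("r%06d", seq_len(n)),
      sex = lab$sex, race = lab$race, age_years = as.integer(age),
      x = pts[, 1], y = pts[, 2],
      block_id = geography$blocks$block_id[bi],
      coarse_unit_id = geography$blocks$block_group_id[bi],
      coarse_level = "block_group",
      stringsAsFactors = FALSE)
  })
}

#' Make a fraction of records demographically unmatchable
#'
#' Emulates records whose demographics match no block in their group (in real
#' registries caused by address changes since the census, or race
#' misclassification): for a seeded random subset of `ceiling(fraction * n)`
#' records, the race is switched to one with zero count for the record's
#' sex and age bin in every block of its group. Records for which no such
#' race exists are skipped and the next candidate in the permutation is used,
#' so the altered count is exact whenever enough feasible records exist.
#'
#' @param records data.frame from [sample_records()].
#' @param geography the `census_geography` with counts.
#' @param fraction fraction in `[0, 1)` of records to alter.
#' @param seed seed for the candidate permutation.
#' @return `records` with altered `race` values and a logical `unmatchable`
#'   column marking the altered rows.
#' @export
make_unmatchable <- function(records, geography, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  records$unmatchable <- FALSE
  m <- ceiling(fraction * nrow(records))
  if (m == 0) return(records)
  schema <- geography$schema
  races <- schema$race_labels
  altered <- 0L
  with_seed(seed * 7L + 303L, {
    ord <- sample.int(nrow(records))
    for (i in ord) {
      if (altered >= m) break
      rec <- records[i, ]
      rows <- unit_block_rows(geography, rec$coarse_unit_id, "block_group")
      cand <- setdiff(races, rec$race)
      idx <- category_index(schema, rec$sex, cand,
                            rep(rec$age_years, length(cand)))
      tot <- colSums(geography$counts[rows, idx, drop = FALSE])
      ok <- which(tot == 0L)
      if (!length(ok)) next
      records$race[i] <- cand[ok[1]]
      records$unmatchable[i] <- TRUE
      altered <- altered + 1L
    }
  })
  if (altered < m)
    warning("only ", altered, " of ", m,
            " requested records could be made unmatchable")
  records
}

#' Generate a complete scenario: geography, counts and records
#'
#' Convenience wrapper: [generate_geography()], [assign_population()],
#' [sample_records()], then [make_unmatchable()] if the config requests it.
#'
#' @param config a [scenario_config()] or preset name for
#'   [scenario_preset()].
#' @param seed master seed when `config` is a preset name.
#' @return list with elements `geography`, `records`, `config`.
#' @export
generate_scenario <- function(config, seed = 1L) {
  if (is.character(config)) config <- scenario_preset(config, seed = seed)
  g <- generate_geography(config)
  g <- assign_population(g, config)
  rec <- sample_records(g, config)
  if (config$unmatchable_fraction > 0)
    rec <- make_unmatchable(rec, g, config$unmatchable_fraction,
                            seed = config$seed)
  list(geography = g, records = rec, config = config)
}
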