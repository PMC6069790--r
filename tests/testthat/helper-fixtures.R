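# Shared fixtures: a tiny hand-checkable geography and cached preset
# scenarios (generation is deterministic per seed, caching just saves time).

.fixtures <- new.env(parent = emptyenv())

cached_scenario <- function(name, seed = 1L, ...) {
  key <- paste(name, seed, paste(deparse(list(...)), collapse = ""),
               sep = "#")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_scenario(
      scenario_preset(name, seed = seed, ...))
  .fixtures[[key]]
}

tiny_schema <- function() {
  demographic_schema(sex_labels = c("M", "F"), race_labels = c("A", "B"),
                     age_bin_edges = c(0, 18, 65))
}

# one block group of four 10x10 m blocks on a 2x2 grid plus a second group
# of two blocks; a single tract and county
tiny_geography <- function(counts = NULL) {
  blocks <- data.frame(
    block_id = c("b1", "b2", "b3", "b4", "c1", "c2"),
    block_group_id = c("g1", "g1", "g1", "g1", "g2", "g2"),
    tract_id = "t1", county_id = "co1", stringsAsFactors = FALSE)
  polys <- list(
    b1 = rect_polygon(0, 0, 10, 10),   b2 = rect_polygon(10, 0, 20, 10),
    b3 = rect_polygon(0, 10, 10, 20),  b4 = rect_polygon(10, 10, 20, 20),
    c1 = rect_polygon(30, 0, 40, 20),  c2 = rect_polygon(40, 0, 50, 20))
  census_geography(tiny_schema(), blocks, polys, counts)
}

# counts matrix helper for the tiny geography: set one category's counts
tiny_counts <- function(category, per_block) {
  m <- matrix(0L, 6, n_categories(tiny_schema()),
              dimnames = list(c("b1", "b2", "b3", "b4", "c1", "c2"), NULL))
  m[seq_along(per_block), category] <- as.integer(per_block)
  m
}

# a record living in the tiny geography
tiny_record <- function(sex = "M", race = "A", age = 30, unit = "g1",
                        level = "block_group", x = NA, y = NA) {
  data.frame(record_id = "r1", sex = sex, race = race,
             age_years = as.integer(age), x = x, y = y,
             coarse_unit_id = unit, coarse_level = level,
             stringsAsFactors = FALSE)
}

gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}
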