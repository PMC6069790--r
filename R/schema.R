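# Demographic category space: sex x race x age bin.

#' Construct a demographic schema
#'
#' A schema defines the category space used for block-level population counts:
#' the cross product of sex labels, race labels and right-open age bins.
#' Category indices are sex-major, then race, then age bin, and are 1-based
#' (the first (sex, race, bin) triple has index 1), so an index addresses a
#' column of a counts matrix directly.
#'
#' @param sex_labels character vector of sex labels, order fixes the index.
#' @param race_labels character vector of race labels, order fixes the index.
#' @param age_bin_edges strictly increasing integer vector of bin lower/upper
#'   boundaries in years. Bins are `[edge[i], edge[i+1])` plus a final
#'   open-ended bin `[last edge, Inf)`; `length(edges) = n_bins`, with
#'   `edges[1]` the lower bound of the first bin (usually 0).
#' @return An object of class `demographic_schema`.
#' @examples
#' sc <- default_schema()
#' n_categories(sc)  # 414
#' @export
demographic_schema <- function(sex_labels, race_labels, age_bin_edges) {
  stopifnot(is.character(sex_labels), length(sex_labels) >= 1,
            is.character(race_labels), length(race_labels) >= 1,
            is.numeric(age_bin_edges), length(age_bin_edges) >= 1)
  if (anyDuplicated(sex_labels) || anyDuplicated(race_labels))
    stop("schema labels must be unique")
  if (is.unsorted(age_bin_edges, strictly = TRUE))
    stop("age_bin_edges must be strictly increasing")
  if (age_bin_edges[1] != 0)
    stop("age_bin_edges must start at 0 so every non-negative age maps to a bin")
  structure(
    list(sex_labels = sex_labels,
         race_labels = race_labels,
         age_bin_edges = as.integer(age_bin_edges)),
    class = "demographic_schema")
}

#' Default SF1-style schema: 2 sexes, 9 race groups, 23 age ranges
#'
#' The decennial-census block tabulation style: counts by sex for nine
#' race/ethnicity groups over 23 age ranges, giving
#' 2 x 9 x 23 = 414 categories.
#'
#' @return A `demographic_schema`.
#' @export
default_schema <- function() {
  demographic_schema(
    sex_labels = c("Male", "Female"),
    race_labels = c("White", "Black", "AIAN", "Asian", "NHPI",
                    "Other", "TwoOrMore", "Hispanic", "WhiteNonHispanic"),
    # under 5, 5-9, 10-14, 15-17, 18-19, 20, 21, 22-24, then five-year bins
    # to 59, 60-61, 62-64, 65-66, 67-69, 70-74, 75-79, 80-84, 85+
    age_bin_edges = c(0, 5, 10, 15, 18, 20, 21, 22, 25, 30, 35, 40, 45,
                      50, 55, 60, 62, 65, 67, 70, 75, 80, 85))
}

#' @export
print.demographic_schema <- function(x, ...) {
  cat("<demographic_schema>", length(x$sex_labels), "sexes x",
      length(x$race_labels), "races x", length(x$age_bin_edges),
      "age bins =", n_categories(x), "categories\n")
  invisible(x)
}

#' Number of categories in a schema
#' @param schema a `demographic_schema`.
#' @return integer count of (sex, race, age-bin) categories.
#' @export
n_categories <- function(schema) {
  length(schema$sex_labels) * length(schema$race_labels) *
    length(schema$age_bin_edges)
}

#' Age bin index for an age in years
#'
#' Bins are right-open, the last bin open-ended, so every non-negative
#' integer age maps to exactly one bin.
#'
#' @param schema a `demographic_schema`.
#' @param age_years non-negative numeric vector of ages.
#' @return integer vector of 1-based bin indices.
#' @export
age_bin_index <- function(schema, age_years) {
  if (any(age_years < 0)) stop("age_years must be non-negative")
  findInterval(age_years, schema$age_bin_edges)
}

#' Human-readable labels for a schema's age bins ("0-4", ..., "85+")
#' @param schema a `demographic_schema`.
#' @return character vector, one label per bin.
#' @export
age_bin_labels <- function(schema) {
  e <- schema$age_bin_edges
  n <- length(e)
  c(paste0(e[-n], "-", e[-1] - 1L), paste0(e[n], "+"))
}

#' Category index for a (sex, race, age) triple
#'
#' Maps demographics to the 1-based column index of the counts table.
#' The map is a bijection over (sex, race, age-bin) triples: sex-major,
#' then race, then age bin.
#'
#' @param schema a `demographic_schema`.
#' @param sex,race label(s) present in the schema; vectors are recycled
#'   to a common length.
#' @param age_years non-negative age(s) in years.
#' @return integer vector of category indices in `[1, n_categories(schema)]`.
#' @seealso [category_labels()] for the inverse map.
#' @export
category_index <- function(schema, sex, race, age_years) {
  si <- match(sex, schema$sex_labels)
  if (anyNA(si)) {
    bad <- unique(sex[is.na(si)])
    stop("unknown sex label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ri <- match(race, schema$race_labels)
  if (anyNA(ri)) {
    bad <- unique(race[is.na(ri)])
    stop("unknown race label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ai <- age_bin_index(schema, age_years)
  nr <- length(schema$race_labels)
  nb <- length(schema$age_bin_edges)
  as.integer((si - 1L) * nr * nb + (ri - 1L) * nb + ai)
}

#' Decode category indices back to (sex, race, age_bin) labels
#'
#' @param schema a `demographic_schema`.
#' @param index integer vector of category indices.
#' @return data.frame with columns `sex`, `race`, `age_bin` (bin label).
#' @export
category_labels <- function(schema, index = seq_len(n_categories(schema))) {
  stopifnot(all(index >= 1), all(index <= n_categories(schema)))
  nr <- length(schema$race_labels)
  nb <- length(schema$age_bin_edges)
  i0 <- as.integer(index) - 1L
  data.frame(
    sex = schema$sex_labels[i0 %/% (nr * nb) + 1L],
    race = schema$race_labels[(i0 %/% nb) %% nr + 1L],
    age_bin = age_bin_labels(schema)[i0 %% nb + 1L],
    stringsAsFactors = FALSE)
}

#' Remap record race labels onto schema race labels
#'
#' Registry race coding rarely matches census tabulation groups one-to-one
#' (e.g. "white, unknown ethnicity" vs. "white Hispanic"); rather than
#' hard-coding a correspondence, callers supply a named mapping table.
#'
#' @param records data.frame with a `race` column.
#' @param mapping named character vector: `names(mapping)` are record-side
#'   labels, values are schema race labels. Labels absent from the table are
#'   passed through unchanged.
#' @return `records` with `race` remapped.
#' @export
map_race_labels <- function(records, mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  hit <- records$race %in% names(mapping)
  records$race[hit] <- unname(mapping[records$race[hit]])
  records
}
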