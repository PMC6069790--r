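# The four geoimputation strategies.
#
# S1  random point in the whole coarse unit            (stochastic)
# S2  random point within demographically matching blocks (stochastic)
# S3  centroid of the maximum-weight block             (deterministic)
# S4  demographically weighted mean of block centroids (deterministic)
#
# Weights are the record's demographic category count in a block divided by
# the coarse unit's total for that category.

STOCHASTIC <- c("S1", "S2")
DETERMINISTIC <- c("S3", "S4")

imputed_row <- function(record_id, strategy, replicate, xy = c(NA_real_,
                        NA_real_), status = "imputed",
                        fallback_used = FALSE) {
  data.frame(record_id = record_id, strategy = strategy,
             replicate = as.integer(replicate),
             x = xy[1], y = xy[2], status = status,
             fallback_used = fallback_used, stringsAsFactors = FALSE)
}

# uniform point over the union of the given block rows: block ~ area, then
# uniform inside (exact for blocks tiling the unit)
uniform_point_over_blocks <- function(g, rows) {
  i <- if (length(rows) == 1) rows else
    rows[sample.int(length(rows), 1, prob = g$blocks$area_m2[rows])]
  random_point_in_polygon(g$polygons[[g$blocks$block_id[i]]], 1)[1, ]
}

record_unit_rows <- function(g, record) {
  unit_block_rows(g, record$coarse_unit_id, record$coarse_level)
}

record_category <- function(g, record) {
  category_index(g$schema, record$sex, record$race, record$age_years)
}

#' Strategy 1: uniform random point in the coarse unit
#'
#' Assigns the record to a point drawn uniformly over its coarse unit
#' (block group by default); never unimputable. Uses the current RNG state;
#' seed with `set.seed()` or use [impute_batch()] for per-record substreams.
#'
#' @param record one-row data.frame with `record_id`, `coarse_unit_id`,
#'   `coarse_level`.
#' @param geography a `census_geography`.
#' @param replicate replicate index recorded in the output.
#' @return one-row data.frame: `record_id`, `strategy`, `replicate`, `x`,
#'   `y`, `status`, `fallback_used`.
#' @export
impute_s1 <- function(record, geography, replicate = 1L) {
  rows <- record_unit_rows(geography, record)
  imputed_row(record$record_id, "S1", replicate,
              uniform_point_over_blocks(geography, rows))
}

#' Strategy 2: random point within matching blocks
#'
#' Restricts the random point to member blocks with positive count for the
#' record's demographic category: a matching block is chosen with probability
#' proportional to its area (so the point is uniform over the union of
#' matching blocks), then the point is uniform inside it. With
#' `weighting = "population"` blocks are instead chosen proportional to their
#' category count. If no block matches, the strategy falls back to the whole
#' unit (S1 behaviour) and flags `fallback_used = TRUE` so the accounting
#' stays auditable.
#'
#' @inheritParams impute_s1
#' @param weighting block selection law among matching blocks.
#' @export
impute_s2 <- function(record, geography, replicate = 1L,
                      weighting = c("area", "population")) {
  weighting <- match.arg(weighting)
  rows <- record_unit_rows(geography, record)
  cat <- record_category(geography, record)
  cnt <- geography$counts[rows, cat]
  match_rows <- rows[cnt > 0L]
  if (!length(match_rows))
    return(within_fallback(record, geography, rows, replicate))
  i <- if (length(match_rows) == 1) match_rows else {
    prob <- switch(weighting,
                   area = geography$blocks$area_m2[match_rows],
                   population = cnt[cnt > 0L])
    match_rows[sample.int(length(match_rows), 1, prob = prob)]
  }
  xy <- random_point_in_polygon(
    geography$polygons[[geography$blocks$block_id[i]]], 1)[1, ]
  imputed_row(record$record_id, "S2", replicate, xy)
}

within_fallback <- function(record, geography, rows, replicate) {
  imputed_row(record$record_id, "S2", replicate,
              uniform_point_over_blocks(geography, rows),
              fallback_used = TRUE)
}

#' Strategy 3: centroid of the maximum-weight block
#'
#' Deterministic: the record goes to the centroid of the member block with
#' the largest demographic weight for its category, ties broken by ascending
#' block id. Every record of a given (unit, category) maps to the same point,
#' so this strategy is prone to artificial clustering. Unimputable when the
#' unit has no matching population for the category.
#'
#' @inheritParams impute_s1
#' @export
impute_s3 <- function(record, geography) {
  rows <- record_unit_rows(geography, record)
  cat <- record_category(geography, record)
  cnt <- geography$counts[rows, cat]
  if (sum(cnt) == 0L)
    return(imputed_row(record$record_id, "S3", 1L, status = "unimputable"))
  ids <- geography$blocks$block_id[rows]
  ord <- order(ids)  # tie-break: ascending block_id
  best <- rows[ord][which.max(cnt[ord])]
  imputed_row(record$record_id, "S3", 1L,
              c(geography$blocks$centroid_x[best],
                geography$blocks$centroid_y[best]))
}

#' Strategy 4: demographically weighted mean of block centroids
#'
#' Deterministic: the weighted mean center of the member block centroids,
#' weights equal to each block's share of the unit's population for the
#' record's category (zero-weight blocks contribute nothing). The result lies
#' in the convex hull of matching-block centroids; two records collide only
#' when their categories yield identical weight vectors in the same unit.
#' Unimputable when the unit total for the category is zero.
#'
#' @inheritParams impute_s1
#' @export
impute_s4 <- function(record, geography) {
  rows <- record_unit_rows(geography, record)
  cat <- record_category(geography, record)
  cnt <- geography$counts[rows, cat]
  tot <- sum(cnt)
  if (tot == 0L)
    return(imputed_row(record$record_id, "S4", 1L, status = "unimputable"))
  w <- cnt / tot
  imputed_row(record$record_id, "S4", 1L,
              c(sum(w * geography$blocks$centroid_x[rows]),
                sum(w * geography$blocks$centroid_y[rows])))
}

# stable 31-polynomial string hash mod 2^31-1, platform independent
stable_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

substream_seed <- function(master_seed, record_id, strategy, replicate) {
  key <- paste(record_id, strategy, replicate, sep = "|")
  as.integer((as.numeric(master_seed) + stable_hash(key)) %% 2147483647)
}

#' Impute a batch of records with several strategies and replicates
#'
#' Stochastic strategies (S1, S2) produce `n_replicates` rows per record,
#' each drawn from an RNG substream seeded by a stable hash of
#' (record id, strategy, replicate) plus the master seed, so results do not
#' depend on batch order or on which other strategies run. Deterministic
#' strategies (S3, S4) produce one row per record. Per-record failures are
#' collected and reported as `status = "error"` rows with a warning rather
#' than aborting the batch.
#'
#' @param records data.frame of person records (see [sample_records()] /
#'   [read_records()]).
#' @param geography a `census_geography` with counts.
#' @param strategies subset of c("S1","S2","S3","S4").
#' @param n_replicates replicates for stochastic strategies (>= 1).
#' @param seed master seed; mandatory when a stochastic strategy is
#'   requested.
#' @param s2_weighting passed to [impute_s2()].
#' @return data.frame with one row per (record, strategy, replicate):
#'   `record_id`, `strategy`, `replicate`, `x`, `y`, `status`,
#'   `fallback_used`.
#' @export
impute_batch <- function(records, geography,
                         strategies = c("S1", "S2", "S3", "S4"),
                         n_replicates = 1L, seed = NULL,
                         s2_weighting = "area") {
  strategies <- match.arg(strategies, c("S1", "S2", "S3", "S4"),
                          several.ok = TRUE)
  stopifnot(n_replicates >= 1)
  if (any(strategies %in% STOCHASTIC) && is.null(seed))
    stop("a master seed is required for stochastic strategies")
  n <- nrow(records)
  g <- geography
  cat_idx <- category_index(g$schema, records$sex, records$race,
                            records$age_years)
  # cache member-block rows per coarse unit
  ucache <- new.env(parent = emptyenv())
  rows_of <- function(uid, lvl) {
    key <- paste0(lvl, ":", uid)
    if (is.null(ucache[[key]]))
      ucache[[key]] <- unit_block_rows(g, uid, lvl)
    ucache[[key]]
  }
  errors <- character(0)
  out <- vector("list", length(strategies))
  for (si in seq_along(strategies)) {
    st <- strategies[si]
    stoch <- st %in% STOCHASTIC
    nrep <- if (stoch) as.integer(n_replicates) else 1L
    m <- n * nrep
    rid <- rep(records$record_id, each = nrep)
    repl <- rep(seq_len(nrep), times = n)
    x <- rep(NA_real_, m); y <- rep(NA_real_, m)
    status <- rep("imputed", m)
    fallback <- rep(FALSE, m)
    k <- 0L
    for (i in seq_len(n)) {
      res <- tryCatch({
        rows <- rows_of(records$coarse_unit_id[i], records$coarse_level[i])
        cnt <- g$counts[rows, cat_idx[i]]
        switch(st,
          S1 = {
            for (r in seq_len(nrep)) {
              set.seed(substream_seed(seed, records$record_id[i], st, r))
              xy <- uniform_point_over_blocks(g, rows)
              x[k + r] <- xy[1]; y[k + r] <- xy[2]
            }
          },
          S2 = {
            match_rows <- rows[cnt > 0L]
            for (r in seq_len(nrep)) {
              set.seed(substream_seed(seed, records$record_id[i], st, r))
              if (!length(match_rows)) {
                xy <- uniform_point_over_blocks(g, rows)
                fallback[k + r] <- TRUE
              } else if (length(match_rows) == 1) {
                xy <- random_point_in_polygon(
                  g$polygons[[g$blocks$block_id[match_rows]]], 1)[1, ]
              } else {
                prob <- switch(s2_weighting,
                               area = g$blocks$area_m2[match_rows],
                               population = cnt[cnt > 0L])
                j <- match_rows[sample.int(length(match_rows), 1,
                                           prob = prob)]
                xy <- random_point_in_polygon(
                  g$polygons[[g$blocks$block_id[j]]], 1)[1, ]
              }
              x[k + r] <- xy[1]; y[k + r] <- xy[2]
            }
          },
          S3 = {
            if (sum(cnt) == 0L) status[k + 1L] <- "unimputable"
            else {
              ids <- g$blocks$block_id[rows]
              ord <- order(ids)  # tie-break: ascending block_id
              best <- rows[ord][which.max(cnt[ord])]
              x[k + 1L] <- g$blocks$centroid_x[best]
              y[k + 1L] <- g$blocks$centroid_y[best]
            }
          },
          S4 = {
            tot <- sum(cnt)
            if (tot == 0L) status[k + 1L] <- "unimputable"
            else {
              w <- cnt / tot
              x[k + 1L] <- sum(w * g$blocks$centroid_x[rows])
              y[k + 1L] <- sum(w * g$blocks$centroid_y[rows])
            }
          })
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, paste0(records$record_id[i], "/", st, ": ",
                                   conditionMessage(res)))
        status[k + seq_len(nrep)] <- "error"
        x[k + seq_len(nrep)] <- NA_real_
        y[k + seq_len(nrep)] <- NA_real_
      }
      k <- k + nrep
    }
    out[[si]] <- data.frame(record_id = rid, strategy = st,
                            replicate = repl, x = x, y = y,
                            status = status, fallback_used = fallback,
                            stringsAsFactors = FALSE)
  }
  if (length(errors))
    warning(length(errors), " record(s) failed: ",
            paste(utils::head(errors, 5), collapse = "; "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of records each strategy could impute
#'
#' A record counts as imputed by a strategy if at least one of its replicate
#' rows has `status = "imputed"`. The deterministic strategies fail exactly
#' on records whose category has no matching population in their coarse
#' unit; S1 never fails and S2 falls back instead of failing.
#'
#' @param imputed output of [impute_batch()].
#' @return data.frame: `strategy`, `n_records`, `n_imputed`, `fraction`.
#' @export
imputable_fraction <- function(imputed) {
  if (!nrow(imputed)) stop("empty imputation table")
  res <- do.call(rbind, lapply(split(imputed, imputed$strategy), function(d) {
    tot <- unique(d$record_id)
    ok <- unique(d$record_id[d$status == "imputed"])
    data.frame(strategy = d$strategy[1], n_records = length(tot),
               n_imputed = length(ok),
               fraction = length(ok) / length(tot),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
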