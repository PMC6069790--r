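test_that("S1 samples uniformly over the coarse unit", {
  cat <- category_index(tiny_schema(), "M", "A", 30)
  g <- tiny_geography(tiny_counts(cat, c(1, 1, 1, 1)))
  rec <- tiny_record(unit = "g2")  # g2 = two 10x20 blocks spanning x 30..50
  set.seed(1); a <- impute_s1(rec, g)
  set.seed(1); b <- impute_s1(rec, g)
  expect_identical(a, b)
  expect_equal(a$status, "imputed")
  expect_true(a$x > 30 && a$x < 50 && a$y > 0 && a$y < 20)
  # per-block hit frequencies proportional to areas (binomial 3 sigma):
  # g1 blocks are equal-area quadrants, track hits in b1
  rec1 <- tiny_record(unit = "g1")
  set.seed(2)
  hits <- replicate(4000, {
    p <- impute_s1(rec1, g)
    (p$x < 10) + 2 * (p$y < 10)
  })
  n1 <- sum(hits == 3)  # b1: x<10 & y<10
  expect_lt(abs(n1 - 1000), 3 * sqrt(4000 * 0.25 * 0.75))
})

test_that("S2 restricts to matching blocks and splits by area", {
  cat <- category_index(tiny_schema(), "M", "A", 30)
  g <- tiny_geography(tiny_counts(cat, c(0, 3, 0, 9)))  # b2, b4 match
  rec <- tiny_record()
  set.seed(3)
  pts <- do.call(rbind, replicate(4000, impute_s2(rec, g),
                                  simplify = FALSE))
  expect_true(all(pts$status == "imputed"), info = "never unimputable")
  expect_false(any(pts$fallback_used))
  in_b2 <- pts$x > 10 & pts$y < 10
  in_b4 <- pts$x > 10 & pts$y > 10
  expect_true(all(in_b2 | in_b4))  # containment in matching blocks only
  # equal areas -> 50/50 within 3 sigma
  expect_lt(abs(sum(in_b2) - 2000), 3 * sqrt(4000 * 0.25))
  # single matching block -> always inside it
  g1 <- tiny_geography(tiny_counts(cat, c(0, 0, 5, 0)))
  set.seed(4)
  p <- impute_s2(rec, g1)
  expect_true(p$x < 10 && p$y > 10)
})

test_that("S2 falls back to the whole unit when nothing matches", {
  cat <- category_index(tiny_schema(), "M", "A", 30)
  g <- tiny_geography(tiny_counts(cat, c(0, 0, 0, 0)))
  set.seed(5)
  p <- impute_s2(tiny_record(), g)
  expect_equal(p$status, "imputed")
  expect_true(p$fallback_used)
  expect_true(p$x > 0 && p$x < 20 && p$y > 0 && p$y < 20)
})

test_that("S3 picks the max-weight block's centroid, ties by block id", {
  cat <- category_index(tiny_schema(), "M", "A", 30)
  g <- tiny_geography(tiny_counts(cat, c(1, 3, 0, 0)))  # weights .25/.75
  p <- impute_s3(tiny_record(), g)
  expect_equal(c(p$x, p$y), c(15, 5))  # centroid of b2
  # tie between b1 and b2 -> ascending block_id wins
  gt <- tiny_geography(tiny_counts(cat, c(3, 3, 0, 0)))
  pt <- impute_s3(tiny_record(), gt)
  expect_equal(c(pt$x, pt$y), c(5, 5))
  # all-zero -> unimputable; two same-category records land identically
  g0 <- tiny_geography(tiny_counts(cat, c(0, 0, 0, 0)))
  expect_equal(impute_s3(tiny_record(), g0)$status, "unimputable")
  p2 <- impute_s3(tiny_record(), g)
  expect_identical(c(p$x, p$y), c(p2$x, p2$y))
})

test_that("S4 is the weighted mean of centroids and matches brute force", {
  cat <- category_index(tiny_schema(), "M", "A", 30)
  g <- tiny_geography(tiny_counts(cat, c(1, 3, 0, 0)))
  p <- impute_s4(tiny_record(), g)
  # centroids (5,5), (15,5) with weights .25/.75 -> (12.5, 5)
  expect_equal(c(p$x, p$y), c(12.5, 5))
  g0 <- tiny_geography(tiny_counts(cat, c(0, 0, 0, 0)))
  expect_equal(impute_s4(tiny_record(), g0)$status, "unimputable")
  # 4-block fixture vs an independent brute-force sum over rectangles
  per_block <- c(2, 5, 1, 9)
  gb <- tiny_geography(tiny_counts(cat, per_block))
  rects <- list(c(0, 0, 10, 10), c(10, 0, 20, 10),
                c(0, 10, 10, 20), c(10, 10, 20, 20))
  w <- per_block / sum(per_block)
  oracle <- Reduce(`+`, Map(function(wi, r)
    wi * c((r[1] + r[3]) / 2, (r[2] + r[4]) / 2), w, rects))
  pb <- impute_s4(tiny_record(), gb)
  expect_equal(c(pb$x, pb$y), oracle, tolerance = 1e-9)
  # single matching block: S3 and S4 coincide at that block's centroid
  g1 <- tiny_geography(tiny_counts(cat, c(0, 0, 8, 0)))
  p3 <- impute_s3(tiny_record(), g1)
  p4 <- impute_s4(tiny_record(), g1)
  expect_equal(c(p3$x, p3$y), c(p4$x, p4$y))
  expect_equal(c(p4$x, p4$y), c(5, 15))
})

test_that("S4 collides only on identical weight vectors", {
  sc <- tiny_schema()
  catA <- category_index(sc, "M", "A", 30)
  catB <- category_index(sc, "M", "B", 30)
  m <- tiny_counts(catA, c(1, 3, 0, 0))
  m[1:4, catB] <- c(3L, 1L, 0L, 0L)   # different weight vector
  g <- tiny_geography(m)
  pa <- impute_s4(tiny_record(race = "A"), g)
  pb <- impute_s4(tiny_record(race = "B"), g)
  expect_false(isTRUE(all.equal(c(pa$x, pa$y), c(pb$x, pb$y))))
  m2 <- m; m2[1:4, catB] <- c(2L, 6L, 0L, 0L)  # proportional -> same weights
  g2 <- tiny_geography(m2)
  pa2 <- impute_s4(tiny_record(race = "A"), g2)
  pb2 <- impute_s4(tiny_record(race = "B"), g2)
  expect_equal(c(pa2$x, pa2$y), c(pb2$x, pb2$y))
})

test_that("batch has the right shape, is seed-stable, order-invariant", {
  sc <- cached_scenario("uniform", seed = 2)
  rec <- sc$records[1:10, ]
  imp <- impute_batch(rec, sc$geography, n_replicates = 10, seed = 42)
  expect_equal(nrow(imp), 10 * (10 + 10 + 1 + 1))  # 220
  imp2 <- impute_batch(rec, sc$geography, n_replicates = 10, seed = 42)
  expect_identical(imp, imp2)
  # reversing record order must not change any imputed point
  imp3 <- impute_batch(rec[10:1, ], sc$geography, n_replicates = 10,
                       seed = 42)
  key <- function(d) d[order(d$record_id, d$strategy, d$replicate), ]
  expect_equal(key(imp3)$x, key(imp)$x)
  expect_error(impute_batch(rec, sc$geography, c("S1")), "seed")
})

test_that("strategy contracts hold on seeded records from each preset", {
  for (name in c("uniform", "clustered_minorities", "density_gradient")) {
    sc <- cached_scenario(name, seed = 1)
    g <- sc$geography
    rec <- sc$records[seq_len(min(400, nrow(sc$records))), ]
    imp <- impute_batch(rec, g, n_replicates = 1, seed = 9)
    ok <- imp[imp$status == "imputed", ]
    i <- match(ok$record_id, rec$record_id)
    rows_of <- split(seq_len(nrow(g$blocks)), g$blocks$block_group_id)
    cats <- category_index(g$schema, rec$sex, rec$race, rec$age_years)
    for (k in seq_len(nrow(ok))) {
      rows <- rows_of[[rec$coarse_unit_id[i[k]]]]
      cnt <- g$counts[rows, cats[i[k]]]
      ids <- g$blocks$block_id[rows]
      inside <- vapply(ids, function(b)
        point_in_polygon(g$polygons[[b]], ok$x[k], ok$y[k]), logical(1))
      if (ok$strategy[k] == "S1") {
        expect_true(any(inside))                       # in the unit
      } else if (ok$strategy[k] == "S2" && !ok$fallback_used[k]) {
        expect_true(any(inside & cnt > 0))             # in a matching block
      } else if (ok$strategy[k] == "S3") {             # some member centroid
        expect_true(any(abs(g$blocks$centroid_x[rows] - ok$x[k]) < 1e-9 &
                          abs(g$blocks$centroid_y[rows] - ok$y[k]) < 1e-9))
      } else if (ok$strategy[k] == "S4") {             # convex hull box
        mrows <- rows[cnt > 0]
        expect_true(
          ok$x[k] >= min(g$blocks$centroid_x[mrows]) - 1e-9 &
          ok$x[k] <= max(g$blocks$centroid_x[mrows]) + 1e-9 &
          ok$y[k] >= min(g$blocks$centroid_y[mrows]) - 1e-9 &
          ok$y[k] <= max(g$blocks$centroid_y[mrows]) + 1e-9)
      }
    }
  }
})

test_that("unmatchable records break S3/S4 but never S1, and flag S2", {
  sc <- cached_scenario("uniform", seed = 2)
  rec <- make_unmatchable(sc$records[1:200, ], sc$geography, 0.1, seed = 8)
  imp <- impute_batch(rec, sc$geography, n_replicates = 2, seed = 10)
  bad <- rec$record_id[rec$unmatchable]
  for (st in c("S3", "S4")) {
    d <- imp[imp$strategy == st, ]
    expect_setequal(d$record_id[d$status == "unimputable"], bad)
  }
  expect_true(all(imp$status[imp$strategy == "S1"] == "imputed"))
  s2 <- imp[imp$strategy == "S2", ]
  expect_setequal(unique(s2$record_id[s2$fallback_used]), bad)
  frac <- imputable_fraction(imp)
  expect_equal(frac$fraction[frac$strategy == "S4"],
               1 - length(bad) / 200)
})
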