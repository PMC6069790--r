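test_that("coarsening rewrites the unit id at each level and is idempotent", {
  sc <- cached_scenario("uniform", seed = 2)
  g <- sc$geography
  rec <- sc$records[1:100, ]
  bg <- coarsen(rec, g, "block_group")
  expect_equal(bg$coarse_unit_id,
               g$blocks$block_group_id[match(rec$block_id,
                                             g$blocks$block_id)])
  tr <- coarsen(rec, g, "tract")
  expect_identical(coarsen(tr, g, "tract"), tr)
  # containment lookup agrees with the provenance block id
  rec2 <- rec; rec2$block_id <- NULL
  expect_equal(coarsen(rec2, g, "tract")$coarse_unit_id, tr$coarse_unit_id)
  # single-county geography: all records share one county id
  co <- coarsen(rec, g, "county")
  expect_true(length(unique(co$coarse_unit_id)) >= 1)
  expect_equal(co$coarse_level, rep("county", 100))
})

test_that("summary quartiles use linear interpolation; se undefined at n=1", {
  err <- data.frame(record_id = sprintf("r%d", 1:6),
                    strategy = c(rep("S1", 5), "S2"),
                    replicate = 1L, error_m = c(1, 2, 3, 4, 5, 7),
                    status = "imputed", stringsAsFactors = FALSE)
  s <- stratified_summary(err, "strategy")
  s1 <- s[s$strategy == "S1", ]
  expect_equal(s1[, c("median_m", "q1_m", "q3_m", "min_m", "max_m")],
               data.frame(median_m = 3, q1_m = 2, q3_m = 4, min_m = 1,
                          max_m = 5), ignore_attr = TRUE)
  expect_equal(s1$se_m, sd(1:5) / sqrt(5))
  expect_true(is.na(s$se_m[s$strategy == "S2"]))  # n = 1: missing, not 0
  expect_error(stratified_summary(err, "nope"), "unknown")
})

test_that("summary statistics match brute-force recomputation", {
  set.seed(21)
  err <- data.frame(record_id = sprintf("r%03d", 1:100),
                    strategy = sample(c("S1", "S4"), 100, TRUE),
                    replicate = 1L,
                    error_m = rlnorm(100, 6, 1),
                    race = sample(c("White", "Black"), 100, TRUE),
                    status = "imputed", stringsAsFactors = FALSE)
  s <- stratified_summary(err, c("strategy", "race"))
  for (k in seq_len(nrow(s))) {
    v <- err$error_m[err$strategy == s$strategy[k] & err$race == s$race[k]]
    expect_equal(s$mean_m[k], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(s$n[k], length(v))
    expect_equal(s$min_m[k], min(v))
    expect_equal(s$max_m[k], max(v))
    expect_equal(s$se_m[k], sqrt(sum((v - mean(v))^2) / (length(v) - 1)) /
                   sqrt(length(v)), tolerance = 1e-12)
  }
})

test_that("density decades are right-open and partition the rows", {
  err <- data.frame(record_id = sprintf("r%d", 1:4), strategy = "S1",
                    replicate = 1L, error_m = c(10, 20, 30, 40),
                    density_per_km2 = c(50, 100, 99.999, 0.5),
                    status = "imputed", stringsAsFactors = FALSE)
  e <- assign_density_bins(err)
  expect_equal(e$density_bin,
               c("[1e+01,1e+02)", "[1e+02,1e+03)", "[1e+01,1e+02)",
                 "[1e-01,1e+00)"))
  expect_equal(bin_decade(e$density_bin), c(1L, 2L, 1L, -1L))
  d <- density_bins(err)
  expect_equal(sum(d$n), 4)
  err$density_per_km2[1] <- 0
  expect_error(assign_density_bins(err), "positive")
})

test_that("multiple imputation averages per record first, rejects S3/S4", {
  err <- data.frame(record_id = rep(c("r1", "r2"), each = 2),
                    strategy = "S1", replicate = c(1L, 2L, 1L, 2L),
                    error_m = c(10, 20, 100, 200),
                    density_bin = "[1e+01,1e+02)",
                    status = "imputed", stringsAsFactors = FALSE)
  s <- multiple_imputation_summary(err)
  expect_equal(s$n, 2)                    # one observation per record
  expect_equal(s$mean_m, mean(c(15, 150)))
  expect_equal(s$replicate_sd_m, mean(c(sd(c(10, 20)), sd(c(100, 200)))))
  err3 <- err; err3$strategy <- "S3"
  expect_error(multiple_imputation_summary(err3), "deterministic")
})

test_that("coarser units cannot improve accuracy on a degenerate geography", {
  # one group = one tract = one county: identical results at all levels
  cat <- category_index(tiny_schema(), "M", "A", 30)
  m <- tiny_counts(cat, c(2, 1, 1, 1)); m[5:6, cat] <- 0L
  blocks4 <- data.frame(block_id = c("b1", "b2", "b3", "b4"),
                        block_group_id = "g1", tract_id = "t1",
                        county_id = "co1", stringsAsFactors = FALSE)
  g <- census_geography(tiny_schema(), blocks4,
                        list(b1 = rect_polygon(0, 0, 10, 10),
                             b2 = rect_polygon(10, 0, 20, 10),
                             b3 = rect_polygon(0, 10, 10, 20),
                             b4 = rect_polygon(10, 10, 20, 20)),
                        m[1:4, ])
  rec <- tiny_record(x = 3, y = 4)
  rec$block_id <- "b1"
  sv <- sensitivity_by_level(rec, g, strategies = c("S1", "S3", "S4"),
                             seed = 2)
  ov <- sv$overall
  for (st in unique(ov$strategy))
    expect_equal(unique(ov$mean_m[ov$strategy == st]),
                 ov$mean_m[ov$strategy == st][1])
})

test_that("tract aggregation keeps the max error and drops sparse tracts", {
  sc <- cached_scenario("uniform", seed = 2)
  g <- sc$geography
  rec <- sc$records[1:300, ]
  imp <- impute_batch(rec, g, "S4", seed = 1)
  err <- evaluate_errors(imp, rec, g)
  res <- tract_accuracy_aggregation(err, g, min_records_per_km2 = 0)
  expect_equal(length(res$dropped), 0)  # threshold 0 keeps everything
  tract_of <- g$blocks$tract_id[match(err$coarse_unit_id,
                                      g$blocks$block_group_id)]
  for (k in seq_len(nrow(res$table))) {
    v <- err$error_m[tract_of == res$table$tract_id[k] &
                       err$status == "imputed"]
    expect_equal(res$table$max_error_m[k], max(v))
    expect_equal(res$table$n[k], length(v))
  }
  # an aggressive threshold drops tracts and lists them
  res2 <- tract_accuracy_aggregation(err, g, min_records_per_km2 = 1e9)
  expect_equal(nrow(res2$table), 0)
  expect_setequal(res2$dropped, res$table$tract_id)
})

test_that("IDW reproduces samples exactly and matches brute force", {
  one <- data.frame(x = 5, y = 5, value = 3.25)
  grid <- list(xmin = 0, xmax = 10, ymin = 0, ymax = 10, nx = 3, ny = 3)
  g1 <- idw_interpolate(one, grid)
  expect_true(all(g1$value == 3.25))  # single sample -> constant surface
  set.seed(31)
  smp <- data.frame(x = runif(5, 0, 10), y = runif(5, 0, 10),
                    value = runif(5, 0, 100))
  smp$x[3] <- 5; smp$y[3] <- 5  # coincide with the central grid cell
  out <- idw_interpolate(smp, grid, power = 2)
  centre <- out[out$x == 5 & out$y == 5, ]
  expect_equal(centre$value, smp$value[3])  # exact-hit rule
  for (k in seq_len(nrow(out))) {
    d <- sqrt((out$x[k] - smp$x)^2 + (out$y[k] - smp$y)^2)
    expected <- if (any(d < 1e-9)) smp$value[which(d < 1e-9)[1]]
                else sum(smp$value * d^-2) / sum(d^-2)
    expect_equal(out$value[k], expected, tolerance = 1e-9)
  }
  expect_true(all(out$value >= min(smp$value) & out$value <= max(smp$value)))
  expect_error(idw_interpolate(smp[0, ], grid), "1")
})

test_that("imputable fraction counts records, not rows", {
  imp <- data.frame(record_id = sprintf("r%d", rep(1:10, 2)),
                    strategy = rep(c("S1", "S4"), each = 10),
                    replicate = 1L, x = 0, y = 0,
                    status = c(rep("imputed", 10),
                               rep(c("imputed", "unimputable"), c(8, 2))),
                    fallback_used = FALSE, stringsAsFactors = FALSE)
  f <- imputable_fraction(imp)
  expect_equal(f$fraction[f$strategy == "S4"], 0.8)
  expect_equal(f$fraction[f$strategy == "S1"], 1)
})
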