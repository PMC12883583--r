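test_that("inclusion filter keeps exactly those with data on each construct", {
  p <- tiny_panel(n = 4, T = 3)
  p$data[1, c("cm_1", "cm_2", "cm_3")] <- NA          # no marker data
  p$data[2, c("dep_1", "dep_2")] <- NA                # one dep value left
  p$data[2, c("cm_1", "cm_3")] <- NA                  # one cm value left
  f <- inclusion_filter(p)
  expect_equal(f$data$id, c(2, 3, 4))
  expect_equal(attr(f, "preprocess_log")$n_dropped, 1L)
  # all-complete panel passes through unchanged
  p2 <- tiny_panel(n = 4, T = 3)
  f2 <- inclusion_filter(p2)
  expect_equal(f2$data, p2$data)
})

test_that("outlier masking uses 5-IQR fences with strict inequality", {
  x <- c(1, 2, 3, 4, 100)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)   # type-7 quartiles
  fence <- q[2] + 5 * (q[2] - q[1])
  expect_gt(100, fence)
  masked <- mask_outliers(x)
  expect_true(is.na(masked[5]))
  expect_equal(masked[1:4], x[1:4], ignore_attr = TRUE)
  # value exactly at the fence is kept (strict "greater than")
  y <- c(1, 2, 3, 4, fence)
  expect_false(anyNA(mask_outliers(y)))
  # constant series: IQR = 0, nothing masked
  expect_false(anyNA(mask_outliers(rep(7, 10))))
  # no-op when nothing is extreme
  z <- c(2.2, 3.1, 4.4, 5.0, 3.3)
  expect_equal(mask_outliers(z), z, ignore_attr = TRUE)
  # NAs are ignored for quartiles and preserved
  w <- c(NA, 1, 2, 3, 4, 1000)
  mw <- mask_outliers(w)
  expect_true(is.na(mw[1]) && is.na(mw[6]))
  expect_error(mask_outliers(c(1, 2, 3)), "at least 4")
  expect_warning(mask_outliers(c(NA_real_, NA_real_)), "all-missing")
})

test_that("transforms honour their domains and propagate missingness", {
  expect_equal(transform_series(4, "sqrt"), 2)
  expect_equal(transform_series(1, "ln"), 0)
  expect_equal(transform_series(c(9, NA), "sqrt"), c(3, NA))
  expect_error(transform_series(-1, "sqrt", context = "dep wave 2"),
               "dep wave 2")
  expect_error(transform_series(0, "ln"), "domain")
})

test_that("min-max normalization maps extremes to 0 and 1 and is invertible", {
  nm <- minmax_normalize(c(2, 4, 6))
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 26))$values, c(0, 1))
  nm2 <- minmax_normalize(c(1, NA, 3))
  expect_equal(nm2$values, c(0, NA, 1))
  expect_error(minmax_normalize(c(2, 2, 2)), "distinct")
  # record inverts the map, including back to the raw scale
  x <- c(0, 1, 4, 9, 16)
  tx <- transform_series(x, "sqrt")
  nm3 <- minmax_normalize(tx, construct = "dep", wave = 1, kind = "sqrt")
  expect_equal(denormalize(nm3$values, nm3$record), tx)
  expect_equal(denormalize(nm3$values, nm3$record, to = "raw"), x)
})

test_that("the pipeline runs clean -> transform -> normalize in order", {
  p <- tiny_panel(n = 8, T = 3)
  # a negative extreme in a log-transformed construct: must be masked
  # before the transform, so no domain error is raised
  p$data$cm_2[3] <- -50
  mp <- preprocess_panel(p)
  expect_true(is.na(mp$data$cm_2[3]))
  m <- panel_matrix(mp)
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  expect_equal(mp$log$n_cells_masked, 1L)
  expect_equal(mp$log$n_dropped, 0L)
  # without the outlier no cell is missing
  p2 <- tiny_panel(n = 8, T = 3)
  mp2 <- preprocess_panel(p2)
  expect_false(anyNA(mp2$data))
})

test_that("normalization preserves ranks within each variable", {
  p <- tiny_panel(n = 12, T = 3)
  mp <- preprocess_panel(p)
  for (col in c("dep_1", "cm_3")) {
    expect_equal(rank(mp$data[[col]]), rank(p$data[[col]]))
  }
})

test_that("preprocessing is idempotent for identity transforms on clean data", {
  p <- tiny_panel(n = 10, T = 3)
  tf <- c(dep = "identity", cm = "identity")
  mp <- preprocess_panel(p, transforms = tf)
  again <- preprocess_panel(raw_panel(mp$data, mp$schedule), transforms = tf)
  expect_equal(again$data, mp$data)
})

test_that("per-construct normalization shares bounds across waves", {
  p <- tiny_panel(n = 10, T = 3)
  mp <- preprocess_panel(p, transforms = c(dep = "identity", cm = "identity"),
                         normalize = "per_construct")
  recs <- mp$records[paste0("dep_", 1:3)]
  expect_length(unique(vapply(recs, `[[`, numeric(1), "min")), 1L)
  expect_length(unique(vapply(recs, `[[`, numeric(1), "max")), 1L)
  m <- as.matrix(mp$data[, paste0("dep_", 1:3)])
  expect_equal(min(m), 0)
  expect_equal(max(m), 1)
})
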