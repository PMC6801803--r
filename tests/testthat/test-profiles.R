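test_that("shape and map dialects parse, roundtrip, and validate", {
  tf <- withr::local_tempfile()
  writeLines(c("1 0.1", "2 -999", "3 1.2"), tf)
  p <- read_shape(tf, sequence = "GAU")
  expect_equal(p$reactivity, c(0.1, NA, 1.2))
  expect_equal(p$base, c("G", "A", "U"))

  tf2 <- withr::local_tempfile()
  writeLines(c("5\t0.82\t0.04\tA", "6\t-999\t0\tC", "7\t1.3\t0.1\tG"), tf2)
  m <- read_map(tf2)
  expect_equal(m$position, 5:7)
  expect_equal(m$reactivity[1], 0.82)
  expect_equal(m$base[1], "A")
  expect_true(is.na(m$reactivity[2]))

  # roundtrips preserve every value in both dialects
  prof <- reactivity_profile("GGAUCCA", c(0.5, NA, 0, 2.25, 0.125, 1, NA))
  f1 <- withr::local_tempfile(); write_shape(prof, f1)
  expect_equal(read_shape(f1, sequence = "GGAUCCA")$reactivity,
               prof$reactivity)
  f2 <- withr::local_tempfile(); write_map(prof, f2)
  back <- read_map(f2)
  expect_equal(back$reactivity, prof$reactivity)
  expect_equal(back$base, prof$base)

  # malformed files are rejected with the first bad row named
  f3 <- withr::local_tempfile()
  writeLines(c("1 0.1", "3 0.2"), f3)
  expect_error(read_shape(f3), "row 2", class = "shapefold_format_error")
  f4 <- withr::local_tempfile()
  writeLines(c("1 0.1", "2 -0.5"), f4)
  expect_error(read_shape(f4), "negative",
               class = "shapefold_format_error")
})

test_that("profile construction enforces the reagent conventions", {
  p <- reactivity_profile("GAUC", c(-999, -0.2, 0.5, 1))
  expect_true(is.na(p$reactivity[1]))   # sentinel -> no data
  expect_equal(p$reactivity[2], 0)      # negative clamped
  d <- reactivity_profile("GAUC", c(1, 1, 1, 1), reagent = "DMS")
  expect_true(all(is.na(d$reactivity[d$base %in% c("G", "U")])))
  expect_false(anyNA(d$reactivity[d$base %in% c("A", "C")]))
  expect_error(reactivity_profile("GA", 1), class = "shapefold_length_error")
})

test_that("2%/8% normalization: definition, invariances, errors", {
  expect_equal(normalize_reactivities(rep(0.5, 100)), rep(1.0, 100))

  set.seed(11)
  x <- rgamma(80, 1)
  x[c(3, 17)] <- NA
  nx <- normalize_reactivities(x)
  expect_true(all(is.na(nx[c(3, 17)])))          # passthrough
  expect_equal(normalize_reactivities(7.3 * x), nx)  # scale invariance
  expect_equal(normalize_reactivities(nx), nx, tolerance = 1e-12)

  expect_error(normalize_reactivities(rep(1, 19)),
               class = "shapefold_data_error")
  expect_error(normalize_reactivities(rep(0, 25)),
               class = "shapefold_data_error")
})

test_that("pearson_r: exact cases, missing data, affine invariance", {
  expect_equal(pearson_r(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(1:3, c(3, 2, 1))$r, -1)
  hand <- pearson_r(1:4, c(1, 3, 2, 4))
  expect_equal(hand$r, 0.8)
  expect_equal(hand$n_used, 4L)

  r0 <- pearson_r(c(1, NA, 2, 5, 3), c(2, 9, 1, NA, 4))
  expect_equal(r0$n_used, 3L)

  set.seed(2)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson_r(3.2 * x + 1, y)$r, pearson_r(x, y)$r)

  expect_error(pearson_r(c(1, 2, NA), c(1, NA, 2)),
               class = "shapefold_data_error")
  expect_error(pearson_r(rep(1, 5), 1:5), class = "shapefold_data_error")
  expect_error(pearson_r(1:3, 1:4), class = "shapefold_length_error")
})
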