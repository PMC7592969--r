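test_that("DVH files are read with normalization and label handling", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# PTV", "dose_gy,volume_pct", "0,100", "50,100", "55,0"), f)
  dvh <- read_dvh(f)
  expect_s3_class(dvh, "cumulative_dvh")
  expect_equal(dvh$dose_gy, c(0, 50, 55))
  expect_equal(dvh$volume_fraction, c(1, 1, 0))
  expect_equal(dvh$label, "PTV")

  # fraction dialect (no volume above 1.5) is taken as-is
  writeLines(c("0,1", "50,0.5", "55,0"), f)
  expect_equal(read_dvh(f)$volume_fraction, c(1, 0.5, 0))
})

test_that("malformed DVH files are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,100", "10,110"), f)  # volume rising above 100%
  expect_error(read_dvh(f), "malformed")
  writeLines(c("-5,100", "10,0"), f)
  expect_error(read_dvh(f), "negative dose|start at 0")
  writeLines(c("0,100", "10,50"), f)   # never reaches zero volume
  expect_error(read_dvh(f), "reach 0")
  expect_error(cumulative_dvh(c(0, 10, 5), c(1, 0.5, 0)),
               "strictly increasing")
})

test_that("write/read round-trip is lossless to 1e-9", {
  withr::local_seed(11)
  f <- withr::local_tempfile(fileext = ".csv")
  for (i in 1:10) {
    dvh <- random_ptv_dvh(sample(c(40, 48, 50, 54, 60), 1))
    write_dvh(dvh, f)
    back <- read_dvh(f)
    expect_equal(back$dose_gy, dvh$dose_gy, tolerance = 1e-9)
    expect_equal(back$volume_fraction, dvh$volume_fraction, tolerance = 1e-9)
    expect_equal(back$label, dvh$label)
  }
})

test_that("cumulative-to-differential conversion drops volume into bins", {
  dd <- cumulative_to_differential(cumulative_dvh(c(0, 50, 55), c(1, 1, 0)))
  nz <- dd$bin_volume_fraction > 0
  expect_equal(dd$bin_dose_gy[nz], 52.5)
  expect_equal(dd$bin_volume_fraction[nz], 1)

  dd2 <- cumulative_to_differential(cumulative_dvh(c(0, 10, 20), c(1, 0.5, 0)))
  expect_equal(dd2$bin_dose_gy, c(5, 15))
  expect_equal(dd2$bin_volume_fraction, c(0.5, 0.5))

  expect_error(cumulative_to_differential(
    structure(list(dose_gy = 0, volume_fraction = 1, label = ""),
              class = "cumulative_dvh")), "degenerate")
})

test_that("differential volumes conserve total volume on random DVHs", {
  withr::local_seed(21)
  for (i in 1:50) {
    dd <- cumulative_to_differential(random_ptv_dvh(50))
    expect_lt(abs(sum(dd$bin_volume_fraction) - 1), 1e-9)
    expect_true(all(dd$bin_volume_fraction >= 0))
  }
})

test_that("dose_at_volume interpolates linearly and handles boundaries", {
  dvh <- cumulative_dvh(c(0, 40, 60), c(1, 1, 0))
  expect_equal(dose_at_volume(dvh, 0.95), 41)
  expect_equal(dose_at_volume(dvh, 1), 40)  # full coverage up to 40 Gy
  expect_equal(dose_at_volume(dvh, 0.5), 50)
  expect_error(dose_at_volume(dvh, 0), "\\(0, 1\\]")
  expect_error(dose_at_volume(dvh, 1.01), "\\(0, 1\\]")
})

test_that("dose_at_volume agrees with a bisection scan oracle", {
  withr::local_seed(31)
  for (i in 1:100) {
    dvh <- random_ptv_dvh(sample(c(40, 48, 50, 54, 60), 1))
    qs <- c(stats::runif(3, 0.01, 0.999), 0.95, 0.99, 1 - 1e-4)
    got <- dose_at_volume(dvh, qs)
    want <- vapply(qs, function(q) oracle_dose_at_volume(dvh, q), numeric(1))
    expect_true(all(abs(got - want) < 1e-6))
  }
})

test_that("dose_at_volume is non-increasing in the coverage fraction", {
  withr::local_seed(41)
  qs <- seq(0.01, 1, length.out = 60)
  for (i in 1:20) {
    d <- dose_at_volume(random_ptv_dvh(50), qs)
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("extract_metrics reproduces hand values and the metric ordering", {
  # all volume between 50 and 55 Gy: mean dose is the bin midpoint
  m <- extract_metrics(cumulative_dvh(c(0, 50, 55), c(1, 1, 0)), 50)
  expect_equal(unname(m["DMEAN"]), 52.5)
  expect_equal(unname(m["RX"]), 50)
  expect_named(m, dose_metric_names())

  withr::local_seed(51)
  for (i in 1:100) {
    mm <- extract_metrics(random_ptv_dvh(50), 50)
    expect_true(all(diff(mm[c("DMIN", "D99", "D98", "D95", "DMEAN", "DMAX")])
                    >= -1e-9))
  }
})

test_that("mean dose equals the area under the cumulative curve", {
  withr::local_seed(61)
  for (i in 1:100) {
    dvh <- random_ptv_dvh(sample(c(40, 54, 60), 1))
    m <- extract_metrics(dvh, 50)
    expect_lt(abs(unname(m["DMEAN"]) - oracle_mean_dose(dvh)), 1e-6)
  }
})
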