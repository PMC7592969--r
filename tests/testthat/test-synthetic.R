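test_that("cohort generation is reproducible and prefix-stable", {
  spec <- cohort_spec(n_tumors = 40, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # growing the cohort leaves earlier tumors untouched
  big <- generate_cohort(cohort_spec(n_tumors = 80, seed = 5))
  expect_identical(big[1:40, ], a)
  # outcome simulation is seeded too
  fu1 <- simulate_outcomes(a, spec)
  fu2 <- simulate_outcomes(a, spec)
  expect_identical(fu1, fu2)
})

test_that("scheme frequencies match the prescribed mix at large n", {
  co <- big_cohort()  # n = 10,000
  freq <- table(paste(co$total_dose_gy, co$n_fractions, sep = "/")) /
    nrow(co)
  mix <- default_scheme_mix()
  want <- stats::setNames(mix$prob,
                          paste(mix$total_dose_gy, mix$n_fractions,
                                sep = "/"))
  for (k in names(want)) {
    expect_lt(abs(freq[[k]] - want[[k]]), 0.015)
  }
})

test_that("target volumes have the prescribed median and bounds", {
  co <- big_cohort()
  expect_gt(stats::median(co$target_volume_cc), 18)
  expect_lt(stats::median(co$target_volume_cc), 27)
  expect_true(all(co$target_volume_cc >= 5.8))
  expect_true(all(co$target_volume_cc <= 163.4))
  expect_equal(co$diameter_cm, diameter_from_volume(co$target_volume_cc))
})

test_that("generated cohorts satisfy every structural invariant (fuzz)", {
  co <- big_cohort()
  # every DVH valid: the constructor enforces invariants, so re-validate
  for (i in sample(nrow(co), 500)) {
    dvh <- co$ptv_dvh[[i]]
    expect_s3_class(dvh, "cumulative_dvh")
    expect_identical(dvh$volume_fraction[1], 1)
    expect_true(all(diff(dvh$volume_fraction) <= 0))
    expect_identical(dvh$volume_fraction[length(dvh$volume_fraction)], 0)
    expect_gte(max(dvh$dose_gy), 0.8 * co$total_dose_gy[i])
  }
  expect_true(all(co$followup_months > 0))
  expect_true(all(co$total_dose_gy / co$n_fractions <= 40))
})

test_that("generated DVHs hit their requested shape targets", {
  withr::local_seed(141)
  n_draw <- 1000
  rx <- sample(c(40, 48, 50, 54, 60), n_draw, replace = TRUE)
  d95r <- stats::runif(n_draw, 0.98, 1.02)
  d99r <- pmin(stats::runif(n_draw, 0.95, 1.00), d95r)
  dmaxr <- pmax(stats::runif(n_draw, 1.10, 1.25), d95r)
  steep <- stats::runif(n_draw, 1, 3)
  for (i in seq_len(n_draw)) {
    dvh <- generate_ptv_dvh(rx[i],
                            dvh_shape_params(d99r[i], d95r[i], dmaxr[i],
                                             steep[i]))
    m <- extract_metrics(dvh, rx[i])
    expect_lt(abs(m[["D95"]] - rx[i] * d95r[i]) / (rx[i] * d95r[i]), 0.01)
    expect_lt(abs(m[["D99"]] - rx[i] * d99r[i]) / (rx[i] * d99r[i]), 0.01)
    expect_lt(abs(m[["DMAX"]] - rx[i] * dmaxr[i]) / (rx[i] * dmaxr[i]), 0.01)
    expect_true(all(diff(m[c("DMIN", "D99", "D98", "D95", "DMEAN", "DMAX")])
                    >= -1e-9))
  }
})

test_that("a degenerate shape collapses to a step DVH at the prescription", {
  dvh <- generate_ptv_dvh(50, dvh_shape_params(1, 1, 1, 1e-4))
  m <- extract_metrics(dvh, 50)
  expect_true(all(abs(m - 50) / 50 < 0.005))
  expect_error(dvh_shape_params(1.05, 1.0, 1.2, 2), "d99 <= d95")
  expect_error(dvh_shape_params(0.97, 1, 1.2, 0), "steepness")
})

test_that("forcing TCP to one produces a cohort with zero recurrences", {
  spec <- cohort_spec(n_tumors = 300, seed = 23,
                      tcp_params = tcp_params(tcd50_gy = -1e5))
  co <- generate_cohort(spec)
  fu <- simulate_outcomes(co, spec)
  expect_false(any(fu$event))
  expect_true(all(fu$tcp > 1 - 1e-12))
})

test_that("simulated 2-year control agrees with the cohort mean TCP", {
  co <- big_cohort()
  curve <- km_fit(data.frame(time = co$followup_months,
                             event = co$recurrence_event))
  km24 <- actuarial_rate(curve, 24)
  mean_tcp <- mean(parameterize_cohort(co, "D99")$tcp)
  expect_lt(abs(km24 - mean_tcp), 0.015)
})

test_that("organ-at-risk DVHs are valid and land on the toxicity scale", {
  spec <- cohort_spec(n_tumors = 1000, seed = 29)
  co <- generate_cohort(spec)
  lung <- generate_oar_dvhs(co, "lung", seed = 29)
  expect_length(lung, 1000)
  sums <- vapply(lung, function(d) sum(d$bin_volume_fraction), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  # most volume at low dose
  low <- vapply(lung, function(d) {
    sum(d$bin_volume_fraction[d$bin_dose_gy < 5])
  }, numeric(1))
  expect_gt(mean(low), 0.5)
  schemes <- lapply(seq_len(nrow(co)), function(i) scheme_of(co, i))
  res <- predict_toxicity(lung, schemes)
  expect_gt(res$predicted_incidence, 0.01)
  expect_lt(res$predicted_incidence, 0.06)

  rib <- generate_oar_dvhs(co, "rib", seed = 29)
  expect_equal(length(rib), round(21 / 109 * 1000))
  rib_ids <- names(rib)
  expect_true(all(co$location[match(rib_ids, co$tumor_id)] == "peripheral"))
  # rib DVHs reach into the PTV dose range
  hi <- vapply(rib, function(d) {
    max(d$bin_dose_gy[d$bin_volume_fraction > 0])
  }, numeric(1))
  rx <- co$total_dose_gy[match(rib_ids, co$tumor_id)]
  expect_true(all(hi >= 0.8 * rx))
  expect_error(generate_oar_dvhs(co, "heart"), "should be one of")
})

test_that("zero dose means zero complication probability", {
  dd <- differential_dvh(c(0.25, 0.75), c(1, 0))
  p <- predict_toxicity(list(dd), fractionation_scheme(50, 5))
  expect_lt(p$predicted_incidence, 1e-6)
})
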