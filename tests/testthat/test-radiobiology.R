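test_that("BED follows the linear-quadratic form", {
  expect_equal(bed(50, fractionation_scheme(50, 5), 10), 100)   # d = a/b
  expect_equal(bed(54, fractionation_scheme(54, 3), 10), 151.2) # 54*(1+1.8)
  expect_equal(bed(0, fractionation_scheme(50, 5), 10), 0)
  expect_error(bed(50, fractionation_scheme(50, 5), 0), "alpha/beta")
  expect_error(bed(-1, fractionation_scheme(50, 5), 10), "non-negative")
})

test_that("BED is superlinear in dose at fixed fraction number", {
  sc <- fractionation_scheme(50, 5)
  for (D in c(10, 30, 50, 70)) {
    expect_gt(bed(2 * D, sc, 10), 2 * bed(D, sc, 10))
  }
})

test_that("size adjustment subtracts c per cm of diameter", {
  expect_equal(sbed(100, 2), 80)
  expect_equal(sbed(100, 3, tcp_params(c_gy_per_cm = 0)), 100)
  L <- seq(1, 7, by = 0.5)
  expect_true(all(diff(sbed(120, L)) < 0))
  expect_error(sbed(100, 0), "positive")
})

test_that("TCP is the logistic in sBED with the published constants", {
  expect_identical(tcp(0), 0.5)                     # sBED = TCD50 midpoint
  z <- 51 / 31
  expect_lt(abs(tcp(51) - exp(z) / (1 + exp(z))), 1e-12)
  s <- seq(-100, 250, by = 5)
  p <- tcp(s)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  # overflow-safe far into both tails
  expect_equal(tcp(c(-3.1e5, 3.1e5)), c(0, 1))
  expect_error(tcp_params(k_gy = 0), "positive")
})

test_that("EQD converts bin doses to 2-Gy-fraction equivalents", {
  for (n_fx in 3:5) {
    sc <- fractionation_scheme(50, n_fx)
    expect_equal(eqd(2 * n_fx, sc, 3), 2 * n_fx)  # 2 Gy/fx identity
    expect_equal(eqd(2 * n_fx, sc, 10), 2 * n_fx)
  }
  expect_equal(eqd(60, fractionation_scheme(60, 5), 3), 180)
  expect_equal(eqd(0, fractionation_scheme(50, 5), 3), 0)
  expect_error(eqd(10, fractionation_scheme(50, 5), -3), "alpha/beta")
})

test_that("EUD at a = 1 equals the volume-weighted mean EQD (loop oracle)", {
  withr::local_seed(71)
  sc <- fractionation_scheme(50, 5)
  pars <- ntcp_params()
  for (i in 1:100) {
    dd <- random_ddvh(sample(5:40, 1))
    acc <- 0
    for (j in seq_along(dd$bin_dose_gy)) {
      d_j <- dd$bin_dose_gy[j]
      acc <- acc + dd$bin_volume_fraction[j] *
        d_j * (3 + d_j / 5) / (3 + 2)
    }
    expect_lt(abs(eud(dd, sc, pars) - acc), 1e-9)
  }
})

test_that("EUD reduces a uniform distribution to its EQD for any exponent", {
  sc <- fractionation_scheme(54, 3)
  dd <- differential_dvh(42, 1)
  for (a in c(0.5, 1, 2, 8)) {
    expect_equal(eud(dd, sc, ntcp_params(a = a)), eqd(42, sc, 3),
                 tolerance = 1e-12)
  }
  expect_error(ntcp_params(a = 0), "a = 0")
})

test_that("EUD is non-decreasing in the volume-effect exponent", {
  withr::local_seed(81)
  sc <- fractionation_scheme(50, 5)
  for (i in 1:20) {
    dd <- random_ddvh(20)
    e <- vapply(c(0.5, 1, 2, 4, 8),
                function(a) eud(dd, sc, ntcp_params(a = a)), numeric(1))
    expect_true(all(diff(e) >= -1e-9))
  }
})

test_that("NTCP is the Lyman-type logistic in EUD", {
  expect_identical(ntcp(45), 0.5)                      # EUD = TD50
  expect_lt(abs(ntcp(90) - 1 / (1 + 0.5^4.8)), 1e-12)
  expect_identical(ntcp(0), 0)                         # no dose
  e <- seq(1, 150, by = 1)
  expect_true(all(diff(ntcp(e)) > 0))
  expect_error(ntcp_params(td50_gy = -1), "TD50")
})

test_that("sphere-equivalent diameter inverts the volume of a sphere", {
  expect_equal(diameter_from_volume(4 * pi / 3), 2)
  expect_equal(diameter_from_volume(22.4), 2 * (3 * 22.4 / (4 * pi))^(1 / 3))
  v <- seq(1, 170, by = 3)
  expect_true(all(diff(diameter_from_volume(v)) > 0))
  expect_error(diameter_from_volume(0), "positive")
})

test_that("TCP ordering across the seven metrics follows the dose ordering", {
  withr::local_seed(91)
  for (i in 1:20) {
    dvh <- random_ptv_dvh(50)
    m <- extract_metrics(dvh, 50)
    sc <- fractionation_scheme(50, 5)
    p <- tcp(sbed(bed(m[c("DMIN", "D99", "D98", "D95", "DMEAN", "DMAX")],
                      sc, 10), 3))
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("the size penalty makes TCP decrease with tumor diameter", {
  L <- seq(1.5, 7, by = 0.25)
  p <- tcp(sbed(110, L))
  expect_true(all(diff(p) < 0))
})

test_that("fractionation schemes validate their inputs", {
  expect_error(fractionation_scheme(0, 5), "positive")
  expect_error(fractionation_scheme(50, 0), "positive integer")
  expect_error(fractionation_scheme(200, 4), "40 Gy")
  sc <- fractionation_scheme(54, 3)
  expect_equal(sc$total_dose_gy / sc$n_fractions, 18)
})
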