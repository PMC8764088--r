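test_that("mixing model returns the background delta when source equals it", {
  p <- isotope_pair("c", 330, 430, d15n_start = 6.7, d15n_end = 6.7)
  expect_equal(two_source_mixing(p)$d15n_flux, 6.7, tolerance = 1e-12)
})

test_that("mixing model inverts a forward-mixed source signature", {
  fwd <- forward_mix(330, 6.7, 100, -20)
  expect_equal(fwd$d_end, 0.4907, tolerance = 1e-4)
  p <- isotope_pair("c", 330, fwd$c_end, d15n_start = 6.7,
                    d15n_end = fwd$d_end)
  expect_equal(two_source_mixing(p)$d15n_flux, -20, tolerance = 1e-12)
})

test_that("mixing inversion recovers random source deltas to 1e-9 relative", {
  set.seed(42)
  for (i in 1:200) {
    c0 <- runif(1, 300, 400)
    d0 <- runif(1, -10, 50)
    ds <- runif(1, -60, 40)
    a <- runif(1, 31, 500)
    fwd <- forward_mix(c0, d0, a, ds)
    p <- isotope_pair("c", c0, fwd$c_end, d15n_start = d0,
                      d15n_end = fwd$d_end)
    got <- two_source_mixing(p)$d15n_flux
    expect_lt(abs(got - ds) / max(abs(ds), 1e-6), 1e-9)
  }
})

test_that("the 31 ppb minimum-increase rule is inclusive on the keep side", {
  at <- function(a) {
    fwd <- forward_mix(330, 6.7, a, -20)
    two_source_mixing(isotope_pair("c", 330, fwd$c_end,
                                   d15n_start = 6.7, d15n_end = fwd$d_end))
  }
  expect_false(at(30)$valid)
  expect_true(is.na(at(30)$d15n_flux))
  expect_match(at(30)$reason, "31")
  expect_true(at(31)$valid)
  expect_true(at(100)$valid)

  flat <- two_source_mixing(isotope_pair("c", 330, 330,
                                         d15n_start = 6.7, d15n_end = 6.7))
  expect_false(flat$valid)
  expect_match(flat$reason, "no concentration change")
})

test_that("invalid pairs are retained in table output, never dropped", {
  pairs <- generate_isotope_pairs(added_amounts = c(10, 30, 31, 100))
  sig <- two_source_mixing_table(pairs)
  expect_equal(nrow(sig), 4)
  expect_equal(sum(sig$valid), 2)
  expect_true(all(is.na(sig$d15n_flux[!sig$valid])))
})

test_that("site preference is the alpha-beta difference and antisymmetric", {
  expect_equal(site_preference(10, 2), 8)
  expect_equal(site_preference(0, 0), 0)
  set.seed(1)
  a <- rnorm(50, 10, 5); b <- rnorm(50, 2, 5)
  expect_equal(site_preference(a, b), -site_preference(b, a))
  # panel mean equals mean of per-sample SPs
  expect_equal(mean(site_preference(a, b)), mean(a - b))
})

test_that("flux site preference comes from per-position mixing", {
  fa <- forward_mix(330, 15, 100, 2)
  fb <- forward_mix(330, 8, 100, -5)
  p <- isotope_pair("c", 330, 430,
                    d15n_alpha_start = 15, d15n_alpha_end = fa$d_end,
                    d15n_beta_start = 8, d15n_beta_end = fb$d_end)
  expect_equal(two_source_mixing(p)$sp_flux, 2 - (-5), tolerance = 1e-9)
})

test_that("dissolved-phase delta correction matches the fractionation algebra", {
  expect_equal(dissolved_delta_correction(0, "15N"),
               (1 / 0.99925 - 1) * 1000, tolerance = 1e-12)
  expect_equal(dissolved_delta_correction(0, "18O"),
               (1 / 0.99894 - 1) * 1000, tolerance = 1e-12)
  expect_equal(round(dissolved_delta_correction(0, "15N"), 4), 0.7506)
  expect_equal(round(dissolved_delta_correction(0, "18O"), 4), 1.0611)
  # applying alpha_eq forward recovers the headspace value
  d <- dissolved_delta_correction(6.0, "15N")
  expect_equal(((d / 1000 + 1) * 0.99925 - 1) * 1000, 6.0,
               tolerance = 1e-12)
  xs <- seq(-50, 50, by = 10)
  expect_true(all(diff(dissolved_delta_correction(xs, "18O")) > 0))
  expect_error(dissolved_delta_correction(-1000, "15N"), "-1000")
})

test_that("reduction-vector projection decomposes orthogonally", {
  v <- reduction_vector(slope = 2.4, anchor = c(0, 0))
  at_anchor <- reduction_projection(c(0, 0), v)
  expect_equal(at_anchor$progress, 0)
  expect_equal(at_anchor$residual, 0)

  on_line <- reduction_projection(c(1, 2.4), v)
  expect_equal(on_line$progress, sqrt(1 + 2.4^2), tolerance = 1e-12)
  expect_equal(on_line$residual, 0, tolerance = 1e-12)

  above <- reduction_projection(c(0, 1), v)
  expect_gt(above$residual, 0)

  shift <- c(6.7, 44.6)
  v2 <- reduction_vector(2.4, anchor = shift)
  p2 <- reduction_projection(c(1, 2.4) + shift, v2)
  expect_equal(p2$progress, on_line$progress, tolerance = 1e-12)
  expect_equal(p2$residual, on_line$residual, tolerance = 1e-12)
})

test_that("end-member classification handles the box taxonomy", {
  boxes <- endmember_boxes(list(nit = c(-65, -45, 15, 40),
                                den = c(-45, -5, 5, 35),
                                wide = c(-50, 0, 0, 50)))
  expect_equal(classify_endmember(c(-55, 25), boxes), "nit")
  expect_equal(classify_endmember(c(100, 100), boxes), "outside")
  expect_equal(classify_endmember(c(-20, 20), boxes), "ambiguous")
  expect_error(endmember_boxes(list()), "non-empty")
  expect_error(endmember_boxes(list(bad = c(1, -1, 0, 2))), "min < max")
})
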