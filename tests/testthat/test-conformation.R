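test_that("quadratic interpolation recovers Gaussian band centres", {
  # off-grid centre: interpolation must beat the 1 nm grid
  s <- gen_band_spectrum(band_spec(336.4, 18, 800), axis = seq(285, 500, 1))
  est <- peak_position(s)
  expect_equal(est$method, "quadratic_interp")
  expect_lt(abs(est$position - 336.4), 0.01)
  # on-grid centre to sub-millistep accuracy
  est2 <- peak_position(gen_band_spectrum(band_spec(336, 20, 1),
                                          axis = seq(285, 500, 1)))
  expect_lt(abs(est2$position - 336), 1e-3)
})

test_that("edge maxima and flat spectra are flagged", {
  mono <- spectrum_series(1:10, 1:10)
  expect_warning(est <- peak_position(mono), class = "edge_peak")
  expect_true("edge_peak" %in% est$flags)
  expect_equal(est$position, 10)

  flat <- spectrum_series(1:10, rep(2, 10))
  expect_warning(estf <- peak_position(flat), class = "edge_peak")
  expect_true("tie" %in% estf$flags)
  expect_equal(estf$position, 1)   # tie broken to smallest axis value
})

test_that("windows restrict the search and amide I defaults apply", {
  two <- gen_band_spectrum(list(band_spec(1550, 12, 5),
                                band_spec(1638.45, 10, 4)),
                           axis = seq(1450, 1750, 1),
                           axis_kind = "wavenumber_cm-1")
  # global maximum is the 1550 band; the amide I window must find 1638.45
  expect_lt(abs(peak_position(two)$position - 1550), 0.01)
  inwin <- peak_position(two, window = c(1600, 1700))
  expect_lt(abs(inwin$position - 1638.45), 0.01)
})

test_that("peak shifts follow the sign convention per channel", {
  a <- gen_band_spectrum(band_spec(336, 20, 1000), axis = seq(285, 500, 1))
  expect_equal(peak_shift(a, a, "trp_delta60")$delta, 0)

  # complex band moved +7 nm: red shift, positive delta
  b <- gen_band_spectrum(band_spec(343, 20, 1000), axis = seq(285, 500, 1))
  sh <- peak_shift(a, b, "trp_delta60")
  expect_equal(sh$delta, 7, tolerance = 1e-6)

  # amide I band moving to lower wavenumber: negative delta
  free <- gen_band_spectrum(band_spec(1638.45, 10, 4),
                            axis = seq(1450, 1750, 1),
                            axis_kind = "wavenumber_cm-1")
  cplx <- gen_band_spectrum(band_spec(1633.59, 10, 4),
                            axis = seq(1450, 1750, 1),
                            axis_kind = "wavenumber_cm-1")
  ir <- peak_shift(free, cplx, "amide_I")
  expect_equal(ir$delta, -4.86, tolerance = 1e-3)

  # mismatched axis kinds are refused
  expect_error(peak_shift(a, free, "uv"), class = "unit_error")
})

test_that("UV additivity difference detects complex formation", {
  r <- uv_additivity(0.2578, 0.3947, 0.60)
  expect_equal(r$difference, 0.0525)
  expect_true(r$interaction_flag)
  r0 <- uv_additivity(0.3, 0.2, 0.5)
  expect_equal(r0$difference, 0)
  expect_false(r0$interaction_flag)
  rneg <- uv_additivity(0.2, 0.2, 0.6)
  expect_lt(rneg$difference, 0)
  expect_false(rneg$interaction_flag)
})

test_that("CD bookkeeping reproduces published fraction changes", {
  free <- cd_fractions(ref_cd$free[1], ref_cd$free[2], ref_cd$free[3],
                       "free")
  lut <- cd_fractions(ref_cd$luteoloside[1], ref_cd$luteoloside[2],
                      ref_cd$luteoloside[3], "luteoloside")
  ch <- cd_change(free, lut)
  expect_equal(ch$alpha_helix_decrease, 1.99)
  expect_equal(ch$random_coil_increase, 2.91)

  hyp <- cd_fractions(ref_cd$hyperoside[1], ref_cd$hyperoside[2],
                      ref_cd$hyperoside[3], "hyperoside")
  expect_equal(cd_change(free, hyp)$alpha_helix_decrease, 1.20)

  # identical fractions: all deltas zero
  same <- cd_change(free, free)
  expect_equal(unname(same$deltas), c(0, 0, 0))
})

test_that("fraction sums outside 99-101 are flagged, not rejected", {
  # a published row closing at 99.60 sits inside the +/-1 point band
  lutn <- cd_fractions(ref_cd$luteolin[1], ref_cd$luteolin[2],
                       ref_cd$luteolin[3], "luteolin")
  expect_equal(lutn$total, 99.60)
  expect_length(lutn$flags, 0)

  off <- cd_fractions(6.0, 46.0, 46.0, "bad row")     # sums to 98
  expect_true("sum_deviation" %in% off$flags)
  free <- cd_fractions(7.50, 51.50, 41.00)
  expect_length(free$flags, 0)
  expect_true("sum_deviation" %in% cd_change(free, off)$flags)
  expect_error(cd_fractions(-1, 50, 51), class = "malformed_input")
})

test_that("per-fraction deltas conserve the row-sum identity", {
  set.seed(11)
  for (i in 1:10) {
    a <- cd_fractions(runif(1, 5, 10), runif(1, 40, 55), runif(1, 35, 45))
    b <- cd_fractions(runif(1, 5, 10), runif(1, 40, 55), runif(1, 35, 45))
    ch <- cd_change(a, b)
    expect_equal(sum(ch$deltas), a$total - b$total, tolerance = 1e-12)
  }
})

test_that("random-coil ranking orders ligands and breaks ties stably", {
  inc <- vapply(c("quercetin", "hyperoside", "luteolin", "luteoloside"),
                function(sys) ref_cd[[sys]][3] - ref_cd$free[3], 1)
  expect_equal(rank_by_random_coil(inc),
               c("luteolin", "hyperoside", "quercetin", "luteoloside"),
               ignore_attr = TRUE)
  expect_false(attr(rank_by_random_coil(inc), "tie"))

  tied <- c(b = 2, a = 2, c = 1)
  r <- rank_by_random_coil(tied)
  expect_equal(r, c("a", "b", "c"), ignore_attr = TRUE)
  expect_true(attr(r, "tie"))

  expect_equal(rank_by_random_coil(c(x = 1, y = 3)), c("y", "x"),
               ignore_attr = TRUE)
})
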