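oc <- optics_constants()

test_that("SRK/T chain reproduces hand-evaluated intermediates", {
  s <- srkt_elp(43.3, 23.03, oc)
  # step-by-step oracle: r = 337.5/43.3, LCOR = AL (short branch),
  # Cw = -5.41 + 0.58412*LCOR + 0.098*K, H = r - sqrt(r^2 - Cw^2/4),
  # ACDconst = 0.62467*119.1 - 68.747, offset = ACDconst - 3.336
  r <- 337.5 / 43.3
  cw <- -5.41 + 0.58412 * 23.03 + 0.098 * 43.3
  h <- r - sqrt(r^2 - cw^2 / 4)
  expect_equal(s$r_mm, r)
  expect_equal(s$cw_mm, cw)
  expect_equal(s$h_mm, h)
  expect_equal(s$acd_const_mm, 0.62467 * 119.1 - 68.747)
  expect_equal(s$elp_mm, h + (0.62467 * 119.1 - 68.747) - 3.336)
  expect_equal(s$elp_mm, 5.31, tolerance = 0.002)

  # long-eye branch of the corrected axial length
  s_long <- srkt_elp(43.3, 25.0, oc)
  expect_equal(s_long$lcor_mm, -3.446 + 1.716 * 25 - 0.0237 * 25^2)
  expect_equal(s_long$lcor_mm, 24.64, tolerance = 0.01)
  # short branch passes AL through
  expect_equal(srkt_elp(43.3, 24.0, oc)$lcor_mm, 24.0)
})

test_that("steep-cornea corneal height clamps instead of producing NaN", {
  # K = 59, AL = 40 gives cw^2/4 > r^2
  s <- srkt_elp(59, 40, oc)
  expect_true(is.finite(s$h_mm))
  expect_equal(s$h_mm, s$r_mm)
})

test_that("SRK/T domain errors identify out-of-range inputs", {
  expect_error(srkt_elp(25, 23, oc), "k_d")
  expect_error(srkt_elp(43, 45, oc), "al_mm")
  expect_error(srkt_elp(NaN, 23, oc), "k_d")
})

test_that("emmetropic SRK/T power matches the closed-form oracle and is monotone", {
  # P = 1000*na*(na*r - (nc-1)*LOPT) / ((LOPT-ELP)*(na*r - (nc-1)*ELP))
  s <- srkt_elp(43.3, 23.03, oc)
  lopt <- 23.03 + 0.65696 - 0.02029 * 23.03
  p_oracle <- 1000 * 1.336 * (1.336 * s$r_mm - 0.333 * lopt) /
    ((lopt - s$elp_mm) * (1.336 * s$r_mm - 0.333 * s$elp_mm))
  expect_equal(srkt_power_emmetropia(43.3, 23.03, oc), p_oracle)
  expect_equal(p_oracle, 23.1, tolerance = 0.05)

  # larger A-constant -> deeper predicted ELP -> more power
  oc_hi <- optics_constants(a_constant = 119.6)
  expect_gt(srkt_power_emmetropia(43.3, 23.03, oc_hi),
            srkt_power_emmetropia(43.3, 23.03, oc))
  # longer eye -> less power (finite differences across the range)
  als <- seq(21, 26, 0.5)
  p <- srkt_power_emmetropia(43.3, als, oc)
  expect_true(all(diff(p) < 0))
})

test_that("clinical lens choice rounds to step, ties toward lower power, and clamps", {
  step_oc <- oc
  pick <- function(p) {
    r <- ceiling(p / 0.5 - 0.5) * 0.5
    min(max(r, 6), 35)
  }
  # verify via biometry whose unrounded powers bracket the conventions
  p <- srkt_power_emmetropia(43.3, 23.03, oc)   # 23.14 -> 23.0
  expect_equal(clinical_iol_choice(43.3, 23.03, oc), 23.0)
  expect_equal(pick(23.25), 23.0)  # tie rounds down
  expect_equal(pick(23.26), 23.5)
  expect_equal(pick(36.2), 35.0)   # clamp at range top
  # very long flat eye lands below 6 D and clamps up
  expect_gte(clinical_iol_choice(39.5, 40 - 1e-9, optics_constants(a_constant = 113)), 6)
})

test_that("reversed vergence formula matches the hand-evaluated chain", {
  elp <- srkt_elp(43.3, 23.03, oc)$elp_mm
  # oracle: nested vergence chain evaluated step by step
  v3 <- 1336 / (23.03 - elp)
  v1 <- 1 / (elp / 1336 + 1 / (v3 - 21))
  rx_oracle <- 1 / (12 / 1000 - 1 / (43.3 - v1))
  expect_equal(rx_theor_post(43.3, 23.03, elp, 21, oc), rx_oracle)
  expect_equal(rx_oracle, 1.40, tolerance = 0.005)

  # near-zero residual at the SRK/T emmetropic power (not exactly zero:
  # the power formula uses the optical axial length, the vergence chain AL)
  p_emm <- srkt_power_emmetropia(43.3, 23.03, oc)
  expect_lt(abs(rx_theor_post(43.3, 23.03, elp, p_emm, oc)), 0.15)
})

test_that("refraction is strictly decreasing in implanted power", {
  elp <- srkt_elp(43.3, 23.03, oc)$elp_mm
  iols <- seq(6, 35, 0.25)
  rx <- rx_theor_post(43.3, 23.03, elp, iols, oc)
  expect_true(all(diff(rx) < 0))
})

test_that("zero vertex distance reduces to the corneal-plane residual", {
  oc0 <- optics_constants(vertex_distance_mm = 0)
  elp <- 5.31
  for (iol in c(18, 21, 25)) {
    v3 <- 1336 / (23.03 - elp)
    v1 <- 1 / (elp / 1336 + 1 / (v3 - iol))
    expect_equal(rx_theor_post(43.3, 23.03, elp, iol, oc0), v1 - 43.3)
  }
})

test_that("vergence domain errors are raised", {
  expect_error(rx_theor_post(43.3, 23.03, 24, 21, oc), "axial length")
  elp <- 5.31
  v3 <- 1336 / (23.03 - elp)
  expect_error(rx_theor_post(43.3, 23.03, elp, v3, oc), "singular")
  expect_error(rx_theor_post(43.3, NA, elp, 21, oc), "non-finite")
})

test_that("refraction change per 0.5 D and per 1.0 D of IOL power", {
  elp <- srkt_elp(43.3, 23.03, oc)$elp_mm
  d05 <- rx_05iol(43.3, 23.03, elp, 23.1, oc)
  expect_equal(d05, 0.346, tolerance = 0.005)
  d10 <- rx_theor_post(43.3, 23.03, elp, 23.1, oc) -
    rx_theor_post(43.3, 23.03, elp, 24.1, oc)
  expect_equal(d10, 0.69, tolerance = 0.01)

  # positive for any eye in the population ranges
  eyes <- random_eyes(200, seed = 11)
  elps <- srkt_elp(eyes$k_d, eyes$al_mm, oc)$elp_mm
  expect_true(all(rx_05iol(eyes$k_d, eyes$al_mm, elps, eyes$iol_d, oc) > 0))
})

test_that("local linearity: curvature of Rx in IOL is small near emmetropia", {
  eyes <- random_eyes(100, seed = 3)
  elps <- srkt_elp(eyes$k_d, eyes$al_mm, oc)$elp_mm
  p <- srkt_power_emmetropia(eyes$k_d, eyes$al_mm, oc)
  for (dp in c(-2, 0, 1)) {
    r0 <- rx_theor_post(eyes$k_d, eyes$al_mm, elps, p + dp, oc)
    r1 <- rx_theor_post(eyes$k_d, eyes$al_mm, elps, p + dp + 0.5, oc)
    r2 <- rx_theor_post(eyes$k_d, eyes$al_mm, elps, p + dp + 1, oc)
    expect_lt(max(abs(r2 - 2 * r1 + r0)), 0.02)
  }
})

test_that("ideal-power arithmetic and the back-calculation identity", {
  expect_equal(iol_ideal(23.0, 0.50, 0.346), 23.0 + (0.5 / 0.346) * 0.5)
  expect_equal(iol_ideal(23.0, 0, 0.4), 23.0)
  expect_equal(iol_ideal(23.0, -0.346, 0.346), 22.5)
  expect_error(iol_ideal(23, 0.5, 0), "positive")

  expect_equal(rx_predicted(23.0, 23.0, 0.346, 0.7), 0.7)
  expect_equal(rx_predicted(23.0, 24.0, 0.346, 0.5), -2 * 0.346 + 0.5)
  expect_error(rx_predicted(23, 23, -0.1, 0), "positive")
})

test_that("round trip: predicting the ideal power cancels the residual", {
  eyes <- random_eyes(1000, seed = 5)
  elps <- srkt_elp(eyes$k_d, eyes$al_mm, oc)$elp_mm
  r05 <- rx_05iol(eyes$k_d, eyes$al_mm, elps, eyes$iol_d, oc)
  ideal <- iol_ideal(eyes$iol_d, eyes$rx_post_d, r05)
  resid <- rx_predicted(eyes$iol_d, ideal, r05, eyes$rx_post_d)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("closed-form required power zeroes the vergence residual", {
  eyes <- random_eyes(200, seed = 9)
  elps <- srkt_elp(eyes$k_d, eyes$al_mm, oc)$elp_mm
  req <- iol_required_for_emmetropia(eyes$k_d, eyes$al_mm, elps, oc)
  expect_lt(max(abs(rx_theor_post(eyes$k_d, eyes$al_mm, elps, req, oc))), 1e-9)
})
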