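test_that("surrogate dose puts the prescription isodose on the PTV surface", {
  case <- small_case()
  plan <- synth_dose(case$ptv, 0.65, 6000, width = 8)
  expect_equal(plan$d_max, 6000 / 0.65)
  expect_true(all(plan$dose >= 0 & plan$dose <= plan$d_max))
  # the 6000 cGy level of the SI profile crosses at the PTV surface,
  # located independently from the PTV mask extent
  ctr <- case$phantom$geometry$tumor_center_mid
  pr <- extract_profile(plan$dose, ctr, "superior", 40, step_mm = 0.1)
  cross <- pr$position[which(pr$dose < 6000)[1]]
  z_surface <- max(which(apply(unclass(case$ptv), 3, any))) - 1 + 0.5 -
    ctr[3]
  expect_lt(abs(cross - z_surface), 0.6)
  # far outside: Gaussian tail
  far <- unclass(plan$dose)[1, 1, 1]
  expect_lt(far, 0.002 * plan$d_max)
  expect_error(synth_dose(case$ptv, 1.2), "iso_level")
  empty <- new_mask(array(FALSE, c(4, 4, 4)))
  expect_error(synth_dose(empty, 0.65), "non-empty")
})

test_that("dose is monotone nonincreasing in signed distance to the PTV", {
  case <- small_case()
  plan <- synth_dose(case$ptv, 0.85, 6000, width = 6)
  sd <- unclass(signed_distance(case$ptv))
  set.seed(5)
  i <- sample(length(sd), 4000)
  ord <- order(sd[i])
  d_sorted <- unclass(plan$dose)[i][ord]
  expect_true(all(diff(d_sorted) <= 1e-9))
})

test_that("coverage meets the 95% planning constraint and behaves on uniform doses", {
  for (diam in c(20, 30)) {
    case <- small_case(diam, 10)
    for (iso in c(0.65, 0.85)) {
      plan <- synth_dose(case$ptv, iso, 6000, width = 10)
      expect_gte(check_coverage(plan, case$ptv), 0.95)
    }
  }
  case <- small_case()
  u <- uniform_volume(6000, dim(case$ptv))
  expect_equal(check_coverage(u, case$ptv, prescription = 6000), 1)
  expect_equal(check_coverage(uniform_volume(0, dim(case$ptv)), case$ptv,
                              prescription = 6000), 0)
})

test_that("at equal width the 65% plan is hotter and falls off faster at the surface", {
  case <- small_case()
  w <- 8
  p65 <- synth_dose(case$ptv, 0.65, 6000, w)
  p85 <- synth_dose(case$ptv, 0.85, 6000, w)
  expect_gt(p65$d_max, p85$d_max)
  ctr <- case$phantom$geometry$tumor_center_mid
  pr65 <- extract_profile(p65$dose, ctr, "superior", 40, step_mm = 0.1)
  pr85 <- extract_profile(p85$dose, ctr, "superior", 40, step_mm = 0.1)
  z_surf <- max(which(apply(unclass(case$ptv), 3, any))) - 1 + 0.5 - ctr[3]
  g65 <- mean_gradient(pr65, z_surf - 0.5, 1)
  g85 <- mean_gradient(pr85, z_surf - 0.5, 1)
  # analytic ratio of surface fall-offs: (dmax/w) phi(qnorm(iso))
  want_ratio <- ((6000 / 0.65) * dnorm(qnorm(0.65))) /
    ((6000 / 0.85) * dnorm(qnorm(0.85)))
  expect_equal(g65 / g85, want_ratio, tolerance = 0.05)
  expect_lt(g65, g85) # both negative, 65% steeper
})

test_that("width calibration matches the target gradient and round-trips", {
  case <- small_case(30, 20)
  w65 <- calibrate_width(case$ptv, case$itv, 0.65, -249)
  w85 <- calibrate_width(case$ptv, case$itv, 0.85, -137)
  expect_lt(w85, w65) # shallower target at 85% needs a narrower penumbra
  # measured profile gradient over [ITV boundary, +4.5 mm] ~ target
  ctr <- case$phantom$geometry$tumor_center_mid
  x0 <- case$phantom$geometry$diameter_mm / 2 +
    case$phantom$geometry$amplitude_mm / 2
  p65 <- synth_dose(case$ptv, 0.65, 6000, w65)
  p85 <- synth_dose(case$ptv, 0.85, 6000, w85)
  pr65 <- extract_profile(p65$dose, ctr, "superior", 40, step_mm = 0.1)
  pr85 <- extract_profile(p85$dose, ctr, "superior", 40, step_mm = 0.1)
  g65 <- mean_gradient(pr65, x0, 4.5)
  g85 <- mean_gradient(pr85, x0, 4.5)
  expect_equal(g65, -249, tolerance = 0.02)
  expect_equal(g85, -137, tolerance = 0.02)
  # 65% penumbra steeper pointwise over the boundary interval
  xs <- seq(x0, x0 + 4.5, by = 0.5)
  s65 <- diff(approx(pr65$position, pr65$dose, xs)$y)
  s85 <- diff(approx(pr85$position, pr85$dose, xs)$y)
  expect_true(all(s65 < s85))
  # round-trip: calibrating to an achieved gradient recovers the width
  w_rt <- calibrate_width(case$ptv, case$itv, 0.65, g65)
  expect_equal(w_rt, w65, tolerance = 0.05)
  # steeper targets give narrower widths (monotone on the wide branch)
  expect_lt(calibrate_width(case$ptv, case$itv, 0.65, -300), w65)
  expect_error(calibrate_width(case$ptv, case$itv, 0.65, 100), "negative")
  expect_error(calibrate_width(case$ptv, case$itv, 0.85, -5000),
               "not attainable")
})
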