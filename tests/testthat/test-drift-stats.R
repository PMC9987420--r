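test_that("Maxwell radial CDF: closed form agrees with quadrature to 1e-10", {
  integrand <- function(t, delta) {
    t^2 * sqrt(2 / pi) / delta^3 * exp(-t^2 / (2 * delta^2))
  }
  for (delta in c(1, 1.5)) {
    rs <- seq(0.05, 5 * delta, length.out = 100)
    quad <- vapply(rs, function(r)
      integrate(integrand, 0, r, delta = delta, rel.tol = 1e-13)$value,
      numeric(1))
    expect_lt(max(abs(maxwell_cdf(rs, delta) - quad)), 1e-10)
  }
  expect_equal(maxwell_cdf(0), 0)
  expect_equal(maxwell_cdf(1e4), 1)
  expect_error(maxwell_cdf(-1), "r")
  expect_error(maxwell_cdf(1, delta = 0), "delta")
})

test_that("cumulative drift probabilities at 1 and 2 sigma match the reported values", {
  expect_equal(100 * maxwell_cdf(1), 19.9, tolerance = 0.1 / 19.9)
  expect_equal(100 * maxwell_cdf(2), 73.9, tolerance = 0.1 / 73.9)
})

test_that("bin probabilities reproduce the radial partition table and are scale-free", {
  p <- bin_probabilities()
  expect_length(p, 12)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # the reported 12-bin table, percent, one decimal
  reported_pct <- c(0.4, 2.7, 6.4, 10.4, 13.3, 14.6, 14.0, 12.1, 9.4, 6.7,
              4.4, 5.6)
  expect_lt(max(abs(100 * p - reported_pct)), 0.05)
  expect_equal(which.max(p), 6L)
  expect_equal(which.min(p), 1L)
  # independent of the sigma values (computed in sigma units)
  p2 <- bin_probabilities(drift_model(delta = c(3, 2, 0.7)))
  expect_equal(p2, p)
})

test_that("node grid pairs bin midpoints with per-axis sigmas", {
  nd <- node_grid()
  expect_equal(nrow(nd), 6 * 12)
  si <- nd[nd$direction == "superior", ]
  expect_equal(si$r_mm, (2 * (1:12) - 1) * 0.125 * 1.5)
  ml <- nd[nd$direction == "left", ]
  expect_equal(ml$r_mm, (2 * (1:12) - 1) * 0.125 * 1.2)
  expect_true(all(tapply(nd$r_mm, nd$direction, function(r)
    all(diff(r) > 0))))
})

test_that("node interpolation anchors at zero and extrapolates the last segment", {
  ep <- expand.grid(structure = "ITV", endpoint = 99,
                    direction = shift_directions(),
                    magnitude_mm = c(0.5, 1.5, 2.5, 3.5, 4.5))
  ep$delta_pct <- -2 * ep$magnitude_mm # linear degradation
  nd <- interp_delta(ep, drift_model())
  # a node at half the first magnitude interpolates against (0, 0)
  expect_equal(nd$delta_pct, -2 * nd$r_mm)
  # node exactly at a sampled magnitude returns the sample
  ep2 <- ep[ep$direction == "superior", ]
  ep2$delta_pct <- c(-1, -3, -3.5, -6, -7)[match(ep2$magnitude_mm,
                                                 c(0.5, 1.5, 2.5, 3.5, 4.5))]
  ep2 <- do.call(rbind, lapply(shift_directions(), function(d)
    transform(ep2, direction = d)))
  model_wide <- drift_model(delta = c(4, 4, 4)) # nodes 0.5..11.5 mm
  nd2 <- interp_delta(ep2, model_wide)
  expect_equal(nd2$delta_pct[nd2$i == 1], rep(-1, 6)) # node at 0.5 mm
  # nodes beyond 4.5 mm follow the final segment slope (-1 %/mm)
  far <- nd2[nd2$i == 12 & nd2$direction == "superior", ]
  expect_equal(far$delta_pct, -7 - 1 * (far$r_mm - 4.5))
  # monotone samples stay monotone after interpolation
  one <- nd2[nd2$direction == "left", ]
  expect_true(all(diff(one$delta_pct[order(one$i)]) <= 0))
  expect_error(interp_delta(ep[0, ], drift_model()), "empty")
})

test_that("direction averaging needs all six directions and averages them", {
  nd <- expand.grid(structure = "ITV", endpoint = 99,
                    direction = shift_directions(), i = 1:12)
  nd$r_mm <- nd$i
  nd$delta_pct <- ifelse(nd$direction %in%
                           c("anterior", "posterior", "right"), -1, -2)
  avg <- direction_average(nd)
  expect_equal(avg$delta_pct, rep(-1.5, 12))
  # invariant under permutation of direction labels
  nd_perm <- nd[sample(nrow(nd)), ]
  expect_equal(direction_average(nd_perm)$delta_pct, rep(-1.5, 12))
  expect_error(direction_average(nd[nd$direction != "left", ]),
               "6 directions")
})

test_that("probability weighting is a proper expectation over the bins", {
  p <- bin_probabilities()
  expect_equal(weighted_mean_delta(p, rep(-3.3, 12)), -3.3)
  expect_equal(weighted_mean_delta(p, rep(0, 12)), 0)
  vals <- -(1:12)
  got <- weighted_mean_delta(p, vals)
  # oracle: expectation of the bin index under quadrature probabilities
  integrand <- function(t) t^2 * sqrt(2 / pi) * exp(-t^2 / 2)
  q <- vapply((0:11) * 0.25, function(r)
    integrate(integrand, 0, r, rel.tol = 1e-12)$value, numeric(1))
  p_ind <- c(diff(q), 1 - q[12])
  expect_equal(got, sum(p_ind * vals), tolerance = 1e-8)
  expect_equal(got, -6.8282, tolerance = 1e-4)
  expect_true(got >= min(vals) && got <= max(vals))
  expect_error(weighted_mean_delta(p, 1:5), "length")
})

test_that("drift summary chains interpolation, averaging and weighting", {
  ep <- expand.grid(structure = c("ITV", "GTV"), endpoint = c(99, 95),
                    direction = shift_directions(),
                    magnitude_mm = c(0.5, 1.5, 2.5, 3.5, 4.5))
  ep$delta_pct <- -2 * ep$magnitude_mm
  ws <- drift_weighted_summary(ep, drift_model())
  expect_equal(nrow(ws), 4)
  # linear-in-magnitude degradation: weighted mean = -2 E[r], with E[r]
  # mixing SI/AP sigma 1.5 (4 directions) and ML sigma 1.2 (2 directions)
  p <- bin_probabilities()
  r_units <- (2 * (1:12) - 1) * 0.125
  e_r <- sum(p * r_units) * (4 * 1.5 + 2 * 1.2) / 6
  expect_equal(ws$weighted_mean_pct, rep(-2 * e_r, 4))
})
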