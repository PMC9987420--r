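test_that("cosine trajectory hits peak, valley, zero crossing and rejects bad input", {
  off <- tumor_trajectory(20, 11)
  expect_length(off, 11)
  expect_equal(off[1], 10)
  expect_equal(off[11], -10)
  expect_equal(off[6], 0)            # cos(pi/2) at the mid phase
  expect_true(all(diff(off) < 0))    # strictly monotone over the half-cycle
  expect_equal(tumor_trajectory(0, 11), rep(0, 11))
  expect_error(tumor_trajectory(-1, 11), "amplitude")
  expect_error(tumor_trajectory(10, 1), "n_phases")
})

test_that("rasterized phase assigns 0/-720/0 HU and matches the analytic sphere volume", {
  g <- small_geom()
  ph <- rasterize_phase(g, offset_mm = 3)
  ctr <- g$tumor_center_mid + c(0, 0, 3)
  idx <- round(ctr / g$spacing_mm) + 1L
  expect_equal(ph$ct[idx[1], idx[2], idx[3]], 0)       # tumor centre
  expect_equal(ph$ct[idx[1], idx[2], 5], -720)         # lung, far inferior
  expect_equal(ph$ct[1, 1, 1], 0)                      # chest wall
  # voxel count of the 20 mm sphere vs (4/3) pi r^3 within 2%
  expect_equal(sum(ph$gtv), 4 / 3 * pi * 10^3, tolerance = 0.02)
  expect_error(phantom_geometry(60, 30, dim = c(70L, 70L, 90L)),
               "chest wall|grid")
})

test_that("AVG is the phase mean, MIP the phase max, and both collapse for a static tumor", {
  case <- small_case()
  ph <- case$phantom
  avg <- compose_avg(ph)
  mip <- compose_mip(ph)
  expect_true(all(mip >= avg))
  # hand-mean at sampled voxels: a voxel inside the tumor in k of 11
  # phases averages (k*0 + (11-k)*(-720)) / 11
  idx <- which(unclass(case$itv) & !unclass(ph$gtvs[[1]]), arr.ind = TRUE)
  set.seed(42)
  for (r in sample(nrow(idx), 25)) {
    v <- idx[r, ]
    k <- sum(vapply(ph$gtvs, function(m) m[v[1], v[2], v[3]], logical(1)))
    expect_equal(avg[v[1], v[2], v[3]], (11 - k) * (-720) / 11)
  }
  # zero amplitude: AVG and MIP equal the static anatomy
  st <- build_phantom(small_geom(20, 0))
  expect_equal(unclass(compose_avg(st)), unclass(st$phases[[1]]),
               ignore_attr = TRUE)
  expect_equal(unclass(compose_mip(st)), unclass(st$phases[[1]]),
               ignore_attr = TRUE)
})

test_that("thresholding the MIP recovers exactly the union of phase GTVs", {
  for (diam in c(20, 30)) {
    case <- small_case(diam, 10)
    ph <- case$phantom
    rec <- threshold_gtv(compose_mip(ph), ph$lung)
    expect_identical(unclass(rec) == TRUE, unclass(union_itv(ph$gtvs)) == TRUE)
  }
  # single static phase: threshold recovers the rasterized GTV
  st <- build_phantom(small_geom(20, 0))
  rec <- threshold_gtv(st$phases[[1]], st$lung)
  expect_identical(unclass(rec) == TRUE, unclass(st$gtvs[[1]]) == TRUE)
  expect_error(threshold_gtv(st$phases[[1]], st$lung, hu_cut = -800),
               "hu_cut")
  # a cut just above lung HU keeps pure lung out
  lungish <- new_volume(array(-720, c(6, 6, 6)))
  alltrue <- new_mask(array(TRUE, c(6, 6, 6)))
  expect_equal(sum(threshold_gtv(lungish, alltrue, -719)), 0)
})

test_that("ITV is a capsule: union geometry, extent and analytic volume", {
  case <- small_case(20, 10)
  itv <- case$itv
  # SI extent = diameter + amplitude = 30 mm -> 31 voxel planes at 1 mm
  zs <- range(which(apply(unclass(itv), 3, any)))
  expect_equal(diff(zs) * 1, 30, tolerance = 0.04)
  # analytic capsule: sphere r 10 plus cylinder r 10, h 10 (mm^3)
  expect_equal(sum(itv), 4 / 3 * pi * 1000 + pi * 100 * 10,
               tolerance = 0.03)
  # contains every phase GTV; static case collapses to the GTV
  for (gtv in case$phantom$gtvs) expect_true(all(itv[unclass(gtv)]))
  st <- build_phantom(small_geom(20, 0))
  expect_identical(unclass(union_itv(st$gtvs)) == TRUE,
                   unclass(st$gtvs[[1]]) == TRUE)
})

test_that("ITV volume is nondecreasing in amplitude and GTV-ITV-PTV nest", {
  vols <- sapply(c(0, 6, 12), function(a)
    sum(union_itv(build_phantom(small_geom(20, a))$gtvs)))
  expect_true(all(diff(vols) > 0))
  case <- small_case()
  expect_true(all(case$ptv[unclass(case$itv)]))
  for (gtv in case$phantom$gtvs) expect_true(all(case$itv[unclass(gtv)]))
})

test_that("margin expansion dilates by a Euclidean ball", {
  # ball r 15 + 5 mm margin ~ ball r 20
  d <- c(50L, 50L, 50L)
  ctr <- (d - 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) - ctr[a])
  dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  ball15 <- new_mask(dist2 <= 15^2)
  grown <- expand_margin(ball15, 5)
  # discrete dilation loses a thin crescent of the analytic ball
  expect_equal(sum(grown), sum(dist2 <= 20^2), tolerance = 0.03)
  expect_true(all(grown[unclass(ball15)]))
  # margin 0 is the identity
  expect_identical(unclass(expand_margin(ball15, 0)), unclass(ball15))
  expect_error(expand_margin(ball15, -1), "margin")
  # brute-force Minkowski oracle on a tiny random mask
  set.seed(11)
  m <- array(stats::runif(9 * 9 * 9) < 0.06, c(9L, 9L, 9L))
  m[5, 5, 5] <- TRUE
  msk <- new_mask(m)
  got <- expand_margin(msk, 2.2)
  idx <- which(m, arr.ind = TRUE)
  all_idx <- which(array(TRUE, dim(m)), arr.ind = TRUE)
  want <- apply(all_idx, 1, function(v)
    min(colSums((t(idx) - v)^2)) <= 2.2^2)
  expect_identical(as.vector(unclass(got)), as.vector(want))
})

test_that("exact distance transform agrees with brute force and carries the half-sample surface shift", {
  set.seed(3)
  m <- array(stats::runif(8 * 9 * 10) < 0.08, c(8L, 9L, 10L))
  m[4, 4, 4] <- TRUE
  sp <- 1.5
  msk <- new_mask(m, spacing = sp)
  sd <- signed_distance(msk)
  idx_in <- which(m, arr.ind = TRUE)
  idx_out <- which(!m, arr.ind = TRUE)
  bf <- function(v, idx) sqrt(min(colSums((t(idx) - v)^2))) * sp
  all_idx <- which(array(TRUE, dim(m)), arr.ind = TRUE)
  for (r in sample(nrow(all_idx), 40)) {
    v <- all_idx[r, ]
    inside <- m[v[1], v[2], v[3]]
    want <- if (inside) -(bf(v, idx_out) - sp / 2) else bf(v, idx_in) - sp / 2
    expect_equal(sd[v[1], v[2], v[3]], want)
  }
  expect_true(all(sd[m] < 0) && all(sd[!m] > 0))
})
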