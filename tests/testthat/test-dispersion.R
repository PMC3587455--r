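test_that("sigma curves match the published neutral-class values", {
  met <- met_neutral()
  expect_equal(stability_class(met$shf, met$u10), "D")
  s <- dispersion_sigmas(100, met)
  # Briggs open-country class D at 100 m, evaluated by hand:
  # sigma_y = 0.08*100/sqrt(1 + 1e-4*100), sigma_z = 0.06*100/sqrt(1 + 0.15)
  expect_equal(s$sigma_y, 7.96030, tolerance = 1e-5)
  expect_equal(s$sigma_z, 5.59503, tolerance = 1e-5)
})

test_that("sigmas grow with distance and order by stability", {
  met <- met_neutral()
  d <- c(10, 20, 50, 100, 200, 225)
  s <- dispersion_sigmas(d, met)
  expect_true(all(diff(s$sigma_y) > 0))
  expect_true(all(diff(s$sigma_z) > 0))
  conv <- met_hour(u10 = 1.5, shf = 300)   # strongly convective -> class A
  stab <- met_hour(u10 = 1.5, shf = -60)   # stable night -> class F
  expect_equal(stability_class(conv$shf, conv$u10), "A")
  expect_equal(stability_class(stab$shf, stab$u10), "F")
  expect_gt(dispersion_sigmas(100, conv)$sigma_z,
            dispersion_sigmas(100, stab)$sigma_z)
  expect_error(dispersion_sigmas(0, met), "positive")
})

test_that("vertical spread is capped at the boundary-layer height", {
  met <- met_hour(u10 = 1.5, shf = 300, pblh = 30)
  expect_equal(dispersion_sigmas(200, met)$sigma_z, 30)  # 0.2*200 = 40 uncapped
})

test_that("point source concentration matches the closed form", {
  met <- met_neutral()   # u = 5, wind from the west
  s <- dispersion_sigmas(100, met)
  # centreline, 100 m downwind (east of source)
  expect_equal(point_source_chi(100, 0, met, Q = 1),
               1 / (pi * 5 * s$sigma_y * s$sigma_z) * 1e6, tolerance = 1e-12)
  # crosswind offset applies the lateral Gaussian factor
  expect_equal(point_source_chi(100, 8, met, Q = 1),
               point_source_chi(100, 0, met, Q = 1) *
                 exp(-8^2 / (2 * s$sigma_y^2)), tolerance = 1e-12)
  # upwind of the source plane: zero
  expect_equal(point_source_chi(-10, 0, met, Q = 1), 0)
  # linearity and the zero-emission limit
  expect_equal(point_source_chi(100, 5, met, Q = 0), 0)
  expect_equal(point_source_chi(100, 5, met, Q = 3),
               3 * point_source_chi(100, 5, met, Q = 1))
})

test_that("crosswind-integrated flux recovers the emitted mass rate", {
  # unit road source: 1 g/km/s over 10 m emits 0.01 g/s
  for (met in list(met_neutral(), met_hour(u10 = 2, wdir = 200, shf = 150),
                   met_hour(u10 = 1, wdir = 45, shf = -60))) {
    for (d in c(50, 150, 220)) {
      flux <- transect_mass_flux(d, met)
      expect_equal(flux, 0.01, tolerance = 0.01)
    }
  }
})

test_that("kernels are symmetric, truncated and linear", {
  met <- met_hour(u10 = 4, wdir = 270, shf = 10)  # wind along +x
  k <- build_kernel("open", met)
  expect_s3_class(k, "kernel_grid")
  expect_equal(dim(k$chi), c(91, 91))
  expect_true(all(k$chi >= 0))
  # symmetry about the wind axis (y -> -y)
  expect_equal(k$chi, k$chi[, 91:1], tolerance = 1e-12)
  # exact zero beyond the 225 m radial cutoff
  g <- expand.grid(dx = k$offsets, dy = k$offsets)
  outside <- matrix(g$dx^2 + g$dy^2 > 225^2, 91)
  expect_true(all(k$chi[outside] == 0))
  # linearity of the plume in emission rate
  chi1 <- source_chi(60, 10, "open", met, rate = 1)
  chi2 <- source_chi(60, 10, "open", met, rate = 2)
  expect_equal(chi2, 2 * chi1)
  # centreline decay beyond the near-field maximum
  cl <- source_chi(seq(20, 220, by = 5), 0, "open", met)
  expect_true(all(diff(cl[-(1:2)]) <= 1e-12))
})

test_that("kernel evaluation is rotationally consistent", {
  # rotating the wind and the receptor offsets together leaves chi unchanged
  met1 <- met_hour(u10 = 4, wdir = 270, shf = 10)
  met2 <- met_hour(u10 = 4, wdir = 200, shf = 10)
  th <- 70 * pi / 180    # map-frame rotation matching the wdir change
  pts <- cbind(c(50, 100, 30, -40), c(0, 20, -60, 80))
  rot <- cbind(cos(th) * pts[, 1] - sin(th) * pts[, 2],
               sin(th) * pts[, 1] + cos(th) * pts[, 2])
  expect_equal(point_source_chi(pts[, 1], pts[, 2], met1),
               point_source_chi(rot[, 1], rot[, 2], met2), tolerance = 1e-9)
})

test_that("canyon adjustment enhances only the canyon footprint", {
  # wind perpendicular to a north-south canyon axis
  met_perp <- met_hour(u10 = 3, wdir = 270, shf = 10)
  base <- build_kernel("canyon_NS", met_perp, canyon_c = 0)  # no enhancement
  k <- build_kernel("canyon_NS", met_perp)
  f <- recirculation_factor(25, 30, 2)
  expect_equal(f, 1 + 2 * 25 / 30)
  g <- expand.grid(dx = k$offsets, dy = k$offsets)
  inside <- matrix(abs(g$dx) <= 15, 91)   # within width/2 of the NS axis
  expect_equal(k$chi[inside], base$chi[inside] * f, tolerance = 1e-12)
  expect_equal(k$chi[!inside], base$chi[!inside], tolerance = 1e-12)

  # along-axis wind: kernel unchanged
  met_along <- met_hour(u10 = 3, wdir = 10, shf = 10)  # 10 deg off the NS axis
  k2 <- build_kernel("canyon_NS", met_along, canyon_c = 0)
  k3 <- build_kernel("canyon_NS", met_along)
  expect_equal(k3$chi, k2$chi)

  expect_error(canyon_adjust(base, "open", met_perp), "canyon")
})

test_that("recirculation enhancement grows with aspect ratio", {
  # street-canyon geometry (25 m buildings / 30 m street) traps more than
  # the typical-road geometry (10 m / 20 m)
  expect_gt(recirculation_factor(25, 30), recirculation_factor(10, 20))
  expect_gte(recirculation_factor(25, 30), 1)
})

test_that("kernel bilinear sampling is exact at nodes and linear between", {
  met <- met_hour(u10 = 4, wdir = 250, shf = 80)
  k <- build_kernel("typical", met)
  # node exactness
  i <- c(30, 46, 60); j <- c(50, 46, 20)
  expect_equal(kernel_chi(k, k$offsets[i], k$offsets[j]),
               k$chi[cbind(i, j)], tolerance = 1e-12)
  # midpoint between two x-adjacent nodes is their average
  expect_equal(kernel_chi(k, (k$offsets[40] + k$offsets[41]) / 2, k$offsets[50]),
               (k$chi[40, 50] + k$chi[41, 50]) / 2, tolerance = 1e-12)
  # outside the kernel extent: zero
  expect_equal(kernel_chi(k, 500, 0), 0)
})

test_that("met validation catches malformed tables", {
  expect_error(validate_met(data.frame(u10 = 1)), "missing")
  bad <- met_neutral(); bad$pblh <- -1
  expect_error(validate_met(bad), "pblh")
})
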