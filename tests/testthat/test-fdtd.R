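# Heavier solver validations.  The vacuum reference solve is shared with the
# acceptance tests through the fixture cache.

sphere_phantom <- function(radius = 30, spacing = 5, tissue = "muscle") {
  tab <- tissue_table()
  half <- ceiling(radius / spacing) * spacing
  cs <- seq(-half, half, by = spacing)
  n <- length(cs)
  X <- array(rep(cs, n * n), c(n, n, n))
  Y <- array(rep(rep(cs, each = n), n), c(n, n, n))
  Z <- array(rep(cs, each = n * n), c(n, n, n))
  lab <- array(0L, c(n, n, n))
  lab[X^2 + Y^2 + Z^2 <= radius^2] <- tab$label[tab$tissue == tissue]
  structure(list(labels = lab, spacing = spacing,
                 origin = c(cs[1], cs[1], cs[1]), label_map = tab,
                 tumor_center = c(0, 0, 0), tumor_radius = 0,
                 composition_class = "HD", core_mask = NULL),
            class = "voxel_phantom")
}

test_that("vacuum solve reproduces the analytic dipole field shape", {
  fld <- vacuum_field()
  co <- field_coords(fld)
  i0 <- which(co[[1]] == 0); k0 <- which(co[[3]] == 0)
  rr <- seq(40, 88, by = 8)
  dip <- dipole_spec()
  En <- vapply(rr, function(r) fld$E[i0, which(co[[2]] == r), k0, 1],
               complex(1))
  Ea <- analytic_dipole_field(dip, list(eps_r = 1, sigma = 0),
                              cbind(0, rr, 0))[, 1]
  err <- Mod(En / En[1] - Ea / Ea[1]) / Mod(Ea / Ea[1])
  expect_lt(max(err), 0.10)
  expect_true(all(is.finite(fld$E)))
})

test_that("radiated transverse field vanishes on the dipole axis", {
  fld <- vacuum_field()
  co <- field_coords(fld)
  j0 <- which(co[[2]] == 0); k0 <- which(co[[3]] == 0)
  ia <- which(co[[1]] == 80)
  eq_mag <- sqrt(sum(Mod(fld$E[which(co[[1]] == 0),
                               which(co[[2]] == 80), k0, ])^2))
  expect_lt(Mod(fld$E[ia, j0, k0, 2]) / eq_mag, 0.01)
  expect_lt(Mod(fld$E[ia, j0, k0, 3]) / eq_mag, 0.01)
})

test_that("solver is linear in the source amplitude", {
  dom <- list(xlim = c(-70, 70), ylim = c(-50, 50), zlim = c(-50, 50))
  cfg <- solver_config(spacing = 5, margin = 10)
  f1 <- fdtd_unit_field(dipole_spec(amplitude = 1), config = cfg,
                        domain = dom, normalize = FALSE)
  f2 <- fdtd_unit_field(dipole_spec(amplitude = 2), config = cfg,
                        domain = dom, normalize = FALSE)
  expect_equal(f2$E, 2 * f1$E, tolerance = 1e-10)
  # accepted power is quadratic in amplitude
  d1 <- attr(f1, "diagnostics"); d2 <- attr(f2, "diagnostics")
  expect_equal(d2$accepted_power, 4 * d1$accepted_power, tolerance = 1e-9)
  expect_equal(d2$Z_in, d1$Z_in, tolerance = 1e-9)
  expect_gt(d1$accepted_power, 0)
})

test_that("opposite antennas give mirror-image fields around a sphere", {
  ph <- sphere_phantom(radius = 30, spacing = 4)
  geom <- array_geometry(8, 60)
  dips <- place_array(geom, ph)
  cfg <- solver_config(margin = 10)
  f1 <- fdtd_unit_field(dips[[1]], ph, cfg)
  f5 <- fdtd_unit_field(dips[[5]], ph, cfg)
  d <- dim(f1$E)
  mir <- f5$E[, rev(seq_len(d[2])), rev(seq_len(d[3])), , drop = FALSE]
  mir[, , , 2] <- -mir[, , , 2]
  mir[, , , 3] <- -mir[, , , 3]
  # residual asymmetry is bounded by the phasor convergence tolerance
  scale <- max(Mod(f1$E))
  expect_lt(max(Mod(f1$E - mir)) / scale, 1e-3)
})

test_that("fields in a lossy tissue medium track the analytic oracle", {
  # an electrically short dipole (0.7 in-medium wavelengths tip to tip), for
  # which the oracle's sinusoidal-current assumption is accurate, radiating
  # into glandular tissue
  med <- list(eps_r = 59.47, sigma = 1.079)
  dip <- dipole_spec(arm_length = 12, gap = 3)
  dom <- list(xlim = c(-50, 50), ylim = c(-85, 85), zlim = c(-50, 50))
  cfg <- solver_config(spacing = 3, margin = 9, background = med)
  fld <- fdtd_unit_field(dip, config = cfg, domain = dom)
  co <- field_coords(fld)
  i0 <- which(co[[1]] == 0); k0 <- which(co[[3]] == 0)
  rr <- seq(39, 81, by = 6)    # 1 to 2 in-medium wavelengths
  En <- vapply(rr, function(r) fld$E[i0, which(co[[2]] == r), k0, 1],
               complex(1))
  Ea <- analytic_dipole_field(dip, med, cbind(0, rr, 0))[, 1]
  # amplitude envelope (attenuation + spreading)
  amp_err <- abs(Mod(En / En[1]) - Mod(Ea / Ea[1])) / Mod(Ea / Ea[1])
  expect_lt(max(amp_err), 0.10)
  # numerical dispersion: radial phase accumulation in the propagating zone
  # tracks the oracle within 3% of the in-medium wavenumber (about 13 cells
  # per wavelength here; the error scales as the inverse square of that)
  k_re <- Re(2 * pi * 1e9 * sqrt(1.25663706212e-6 * 8.8541878128e-12 *
                                   (med$eps_r - 1i * med$sigma /
                                      (2 * pi * 1e9 * 8.8541878128e-12))))
  slope <- function(E) {
    ph <- Arg(E)
    ph <- ph - cumsum(c(0, round(diff(ph) / (2 * pi)))) * 2 * pi
    unname(coef(lm(ph ~ I(rr / 1000)))[2])
  }
  expect_lt(abs(slope(En) - slope(Ea)) / k_re, 0.03)
  # attenuation: decay much faster than the lossless 1/r envelope
  expect_lt(Mod(En[length(En)] / En[1]),
            0.5 * rr[1] / rr[length(rr)])
})

test_that("convergence and configuration errors are reported", {
  dom <- list(xlim = c(-60, 60), ylim = c(-40, 40), zlim = c(-40, 40))
  cfg <- solver_config(spacing = 5, margin = 10, tol = 1e-12,
                       max_windows = 3)
  expect_error(fdtd_unit_field(dipole_spec(), config = cfg, domain = dom),
               "convergence error")
  cfg2 <- solver_config(spacing = 5, margin = 10, tol = 1e-12,
                        max_windows = 3, on_nonconvergence = "warn")
  expect_warning(fdtd_unit_field(dipole_spec(), config = cfg2, domain = dom),
                 "convergence error")
  w <- capture_warnings(
    fdtd_unit_field(dipole_spec(frequency = 8e9), config =
                      solver_config(spacing = 5, margin = 10,
                                    max_windows = 6,
                                    on_nonconvergence = "warn"),
                    domain = dom))
  expect_true(any(grepl("coarse grid", w)))
})

test_that("reflection helper handles matched and open ports", {
  expect_equal(reflection_db(50 + 0i), -150)
  expect_equal(reflection_db(1e12), 0, tolerance = 1e-6)
  expect_lt(reflection_db(63.8 + 0i), -15)
})
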