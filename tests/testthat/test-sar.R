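test_that("pointwise SAR follows sigma |E|^2 / (2 rho)", {
  expect_equal(pointwise_sar(c(100 + 0i, 0, 0), 0.978, 1090),
               0.978 * 1e4 / (2 * 1090))
  expect_equal(pointwise_sar(c(0i, 0i, 0i), 1, 1000), 0)
  expect_equal(pointwise_sar(c(3 + 4i, 1i, 2), 0, 1000), 0)
  # array input, mixed components
  E <- array(complex(real = 1:24, imaginary = 24:1), c(2, 2, 2, 3))
  s <- pointwise_sar(E, 0.5, 1000)
  expect_equal(dim(s), c(2, 2, 2))
  l <- 3
  expect_equal(s[l], 0.5 / 2000 * sum(Mod(E[l + c(0, 8, 16)])^2))
  expect_error(pointwise_sar(c(1, 0, 0), 1, 0), "positive")
})

test_that("excitation vectors validate and gauge correctly", {
  e <- excitation(rep(1, 8))
  expect_equal(sum(e$powers), 8)
  expect_error(excitation(c(-1, 1)), "non-negative")
  expect_error(excitation(c(1, 1), c(0, 200)), "180")
  A <- c(2i, 1 + 1i)
  e2 <- sarfocus:::.as_excitation(A, reference = 2, total_power = 8)
  expect_equal(e2$phases[2], 0)
  expect_equal(sum(e2$powers), 8)
  expect_equal(e2$phases[1], 45)   # 90 - 45 relative to reference
})

test_that("field combination reproduces identity and cancellation", {
  uf <- synthetic_unit_fields(2)
  one <- combine_fields(uf, excitation(c(1, 0), c(0, 0)))
  expect_equal(one$E, uf[[1]]$E)
  # two copies of the same field, equal power, opposite phase: cancellation
  uf2 <- list(uf[[1]], uf[[1]])
  z <- combine_fields(uf2, excitation(c(2, 2), c(0, 180)))
  expect_lt(max(Mod(z$E)), 1e-12)
  # grid mismatch rejected
  bad <- uf
  bad[[2]]$origin <- bad[[2]]$origin + 1
  expect_error(combine_fields(bad, excitation(c(1, 1))), "grid mismatch")
})

test_that("quadratic form reproduces brute-force superposition SAR", {
  uf <- synthetic_unit_fields(8, dims = c(10, 10, 10), seed = 11)
  set.seed(12)
  nvox <- 1000
  sigma <- runif(nvox, 0.05, 1.6)
  rho <- runif(nvox, 900, 1110)
  idx <- sample(nvox, 120)
  form <- sar_quadratic_form(uf, idx, sigma, rho)
  expect_equal(form$n_voxels, 120)
  # Hermitian by construction, PSD, real non-negative diagonal
  expect_identical(form$H, Conj(t(form$H)))
  expect_true(all(Im(diag(form$H)) == 0))
  expect_true(all(Re(diag(form$H)) >= 0))
  expect_true(all(eigen(form$H, symmetric = TRUE, only.values = TRUE)$values
                  > -1e-12 * max(Mod(form$H))))
  for (rep in 1:5) {
    exc <- random_excitation()
    got <- sar_vol(form, exc)
    want <- brute_mean_sar(uf, exc, sigma, rho, idx)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("single-voxel region matches pointwise SAR of the combined field", {
  uf <- synthetic_unit_fields(8, dims = c(5, 5, 5), seed = 21)
  sigma <- array(0.9, c(5, 5, 5)); rho <- array(1050, c(5, 5, 5))
  form <- sar_quadratic_form(uf, 33, sigma, rho)
  set.seed(22)
  for (rep in 1:20) {
    exc <- random_excitation()
    cf <- combine_fields(uf, exc)
    E <- cf$E[arrayInd(33, c(5, 5, 5))[1], arrayInd(33, c(5, 5, 5))[2],
              arrayInd(33, c(5, 5, 5))[3], ]
    expect_equal(sar_vol(form, exc), pointwise_sar(E, 0.9, 1050),
                 tolerance = 1e-10)
  }
})

test_that("single-antenna form collapses to its mean unit-field SAR", {
  uf <- synthetic_unit_fields(1, dims = c(6, 6, 6), seed = 31)
  sigma <- array(1.1, c(6, 6, 6)); rho <- array(1000, c(6, 6, 6))
  idx <- 1:216
  form <- sar_quadratic_form(uf, idx, sigma, rho)
  want <- mean(pointwise_sar(uf[[1]]$E, sigma, rho))
  expect_equal(Re(form$H[1, 1]), want, tolerance = 1e-12)
})

test_that("SARvol is gauge-invariant, quadratic in power, and additive", {
  uf <- synthetic_unit_fields(8, seed = 41)
  sigma <- array(1, c(10, 10, 10)); rho <- array(1000, c(10, 10, 10))
  form <- sar_quadratic_form(uf, 1:500, sigma, rho)
  set.seed(42)
  exc <- random_excitation()
  v0 <- sar_vol(form, exc)
  # common phase shift leaves SARvol unchanged
  shifted <- excitation(exc$powers,
                        (exc$phases + 60 + 180) %% 360 - 180)
  expect_equal(sar_vol(form, shifted), v0, tolerance = 1e-12)
  # power scaling scales SARvol linearly
  expect_equal(sar_vol(form, excitation(3 * exc$powers, exc$phases)), 3 * v0,
               tolerance = 1e-12)
  expect_equal(sar_vol(form, excitation(0 * exc$powers, exc$phases)), 0)
  # sum rule over two disjoint equal-size regions
  fa <- sar_quadratic_form(uf, 1:250, sigma, rho)
  fb <- sar_quadratic_form(uf, 251:500, sigma, rho)
  expect_equal(v0, (sar_vol(fa, exc) + sar_vol(fb, exc)) / 2,
               tolerance = 1e-12)
})

test_that("polar accessors match the Hermitian representation", {
  uf <- synthetic_unit_fields(4, seed = 51)
  sigma <- array(1, c(10, 10, 10)); rho <- array(1000, c(10, 10, 10))
  form <- sar_quadratic_form(uf, 1:100, sigma, rho)
  po <- form_polar(form)
  expect_equal(po$beta * exp(1i * po$Omega), form$H, tolerance = 1e-12)
})

test_that("dB map normalizes to 0 dB and preserves voxel ranking", {
  uf <- synthetic_unit_fields(3, dims = c(6, 6, 6), seed = 61)
  ph <- block_phantom("gland", n = c(6, 6, 6))
  ph$labels[1, 1, 1] <- 0L   # one air voxel gets masked
  m <- sar_map(uf, excitation(rep(1, 3)), ph)
  expect_equal(max(m$db, na.rm = TRUE), 0)
  expect_true(is.na(m$db[1, 1, 1]))
  expect_equal(m$db[which.max(m$sar)], 0)
  expect_equal(10 * log10(0.1), -10)   # scale convention
  ok <- !is.na(m$sar)
  expect_equal(rank(m$sar[ok]), rank(m$db[ok]))
})

test_that("power normalization rescales fields and round-trips", {
  uf <- synthetic_unit_fields(1, seed = 71)[[1]]
  f2 <- normalize_to_power(uf, 4)
  expect_equal(f2$E, uf$E / 2)
  expect_equal(f2$accepted_power, 1)
  expect_equal(normalize_to_power(uf, 1)$E, uf$E)
  expect_error(normalize_to_power(uf, 0), "positive")
})
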