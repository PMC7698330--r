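test_that("tumor perfusion has the stated endpoints and monotone decay", {
  expect_identical(tumor_perfusion(37), 0.8)
  expect_equal(tumor_perfusion(1e6), 0.4, tolerance = 1e-12)
  expect_equal(tumor_perfusion(42), 0.4 + 0.4 * exp(-625 / 880))
  Ts <- seq(37, 80, by = 0.25)
  expect_true(all(diff(tumor_perfusion(Ts)) <= 0))
})

test_that("stability bound matches the uniform-medium formula and scaling", {
  cfg <- thermal_config(h = 0)
  bp3 <- block_phantom("muscle", spacing = 3)
  tab <- tissue_table()
  m <- tab[tab$tissue == "muscle", ]
  b3 <- stability_bound(bp3, cfg)
  pure <- m$rho * m$C * 0.003^2 / (6 * m$k)
  # bound equals rho C dx^2 / (6 k) up to the perfusion correction
  expect_lt(b3, pure)
  expect_equal(b3, m$rho * m$C / (6 * m$k / 0.003^2 + m$perfusion),
               tolerance = 1e-12)
  # halving the spacing quarters the (conduction-dominated) bound
  bp15 <- block_phantom("muscle", spacing = 1.5)
  expect_equal(stability_bound(bp15, cfg) / b3, 0.25, tolerance = 0.02)
  # the bound is the minimum over tissues present
  mixed <- block_phantom("muscle", spacing = 3)
  mixed$labels[1:6, , ] <- 2L    # fat half
  bf <- block_phantom("fat", spacing = 3)
  expect_lte(stability_bound(mixed, cfg),
             min(b3, stability_bound(bf, cfg)) + 1e-12)
})

test_that("oversized time steps are refused", {
  bp <- block_phantom("muscle")
  cfg <- thermal_config(dt = 1e4)
  expect_error(step_bioheat(37, 0, bp, cfg, duration = 100), "unstable")
})

test_that("uniform equilibrium at blood temperature is exact", {
  bp <- block_phantom("muscle", HGR = 0)
  cfg <- thermal_config(h = 0)
  r <- step_bioheat(37, 0, bp, cfg, duration = 300)
  expect_equal(max(abs(r$T[bp$labels != 0] - 37)), 0)
})

test_that("uniform perfused block reaches the analytic steady state", {
  bp <- block_phantom("gland", n = c(8, 8, 8))
  cfg <- thermal_config(h = 0)
  tab <- tissue_table(); g <- tab[tab$tissue == "gland", ]
  Q <- 4000
  T_ss <- 37 + (g$rho * g$HGR + Q) / g$perfusion
  r <- step_bioheat(37, Q, bp, cfg, duration = 2500)
  expect_equal(max(abs(r$T[bp$labels != 0] - T_ss)) / (T_ss - 37), 0,
               tolerance = 0.005)
})

test_that("pure-diffusion slab follows the Fourier series transient", {
  # 1-D slab, fixed-temperature faces, no perfusion / sources
  n <- c(81, 3, 3)
  bp <- block_phantom("muscle", n = n, spacing = 1, HTR = 0, HGR = 0)
  fixed <- array(FALSE, n)
  fixed[1, , ] <- TRUE; fixed[n[1], , ] <- TRUE
  T0 <- array(37, n)
  Tf <- 47
  T0[fixed] <- Tf
  cfg <- thermal_config(h = 0)
  t_end <- 400
  r <- step_bioheat(T0, 0, bp, cfg, duration = t_end, fixed_mask = fixed)
  tab <- tissue_table(); m <- tab[tab$tissue == "muscle", ]
  alpha <- m$k / (m$rho * m$C)
  L <- (n[1] - 1) * 1e-3
  series <- function(x, t) {
    s <- 0
    for (q in seq(1, 399, by = 2))
      s <- s + 4 / (pi * q) * sin(q * pi * x / L) *
        exp(-alpha * (q * pi / L)^2 * t)
    Tf + (37 - Tf) * s
  }
  probes <- c(11, 21, 41, 61)
  got <- r$T[probes, 2, 2]
  want <- vapply(probes, function(i) series((i - 1) * 1e-3, t_end), 0)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("energy is conserved on an insulated domain without sinks", {
  bp <- block_phantom("skin", n = c(10, 10, 10), HTR = 0, HGR = 0)
  cfg <- thermal_config(h = 0)
  set.seed(5)
  T0 <- array(37 + runif(1000, 0, 5), dim(bp$labels))
  r <- step_bioheat(T0, 0, bp, cfg, duration = 500)
  # uniform rho C: mean temperature is the conserved quantity
  expect_equal(mean(r$T), mean(T0), tolerance = 1e-12)
})

test_that("linear-perfusion maximum principle and monotone response to Q", {
  bp <- block_phantom("gland", n = c(8, 8, 8))
  bp$labels[1, , ] <- 1L   # one skin face exposed to ambient cooling
  bp$label_map$HGR <- 0    # no metabolic sources anywhere for the bound
  cfg <- thermal_config(h = 10)
  r0 <- step_bioheat(37, 0, bp, cfg, duration = 1500)
  r1 <- step_bioheat(37, 3000, bp, cfg, duration = 1500)
  tis <- bp$labels != 0
  gl <- bp$labels == 4L    # the skin layer generates metabolic heat
  expect_true(all(r0$T[tis] >= cfg$T_ext - 1e-9))
  expect_true(all(r0$T[gl] <= cfg$T_b + 1e-9))
  expect_true(all(r1$T[tis] >= r0$T[tis] - 1e-12))
})

test_that("doubling Q doubles the elevation for linear tissues", {
  bp <- block_phantom("fat", n = c(9, 9, 9))
  cfg <- thermal_config(h = 0)
  base <- step_bioheat(37, 0, bp, cfg, duration = 800)
  r1 <- step_bioheat(37, 1000, bp, cfg, duration = 800)
  r2 <- step_bioheat(37, 2000, bp, cfg, duration = 800)
  d1 <- r1$T - base$T
  d2 <- r2$T - base$T
  expect_equal(d2[bp$labels != 0], 2 * d1[bp$labels != 0],
               tolerance = 1e-9)
})

test_that("nonlinear tumor perfusion accumulates more heat than constant", {
  # same block and source; tumor label engages omega(T), which falls below
  # omega(37) when heated, so the nonlinear variant must end at least as hot
  n <- c(9, 9, 9)
  tumor <- block_phantom("muscle", n = n)
  tumor$labels[] <- 6L
  const <- block_phantom("muscle", n = n)
  # constant-perfusion twin: muscle block with HTR chosen so its perfusion
  # coefficient equals C_b * omega(37)
  cb <- 3617
  htr_eq <- cb * tumor_perfusion(37) / (1050 * cb * 1090) * 60 / 1e-6
  const <- block_phantom("muscle", n = n, HTR = htr_eq)
  const$labels[] <- 5L
  cfg <- thermal_config(h = 0)
  Q <- 3e4
  rt <- step_bioheat(37, Q, tumor, cfg, duration = 2000)
  rc <- step_bioheat(37, Q, const, cfg, duration = 2000)
  expect_gt(max(rt$T), 40)  # the source heats appreciably
  expect_true(all(rt$T[tumor$labels != 0] >= rc$T[const$labels != 0] - 1e-9))
})

test_that("treatment simulation turns the source off and cools", {
  bp <- block_phantom("muscle", n = c(8, 8, 8))
  bp$labels[4:5, 4:5, 4:5] <- 6L
  bp$tumor_center <- c(10.5, 10.5, 10.5)
  cfg <- thermal_config(h = 0, exposure_duration = 900,
                        cooldown_duration = 600, record_dt = 30)
  sim <- simulate_treatment(bp, 2e4, cfg)
  n_exp <- sum(sim$time <= 900)
  # heating while on
  expect_gt(sim$T_tumor_max[n_exp], sim$T_tumor_max[1])
  # non-increasing tumor temperature after turn-off
  post <- sim$T_tumor_max[sim$time >= 900]
  expect_true(all(diff(post) <= 1e-9))
  expect_equal(sim$tumor_max_end, max(sim$T_end_exposure[bp$labels == 6L]))
  expect_named(sim$tissue_max,
               c("skin", "fat", "breast_fat", "gland", "muscle", "tumor"))
  # Q = 0 throughout stays at the source-free profile
  sim0 <- simulate_treatment(bp, 0, cfg)
  ref <- step_bioheat(37, 0, bp, cfg, duration = 900)
  expect_equal(sim0$T_end_exposure, ref$T, tolerance = 1e-12)
})
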