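test_that("tumor sphere is voxelized at the right volume and location", {
  ph <- breast_phantom(spacing = 1, tumor_radius = 12, seed = 1)
  vol_analytic <- 4 / 3 * pi * 12^3
  expect_lt(abs(sum(ph$labels == 6L) - vol_analytic) / vol_analytic, 0.02)
  # the voxel holding the tumor center is tumor for several spacings
  for (s in c(1, 2, 3)) {
    ph2 <- breast_phantom(spacing = s, tumor_radius = 6, seed = 1)
    idx <- sarfocus:::.voxel_index(ph2, ph2$tumor_center)
    expect_equal(ph2$labels[idx], 6L)
  }
  # zero radius -> no tumor voxels
  ph0 <- breast_phantom(spacing = 3, tumor_radius = 0, seed = 1)
  expect_equal(sum(ph0$labels == 6L), 0)
})

test_that("HD phantom composition lands in the heterogeneously-dense band", {
  ph <- breast_phantom(spacing = 3, tumor_radius = 12, seed = 1)
  fr <- composition_report(ph)$soft_fractions
  expect_gte(fr[["gland"]], 0.51)
  expect_lte(fr[["gland"]], 0.75)
  # class targets hit within 5 percentage points
  expect_lt(abs(fr[["muscle"]] - 0.20), 0.05)
  expect_lt(abs(fr[["gland"]] - 0.60), 0.05)
  expect_lt(abs(fr[["fat"]] - 0.20), 0.05)
})

test_that("other composition classes track their targets", {
  targets <- list(PF = c(0.10, 0.20, 0.70), SFG = c(0.20, 0.40, 0.40),
                  ED = c(0.20, 0.70, 0.10))
  for (cl in names(targets)) {
    ph <- breast_phantom(spacing = 3, tumor_radius = 0,
                         composition_class = cl, seed = 2)
    fr <- composition_report(ph)$soft_fractions
    expect_lt(max(abs(fr - targets[[cl]])), 0.05, label = cl)
  }
})

test_that("composition report fractions sum to one over tissue voxels", {
  ph <- breast_phantom(spacing = 4, tumor_radius = 8, seed = 3)
  rep <- composition_report(ph)
  expect_equal(sum(rep$fractions), 1, tolerance = 1e-12)
  bp0 <- block_phantom("muscle")
  bp0$labels[] <- 0L
  expect_error(composition_report(bp0), "empty")
  # all-muscle block reports pure muscle
  bp <- block_phantom("muscle")
  expect_equal(composition_report(bp)$fractions[["muscle"]], 1)
})

test_that("tumor volume fraction scales as the radius cubed", {
  ph12 <- breast_phantom(spacing = 2, tumor_radius = 12, seed = 1)
  ph4 <- breast_phantom(spacing = 2, tumor_radius = 4, seed = 1)
  f12 <- composition_report(ph12)$fractions[["tumor"]]
  f4 <- composition_report(ph4)$fractions[["tumor"]]
  expect_equal(f12 / f4, (12 / 4)^3, tolerance = 0.15)
})

test_that("phantom generation is deterministic and scales with spacing", {
  a <- breast_phantom(spacing = 3, tumor_radius = 10, seed = 7)
  b <- breast_phantom(spacing = 3, tumor_radius = 10, seed = 7)
  expect_identical(a$labels, b$labels)
  d <- breast_phantom(spacing = 3, tumor_radius = 10, seed = 8)
  expect_false(identical(a$labels, d$labels))
  # voxel counts scale ~ spacing^-3
  n4 <- sum(breast_phantom(spacing = 4, tumor_radius = 0, seed = 1)$labels != 0)
  n2 <- sum(breast_phantom(spacing = 2, tumor_radius = 0, seed = 1)$labels != 0)
  expect_equal(n2 / n4, 8, tolerance = 0.15)
})

test_that("breast interior is sealed by skin and muscle", {
  ph <- breast_phantom(spacing = 3, tumor_radius = 12, seed = 1)
  lab <- ph$labels
  interior <- lab %in% c(2L, 3L, 4L, 6L)
  dim(interior) <- dim(lab)
  touches_air <- array(FALSE, dim(lab))
  for (axis in 1:3) for (by in c(-1, 1)) {
    nb <- sarfocus:::.shift3(lab, axis, by, fill = 0L)
    touches_air <- touches_air | (interior & nb == 0L)
  }
  expect_equal(sum(touches_air), 0)
})

test_that("geometry errors are raised", {
  expect_error(breast_phantom(spacing = 3, tumor_radius = 12,
                              tumor_center = c(0, -60, 12), seed = 1),
               "outside the gland core")
  expect_error(breast_phantom(spacing = 8, tumor_radius = 12, seed = 1),
               "resolution")
})

test_that("NIfTI + JSON round trip preserves the phantom", {
  ph <- breast_phantom(spacing = 4, tumor_radius = 10, seed = 5)
  p <- withr::local_tempfile(fileext = ".nii")
  write_phantom(ph, p)
  ph2 <- read_phantom(p)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$spacing, ph$spacing)
  expect_equal(ph2$origin, ph$origin)
  expect_equal(ph2$tumor_center, ph$tumor_center)
  img <- RNifti::readNifti(p)
  expect_equal(unname(RNifti::pixdim(img)[1:3]), rep(4, 3))
})
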