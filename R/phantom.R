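#' Generate a synthetic voxel breast phantom
#'
#' Builds a voxelized hemispherical breast resting on a cylindrical
#' pectoral-muscle slab: an outer skin shell, a subcutaneous fat shell, and a
#' glandular core interspersed with seeded lobulated breast-fat inclusions,
#' with an optional spherical tumor overwriting the core.  The glandular /
#' fat / muscle make-up is steered by a mammographic composition class:
#' predominantly fatty (`PF`; muscle 10%, gland 20%, fat 70% of soft tissue),
#' scattered fibro-glandular (`SFG`; 20/40/40), heterogeneously dense
#' (`HD`; 20/60/20) or extremely dense (`ED`; 20/70/10).  The slab thickness
#' and the breast-fat fraction of the core are derived from the class targets
#' so that the realized voxel composition lands within a few percentage
#' points of them.
#'
#' Coordinates are in mm, right-handed, with the antenna-array center at the
#' origin.  Voxel centers lie on integer multiples of `spacing`, so a tumor
#' center on that lattice (the default `(0, -12, 12)` for any spacing that
#' divides 12 mm) coincides exactly with a voxel center.  The breast dome
#' points toward -x; the chest wall (muscle slab) sits behind the base plane
#' at `base_x`.
#'
#' Voxels are assigned to the tumor sphere by the center-of-voxel-inside-
#' sphere rule.  Labels: 0 air, 1 skin, 2 fat, 3 breast fat, 4 gland,
#' 5 muscle, 6 tumor.
#'
#' @param spacing voxel edge length (mm)
#' @param breast_radius outer breast radius (mm)
#' @param skin_thickness skin shell thickness (mm)
#' @param fat_thickness subcutaneous fat shell thickness (mm); `NULL` picks a
#'   class default (5 mm, thinned for `ED`)
#' @param slab_thickness muscle slab thickness (mm); `NULL` derives it from
#'   the class muscle fraction
#' @param breast_fat_fraction fraction of the core carved into breast-fat
#'   lobules; `NULL` derives it from the class gland fraction
#' @param tumor_radius tumor sphere radius (mm); 0 for no tumor
#' @param tumor_center tumor center (mm), length-3
#' @param composition_class one of `"PF"`, `"SFG"`, `"HD"`, `"ED"`
#' @param base_x x-coordinate of the breast base plane (mm)
#' @param seed integer seed for the lobular noise field
#' @return An object of class `voxel_phantom`: a list with `labels` (3-D
#'   integer array), `spacing` (mm), `origin` (mm coords of the center of
#'   voxel `[1,1,1]`), `label_map` (tissue table), `tumor_center`,
#'   `tumor_radius`, `composition_class` and `core_mask` (logical array of
#'   the gland/breast-fat core region before tumor insertion).
#' @export
#' @examples
#' ph <- breast_phantom(spacing = 4, tumor_radius = 12, seed = 1)
#' composition_report(ph)
breast_phantom <- function(spacing = 3,
                           breast_radius = 70,
                           skin_thickness = 2,
                           fat_thickness = NULL,
                           slab_thickness = NULL,
                           breast_fat_fraction = NULL,
                           tumor_radius = 12,
                           tumor_center = c(0, -12, 12),
                           composition_class = c("HD", "PF", "SFG", "ED"),
                           base_x = 25,
                           seed = 1L) {
  composition_class <- match.arg(composition_class)
  if (spacing <= 0) stop("spacing must be positive")
  if (spacing > skin_thickness * 2.5)
    stop("resolution error: spacing too coarse to resolve the skin shell")
  targets <- switch(composition_class,
    PF  = c(muscle = 0.10, gland = 0.20, fat = 0.70),
    SFG = c(muscle = 0.20, gland = 0.40, fat = 0.40),
    HD  = c(muscle = 0.20, gland = 0.60, fat = 0.20),
    ED  = c(muscle = 0.20, gland = 0.70, fat = 0.10))
  if (is.null(fat_thickness))
    fat_thickness <- if (composition_class == "ED") 2 else 5

  Rb <- breast_radius
  Ri <- Rb - skin_thickness        # interior (non-skin) radius
  Rc <- Ri - fat_thickness         # gland/breast-fat core radius
  if (Rc <= 0) stop("shells exceed breast radius")

  # continuous volumes drive the class-derived defaults
  v_int  <- 2 / 3 * pi * Ri^3                 # all soft tissue inside skin
  v_core <- 2 / 3 * pi * Rc^3
  if (is.null(slab_thickness)) {
    m <- targets[["muscle"]]
    slab_thickness <- m / (1 - m) * v_int / (pi * Rb^2)
    # snap to whole voxel layers so the slab is resolved
    slab_thickness <- max(spacing, round(slab_thickness / spacing) * spacing)
  }
  if (is.null(breast_fat_fraction)) {
    gland_target <- targets[["gland"]] / (1 - targets[["muscle"]]) * v_int
    breast_fat_fraction <- min(0.95, max(0, 1 - gland_target / v_core))
  }

  # lattice of voxel centers on integer multiples of spacing, one-voxel air
  # margin so every tissue voxel has its air neighbours represented
  cmax <- function(x) spacing * (floor(x / spacing) + 1L)
  xr <- c(-cmax(Rb - base_x), cmax(base_x + slab_thickness))
  yr <- zr <- c(-cmax(Rb), cmax(Rb))
  xs <- seq(xr[1], xr[2], by = spacing)
  ys <- seq(yr[1], yr[2], by = spacing)
  zs <- seq(zr[1], zr[2], by = spacing)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))

  cx <- c(base_x, 0, 0)                       # hemisphere center
  r2 <- (X - cx[1])^2 + Y^2 + Z^2             # squared distance to center
  lat2 <- Y^2 + Z^2
  labels <- array(0L, c(nx, ny, nz))

  hemi <- X <= base_x & r2 <= Rb^2
  labels[hemi] <- 1L                                      # skin by default
  labels[hemi & r2 <= Ri^2] <- 2L                         # subcutaneous fat
  core <- hemi & r2 <= Rc^2
  labels[core] <- 4L                                      # gland core
  slab <- X > base_x & X <= base_x + slab_thickness & lat2 <= Rb^2
  labels[slab] <- 5L                                      # muscle

  # seeded lobulated breast-fat inclusions: smooth Gaussian field thresholded
  # at the exact core quantile so the realized fraction matches the target
  if (breast_fat_fraction > 0 && any(core)) {
    noise <- .smooth_noise(xs, ys, zs, scale_mm = 12, seed = seed)
    thr <- quantile(noise[core], 1 - breast_fat_fraction, names = FALSE)
    labels[core & noise > thr] <- 3L
  }

  # close the skin shell: at coarse spacings the thin geometric shell can
  # miss voxel centers, so any interior tissue voxel left facing air is
  # relabeled skin (guarantees a watertight shell at every resolution)
  interior <- array(labels %in% c(2L, 3L, 4L), dim(labels))
  exposed <- array(FALSE, dim(labels))
  for (axis in 1:3) for (by in c(-1, 1))
    exposed <- exposed | (interior & .shift3(labels, axis, by, fill = 0L) == 0L)
  labels[exposed] <- 1L
  core <- core & !exposed

  core_mask <- core
  if (tumor_radius > 0) {
    t2 <- (X - tumor_center[1])^2 + (Y - tumor_center[2])^2 +
      (Z - tumor_center[3])^2
    tum <- t2 <= tumor_radius^2
    if (!any(tum)) {
      # a sub-voxel tumor still claims the voxel holding its center
      idx <- which.min(t2)
      tum[idx] <- TRUE
    }
    if (any(tum & !core_mask))
      stop("geometry error: tumor sphere extends outside the gland core")
    labels[tum] <- 6L
  }

  structure(list(
    labels = labels,
    spacing = spacing,
    origin = c(xs[1], ys[1], zs[1]),
    label_map = tissue_table(),
    tumor_center = tumor_center,
    tumor_radius = tumor_radius,
    composition_class = composition_class,
    core_mask = core_mask
  ), class = "voxel_phantom")
}

# smooth Gaussian random field: white noise on a coarse lattice, trilinearly
# interpolated to the voxel lattice; deterministic given the seed
.smooth_noise <- function(xs, ys, zs, scale_mm, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pad <- scale_mm
  gx <- seq(min(xs) - pad, max(xs) + pad, by = scale_mm)
  gy <- seq(min(ys) - pad, max(ys) + pad, by = scale_mm)
  gz <- seq(min(zs) - pad, max(zs) + pad, by = scale_mm)
  g <- array(rnorm(length(gx) * length(gy) * length(gz)),
             c(length(gx), length(gy), length(gz)))
  interp1 <- function(grid, x) {
    # index and fraction of x within grid (uniform spacing)
    u <- (x - grid[1]) / (grid[2] - grid[1])
    i0 <- pmin(pmax(floor(u), 0), length(grid) - 2)
    list(i = i0 + 1L, f = u - i0)
  }
  ix <- interp1(gx, xs); iy <- interp1(gy, ys); iz <- interp1(gz, zs)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  out <- array(0, c(nx, ny, nz))
  FX <- array(rep(ix$f, ny * nz), c(nx, ny, nz))
  FY <- array(rep(rep(iy$f, each = nx), nz), c(nx, ny, nz))
  FZ <- array(rep(iz$f, each = nx * ny), c(nx, ny, nz))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) FX else 1 - FX) * (if (dy) FY else 1 - FY) *
      (if (dz) FZ else 1 - FZ)
    out <- out + w * g[ix$i + dx, iy$i + dy, iz$i + dz, drop = FALSE]
  }
  out
}

#' Per-tissue volume fractions of a phantom
#'
#' Reports the volume fraction of each tissue over all non-air voxels, plus
#' the soft-tissue fractions (muscle / gland / fat, with the two fat
#' compartments pooled and the tumor counted as gland-replacing) used to
#' check a phantom against its mammographic composition class.
#'
#' @param phantom a `voxel_phantom`
#' @return list with `fractions` (named, over non-air voxels, summing to 1),
#'   `soft_fractions` (muscle/gland/fat over non-skin soft tissue) and
#'   `n_voxels` (non-air voxel count)
#' @export
composition_report <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  lab <- phantom$labels
  n <- sum(lab != 0L)
  if (n == 0) stop("empty phantom")
  lt <- .label_rows(phantom$label_map)
  counts <- vapply(lt$label, function(l) sum(lab == l), numeric(1))
  names(counts) <- lt$tissue
  fractions <- counts / n
  soft <- c(
    muscle = counts[["muscle"]],
    gland  = counts[["gland"]] + counts[["tumor"]],
    fat    = counts[["fat"]] + counts[["breast_fat"]]
  )
  list(fractions = fractions,
       soft_fractions = soft / sum(soft),
       n_voxels = n)
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel breast phantom: %d x %d x %d voxels @ %g mm (%s class)\n",
              d[1], d[2], d[3], x$spacing, x$composition_class))
  cat(sprintf("  tumor: r = %g mm at (%g, %g, %g) mm; %d tumor voxels\n",
              x$tumor_radius, x$tumor_center[1], x$tumor_center[2],
              x$tumor_center[3], sum(x$labels == 6L)))
  fr <- composition_report(x)$soft_fractions
  cat(sprintf("  soft tissue: muscle %.1f%%, gland %.1f%%, fat %.1f%%\n",
              100 * fr[["muscle"]], 100 * fr[["gland"]], 100 * fr[["fat"]]))
  invisible(x)
}

# physical mm coordinates of voxel centers along each axis
.grid_coords <- function(phantom) {
  d <- dim(phantom$labels)
  lapply(1:3, function(a) phantom$origin[a] + (seq_len(d[a]) - 1) * phantom$spacing)
}

# linear index of the voxel whose center is nearest to point p (mm)
.voxel_index <- function(phantom, p) {
  d <- dim(phantom$labels)
  ijk <- vapply(1:3, function(a) {
    i <- round((p[a] - phantom$origin[a]) / phantom$spacing) + 1
    min(max(i, 1), d[a])
  }, numeric(1))
  as.integer(ijk[1] + d[1] * (ijk[2] - 1) + d[1] * d[2] * (ijk[3] - 1))
}

#' Write / read a phantom as a NIfTI label volume with JSON sidecar
#'
#' The label array is stored as an integer NIfTI-1 volume with the voxel
#' spacing in the header; phantom metadata (origin, tumor, class) and the
#' tissue table go to a JSON sidecar next to it.
#'
#' @param phantom a `voxel_phantom`
#' @param path output `.nii` path (sidecar gets extension `.json`)
#' @return `path` invisibly (`write_phantom`); a `voxel_phantom`
#'   (`read_phantom`)
#' @export
write_phantom <- function(phantom, path) {
  img <- RNifti::asNifti(phantom$labels * 1L)
  RNifti::pixdim(img) <- rep(phantom$spacing, 3)
  RNifti::writeNifti(img, path)
  meta <- list(
    origin = phantom$origin,
    spacing = phantom$spacing,
    tumor_center = phantom$tumor_center,
    tumor_radius = phantom$tumor_radius,
    composition_class = phantom$composition_class,
    label_map = phantom$label_map[, c("tissue", "label", "eps_r", "sigma",
                                      "rho", "C", "k", "HTR", "HGR")]
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_phantom
#' @param path_nii path of a phantom written by [write_phantom()]
#' @export
read_phantom <- function(path_nii) {
  img <- RNifti::readNifti(path_nii)
  meta <- jsonlite::read_json(.sidecar_path(path_nii), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim = dim(img))
  structure(list(
    labels = labels,
    spacing = meta$spacing,
    origin = unlist(meta$origin),
    label_map = tissue_table(),
    tumor_center = unlist(meta$tumor_center),
    tumor_radius = meta$tumor_radius,
    composition_class = meta$composition_class,
    core_mask = NULL
  ), class = "voxel_phantom")
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
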