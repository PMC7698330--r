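#' Pipeline configuration
#'
#' Assembles the configuration of the full planning study: phantom
#' generation, array geometry, EM solver, optimization and thermal
#' simulation, plus the tumor-radius sweep.
#'
#' `field_mode = "per-radius"` recomputes the eight unit fields for every
#' tumor radius (the tumor carries muscle dielectrics, which differ from the
#' gland it replaces).  `field_mode = "shared"` computes them once on a
#' reference phantom (largest radius in the sweep) and reuses them across
#' radii -- an approximation that perturbs only the small tumor-volume
#' dielectric contrast, at an eight-fold runtime saving per additional
#' radius.
#'
#' @param spacing phantom and EM grid spacing (mm)
#' @param radii tumor radii of the sweep (mm)
#' @param composition_class phantom composition class
#' @param phantom_seed seed of the phantom's lobular noise
#' @param tumor_center tumor center (mm)
#' @param n_antennas,ring_radius array geometry
#' @param total_power array power budget (W)
#' @param field_mode `"per-radius"` or `"shared"` (see Details)
#' @param solver a [solver_config()]
#' @param thermal a [thermal_config()]
#' @param phantom_args extra arguments for [breast_phantom()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(spacing = 3, radii = c(2, 4, 6, 8, 10, 12),
                            composition_class = "HD", phantom_seed = 1L,
                            tumor_center = c(0, -12, 12),
                            n_antennas = 8, ring_radius = 100,
                            total_power = 8,
                            field_mode = c("per-radius", "shared"),
                            solver = solver_config(),
                            thermal = thermal_config(),
                            phantom_args = list()) {
  structure(list(spacing = spacing, radii = radii,
                 composition_class = composition_class,
                 phantom_seed = phantom_seed, tumor_center = tumor_center,
                 n_antennas = n_antennas, ring_radius = ring_radius,
                 total_power = total_power,
                 field_mode = match.arg(field_mode),
                 solver = solver, thermal = thermal,
                 phantom_args = phantom_args),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `solver` and
#' `thermal` sub-blocks mirror [solver_config()] and [thermal_config()].
#' Unknown keys raise an error.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$solver)) y$solver <- do.call(solver_config, y$solver)
  if (!is.null(y$thermal)) y$thermal <- do.call(thermal_config, y$thermal)
  if (!is.null(y$tumor_center)) y$tumor_center <- as.numeric(y$tumor_center)
  if (!is.null(y$radii)) y$radii <- as.numeric(y$radii)
  do.call(pipeline_config, y)
}

.sweep_phantom <- function(config, radius) {
  do.call(breast_phantom, c(list(
    spacing = config$spacing, tumor_radius = radius,
    tumor_center = config$tumor_center,
    composition_class = config$composition_class,
    seed = config$phantom_seed), config$phantom_args))
}

#' Solve the per-antenna unit fields for a phantom
#'
#' Runs one FDTD solve per antenna of the ring array and returns the list of
#' unit-power complex field volumes on the phantom grid.
#'
#' @param phantom a `voxel_phantom`
#' @param config a [pipeline_config()]
#' @param verbose print per-antenna progress
#' @return list of [complex_field()]s
#' @export
solve_unit_fields <- function(phantom, config, verbose = interactive()) {
  geom <- array_geometry(config$n_antennas, config$ring_radius)
  dipoles <- place_array(geom, phantom)
  lapply(seq_along(dipoles), function(i) {
    t0 <- Sys.time()
    fld <- fdtd_unit_field(dipoles[[i]], phantom, config$solver)
    fld$antenna <- i
    if (verbose) {
      di <- attr(fld, "diagnostics")
      message(sprintf("antenna %d: %d windows, drift %.1e, %.1fs",
                      i, di$windows, di$drift,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    fld
  })
}

#' Run the tumor-radius sweep
#'
#' The full planning study: for each tumor radius, generate the phantom,
#' solve (or reuse) the eight unit fields, build tumor and healthy SAR
#' quadratic forms, optimize the excitation, map SAR and the heat source
#' Q = rho * SAR at the power budget, and run the transient bioheat
#' exposure + cool-down.  Deterministic given the configuration seeds.
#'
#' @param config a [pipeline_config()]
#' @param verbose print stage progress
#' @return object of class `sweep_result`: list with `records` (one per
#'   radius) and `config`.  Each record holds `radius`, `excitation`,
#'   `ratio`, `sar_max_tumor` (W/kg), `sarvol_tumor`,
#'   `sarvol_tumor_uniform`, `time` / `T_center` / `T_tumor_max` series,
#'   `T_center_end` and `T_tumor_max_end` (deg C at source turn-off),
#'   `tissue_max`, and `profiles` (Q and T along x and y through the tumor
#'   center)
#' @export
run_radius_sweep <- function(config = pipeline_config(),
                             verbose = interactive()) {
  shared_fields <- NULL
  if (config$field_mode == "shared") {
    ref <- .sweep_phantom(config, max(config$radii))
    if (verbose) message("solving shared unit fields (reference phantom)")
    shared_fields <- solve_unit_fields(ref, config, verbose)
  }
  records <- lapply(config$radii, function(r) {
    if (verbose) message(sprintf("-- tumor radius %g mm", r))
    ph <- .sweep_phantom(config, r)
    fields <- if (is.null(shared_fields))
      solve_unit_fields(ph, config, verbose) else shared_fields
    gp <- phantom_property_grids(ph)
    tumor <- ph$labels == 6L
    healthy <- ph$labels != 0L & !tumor
    Ht <- sar_quadratic_form(fields, tumor, gp$sigma, gp$rho, "tumor")
    Hh <- sar_quadratic_form(fields, healthy, gp$sigma, gp$rho, "healthy")
    prob <- sar_problem(Ht, Hh, total_power = config$total_power)
    opt <- optimal_excitation(prob)
    unif <- uniform_excitation(config$n_antennas, config$total_power)
    map <- sar_map(fields, opt$excitation, ph)
    Q <- map$sar * gp$rho
    Q[!is.finite(Q)] <- 0
    sim <- simulate_treatment(ph, Q, config$thermal)
    n_exp <- sum(sim$time <= config$thermal$exposure_duration)
    list(radius = r,
         excitation = opt$excitation,
         ratio = opt$ratio,
         sar_max_tumor = max(map$sar[tumor]),
         sarvol_tumor = sar_vol(Ht, opt$excitation),
         sarvol_tumor_uniform = sar_vol(Ht, unif),
         sarvol_healthy = sar_vol(Hh, opt$excitation),
         time = sim$time, T_center = sim$T_center,
         T_tumor_max = sim$T_tumor_max,
         T_center_end = sim$T_center[n_exp],
         T_tumor_max_end = sim$tumor_max_end,
         tissue_max = sim$tissue_max,
         profiles = list(
           Q_x = extract_profile(Q, ph, "x"),
           Q_y = extract_profile(Q, ph, "y"),
           T_x = extract_profile(sim$T_end_exposure, ph, "x"),
           T_y = extract_profile(sim$T_end_exposure, ph, "y")),
         db_slice = {
           # renormalize the displayed slice to its own 0 dB maximum
           sl <- .axial_slice(map$db, ph)
           sl - max(sl, na.rm = TRUE)
         })
  })
  structure(list(records = records, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("tumor-radius sweep:\n")
  print(sweep_summary(x))
  invisible(x)
}

#' Summary table of a sweep
#'
#' @param sweep a `sweep_result`
#' @return data.frame with one row per radius
#' @export
sweep_summary <- function(sweep) {
  do.call(rbind, lapply(sweep$records, function(r) {
    data.frame(radius_mm = r$radius,
               sar_ratio = r$ratio,
               sar_max_tumor = r$sar_max_tumor,
               sarvol_tumor = r$sarvol_tumor,
               sarvol_tumor_uniform = r$sarvol_tumor_uniform,
               T_center_end = r$T_center_end,
               T_tumor_max_end = r$T_tumor_max_end)
  }))
}

#' Extract a 1-D profile through the tumor center
#'
#' Samples a voxel volume along the x or y axis line passing through the
#' tumor center; offsets are reported relative to the tumor center.
#'
#' @param volume 3-D array on the phantom grid
#' @param phantom the `voxel_phantom`
#' @param axis `"x"` or `"y"`
#' @param center mm point the line passes through (default: tumor center)
#' @return data.frame with `offset_mm` and `value`
#' @export
extract_profile <- function(volume, phantom, axis = c("x", "y"),
                            center = phantom$tumor_center) {
  axis <- match.arg(axis)
  d <- dim(phantom$labels)
  co <- .grid_coords(phantom)
  ijk <- vapply(1:3, function(a) {
    i <- round((center[a] - phantom$origin[a]) / phantom$spacing) + 1
    min(max(i, 1), d[a])
  }, numeric(1))
  if (axis == "x") {
    v <- volume[, ijk[2], ijk[3]]
    off <- co[[1]] - center[1]
  } else {
    v <- volume[ijk[1], , ijk[3]]
    off <- co[[2]] - center[2]
  }
  data.frame(offset_mm = off, value = v)
}

# axial (z = const through tumor center) slice of a volume
.axial_slice <- function(volume, phantom) {
  d <- dim(phantom$labels)
  k <- round((phantom$tumor_center[3] - phantom$origin[3]) / phantom$spacing) + 1
  k <- min(max(k, 1), d[3])
  volume[, , k]
}

#' Write sweep reports
#'
#' Writes, per radius: the optimized excitation table (antenna, power W,
#' phase deg), the transient tumor temperature curves, the Q/T axis
#' profiles and the normalized SAR dB slice (CSV + PNG render); plus a
#' sweep summary table and a run log (configuration, seeds, package
#' version).  All CSVs are deterministic; timestamps appear only in the
#' log.
#'
#' @param sweep a `sweep_result`
#' @param outdir output directory (created if needed)
#' @param png write PNG slice renders
#' @return invisible character vector of files written
#' @export
report_sweep <- function(sweep, outdir, png = TRUE) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(sweep_summary(sweep), "summary.csv")
  for (r in sweep$records) {
    tag <- sprintf("r%02d", r$radius)
    wr(data.frame(antenna = seq_along(r$excitation$powers),
                  power_W = r$excitation$powers,
                  phase_deg = r$excitation$phases),
       sprintf("excitation_%s.csv", tag))
    wr(data.frame(time_s = r$time, T_center = r$T_center,
                  T_tumor_max = r$T_tumor_max),
       sprintf("transient_%s.csv", tag))
    pr <- r$profiles
    wr(data.frame(offset_mm = pr$Q_x$offset_mm, Q_x = pr$Q_x$value,
                  T_x = pr$T_x$value),
       sprintf("profile_x_%s.csv", tag))
    wr(data.frame(offset_mm = pr$Q_y$offset_mm, Q_y = pr$Q_y$value,
                  T_y = pr$T_y$value),
       sprintf("profile_y_%s.csv", tag))
    wr(as.data.frame(r$db_slice), sprintf("sar_db_slice_%s.csv", tag))
    if (png) {
      p <- file.path(outdir, sprintf("sar_db_slice_%s.png", tag))
      grDevices::png(p, width = 640, height = 640)
      sl <- r$db_slice
      sl[!is.finite(sl)] <- NA
      graphics::image(sl, zlim = c(-40, 0), useRaster = TRUE,
                      main = sprintf("normalized SAR (dB), tumor r = %g mm",
                                     r$radius))
      grDevices::dev.off()
      files <- c(files, p)
    }
  }
  log <- c(sprintf("sarfocus %s", as.character(utils::packageVersion("sarfocus"))),
           sprintf("written: %s", format(Sys.time())),
           sprintf("R %s", R.version.string),
           "config:",
           utils::capture.output(utils::str(sweep$config)))
  writeLines(log, file.path(outdir, "log.txt"))
  files <- c(files, file.path(outdir, "log.txt"))
  invisible(files)
}
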