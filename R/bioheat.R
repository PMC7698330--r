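#' Thermal simulation configuration
#'
#' Settings for the transient Pennes bioheat solve: explicit time step (by
#' default half the stability bound), a 30-minute exposure followed by a
#' cool-down, Robin convective exchange on skin-air faces, and the arterial
#' blood reference state.
#'
#' @param dt time step (s); `NULL` picks `dt_fraction` of the stability
#'   bound
#' @param dt_fraction fraction of the explicit stability bound used when
#'   `dt` is `NULL`
#' @param exposure_duration heating phase length (s)
#' @param cooldown_duration post-exposure phase length (s)
#' @param h effective convective heat transfer coefficient at the skin
#'   (W/m^2/K; lumps convection, radiation and evaporation)
#' @param T_ext ambient temperature (deg C)
#' @param T_b arterial blood temperature (deg C)
#' @param T_0 initial tissue temperature (deg C)
#' @param rho_b,C_b arterial blood density (kg/m^3) and specific heat
#'   (J/kg/K)
#' @param record_dt sampling interval of the recorded time series (s)
#' @return list of class `thermal_config`
#' @export
thermal_config <- function(dt = NULL, dt_fraction = 0.5,
                           exposure_duration = 1800,
                           cooldown_duration = 600,
                           h = 10, T_ext = 25, T_b = 37, T_0 = 37,
                           rho_b = 1050, C_b = 3617, record_dt = 30) {
  stopifnot(exposure_duration > 0, cooldown_duration >= 0)
  structure(list(dt = dt, dt_fraction = dt_fraction,
                 exposure_duration = exposure_duration,
                 cooldown_duration = cooldown_duration,
                 h = h, T_ext = T_ext, T_b = T_b, T_0 = T_0,
                 rho_b = rho_b, C_b = C_b, record_dt = record_dt),
            class = "thermal_config")
}

#' Temperature-dependent tumor perfusion
#'
#' The nonlinear volumetric blood-perfusion rate inside the tumor,
#' omega(T) = 0.4 + 0.4 exp(-(T - 37)^4 / 880) kg/m^3/s: 0.8 at the
#' baseline 37 deg C, decaying monotonically toward the 0.4 asymptote as the
#' tumor heats, which reduces convective cooling and lets heat accumulate.
#'
#' @param T temperature (deg C), vectorized
#' @return perfusion rate (kg/m^3/s)
#' @export
#' @examples
#' tumor_perfusion(c(37, 42))
tumor_perfusion <- function(T) {
  0.4 + 0.4 * exp(-(T - 37)^4 / 880)
}

# shift an array by one voxel along an axis, padding with `fill`
.shift3 <- function(A, axis, by, fill = 0) {
  n <- dim(A)
  out <- array(fill, n)
  src <- dst <- lapply(n, seq_len)
  if (by == 1) { dst[[axis]] <- 2:n[axis]; src[[axis]] <- 1:(n[axis] - 1) }
  else { dst[[axis]] <- 1:(n[axis] - 1); src[[axis]] <- 2:n[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

#' Explicit-scheme stability bound
#'
#' Largest stable explicit time step for the bioheat stencil: per voxel,
#' rho C / (sum of face conductances / dx^2 + Robin conductance + perfusion
#' coefficient), minimized over tissue voxels.  For a uniform medium without
#' perfusion this reduces to the classical rho C dx^2 / (6 k).  The tumor
#' uses its maximum perfusion C_b * omega(37).
#'
#' @param phantom a `voxel_phantom`
#' @param config a [thermal_config()]
#' @return maximum stable dt (s)
#' @export
stability_bound <- function(phantom, config = thermal_config()) {
  gp <- phantom_property_grids(phantom)
  dx <- phantom$spacing / 1000
  kk <- gp$k
  tissue <- phantom$labels != 0L
  denom <- array(0, dim(kk))
  for (axis in 1:3) for (by in c(-1, 1)) {
    kn <- .shift3(kk, axis, by)
    nb_tissue <- .shift3(tissue, axis, by, fill = FALSE)
    kf <- ifelse(nb_tissue & tissue, 2 * kk * kn / pmax(kk + kn, 1e-300), 0)
    robin <- (!nb_tissue) & (phantom$labels == 1L)
    denom <- denom + kf / dx^2 + ifelse(robin, config$h / dx, 0)
  }
  perf <- gp$perfusion
  perf[phantom$labels == 6L] <- config$C_b * tumor_perfusion(config$T_b)
  denom <- denom + perf
  rhoC <- gp$rho * gp$C
  min((rhoC / pmax(denom, 1e-300))[tissue])
}

# shared argument assembly for the compiled stepper
.bioheat_args <- function(phantom, Q, config) {
  gp <- phantom_property_grids(phantom)
  src <- gp$hgr_vol + Q
  list(dims = as.integer(dim(phantom$labels)),
       dx = phantom$spacing / 1000,
       labels = as.integer(phantom$labels),
       rhoC = as.numeric(gp$rho * gp$C),
       k = as.numeric(gp$k),
       perf = as.numeric(gp$perfusion),
       src = as.numeric(src),
       tumor = as.logical(phantom$labels == 6L))
}

#' Advance the bioheat equation
#'
#' Explicit forward-Euler update of rho C dT/dt = div(k grad T) +
#' perfusion * (T_b - T) + rho HGR + Q with harmonic-mean face
#' conductivities, Robin skin-air faces, insulated domain boundary, and the
#' nonlinear perfusion of [tumor_perfusion()] inside the tumor (evaluated at
#' the current temperature).  Air voxels are not solved.
#'
#' @param T0 initial temperature array (deg C), or a scalar
#' @param Q external volumetric heat source (W/m^3), array or scalar
#' @param phantom a `voxel_phantom`
#' @param config a [thermal_config()]
#' @param duration time to advance (s)
#' @param fixed_mask optional logical array of voxels held at their initial
#'   temperature (Dirichlet)
#' @param record_voxel optional mm-point whose voxel trace is recorded
#' @return list with `T` (final array), `time`, and recorded series
#'   `T_center`, `T_tumor_max`
#' @export
step_bioheat <- function(T0, Q, phantom, config = thermal_config(),
                         duration = NULL, fixed_mask = NULL,
                         record_voxel = phantom$tumor_center) {
  dims <- dim(phantom$labels)
  if (length(T0) == 1) T0 <- array(T0, dims)
  if (length(Q) == 1) Q <- array(Q, dims)
  bound <- stability_bound(phantom, config)
  dt <- if (is.null(config$dt)) config$dt_fraction * bound else config$dt
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("unstable time step: dt = %.3g s exceeds the bound %.3g s",
                 dt, bound))
  if (is.null(duration)) duration <- config$exposure_duration
  nsteps <- max(1L, ceiling(duration / dt))
  dt <- duration / nsteps
  rec_every <- max(1L, floor(config$record_dt / dt))
  a <- .bioheat_args(phantom, Q, config)
  rid <- if (is.null(record_voxel)) -1L else .voxel_index(phantom, record_voxel) - 1L
  res <- bioheat_run_cpp(a$dims, a$dx, a$labels, a$rhoC, a$k, a$perf, a$src,
                         as.numeric(T0), config$T_b, dt, nsteps,
                         config$h, config$T_ext, 1L, a$tumor,
                         config$C_b, 0.4, 0.4, 880,
                         if (is.null(fixed_mask)) logical(0) else as.logical(fixed_mask),
                         rid, as.integer(rec_every))
  list(T = array(res$T, dims), time = res$time, T_center = res$T_center,
       T_tumor_max = res$T_tumor_max, dt = dt)
}

#' Simulate a full hyperthermia exposure
#'
#' Runs the heating phase with the external source Q on for
#' `exposure_duration`, then the cool-down with Q = 0, recording the
#' tumor-center temperature trajectory and the whole-tumor maximum.
#'
#' @param phantom a `voxel_phantom`
#' @param Q external volumetric heat source (W/m^3) during exposure, e.g.
#'   `rho * SAR` from [sar_map()]
#' @param config a [thermal_config()]
#' @return list with `time` and the `T_center` / `T_tumor_max` series over
#'   both phases, `T_end_exposure` (temperature array at source turn-off),
#'   `T_final`, `tumor_max_end` (max tumor temperature at end of exposure),
#'   `tissue_max` (named per-tissue maxima at end of exposure) and `dt`
#' @export
simulate_treatment <- function(phantom, Q, config = thermal_config()) {
  heat <- step_bioheat(config$T_0, Q, phantom, config,
                       duration = config$exposure_duration)
  out <- list(time = heat$time, T_center = heat$T_center,
              T_tumor_max = heat$T_tumor_max)
  T_end <- heat$T
  if (config$cooldown_duration > 0) {
    cool <- step_bioheat(T_end, 0, phantom, config,
                         duration = config$cooldown_duration)
    out$time <- c(out$time, cool$time[-1] + config$exposure_duration)
    out$T_center <- c(out$T_center, cool$T_center[-1])
    out$T_tumor_max <- c(out$T_tumor_max, cool$T_tumor_max[-1])
    out$T_final <- cool$T
  } else {
    out$T_final <- T_end
  }
  out$T_end_exposure <- T_end
  tum <- phantom$labels == 6L
  out$tumor_max_end <- if (any(tum)) max(T_end[tum]) else NA_real_
  lt <- .label_rows(phantom$label_map)
  out$tissue_max <- vapply(lt$label, function(l) {
    m <- phantom$labels == l
    if (any(m)) max(T_end[m]) else NA_real_
  }, numeric(1))
  names(out$tissue_max) <- lt$tissue
  out$dt <- heat$dt
  out
}
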