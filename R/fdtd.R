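#' FDTD solver configuration
#'
#' Settings for the time-harmonic finite-difference time-domain solve of one
#' dipole's field.  The time step is set from the Courant bound
#' `courant * dx / (c sqrt(3))` and then rounded down so a source period is
#' an integer number of steps (unbiased phasor demodulation).  The solve
#' runs a raised-cosine source ramp, then demodulates the whole field at the
#' drive frequency over successive windows until the port phasors change by
#' less than `tol` between windows.
#'
#' @param spacing grid spacing (mm); defaults to the phantom's when a
#'   phantom is supplied to [fdtd_unit_field()]
#' @param margin air margin between the structure and the absorbing layers
#'   (mm)
#' @param pml_cells CPML thickness (cells per face)
#' @param courant Courant number fraction (of the 3-D stability limit)
#' @param ramp_periods source ramp-up length (periods)
#' @param window_periods demodulation window length (periods)
#' @param tol relative phasor drift between successive windows declaring
#'   steady state
#' @param max_windows maximum number of windows before giving up
#' @param pml_m CPML polynomial grading order
#' @param pml_sigma_factor CPML conductivity scale (fraction of the standard
#'   optimum)
#' @param pml_alpha CPML complex-frequency-shift parameter (S/m)
#' @param background homogeneous background medium (`eps_r`, `sigma`)
#'   filling the domain outside the phantom
#' @param on_nonconvergence `"error"` or `"warn"` when the phasor drift
#'   never falls below `tol`
#' @return list of class `solver_config`
#' @export
solver_config <- function(spacing = NULL, margin = 12, pml_cells = 8,
                          courant = 0.99, ramp_periods = 4,
                          window_periods = 4, tol = 1e-3, max_windows = 40,
                          pml_m = 3, pml_sigma_factor = 0.8,
                          pml_alpha = 0.15,
                          background = list(eps_r = 1, sigma = 0),
                          on_nonconvergence = "error") {
  structure(list(spacing = spacing, margin = margin, pml_cells = pml_cells,
                 courant = courant, ramp_periods = ramp_periods,
                 window_periods = window_periods, tol = tol,
                 max_windows = max_windows, pml_m = pml_m,
                 pml_sigma_factor = pml_sigma_factor, pml_alpha = pml_alpha,
                 background = background,
                 on_nonconvergence = on_nonconvergence),
            class = "solver_config")
}

# build the EM lattice (voxel centers on multiples of dx, in mm) covering
# the phantom / requested domain plus dipole, margin and PML
.em_lattice <- function(dipole, phantom, config, domain) {
  dx <- if (!is.null(phantom)) phantom$spacing else config$spacing
  if (is.null(dx)) stop("configuration error: spacing required without a phantom")
  n_arm <- max(1L, round(dipole$arm_length / dx))
  wire_x <- c(-n_arm * dx, (n_arm + 1) * dx)
  ext <- function(lo, hi) c(lo, hi)
  if (!is.null(phantom)) {
    co <- .grid_coords(phantom)
    xr <- range(co[[1]]); yr <- range(co[[2]]); zr <- range(co[[3]])
  } else if (!is.null(domain)) {
    xr <- domain$xlim; yr <- domain$ylim; zr <- domain$zlim
  } else {
    xr <- yr <- zr <- c(0, 0)
  }
  fy <- dipole$feed_position[2]; fz <- dipole$feed_position[3]
  xr <- range(c(xr, wire_x))
  yr <- range(c(yr, fy)); zr <- range(c(zr, fz))
  pad <- config$margin + config$pml_cells * dx
  snap <- function(r) {
    lo <- floor((r[1] - pad) / dx) * dx
    hi <- ceiling((r[2] + pad) / dx) * dx
    seq(lo, hi, by = dx)
  }
  list(xs = snap(xr), ys = snap(yr), zs = snap(zr), dx = dx)
}

# 0-based linear index into the EM lattice from 1-based (i,j,k)
.lin0 <- function(i, j, k, n) {
  as.integer((i - 1) + n[1] * ((j - 1) + n[2] * (k - 1)))
}

#' Complex unit field of one dipole via FDTD
#'
#' Solves the time-harmonic field of a single dipole antenna (PEC thin wire
#' with a resistive edge-port source) in the presence of a voxel phantom or
#' a homogeneous background, extracts the steady-state phasor at the drive
#' frequency, and normalizes the result to 1 W accepted port power so that
#' array superposition can use amplitudes A_n = sqrt(P_n / 1 W).
#'
#' The wire is a one-cell PEC line along x (arms `round(arm_length/dx)`
#' cells each, one-cell feed gap); the feed point is snapped to the lattice.
#' The returned field components are collocated at voxel centers.
#'
#' @param dipole a [dipole_spec()]
#' @param phantom optional `voxel_phantom` (its grid defines the returned
#'   field volume)
#' @param config a [solver_config()]
#' @param domain for phantom-free runs: list with `xlim`, `ylim`, `zlim`
#'   (mm) of the working region
#' @param normalize normalize to 1 W accepted power (default TRUE)
#' @return a [complex_field()] on the phantom grid (or the working region
#'   when no phantom is given), with attribute `diagnostics` (a list with
#'   `Z_in`, `accepted_power` of the raw solve, `windows`, `drift`,
#'   `converged`)
#' @export
fdtd_unit_field <- function(dipole, phantom = NULL,
                            config = solver_config(), domain = NULL,
                            normalize = TRUE) {
  lat <- .em_lattice(dipole, phantom, config, domain)
  dx <- lat$dx
  n <- c(length(lat$xs), length(lat$ys), length(lat$zs))
  nn <- prod(n)

  # wavelength resolution guard in the densest medium present
  eps_max <- config$background$eps_r
  if (!is.null(phantom)) eps_max <- max(eps_max, phantom$label_map$eps_r[!is.na(phantom$label_map$label)])
  lam_min <- .c0 / (dipole$frequency * sqrt(eps_max)) * 1000
  if (lam_min / dx < 8)
    warning(sprintf("coarse grid: %.1f cells per wavelength in the densest tissue",
                    lam_min / dx))

  eps <- rep(config$background$eps_r, nn)
  sig <- rep(config$background$sigma, nn)
  if (!is.null(phantom)) {
    gp <- phantom_property_grids(phantom)
    d <- dim(phantom$labels)
    off <- round((phantom$origin - c(lat$xs[1], lat$ys[1], lat$zs[1])) / dx)
    stopifnot(all(off >= 0), all(off + d <= n))
    ii <- rep(seq_len(d[1]) + off[1], times = d[2] * d[3])
    jj <- rep(rep(seq_len(d[2]) + off[2], each = d[1]), times = d[3])
    kk <- rep(seq_len(d[3]) + off[3], each = d[1] * d[2])
    idx <- ii + n[1] * (jj - 1) + n[1] * n[2] * (kk - 1)
    tissue <- phantom$labels != 0L
    eps[idx[tissue]] <- gp$eps_r[tissue]
    sig[idx[tissue]] <- gp$sigma[tissue]
  }

  # wire and feed on the lattice
  i0 <- which.min(abs(lat$xs - dipole$feed_position[1]))
  j0 <- which.min(abs(lat$ys - dipole$feed_position[2]))
  k0 <- which.min(abs(lat$zs - dipole$feed_position[3]))
  n_arm <- max(1L, round(dipole$arm_length / dx))
  arm_i <- c(seq(i0 - n_arm, i0 - 1), seq(i0 + 1, i0 + n_arm))
  if (any(arm_i < 2) || any(arm_i > n[1] - 1))
    stop("geometry error: dipole arms reach the domain boundary")
  pec <- .lin0(arm_i, j0, k0, n)
  feed <- .lin0(i0, j0, k0, n)
  if (!is.null(phantom) &&
      (sig[feed + 1] != config$background$sigma ||
       eps[feed + 1] != config$background$eps_r))
    stop("geometry error: phantom intersects the dipole feed")

  # convergence probes: a few cells between the feed and the domain center
  pr <- unique(c(
    .lin0(i0, max(j0 - round(n[2] / 4), 2), k0, n),
    .lin0(i0, round(n[2] / 2), round(n[3] / 2), n),
    .lin0(max(i0 - 3, 2), j0, max(k0 - round(n[3] / 4), 2), n)))

  res <- fdtd_harmonic_cpp(
    as.integer(n), dx / 1000, config$courant, eps, sig,
    pec, feed, dipole$source_resistance, dipole$frequency,
    dipole$amplitude, dipole$phase,
    config$pml_cells, config$pml_m, config$pml_sigma_factor,
    config$pml_alpha, config$background$eps_r,
    config$ramp_periods, config$window_periods, config$tol,
    config$max_windows, pr)

  if (!res$converged) {
    msg <- sprintf("convergence error: phasor drift %.2g after %d windows",
                   res$drift, res$windows)
    if (identical(config$on_nonconvergence, "error")) stop(msg)
    warning(msg)
  }

  # accepted power from the port circuit: source EMF power minus the drop
  # across the internal resistance
  Vs <- dipole$amplitude * exp(1i * dipole$phase * pi / 180)
  V <- res$V; I <- res$I
  P_acc <- 0.5 * Re(Vs * Conj(I)) - 0.5 * Mod(I)^2 * dipole$source_resistance
  Z_in <- V / I

  E <- array(0i, c(n, 3L))
  E[, , , 1] <- .collocate(array(res$Ex, n), 1)
  E[, , , 2] <- .collocate(array(res$Ey, n), 2)
  E[, , , 3] <- .collocate(array(res$Ez, n), 3)

  origin <- c(lat$xs[1], lat$ys[1], lat$zs[1])
  if (!is.null(phantom)) {
    d <- dim(phantom$labels)
    off <- round((phantom$origin - origin) / dx)
    E <- E[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
           off[3] + seq_len(d[3]), , drop = FALSE]
    origin <- phantom$origin
  } else if (!is.null(domain)) {
    keep <- function(coords, lim) which(coords >= lim[1] & coords <= lim[2])
    ix <- keep(lat$xs, domain$xlim); iy <- keep(lat$ys, domain$ylim)
    iz <- keep(lat$zs, domain$zlim)
    E <- E[ix, iy, iz, , drop = FALSE]
    origin <- c(lat$xs[ix[1]], lat$ys[iy[1]], lat$zs[iz[1]])
  }

  if (P_acc <= 0) stop("non-positive accepted port power")
  fld <- complex_field(E, dx, origin,
                       accepted_power = P_acc,
                       frequency = dipole$frequency)
  if (normalize) fld <- normalize_to_power(fld, P_acc)
  attr(fld, "diagnostics") <- list(
    Z_in = Z_in, accepted_power = P_acc, windows = res$windows,
    drift = res$drift, converged = res$converged,
    V = V, I = I, dt = res$dt, steps_per_period = res$steps_per_period,
    feed_snapped = c(lat$xs[i0], lat$ys[j0], lat$zs[k0]))
  fld
}

# average staggered Yee components back to voxel centers along their axis
.collocate <- function(A, axis) {
  n <- dim(A)
  idx <- function(shift) {
    i <- pmax(seq_len(n[axis]) - shift, 1)
    switch(axis,
           A[i, , , drop = FALSE],
           A[, i, , drop = FALSE],
           A[, , i, drop = FALSE])
  }
  (idx(0) + idx(1)) / 2
}

#' Port reflection and input impedance sweep
#'
#' Runs a broadband (Gaussian-modulated) excitation of a single dipole and
#' returns the input impedance Z_in(f) = V(f)/I(f) and the reflection
#' coefficient S11(f) against a 50 Ohm reference from the Fourier-transformed
#' port voltage and current.
#'
#' @param dipole a [dipole_spec()]
#' @param config a [solver_config()] (`spacing` must be set)
#' @param domain working-region limits as in [fdtd_unit_field()]
#' @param f_range frequency band to report (Hz)
#' @param f_center,bandwidth source pulse center and bandwidth (Hz)
#' @param nsteps number of time steps (must cover the ringdown)
#' @param Zref reference impedance for S11 (Ohm)
#' @return data.frame with `freq` (Hz), `S11_dB`, `R` and `X` (Ohm), plus
#'   attributes `resonance` (frequency of minimum S11) and `S11_min_dB`
#' @export
port_metrics <- function(dipole, config = solver_config(spacing = 2),
                         domain = list(xlim = c(-100, 100),
                                       ylim = c(-50, 50),
                                       zlim = c(-50, 50)),
                         f_range = c(0.8e9, 1.8e9),
                         f_center = 1.3e9, bandwidth = 0.7e9,
                         nsteps = 6000, Zref = 50) {
  lat <- .em_lattice(dipole, NULL, config, domain)
  dx <- lat$dx
  n <- c(length(lat$xs), length(lat$ys), length(lat$zs))
  eps <- rep(config$background$eps_r, prod(n))
  sig <- rep(config$background$sigma, prod(n))
  i0 <- which.min(abs(lat$xs - dipole$feed_position[1]))
  j0 <- which.min(abs(lat$ys - dipole$feed_position[2]))
  k0 <- which.min(abs(lat$zs - dipole$feed_position[3]))
  n_arm <- max(1L, round(dipole$arm_length / dx))
  arm_i <- c(seq(i0 - n_arm, i0 - 1), seq(i0 + 1, i0 + n_arm))
  pec <- .lin0(arm_i, j0, k0, n)
  feed <- .lin0(i0, j0, k0, n)

  res <- fdtd_port_cpp(as.integer(n), dx / 1000, config$courant, eps, sig,
                       pec, feed, dipole$source_resistance,
                       f_center, bandwidth, dipole$amplitude,
                       config$pml_cells, config$pml_m,
                       config$pml_sigma_factor, config$pml_alpha,
                       config$background$eps_r, nsteps)
  np <- 2^ceiling(log2(length(res$V) * 4))
  freq <- (seq_len(np) - 1) / (np * res$dt)
  Vf <- fft(c(res$V, rep(0, np - length(res$V))))
  If <- fft(c(res$I, rep(0, np - length(res$I))))
  keep <- freq >= f_range[1] & freq <= f_range[2]
  if (max(Mod(If[keep])) == 0) stop("singular-impedance error: zero port current")
  Z <- Vf[keep] / If[keep]
  s11 <- reflection_db(Z, Zref)
  out <- data.frame(freq = freq[keep], S11_dB = s11,
                    R = Re(Z), X = Im(Z))
  attr(out, "resonance") <- out$freq[which.min(out$S11_dB)]
  attr(out, "S11_min_dB") <- min(out$S11_dB)
  out
}

#' Reflection coefficient in dB against a reference impedance
#'
#' S11 = (Z - Zref) / (Z + Zref); a perfectly matched load gives -Inf dB,
#' reported as `floor_db`.
#'
#' @param Z complex input impedance(s), Ohm
#' @param Zref reference impedance, Ohm
#' @param floor_db value reported for a perfect match
#' @return magnitude of S11 in dB
#' @export
reflection_db <- function(Z, Zref = 50, floor_db = -150) {
  g <- Mod((Z - Zref) / (Z + Zref))
  db <- ifelse(g <= 10^(floor_db / 20), floor_db, 20 * log10(g))
  pmax(db, floor_db)
}
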