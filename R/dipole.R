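#' Shortened half-wave dipole specification
#'
#' Geometry and drive of one applicator: two symmetric arms of length
#' `arm_length` along the x direction, a feed gap of length `gap` between
#' them, driven by a sinusoidal voltage source of amplitude `amplitude` with
#' a 50 Ohm internal resistance.  The default arm length corresponds to a
#' 1 GHz half-wave dipole shortened by the factor `k_s`:
#' 2 * arm_length + gap ~ k_s * lambda / 2 with k_s = 0.67.
#'
#' @param feed_position mm coordinates of the feed-gap center
#' @param arm_length arm length L_d (mm)
#' @param wire_radius wire radius (mm)
#' @param gap feed gap length d (mm)
#' @param axis dipole axis unit vector (arms extend along it)
#' @param source_resistance source internal resistance (Ohm)
#' @param frequency drive frequency (Hz)
#' @param amplitude source voltage amplitude A_m (V)
#' @param phase source phase (deg)
#' @param k_s shortening factor relative to the resonant half-wave length
#' @return object of class `dipole_spec`
#' @export
dipole_spec <- function(feed_position = c(0, 0, 0), arm_length = 50,
                        wire_radius = 1, gap = 1, axis = c(1, 0, 0),
                        source_resistance = 50, frequency = 1e9,
                        amplitude = 1, phase = 0, k_s = 0.67) {
  structure(list(feed_position = feed_position, arm_length = arm_length,
                 wire_radius = wire_radius, gap = gap,
                 axis = axis / sqrt(sum(axis^2)),
                 source_resistance = source_resistance,
                 frequency = frequency, amplitude = amplitude,
                 phase = phase, k_s = k_s),
            class = "dipole_spec")
}

#' Ring array geometry
#'
#' @param n_antennas number of dipoles
#' @param ring_radius ring radius R (mm); feed points lie on a circle of this
#'   radius in the x = 0 plane
#' @param start_angle angular position of antenna 1 (deg, measured from +y
#'   toward +z)
#' @return object of class `array_geometry`
#' @export
array_geometry <- function(n_antennas = 8, ring_radius = 100,
                           start_angle = 0) {
  structure(list(n_antennas = n_antennas, ring_radius = ring_radius,
                 angles = start_angle + (seq_len(n_antennas) - 1) *
                   360 / n_antennas),
            class = "array_geometry")
}

#' Place the dipole ring around a phantom
#'
#' Returns one [dipole_spec()] per antenna with feed points evenly spaced on
#' the ring `(0, R cos(theta_k), R sin(theta_k))` and arms along x.
#'
#' @param geometry an [array_geometry()]
#' @param phantom optional `voxel_phantom`; if given, every wire is checked
#'   for intersection with tissue voxels
#' @param ... further arguments passed to [dipole_spec()]
#' @return list of `dipole_spec`
#' @export
place_array <- function(geometry, phantom = NULL, ...) {
  th <- geometry$angles * pi / 180
  specs <- lapply(seq_len(geometry$n_antennas), function(k) {
    dipole_spec(feed_position = c(0, geometry$ring_radius * cos(th[k]),
                                  geometry$ring_radius * sin(th[k])), ...)
  })
  if (!is.null(phantom)) {
    co <- .grid_coords(phantom)
    h <- specs[[1]]$gap / 2 + specs[[1]]$arm_length
    for (s in specs) {
      near <- abs(co[[2]] - s$feed_position[2]) <= phantom$spacing / 2
      nearz <- abs(co[[3]] - s$feed_position[3]) <= phantom$spacing / 2
      inx <- abs(co[[1]]) <= h
      if (any(near) && any(nearz) && any(inx) &&
          any(phantom$labels[inx, near, nearz] != 0L))
        stop("geometry error: phantom intersects a dipole wire")
    }
  }
  specs
}

#' Analytic field of a center-fed thin-wire dipole
#'
#' Closed-form near/far field of a finite dipole with the assumed sinusoidal
#' current distribution I(s) = I0 sin(k (h - |s|)) (h = arm length + gap/2)
#' in a homogeneous, possibly lossy medium, using the complex wavenumber
#' k = omega sqrt(mu0 eps_c) with eps_c = eps0 (eps_r - j sigma / (omega
#' eps0)) and intrinsic impedance eta = sqrt(mu0 / eps_c).  This is the
#' standard induced-EMF near-field solution; it serves as the validation
#' oracle for the FDTD solver.
#'
#' @param dipole a [dipole_spec()]
#' @param medium list or tissue-table row with `eps_r` and `sigma`
#' @param points n x 3 matrix of mm coordinates
#' @param I0 current-distribution maximum I0 (A)
#' @return n x 3 complex matrix of E-field components (V/m), using the
#'   exp(+j omega t) phasor convention
#' @export
analytic_dipole_field <- function(dipole, medium, points, I0 = 1) {
  points <- matrix(points, ncol = 3)
  w <- 2 * pi * dipole$frequency
  eps_c <- .eps0 * (medium$eps_r - 1i * medium$sigma / (w * .eps0))
  k <- w * sqrt(.mu0 * eps_c)     # principal root: Re > 0, Im < 0 for loss
  if (Re(k) < 0) k <- -k
  eta <- sqrt(.mu0 / eps_c)
  h <- (dipole$arm_length + dipole$gap / 2) / 1000   # half length, m

  # local cylindrical coordinates about the dipole axis
  ax <- dipole$axis
  rel <- sweep(points, 2, dipole$feed_position) / 1000
  z <- rel %*% ax                                   # axial coordinate, m
  rad_vec <- rel - outer(as.vector(z), ax)
  rho <- sqrt(rowSums(rad_vec^2))
  inside <- rho * 1000 < dipole$wire_radius &
    abs(z) * 1000 <= dipole$arm_length + dipole$gap / 2
  if (any(inside))
    stop("domain error: point inside the wire radius")

  R1 <- sqrt(rho^2 + (z - h)^2)
  R2 <- sqrt(rho^2 + (z + h)^2)
  r0 <- sqrt(rho^2 + z^2)
  ckh <- cos(k * h)
  Ez <- -1i * eta * I0 / (4 * pi) *
    (exp(-1i * k * R1) / R1 + exp(-1i * k * R2) / R2 -
       2 * ckh * exp(-1i * k * r0) / r0)
  on_axis <- rho < 1e-12
  rho_safe <- ifelse(on_axis, 1, rho)
  Erho <- 1i * eta * I0 / (4 * pi * rho_safe) *
    ((z - h) * exp(-1i * k * R1) / R1 + (z + h) * exp(-1i * k * R2) / R2 -
       2 * z * ckh * exp(-1i * k * r0) / r0)
  Erho[on_axis] <- 0                                # symmetry: no transverse
  rho_hat <- rad_vec / rho_safe
  rho_hat[on_axis, ] <- 0
  out <- outer(as.vector(Ez), ax) + as.vector(Erho) * rho_hat
  out
}
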