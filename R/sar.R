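#' Complex field volume constructor
#'
#' Wraps a per-voxel complex 3-vector electric field (V/m) for one antenna
#' driven at unit accepted power, together with its grid metadata.
#'
#' @param E complex array of dimension `c(nx, ny, nz, 3)` (x, y, z field
#'   components)
#' @param spacing voxel edge length (mm)
#' @param origin mm coordinates of the center of voxel `[1,1,1]`
#' @param accepted_power accepted port power (W) the field corresponds to
#' @param antenna antenna index
#' @param frequency excitation frequency (Hz)
#' @return object of class `complex_field`
#' @export
complex_field <- function(E, spacing, origin, accepted_power = 1,
                          antenna = NA_integer_, frequency = 1e9) {
  stopifnot(length(dim(E)) == 4, dim(E)[4] == 3)
  structure(list(E = E, spacing = spacing, origin = origin,
                 accepted_power = accepted_power, antenna = antenna,
                 frequency = frequency),
            class = "complex_field")
}

#' Pointwise specific absorption rate
#'
#' SAR = sigma * |E|^2 / (2 rho), with |E|^2 the sum of squared moduli of
#' the three complex field components (peak-amplitude phasor convention).
#'
#' @param E complex 3-vector, or an array whose last dimension has length 3
#' @param sigma electrical conductivity (S/m), scalar or per-voxel
#' @param rho mass density (kg/m^3), scalar or per-voxel; must be positive
#' @return SAR in W/kg (same shape as one field component)
#' @export
#' @examples
#' pointwise_sar(c(100 + 0i, 0, 0), sigma = 0.978, rho = 1090)
pointwise_sar <- function(E, sigma, rho) {
  if (any(rho <= 0)) stop("rho must be positive")
  d <- dim(E)
  if (is.null(d)) {
    mag2 <- sum(Mod(E)^2)
  } else {
    n <- prod(d[-length(d)])
    Em <- matrix(E, nrow = n)
    mag2 <- rowSums(Mod(Em)^2)
    if (length(d) > 2) dim(mag2) <- d[-length(d)]
  }
  sigma * mag2 / (2 * rho)
}

#' Per-antenna excitation (powers and phases)
#'
#' The optimizer's decision variables: per-antenna input power P_i (W) and
#' source phase phi_i (degrees, in (-180, 180]).  The implied complex
#' amplitude is A_i = sqrt(P_i / 1 W) * exp(j * phi_i).
#'
#' @param powers numeric vector of non-negative powers (W)
#' @param phases numeric vector of phases (degrees)
#' @return object of class `excitation`
#' @export
excitation <- function(powers, phases = rep(0, length(powers))) {
  stopifnot(length(powers) == length(phases))
  if (any(powers < 0)) stop("powers must be non-negative")
  if (any(phases < -180 - 1e-9 | phases > 180 + 1e-9))
    stop("phases must lie in [-180, 180] degrees")
  structure(list(powers = as.numeric(powers), phases = as.numeric(phases)),
            class = "excitation")
}

#' @export
print.excitation <- function(x, ...) {
  cat(sprintf("excitation: %d antennas, total power %.4f W\n",
              length(x$powers), sum(x$powers)))
  print(data.frame(antenna = seq_along(x$powers),
                   power_W = round(x$powers, 4),
                   phase_deg = round(x$phases, 4)))
  invisible(x)
}

# complex amplitude vector A_n = sqrt(P_n) exp(j phi_n)
.amplitudes <- function(exc) {
  sqrt(exc$powers) * exp(1i * exc$phases * pi / 180)
}

# complex amplitudes -> excitation, phase gauged to the reference antenna
.as_excitation <- function(A, reference = length(A), total_power = NULL) {
  P <- Mod(A)^2
  if (!is.null(total_power)) P <- P * total_power / sum(P)
  ph <- Arg(A) - Arg(A[reference])
  ph[Mod(A) == 0] <- 0
  ph <- (ph / pi * 180 + 180) %% 360 - 180
  ph[ph == -180] <- 180
  ph[reference] <- 0
  excitation(P, ph)
}

#' Superpose per-antenna unit fields under an excitation
#'
#' E(r) = sum_n A_n exp(j phi_n) E_n(r), componentwise, where E_n are the
#' unit-power per-antenna fields.
#'
#' @param unit_fields list of `complex_field` objects on a common grid
#' @param exc an [excitation()]
#' @return a `complex_field` of the combined array field
#' @export
combine_fields <- function(unit_fields, exc) {
  stopifnot(length(unit_fields) == length(exc$powers))
  f1 <- unit_fields[[1]]
  for (f in unit_fields) {
    if (!identical(dim(f$E), dim(f1$E)) ||
        !isTRUE(all.equal(f$spacing, f1$spacing)) ||
        !isTRUE(all.equal(f$origin, f1$origin)))
      stop("grid mismatch between unit fields")
  }
  A <- .amplitudes(exc)
  E <- array(0i, dim(f1$E))
  for (n in seq_along(unit_fields)) {
    if (A[n] != 0) E <- E + A[n] * unit_fields[[n]]$E
  }
  complex_field(E, f1$spacing, f1$origin, accepted_power = sum(exc$powers),
                antenna = NA_integer_, frequency = f1$frequency)
}

#' Region-averaged SAR as an excitation-independent Hermitian form
#'
#' Precomputes the N x N Hermitian matrix H with entries
#' H_mn = (1/M) sum_l [sigma_l / (2 rho_l)] conj(E_m(r_l)) . E_n(r_l)
#' over the M voxels of a region, so that the region-mean SAR of any
#' excitation A is the real quadratic form Re(A^H H A) -- independent of the
#' antenna amplitudes and phases used to build it.  The polar decomposition
#' of the entries (modulus `beta` and argument `Omega`) is available through
#' [form_polar()].
#'
#' @param unit_fields list of `complex_field` objects (unit accepted power)
#' @param region_mask logical array (or integer indices) selecting the voxels
#'   of the region
#' @param sigma,rho per-voxel conductivity (S/m) and density (kg/m^3) arrays
#'   on the same grid (see [phantom_property_grids()])
#' @param region_id optional label for the region
#' @return object of class `sar_form`: list with the Hermitian `H`,
#'   `n_voxels` (M) and `region_id`
#' @export
sar_quadratic_form <- function(unit_fields, region_mask, sigma, rho,
                               region_id = NULL) {
  idx <- if (is.logical(region_mask)) which(region_mask) else as.integer(region_mask)
  M <- length(idx)
  if (M == 0) stop("empty region")
  N <- length(unit_fields)
  nvox <- prod(dim(unit_fields[[1]]$E)[1:3])
  w <- as.numeric(sigma)[idx] / (2 * as.numeric(rho)[idx])
  # F[[n]]: M x 3 complex component matrix of antenna n over the region
  F <- lapply(unit_fields, function(f) {
    Em <- matrix(f$E, nrow = nvox)
    Em[idx, , drop = FALSE]
  })
  H <- matrix(0i, N, N)
  for (m in seq_len(N)) {
    Fmw <- Conj(F[[m]]) * w
    for (n in m:N) {
      H[m, n] <- sum(Fmw * F[[n]]) / M
      if (n > m) H[n, m] <- Conj(H[m, n])
    }
  }
  # enforce exactly real diagonal (roundoff from the sum above)
  diag(H) <- Re(diag(H))
  structure(list(H = H, n_voxels = M, region_id = region_id),
            class = "sar_form")
}

#' @rdname sar_quadratic_form
#' @param form a `sar_form`
#' @return `form_polar`: list of matrices `beta` (moduli, W/kg per W) and
#'   `Omega` (arguments, radians)
#' @export
form_polar <- function(form) {
  list(beta = Mod(form$H), Omega = Arg(form$H))
}

#' Region-mean SAR of an excitation
#'
#' Evaluates Re(A^H H A) with A_n = sqrt(P_n) exp(j phi_n); equals the voxel
#' mean of the pointwise SAR of the combined field over the form's region.
#'
#' @param form a [sar_quadratic_form()]
#' @param exc an [excitation()]
#' @return mean SAR over the region (W/kg)
#' @export
sar_vol <- function(form, exc) {
  A <- .amplitudes(exc)
  stopifnot(length(A) == nrow(form$H))
  v <- Re(Conj(A) %*% form$H %*% A)[1]
  if (v < -1e-9 * max(Mod(form$H)) * sum(exc$powers))
    stop("internal-consistency error: negative region SAR")
  max(v, 0)
}

#' Voxelwise SAR map and normalized dB map
#'
#' Computes the pointwise SAR of a combined field over the phantom, and the
#' map normalized to its maximum on a decibel scale,
#' 10 log10(SAR / SAR_max).  Air voxels are masked to `NA`.
#'
#' @param unit_fields list of per-antenna unit fields
#' @param exc an [excitation()]
#' @param phantom the `voxel_phantom` the fields were computed on
#' @return list with `sar` (W/kg), `db` (dB, max 0), and `sar_max`
#' @export
sar_map <- function(unit_fields, exc, phantom) {
  E <- combine_fields(unit_fields, exc)
  gp <- phantom_property_grids(phantom)
  sar <- pointwise_sar(E$E, gp$sigma, pmax(gp$rho, 1))
  sar[phantom$labels == 0L] <- NA_real_
  smax <- max(sar, na.rm = TRUE)
  if (!is.finite(smax) || smax <= 0) stop("all-zero SAR: dB map undefined")
  list(sar = sar, db = 10 * log10(sar / smax), sar_max = smax)
}

#' Per-voxel dielectric and thermal property grids of a phantom
#'
#' Expands the label array into per-voxel property arrays (air voxels get
#' vacuum dielectrics and zero thermal properties).
#'
#' @param phantom a `voxel_phantom`
#' @return list of arrays: `eps_r`, `sigma`, `rho`, `C`, `k`, `perfusion`
#'   (W/m^3/K; 0 in the tumor, whose perfusion is temperature-dependent),
#'   `hgr_vol` (rho * HGR, W/m^3)
#' @export
phantom_property_grids <- function(phantom) {
  tab <- phantom$label_map
  lab <- phantom$labels
  eps_r <- .property_grid(lab, tab, "eps_r", air = 1)
  sigma <- .property_grid(lab, tab, "sigma", air = 0)
  rho   <- .property_grid(lab, tab, "rho", air = 0)
  Cp    <- .property_grid(lab, tab, "C", air = 0)
  kk    <- .property_grid(lab, tab, "k", air = 0)
  tabp <- tab
  tabp$perfusion[is.na(tabp$perfusion)] <- 0   # tumor handled nonlinearly
  perf <- .property_grid(lab, tabp, "perfusion", air = 0)
  hgr <- .property_grid(lab, tab, "HGR", air = 0) * rho
  list(eps_r = eps_r, sigma = sigma, rho = rho, C = Cp, k = kk,
       perfusion = perf, hgr_vol = hgr)
}

#' Rescale a field volume to unit accepted power
#'
#' Scales the complex field by 1/sqrt(measured port power) so downstream
#' superposition can use amplitudes A_n = sqrt(P_n / 1 W).
#'
#' @param field a `complex_field`
#' @param measured_port_power accepted port power (W) of the raw solve
#' @return the normalized `complex_field` (accepted_power = 1)
#' @export
normalize_to_power <- function(field, measured_port_power) {
  if (!is.numeric(measured_port_power) || measured_port_power <= 0)
    stop("measured port power must be positive")
  field$E <- field$E / sqrt(measured_port_power)
  field$accepted_power <- 1
  field
}
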