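#' Dielectric and thermal tissue parameter table
#'
#' Returns the tissue property table used throughout the planning pipeline:
#' relative permittivity and electrical conductivity at 1 GHz, mass density,
#' specific heat, thermal conductivity, blood heat transfer rate (HTR) and
#' metabolic heat generation rate (HGR) for the tissues of a female breast
#' phantom, plus arterial blood.  The tumor entry carries the muscle
#' dielectric and thermal constants; its perfusion is temperature-dependent
#' (see [tumor_perfusion()]) and is therefore flagged rather than given a
#' constant HTR.
#'
#' The `perfusion` column is the volumetric perfusion coefficient
#' rho_b * C_b * rho * HTR (W/m^3/K) computed by [perfusion_coefficient()]
#' with arterial blood density 1050 kg/m^3 and specific heat 3617 J/kg/K.
#'
#' @param rho_b arterial blood mass density (kg/m^3)
#' @param C_b arterial blood specific heat (J/kg/K)
#' @return A data.frame with one row per tissue and columns `tissue`,
#'   `label` (integer voxel label; `NA` for blood, which is not a spatial
#'   tissue), `eps_r`, `sigma` (S/m), `rho` (kg/m^3), `C` (J/kg/K),
#'   `k` (W/m/K), `HTR` (mL/min/kg; `NA` for the tumor), `HGR` (W/kg),
#'   `perfusion` (W/m^3/K) and `htr_temp_dependent` (logical).
#' @export
#' @examples
#' tab <- tissue_table()
#' tab[tab$tissue == "gland", c("sigma", "rho", "HTR")]
tissue_table <- function(rho_b = 1050, C_b = 3617) {
  tab <- data.frame(
    tissue = c("blood", "breast_fat", "gland", "fat", "muscle", "skin", "tumor"),
    label  = c(NA_integer_, 3L, 4L, 2L, 5L, 1L, 6L),
    eps_r  = c(61.06, 5.41, 59.47, 11.29, 54.81, 40.94, 54.81),
    sigma  = c(1.583, 0.053, 1.079, 0.116, 0.978, 0.900, 0.978),
    rho    = c(1050, 911, 1041, 911, 1090, 1109, 1090),
    C      = c(3617, 2348, 2960, 2348, 3421, 3391, 3421),
    k      = c(0.517, 0.209, 0.334, 0.211, 0.495, 0.372, 0.495),
    HTR    = c(10000, 47, 150, 33, 37, 106, NA_real_),
    HGR    = c(0, 0.728, 2.323, 0.507, 0.906, 1.648, 0.906),
    stringsAsFactors = FALSE
  )
  tab$htr_temp_dependent <- tab$tissue == "tumor"
  tab$perfusion <- NA_real_
  ok <- !is.na(tab$HTR)
  tab$perfusion[ok] <- perfusion_coefficient(tab$rho[ok], tab$HTR[ok],
                                             rho_b = rho_b, C_b = C_b)
  tab
}

#' Volumetric blood-perfusion coefficient
#'
#' Converts a tissue's heat transfer rate HTR (mL/min/kg) into the volumetric
#' perfusion coefficient rho_b * C_b * rho * HTR_SI (W/m^3/K) that multiplies
#' the (T_b - T) sink term of the Pennes bioheat equation.  The unit
#' conversion is HTR_SI = HTR * 1e-6 / 60 (m^3/s/kg).
#'
#' @param rho tissue mass density (kg/m^3), or a one-row tissue-table entry
#'   (anything with `$rho` and `$HTR`) in which case `HTR` is taken from it
#' @param HTR heat transfer rate (mL/min/kg)
#' @param rho_b arterial blood mass density (kg/m^3)
#' @param C_b arterial blood specific heat (J/kg/K)
#' @return perfusion coefficient(s) in W/m^3/K (unrounded)
#' @export
#' @examples
#' # breast gland: prints as 9884 W/m^3/K
#' round(perfusion_coefficient(1041, 150))
perfusion_coefficient <- function(rho, HTR = NULL, rho_b = 1050, C_b = 3617) {
  if (is.list(rho)) {
    props <- rho
    rho <- props$rho
    if (is.null(HTR)) HTR <- props$HTR
  }
  if (any(is.na(HTR))) stop("HTR is undefined (temperature-dependent entry?)")
  if (any(HTR < 0)) stop("HTR must be non-negative")
  if (any(rho < 0)) stop("rho must be non-negative")
  rho_b * C_b * rho * HTR * 1e-6 / 60
}

#' Write the tissue table as CSV
#'
#' Exports the tissue parameter table with columns in the conventional order
#' (permittivity, conductivity, density, specific heat, thermal conductivity,
#' HTR, perfusion coefficient, HGR).
#'
#' @param tab tissue table from [tissue_table()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_tissue_csv <- function(tab, path) {
  out <- tab[, c("tissue", "eps_r", "sigma", "rho", "C", "k",
                 "HTR", "perfusion", "HGR")]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# label -> row lookup helpers used by the solvers
.label_rows <- function(tab) {
  tab <- tab[!is.na(tab$label), ]
  tab[order(tab$label), ]
}

# per-voxel property grid for a labeled phantom (0 = air -> `air` value)
.property_grid <- function(labels, tab, field, air = 0) {
  lt <- .label_rows(tab)
  lut <- rep(air, max(lt$label) + 1L)
  lut[lt$label + 1L] <- lt[[field]]
  arr <- lut[as.integer(labels) + 1L]
  dim(arr) <- dim(labels)
  arr
}
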