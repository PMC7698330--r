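#' Write / read a complex field volume as paired NIfTI volumes
#'
#' Stores the three complex components as six scalar NIfTI volumes
#' (`<stem>_Ex_re.nii`, `<stem>_Ex_im.nii`, ...) with the voxel spacing in
#' each header, plus a JSON sidecar (`<stem>.json`) carrying the grid
#' origin, normalization and antenna index.
#'
#' @param field a [complex_field()]
#' @param stem output path stem (no extension)
#' @return `stem` invisibly (`write_field`); a `complex_field` (`read_field`)
#' @export
write_field <- function(field, stem) {
  comp <- c("Ex", "Ey", "Ez")
  for (c_i in 1:3) {
    for (part in c("re", "im")) {
      arr <- if (part == "re") Re(field$E[, , , c_i]) else Im(field$E[, , , c_i])
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- rep(field$spacing, 3)
      RNifti::writeNifti(img, sprintf("%s_%s_%s.nii", stem, comp[c_i], part))
    }
  }
  meta <- list(spacing = field$spacing, origin = field$origin,
               accepted_power = field$accepted_power,
               antenna = field$antenna, frequency = field$frequency)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(stem)
}

#' @rdname write_field
#' @export
read_field <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  comp <- c("Ex", "Ey", "Ez")
  parts <- lapply(comp, function(cc) {
    re <- array(RNifti::readNifti(sprintf("%s_%s_re.nii", stem, cc)))
    im <- array(RNifti::readNifti(sprintf("%s_%s_im.nii", stem, cc)))
    complex(real = re, imaginary = im)
  })
  d <- dim(RNifti::readNifti(sprintf("%s_Ex_re.nii", stem)))
  E <- array(c(parts[[1]], parts[[2]], parts[[3]]), c(d, 3))
  fld <- complex_field(E, meta$spacing, unlist(meta$origin),
                       accepted_power = meta$accepted_power,
                       antenna = if (is.null(meta$antenna)) NA_integer_ else meta$antenna,
                       frequency = meta$frequency)
  fld
}

#' Write / read a SAR quadratic form as JSON
#'
#' The Hermitian matrix is stored as real and imaginary parts together with
#' the region metadata.
#'
#' @param form a [sar_quadratic_form()]
#' @param path output `.json` path
#' @return `path` invisibly (`write_form`); a `sar_form` (`read_form`)
#' @export
write_form <- function(form, path) {
  obj <- list(H_re = Re(form$H), H_im = Im(form$H),
              n_voxels = form$n_voxels, region_id = form$region_id)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_form
#' @export
read_form <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(complex(real = obj$H_re, imaginary = obj$H_im),
              nrow = nrow(obj$H_re))
  structure(list(H = H, n_voxels = obj$n_voxels,
                 region_id = obj$region_id),
            class = "sar_form")
}

#' Write an excitation as a settings table
#'
#' CSV with the antenna number, input power (W) and source phase (deg) --
#' the schema of a published optimal-settings table.
#'
#' @param exc an [excitation()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_excitation_csv <- function(exc, path) {
  write.csv(data.frame(antenna = seq_along(exc$powers),
                       power_W = exc$powers,
                       phase_deg = exc$phases),
            path, row.names = FALSE)
  invisible(path)
}
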