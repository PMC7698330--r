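# Shared fixtures.  Heavy FDTD-based results are computed once per test run
# and cached, so several test files can assert on the same sweep.

fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, builder) {
  if (!exists(name, fixture_cache)) assign(name, builder(), fixture_cache)
  get(name, fixture_cache)
}

# uniform rectangular block phantom of a single tissue, optionally with
# overridden thermal constants (e.g. zero perfusion for diffusion-only tests)
block_phantom <- function(tissue = "muscle", n = c(12, 12, 12), spacing = 3,
                          HTR = NULL, HGR = NULL) {
  tab <- tissue_table()
  if (!is.null(HTR)) tab$HTR[tab$tissue == tissue] <- HTR
  if (!is.null(HGR)) tab$HGR[tab$tissue == tissue] <- HGR
  tab$perfusion <- NA_real_
  ok <- !is.na(tab$HTR)
  tab$perfusion[ok] <- perfusion_coefficient(tab$rho[ok], tab$HTR[ok])
  lab <- array(tab$label[tab$tissue == tissue], n)
  structure(list(labels = lab, spacing = spacing, origin = c(0, 0, 0),
                 label_map = tab, tumor_center = c(0, 0, 0),
                 tumor_radius = 0, composition_class = "HD",
                 core_mask = NULL),
            class = "voxel_phantom")
}

# seeded synthetic per-antenna complex field volumes on a small grid
synthetic_unit_fields <- function(n_antennas = 8, dims = c(10, 10, 10),
                                  seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_antennas), function(i) {
    E <- array(complex(real = rnorm(prod(dims) * 3),
                       imaginary = rnorm(prod(dims) * 3)),
               c(dims, 3))
    complex_field(E, spacing = 3, origin = c(0, 0, 0), antenna = i)
  })
}

# seeded random feasible excitation (powers summing to `total`)
random_excitation <- function(n = 8, total = 8) {
  p <- runif(n)
  excitation(p / sum(p) * total, runif(n, -180, 180))
}

# independent brute-force oracle: explicit superposition + pointwise SAR,
# plain loops, no package vectorization
brute_mean_sar <- function(unit_fields, exc, sigma, rho, idx) {
  A <- sqrt(exc$powers) * exp(1i * exc$phases * pi / 180)
  tot <- 0
  for (l in idx) {
    E <- c(0i, 0i, 0i)
    for (n in seq_along(unit_fields)) {
      d <- dim(unit_fields[[n]]$E)
      nvox <- prod(d[1:3])
      for (comp in 1:3)
        E[comp] <- E[comp] + A[n] * unit_fields[[n]]$E[l + (comp - 1) * nvox]
    }
    tot <- tot + sigma[l] / (2 * rho[l]) * sum(Mod(E)^2)
  }
  tot / length(idx)
}

# random Hermitian positive (semi)definite matrix fixtures
random_psd <- function(n, rank = n, scale = 1) {
  G <- matrix(complex(real = rnorm(n * rank), imaginary = rnorm(n * rank)),
              rank, n)
  H <- t(Conj(G)) %*% G / rank * scale
  (H + t(Conj(H))) / 2
}

as_form <- function(H, M = 100, id = NULL) {
  structure(list(H = H, n_voxels = M, region_id = id), class = "sar_form")
}

# published optimized array settings (reference data for convention checks)
table2_path <- function() {
  system.file("extdata", "optimized_settings_reference.csv",
              package = "sarfocus")
}

# the default-condition radius sweep used by the pipeline and acceptance
# tests: default HD phantom at 3 mm, unit fields recomputed per radius
default_sweep <- function() {
  cache_get("sweep", function() {
    cfg <- pipeline_config(field_mode = "per-radius",
                           solver = solver_config(),
                           thermal = thermal_config())
    run_radius_sweep(cfg, verbose = FALSE)
  })
}

# a vacuum unit-field solve shared by the EM validation tests
vacuum_field <- function() {
  cache_get("vacuum", function() {
    fdtd_unit_field(dipole_spec(), phantom = NULL,
                    config = solver_config(spacing = 4, margin = 16),
                    domain = list(xlim = c(-90, 90), ylim = c(-90, 90),
                                  zlim = c(-90, 90)))
  })
}

field_coords <- function(fld) {
  d <- dim(fld$E)
  lapply(1:3, function(a) fld$origin[a] + (seq_len(d[a]) - 1) * fld$spacing)
}
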