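#' Tumor-to-healthy SAR optimization problem
#'
#' Bundles the tumor and healthy-region SAR quadratic forms with the array
#' power budget and phase gauge used when converting the optimal complex
#' amplitudes back to per-antenna powers and phases.
#'
#' @param H_tumor `sar_form` over the tumor region
#' @param H_healthy `sar_form` over the healthy region (all non-tumor,
#'   non-air tissue by default elsewhere in the pipeline)
#' @param total_power total array input power constraint (W)
#' @param reference index of the phase-reference antenna (phase fixed at 0)
#' @return object of class `sar_problem`
#' @export
sar_problem <- function(H_tumor, H_healthy, total_power = 8,
                        reference = nrow(H_tumor$H)) {
  stopifnot(inherits(H_tumor, "sar_form"), inherits(H_healthy, "sar_form"),
            nrow(H_tumor$H) == nrow(H_healthy$H))
  if (total_power <= 0) stop("total_power must be positive")
  structure(list(H_tumor = H_tumor, H_healthy = H_healthy,
                 total_power = total_power, reference = reference),
            class = "sar_problem")
}

#' Tumor-to-healthy SAR ratio of an excitation
#'
#' The dimensionless objective SARvol(tumor) / SARvol(healthy); invariant to
#' a common rescaling of all powers and to a common phase shift.
#'
#' @param exc an [excitation()]
#' @param problem a [sar_problem()]
#' @return the SAR ratio
#' @export
sar_ratio <- function(exc, problem) {
  den <- sar_vol(problem$H_healthy, exc)
  if (den <= 0) stop("healthy-region SAR is zero for this excitation")
  sar_vol(problem$H_tumor, exc) / den
}

#' Optimal antenna powers and phases (generalized Rayleigh quotient)
#'
#' Maximizes A^H H_t A / A^H H_h A over complex excitation amplitudes A.
#' The exact maximizer is the principal generalized eigenvector of
#' (H_t, H_h), computed by whitening the healthy form: with
#' H_h = U D U^H, B = D^-1/2 U^H H_t U D^-1/2, the optimum is
#' A = U D^-1/2 v1 with v1 the principal eigenvector of B, and the achieved
#' ratio is the principal eigenvalue.  The amplitude vector is converted to
#' per-antenna powers rescaled to the exact power budget (the ratio is
#' scale-invariant, so post-hoc rescaling is lossless) and phases gauged so
#' the reference antenna sits at 0 degrees.
#'
#' A nearly singular healthy form is Tikhonov-regularized (with a warning)
#' before whitening.
#'
#' @param problem a [sar_problem()]
#' @return list with `excitation` (the optimum), `ratio` (achieved SAR
#'   ratio) and `eigenvalue` (principal generalized eigenvalue; equals
#'   `ratio` up to numerical precision)
#' @export
optimal_excitation <- function(problem) {
  Ht <- problem$H_tumor$H
  Hh <- problem$H_healthy$H
  eh <- eigen(Hh, symmetric = TRUE)
  tol <- max(eh$values) * 1e-12
  if (any(eh$values < tol)) {
    warning("healthy-region form is near-singular; regularizing")
    reg <- max(eh$values) * 1e-10
    eh$values <- eh$values + reg
    if (any(eh$values <= 0)) stop("healthy-region form is singular")
  }
  W <- eh$vectors %*% (t(Conj(eh$vectors)) / sqrt(eh$values))
  B <- t(Conj(W)) %*% Ht %*% W
  B <- (B + t(Conj(B))) / 2
  eb <- eigen(B, symmetric = TRUE)
  A <- as.vector(W %*% eb$vectors[, 1])
  exc <- .as_excitation(A, reference = problem$reference,
                        total_power = problem$total_power)
  list(excitation = exc, ratio = sar_ratio(exc, problem),
       eigenvalue = eb$values[1])
}

#' Derivative-free stochastic refinement of an excitation
#'
#' Seeded cross-check of the eigen solution: multistart Nelder-Mead over the
#' 2N-1 free real parameters (per-antenna amplitude moduli and all but the
#' reference phase), starting from the supplied excitation and from seeded
#' random perturbations of it.  Returns the best excitation found, which is
#' never worse than the start.
#'
#' @param problem a [sar_problem()]
#' @param start starting [excitation()]
#' @param seed integer seed
#' @param n_starts number of random restarts (in addition to the start point)
#' @return list with `excitation` and `ratio`
#' @export
stochastic_refine <- function(problem, start, seed = 1L, n_starts = 8L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  N <- length(start$powers)
  ref <- problem$reference
  free <- setdiff(seq_len(N), ref)
  par0 <- c(sqrt(start$powers), start$phases[free] * pi / 180)
  obj <- function(par) {
    a <- abs(par[seq_len(N)])
    if (sum(a) == 0) return(Inf)
    ph <- numeric(N)
    ph[free] <- par[-seq_len(N)]
    A <- a * exp(1i * ph)
    exc <- .as_excitation(A, reference = ref, total_power = problem$total_power)
    den <- sar_vol(problem$H_healthy, exc)
    if (den <= 0) return(Inf)
    -sar_vol(problem$H_tumor, exc) / den
  }
  best_par <- par0
  best_val <- obj(par0)
  starts <- c(list(par0), lapply(seq_len(n_starts), function(i) {
    par0 + rnorm(length(par0), sd = c(rep(0.5, N), rep(1, N - 1)))
  }))
  for (p0 in starts) {
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
  }
  a <- abs(best_par[seq_len(N)])
  ph <- numeric(N)
  ph[free] <- best_par[-seq_len(N)]
  exc <- .as_excitation(a * exp(1i * ph), reference = ref,
                        total_power = problem$total_power)
  ratio <- sar_ratio(exc, problem)
  if (ratio < sar_ratio(start, problem)) {
    exc <- start
    ratio <- sar_ratio(start, problem)
  }
  list(excitation = exc, ratio = ratio)
}

#' Uniform (unoptimized) excitation
#'
#' All antennas at equal power and zero phase -- the array's state before
#' optimization.
#'
#' @param n number of antennas
#' @param total_power total array power (W)
#' @return an [excitation()]
#' @export
uniform_excitation <- function(n = 8, total_power = n) {
  excitation(rep(total_power / n, n), rep(0, n))
}
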