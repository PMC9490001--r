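#' Physical constants used throughout the package
#'
#' SI values. Gyromagnetic ratios in rad s^-1 T^-1; gamma_N (15N) and the
#' 15N CSA are negative by convention.
#' @keywords internal
.nmr_const <- list(
  mu0      = 4e-7 * pi,        # vacuum permeability, T m / A
  hbar     = 1.054571817e-34,  # reduced Planck constant, J s
  gamma_H  = 2.6752218744e8,   # 1H,  rad s^-1 T^-1
  gamma_N  = -2.7126180e7,     # 15N, rad s^-1 T^-1
  gamma_C  = 6.728284e7,       # 13C, rad s^-1 T^-1
  kB       = 0.0083144621      # Boltzmann constant, kJ mol^-1 K^-1
)

#' Atomic masses (u) for mass-weighted geometry
#' @keywords internal
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)

#' Spectrometer and interaction parameters for relaxation analysis
#'
#' Bundles the static-field and spin-interaction constants entering the
#' dipolar/CSA relaxation expressions: the proton Larmor frequency, the
#' effective N-H bond length and the axially symmetric 15N chemical shift
#' anisotropy. Defaults are the conventional model-free values
#' (r = 1.02 A, CSA = -160 ppm) at a 700 MHz spectrometer.
#'
#' @param frequency_MHz proton Larmor frequency in MHz (> 0)
#' @param r_NH effective N-H bond length in Angstrom
#' @param csa_ppm 15N chemical shift anisotropy in ppm (negative)
#' @return object of class \code{field_params} with angular frequencies
#'   (rad/s), the dipolar coupling constant \code{d2} and CSA constant
#'   \code{c2} pre-computed.
#' @export
field_params <- function(frequency_MHz = 700, r_NH = 1.02, csa_ppm = -160) {
  stopifnot(is.numeric(frequency_MHz), frequency_MHz > 0,
            r_NH > 0, is.finite(csa_ppm))
  k <- .nmr_const
  wH <- 2 * pi * frequency_MHz * 1e6          # rad/s
  wN <- wH * k$gamma_N / k$gamma_H            # negative
  r <- r_NH * 1e-10
  # dipolar constant d = (mu0/4pi) * gammaH*gammaN*hbar / r^3  (rad/s)
  d <- (k$mu0 / (4 * pi)) * k$gamma_H * k$gamma_N * k$hbar / r^3
  c <- wN * csa_ppm * 1e-6 / sqrt(3)          # CSA constant (rad/s)
  structure(list(frequency_MHz = frequency_MHz, r_NH = r_NH,
                 csa_ppm = csa_ppm, wH = wH, wN = wN,
                 d2 = d^2, c2 = c^2,
                 gamma_ratio = k$gamma_H / k$gamma_N),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("<field_params> 1H %g MHz, r(N-H) %.3f A, 15N CSA %g ppm\n",
              x$frequency_MHz, x$r_NH, x$csa_ppm))
  invisible(x)
}

#' Static dipolar coupling constant for an RDC pair type
#'
#' Returns D_max in Hz for a unit bond vector, i.e. the prefactor in
#' D = D_max * t(v) %*% S %*% v with S the Saupe order matrix. Effective
#' bond lengths: r(N-H) = 1.02 A, r(C'-N) = 1.329 A.
#'
#' @param pair \code{"N-H"} or \code{"C-N"}
#' @return scalar, Hz (negative for both pairs)
#' @export
rdc_dmax <- function(pair) {
  k <- .nmr_const
  switch(match.arg(pair, c("N-H", "C-N")),
    "N-H" = (k$mu0 / (4 * pi)) * k$gamma_H * k$gamma_N * k$hbar /
              (2 * pi * (1.02e-10)^3),
    "C-N" = (k$mu0 / (4 * pi)) * k$gamma_C * k$gamma_N * k$hbar /
              (2 * pi * (1.329e-10)^3))
}

# Deterministic fan-out of one user seed into per-generator streams.
# stream ids: relaxation = 1, ensemble = 2, rdc = 3, hx = 4, refine = 5.
# Documented splitting rule: seed * 16 + id, folded into [0, 2^31-1).
#' @keywords internal
split_seed <- function(seed, stream) {
  ids <- c(relaxation = 1, ensemble = 2, rdc = 3, hx = 4, refine = 5)
  if (is.character(stream)) stream <- ids[[stream]]
  as.integer((as.numeric(seed) * 16 + stream) %% 2147483647)
}
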