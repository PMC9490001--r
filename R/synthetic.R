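#' Synthetic per-residue relaxation data with known truth
#'
#' Forward-models (R1, R2, NOE) triples from the Lipari-Szabo spectral
#' density for a table of true per-residue parameters and adds relative
#' Gaussian noise. The truth is returned alongside, for
#' parameter-recovery scoring. The supplied seed is fanned out through
#' the package's seed-splitting rule (see \code{split_seed}).
#'
#' @param truth data.frame(residue, S2) with optional tau_e (ps) and
#'   R_ex (s^-1) columns
#' @param tau_m_ns shared rotational correlation time (ns)
#' @param field a \code{field_params}
#' @param noise relative Gaussian noise level (default 0.03)
#' @param seed integer seed (mandatory)
#' @return list(records, truth, tau_m_ns); records has columns residue,
#'   R1, R1_err, R2, R2_err, NOE, NOE_err
#' @export
synth_relaxation <- function(truth, tau_m_ns = 5,
                             field = field_params(), noise = 0.03,
                             seed) {
  stopifnot(!missing(seed))
  truth <- as.data.frame(truth)
  if (!"tau_e" %in% names(truth)) truth$tau_e <- 0
  if (!"R_ex" %in% names(truth)) truth$R_ex <- 0
  set.seed(split_seed(seed, "relaxation"))
  rates <- t(vapply(seq_len(nrow(truth)), function(i)
    lipari_szabo_rates(truth$S2[i], tau_m_ns, truth$tau_e[i],
                       truth$R_ex[i], field), numeric(3)))
  noisy <- rates * (1 + matrix(rnorm(length(rates), sd = noise),
                               nrow(rates), 3))
  records <- data.frame(residue = truth$residue,
                        R1 = noisy[, 1], R1_err = abs(rates[, 1]) * noise,
                        R2 = noisy[, 2], R2_err = abs(rates[, 2]) * noise,
                        NOE = noisy[, 3],
                        NOE_err = abs(rates[, 3]) * noise)
  if (noise == 0) {
    records$R1_err <- records$R2_err <- records$NOE_err <- 1e-6
  }
  list(records = records, truth = truth, tau_m_ns = tau_m_ns)
}

#' Two-state (open/closed) toy conformational ensemble
#'
#' Samples conformations of the hinged helical chain from two Gaussian
#' wells in the hinge torsion, which map to distinct basins in the
#' radius of gyration and an end-to-end side-chain distance (the
#' package's two reaction coordinates). With
#' \code{coords_only = TRUE} only the reaction coordinates are returned
#' (computed through a dense torsion-to-coordinate interpolation), which
#' scales to very large sample counts.
#'
#' @param n number of conformations
#' @param populations length-2 well populations, summing to 1
#' @param wells length-2 hinge psi torsions (degrees) of the two wells;
#'   defaults give a compact (bent) majority state and an open
#'   (extended) minority state
#' @param well_sd Gaussian width of each well in the hinge torsion (deg)
#' @param n_res chain length
#' @param pair residue pair for the local distance coordinate (default
#'   residues 2 and n_res - 1)
#' @param seed integer seed (mandatory)
#' @param coords_only return reaction coordinates only: the two wells
#'   are then emitted as exact equal-width 2D Gaussians in (Rg,
#'   distance) centred on the well conformations, so basin free-energy
#'   differences reduce to the population closed form (the full
#'   conformational mode carries an additional well-entropy term
#'   because the torsion-to-coordinate mapping compresses the wells
#'   differently)
#' @param coord_sd well widths (Rg, distance; Angstrom) for
#'   \code{coords_only}
#' @return list(ensemble or coordinates, truth); truth holds per-well
#'   hinge means, populations and well means of (Rg, distance)
#' @export
synth_two_state_ensemble <- function(n, populations = c(0.7, 0.3),
                                     wells = c(100, -47), well_sd = 6,
                                     n_res = 20, pair = NULL, seed,
                                     coords_only = FALSE,
                                     coord_sd = c(0.15, 0.4)) {
  stopifnot(!missing(seed), length(populations) == 2,
            abs(sum(populations) - 1) < 1e-9, length(wells) == 2)
  if (abs(wells[1] - wells[2]) < 1e-9)
    warning("degenerate wells: identical hinge means")
  if (is.null(pair)) pair <- c(2L, n_res - 1L)
  set.seed(split_seed(seed, "ensemble"))
  well <- sample.int(2, n, replace = TRUE, prob = populations)
  coord_of <- function(p) {
    cf <- build_hinged_chain(n_res, hinge_psi = p)
    c(radius_of_gyration(cf),
      sidechain_distance(cf, pair[1], pair[2], mode = "centroid"))
  }
  truth_means <- vapply(wells, coord_of, numeric(2))
  truth <- list(wells_psi = wells, populations = populations,
                well_rg = truth_means[1, ], well_dist = truth_means[2, ],
                pair = pair)
  if (coords_only) {
    return(list(coordinates = data.frame(
      rg = rnorm(n, truth_means[1, well], coord_sd[1]),
      dist = rnorm(n, truth_means[2, well], coord_sd[2]),
      well = well), truth = truth))
  }
  psi <- rnorm(n, mean = wells[well], sd = well_sd)
  ens <- lapply(seq_len(n), function(i)
    build_hinged_chain(n_res, hinge_psi = psi[i], model_id = i))
  list(ensemble = ens, truth = truth)
}

#' Synthetic RDC tables from a known ensemble and tensors
#'
#' Ensemble-averages the back-calculated couplings of the supplied
#' conformations under known alignment tensor(s) and adds Gaussian noise,
#' one table block per alignment medium. Truth (tensors and generating
#' ensemble) is returned for recovery tests.
#'
#' @param ensemble list of \code{conformation} (the generating ensemble)
#' @param tensors an \code{alignment_tensor} or named list of them (one
#'   per medium)
#' @param pairs coupling types to emit (default "N-H")
#' @param noise additive Gaussian noise SD in Hz (default 1)
#' @param seed integer seed (mandatory)
#' @return list(rdcs, truth); rdcs has columns residue, pair, medium,
#'   D_exp, error
#' @export
synth_rdc <- function(ensemble, tensors, pairs = "N-H", noise = 1,
                      seed) {
  stopifnot(!missing(seed))
  if (inherits(tensors, "alignment_tensor"))
    tensors <- list(default = tensors)
  set.seed(split_seed(seed, "rdc"))
  out <- lapply(names(tensors), function(med) {
    per_conf <- lapply(ensemble, back_calculate_rdc,
                       tensor = tensors[[med]], pairs = pairs)
    base <- per_conf[[1]][, c("residue", "pair")]
    D <- rowMeans(vapply(per_conf, `[[`, numeric(nrow(base)), "D_calc"))
    data.frame(residue = base$residue, pair = base$pair, medium = med,
               D_exp = D + rnorm(length(D), sd = noise),
               error = rep(if (noise > 0) noise else 1, length(D)))
  })
  list(rdcs = do.call(rbind, out),
       truth = list(tensors = tensors, ensemble = ensemble))
}

#' Synthetic hydrogen-exchange data with known protection factors
#'
#' Builds per-residue two-state exchange models targeting the given
#' protection factors in the EX2 regime (k_cl = ex2_margin * k_int,
#' k_op = k_cl * 10^-logP), computes k_obs exactly from the two-state
#' expression, and emits exponential HSQC decay curves on the supplied
#' time grid with relative Gaussian noise. Residues exchanging faster
#' than \code{fast_frac} completion before the first time point are
#' routed to CLEANEX-style buildup tables on the short mixing-time grid
#' instead.
#'
#' @param sequence one-letter sequence; intrinsic rates are computed
#'   from it via \code{intrinsic_rates}
#' @param logP target per-amide protection factors (recycled)
#' @param times decay time grid (s)
#' @param noise relative intensity noise (default 0.05)
#' @param seed integer seed (mandatory)
#' @param pD,temperature_K,direction passed to \code{intrinsic_rates}
#' @param ex2_margin k_cl / k_int ratio enforcing the EX2 limit
#' @param fast_frac completion fraction before times[1] that routes a
#'   residue to CLEANEX (default 0.95)
#' @param cleanex_tau CLEANEX mixing-time grid (s)
#' @return list(curves, cleanex, truth); truth has residue, aa, k_int,
#'   k_op, k_cl, k_obs, logP_true
#' @export
synth_hx <- function(sequence, logP = 3, times = NULL, noise = 0.05,
                     seed, pD = 7.0, temperature_K = 310,
                     direction = "D2O", ex2_margin = 1000,
                     fast_frac = 0.95,
                     cleanex_tau = c(0, 0.010, 0.015, 0.020, 0.025)) {
  stopifnot(!missing(seed))
  ki <- intrinsic_rates(sequence, pD, temperature_K, direction)
  logP <- rep_len(logP, nrow(ki))
  k_cl <- ex2_margin * ki$k_int
  k_op <- k_cl * 10^(-logP)
  k_obs <- vapply(seq_len(nrow(ki)), function(i)
    simulate_kobs(ex2_model(k_op[i], k_cl[i], ki$k_int[i])), numeric(1))
  if (is.null(times)) times <- 120 * 2^(0:8)   # 2 min to ~8.5 h
  set.seed(split_seed(seed, "hx"))
  fast <- (1 - exp(-k_obs * times[1])) > fast_frac
  curves <- list(); cleanex <- list()
  for (i in seq_len(nrow(ki))) {
    if (fast[i]) {
      ratio <- 1 - exp(-k_obs[i] * cleanex_tau)
      ratio <- ratio + rnorm(length(ratio), sd = noise * pmax(ratio, 0.02))
      cleanex[[as.character(ki$residue[i])]] <-
        data.frame(residue = ki$residue[i], tau = cleanex_tau,
                   ratio = ratio)
    } else {
      ii <- exp(-k_obs[i] * times) * (1 + rnorm(length(times), sd = noise))
      curves[[length(curves) + 1L]] <-
        decay_curve(residue_id(ki$residue[i], ki$aa[i]), times,
                    pmax(ii, 0),
                    errors = rep(noise, length(times)))
    }
  }
  truth <- data.frame(residue = ki$residue, aa = ki$aa,
                      k_int = ki$k_int, k_op = k_op, k_cl = k_cl,
                      k_obs = k_obs,
                      logP_true = log10(ki$k_int / k_obs),
                      fast = fast)
  list(curves = curves, cleanex = cleanex, truth = truth)
}
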