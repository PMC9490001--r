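#' Simulated-annealing schedule
#'
#' Deterministic temperature ladder: within each cycle the temperature
#' ramps T_low -> T_high -> T_low (triangular), conformations being
#' extracted in a window at the end of each cycle when the system is back
#' at the low temperature. Defaults mirror a 50-cycle protocol with the
#' first 20 cycles discarded as burn-in and an extraction window covering
#' the final 1/8 of each cycle.
#'
#' @param T_low,T_high temperatures (K), T_high > T_low > 0
#' @param n_cycles number of annealing cycles
#' @param burn_in_cycles cycles excluded from ensemble extraction
#' @param steps_per_cycle Monte-Carlo moves per cycle
#' @param extraction_frac final fraction of each cycle eligible for
#'   extraction, in (0, 1]
#' @param frames_per_window snapshots recorded per extraction window
#' @return object of class \code{annealing_schedule}
#' @export
build_schedule <- function(T_low = 310, T_high = 500, n_cycles = 50,
                           burn_in_cycles = 20, steps_per_cycle = 10000,
                           extraction_frac = 1 / 8,
                           frames_per_window = 1) {
  if (!(T_high > T_low && T_low > 0))
    stop("validation error: need T_high > T_low > 0")
  if (burn_in_cycles >= n_cycles)
    stop("validation error: burn_in_cycles must be < n_cycles")
  if (!(extraction_frac > 0 && extraction_frac <= 1))
    stop("validation error: extraction_frac must be in (0, 1]")
  stopifnot(steps_per_cycle >= 1, frames_per_window >= 1)
  structure(list(T_low = T_low, T_high = T_high, n_cycles = n_cycles,
                 burn_in_cycles = burn_in_cycles,
                 steps_per_cycle = as.integer(steps_per_cycle),
                 extraction_frac = extraction_frac,
                 frames_per_window = as.integer(frames_per_window)),
            class = "annealing_schedule")
}

#' @export
print.annealing_schedule <- function(x, ...) {
  cat(sprintf(
    "<annealing_schedule> %d cycles (%d burn-in), %d-%d K, %d steps/cycle\n",
    x$n_cycles, x$burn_in_cycles, x$T_low, x$T_high, x$steps_per_cycle))
  invisible(x)
}

#' Restraint force-constant ramp
#'
#' The restraint force constant alpha is raised gently over a sequence of
#' equilibration stages before annealing begins; multipliers must be
#' non-decreasing and end at 1.
#'
#' @param alpha_target final force constant (energy per Hz^2), >= 0
#' @param profile per-stage multipliers, non-decreasing, last = 1
#' @return object of class \code{restraint_ramp}
#' @export
restraint_ramp <- function(alpha_target,
                           profile = seq(0.1, 1, length.out = 10)) {
  stopifnot(alpha_target >= 0)
  if (any(diff(profile) < 0) || abs(profile[length(profile)] - 1) > 1e-12)
    stop("validation error: ramp multipliers must be non-decreasing and end at 1")
  structure(list(alpha_target = alpha_target, profile = profile),
            class = "restraint_ramp")
}

# Torsion pivot: rotate the chain downstream of residue r's phi or psi
# bond about that bond axis (preserves bonded geometry).
.torsion_pivot <- function(X, resno, atom, r, phi_move, angle) {
  ri <- which(resno == r)
  if (phi_move) {
    a1 <- ri[atom[ri] == "N"]; a2 <- ri[atom[ri] == "CA"]
    sel <- c(ri[atom[ri] %in% c("C", "O", "CB")], which(resno > r))
  } else {
    a1 <- ri[atom[ri] == "CA"]; a2 <- ri[atom[ri] == "C"]
    sel <- c(ri[atom[ri] == "O"], which(resno > r))
  }
  if (length(a1) != 1L || length(a2) != 1L) return(X)
  origin <- X[a2, ]
  R <- rotation_matrix(X[a2, ] - X[a1, ], angle)
  X[sel, ] <- sweep(sweep(X[sel, , drop = FALSE], 2, origin) %*% t(R),
                    2, origin, `+`)
  X
}

.cycle_temperature <- function(frac, T_low, T_high) {
  tri <- ifelse(frac <= 0.5, 2 * frac, 2 * (1 - frac))
  T_low + (T_high - T_low) * tri
}

# Prepare RDC bookkeeping shared across replicas (common topology).
.refine_rdc_setup <- function(conf, rdcs) {
  rdcs <- as.data.frame(rdcs)
  if (!"medium" %in% names(rdcs)) rdcs$medium <- "default"
  lapply(split(rdcs, rdcs$medium), function(sub) {
    dz <- .rdc_design(conf, sub)
    rec <- dz$records
    if (nrow(rec) == 0)
      stop("validation error: no overlap between structure and RDC table")
    idx <- .rdc_atom_index(conf, rec)
    w <- if ("error" %in% names(rec) && all(is.finite(rec$error)) &&
             all(rec$error > 0)) 1 / rec$error^2 else rep(1, nrow(rec))
    list(records = rec, idx = idx,
         dmax = vapply(rec$pair, rdc_dmax, numeric(1)),
         w = w, D_exp = rec$D_exp)
  })
}

.design_matrix_fast <- function(X, setup) {
  U <- X[setup$idx[, 2], , drop = FALSE] - X[setup$idx[, 1], , drop = FALSE]
  V <- U / sqrt(rowSums(U^2))
  cbind(V[, 1]^2 - V[, 3]^2, V[, 2]^2 - V[, 3]^2,
        2 * V[, 1] * V[, 2], 2 * V[, 1] * V[, 3],
        2 * V[, 2] * V[, 3]) * setup$dmax
}

# couplings for one replica under fixed tensor components, no design
# matrix allocation (hot path of the sampler)
.calc_D_fast <- function(X, setup, s5) {
  U <- X[setup$idx[, 2], , drop = FALSE] - X[setup$idx[, 1], , drop = FALSE]
  n2 <- U[, 1]^2 + U[, 2]^2 + U[, 3]^2
  setup$dmax / n2 *
    ((U[, 1]^2 - U[, 3]^2) * s5[1] + (U[, 2]^2 - U[, 3]^2) * s5[2] +
     2 * (U[, 1] * U[, 2] * s5[3] + U[, 1] * U[, 3] * s5[4] +
          U[, 2] * U[, 3] * s5[5]))
}

#' Replica-averaged RDC-restrained simulated-annealing refinement
#'
#' Metropolis Monte-Carlo sampling of M replicas under
#' E_total = E_ff + E_rdc, where E_ff is a toy potential and E_rdc the
#' replica-averaged RDC pseudoenergy. Moves mix single-atom Gaussian
#' displacements with chain pivot rotations. The alignment tensor (one
#' per medium) is refit by least squares against the replica-averaged
#' orientational design at a fixed stride of accepted moves and frozen in
#' between. Fully reproducible given a seed.
#'
#' @param start starting \code{conformation} (all replicas initialised
#'   from it with a small coordinate jitter)
#' @param rdcs RDC table (residue, pair, D_exp; optional medium, error)
#' @param M replica count
#' @param schedule an \code{annealing_schedule}
#' @param ramp a \code{restraint_ramp}
#' @param potential a \code{toy_potential}
#' @param seed RNG seed (mandatory)
#' @param tensor_mode \code{"shared-svd"} (tensor refit against the data
#'   at \code{refit_stride}) or \code{"fixed"} (known tensors supplied
#'   via \code{tensors}, e.g. from a synthetic-truth record or a shape
#'   prediction)
#' @param tensors named list of \code{alignment_tensor} per medium, for
#'   \code{tensor_mode = "fixed"}
#' @param move_sd single-atom move size (A)
#' @param pivot_prob probability of a pivot move
#' @param pivot_sd pivot angle SD (radians)
#' @param refit_stride tensor refit interval in accepted moves
#' @param eq_steps_per_stage equilibration steps per ramp stage
#' @param jitter initial replica jitter (A)
#' @param init_pivots number of random torsion pivots applied to each
#'   replica before equilibration (overdispersed initialisation so the
#'   replica ensemble starts spread over conformational space; 0 starts
#'   all replicas at the input structure)
#' @param init_pivot_sd angle SD (radians) of the initial pivots
#' @return object of class \code{refinement_trajectory}: per-cycle frames,
#'   an energy/acceptance/Q log, the final ensemble and final Q
#' @export
run_refinement <- function(start, rdcs, M, schedule, ramp, potential,
                           seed, move_sd = 0.06, pivot_prob = 0.15,
                           pivot_sd = 0.25, refit_stride = 100,
                           eq_steps_per_stage = 200, jitter = 0.02,
                           init_pivots = 0, init_pivot_sd = 1,
                           tensor_mode = c("shared-svd", "fixed"),
                           tensors = NULL) {
  tensor_mode <- match.arg(tensor_mode)
  starts <- if (inherits(start, "conformation")) list(start)
            else if (inherits(start, "replica_ensemble")) start$replicas
            else start
  start <- starts[[1]]
  stopifnot(inherits(start, "conformation"), M >= 1,
            inherits(schedule, "annealing_schedule"),
            inherits(ramp, "restraint_ramp"),
            inherits(potential, "toy_potential"))
  set.seed(as.integer(seed))
  kB <- .nmr_const$kB
  X0 <- coords(start)
  n_at <- nrow(X0)
  resno <- start$resno
  res <- sort(unique(resno))
  setups <- if (is.null(rdcs) || nrow(as.data.frame(rdcs)) == 0L)
    structure(list(), names = character(0))
  else .refine_rdc_setup(start, rdcs)
  Xs <- lapply(seq_len(M), function(m) {
    X <- coords(starts[[(m - 1L) %% length(starts) + 1L]]) +
      matrix(rnorm(3 * n_at, sd = jitter), n_at, 3)
    if (init_pivots > 0 && length(res) > 2)
      for (k in seq_len(init_pivots))
        X <- .torsion_pivot(X, resno, start$atom,
                            res[sample.int(length(res) - 2, 1) + 1L],
                            runif(1) < 0.5, rnorm(1, sd = init_pivot_sd))
    X
  })
  Eff <- vapply(Xs, function(X) toy_energy(potential, X), numeric(1))

  # per-medium mutable state (environment: reference semantics so the
  # inner sampling loop and the energy closures see the same couplings)
  st <- new.env(parent = emptyenv())
  st$s5 <- lapply(setups, function(su) rep(0, 5))
  if (tensor_mode == "fixed") {
    if (inherits(tensors, "alignment_tensor"))
      tensors <- setNames(list(tensors), names(setups)[1])
    for (med in names(setups)) {
      if (is.null(tensors[[med]]))
        stop("tensor_mode = 'fixed' needs a tensor for medium ", med)
      st$s5[[med]] <- tensor_components(tensors[[med]])
    }
  }
  st$D <- lapply(setups, function(su) matrix(0, length(su$D_exp), M))
  refit <- function() {
    for (med in names(setups)) {
      su <- setups[[med]]
      As <- lapply(Xs, .design_matrix_fast, setup = su)
      if (tensor_mode == "shared-svd") {
        Abar <- Reduce(`+`, As) / M
        st$s5[[med]] <- tryCatch(qr.solve(Abar, su$D_exp),
                                 error = function(e) st$s5[[med]])
      }
      s5 <- st$s5[[med]]
      st$D[[med]] <- matrix(vapply(As, function(A) as.numeric(A %*% s5),
                                   numeric(length(su$D_exp))), ncol = M)
    }
  }
  e_rdc <- function(alpha) {
    if (alpha == 0) return(0)
    s <- 0
    for (med in names(setups)) {
      su <- setups[[med]]
      dbar <- rowMeans(st$D[[med]])
      s <- s + sum(su$w * (dbar - su$D_exp)^2)
    }
    alpha * s
  }
  ens_q <- function() {
    if (length(setups) == 0L) return(NA_real_)
    dc <- unlist(lapply(names(setups), function(med)
      rowMeans(st$D[[med]])))
    de <- unlist(lapply(setups, `[[`, "D_exp"))
    q_factor(dc, de)
  }
  refit()

  conf_template <- start
  as_conf <- function(X, id) {
    conf_template$x <- X[, 1]; conf_template$y <- X[, 2]
    conf_template$z <- X[, 3]
    attr(conf_template, "model_id") <- as.integer(id)
    conf_template
  }

  n_acc_since_refit <- 0L
  do_steps <- function(n_steps, temps, alpha, record_at = integer(0)) {
    frames <- list()
    acc <- 0L
    Erdc_cur <- e_rdc(alpha)
    for (s in seq_len(n_steps)) {
      Tk <- temps[s]
      m <- sample.int(M, 1)
      X <- Xs[[m]]
      if (length(res) > 2 && runif(1) < pivot_prob) {
        r <- res[sample.int(length(res) - 2, 1) + 1L]
        Xn <- .torsion_pivot(X, resno, start$atom, r, runif(1) < 0.5,
                             rnorm(1, sd = pivot_sd))
      } else {
        a <- sample.int(n_at, 1)
        Xn <- X
        Xn[a, ] <- Xn[a, ] + rnorm(3, sd = move_sd)
      }
      Eff_new <- toy_energy(potential, Xn)
      Dold <- lapply(st$D, function(Dm) Dm[, m])
      for (med in names(setups))
        st$D[[med]][, m] <- .calc_D_fast(Xn, setups[[med]],
                                         st$s5[[med]])
      Erdc_new <- e_rdc(alpha)
      dE <- (Eff_new - Eff[m]) + (Erdc_new - Erdc_cur)
      if (dE <= 0 || runif(1) < exp(-dE / (kB * Tk))) {
        Xs[[m]] <<- Xn
        Eff[m] <<- Eff_new
        Erdc_cur <- Erdc_new
        acc <- acc + 1L
        n_acc_since_refit <<- n_acc_since_refit + 1L
        if (n_acc_since_refit >= refit_stride) {
          refit()
          Erdc_cur <- e_rdc(alpha)
          n_acc_since_refit <<- 0L
        }
      } else {
        for (med in names(setups)) st$D[[med]][, m] <- Dold[[med]]
      }
      if (s %in% record_at)
        frames[[length(frames) + 1L]] <- replica_ensemble(
          lapply(seq_len(M), function(mm) as_conf(Xs[[mm]], mm)))
    }
    list(frames = frames, acc_rate = acc / n_steps,
         E_rdc = Erdc_cur)
  }

  # equilibration: raise alpha along the ramp at the low temperature
  if (ramp$alpha_target > 0) {
    for (mult in ramp$profile) {
      do_steps(eq_steps_per_stage,
               rep(schedule$T_low, eq_steps_per_stage),
               ramp$alpha_target * mult)
    }
  }

  S <- schedule$steps_per_cycle
  temps <- .cycle_temperature(seq_len(S) / S, schedule$T_low,
                              schedule$T_high)
  w0 <- ceiling((1 - schedule$extraction_frac) * S)
  record_at <- unique(round(seq(w0 + 1, S,
                                length.out = schedule$frames_per_window)))
  cycles <- vector("list", schedule$n_cycles)
  log <- vector("list", schedule$n_cycles)
  for (cyc in seq_len(schedule$n_cycles)) {
    out <- do_steps(S, temps, ramp$alpha_target, record_at)
    cycles[[cyc]] <- out$frames
    log[[cyc]] <- data.frame(cycle = cyc, E_ff = mean(Eff),
                             E_rdc = out$E_rdc,
                             acc_rate = out$acc_rate, Q = ens_q())
  }
  refit()
  final <- replica_ensemble(lapply(seq_len(M), function(m)
    as_conf(Xs[[m]], m)))
  structure(list(cycles = cycles, log = do.call(rbind, log),
                 schedule = schedule, final = final,
                 Q_final = ens_q()),
            class = "refinement_trajectory")
}

#' @export
print.refinement_trajectory <- function(x, ...) {
  cat(sprintf(
    "<refinement_trajectory> %d cycles, M = %d, final Q = %.3f\n",
    length(x$cycles), x$final$M, x$Q_final))
  invisible(x)
}

#' Pool the refined ensemble from a trajectory
#'
#' Collects every replica from each post-burn-in cycle's extraction
#' window, giving (n_cycles - burn_in) * M * frames_per_window
#' conformations.
#'
#' @param traj a \code{refinement_trajectory}
#' @param schedule schedule used for extraction (default: the
#'   trajectory's own)
#' @return list of \code{conformation}
#' @export
extract_ensemble <- function(traj, schedule = NULL) {
  if (is.null(schedule)) schedule <- traj$schedule
  if (length(traj$cycles) < schedule$n_cycles)
    stop("truncated trajectory: ", length(traj$cycles), " cycles, need ",
         schedule$n_cycles)
  keep <- seq(schedule$burn_in_cycles + 1L, schedule$n_cycles)
  out <- list()
  for (cyc in keep) {
    frames <- traj$cycles[[cyc]]
    if (length(frames) == 0L)
      stop("empty extraction window in cycle ", cyc)
    for (fr in frames) out <- c(out, fr$replicas)
  }
  if (length(out) == 0L) stop("empty extraction window")
  out
}
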