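#' Saupe alignment tensor
#'
#' Wraps a traceless symmetric 3x3 order matrix (5 independent
#' components). Derived quantities follow the usual conventions:
#' eigenvalues ordered by magnitude |Szz| >= |Syy| >= |Sxx|, axial
#' component Szz/2 and rhombicity R = (2/3)(Sxx - Syy)/Szz.
#'
#' @param S 3x3 numeric matrix, symmetric and traceless to 1e-12
#' @return object of class \code{alignment_tensor}
#' @export
alignment_tensor <- function(S) {
  S <- as.matrix(S)
  stopifnot(all(dim(S) == c(3, 3)))
  if (max(abs(S - t(S))) > 1e-12 * max(1, max(abs(S))))
    stop("Saupe matrix must be symmetric")
  if (abs(sum(diag(S))) > 1e-12 * max(1, max(abs(S))))
    stop("Saupe matrix must be traceless")
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values))          # |Sxx| <= |Syy| <= |Szz|
  vals <- e$values[ord]
  Szz <- vals[3]; Syy <- vals[2]; Sxx <- vals[1]
  structure(list(S = S,
                 eigenvalues = c(Sxx = Sxx, Syy = Syy, Szz = Szz),
                 axes = e$vectors[, ord, drop = FALSE],
                 rhombicity = if (abs(Szz) > 0)
                   (2 / 3) * (Sxx - Syy) / Szz else NA_real_),
            class = "alignment_tensor")
}

#' @export
print.alignment_tensor <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf(
    "<alignment_tensor> Szz = %.3e, rhombicity R = %.3f, Da(N-H) = %.2f Hz\n",
    ev["Szz"], x$rhombicity, rdc_dmax("N-H") * ev["Szz"] / 2))
  invisible(x)
}

#' Build a Saupe tensor from its 5 independent components
#'
#' @param s5 numeric vector (Sxx, Syy, Sxy, Sxz, Syz); Szz = -Sxx-Syy
#' @return \code{alignment_tensor}
#' @export
tensor_from_components <- function(s5) {
  stopifnot(length(s5) == 5)
  S <- matrix(c(s5[1], s5[3], s5[4],
                s5[3], s5[2], s5[5],
                s5[4], s5[5], -s5[1] - s5[2]), 3, 3)
  alignment_tensor(S)
}

#' @keywords internal
tensor_components <- function(tensor) {
  S <- tensor$S
  c(S[1, 1], S[2, 2], S[1, 2], S[1, 3], S[2, 3])
}

# Row of the linear design relating the 5 Saupe components to
# D/Dmax = v' S v for a unit vector v.
.design_row <- function(v) {
  c(v[1]^2 - v[3]^2, v[2]^2 - v[3]^2,
    2 * v[1] * v[2], 2 * v[1] * v[3], 2 * v[2] * v[3])
}

#' Internuclear unit bond vectors of a conformation
#'
#' For \code{"N-H"}: the amide N to H vector of each residue carrying both
#' atoms (prolines, lacking the amide proton, are absent). For
#' \code{"C-N"}: the C' of residue i-1 to N of residue i vector, indexed
#' by residue i. Residues missing the required atoms are skipped with a
#' warning (prolines and chain termini silently).
#'
#' @param conf a \code{conformation}
#' @param pair \code{"N-H"} or \code{"C-N"}
#' @return data.frame(residue, vx, vy, vz) of unit vectors
#' @export
bond_vectors <- function(conf, pair = "N-H") {
  pair <- match.arg(pair, c("N-H", "C-N"))
  res <- sort(unique(conf$resno))
  get <- function(rn, at) {
    i <- which(conf$resno == rn & conf$atom == at)
    if (length(i) != 1L) return(NULL)
    c(conf$x[i], conf$y[i], conf$z[i])
  }
  rows <- list(); skipped <- integer(0)
  for (rn in res) {
    if (pair == "N-H") {
      a <- get(rn, "N"); b <- get(rn, "H")
      expected <- !(conf$aa[match(rn, conf$resno)] == "P" ||
                    rn == min(res))
    } else {
      if (rn == min(res)) next
      a <- get(rn - 1L, "C"); b <- get(rn, "N")
      expected <- TRUE
    }
    if (is.null(a) || is.null(b)) {
      if (expected) skipped <- c(skipped, rn)
      next
    }
    u <- b - a
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) stop("geometry error: zero-length bond vector at residue ",
                        rn)
    rows[[length(rows) + 1L]] <- c(rn, u / nu)
  }
  if (length(skipped))
    warning("residues missing ", pair, " atoms skipped: ",
            paste(skipped, collapse = ", "))
  m <- do.call(rbind, rows)
  data.frame(residue = as.integer(m[, 1]),
             vx = m[, 2], vy = m[, 3], vz = m[, 4])
}

#' Back-calculate RDCs from a structure and alignment tensor
#'
#' D_calc = D_max(pair) * v' S v for each unit bond vector v.
#'
#' @param conf a \code{conformation}
#' @param tensor an \code{alignment_tensor}
#' @param pairs character vector of coupling types to compute
#' @return data.frame(residue, pair, D_calc) in Hz
#' @export
back_calculate_rdc <- function(conf, tensor, pairs = "N-H") {
  stopifnot(inherits(tensor, "alignment_tensor"))
  bad <- setdiff(pairs, c("N-H", "C-N"))
  if (length(bad)) stop("validation error: unknown pair type: ",
                        paste(bad, collapse = ", "))
  out <- lapply(pairs, function(p) {
    bv <- bond_vectors(conf, p)
    V <- as.matrix(bv[, c("vx", "vy", "vz")])
    d <- rdc_dmax(p) * rowSums((V %*% tensor$S) * V)
    data.frame(residue = bv$residue, pair = p, D_calc = d)
  })
  do.call(rbind, out)
}

#' RDC quality (Q) factor
#'
#' Q = rms(D_calc - D_exp) / rms(D_exp) (Cornilescu convention).
#'
#' @param D_calc,D_exp numeric vectors of equal length >= 1
#' @return scalar Q
#' @export
q_factor <- function(D_calc, D_exp) {
  stopifnot(length(D_calc) == length(D_exp), length(D_exp) >= 1)
  denom <- sqrt(mean(D_exp^2))
  if (denom == 0) stop("undefined Q: rms(D_exp) = 0")
  sqrt(mean((D_calc - D_exp)^2)) / denom
}

# Match RDC rows to bond vectors; returns design matrix (rows scaled by
# Dmax) and the matched record subset.
.rdc_design <- function(conf, rdcs) {
  rdcs <- as.data.frame(rdcs)
  stopifnot(all(c("residue", "pair", "D_exp") %in% names(rdcs)))
  A <- matrix(NA_real_, nrow(rdcs), 5)
  keep <- logical(nrow(rdcs))
  for (p in unique(rdcs$pair)) {
    bv <- suppressWarnings(bond_vectors(conf, p))
    sel <- which(rdcs$pair == p)
    m <- match(rdcs$residue[sel], bv$residue)
    ok <- !is.na(m)
    keep[sel[ok]] <- TRUE
    V <- as.matrix(bv[m[ok], c("vx", "vy", "vz")])
    A[sel[ok], ] <- rdc_dmax(p) *
      t(apply(V, 1, .design_row))
  }
  list(A = A[keep, , drop = FALSE], records = rdcs[keep, , drop = FALSE],
       keep = keep)
}

#' Fit the alignment tensor to measured RDCs by SVD
#'
#' Weighted linear least-squares solution for the 5 independent Saupe
#' components given one conformation and its measured couplings, plus the
#' Q factor of the fit. Weights are 1/error^2 where errors are present.
#'
#' @param conf a \code{conformation}
#' @param rdcs data.frame(residue, pair, D_exp) with optional error column
#' @param cond_max condition-number limit for the design matrix
#' @return list(tensor, Q, D_calc, records)
#' @export
svd_fit_tensor <- function(conf, rdcs, cond_max = 1e8) {
  rdcs <- as.data.frame(rdcs)
  if ("medium" %in% names(rdcs) && length(unique(rdcs$medium)) > 1L)
    stop("multiple alignment media present; fit one medium at a time")
  dz <- .rdc_design(conf, rdcs)
  A <- dz$A; rec <- dz$records
  if (nrow(A) < 5L)
    stop("underdetermined: need >= 5 couplings with bond vectors, have ",
         nrow(A))
  w <- if ("error" %in% names(rec) && all(is.finite(rec$error)) &&
           all(rec$error > 0)) 1 / rec$error^2 else rep(1, nrow(rec))
  sw <- sqrt(w)
  sv <- svd(A * sw)
  if (min(sv$d) <= 0 || max(sv$d) / min(sv$d) > cond_max)
    stop(sprintf(
      "conditioning error: design matrix condition number %.3g",
      if (min(sv$d) > 0) max(sv$d) / min(sv$d) else Inf))
  s5 <- sv$v %*% ((t(sv$u) %*% (rec$D_exp * sw)) / sv$d)
  tensor <- tensor_from_components(as.numeric(s5))
  d_calc <- as.numeric(A %*% s5)
  list(tensor = tensor, Q = q_factor(d_calc, rec$D_exp),
       D_calc = d_calc, records = rec)
}

#' Shape-based (steric) alignment tensor prediction
#'
#' Predicts the alignment tensor of a conformation from molecular shape
#' alone: the anisotropic part of the heavy-atom gyration tensor, scaled
#' by a configurable overall alignment magnitude. This is a deliberately
#' simple geometric model: a rod-like molecule gives an axially symmetric
#' tensor along the rod and a spherical one gives (near) zero alignment.
#'
#' @param conf a \code{conformation}
#' @param scale overall alignment magnitude (dimensionless Saupe scale)
#' @param iso_tol relative anisotropy below which the shape is reported
#'   as isotropic
#' @return \code{alignment_tensor}
#' @export
steric_tensor <- function(conf, scale = 1e-3, iso_tol = 1e-3) {
  heavy <- conf[conf$element != "H", , drop = FALSE]
  X <- as.matrix(heavy[, c("x", "y", "z")])
  if (nrow(X) < 3L) stop("need >= 3 heavy atoms")
  Xc <- sweep(X, 2, colMeans(X))
  G <- crossprod(Xc) / nrow(Xc)
  if (sum(diag(G)) < 1e-12) stop("geometry error: collinear/degenerate atoms")
  aniso <- G / sum(diag(G)) - diag(3) / 3
  if (max(abs(eigen(aniso, symmetric = TRUE,
                    only.values = TRUE)$values)) < iso_tol) {
    warning("near-isotropic shape: steric tensor ~ 0")
  }
  alignment_tensor(scale * aniso)
}

#' Replica-ensemble container
#'
#' @param replicas list of \code{conformation} sharing one atom topology
#' @return list of class \code{replica_ensemble}
#' @export
replica_ensemble <- function(replicas) {
  if (inherits(replicas, "conformation")) replicas <- list(replicas)
  stopifnot(length(replicas) >= 1L)
  ref <- replicas[[1]]
  for (m in seq_along(replicas)) {
    r <- replicas[[m]]
    if (nrow(r) != nrow(ref) || !all(r$atom == ref$atom) ||
        !all(r$resno == ref$resno))
      stop("replica ", m, " does not share the ensemble topology")
  }
  structure(list(replicas = replicas, M = length(replicas)),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat(sprintf("<replica_ensemble> M = %d replicas, %d atoms each\n",
              x$M, nrow(x$replicas[[1]])))
  invisible(x)
}

#' Ensemble-averaged back-calculated RDCs
#'
#' D_calc(i) = (1/M) sum_m D_calc(i, replica m), with each replica's
#' alignment tensor obtained according to \code{mode}:
#' \describe{
#'   \item{per-replica-svd}{tensor fit by SVD to D_exp for each replica}
#'   \item{shared-svd}{one tensor per medium fit to D_exp against the
#'     replica-averaged orientational design}
#'   \item{per-replica-steric}{shape-predicted tensor per replica}
#'   \item{fixed-tensor}{a supplied tensor (or one per medium) applied to
#'     every replica}
#' }
#' Media are handled independently (one tensor per medium).
#'
#' @param ens a \code{replica_ensemble}
#' @param rdcs data.frame(residue, pair, D_exp) with optional medium and
#'   error columns
#' @param mode tensor mode, see above
#' @param tensor an \code{alignment_tensor}, or named list per medium
#'   (required for \code{"fixed-tensor"})
#' @param steric_scale alignment magnitude for the steric mode
#' @return data.frame: the matched rdc rows plus a D_calc column
#' @export
ensemble_average_rdc <- function(ens, rdcs,
                                 mode = c("shared-svd", "per-replica-svd",
                                          "per-replica-steric",
                                          "fixed-tensor"),
                                 tensor = NULL, steric_scale = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "replica_ensemble"))
  rdcs <- as.data.frame(rdcs)
  if (!"medium" %in% names(rdcs)) rdcs$medium <- "default"
  out <- lapply(split(rdcs, rdcs$medium), function(sub) {
    med <- sub$medium[1]
    designs <- lapply(ens$replicas, function(r) .rdc_design(r, sub))
    keep <- designs[[1]]$keep
    if (!any(keep))
      stop("validation error: no overlap between ensemble and RDC table")
    rec <- designs[[1]]$records
    Amats <- lapply(designs, `[[`, "A")
    dc <- switch(mode,
      "fixed-tensor" = {
        tns <- if (inherits(tensor, "alignment_tensor")) tensor
               else tensor[[med]]
        if (is.null(tns)) stop("fixed-tensor mode needs a tensor for medium ",
                               med)
        s5 <- tensor_components(tns)
        Reduce(`+`, lapply(Amats, function(A) A %*% s5)) / ens$M
      },
      "shared-svd" = {
        Abar <- Reduce(`+`, Amats) / ens$M
        s5 <- qr.solve(Abar, rec$D_exp)
        Abar %*% s5
      },
      "per-replica-svd" = {
        Reduce(`+`, lapply(seq_along(ens$replicas), function(m) {
          ft <- svd_fit_tensor(ens$replicas[[m]], sub)
          Amats[[m]] %*% tensor_components(ft$tensor)
        })) / ens$M
      },
      "per-replica-steric" = {
        Reduce(`+`, lapply(seq_along(ens$replicas), function(m) {
          st <- steric_tensor(ens$replicas[[m]], scale = steric_scale)
          Amats[[m]] %*% tensor_components(st)
        })) / ens$M
      })
    rec$D_calc <- as.numeric(dc)
    rec
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Atom-row lookup for gradient assembly: for each matched coupling, the
# replica atom indices of the two bonded atoms.
.rdc_atom_index <- function(conf, records) {
  idx <- matrix(NA_integer_, nrow(records), 2)
  for (i in seq_len(nrow(records))) {
    rn <- records$residue[i]
    if (records$pair[i] == "N-H") {
      idx[i, 1] <- which(conf$resno == rn & conf$atom == "N")
      idx[i, 2] <- which(conf$resno == rn & conf$atom == "H")
    } else {
      idx[i, 1] <- which(conf$resno == rn - 1L & conf$atom == "C")
      idx[i, 2] <- which(conf$resno == rn & conf$atom == "N")
    }
  }
  idx
}

#' Replica-averaged RDC restraint pseudoenergy and gradients
#'
#' E = alpha * sum_i w_i (Dbar_i - Dexp_i)^2, where Dbar is the replica
#' average of the back-calculated couplings and w_i = 1/error_i^2 when
#' errors are present (uniform otherwise). Gradients are taken with
#' respect to every replica's coordinates with the alignment tensor(s)
#' held fixed for the evaluation, matching the fitted-tensor restraint
#' scheme in which tensors are refit at a stride and frozen in between.
#'
#' @param ens a \code{replica_ensemble}
#' @param rdcs data.frame(residue, pair, D_exp), optional medium/error
#' @param alpha restraint force constant (energy per Hz^2), >= 0
#' @param mode tensor mode (see \code{ensemble_average_rdc}); gradients
#'   treat the tensor as fixed in all modes
#' @param tensor tensor(s) for \code{"fixed-tensor"} mode
#' @return list(E, grad) with grad a list of per-replica n x 3 matrices
#' @export
rdc_restraint_energy <- function(ens, rdcs, alpha = 1,
                                 mode = "fixed-tensor", tensor = NULL) {
  stopifnot(alpha >= 0, inherits(ens, "replica_ensemble"))
  rdcs <- as.data.frame(rdcs)
  if (!"medium" %in% names(rdcs)) rdcs$medium <- "default"
  n_at <- nrow(ens$replicas[[1]])
  grad <- lapply(seq_len(ens$M), function(m) matrix(0, n_at, 3))
  E <- 0
  for (med in unique(rdcs$medium)) {
    sub <- rdcs[rdcs$medium == med, , drop = FALSE]
    avg <- ensemble_average_rdc(ens, sub, mode = mode, tensor = tensor)
    w <- if ("error" %in% names(avg) && all(is.finite(avg$error)) &&
             all(avg$error > 0)) 1 / avg$error^2 else rep(1, nrow(avg))
    diff <- avg$D_calc - avg$D_exp
    E <- E + alpha * sum(w * diff^2)
    # frozen tensor per medium for the gradient
    tns <- switch(mode,
      "fixed-tensor" = if (inherits(tensor, "alignment_tensor")) tensor
                       else tensor[[med]],
      "shared-svd" = {
        designs <- lapply(ens$replicas, function(r) .rdc_design(r, sub))
        Abar <- Reduce(`+`, lapply(designs, `[[`, "A")) / ens$M
        tensor_from_components(
          as.numeric(qr.solve(Abar, designs[[1]]$records$D_exp)))
      },
      stop("gradients implemented for fixed-tensor and shared-svd modes"))
    S <- tns$S
    for (m in seq_len(ens$M)) {
      conf <- ens$replicas[[m]]
      idx <- .rdc_atom_index(conf, avg)
      X <- coords(conf)
      for (i in seq_len(nrow(avg))) {
        a <- idx[i, 1]; b <- idx[i, 2]
        u <- X[b, ] - X[a, ]
        nu <- sqrt(sum(u^2))
        v <- u / nu
        dmax <- rdc_dmax(avg$pair[i])
        Sv <- as.numeric(S %*% v)
        vSv <- sum(v * Sv)
        dD_du <- dmax * (2 / nu) * (Sv - vSv * v)   # d D / d r_b
        gpre <- alpha * 2 * w[i] * diff[i] / ens$M
        grad[[m]][b, ] <- grad[[m]][b, ] + gpre * dD_du
        grad[[m]][a, ] <- grad[[m]][a, ] - gpre * dD_du
      }
    }
  }
  list(E = E, grad = grad)
}

#' Write an alignment tensor as JSON
#'
#' @param tensor an \code{alignment_tensor}
#' @param path output path
#' @return invisibly, the path
#' @export
write_tensor_json <- function(tensor, path) {
  ev <- tensor$eigenvalues
  jsonlite::write_json(list(
    S = unclass(tensor$S),
    eigenvalues = as.list(ev),
    Da_NH_Hz = rdc_dmax("N-H") * ev[["Szz"]] / 2,
    rhombicity = tensor$rhombicity), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
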