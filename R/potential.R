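#' Toy potential for desk-scale sampling
#'
#' A coarse bonded potential standing in for a molecular force field in
#' the Monte-Carlo refinement: harmonic bonds and angles (reference
#' values taken from the input geometry), periodic torsional restraints
#' on phi/psi/omega, and a soft excluded-volume repulsion between CA
#' atoms of sequence-distant residues. Residues listed in
#' \code{soft_residues} carry no phi/psi torsion term, leaving the hinge
#' degree of freedom free. Energies in kJ/mol, lengths in Angstrom.
#'
#' @param conf reference \code{conformation} (defines topology and
#'   equilibrium geometry)
#' @param k_bond,k_angle,k_torsion,k_omega,k_ev force constants
#'   (kJ/mol/A^2, kJ/mol/rad^2, kJ/mol, kJ/mol, kJ/mol/A^2)
#' @param r_ev excluded-volume onset distance (A)
#' @param soft_residues residue indices whose phi/psi are unrestrained
#' @param auto build topology from the conformation (default); if FALSE,
#'   supply \code{bonds} (2-column index matrix) and \code{bond_r0}
#' @param bonds,bond_r0 explicit bond list for \code{auto = FALSE}
#' @return object of class \code{toy_potential}
#' @export
toy_potential <- function(conf, k_bond = 1000, k_angle = 300,
                          k_torsion = 5, k_omega = 50, k_ev = 50,
                          r_ev = 4.0, soft_residues = NULL,
                          auto = TRUE, bonds = NULL, bond_r0 = NULL) {
  X <- coords(conf)
  n <- nrow(X)
  aidx <- function(rn, at) {
    i <- which(conf$resno == rn & conf$atom == at)
    if (length(i) == 1L) i else NA_integer_
  }
  if (!auto) {
    stopifnot(!is.null(bonds))
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (is.null(bond_r0))
      bond_r0 <- sqrt(rowSums((X[bonds[, 1], , drop = FALSE] -
                               X[bonds[, 2], , drop = FALSE])^2))
    pot <- list(n_atoms = n, bonds = bonds, bond_r0 = bond_r0,
                k_bond = rep_len(k_bond, nrow(bonds)),
                angles = matrix(integer(0), 0, 3), angle_t0 = numeric(0),
                k_angle = numeric(0),
                torsions = matrix(integer(0), 0, 4), tor_p0 = numeric(0),
                k_tor = numeric(0),
                ev_pairs = matrix(integer(0), 0, 2),
                k_ev = k_ev, r_ev = r_ev, id = "custom")
    class(pot) <- "toy_potential"
    return(pot)
  }
  res <- sort(unique(conf$resno))
  bl <- list()
  for (rn in res) {
    for (pr in list(c("N", "H"), c("N", "CA"), c("CA", "C"),
                    c("CA", "CB"), c("C", "O"))) {
      i <- aidx(rn, pr[1]); j <- aidx(rn, pr[2])
      if (!is.na(i) && !is.na(j)) bl[[length(bl) + 1L]] <- c(i, j)
    }
    if ((rn + 1L) %in% res) {
      i <- aidx(rn, "C"); j <- aidx(rn + 1L, "N")
      if (!is.na(i) && !is.na(j)) bl[[length(bl) + 1L]] <- c(i, j)
    }
  }
  bonds <- do.call(rbind, bl)
  bond_r0 <- sqrt(rowSums((X[bonds[, 1], ] - X[bonds[, 2], ])^2))
  # angles: all pairs of bonded neighbours around each atom
  nbrs <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  al <- list()
  for (j in seq_len(n)) {
    nb <- nbrs[[j]]
    if (length(nb) >= 2)
      for (p in utils::combn(nb, 2, simplify = FALSE))
        al[[length(al) + 1L]] <- c(p[1], j, p[2])
  }
  angles <- do.call(rbind, al)
  angle_t0 <- vapply(seq_len(nrow(angles)), function(r)
    bond_angle(X[angles[r, 1], ], X[angles[r, 2], ], X[angles[r, 3], ]),
    numeric(1))
  # backbone torsion restraints
  tl <- list(); tk <- numeric(0)
  for (rn in res) {
    N <- aidx(rn, "N"); CA <- aidx(rn, "CA"); C <- aidx(rn, "C")
    Cp <- if ((rn - 1L) %in% res) aidx(rn - 1L, "C") else NA
    Nn <- if ((rn + 1L) %in% res) aidx(rn + 1L, "N") else NA
    CAn <- if ((rn + 1L) %in% res) aidx(rn + 1L, "CA") else NA
    soft <- rn %in% soft_residues
    if (!soft && !is.na(Cp)) {                      # phi
      tl[[length(tl) + 1L]] <- c(Cp, N, CA, C); tk <- c(tk, k_torsion)
    }
    if (!soft && !is.na(Nn)) {                      # psi
      tl[[length(tl) + 1L]] <- c(N, CA, C, Nn); tk <- c(tk, k_torsion)
    }
    if (!is.na(Nn) && !is.na(CAn)) {                # omega
      tl[[length(tl) + 1L]] <- c(CA, C, Nn, CAn); tk <- c(tk, k_omega)
    }
  }
  torsions <- if (length(tl)) do.call(rbind, tl) else
    matrix(integer(0), 0, 4)
  tor_p0 <- vapply(seq_len(nrow(torsions)), function(r)
    dihedral_angle(X[torsions[r, 1], ], X[torsions[r, 2], ],
                   X[torsions[r, 3], ], X[torsions[r, 4], ]), numeric(1))
  # excluded volume between CA atoms >= 3 residues apart
  ca <- which(conf$atom == "CA")
  ca_res <- conf$resno[ca]
  ev <- list()
  if (length(ca) > 1)
    for (i in seq_along(ca)) for (j in seq_along(ca))
      if (j > i && abs(ca_res[j] - ca_res[i]) >= 3)
        ev[[length(ev) + 1L]] <- c(ca[i], ca[j])
  ev_pairs <- if (length(ev)) do.call(rbind, ev) else
    matrix(integer(0), 0, 2)
  pot <- list(n_atoms = n, bonds = bonds, bond_r0 = bond_r0,
              k_bond = rep_len(k_bond, nrow(bonds)),
              angles = angles, angle_t0 = angle_t0,
              k_angle = rep_len(k_angle, nrow(angles)),
              torsions = torsions, tor_p0 = tor_p0, k_tor = tk,
              ev_pairs = ev_pairs, k_ev = k_ev, r_ev = r_ev,
              id = "auto-chain")
  class(pot) <- "toy_potential"
  pot
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf(
    "<toy_potential> %d atoms: %d bonds, %d angles, %d torsions, %d EV pairs\n",
    x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
    nrow(x$ev_pairs)))
  invisible(x)
}

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Toy-potential energy
#'
#' @param pot a \code{toy_potential}
#' @param X n x 3 coordinate matrix (Angstrom)
#' @return energy in kJ/mol
#' @export
toy_energy <- function(pot, X) {
  E <- 0
  if (nrow(pot$bonds)) {
    d <- sqrt(rowSums((X[pot$bonds[, 1], , drop = FALSE] -
                       X[pot$bonds[, 2], , drop = FALSE])^2))
    E <- E + sum(pot$k_bond * (d - pot$bond_r0)^2)
  }
  if (nrow(pot$angles)) {
    u <- X[pot$angles[, 1], , drop = FALSE] -
         X[pot$angles[, 2], , drop = FALSE]
    v <- X[pot$angles[, 3], , drop = FALSE] -
         X[pot$angles[, 2], , drop = FALSE]
    ct <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    th <- acos(pmax(-1, pmin(1, ct)))
    E <- E + sum(pot$k_angle * (th - pot$angle_t0)^2)
  }
  if (nrow(pot$torsions)) {
    # dihedral via dot/triple-product identities (no cross-product
    # matrices): x = (b1.b2)(b2.b3) - (b1.b3)|b2|^2, y = |b2| det[b1 b2 b3]
    Ti <- pot$torsions
    b1 <- X[Ti[, 2], , drop = FALSE] - X[Ti[, 1], , drop = FALSE]
    b2 <- X[Ti[, 3], , drop = FALSE] - X[Ti[, 2], , drop = FALSE]
    b3 <- X[Ti[, 4], , drop = FALSE] - X[Ti[, 3], , drop = FALSE]
    d12 <- rowSums(b1 * b2); d23 <- rowSums(b2 * b3)
    d13 <- rowSums(b1 * b3); d22 <- rowSums(b2 * b2)
    xx <- d12 * d23 - d13 * d22
    tp <- b1[, 1] * (b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2]) +
          b1[, 2] * (b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3]) +
          b1[, 3] * (b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
    phi <- atan2(sqrt(d22) * tp, xx)
    E <- E + sum(pot$k_tor * (1 - cos(phi - pot$tor_p0)))
  }
  if (nrow(pot$ev_pairs)) {
    d <- sqrt(rowSums((X[pot$ev_pairs[, 1], , drop = FALSE] -
                       X[pot$ev_pairs[, 2], , drop = FALSE])^2))
    ov <- pmax(0, pot$r_ev - d)
    E <- E + sum(pot$k_ev * ov^2)
  }
  if (!is.finite(E)) stop("overlap catastrophe: non-finite toy energy")
  E
}

#' Analytic gradient of the toy potential
#'
#' @param pot a \code{toy_potential}
#' @param X n x 3 coordinate matrix
#' @return n x 3 gradient matrix (kJ/mol/A)
#' @export
toy_gradient <- function(pot, X) {
  G <- matrix(0, nrow(X), 3)
  for (r in seq_len(nrow(pot$bonds))) {
    i <- pot$bonds[r, 1]; j <- pot$bonds[r, 2]
    u <- X[i, ] - X[j, ]; d <- sqrt(sum(u^2))
    g <- 2 * pot$k_bond[r] * (d - pot$bond_r0[r]) * u / d
    G[i, ] <- G[i, ] + g; G[j, ] <- G[j, ] - g
  }
  for (r in seq_len(nrow(pot$angles))) {
    i <- pot$angles[r, 1]; j <- pot$angles[r, 2]; k <- pot$angles[r, 3]
    u <- X[i, ] - X[j, ]; v <- X[k, ] - X[j, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    uh <- u / nu; vh <- v / nv
    ct <- max(-1, min(1, sum(uh * vh)))
    th <- acos(ct); st <- sqrt(max(1 - ct^2, 1e-12))
    dth_di <- (ct * uh - vh) / (nu * st)
    dth_dk <- (ct * vh - uh) / (nv * st)
    pre <- 2 * pot$k_angle[r] * (th - pot$angle_t0[r])
    G[i, ] <- G[i, ] + pre * dth_di
    G[k, ] <- G[k, ] + pre * dth_dk
    G[j, ] <- G[j, ] - pre * (dth_di + dth_dk)
  }
  for (r in seq_len(nrow(pot$torsions))) {
    ii <- pot$torsions[r, ]
    p1 <- X[ii[1], ]; p2 <- X[ii[2], ]; p3 <- X[ii[3], ]; p4 <- X[ii[4], ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    phi <- dihedral_angle(p1, p2, p3, p4)
    dA <- -nb2 / sum(n1^2) * n1
    dD <- nb2 / sum(n2^2) * n2
    c1 <- sum(b1 * b2) / sum(b2^2)
    c2 <- sum(b3 * b2) / sum(b2^2)
    dB <- -(1 + c1) * dA + c2 * dD
    dC <- c1 * dA - (1 + c2) * dD
    pre <- pot$k_tor[r] * sin(phi - pot$tor_p0[r])
    G[ii[1], ] <- G[ii[1], ] + pre * dA
    G[ii[2], ] <- G[ii[2], ] + pre * dB
    G[ii[3], ] <- G[ii[3], ] + pre * dC
    G[ii[4], ] <- G[ii[4], ] + pre * dD
  }
  for (r in seq_len(nrow(pot$ev_pairs))) {
    i <- pot$ev_pairs[r, 1]; j <- pot$ev_pairs[r, 2]
    u <- X[i, ] - X[j, ]; d <- sqrt(sum(u^2))
    if (d < pot$r_ev) {
      g <- -2 * pot$k_ev * (pot$r_ev - d) * u / d
      G[i, ] <- G[i, ] + g; G[j, ] <- G[j, ] - g
    }
  }
  G
}
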