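.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric xyz vectors
#' @return angle in radians in (-pi, pi]
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * .unit(b2))
  atan2(y, x)
}

#' Bond angle of three points
#' @param p1,p2,p3 numeric xyz vectors; angle at p2
#' @return angle in radians
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- .unit(p1 - p2); v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v))))
}

# Natural-extension (NeRF) placement: position D from A, B, C given the
# C-D bond length, B-C-D angle and A-B-C-D torsion.
.place_atom <- function(A, B, C, bond, angle, torsion) {
  bc <- .unit(C - B)
  n <- .unit(.cross(B - A, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(angle),
                 sin(angle) * cos(torsion),
                 sin(angle) * sin(torsion))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix about an axis
#'
#' @param axis 3-vector (normalized internally)
#' @param theta rotation angle (radians)
#' @return 3x3 rotation matrix
#' @export
rotation_matrix <- function(axis, theta) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.deg <- pi / 180

#' Build an idealized peptide chain from backbone torsions
#'
#' Constructs N, H, CA, C, O and a CB pseudo-side-chain atom per residue
#' (no CB for glycine, no H for proline) with ideal bond lengths and
#' angles, from per-residue phi/psi (and omega) torsions. Used by the
#' synthetic-data generators and test fixtures.
#'
#' @param n_res number of residues
#' @param phi,psi backbone torsions in degrees (recycled to length n_res)
#' @param omega peptide-bond torsion in degrees (default 180, trans)
#' @param sequence one-letter sequence (default all alanine)
#' @param model_id model identifier
#' @return a \code{conformation}
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, omega = 180,
                          sequence = NULL, model_id = 1L) {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res) * .deg
  psi <- rep_len(psi, n_res) * .deg
  omega <- rep_len(omega, n_res) * .deg
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n_res)

  # ideal geometry (Angstrom, degrees)
  b <- list(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
            N_H = 1.02, CA_CB = 1.53)
  a <- list(N_CA_C = 111.2 * .deg, CA_C_N = 116.2 * .deg,
            C_N_CA = 121.7 * .deg, CA_C_O = 120.8 * .deg,
            C_N_H = 119.5 * .deg, N_CA_CB = 110.5 * .deg)

  pos <- list()   # pos[["i|ATOM"]]
  put <- function(i, at, p) pos[[paste0(i, "|", at)]] <<- p
  getp <- function(i, at) pos[[paste0(i, "|", at)]]

  put(1, "N", c(0, 0, 0))
  put(1, "CA", c(b$N_CA, 0, 0))
  put(1, "C", getp(1, "CA") +
        b$CA_C * c(cos(pi - a$N_CA_C), sin(pi - a$N_CA_C), 0))
  for (i in seq_len(n_res)) {
    if (i > 1) {
      put(i, "N", .place_atom(getp(i - 1, "N"), getp(i - 1, "CA"),
                              getp(i - 1, "C"),
                              b$C_N, a$CA_C_N, psi[i - 1]))
      put(i, "CA", .place_atom(getp(i - 1, "CA"), getp(i - 1, "C"),
                               getp(i, "N"),
                               b$N_CA, a$C_N_CA, omega[i - 1]))
      put(i, "C", .place_atom(getp(i - 1, "C"), getp(i, "N"),
                              getp(i, "CA"),
                              b$CA_C, a$N_CA_C, phi[i]))
      if (aa[i] != "P")
        put(i, "H", .place_atom(getp(i - 1, "CA"), getp(i - 1, "C"),
                                getp(i, "N"),
                                b$N_H, a$C_N_H, 0))
    } else {
      put(1, "H", .place_atom(getp(1, "C"), getp(1, "CA"), getp(1, "N"),
                              b$N_H, a$C_N_H, pi))
    }
    put(i, "O", .place_atom(getp(i, "N"), getp(i, "CA"), getp(i, "C"),
                            b$C_O, a$CA_C_O, psi[i] + pi))
    if (aa[i] != "G")
      put(i, "CB", .place_atom(getp(i, "C"), getp(i, "N"), getp(i, "CA"),
                               b$CA_CB, a$N_CA_CB, -122.6 * .deg))
  }
  keys <- names(pos)
  ord <- order(as.integer(sub("\\|.*", "", keys)),
               match(sub(".*\\|", "", keys),
                     c("N", "H", "CA", "CB", "C", "O")))
  keys <- keys[ord]
  m <- do.call(rbind, pos[keys])
  resno <- as.integer(sub("\\|.*", "", keys))
  atom <- sub(".*\\|", "", keys)
  conformation(data.frame(
    resno = resno, aa = aa[resno], atom = atom,
    element = substr(atom, 1, 1),
    x = m[, 1], y = m[, 2], z = m[, 3],
    stringsAsFactors = FALSE), model_id = model_id)
}

#' Build a hinged two-arm helical chain
#'
#' Two alpha-helical arms joined at a hinge residue whose (phi, psi)
#' controls the inter-arm geometry: the chain's radius of gyration and
#' end-to-end side-chain distance respond monotonically to the hinge
#' opening over a wide range. This is the two-state toy used by the
#' ensemble generators and refinement tests.
#'
#' @param n_res total residues (default 20)
#' @param hinge_res hinge residue index (default middle)
#' @param hinge_phi,hinge_psi hinge torsions in degrees
#' @param model_id model identifier
#' @return a \code{conformation}
#' @export
build_hinged_chain <- function(n_res = 20, hinge_res = NULL,
                               hinge_phi = -57, hinge_psi = -47,
                               model_id = 1L) {
  if (is.null(hinge_res)) hinge_res <- ceiling(n_res / 2)
  stopifnot(hinge_res > 1, hinge_res < n_res)
  phi <- rep(-57, n_res); psi <- rep(-47, n_res)
  phi[hinge_res] <- hinge_phi
  psi[hinge_res] <- hinge_psi
  build_peptide(n_res, phi, psi, model_id = model_id)
}

#' Shipped toy systems for the refinement sampler
#'
#' \describe{
#'   \item{harmonic-dimer}{two atoms and one harmonic bond; used for the
#'     Boltzmann-sampling sanity check}
#'   \item{hinged-chain}{helical two-arm chain with a soft hinge
#'     (default 20 residues)}
#'   \item{beta-hairpin}{idealized two-strand hairpin with a tight turn}
#' }
#'
#' @param kind toy system id
#' @param n_res chain length where applicable
#' @return list(conformation, potential)
#' @export
build_toy_system <- function(kind = c("hinged-chain", "harmonic-dimer",
                                      "beta-hairpin"), n_res = 20) {
  kind <- match.arg(kind)
  if (kind == "harmonic-dimer") {
    conf <- conformation(data.frame(
      resno = c(1L, 1L), aa = "X", atom = c("X1", "X2"), element = "C",
      x = c(0, 1.5), y = 0, z = 0))
    pot <- toy_potential(conf, bonds = cbind(1, 2),
                         bond_r0 = 1.5, k_bond = 2000,
                         auto = FALSE)
    return(list(conformation = conf, potential = pot))
  }
  if (kind == "hinged-chain") {
    conf <- build_hinged_chain(n_res)
    pot <- toy_potential(conf, soft_residues = ceiling(n_res / 2))
    return(list(conformation = conf, potential = pot))
  }
  # beta-hairpin: two extended strands, 4-residue turn
  stopifnot(n_res >= 8)
  half <- floor((n_res - 2) / 2)
  phi <- c(rep(-120, half), -60, -90, rep(-120, n_res - half - 2))
  psi <- c(rep(130, half), -30, 0, rep(130, n_res - half - 2))
  conf <- build_peptide(n_res, phi, psi)
  pot <- toy_potential(conf)
  list(conformation = conf, potential = pot)
}

#' Apply a rigid-body transform to a conformation
#'
#' @param conf a \code{conformation}
#' @param R 3x3 rotation matrix
#' @param t translation 3-vector
#' @return transformed \code{conformation}
#' @export
transform_conformation <- function(conf, R = diag(3), t = c(0, 0, 0)) {
  X <- coords(conf) %*% t(R)
  conf$x <- X[, 1] + t[1]
  conf$y <- X[, 2] + t[2]
  conf$z <- X[, 3] + t[3]
  conf
}
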