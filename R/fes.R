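.atom_masses <- function(conf) {
  m <- .atomic_mass[conf$element]
  m[is.na(m)] <- 12.0
  unname(m)
}

#' Radius of gyration
#'
#' Mass-weighted (default) or uniform-weight Rg about the corresponding
#' centroid. Invariant under rigid-body transforms.
#'
#' @param conf a \code{conformation}
#' @param weighting \code{"mass"} or \code{"uniform"}
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(conf, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  X <- coords(conf)
  if (nrow(X) < 1L) stop("no atoms")
  if (nrow(X) == 1L) {
    warning("single atom: Rg = 0")
    return(0)
  }
  w <- if (weighting == "mass") .atom_masses(conf) else rep(1, nrow(X))
  ctr <- colSums(X * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)) / sum(w))
}

.sidechain_atoms <- function(conf, rn) {
  bb <- c("N", "CA", "C", "O", "H", "OXT")
  sel <- conf$resno == rn & !(conf$atom %in% bb) & conf$element != "H"
  conf[sel, , drop = FALSE]
}

#' Distance between two residues' side chains
#'
#' Default mode: distance between the centroids of the side-chain heavy
#' atoms. Alternatives: minimum heavy-atom distance, a named atom pair,
#' or CA-CA distance.
#'
#' @param conf a \code{conformation}
#' @param resA,resB residue indices
#' @param mode \code{"centroid"}, \code{"min"}, \code{"atoms"} or
#'   \code{"ca"}
#' @param atoms length-2 atom-name vector for \code{mode = "atoms"}
#' @return distance in Angstrom
#' @export
sidechain_distance <- function(conf, resA, resB,
                               mode = c("centroid", "min", "atoms", "ca"),
                               atoms = NULL) {
  mode <- match.arg(mode)
  if (mode == "ca") {
    a <- coords(conf[conf$resno == resA & conf$atom == "CA", ])
    b <- coords(conf[conf$resno == resB & conf$atom == "CA", ])
    stopifnot(nrow(a) == 1L, nrow(b) == 1L)
    return(sqrt(sum((a - b)^2)))
  }
  if (mode == "atoms") {
    stopifnot(length(atoms) == 2L)
    a <- coords(conf[conf$resno == resA & conf$atom == atoms[1], ])
    b <- coords(conf[conf$resno == resB & conf$atom == atoms[2], ])
    stopifnot(nrow(a) == 1L, nrow(b) == 1L)
    return(sqrt(sum((a - b)^2)))
  }
  A <- .sidechain_atoms(conf, resA)
  B <- .sidechain_atoms(conf, resB)
  for (rn in c(resA, resB)) {
    sc <- .sidechain_atoms(conf, rn)
    if (nrow(sc) == 0L)
      stop("residue ", rn, " has no side-chain heavy atoms",
           " (glycine?); try mode = 'ca'")
  }
  XA <- coords(A); XB <- coords(B)
  if (mode == "centroid") {
    sqrt(sum((colMeans(XA) - colMeans(XB))^2))
  } else {
    min(sqrt(outer(rowSums(XA^2), rowSums(XB^2), `+`) -
               2 * XA %*% t(XB)))
  }
}

#' Two-dimensional free-energy surface by Boltzmann inversion
#'
#' Bins samples of two reaction coordinates and converts occupancies to
#' free energies G(bin) = -kB T ln(n_bin / n_max), so the global minimum
#' is 0 kJ/mol. Empty bins carry +Inf as a sentinel and are never
#' interpolated.
#'
#' @param samples two-column matrix or data.frame of (x, y) samples
#' @param bins number of bins per axis (default 40)
#' @param temperature_K temperature (K)
#' @param padding extent padding as a fraction of the data range
#' @return object of class \code{fes_grid}: bin midpoints, counts, G
#' @export
compute_fes <- function(samples, bins = 40, temperature_K = 310,
                        padding = 0.05) {
  samples <- as.matrix(as.data.frame(samples)[, 1:2])
  n <- nrow(samples)
  if (n < 100) warning("fewer than 100 samples: FES will be noisy")
  rng_x <- range(samples[, 1]); rng_y <- range(samples[, 2])
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1)
    r + c(-1, 1) * padding * w
  }
  rng_x <- pad(rng_x); rng_y <- pad(rng_y)
  bx <- seq(rng_x[1], rng_x[2], length.out = bins + 1)
  by <- seq(rng_y[1], rng_y[2], length.out = bins + 1)
  ix <- findInterval(samples[, 1], bx, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(samples[, 2], by, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  tb <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
  counts[] <- as.integer(tb)
  if (sum(counts > 0) == 1L)
    warning("flat-degenerate surface: all samples in one bin")
  kT <- .nmr_const$kB * temperature_K
  G <- matrix(Inf, bins, bins)
  occ <- counts > 0
  G[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(x_mid = (bx[-1] + bx[-length(bx)]) / 2,
                 y_mid = (by[-1] + by[-length(by)]) / 2,
                 x_breaks = bx, y_breaks = by,
                 counts = counts, G = G,
                 temperature_K = temperature_K, n = n),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf(
    "<fes_grid> %dx%d bins, %d samples at %g K, depth %.2f kJ/mol\n",
    nrow(x$G), ncol(x$G), x$n, x$temperature_K,
    max(x$G[is.finite(x$G)])))
  invisible(x)
}

#' Write a FES grid as a long-format per-bin table
#'
#' @param grid a \code{fes_grid}
#' @param path output path
#' @return invisibly, the path
#' @export
write_fes_table <- function(grid, path) {
  df <- expand.grid(ix = seq_along(grid$x_mid),
                    iy = seq_along(grid$y_mid))
  df$x <- grid$x_mid[df$ix]; df$y <- grid$y_mid[df$iy]
  df$count <- grid$counts[cbind(df$ix, df$iy)]
  df$G <- grid$G[cbind(df$ix, df$iy)]
  df$G[!is.finite(df$G)] <- NA
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", paste(c("x", "y", "count", "G"),
                                collapse = "\t")), con)
  writeLines(sprintf("%.17g\t%.17g\t%d\t%s", df$x, df$y, df$count,
                     ifelse(is.na(df$G), "NA", sprintf("%.17g", df$G))),
             con)
  invisible(path)
}

.gauss_smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(mat) {
    out <- mat * 0
    for (d in -r:r) {
      sh <- mat * 0
      src <- max(1, 1 - d):min(nrow(mat), nrow(mat) - d)
      sh[src + d, ] <- mat[src, ]
      out <- out + k[d + r + 1] * sh
    }
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Basin analysis of a free-energy surface
#'
#' Locates local minima of the surface (8-neighbour rule over occupied
#' bins, after optional Gaussian smoothing of the occupancies) and
#' reports free-energy differences between requested basins, plus the
#' overall surface depth (maximum finite G).
#'
#' @param grid a \code{fes_grid}
#' @param points optional data.frame(name, x, y) of requested basin
#'   locations; each must fall in an occupied bin
#' @param smooth_sigma Gaussian smoothing width in bins (0 = off,
#'   default)
#' @return list of class \code{basin_report}: minima table, delta_G
#'   table (|G_b - G_a| with the lower basin named), depth
#' @export
basin_analysis <- function(grid, points = NULL, smooth_sigma = 0) {
  stopifnot(inherits(grid, "fes_grid"))
  if (sum(grid$counts > 0) < 2L) stop("need >= 2 occupied bins")
  cs <- .gauss_smooth2d(grid$counts, smooth_sigma)
  kT <- .nmr_const$kB * grid$temperature_K
  Gs <- matrix(Inf, nrow(cs), ncol(cs))
  occ <- cs > 0
  Gs[occ] <- -kT * log(cs[occ] / max(cs))
  nb <- expand.grid(dx = -1:1, dy = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
  is_min <- matrix(FALSE, nrow(Gs), ncol(Gs))
  for (i in seq_len(nrow(Gs))) for (j in seq_len(ncol(Gs))) {
    if (!is.finite(Gs[i, j])) next
    ok <- TRUE
    for (r in seq_len(nrow(nb))) {
      ii <- i + nb$dx[r]; jj <- j + nb$dy[r]
      if (ii >= 1 && ii <= nrow(Gs) && jj >= 1 && jj <= ncol(Gs) &&
          Gs[ii, jj] < Gs[i, j]) { ok <- FALSE; break }
    }
    is_min[i, j] <- ok
  }
  w <- which(is_min, arr.ind = TRUE)
  # basin G read off the (optionally smoothed) surface used for minima
  # detection; with equal-shape basins smoothing preserves their ratio
  # while suppressing single-bin occupancy noise
  minima <- data.frame(ix = w[, 1], iy = w[, 2],
                       x = grid$x_mid[w[, 1]], y = grid$y_mid[w[, 2]],
                       G = Gs[w])
  minima <- minima[order(minima$G), , drop = FALSE]
  rownames(minima) <- NULL
  delta <- NULL
  if (!is.null(points)) {
    points <- as.data.frame(points)
    bins_of <- function(x, y) {
      c(findInterval(x, grid$x_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE),
        findInterval(y, grid$y_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE))
    }
    basinG <- vapply(seq_len(nrow(points)), function(r) {
      b <- bins_of(points$x[r], points$y[r])
      if (grid$counts[b[1], b[2]] == 0L)
        stop("requested point '", points$name[r], "' lies in an empty bin")
      d2 <- (minima$ix - b[1])^2 + (minima$iy - b[2])^2
      minima$G[which.min(d2)]
    }, numeric(1))
    if (nrow(points) >= 2L) {
      pr <- utils::combn(seq_len(nrow(points)), 2)
      delta <- data.frame(
        a = points$name[pr[1, ]], b = points$name[pr[2, ]],
        delta_G = abs(basinG[pr[1, ]] - basinG[pr[2, ]]),
        lower = ifelse(basinG[pr[1, ]] <= basinG[pr[2, ]],
                       points$name[pr[1, ]], points$name[pr[2, ]]))
    }
  }
  structure(list(minima = minima, delta_G = delta,
                 depth = max(grid$G[is.finite(grid$G)])),
            class = "basin_report")
}

#' @export
print.basin_report <- function(x, ...) {
  cat(sprintf("<basin_report> %d minima, depth %.2f kJ/mol\n",
              nrow(x$minima), x$depth))
  if (!is.null(x$delta_G))
    for (r in seq_len(nrow(x$delta_G)))
      cat(sprintf("  dG(%s, %s) = %.2f kJ/mol (lower: %s)\n",
                  x$delta_G$a[r], x$delta_G$b[r], x$delta_G$delta_G[r],
                  x$delta_G$lower[r]))
  invisible(x)
}

#' Per-residue RMSF of a conformational ensemble
#'
#' Iteratively superposes all models onto the evolving mean structure
#' (backbone atoms by default, via least-squares fitting) and reports
#' the root-mean-square fluctuation of each residue's CA atom about the
#' mean. \code{superpose = "none"} skips fitting, for ensembles built
#' without rigid-body motion.
#'
#' @param ensemble list of \code{conformation} sharing one topology
#' @param superpose \code{"backbone"}, \code{"all"} or \code{"none"}
#' @param max_iter superposition iterations
#' @return data.frame(residue, rmsf) in Angstrom
#' @export
rmsf <- function(ensemble, superpose = c("backbone", "all", "none"),
                 max_iter = 5) {
  superpose <- match.arg(superpose)
  stopifnot(length(ensemble) >= 2L)
  ref <- ensemble[[1]]
  for (m in seq_along(ensemble))
    if (nrow(ensemble[[m]]) != nrow(ref) ||
        !all(ensemble[[m]]$atom == ref$atom) ||
        !all(ensemble[[m]]$resno == ref$resno))
      stop("topology mismatch at model ", m)
  xyz <- do.call(rbind, lapply(ensemble, function(cf)
    as.vector(t(coords(cf)))))
  if (superpose != "none") {
    sel_atoms <- if (superpose == "backbone")
      which(ref$atom %in% c("N", "CA", "C")) else seq_len(nrow(ref))
    inds <- sort(c(3 * (sel_atoms - 1) + 1, 3 * (sel_atoms - 1) + 2,
                   3 * sel_atoms))
    mean_xyz <- colMeans(xyz)
    for (it in seq_len(max_iter)) {
      xyz <- bio3d::fit.xyz(fixed = mean_xyz, mobile = xyz,
                            fixed.inds = inds, mobile.inds = inds)
      new_mean <- colMeans(xyz)
      if (max(abs(new_mean - mean_xyz)) < 1e-8) break
      mean_xyz <- new_mean
    }
  }
  mean_xyz <- colMeans(xyz)
  ca <- which(ref$atom == "CA")
  if (length(ca) == 0L) ca <- seq_len(nrow(ref))
  dev2 <- vapply(ca, function(a) {
    ii <- (3 * (a - 1) + 1):(3 * a)
    mean(rowSums((xyz[, ii, drop = FALSE] -
                    matrix(mean_xyz[ii], nrow(xyz), 3,
                           byrow = TRUE))^2))
  }, numeric(1))
  data.frame(residue = ref$resno[ca], rmsf = sqrt(dev2))
}
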