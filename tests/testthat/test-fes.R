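test_that("radius of gyration matches brute-force sums and symmetry", {
  pair <- conformation(data.frame(
    resno = c(1L, 1L), aa = "X", atom = c("X1", "X2"), element = "C",
    x = c(-1, 1), y = 0, z = 0))
  expect_equal(radius_of_gyration(pair), 1)
  set.seed(6)
  cloud <- conformation(data.frame(
    resno = seq_len(1000), aa = "A", atom = "CA",
    element = sample(c("C", "N", "O"), 1000, TRUE),
    x = rnorm(1000), y = rnorm(1000, 0, 2), z = rnorm(1000, 0, 0.5)))
  m <- c(C = 12.011, N = 14.007, O = 15.999)[cloud$element]
  X <- coords(cloud)
  ctr <- colSums(X * m) / sum(m)
  brute <- sqrt(sum(m * rowSums(sweep(X, 2, ctr)^2)) / sum(m))
  expect_equal(radius_of_gyration(cloud), brute, tolerance = 1e-12)
})

test_that("Rg and side-chain distances are rigid-body invariant", {
  conf <- build_hinged_chain(14, hinge_psi = 75)
  R <- rotation_matrix(c(0.3, 1, -0.2), 2.1)
  conf_t <- transform_conformation(conf, R = R, t = c(5, -3, 11))
  expect_equal(radius_of_gyration(conf_t), radius_of_gyration(conf),
               tolerance = 1e-10)
  expect_equal(sidechain_distance(conf_t, 3, 12),
               sidechain_distance(conf, 3, 12), tolerance = 1e-10)
})

test_that("side-chain distance modes are consistent", {
  conf <- build_peptide(8)
  d_cen <- sidechain_distance(conf, 2, 7, mode = "centroid")
  d_min <- sidechain_distance(conf, 2, 7, mode = "min")
  expect_lte(d_min, d_cen)
  # single-atom side chains: all heavy-atom modes agree
  expect_equal(d_cen, sidechain_distance(conf, 2, 7, mode = "atoms",
                                         atoms = c("CB", "CB")))
  # glycine has no side-chain heavy atoms
  confg <- build_peptide(6, sequence = "AGAAAA")
  expect_error(sidechain_distance(confg, 2, 5), "ca")
  expect_silent(sidechain_distance(confg, 2, 5, mode = "ca"))
  # hand-computed centroid arithmetic on explicit coordinates
  two <- conformation(data.frame(
    resno = c(1L, 1L, 2L, 2L), aa = "A",
    atom = c("CA", "CB", "CA", "CB"), element = "C",
    x = c(0, 1, 5, 6), y = 0, z = 0))
  expect_equal(sidechain_distance(two, 1, 2), 5)
})

test_that("uniform occupancy flattens the surface as n grows", {
  set.seed(10)
  n <- 1e5
  xy <- cbind(runif(n), runif(n))
  g <- compute_fes(xy, bins = 2, temperature_K = 310, padding = 0)
  expect_lt(max(g$G[is.finite(g$G)]), 0.1)
  expect_equal(sum(g$counts), n)
  expect_equal(min(g$G[g$counts > 0]), 0)
})

test_that("two-Gaussian populations give the Boltzmann closed form", {
  set.seed(9)
  n <- 1e5
  w <- sample(1:2, n, TRUE, c(0.7, 0.3))
  xy <- cbind(rnorm(n, c(8.2, 9.4)[w], 0.15),
              rnorm(n, c(24.8, 27.3)[w], 0.3))
  g <- compute_fes(xy, bins = 40, temperature_K = 310)
  ba <- basin_analysis(g, points = data.frame(
    name = c("B1", "D1"), x = c(8.2, 9.4), y = c(24.8, 27.3)),
    smooth_sigma = 1)
  expect_equal(ba$delta_G$delta_G, -kB_kj * 310 * log(0.3 / 0.7),
               tolerance = 0.2 / 2.18)
  expect_equal(ba$delta_G$lower, "B1")
})

test_that("free energies scale exactly linearly in temperature", {
  set.seed(2)
  xy <- cbind(rnorm(5000), rnorm(5000))
  g1 <- compute_fes(xy, bins = 20, temperature_K = 310)
  g2 <- compute_fes(xy, bins = 20, temperature_K = 620)
  fin <- is.finite(g1$G)
  expect_equal(g2$G[fin], 2 * g1$G[fin], tolerance = 1e-12)
})

test_that("Boltzmann reinversion recovers bin populations exactly", {
  set.seed(3)
  xy <- cbind(rnorm(20000), rnorm(20000))
  g <- compute_fes(xy, bins = 15, temperature_K = 353)
  kT <- kB_kj * 353
  occ <- g$counts > 0
  n_back <- max(g$counts) * exp(-g$G[occ] / kT)
  expect_equal(n_back, as.numeric(g$counts[occ]), tolerance = 1e-9)
})

test_that("basin analysis reads hand-built grids directly", {
  set.seed(4)
  # nearly-degenerate two-cell surface built from raw samples
  x <- c(rep(0.1, 1000), rep(0.9, 437))  # counts ratio -> dG = 2.2 at 310 K
  n2 <- round(1000 * exp(-2.2 / (kB_kj * 310)))
  x <- c(rep(0.1, 1000), rep(0.9, n2))
  xy <- cbind(x, 0.5)
  g <- compute_fes(xy, bins = 3, temperature_K = 310, padding = 0)
  ba <- basin_analysis(g, points = data.frame(name = c("a", "b"),
                                              x = c(0.1, 0.9),
                                              y = c(0.5, 0.5)))
  expect_equal(ba$delta_G$delta_G, 2.2, tolerance = 0.02)
  expect_error(basin_analysis(g, points = data.frame(name = "c",
                                                     x = 0.5, y = 0.5)),
               "empty bin")
})

test_that("two-state generator coordinates are bimodal with correct basins", {
  ts <- synth_two_state_ensemble(3e4, populations = c(0.7, 0.3),
                                 seed = 4, coords_only = TRUE)
  g <- compute_fes(ts$coordinates[, c("rg", "dist")], bins = 40,
                   temperature_K = 310)
  ba <- basin_analysis(g, points = data.frame(
    name = c("closed", "open"),
    x = ts$truth$well_rg, y = ts$truth$well_dist), smooth_sigma = 1)
  expect_equal(ba$delta_G$delta_G, -kB_kj * 310 * log(0.3 / 0.7),
               tolerance = 0.2 / 2.18)
  # minima sit within one bin of the generating means
  mins <- ba$minima[order(ba$minima$G)[1:2], ]
  bin_w <- diff(g$x_mid[1:2])
  expect_lt(min(abs(mins$x - ts$truth$well_rg[1])), 1.5 * bin_w)
  expect_lt(min(abs(mins$x - ts$truth$well_rg[2])), 1.5 * bin_w)
})

test_that("RMSF vanishes for rigid ensembles and matches two-point fluctuation", {
  base <- build_peptide(10)
  rigid <- lapply(1:6, function(m)
    transform_conformation(base, R = rotation_matrix(c(1, m, 0), 0.2 * m),
                           t = c(m, -m, 2 * m)))
  r <- rmsf(rigid, superpose = "backbone")
  expect_lt(max(r$rmsf), 1e-8)
  # one residue displaced +/- d in half the models
  d <- 0.5
  ens <- lapply(1:8, function(m) {
    cf <- build_peptide(10, model_id = m)
    i <- which(cf$resno == 5 & cf$atom == "CA")
    cf$x[i] <- cf$x[i] + ifelse(m <= 4, -d, d)
    cf
  })
  r2 <- rmsf(ens, superpose = "none")
  expect_equal(r2$rmsf[r2$residue == 5], d, tolerance = 1e-12)
  expect_equal(max(r2$rmsf[r2$residue != 5]), 0, tolerance = 1e-12)
  # identical copies
  same <- lapply(1:4, function(m) build_peptide(10, model_id = m))
  expect_lt(max(rmsf(same)$rmsf), 1e-12)
  # topology mismatch
  expect_error(rmsf(list(base, build_peptide(9))), "topology")
})
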