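test_that("bond vectors are unit length and correctly oriented", {
  conf <- conformation(data.frame(
    resno = c(2L, 2L), aa = "A", atom = c("N", "H"),
    element = c("N", "H"),
    x = c(0, 1.02), y = 0, z = 0))
  bv <- bond_vectors(conf, "N-H")
  expect_equal(unlist(bv[1, c("vx", "vy", "vz")]), c(vx = 1, vy = 0, vz = 0))
})

test_that("prolines carry no amide N-H vector", {
  conf <- build_peptide(6, sequence = "AAPAAA")
  bv <- bond_vectors(conf, "N-H")
  expect_false(3 %in% bv$residue)
  expect_true(all(c(2, 4, 5, 6) %in% bv$residue))
})

test_that("helical N-H vectors align with the helix axis", {
  conf <- build_peptide(12, phi = -57, psi = -47)
  bv <- bond_vectors(conf, "N-H")
  bv <- bv[bv$residue > 1, ]               # first amide is a chain end
  ca <- coords(conf[conf$atom == "CA", ])
  axis <- prcomp(ca)$rotation[, 1]
  ang <- acos(pmin(1, abs(as.matrix(bv[, 2:4]) %*% axis))) * 180 / pi
  expect_lt(max(ang), 25)
})

test_that("back-calculation matches a brute-force tensor contraction", {
  set.seed(5)
  tn <- random_tensor(5)
  conf <- build_hinged_chain(10, hinge_psi = 70)
  bc <- back_calculate_rdc(conf, tn, c("N-H", "C-N"))
  bvs <- rbind(cbind(suppressWarnings(bond_vectors(conf, "N-H")),
                     pair = "N-H"),
               cbind(suppressWarnings(bond_vectors(conf, "C-N")),
                     pair = "C-N"))
  brute <- vapply(seq_len(nrow(bvs)), function(i) {
    v <- unlist(bvs[i, c("vx", "vy", "vz")])
    rdc_dmax(bvs$pair[i]) * as.numeric(t(v) %*% tn$S %*% v)
  }, numeric(1))
  expect_equal(bc$D_calc, brute, tolerance = 1e-12)
})

test_that("zero tensor gives zero couplings; principal axis gives Dmax*Szz", {
  conf <- build_peptide(6)
  zero <- alignment_tensor(matrix(0, 3, 3))
  expect_true(all(back_calculate_rdc(conf, zero)$D_calc == 0))
  # axially symmetric tensor, vector along the unique axis
  S <- diag(c(-1e-4, -1e-4, 2e-4))
  tn <- alignment_tensor(S)
  conf2 <- conformation(data.frame(
    resno = c(2L, 2L), aa = "A", atom = c("N", "H"), element = c("N", "H"),
    x = 0, y = 0, z = c(0, 1.02)))
  bc <- back_calculate_rdc(conf2, tn)
  expect_equal(bc$D_calc, rdc_dmax("N-H") * 2e-4, tolerance = 1e-12)
})

test_that("unknown pair types are rejected", {
  expect_error(back_calculate_rdc(build_peptide(4), random_tensor(1),
                                  "C-H"), "pair")
})

test_that("Q factor follows the rms convention", {
  d <- c(3, -5, 2, 8)
  expect_equal(q_factor(d, d), 0)
  expect_equal(q_factor(rep(0, 4), d), 1)
  expect_equal(q_factor(1.1 * d, d), 0.1)
  expect_error(q_factor(d, rep(0, 4)), "undefined")
  # scale identity over c in [0, 2]
  for (cc in c(0, 0.4, 1, 1.6, 2))
    expect_equal(q_factor(cc * d, d), abs(cc - 1), tolerance = 1e-12)
})

test_that("SVD tensor fitting solves the noiseless inverse problem", {
  tn <- random_tensor(11)
  conf <- build_hinged_chain(20, hinge_psi = 85)
  bc <- back_calculate_rdc(conf, tn)
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = bc$D_calc)
  ft <- svd_fit_tensor(conf, rdc)
  expect_lt(max(abs(ft$tensor$S - tn$S)), 1e-9)
  expect_lt(ft$Q, 1e-9)
})

test_that("5% Gaussian noise gives Q near 0.05", {
  qs <- vapply(1:6, function(s) {
    set.seed(s)
    tn <- random_tensor(s + 20)
    conf <- build_hinged_chain(52, hinge_psi = 60 + 5 * s)
    bc <- back_calculate_rdc(conf, tn, c("N-H", "C-N"))
    sdn <- 0.05 * sqrt(mean(bc$D_calc^2))
    rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                      D_exp = bc$D_calc + rnorm(nrow(bc), 0, sdn))
    svd_fit_tensor(conf, rdc)$Q
  }, numeric(1))
  expect_lt(abs(mean(qs) - 0.05), 0.02)
})

test_that("underdetermined and degenerate fits fail loudly", {
  tn <- random_tensor(2)
  conf <- build_peptide(5)
  bc <- back_calculate_rdc(conf, tn)
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = bc$D_calc)
  expect_error(svd_fit_tensor(conf, rdc[1:4, ]), "underdetermined")
  # collinear vectors: all N-H along one axis
  conf2 <- conformation(data.frame(
    resno = rep(2:7, each = 2), aa = "A",
    atom = rep(c("N", "H"), 6), element = rep(c("N", "H"), 6),
    x = rep(seq(0, 25, by = 5), each = 2) + rep(c(0, 1.02), 6),
    y = 0, z = 0))
  rdc2 <- data.frame(residue = 2:7, pair = "N-H", D_exp = rnorm(6))
  expect_error(svd_fit_tensor(conf2, rdc2), "condition")
})

test_that("fitted tensor is a least-squares minimum", {
  set.seed(9)
  tn <- random_tensor(9)
  conf <- build_hinged_chain(16, hinge_psi = 40)
  bc <- back_calculate_rdc(conf, tn)
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = bc$D_calc + rnorm(nrow(bc), 0, 0.5))
  ft <- svd_fit_tensor(conf, rdc)
  obj <- function(t5) {
    d <- back_calculate_rdc(conf, tensor_from_components(t5))$D_calc
    sum((d - rdc$D_exp)^2)
  }
  s5 <- c(ft$tensor$S[1, 1], ft$tensor$S[2, 2], ft$tensor$S[1, 2],
          ft$tensor$S[1, 3], ft$tensor$S[2, 3])
  base <- obj(s5)
  for (k in 1:10)
    expect_gt(obj(s5 + rnorm(5, sd = 1e-5)), base)
})

test_that("rotational covariance: rotating frame and tensor together", {
  tn <- random_tensor(3)
  conf <- build_hinged_chain(12, hinge_psi = 95)
  R <- rotation_matrix(c(1, -2, 0.5), 1.1)
  conf_r <- transform_conformation(conf, R = R, t = c(3, -1, 2))
  tn_r <- alignment_tensor(R %*% tn$S %*% t(R))
  d0 <- back_calculate_rdc(conf, tn)$D_calc
  d1 <- back_calculate_rdc(conf_r, tn_r)$D_calc
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("steric tensor reflects molecular shape", {
  rod <- conformation(data.frame(
    resno = 1:30, aa = "A", atom = "CA", element = "C",
    x = seq(0, 43.5, length.out = 30), y = 0, z = 0))
  st <- steric_tensor(rod)
  expect_equal(abs(st$rhombicity), 0, tolerance = 1e-10)
  expect_equal(abs(st$axes[1, 3]), 1, tolerance = 1e-10)
  # regular tetrahedron: isotropic
  tet <- conformation(data.frame(
    resno = 1:4, aa = "A", atom = "CA", element = "C",
    x = c(1, 1, -1, -1), y = c(1, -1, 1, -1), z = c(1, -1, -1, 1)))
  expect_warning(st2 <- steric_tensor(tet), "isotropic")
  expect_lt(max(abs(st2$S)), 1e-12)
  # prolate 2:1:1 cloud: near-zero rhombicity
  set.seed(4)
  cloud <- conformation(data.frame(
    resno = 1:2000, aa = "A", atom = "CA", element = "C",
    x = rnorm(2000, 0, 2), y = rnorm(2000, 0, 1), z = rnorm(2000, 0, 1)))
  expect_lt(abs(steric_tensor(cloud)$rhombicity), 0.05)
})

test_that("ensemble averaging degenerates correctly and matches brute force", {
  tn <- random_tensor(6)
  conf <- build_hinged_chain(10, hinge_psi = 50)
  bc <- back_calculate_rdc(conf, tn)
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = bc$D_calc)
  # identical replicas = single structure
  ens <- replica_ensemble(lapply(1:4, function(m) conf))
  avg <- ensemble_average_rdc(ens, rdc, mode = "fixed-tensor",
                              tensor = tn)
  expect_equal(avg$D_calc, bc$D_calc, tolerance = 1e-12)
  # heterogeneous M = 16: matches an independent loop over replicas
  reps <- lapply(1:16, function(m)
    build_hinged_chain(10, hinge_psi = 20 + 8 * m, model_id = m))
  ens2 <- replica_ensemble(reps)
  avg2 <- ensemble_average_rdc(ens2, rdc, mode = "fixed-tensor",
                               tensor = tn)
  brute <- Reduce(`+`, lapply(reps, function(r)
    back_calculate_rdc(r, tn)$D_calc)) / 16
  expect_equal(avg2$D_calc, brute, tolerance = 1e-12)
})

test_that("two symmetric vectors average to the closed-form mean", {
  # axially symmetric tensor; vectors at +/- theta from the unique axis
  tn <- alignment_tensor(diag(c(-1e-4, -1e-4, 2e-4)))
  theta <- 0.4
  mk <- function(sgn) conformation(data.frame(
    resno = c(2L, 2L), aa = "A", atom = c("N", "H"),
    element = c("N", "H"),
    x = c(0, 1.02 * sin(sgn * theta)), y = 0,
    z = c(0, 1.02 * cos(theta))))
  ens <- replica_ensemble(list(mk(1), mk(-1)))
  rdc <- data.frame(residue = 2L, pair = "N-H", D_exp = 0)
  avg <- ensemble_average_rdc(ens, rdc, mode = "fixed-tensor",
                              tensor = tn)
  d_each <- rdc_dmax("N-H") *
    (2e-4 * cos(theta)^2 - 1e-4 * sin(theta)^2)
  expect_equal(avg$D_calc, d_each, tolerance = 1e-12)
})

test_that("restraint energy is exact in trivial cases", {
  tn <- random_tensor(8)
  conf <- build_hinged_chain(8, hinge_psi = 60)
  ens <- replica_ensemble(list(conf))
  bc <- back_calculate_rdc(conf, tn)
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = bc$D_calc)
  e0 <- rdc_restraint_energy(ens, rdc, alpha = 2, tensor = tn)
  expect_equal(e0$E, 0)
  expect_lt(max(vapply(e0$grad, function(g) max(abs(g)), numeric(1))),
            1e-10)
  # one coupling off by 1 Hz, alpha = 1 -> E = 1
  rdc1 <- rdc[1, , drop = FALSE]
  rdc1$D_exp <- rdc1$D_exp + 1
  e1 <- rdc_restraint_energy(ens, rdc1, alpha = 1, tensor = tn)
  expect_equal(e1$E, 1, tolerance = 1e-12)
})

test_that("analytic restraint gradients match central finite differences", {
  set.seed(12)
  tn <- random_tensor(12)
  ens <- replica_ensemble(lapply(1:3, function(m)
    build_hinged_chain(8, hinge_psi = 40 + 25 * m, model_id = m)))
  bc <- back_calculate_rdc(ens$replicas[[1]], tn, c("N-H", "C-N"))
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = 0.6 * bc$D_calc)
  en <- rdc_restraint_energy(ens, rdc, alpha = 1.5, tensor = tn)
  conf1 <- ens$replicas[[2]]
  h <- 1e-6
  for (at in c("N", "H", "C")) {
    a <- which(conf1$resno == 5 & conf1$atom == at)
    for (d in 1:3) {
      col <- c("x", "y", "z")[d]
      up <- ens; up$replicas[[2]][a, col] <- up$replicas[[2]][a, col] + h
      dn <- ens; dn$replicas[[2]][a, col] <- dn$replicas[[2]][a, col] - h
      fd <- (rdc_restraint_energy(up, rdc, 1.5, tensor = tn)$E -
             rdc_restraint_energy(dn, rdc, 1.5, tensor = tn)$E) / (2 * h)
      expect_equal(en$grad[[2]][a, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("restraint energy is non-negative and permutation symmetric", {
  set.seed(13)
  tn <- random_tensor(13)
  reps <- lapply(1:4, function(m)
    build_hinged_chain(8, hinge_psi = 30 * m, model_id = m))
  bc <- back_calculate_rdc(reps[[1]], tn)
  rdc <- data.frame(residue = bc$residue, pair = bc$pair,
                    D_exp = bc$D_calc + rnorm(nrow(bc)))
  e1 <- rdc_restraint_energy(replica_ensemble(reps), rdc, 2, tensor = tn)
  e2 <- rdc_restraint_energy(replica_ensemble(reps[c(3, 1, 4, 2)]), rdc,
                             2, tensor = tn)
  expect_gte(e1$E, 0)
  expect_equal(e1$E, e2$E, tolerance = 1e-12)
  g1 <- lapply(e1$grad, round, digits = 9)
  g2 <- lapply(e2$grad, round, digits = 9)
  expect_setequal(vapply(g1, function(g) paste(g, collapse = ","),
                         character(1)),
                  vapply(g2, function(g) paste(g, collapse = ","),
                         character(1)))
})

test_that("alignment tensor invariants are enforced", {
  expect_error(alignment_tensor(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                                       3, 3)), "traceless")
  expect_error(alignment_tensor(matrix(rnorm(9), 3, 3)), "symmetric")
  tn <- random_tensor(14)
  expect_equal(sum(tn$eigenvalues), 0, tolerance = 1e-15)
})
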