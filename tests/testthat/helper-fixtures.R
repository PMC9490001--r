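# shared fixtures built in code

# paper-style T1 delay grid (s)
t1_grid <- c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2)

# small random Saupe tensor with realistic magnitude (|S| ~ 1e-4..1e-3)
random_tensor <- function(seed = 1, scale = 3e-4) {
  set.seed(seed)
  tensor_from_components(rnorm(5, sd = scale))
}

# write a wide decay table in the package dialect
write_decay_fixture <- function(path, residues, rates, A = 100,
                                times = t1_grid, na_at = NULL) {
  hdr <- paste0("# residue\taa\t", paste(times, collapse = "\t"))
  rows <- vapply(seq_along(residues), function(i) {
    v <- formatC(A * exp(-rates[i] * times), format = "g", digits = 10)
    if (!is.null(na_at) && i == na_at[1]) v[na_at[2]] <- "NA"
    paste(c(residues[i], "A", v), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# per-residue hinge psi torsion of a hinged-chain conformation
hinge_psi_of <- function(cf, hinge) {
  g <- function(rn, at) unlist(cf[cf$resno == rn & cf$atom == at,
                                  c("x", "y", "z")])
  dihedral_angle(g(hinge, "N"), g(hinge, "CA"), g(hinge, "C"),
                 g(hinge + 1, "N")) * 180 / pi
}

kB_kj <- 0.0083144621
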