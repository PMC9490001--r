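#' Lipari-Szabo spectral density
#'
#' Two-Lorentzian model-free spectral density
#' J(w) = (2/5) [ S2 tau_m / (1 + (w tau_m)^2)
#'              + (1 - S2) tau / (1 + (w tau)^2) ],
#' with 1/tau = 1/tau_m + 1/tau_e. At tau_e = 0 (or S2 = 1) it reduces to
#' the single-Lorentzian rigid-rotor form.
#'
#' @param w angular frequency (rad/s), vectorized
#' @param S2 generalized order parameter in [0, 1]
#' @param tau_m global rotational correlation time (s)
#' @param tau_e internal correlation time (s)
#' @return spectral density values (s/rad)
#' @export
spectral_density <- function(w, S2, tau_m, tau_e = 0) {
  stopifnot(S2 >= 0, S2 <= 1, tau_m > 0, tau_e >= 0)
  j <- S2 * tau_m / (1 + (w * tau_m)^2)
  if (tau_e > 0 && S2 < 1) {
    tau <- tau_m * tau_e / (tau_m + tau_e)
    j <- j + (1 - S2) * tau / (1 + (w * tau)^2)
  }
  0.4 * j
}

#' Forward model-free relaxation rates
#'
#' Computes (R1, R2, NOE) for an amide 15N-1H spin pair from the
#' Lipari-Szabo spectral density inserted into the standard dipolar + CSA
#' expressions, at a single static field.
#'
#' @param S2 order parameter
#' @param tau_m_ns global tumbling time (ns)
#' @param tau_e_ps internal correlation time (ps)
#' @param R_ex exchange contribution to R2 (s^-1)
#' @param field a \code{field_params} object
#' @return named numeric vector c(R1, R2, NOE)
#' @export
lipari_szabo_rates <- function(S2, tau_m_ns, tau_e_ps = 0, R_ex = 0,
                               field = field_params()) {
  tm <- tau_m_ns * 1e-9; te <- tau_e_ps * 1e-12
  J <- function(w) spectral_density(w, S2, tm, te)
  wH <- field$wH; wN <- field$wN
  d2 <- field$d2; c2 <- field$c2
  R1 <- (d2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- (d2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) +
                    6 * J(wH) + 6 * J(wH + wN)) +
        (c2 / 6) * (4 * J(0) + 3 * J(wN)) + R_ex
  sigma <- (d2 / 4) * (6 * J(wH + wN) - J(wH - wN))
  NOE <- 1 + field$gamma_ratio * sigma / R1
  c(R1 = R1, R2 = R2, NOE = NOE)
}

#' Fit a single-exponential decay I(t) = A exp(-R t)
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a log-linear start;
#' parameter errors from the fit covariance. The fitted rate is invariant
#' under rescaling of all intensities.
#'
#' @param curve a \code{decay_curve}
#' @return list with rate (s^-1), amplitude, rate_err, amplitude_err,
#'   residuals and the residue id
#' @export
fit_monoexponential <- function(curve) {
  stopifnot(inherits(curve, "decay_curve"))
  t <- curve$times; y <- curve$intensities
  if (diff(range(y)) < .Machine$double.eps * max(abs(y), 1))
    stop("degenerate input: all intensities equal")
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- lm(log(y[pos]) ~ t[pos])
    A0 <- unname(exp(coef(lf)[1])); R0 <- unname(max(-coef(lf)[2], 1e-12))
  } else {
    A0 <- max(y); R0 <- 1 / max(t)
  }
  w <- if (!is.null(curve$errors) && all(curve$errors > 0))
    1 / curve$errors^2 else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-R * t),
                      start = list(A = A0, R = R0), weights = w,
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    err <- simpleError(paste0("fit error: ", conditionMessage(fit)))
    err$residuals <- y - A0 * exp(-R0 * t)
    stop(err)
  }
  cf <- coef(fit); se <- tryCatch(sqrt(diag(vcov(fit))),
                                  error = function(e) c(NA_real_, NA_real_))
  list(residue = curve$residue, rate = unname(cf[2]),
       amplitude = unname(cf[1]),
       rate_err = unname(se[2]), amplitude_err = unname(se[1]),
       residuals = unname(residuals(fit)))
}

#' Heteronuclear NOE from saturated / unsaturated intensities
#'
#' @param sat saturated peak intensity (vectorized)
#' @param unsat unsaturated (reference) peak intensity, must be > 0
#' @param sat_err,unsat_err optional intensity uncertainties
#' @return data.frame with columns noe and noe_err
#' @export
compute_hetnoe <- function(sat, unsat, sat_err = NA, unsat_err = NA) {
  if (any(unsat <= 0))
    stop("validation error: unsaturated intensity must be > 0")
  noe <- sat / unsat
  err <- abs(noe) * sqrt((sat_err / sat)^2 + (unsat_err / unsat)^2)
  data.frame(noe = noe, noe_err = err)
}

.trimmed_stats <- function(x, trim = 0.1) {
  xs <- sort(x)
  n <- length(xs)
  k <- floor(n * trim)
  core <- xs[(k + 1):(n - k)]
  c(mean = mean(core), sd = sd(core))
}

#' Flag residues in slow conformational exchange from R2/R1 ratios
#'
#' Residues whose R2/R1 ratio exceeds trimmed-mean + k * trimmed-SD of the
#' per-residue ratios are flagged as candidates for slow-timescale
#' exchange. Records with vanishing R1 are excluded with a warning.
#'
#' @param records data.frame with columns residue, R1, R2
#' @param k flag threshold in trimmed SDs (default 1.5)
#' @param trim trimming fraction per tail (default 0.1)
#' @return data.frame(residue, ratio, flag)
#' @export
flag_exchange_residues <- function(records, k = 1.5, trim = 0.1) {
  records <- as.data.frame(records)
  ok <- records$R1 > 1e-8
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " record(s) with R1 ~ 0")
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) < 10L)
    stop("insufficient data: need >= 10 records to flag exchange")
  ratio <- records$R2 / records$R1
  ts <- .trimmed_stats(ratio, trim)
  thr <- ts["mean"] + k * ts["sd"]
  data.frame(residue = records$residue, ratio = ratio,
             flag = ratio > thr)
}

.r2r1_ratio_iso <- function(tau_m, field) {
  r <- lipari_szabo_rates(1, tau_m * 1e9, 0, 0, field)
  unname(r["R2"] / r["R1"])
}

#' Estimate the global rotational correlation time from R2/R1
#'
#' Inverts the isotropic-tumbling R2/R1 relation (rigid limit, internal
#' motions and exchange neglected) for the mean ratio of the supplied
#' records; the records should come from rigid, non-flagged residues.
#' The relation is strictly increasing in tau_m over the physical range,
#' so the inversion is unique. Error from a seeded bootstrap over
#' residues.
#'
#' @param records data.frame with columns residue, R1, R2
#' @param field a \code{field_params}
#' @param n_boot bootstrap resamples (default 200); 0 disables
#' @param seed bootstrap seed
#' @return list(tau_m_ns, tau_m_err_ns, mean_ratio)
#' @export
estimate_tau_m <- function(records, field = field_params(),
                           n_boot = 200, seed = 1) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    stop("insufficient data: no records for tau_m estimation")
  invert <- function(ratio) {
    uniroot(function(tm) .r2r1_ratio_iso(tm, field) - ratio,
            interval = c(0.2e-9, 200e-9), tol = 1e-15)$root * 1e9
  }
  mr <- mean(records$R2 / records$R1)
  tau <- invert(mr)
  err <- NA_real_
  if (n_boot > 0 && nrow(records) > 1L) {
    set.seed(as.integer(seed))
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(records), replace = TRUE)
      invert(mean(records$R2[i] / records$R1[i]))
    })
    err <- sd(bs)
  }
  list(tau_m_ns = tau, tau_m_err_ns = err, mean_ratio = mr)
}

.mf_models <- list(
  list(id = 1L, pars = "S2"),
  list(id = 2L, pars = c("S2", "tau_e")),
  list(id = 3L, pars = c("S2", "R_ex")),
  list(id = 4L, pars = c("S2", "tau_e", "R_ex"))
)

.mf_chi2 <- function(theta, pars, obs, sig, tau_m_ns, field) {
  p <- c(S2 = 1, tau_e = 0, R_ex = 0)
  p[pars] <- theta
  if (!all(is.finite(p)) || p["S2"] < 0 || p["S2"] > 1 ||
      p["tau_e"] < 0 || p["R_ex"] < 0)
    return(1e12)
  pred <- lipari_szabo_rates(p["S2"], tau_m_ns, p["tau_e"], p["R_ex"], field)
  if (!all(is.finite(pred))) return(1e12)   # S2 = tau_e = 0 gives R1 = 0
  sum(((obs - pred) / sig)^2)
}

.mf_fit_one <- function(obs, sig, tau_m_ns, field) {
  lower <- c(S2 = 0, tau_e = 0, R_ex = 0)
  upper <- c(S2 = 1, tau_e = 3000, R_ex = 100)
  inits <- list(c(S2 = 0.85, tau_e = 30, R_ex = 0.5),
                c(S2 = 0.6, tau_e = 150, R_ex = 3),
                c(S2 = 0.95, tau_e = 5, R_ex = 0))
  fits <- lapply(.mf_models, function(m) {
    best <- NULL
    for (ini in inits) {
      o <- tryCatch(
        nlminb(ini[m$pars], .mf_chi2, pars = m$pars, obs = obs, sig = sig,
               tau_m_ns = tau_m_ns, field = field,
               lower = lower[m$pars], upper = upper[m$pars],
               control = list(iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$objective < best$objective))
        best <- o
    }
    k <- length(m$pars)
    list(model = m$id, pars = m$pars, theta = best$par,
         chi2 = best$objective, aic = best$objective + 2 * k)
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
}

.num_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) for (j in i:n) {
    hi <- h * max(abs(x[i]), 1); hj <- h * max(abs(x[j]), 1)
    xpp <- x; xpp[i] <- xpp[i] + hi; xpp[j] <- xpp[j] + hj
    xpm <- x; xpm[i] <- xpm[i] + hi; xpm[j] <- xpm[j] - hj
    xmp <- x; xmp[i] <- xmp[i] - hi; xmp[j] <- xmp[j] + hj
    xmm <- x; xmm[i] <- xmm[i] - hi; xmm[j] <- xmm[j] - hj
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
      (4 * hi * hj)
  }
  H
}

#' Lipari-Szabo model-free fit of per-residue relaxation data
#'
#' Fits each residue's (R1, R2, NOE) triple at a single field with the
#' model-free spectral density, selecting per residue among the four
#' standard models {S2}, {S2, tau_e}, {S2, R_ex}, {S2, tau_e, R_ex} by
#' AIC (chi^2 + 2k). Residues whose best chi^2 exceeds
#' \code{chi2_threshold} are flagged, not dropped.
#'
#' @param records data.frame with columns residue, R1, R2, NOE and
#'   optionally R1_err, R2_err, NOE_err (used as fit weights)
#' @param field a \code{field_params}
#' @param tau_m global tumbling time in ns, or \code{"optimize"} to
#'   estimate it from the unflagged R2/R1 ratios first
#' @param chi2_threshold goodness-of-fit flag threshold (default 11.3,
#'   the 0.99 chi-square quantile at 3 degrees of freedom)
#' @return data.frame(residue, model, S2, S2_err, tau_e, R_ex, chi2,
#'   fit_flag) with the shared tau_m (ns) as attribute \code{tau_m_ns}
#' @export
modelfree_fit <- function(records, field = field_params(),
                          tau_m = "optimize", chi2_threshold = 11.3) {
  records <- as.data.frame(records)
  need <- c("residue", "R1", "R2", "NOE")
  stopifnot(all(need %in% names(records)))
  if (identical(tau_m, "optimize") || identical(tau_m, "auto")) {
    sub <- records
    if (nrow(records) >= 10L) {
      fl <- flag_exchange_residues(records)
      sub <- records[!fl$flag, , drop = FALSE]
    }
    tau_m_ns <- estimate_tau_m(sub, field, n_boot = 0)$tau_m_ns
  } else {
    tau_m_ns <- as.numeric(tau_m)
    stopifnot(tau_m_ns > 0)
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    obs <- c(R1 = records$R1[i], R2 = records$R2[i], NOE = records$NOE[i])
    sig <- c(if ("R1_err" %in% names(records)) records$R1_err[i] else 1,
             if ("R2_err" %in% names(records)) records$R2_err[i] else 1,
             if ("NOE_err" %in% names(records)) records$NOE_err[i] else 1)
    sig[!is.finite(sig) | sig <= 0] <- 1
    ft <- .mf_fit_one(obs, sig, tau_m_ns, field)
    p <- c(S2 = 1, tau_e = 0, R_ex = 0)
    p[ft$pars] <- ft$theta
    s2_err <- NA_real_
    H <- tryCatch(.num_hessian(function(th)
      .mf_chi2(th, ft$pars, obs, sig, tau_m_ns, field), ft$theta),
      error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(solve(H / 2), error = function(e) NULL)
      if (!is.null(cov) && "S2" %in% ft$pars) {
        v <- diag(cov)[match("S2", ft$pars)]
        if (is.finite(v) && v > 0) s2_err <- sqrt(v)
      }
    }
    data.frame(residue = records$residue[i], model = ft$model,
               S2 = unname(p["S2"]), S2_err = s2_err,
               tau_e = unname(p["tau_e"]), R_ex = unname(p["R_ex"]),
               chi2 = ft$chi2, fit_flag = ft$chi2 > chi2_threshold)
  })
  res <- do.call(rbind, out)
  attr(res, "tau_m_ns") <- tau_m_ns
  res
}
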