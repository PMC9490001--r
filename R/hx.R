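#' Two-state opening model for hydrogen exchange
#'
#' closed <-> open (k_op, k_cl), open -> exchanged (k_int). All rates in
#' s^-1 and strictly positive.
#'
#' @param k_op opening rate
#' @param k_cl closing rate
#' @param k_int intrinsic random-coil exchange rate
#' @return list of class \code{ex2_model}
#' @export
ex2_model <- function(k_op, k_cl, k_int) {
  stopifnot(k_op > 0, k_cl > 0, k_int > 0)
  structure(list(k_op = k_op, k_cl = k_cl, k_int = k_int),
            class = "ex2_model")
}

#' Observed exchange rate of the two-state model
#'
#' k_obs = k_op * k_int / (k_cl + k_int). In the EX2 limit
#' (k_cl >> k_int) this reduces to k_op * k_int / k_cl, making the
#' protection factor k_int / k_obs = k_cl / k_op, the opening
#' equilibrium constant's inverse.
#'
#' @param model an \code{ex2_model}
#' @return k_obs (s^-1)
#' @export
simulate_kobs <- function(model) {
  stopifnot(inherits(model, "ex2_model"))
  model$k_op * model$k_int / (model$k_cl + model$k_int)
}

#' Fit an H/D-exchange intensity decay
#'
#' Single-exponential fit of the HSQC peak decay. Flags:
#' \code{"poorly constrained"} when the sampled times cover less than
#' half of 1/k_obs, \code{"increasing"} when intensities trend upward
#' (best-effort fit still returned), \code{"flat"} for constant curves
#' (near-zero rate returned).
#'
#' @param curve a \code{decay_curve}
#' @return list(residue, k_obs, k_obs_err, flags)
#' @export
fit_hx_decay <- function(curve) {
  stopifnot(inherits(curve, "decay_curve"))
  y <- curve$intensities; t <- curve$times
  flags <- character(0)
  rel_spread <- diff(range(y)) / max(abs(y), .Machine$double.eps)
  if (rel_spread < 1e-10) {
    warning("flat decay curve: rate unresolvable, returning ~0")
    return(list(residue = curve$residue, k_obs = 0,
                k_obs_err = NA_real_, flags = "flat"))
  }
  if (coef(lm(y ~ t))[2] > 0) {
    warning("validation warning: increasing intensities; best-effort fit")
    flags <- c(flags, "increasing")
  }
  ft <- tryCatch(fit_monoexponential(curve), error = function(e)
    list(rate = 0, rate_err = NA_real_))   # best effort: bound at no decay
  if (ft$rate > 0 && ft$rate * max(t) < 0.5) {
    warning("decay poorly constrained: time grid covers ",
            sprintf("%.2f", ft$rate * max(t)), " of 1/k_obs")
    flags <- c(flags, "poorly constrained")
  }
  list(residue = curve$residue, k_obs = ft$rate,
       k_obs_err = ft$rate_err,
       flags = if (length(flags)) paste(flags, collapse = ";") else "")
}

#' CLEANEX initial-slope exchange rate
#'
#' Weighted linear fit through the origin of the buildup ratio I/I0
#' against the mixing time: in the short-time regime the initial slope
#' equals the exchange rate k. Mixing times beyond 50 ms fall outside
#' that regime and trigger a warning.
#'
#' @param ratios data.frame with columns tau (mixing time, s) and ratio
#'   (I/I0), optionally error
#' @return list(k, k_err, n)
#' @export
cleanex_initial_slope <- function(ratios) {
  ratios <- as.data.frame(ratios)
  stopifnot(all(c("tau", "ratio") %in% names(ratios)))
  use <- ratios$tau > 0
  if (sum(use) < 2L)
    stop("need >= 2 nonzero mixing times for an initial slope")
  if (any(ratios$tau > 0.050))
    warning("mixing time(s) > 50 ms: outside the initial-slope regime")
  tau <- ratios$tau[use]; y <- ratios$ratio[use]
  w <- if ("error" %in% names(ratios) && all(ratios$error[use] > 0))
    1 / ratios$error[use]^2 else rep(1, length(tau))
  k <- sum(w * tau * y) / sum(w * tau^2)
  resid <- y - k * tau
  dof <- length(tau) - 1L
  k_err <- if (dof > 0)
    sqrt(sum(w * resid^2) / dof / sum(w * tau^2)) else NA_real_
  list(k = k, k_err = k_err, n = length(tau))
}

.intrinsic_table <- function() {
  path <- system.file("extdata", "intrinsic_rate_factors.tsv",
                      package = "nmrdyn")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "intrinsic_rate_factors.tsv")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") | startsWith(lines, "# res\t")]
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
  df <- read.table(text = lines[-1], sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- hdr
  rownames(df) <- df$res
  df
}

# Poly-DL-alanine reference rates (log10; acid/base in 1/(M min), water
# in 1/min, at 293 K) and activation energies (kcal/mol), per the same
# community parameterization as the side-chain table.
.hx_ref <- list(
  D2O = list(lkA = 1.62, lkB = 10.05, lkW = -1.5, pK = 15.05),
  H2O = list(lkA = 1.39, lkB = 10.08, lkW = -1.6, pK = 14.17),
  Ea = c(acid = 14, base = 17, water = 19),   # kcal/mol
  Tref = 293, Rgas = 1.98720425e-3            # kcal/(mol K)
)

#' Sequence-based intrinsic amide exchange rates
#'
#' Per-amide intrinsic (random-coil) exchange rates from the
#' poly-DL-alanine reference rates with nearest-neighbour side-chain
#' corrections, acid/base/water-catalysed terms and Arrhenius temperature
#' correction from 293 K. The first residue carries no backbone amide
#' proton and is not reported.
#'
#' @param sequence one-letter amino-acid sequence (length >= 2)
#' @param pD glass-electrode pD (D2O) or pH (H2O) reading, used directly
#' @param temperature_K sample temperature (K)
#' @param direction \code{"D2O"} for H->D decay experiments,
#'   \code{"H2O"} for H->H (CLEANEX) conditions
#' @return data.frame(residue, aa, k_int) with k_int in s^-1
#' @export
intrinsic_rates <- function(sequence, pD = 7.0, temperature_K = 293,
                            direction = c("D2O", "H2O")) {
  direction <- match.arg(direction)
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) < 2L) stop("sequence length must be >= 2")
  tab <- .intrinsic_table()
  known <- setdiff(rownames(tab), c("NT", "CT", "Dh", "Eh"))
  if (!all(aa %in% known))
    stop("unknown residue code: ",
         paste(unique(aa[!aa %in% known]), collapse = ", "))
  ref <- .hx_ref[[direction]]
  fT <- exp(-(.hx_ref$Ea / .hx_ref$Rgas) *
              (1 / temperature_K - 1 / .hx_ref$Tref))
  n <- length(aa)
  out <- lapply(2:n, function(i) {
    if (aa[i] == "P") return(NULL)      # no amide proton
    la <- tab[aa[i], "acid_L"] + tab[aa[i - 1], "acid_R"]
    lb <- tab[aa[i], "base_L"] + tab[aa[i - 1], "base_R"]
    if (i == 2L) {
      la <- la + tab["NT", "acid_R"]; lb <- lb + tab["NT", "base_R"]
    }
    if (i == n) {
      la <- la + tab["CT", "acid_L"]; lb <- lb + tab["CT", "base_L"]
    }
    k_min <- 10^(ref$lkA + la) * 10^(-pD) * fT["acid"] +
             10^(ref$lkB + lb) * 10^(pD - ref$pK) * fT["base"] +
             10^(ref$lkW) * fT["water"]
    data.frame(residue = i, aa = aa[i], k_int = k_min / 60)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' EX2 protection factors
#'
#' logP = log10(k_int / k_obs), valid in the EX2 limit where the
#' protection factor reports the closed/open equilibrium. Residues with
#' k_obs > k_int (logP < 0) are flagged as nonphysical under EX2 but
#' still reported.
#'
#' @param k_obs data.frame(residue, k_obs) with optional k_obs_err,
#'   method columns
#' @param k_int data.frame(residue, k_int) as from
#'   \code{intrinsic_rates}
#' @return data.frame(residue, aa, method, k_obs, k_obs_err, k_int,
#'   logP, logP_err, flags) with mean/sd of logP as attributes
#'   \code{logP_mean}, \code{logP_sd}
#' @export
protection_factors <- function(k_obs, k_int) {
  k_obs <- as.data.frame(k_obs); k_int <- as.data.frame(k_int)
  stopifnot(all(c("residue", "k_obs") %in% names(k_obs)),
            all(c("residue", "k_int") %in% names(k_int)))
  m <- merge(k_obs, k_int, by = "residue")
  if (nrow(m) == 0L) stop("no matching residues between k_obs and k_int")
  stopifnot(all(m$k_obs > 0), all(m$k_int > 0))
  logP <- log10(m$k_int / m$k_obs)
  err <- if ("k_obs_err" %in% names(m))
    m$k_obs_err / (m$k_obs * log(10)) else NA_real_
  flags <- ifelse(logP < 0, "nonphysical-under-EX2", "")
  if (any(logP < 0))
    warning(sum(logP < 0),
            " residue(s) with k_obs > k_int (logP < 0) under EX2")
  out <- data.frame(residue = m$residue,
                    aa = if ("aa" %in% names(m)) m$aa else "X",
                    method = if ("method" %in% names(m)) m$method
                             else "decay-fit",
                    k_obs = m$k_obs,
                    k_obs_err = if ("k_obs_err" %in% names(m))
                      m$k_obs_err else NA_real_,
                    k_int = m$k_int, logP = logP, logP_err = err,
                    flags = flags)
  attr(out, "logP_mean") <- mean(logP)
  attr(out, "logP_sd") <- sd(logP)
  out
}
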