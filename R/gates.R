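# Unit conversions (fluorescence -> RPU -> RNAP/s), Hill repression
# response evaluation and fitting, and conversion of flux-space binding
# constants to protein-number space.

#' Relative promoter units from median fluorescence
#'
#' `RPU = (<YFP> - <YFP>_0) / (<YFP>_RPU - <YFP>_0)` where `<YFP>_RPU` is
#' the reference-promoter strain and `<YFP>_0` the autofluorescence control.
#' A value below autofluorescence is returned as-is (negative), with a
#' warning.
#'
#' @param yfp Median fluorescence of the sample.
#' @param yfp_ref Median fluorescence of the reference-promoter strain.
#' @param yfp_auto Median autofluorescence.
#' @return Dimensionless RPU.
#' @export
rpu_from_fluorescence <- function(yfp, yfp_ref, yfp_auto) {
  den <- yfp_ref - yfp_auto
  if (den <= 0) stop("reference fluorescence must exceed autofluorescence")
  rpu <- (yfp - yfp_auto) / den
  if (any(rpu < 0)) warning("fluorescence below autofluorescence: negative RPU")
  rpu
}

#' Convert RPU to absolute RNAP flux
#'
#' 1 RPU corresponds to 0.019 RNAP/s per promoter; the per-cell total for
#' the reference plasmid multiplies by its copy number (9), giving
#' 0.171 RNAP/s at 1 RPU.
#'
#' @param rpu Promoter activity in RPU.
#' @param consts A [calibration_constants()] object.
#' @param total If `TRUE`, return the total flux over all plasmid copies.
#' @return RNAP/s.
#' @export
rpu_to_flux <- function(rpu, consts = calibration_constants(),
                        total = FALSE) {
  if (any(rpu < 0)) stop("rpu must be >= 0")
  f <- consts$rpu_to_rnaps * rpu
  if (total) f <- f * consts$n_circuit_copies
  f
}

#' Gate response parameters
#'
#' @param name Gate name.
#' @param y_min,y_max Output promoter activity floor/ceiling, RNAP/s.
#' @param K Half-repression input flux, RNAP/s (flux space).
#' @param n Hill cooperativity.
#' @param k Repressor binding constant, protein number (protein space).
#' @param alpha Translation efficiency of the gate's RBS, proteins/s/mRNA.
#' @param eta Cleavage efficiency of the gate's ribozyme, in `[0,1]`.
#' @return List of class `gate_response`.
#' @export
gate_response <- function(name, y_min, y_max, K = NA_real_, n = 2,
                          k = NA_real_, alpha = NA_real_, eta = NA_real_) {
  if (!(y_min >= 0 && y_min < y_max)) stop("need 0 <= y_min < y_max")
  if (n <= 0) stop("n must be > 0")
  structure(list(name = name, y_min = y_min, y_max = y_max, K = K, n = n,
                 k = k, alpha = alpha, eta = eta), class = "gate_response")
}

#' Evaluate a gate's Hill repression response
#'
#' `y = y_min + (y_max - y_min) * K^n / (K^n + x^n)` where the threshold is
#' the flux-space `K` (input `x` in RNAP/s) or the protein-space binding
#' constant `k` (input `x` a repressor protein count). For NOR gates the
#' input is the sum of the two input promoter activities; callers sum before
#' evaluating.
#'
#' @param x Input (flux or protein count), `>= 0`.
#' @param gate A [gate_response()].
#' @param space `"flux"` (uses `K`) or `"protein"` (uses `k`).
#' @return Output promoter activity, RNAP/s.
#' @export
hill_response <- function(x, gate, space = c("flux", "protein")) {
  space <- match.arg(space)
  thr <- if (space == "flux") gate$K else gate$k
  if (is.na(thr) || thr <= 0) stop("threshold constant not set for space ", space)
  if (any(x < 0)) stop("x must be >= 0")
  gate$y_min + (gate$y_max - gate$y_min) * thr^gate$n / (thr^gate$n + x^gate$n)
}

#' Fit Hill K and n to gate response points by Poisson regression
#'
#' `y_min` and `y_max` are fixed from the observed extremes (they are not
#' fitted); `K` and `n` minimize the Poisson negative log-likelihood of the
#' observed outputs against the Hill prediction, after rescaling outputs to
#' pseudo-counts with a configurable exposure. Derivative-free Nelder-Mead
#' minimization is run from a multistart grid (K at the quartiles of the
#' inputs, n in {1, 2, 4}). Outlier-flagged points are excluded and are
#' supplied by the user, never auto-detected.
#'
#' @param points `data.frame` with columns `x`, `y` (RNAP/s) and optional
#'   logical `outlier`.
#' @param y_min,y_max Fixed response floor/ceiling; default observed
#'   extremes of the non-outlier `y`.
#' @param exposure Pseudo-count scale applied to `y` before likelihood
#'   evaluation.
#' @return List with `K`, `n`, `converged`, `nll`, `n_points`.
#' @export
fit_hill <- function(points, y_min = NULL, y_max = NULL, exposure = 1e6) {
  if (!is.null(points$outlier)) points <- points[!points$outlier, , drop = FALSE]
  x <- points$x; y <- points$y
  if (length(x) < 3) stop("need >= 3 non-outlier points")
  if (diff(range(y)) == 0) stop("all outputs identical: K and n not identifiable")
  if (is.null(y_min)) y_min <- min(y)
  if (is.null(y_max)) y_max <- max(y)
  nll <- function(par) {
    K <- exp(par[1]); n <- exp(par[2])
    mu <- exposure * (y_min + (y_max - y_min) * K^n / (K^n + x^n))
    mu <- pmax(mu, 1e-300)
    sum(mu - exposure * y * log(mu))
  }
  xq <- stats::quantile(x[x > 0], c(0.25, 0.5, 0.75), names = FALSE)
  starts <- expand.grid(K = unique(xq), n = c(1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log(c(starts$K[i], starts$n[i])), nll,
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  # polish from the best start
  best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  list(K = exp(best$par[1]), n = exp(best$par[2]),
       converged = best$convergence == 0, nll = best$value,
       n_points = length(x), y_min = y_min, y_max = y_max)
}

#' Convert a flux-space threshold K to a protein-number binding constant k
#'
#' `k = alpha * K / (gamma * mu * (eta * (1 - b) + b))`, which for the
#' default uncleaved-degradation factor `b = 2` reduces to
#' `alpha * K / (gamma * mu * (2 - eta))`. The conversion passes the
#' steady-state chain flux -> mRNA -> protein: an input flux K sustains
#' `K / (gamma (2 - eta))` transcripts and `alpha m / mu` repressor
#' proteins.
#'
#' @param K Flux-space threshold, RNAP/s.
#' @param alpha Translation efficiency of the gate's RBS, proteins/s/mRNA.
#' @param eta Ribozyme cleavage efficiency in `[0,1]`.
#' @param gamma mRNA degradation rate, 1/s.
#' @param mu Dilution (growth) rate, 1/s.
#' @param b Uncleaved-mRNA degradation factor.
#' @return Binding constant k in protein number.
#' @export
k_from_K <- function(K, alpha, eta, gamma = 0.0067, mu = 0.00026, b = 2) {
  stopifnot(K >= 0, alpha > 0, eta >= 0, eta <= 1, gamma > 0, mu > 0)
  alpha * K / (gamma * mu * (eta * (1 - b) + b))
}
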