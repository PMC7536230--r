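#' Per-nucleotide stranded signal profile
#'
#' The central container of the package: a nonnegative real value for every
#' nucleotide position (0-based) of one strand of one reference sequence,
#' together with a units tag. Profiles hold, depending on the units,
#' normalized transcript levels M(x), RNAP flux J(x) (arbitrary or absolute,
#' per promoter or per cell), ribosome occupancies, or ribosomes per mRNA.
#'
#' @param reference_id Reference (plasmid/genome) name.
#' @param strand `"sense"` or `"antisense"`. Both strands are stored in
#'   genome coordinates; transcription direction is handled by the callers.
#' @param values Numeric vector, one value per nucleotide, all `>= 0`
#'   (`NA` allowed only for units `"ribosomes_per_mrna"`, marking positions
#'   with zero transcript).
#' @param units One of `"arb_mrna"`, `"flux_arb"`, `"rnap_per_s_per_promoter"`,
#'   `"rnap_per_s_total"`, `"arb_occupancy"`, `"ribosomes"`,
#'   `"ribosomes_per_mrna"`.
#' @return An object of class `stranded_profile`.
#' @export
stranded_profile <- function(reference_id, strand, values, units) {
  strand <- match.arg(strand, c("sense", "antisense"))
  units <- match.arg(units, profile_units())
  values <- as.numeric(values)
  if (units != "ribosomes_per_mrna" && anyNA(values)) {
    stop("profile values must not be NA for units '", units, "'")
  }
  if (any(values < 0, na.rm = TRUE)) stop("profile values must be >= 0")
  structure(
    list(reference_id = as.character(reference_id), strand = strand,
         values = values, units = units),
    class = "stranded_profile"
  )
}

profile_units <- function() {
  c("arb_mrna", "flux_arb", "rnap_per_s_per_promoter", "rnap_per_s_total",
    "arb_occupancy", "ribosomes", "ribosomes_per_mrna")
}

#' @export
print.stranded_profile <- function(x, ...) {
  cat(sprintf("<stranded_profile> %s [%s] %d nt, units=%s, total=%.6g\n",
              x$reference_id, x$strand, length(x$values), x$units,
              sum(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.stranded_profile <- function(x) length(x$values)

#' Aligned sequencing fragments
#'
#' Validates a table of mapped read intervals. Coordinates are 0-based,
#' half-open: a fragment covers positions `start, ..., end - 1`.
#'
#' @param reference_id Character vector of reference names.
#' @param start,end Integer vectors, `0 <= start < end`.
#' @param strand Character vector of `"+"` / `"-"`.
#' @param reference_length Optional named vector of reference lengths used to
#'   check `end <= length`.
#' @return A `data.frame` with columns `reference_id`, `start`, `end`,
#'   `strand`, of class `aligned_fragments`.
#' @export
aligned_fragments <- function(reference_id, start, end, strand,
                              reference_length = NULL) {
  n <- length(start)
  stopifnot(length(end) == n)
  reference_id <- rep_len(as.character(reference_id), n)
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  if (any(start < 0L)) stop("fragment start < 0")
  if (any(end <= start)) stop("fragment end must be > start")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(reference_length)) {
    lim <- reference_length[reference_id]
    if (anyNA(lim)) stop("fragment on unknown reference")
    if (any(end > lim)) stop("fragment extends past reference end")
  }
  out <- data.frame(reference_id = reference_id, start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("aligned_fragments", "data.frame")
  out
}

#' Calibration constants for absolute-unit conversions
#'
#' Holds the measured constants connecting arbitrary transcript-profile units
#' to absolute RNAP flux, plus ribosome-pool size. Defaults are the values
#' measured for the reference system: gamma is the shared mRNA degradation
#' rate; `rpu_to_rnaps` is the single-molecule calibration 1 RPU = 0.019
#' RNAP/s per promoter; `copy_ratio` is the circuit/output plasmid copy
#' correction (2.25); the power law `powerlaw_coeff * (gamma*M)^powerlaw_exp`
#' maps normalized profile height to RNAP/s per promoter after multiplication
#' by `copy_ratio * rpu_to_rnaps`; `n_circuit_copies` (9) and
#' `n_output_copies` (4) are plasmid copy numbers; `total_active_ribosomes`
#' is the actively translating pool (20,000 at a 45-min doubling time).
#'
#' @param gamma mRNA degradation rate, 1/s.
#' @param rpu_to_rnaps RNAP/s per promoter at 1 RPU.
#' @param copy_ratio Output/circuit plasmid copy factor.
#' @param powerlaw_coeff,powerlaw_exp Power-law calibration constants.
#' @param n_circuit_copies,n_output_copies Plasmid copy numbers.
#' @param total_active_ribosomes Actively translating ribosomes per cell.
#' @return List of class `calibration_constants`.
#' @export
calibration_constants <- function(gamma = 0.0067,
                                  rpu_to_rnaps = 0.019,
                                  copy_ratio = 2.25,
                                  powerlaw_coeff = 5.05e-5,
                                  powerlaw_exp = 1.64,
                                  n_circuit_copies = 9,
                                  n_output_copies = 4,
                                  total_active_ribosomes = 20000) {
  consts <- list(gamma = gamma, rpu_to_rnaps = rpu_to_rnaps,
                 copy_ratio = copy_ratio, powerlaw_coeff = powerlaw_coeff,
                 powerlaw_exp = powerlaw_exp,
                 n_circuit_copies = n_circuit_copies,
                 n_output_copies = n_output_copies,
                 total_active_ribosomes = total_active_ribosomes)
  if (any(unlist(consts) <= 0)) stop("all calibration constants must be > 0")
  structure(consts, class = "calibration_constants")
}

#' Absolute-flux conversion coefficient
#'
#' The composite coefficient `copy_ratio * rpu_to_rnaps * powerlaw_coeff`
#' (2.25 x 0.019 x 5.05e-5 = 2.16e-6 with the defaults), always computed
#' from its three factors.
#'
#' @param consts A [calibration_constants()] object.
#' @return Numeric scalar.
#' @export
absolute_flux_coefficient <- function(consts = calibration_constants()) {
  consts$copy_ratio * consts$rpu_to_rnaps * consts$powerlaw_coeff
}

#' Translation constants
#'
#' @param omega Ribosome elongation rate, 1/s (15).
#' @param gamma mRNA degradation rate, 1/s (shared with
#'   [calibration_constants()]).
#' @return List of class `translation_constants`.
#' @export
translation_constants <- function(omega = 15, gamma = 0.0067) {
  if (omega <= 0 || gamma <= 0) stop("translation constants must be > 0")
  structure(list(omega = omega, gamma = gamma),
            class = "translation_constants")
}

#' Window configuration for site calling and part strength
#'
#' @param n Averaging-window length in nt (10).
#' @param A Gap between a called site and the averaging window, nt (10).
#' @param ratio_threshold Dimensionless ratio threshold for TSS/TTS calls (5).
#' @param pseudo_flux_frac Pseudo-flux added to ratio denominators, as a
#'   fraction of the profile maximum, so zero-coverage positions do not
#'   produce infinities. Calls whose denominator was dominated by the
#'   pseudo-flux are flagged.
#' @return List of class `window_config`.
#' @export
window_config <- function(n = 10, A = 10, ratio_threshold = 5,
                          pseudo_flux_frac = 1e-12) {
  if (n < 1) stop("n must be >= 1")
  if (A < 0) stop("A must be >= 0")
  if (ratio_threshold <= 1) stop("ratio_threshold must be > 1")
  structure(list(n = as.integer(n), A = as.integer(A),
                 ratio_threshold = ratio_threshold,
                 pseudo_flux_frac = pseudo_flux_frac),
            class = "window_config")
}

# internal: 0-based half-open interval [start, end) -> 1-based R index vector
interval_idx <- function(start, end) (start + 1L):end

check_interval <- function(profile, start, end) {
  if (end <= start) stop("zero-length interval")
  if (start < 0 || end > length(profile$values)) {
    stop("interval [", start, ",", end, ") outside profile of length ",
         length(profile$values))
  }
  invisible(TRUE)
}
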