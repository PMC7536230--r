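# Transcript and ribosome-occupancy profile construction, and conversion
# between arbitrary, flux and absolute units.

#' Build strand-specific transcript profiles from aligned fragments
#'
#' Per-nucleotide fragment coverage is computed separately for each strand,
#' fragments overlapping any masked region (e.g. tRNA genes) are removed
#' entirely, and the coverage is divided by the total number of mapped
#' nucleotides in the sample (the sum of fragment lengths after masking,
#' across both strands) and multiplied by 1e9.
#'
#' @param fragments An [aligned_fragments()] table; all rows must belong to
#'   the reference being profiled.
#' @param reference_length Reference length in nt.
#' @param masked_regions Optional list of 0-based half-open `c(start, end)`
#'   intervals; a fragment overlapping a masked interval by >= 1 nt is
#'   dropped before any counting.
#' @param total_mapped_nt Optional externally supplied normalizer (sum of
#'   post-mask fragment lengths over the *whole sample*, all references).
#'   Defaults to the total over `fragments`; supply it when profiling one
#'   reference of a multi-reference sample.
#' @param reference_id Reference name for the returned profiles; defaults
#'   to the first fragment's reference.
#' @return List with elements `sense` and `antisense`, each a
#'   [stranded_profile()] with units `"arb_mrna"`.
#' @export
build_transcript_profile <- function(fragments, reference_length,
                                     masked_regions = NULL,
                                     total_mapped_nt = NULL,
                                     reference_id = NULL) {
  reference_length <- as.integer(reference_length)
  if (any(fragments$end > reference_length)) {
    stop("fragment extends past reference end")
  }
  kept <- mask_fragments(fragments, masked_regions)
  if (is.null(total_mapped_nt)) {
    total_mapped_nt <- sum(as.numeric(kept$end - kept$start))
  }
  if (nrow(kept) == 0 || total_mapped_nt <= 0) {
    stop("no fragments left after masking: normalizer is zero")
  }
  ref <- reference_id %||%
    (if (nrow(fragments)) fragments$reference_id[1] else "ref")
  out <- lapply(c(sense = "+", antisense = "-"), function(s) {
    f <- kept[kept$strand == s, , drop = FALSE]
    cov <- fragment_coverage(f$start, f$end, reference_length)
    cov * 1e9 / total_mapped_nt
  })
  list(
    sense = stranded_profile(ref, "sense", out$sense, "arb_mrna"),
    antisense = stranded_profile(ref, "antisense", out$antisense, "arb_mrna")
  )
}

# drop fragments overlapping any masked interval by >= 1 nt
mask_fragments <- function(fragments, masked_regions) {
  if (is.null(masked_regions) || length(masked_regions) == 0) return(fragments)
  drop <- rep(FALSE, nrow(fragments))
  for (m in masked_regions) {
    drop <- drop | (fragments$start < m[2] & fragments$end > m[1])
  }
  fragments[!drop, , drop = FALSE]
}

# nt-level depth by difference-accumulation
fragment_coverage <- function(start, end, len) {
  d <- numeric(len + 1L)
  if (length(start)) {
    ts <- tabulate(start + 1L, nbins = len + 1L)
    te <- tabulate(end + 1L, nbins = len + 1L)
    d <- ts - te
  }
  cumsum(d)[seq_len(len)]
}

#' Mean profile height over a gene (FPKM proxy)
#'
#' The transcript abundance of a gene is the arithmetic mean of the
#' normalized profile over its interval.
#'
#' @param profile A [stranded_profile()].
#' @param gene 0-based half-open `c(start, end)` interval.
#' @return Nonnegative scalar.
#' @export
compute_fpkm <- function(profile, gene) {
  check_interval(profile, gene[1], gene[2])
  mean(profile$values[interval_idx(gene[1], gene[2])])
}

#' Convert transcript level to RNAP flux (arbitrary scale)
#'
#' At steady state the RNAP flux at each position is the transcript level
#' times the mRNA degradation rate: J(x) = gamma * M(x).
#'
#' @param profile A profile with units `"arb_mrna"`.
#' @param gamma mRNA degradation rate, 1/s.
#' @return Profile with units `"flux_arb"`.
#' @export
mrna_to_flux <- function(profile, gamma = 0.0067) {
  if (profile$units != "arb_mrna") {
    stop("mrna_to_flux expects units 'arb_mrna', got '", profile$units, "'")
  }
  stranded_profile(profile$reference_id, profile$strand,
                   profile$values * gamma, "flux_arb")
}

#' Convert arbitrary flux to absolute RNAP/s
#'
#' Applies the empirical power-law calibration
#' `J_abs = copy_ratio * rpu_to_rnaps * powerlaw_coeff * (gammaM)^powerlaw_exp`
#' (2.16e-6 * (gammaM)^1.64 with the default constants, the coefficient being
#' computed from its three factors, never hard-coded), yielding RNAP/s per
#' promoter. With `total = TRUE` the result is additionally multiplied by the
#' circuit plasmid copy number to give the per-cell total flux.
#'
#' @param profile A profile with units `"flux_arb"` (gamma*M).
#' @param consts A [calibration_constants()] object.
#' @param total If `TRUE` return per-cell total flux.
#' @return Profile with units `"rnap_per_s_per_promoter"` or
#'   `"rnap_per_s_total"`.
#' @export
flux_to_absolute <- function(profile, consts = calibration_constants(),
                             total = FALSE) {
  if (profile$units != "flux_arb") {
    stop("flux_to_absolute expects units 'flux_arb', got '",
         profile$units, "'")
  }
  if (any(profile$values < 0)) stop("negative flux input")
  coef <- absolute_flux_coefficient(consts)
  v <- coef * profile$values^consts$powerlaw_exp
  if (total) v <- v * consts$n_circuit_copies
  stranded_profile(profile$reference_id, profile$strand, v,
                   if (total) "rnap_per_s_total" else "rnap_per_s_per_promoter")
}

#' Map ribosome footprints to P-site occupancy by center weighting
#'
#' Footprints with length outside `[23, 42]` nt are discarded. For each
#' retained footprint, 11 nt are removed from either end and each nucleotide
#' of the remaining center region receives the same score `1/(len - 22)`,
#' so every retained footprint contributes exactly one ribosome in total.
#'
#' @param footprints An [aligned_fragments()] table of footprint alignments.
#' @param reference_length Reference length in nt.
#' @param length_range Retained footprint length range (inclusive).
#' @param reference_id Reference name for the returned profiles; defaults
#'   to the first footprint's reference.
#' @return List with `sense` and `antisense` profiles, units
#'   `"arb_occupancy"`.
#' @export
map_psites_center_weighted <- function(footprints, reference_length,
                                       length_range = c(23L, 42L),
                                       reference_id = NULL) {
  reference_length <- as.integer(reference_length)
  len <- footprints$end - footprints$start
  keep <- len >= length_range[1] & len <= length_range[2]
  fp <- footprints[keep, , drop = FALSE]
  ref <- reference_id %||%
    (if (nrow(footprints)) footprints$reference_id[1] else "ref")
  out <- lapply(c(sense = "+", antisense = "-"), function(s) {
    f <- fp[fp$strand == s, , drop = FALSE]
    occ <- numeric(reference_length + 1L)
    if (nrow(f)) {
      l <- f$end - f$start
      w <- 1 / (l - 22)
      cs <- f$start + 11L          # center region [start+11, end-11)
      ce <- f$end - 11L
      d <- numeric(reference_length + 1L)
      # weighted difference-accumulation, one pass per footprint length class
      for (uw in unique(w)) {
        sel <- w == uw
        d <- d + uw * (tabulate(cs[sel] + 1L, nbins = reference_length + 1L) -
                       tabulate(ce[sel] + 1L, nbins = reference_length + 1L))
      }
      occ <- cumsum(d)
      occ <- pmax(occ, 0)   # clear float residue of the running sum
    }
    occ[seq_len(reference_length)]
  })
  list(
    sense = stranded_profile(ref, "sense", out$sense, "arb_occupancy"),
    antisense = stranded_profile(ref, "antisense", out$antisense,
                                 "arb_occupancy")
  )
}

#' Normalize a set of occupancy profiles to absolute ribosome numbers
#'
#' The occupancy at each nucleotide is divided by the grand total over all
#' supplied profiles (circuit and genome, both strands) and multiplied by the
#' total number of active ribosomes, so that the returned set sums exactly to
#' that pool size.
#'
#' @param occupancy_set List of [stranded_profile()]s spanning the sample.
#' @param consts A [calibration_constants()] object
#'   (`total_active_ribosomes`).
#' @return List of profiles with units `"ribosomes"`, in the same order.
#' @export
normalize_occupancy_absolute <- function(occupancy_set,
                                         consts = calibration_constants()) {
  total <- sum(vapply(occupancy_set, function(p) sum(p$values), numeric(1)))
  if (total <= 0) stop("all-zero occupancy: cannot normalize")
  scale <- consts$total_active_ribosomes / total
  lapply(occupancy_set, function(p) {
    stranded_profile(p$reference_id, p$strand, p$values * scale, "ribosomes")
  })
}

#' Ribosome occupancy per transcript
#'
#' Divides the absolute ribosome occupancy at each nucleotide by the
#' steady-state transcript count at the same position, J(x)/gamma. Positions
#' with zero flux are returned as `NA`.
#'
#' @param occupancy Profile with units `"ribosomes"`.
#' @param flux Profile in absolute flux units on the same reference/strand.
#' @param gamma mRNA degradation rate, 1/s.
#' @return Profile with units `"ribosomes_per_mrna"`.
#' @export
occupancy_per_transcript <- function(occupancy, flux, gamma = 0.0067) {
  if (occupancy$units != "ribosomes") {
    stop("occupancy must be in units 'ribosomes'")
  }
  if (!flux$units %in% c("rnap_per_s_per_promoter", "rnap_per_s_total")) {
    stop("flux must be in absolute units")
  }
  if (occupancy$reference_id != flux$reference_id ||
      occupancy$strand != flux$strand ||
      length(occupancy$values) != length(flux$values)) {
    stop("occupancy and flux profiles do not match")
  }
  v <- occupancy$values * gamma / flux$values
  v[flux$values == 0] <- NA_real_
  stranded_profile(occupancy$reference_id, occupancy$strand, v,
                   "ribosomes_per_mrna")
}
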