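# TSS/TTS detection and promoter / terminator / ribozyme quantification
# from RNAP flux profiles and raw fragments.

#' Call transcription start sites from a flux profile
#'
#' A TSS is called wherever the flux ratio between neighboring positions
#' exceeds the threshold: on the sense strand `J(x+1)/J(x) > thr` marks a TSS
#' at `x+1`; on the antisense strand the inverse ratio is used and the TSS is
#' at `x` (transcription proceeds toward lower coordinates). A pseudo-flux
#' `pseudo_flux_frac * max(J)` is added to denominators; calls whose
#' denominator was smaller than the pseudo-flux are flagged. Consecutive
#' super-threshold steps within `n` nt are merged to the position of the
#' largest single-step ratio. Calls coinciding with supplied ribozyme
#' cleavage sites are flagged `ribozyme_coincident` (for a promoter
#' immediately upstream of a ribozyme the apparent TSS is the cleavage site,
#' because the short released 5' fragment is lost during sample
#' preparation).
#'
#' @param flux A [stranded_profile()] of RNAP flux (any consistent units).
#' @param cfg A [window_config()].
#' @param ribozyme_sites Integer vector of known cleavage-site positions.
#' @return `data.frame` with columns `position`, `strand`, `kind`, `score`,
#'   `ribozyme_coincident`, `eps_dominated`.
#' @export
call_tss <- function(flux, cfg = window_config(),
                     ribozyme_sites = integer()) {
  J <- flux$values
  L <- length(J)
  if (L < 2) return(empty_site_calls())
  eps <- cfg$pseudo_flux_frac * max(J, 1e-300)
  if (flux$strand == "sense") {
    num <- J[-1]; den <- J[-L]
    pos <- which(num / (den + eps) > cfg$ratio_threshold)  # TSS at x+1 (0-based)
  } else {
    num <- J[-L]; den <- J[-1]
    pos <- which(num / (den + eps) > cfg$ratio_threshold) - 1L  # TSS at x
  }
  if (!length(pos)) return(empty_site_calls())
  score <- (num / (den + eps))[if (flux$strand == "sense") pos else pos + 1L]
  epsdom <- (den <= eps)[if (flux$strand == "sense") pos else pos + 1L]
  calls <- data.frame(position = pos, score = score, eps_dominated = epsdom)
  calls <- merge_adjacent_calls(calls, cfg$n, as.integer(ribozyme_sites))
  data.frame(
    position = calls$position, strand = flux$strand, kind = "TSS",
    score = calls$score,
    ribozyme_coincident = calls$position %in% as.integer(ribozyme_sites),
    eps_dominated = calls$eps_dominated,
    stringsAsFactors = FALSE
  )
}

empty_site_calls <- function() {
  data.frame(position = integer(), strand = character(), kind = character(),
             score = numeric(), ribozyme_coincident = logical(),
             eps_dominated = logical(), stringsAsFactors = FALSE)
}

# Merge super-threshold steps within n nt, keeping the largest-ratio
# position. Two refinements: ratios whose denominator was dominated by the
# pseudo-flux floor are artifacts of that floor and are outranked by any
# genuine (non-floored) step in the same group; and a call at a known
# ribozyme cleavage site is kept as its own call rather than being merged
# with the adjacent promoter's residual uncleaved step.
merge_adjacent_calls <- function(calls, n, ribozyme_sites = integer()) {
  o <- order(calls$position)
  calls <- calls[o, , drop = FALSE]
  at_ribo <- calls$position %in% ribozyme_sites
  kept_ribo <- calls[at_ribo, , drop = FALSE]
  calls <- calls[!at_ribo, , drop = FALSE]
  out <- kept_ribo
  if (nrow(calls)) {
    grp <- cumsum(c(1L, diff(calls$position) > n))
    keep <- unlist(lapply(split(seq_len(nrow(calls)), grp), function(i) {
      cand <- if (any(!calls$eps_dominated[i])) i[!calls$eps_dominated[i]]
              else i
      cand[which.max(calls$score[cand])]
    }), use.names = FALSE)
    out <- rbind(out, calls[keep, , drop = FALSE])
  }
  out[order(out$position), , drop = FALSE]
}

#' Call transcription termination sites by averaged-window ratio
#'
#' The averaged-window ratio at position x is the mean flux over the n
#' positions before x divided by the mean over the n positions from x on
#' (windows `[x-n, x)` and `[x, x+n)`); on the antisense strand the ratio is
#' inverted. Contiguous runs of AWR above the threshold are collapsed to a
#' single TTS at the run's maximum-AWR position (ties broken toward the
#' 5'-most position in transcription direction).
#'
#' @inheritParams call_tss
#' @return `data.frame` as in [call_tss()] with `kind = "TTS"` and the AWR
#'   as `score`.
#' @export
call_tts <- function(flux, cfg = window_config()) {
  J <- flux$values
  L <- length(J)
  n <- cfg$n
  if (L <= 2L * n) return(empty_site_calls())
  eps <- cfg$pseudo_flux_frac * max(J, 1e-300)
  awr <- awr_profile(J, n, eps, flux$strand)
  xs <- n:(L - n)                 # valid 0-based positions
  above <- awr > cfg$ratio_threshold
  if (!any(above)) return(empty_site_calls())
  idx <- which(above)
  grp <- cumsum(c(1L, diff(idx) != 1L))
  res <- lapply(split(idx, grp), function(i) {
    a <- awr[i]
    if (flux$strand == "sense") j <- i[which.max(a)]
    else j <- i[length(a) + 1L - which.max(rev(a))]
    c(pos = xs[j], score = awr[j],
      epsdom = as.numeric(denominator_eps_dominated(J, xs[j], n, eps,
                                                    flux$strand)))
  })
  res <- do.call(rbind, res)
  data.frame(
    position = as.integer(res[, "pos"]), strand = flux$strand, kind = "TTS",
    score = res[, "score"], ribozyme_coincident = FALSE,
    eps_dominated = res[, "epsdom"] > 0, stringsAsFactors = FALSE
  )
}

# AWR over valid positions x in n..L-n (0-based); strand-corrected
awr_profile <- function(J, n, eps, strand) {
  cs <- cumsum(c(0, J))
  xs <- n:(length(J) - n)
  up <- (cs[xs + 1L] - cs[xs - n + 1L]) / n        # mean over [x-n, x)
  dn <- (cs[xs + n + 1L] - cs[xs + 1L]) / n        # mean over [x, x+n)
  if (strand == "sense") up / (dn + eps) else dn / (up + eps)
}

denominator_eps_dominated <- function(J, x, n, eps, strand) {
  if (strand == "sense") mean(J[interval_idx(x, x + n)]) <= eps
  else mean(J[interval_idx(x - n, x)]) <= eps
}

#' Promoter strength at a called TSS
#'
#' The increase in RNAP flux across a TSS: the mean over the downstream
#' window `[TSS+A, TSS+A+n)` minus the mean over the upstream window
#' `[TSS-A-n, TSS-A)`; for antisense promoters the difference is multiplied
#' by -1. Sites whose windows extend past the profile get `NA` (no estimate)
#' rather than a truncated-window value.
#'
#' @param flux A [stranded_profile()] of RNAP flux.
#' @param tss A single-row site call (or a list with `position`, `strand`).
#' @param cfg A [window_config()].
#' @return Scalar delta-J in the units of `flux`, or `NA`.
#' @export
promoter_strength <- function(flux, tss, cfg = window_config()) {
  p <- tss$position; n <- cfg$n; A <- cfg$A
  J <- flux$values; L <- length(J)
  if (p - A - n < 0 || p + A + n > L) return(NA_real_)
  dn <- mean(J[interval_idx(p + A, p + A + n)])
  up <- mean(J[interval_idx(p - A - n, p - A)])
  dj <- dn - up
  if (identical(tss$strand, "antisense")) dj <- -dj
  dj
}

#' Terminator strength at a called TTS
#'
#' The fold-decrease in RNAP flux across a TTS: the mean over the upstream
#' window `[TTS-A-n, TTS-A)` divided by the mean over the downstream window
#' `[TTS+A, TTS+A+n)`; inverted for antisense terminators. A pseudo-flux is
#' added to the denominator.
#'
#' @inheritParams promoter_strength
#' @param tts A single-row site call.
#' @return Dimensionless fold T_S, or `NA` if windows are out of bounds.
#' @export
terminator_strength <- function(flux, tts, cfg = window_config()) {
  p <- tts$position; n <- cfg$n; A <- cfg$A
  J <- flux$values; L <- length(J)
  if (p - A - n < 0 || p + A + n > L) return(NA_real_)
  eps <- cfg$pseudo_flux_frac * max(J, 1e-300)
  up <- mean(J[interval_idx(p - A - n, p - A)])
  dn <- mean(J[interval_idx(p + A, p + A + n)])
  if (identical(tts$strand, "antisense")) dn / (up + eps) else up / (dn + eps)
}

#' Ribozyme cleavage efficiency from raw fragments
#'
#' The cleavage site is a 0-based boundary coordinate between the released
#' 5' piece and the retained 3' transcript. Cut fragments either end
#' exactly at the site or begin with it; uncut fragments span it. Only the
#' cut fragments downstream of the site (those beginning with it) enter
#' `F_cut` -- counting the upstream, end-at-site pieces as well would tally
#' cleaved read-through molecules twice and bias `CE` upward wherever
#' terminator read-through is appreciable. `CE = F_cut/(F_cut + F_uncut)`.
#' Fragments that neither abut nor overlap the site are ignored.
#'
#' @param fragments An [aligned_fragments()] table.
#' @param cleavage_site 0-based boundary coordinate.
#' @param strand `"+"` or `"-"`; only matching fragments are counted. On
#'   the minus strand the downstream (3') piece is the one *ending* at the
#'   site boundary.
#' @return List with `ce` (in `[0,1]`, `NA` if no informative fragments),
#'   `f_cut`, `f_uncut`, and `f_cut_upstream` (the end-at-site cut
#'   fragments, reported but not counted).
#' @export
ribozyme_ce <- function(fragments, cleavage_site, strand = "+") {
  f <- fragments[fragments$strand == strand, , drop = FALSE]
  if (strand == "+") {
    cut <- sum(f$start == cleavage_site)
    cut_up <- sum(f$end == cleavage_site)
  } else {
    cut <- sum(f$end == cleavage_site)
    cut_up <- sum(f$start == cleavage_site)
  }
  uncut <- sum(f$start < cleavage_site & f$end > cleavage_site)
  ce <- if (cut + uncut == 0) NA_real_ else cut / (cut + uncut)
  list(ce = ce, f_cut = cut, f_uncut = uncut, f_cut_upstream = cut_up)
}
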