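# Gene-level quantities: ribosome density and its normalizations,
# steady-state mRNA count, translation efficiency, ribosome usage,
# proteome fraction, and the repressor off-target screen.

#' Fit a 5'-elevation decay model to a genome-wide metagene
#'
#' Ribosome occupancy is elevated at the beginning of genes. Each gene's
#' occupancy over its first 300 nt is normalized by that gene's distal mean
#' (beyond 150 nt), the normalized traces are averaged into a metagene, and
#' `f(d) = 1 + a * exp(-d / lambda)` is fitted over distances d in [0, 300).
#' The fitted function (with `f(Inf) = 1` by construction) is used to
#' correct per-nucleotide occupancies before averaging. A degenerate fit
#' (`a <= 0`) falls back to the identity model with a warning.
#'
#' @param occupancy_set List of [stranded_profile()]s keyed (named) by
#'   reference.
#' @param genes `data.frame` with columns `reference_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`).
#' @param d_max Fit range in nt from the start codon.
#' @return Object of class `decay_model`: list with `a`, `lambda`, and
#'   `correction(d)` giving `f(d)`.
#' @export
fit_decay_model <- function(occupancy_set, genes, d_max = 300L) {
  traces <- list()
  for (i in seq_len(nrow(genes))) {
    v <- gene_values(occupancy_set, genes[i, ])
    if (length(v) < d_max || sum(v) == 0) next
    distal <- mean(v[151:min(length(v), d_max)])
    if (distal <= 0) next
    traces[[length(traces) + 1L]] <- v[seq_len(d_max)] / distal
  }
  if (length(traces) < 20) {
    stop("need >= 20 genes with nonzero occupancy to fit the decay model")
  }
  meta <- colMeans(do.call(rbind, traces))
  d <- seq_len(d_max) - 1L
  df <- data.frame(d = d, y = meta)
  # fit with a free baseline, then rescale so f(Inf) = 1: the per-gene
  # distal normalization leaves the metagene baseline slightly off one
  fit <- suppressWarnings(tryCatch(
    stats::nls(y ~ c0 + a * exp(-d / lambda), data = df,
               start = list(c0 = stats::median(meta[151:d_max]),
                            a = max(meta[1] - 1, 0.5), lambda = 60),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL
  ))
  if (is.null(fit)) {
    a <- 0; lambda <- Inf
  } else {
    cf <- stats::coef(fit)
    c0 <- unname(cf["c0"])
    a <- if (is.finite(c0) && c0 > 0) unname(cf["a"]) / c0 else 0
    lambda <- unname(cf["lambda"])
  }
  if (!is.finite(a) || a <= 1e-6 || !is.finite(lambda) || lambda <= 0) {
    warning("degenerate decay fit; using identity correction")
    return(identity_decay_model())
  }
  structure(list(a = a, lambda = lambda,
                 correction = function(d) 1 + a * exp(-d / lambda)),
            class = "decay_model")
}

#' Identity decay model (no 5' correction)
#' @return A `decay_model` with `f(d) = 1`.
#' @export
identity_decay_model <- function() {
  structure(list(a = 0, lambda = Inf, correction = function(d) rep(1, length(d))),
            class = "decay_model")
}

# occupancy values of one gene in translation order (5'->3')
gene_values <- function(occupancy_set, gene) {
  strand <- if (gene$strand %in% c("+", "sense")) "sense" else "antisense"
  prof <- pick_profile(occupancy_set, gene$reference_id, strand)
  v <- prof$values[interval_idx(gene$start, gene$end)]
  if (strand == "antisense") rev(v) else v
}

pick_profile <- function(profile_set, reference_id, strand) {
  for (p in profile_set) {
    if (p$reference_id == reference_id && p$strand == strand) return(p)
  }
  stop("no profile for reference '", reference_id, "' strand ", strand)
}

#' Ribosome density of a gene
#'
#' Mean per-nucleotide ribosome occupancy over the gene with three
#' normalizations: (1) the first and last five codons (15 nt each end) are
#' excluded; (2) each position is divided by the fitted 5'-elevation decay
#' correction at its distance from the start codon; (3) if the mean raw
#' density exceeds one, the top and bottom 5% of values are clipped to the
#' 5th/95th percentiles (90% winsorization).
#'
#' @param occupancy A [stranded_profile()] in absolute units, or a list of
#'   profiles (one is selected by the gene's reference/strand).
#' @param gene One-row `data.frame` with `reference_id`, `start`, `end`,
#'   `strand` (or a list with those fields).
#' @param decay_model A `decay_model`; defaults to identity.
#' @param winsorize Apply normalization (3).
#' @return Scalar ribosome density (ribosomes per nt).
#' @export
compute_rd <- function(occupancy, gene, decay_model = identity_decay_model(),
                       winsorize = TRUE) {
  if (inherits(occupancy, "stranded_profile")) occupancy <- list(occupancy)
  glen <- gene$end - gene$start
  if (glen <= 30) stop("gene too short to trim five codons from each end")
  v <- gene_values(occupancy, gene)           # 5'->3'
  trimmed <- v[16:(glen - 15)]
  d <- (16:(glen - 15)) - 1L                  # nt distance from start codon
  corrected <- trimmed / decay_model$correction(d)
  if (winsorize && mean(trimmed) > 1) {
    q <- stats::quantile(corrected, c(0.05, 0.95), names = FALSE)
    corrected <- pmin(pmax(corrected, q[1]), q[2])
  }
  mean(corrected)
}

#' Steady-state mRNA count of a gene
#'
#' Mean absolute RNAP flux over a 10-nt window at the 3' end of the gene
#' (positions -10 to 0, optionally shifted into the coding region to avoid
#' internal cryptic promoters), divided by the mRNA degradation rate.
#'
#' @param flux A [stranded_profile()] in absolute units (or list thereof).
#' @param gene One-row gene record (`reference_id`, `start`, `end`,
#'   `strand`).
#' @param gamma mRNA degradation rate, 1/s.
#' @param window_shift Shift of the averaging window into the gene, nt.
#' @param window Window length, nt.
#' @return Scalar transcript count.
#' @export
steady_state_mrna <- function(flux, gene, gamma = 0.0067, window_shift = 0L,
                              window = 10L) {
  if (inherits(flux, "stranded_profile")) flux <- list(flux)
  strand <- if (gene$strand %in% c("+", "sense")) "sense" else "antisense"
  prof <- pick_profile(flux, gene$reference_id, strand)
  if (strand == "sense") {
    a <- gene$end - window - window_shift; b <- gene$end - window_shift
  } else {
    a <- gene$start + window_shift; b <- gene$start + window_shift + window
  }
  if (a < gene$start || b > gene$end) stop("averaging window outside gene")
  mean(prof$values[interval_idx(a, b)]) / gamma
}

#' Translation efficiency
#'
#' Proteins produced per mRNA per second: `TE = RD * omega / m_ss`.
#'
#' @param rd Ribosome density (ribosomes per nt over the gene).
#' @param m_ss Steady-state mRNA count.
#' @param consts A [translation_constants()] object.
#' @return Scalar TE, `NA` if `m_ss` is zero.
#' @export
translation_efficiency <- function(rd, m_ss,
                                   consts = translation_constants()) {
  if (m_ss == 0) return(NA_real_)
  rd * consts$omega / m_ss
}

#' Ribosome usage of a gene
#'
#' Number of ribosomes sequestered by the gene at steady state: the sum of
#' the absolute occupancy profile over the gene (no trimming or
#' winsorization).
#'
#' @inheritParams compute_rd
#' @return Scalar ribosome count.
#' @export
ribosome_usage <- function(occupancy, gene) {
  if (inherits(occupancy, "stranded_profile")) occupancy <- list(occupancy)
  sum(gene_values(occupancy, gene))
}

#' Proteome fraction per gene
#'
#' The fraction of the total cellular proteome occupied by each gene
#' product: `Phi(i) = RD_i * MW_i / sum_k RD_k * MW_k`.
#'
#' @param genes `data.frame` with columns `rd` and `mw` (Da); any other
#'   columns are carried through.
#' @return The input with an added `proteome_fraction` column summing to 1.
#' @export
proteome_fraction <- function(genes) {
  w <- genes$rd * genes$mw
  if (any(w < 0) || anyNA(w)) stop("rd and mw must be nonnegative")
  tot <- sum(w)
  if (tot == 0) stop("all RD*MW products are zero")
  genes$proteome_fraction <- w / tot
  genes
}

#' Screen native genes for repressor off-target binding
#'
#' For each gene, the mean ribosome density over the states in which the
#' repressor is off is divided by the mean over the states in which it is
#' on; genes with fold-repression strictly above the threshold are returned,
#' sorted by decreasing fold. Genes with zero mean ON density are flagged
#' with infinite fold.
#'
#' @param rd_by_state Numeric matrix, genes x states (rownames = gene
#'   names).
#' @param repressor_on_states Character or integer vector naming the states
#'   (columns) in which the repressor is on.
#' @param fold_threshold Flagging threshold (5).
#' @return `data.frame` with columns `gene`, `fold_repression`, sorted
#'   descending.
#' @export
offtarget_screen <- function(rd_by_state, repressor_on_states,
                             fold_threshold = 5) {
  states <- colnames(rd_by_state)
  if (is.character(repressor_on_states)) {
    on_idx <- match(repressor_on_states, states)
    if (anyNA(on_idx)) stop("unknown state name")
  } else on_idx <- as.integer(repressor_on_states)
  off_idx <- setdiff(seq_len(ncol(rd_by_state)), on_idx)
  if (!length(on_idx) || !length(off_idx)) {
    stop("both ON and OFF state subgroups must be non-empty")
  }
  rd_on <- rowMeans(rd_by_state[, on_idx, drop = FALSE])
  rd_off <- rowMeans(rd_by_state[, off_idx, drop = FALSE])
  fold <- ifelse(rd_on == 0, ifelse(rd_off > 0, Inf, NA_real_),
                 rd_off / rd_on)
  hit <- which(!is.na(fold) & fold > fold_threshold)
  out <- data.frame(
    gene = if (is.null(rownames(rd_by_state))) as.character(hit)
           else rownames(rd_by_state)[hit],
    fold_repression = fold[hit], stringsAsFactors = FALSE
  )
  out[order(-out$fold_repression), , drop = FALSE]
}
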