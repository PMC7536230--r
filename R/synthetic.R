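# Ground-truth synthetic data: noise-free flux profiles built from the
# circuit model, fragment/footprint sampling with Poisson counting noise,
# and a background genome for proteome-fraction and off-target tests.
#
# The synthetic world is defined in transcript-molecule space (M, the
# normalized profile height the sequencing pipeline reconstructs). Planted
# part parameters are expressed in the printed absolute units through the
# same calibration maps the analysis applies, so that running the analysis
# on sampled data recovers the planted values in expectation:
#   * a promoter of absolute strength y on top of an upstream flux J0 adds
#     an M-step  Minv(J0 + y) - Minv(J0), with Minv the inverse of the
#     power-law calibration;
#   * a terminator of strength T_S (a flux fold) is a molecule fold
#     T_S^(1/powerlaw_exp);
#   * a ribozyme of efficiency eta cleaves that fraction of molecules at
#     its site; released 5' pieces shorter than `discard_5p_below` nt are
#     lost during library preparation.
# Global totals are constructed so the pipeline's fixed normalizers (the
# 1e9 mapped-nucleotide scale and the 20,000-ribosome pool) hold exactly
# in expectation; the genome background absorbs the remainder.

M_BUDGET <- 1e9

# molecule <-> per-cell total flux maps (the per-promoter power law times
# the circuit copy number, inverted)
inv_powerlaw <- function(J, consts) {
  (J / consts$n_circuit_copies /
     absolute_flux_coefficient(consts))^(1 / consts$powerlaw_exp) /
    consts$gamma
}

fwd_powerlaw <- function(M, consts) {
  consts$n_circuit_copies * absolute_flux_coefficient(consts) *
    (consts$gamma * M)^consts$powerlaw_exp
}

#' Synthetic circuit annotation
#'
#' Builds a compact annotated layout of the seven-gate circuit plus the
#' yfp output transcription unit, with the geometry the analysis assumes:
#' input promoters in tandem upstream of the gate's ribozyme insulator
#' (the last TSS 10 nt before the cleavage site, so the released 5' piece
#' is lost and the apparent TSS is the cleavage site), an RBS, the CDS,
#' and a terminator whose flux drop is jittered over a poly-T window.
#'
#' @param topo A [circuit_topology()].
#' @param cds_length CDS length, nt.
#' @param tss_spacing Spacing between tandem input promoter TSSs, nt.
#' @param polyT_width Terminator drop window, nt.
#' @return `data.frame` of class `circuit_annotation` with columns `part`,
#'   `class`, `reference_id`, `start`, `end`, `strand`, `gene`, `site`,
#'   `param_id`; attribute `reference_lengths`.
#' @export
synthetic_circuit_annotation <- function(topo = circuit_topology(),
                                         cds_length = 600L,
                                         tss_spacing = 30L,
                                         polyT_width = 8L) {
  rows <- list()
  add <- function(part, class, ref, start, end, gene, site, param_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      part = part, class = class, reference_id = ref,
      start = as.integer(start), end = as.integer(end), strand = "+",
      gene = gene, site = as.integer(site), param_id = param_id,
      stringsAsFactors = FALSE)
  }
  lay_gene <- function(gene, ref, cursor) {
    proms <- topo$inputs[[gene]]
    np <- length(proms)
    # last TSS sits 10 nt before the cleavage site
    tss <- cursor + 60L + (seq_len(np) - 1L) * tss_spacing
    r <- tss[np] + 10L
    gp <- topo$gene_parts[[gene]]
    for (i in seq_len(np)) {
      add(paste0("P_", proms[i]), "promoter", ref, tss[i] - 30L, tss[i],
          gene, tss[i], proms[i])
    }
    add(gp$ribozyme, "ribozyme", ref, tss[np], r, gene, r, gp$ribozyme)
    add(gp$rbs, "rbs", ref, r, r + 20L, gene, r, gp$rbs)
    cds_start <- r + 20L
    add(gene, "cds", ref, cds_start, cds_start + cds_length, gene,
        cds_start, gp$rbs)
    t0 <- cds_start + cds_length + 30L
    add(gp$terminator, "terminator", ref, t0, t0 + polyT_width, gene, t0,
        gp$terminator)
    t0 + polyT_width + 80L
  }
  cursor <- 0L
  circuit_genes <- setdiff(topo$genes, "yfp")
  for (g in circuit_genes) cursor <- lay_gene(g, "circuit", cursor)
  circuit_len <- cursor + 60L
  out_end <- lay_gene("yfp", "output", 0L)
  ann <- do.call(rbind, rows)
  class(ann) <- c("circuit_annotation", "data.frame")
  attr(ann, "reference_lengths") <- c(circuit = circuit_len,
                                      output = out_end + 60L)
  ann
}

#' Noise-free flux profiles from the forward model
#'
#' Sweeps each reference strand once, maintaining the set of active
#' transcript "streams": a promoter adds its state-dependent absolute
#' activity (converted to an M-step at the current flux level), a ribozyme
#' cleaves the stated fraction of every crossing molecule (released 5'
#' pieces shorter than `discard_5p_below` are lost), and a terminator peels
#' off molecules geometrically across its poly-T window so that the total
#' molecule fold over the window is `T_S^(1/powerlaw_exp)`. Returns both
#' the transcript classes (intervals with constant molecule abundance,
#' used for fragment sampling) and per-strand analytic profiles.
#'
#' @param annotation A [synthetic_circuit_annotation()]-style table.
#' @param activities Named vector of absolute promoter activities (RNAP/s
#'   per cell) for every `param_id` among the annotated promoters.
#' @param params A [circuit_params()] (terminator folds, ribozyme
#'   efficiencies).
#' @param consts A [calibration_constants()].
#' @param discard_5p_below Released 5' cleavage pieces shorter than this
#'   many nt are lost.
#' @return List with `classes` (`data.frame`: reference_id, strand, start,
#'   end, amount), `M` and `J` (lists of [stranded_profile()] pairs per
#'   reference).
#' @export
forward_flux <- function(annotation, activities, params,
                         consts = calibration_constants(),
                         discard_5p_below = 50L) {
  part_tbl <- params$parts_table
  term_fold <- stats::setNames(
    part_tbl$value[part_tbl$class == "terminator"],
    part_tbl$part[part_tbl$class == "terminator"])
  ribo_eta <- stats::setNames(
    part_tbl$value[part_tbl$class == "ribozyme"],
    part_tbl$part[part_tbl$class == "ribozyme"])
  ref_len <- attr(annotation, "reference_lengths")
  classes <- list(); Mp <- list(); Jp <- list()
  for (ref in names(ref_len)) {
    L <- ref_len[[ref]]
    for (strand in c("sense", "antisense")) {
      bed_strand <- if (strand == "sense") "+" else "-"
      ann <- annotation[annotation$reference_id == ref &
                          annotation$strand == bed_strand, , drop = FALSE]
      ev <- build_events(ann, activities, term_fold, ribo_eta, strand, L)
      cls <- sweep_classes(ev, L, consts, discard_5p_below)
      if (strand == "antisense" && nrow(cls)) {
        new_start <- L - cls$end; new_end <- L - cls$start
        cls$start <- new_start; cls$end <- new_end
      }
      if (nrow(cls)) {
        cls$reference_id <- ref; cls$strand <- bed_strand
        classes[[paste(ref, strand)]] <- cls
      }
      M <- class_coverage(cls, L)
      Mp[[ref]][[strand]] <- stranded_profile(ref, strand, M, "arb_mrna")
      Jp[[ref]][[strand]] <- stranded_profile(ref, strand,
                                              fwd_powerlaw(M, consts),
                                              "rnap_per_s_total")
    }
  }
  cls_all <- if (length(classes)) do.call(rbind, classes) else
    data.frame(start = integer(), end = integer(), amount = numeric(),
               reference_id = character(), strand = character())
  rownames(cls_all) <- NULL
  list(classes = cls_all, M = Mp, J = Jp)
}

# events in sweep coordinates (reflected for antisense)
build_events <- function(ann, activities, term_fold, ribo_eta, strand, L) {
  if (!nrow(ann)) return(NULL)
  ev <- list()
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    if (a$class == "promoter") {
      y <- activities[[a$param_id]]
      pos <- if (strand == "sense") a$site else L - 1L - a$site
      ev[[length(ev) + 1L]] <- list(type = "promoter", pos = pos, y = y)
    } else if (a$class == "ribozyme") {
      pos <- if (strand == "sense") a$site else L - a$site
      ev[[length(ev) + 1L]] <- list(type = "ribozyme", pos = pos,
                                    eta = ribo_eta[[a$param_id]])
    } else if (a$class == "terminator") {
      w <- a$end - a$start
      pos <- if (strand == "sense") a$start else L - a$end
      ev[[length(ev) + 1L]] <- list(type = "terminator", pos = pos, w = w,
                                    T_S = term_fold[[a$param_id]])
    }
  }
  ev[order(vapply(ev, function(e) e$pos, numeric(1)))]
}

# one sense-direction sweep; returns classes [start, end) with amounts
sweep_classes <- function(events, L, consts, discard_5p_below) {
  out_s <- integer(); out_e <- integer(); out_a <- numeric()
  emit <- function(s, e, a) {
    if (e > s && a > 0) {
      out_s[length(out_s) + 1L] <<- s
      out_e[length(out_e) + 1L] <<- e
      out_a[length(out_a) + 1L] <<- a
    }
  }
  origin <- integer(); amount <- numeric()   # active streams
  for (ev in events) {
    if (ev$type == "promoter") {
      # add the M-step that raises the observed absolute flux by exactly y
      # on top of the current observed level (read-through included)
      M_cur <- sum(amount)
      Mnew <- inv_powerlaw(fwd_powerlaw(M_cur, consts) + ev$y, consts) -
        M_cur
      origin <- c(origin, ev$pos); amount <- c(amount, Mnew)
    } else if (ev$type == "ribozyme") {
      r <- ev$pos; eta <- ev$eta
      if (length(origin)) {
        cleaved <- eta * amount
        keep5p <- (r - origin) >= discard_5p_below
        for (i in which(keep5p)) emit(origin[i], r, cleaved[i])
        amount <- amount * (1 - eta)
        origin <- c(origin, r); amount <- c(amount, sum(cleaved))
      }
    } else if (ev$type == "terminator") {
      f <- ev$T_S^(1 / consts$powerlaw_exp / ev$w)   # per-nt molecule fold
      for (j in seq_len(ev$w)) {
        stopfrac <- 1 - 1 / f
        for (i in seq_along(origin)) {
          emit(origin[i], ev$pos + j - 1L, amount[i] * stopfrac)
        }
        amount <- amount / f
      }
    }
  }
  for (i in seq_along(origin)) emit(origin[i], L, amount[i])
  data.frame(start = out_s, end = out_e, amount = out_a)
}

class_coverage <- function(classes, L) {
  v <- numeric(L + 1L)
  if (nrow(classes)) {
    for (i in seq_len(nrow(classes))) {
      v[classes$start[i] + 1L] <- v[classes$start[i] + 1L] + classes$amount[i]
      v[classes$end[i] + 1L] <- v[classes$end[i] + 1L] - classes$amount[i]
    }
  }
  cumsum(v)[seq_len(L)]
}

#' Sample aligned fragments from transcript classes
#'
#' Fragment lengths are uniform in `length_range`; a fragment is placed by
#' choosing a transcript class with probability proportional to
#' `amount * (length + L - 1)` and a start uniform over all placements
#' overlapping the class, then truncating at the class boundaries (the
#' molecule's physical ends). Truncated boundary tags of at least 2 nt
#' are retained (the end-enriching protocol preserves native molecule
#' ends); with this threshold every category of site-informative fragment
#' -- beginning at a boundary, ending at one, or spanning an interior
#' position -- has exactly L - 1 effective placements per drawn length L,
#' which is the property that keeps the cut/uncut cleavage-efficiency
#' estimator unbiased on sampled data. The ~1% of retained tags shorter
#' than the library minimum lie within 10 nt of molecule ends, inside the
#' gap regions the window estimators skip. The total count is Poisson.
#'
#' @param classes Class table from [forward_flux()].
#' @param depth Expected number of fragments.
#' @param length_range Library size range, nt.
#' @param seed Integer seed.
#' @return An [aligned_fragments()] table.
#' @export
sample_fragments <- function(classes, depth, length_range = c(10L, 45L),
                             seed = 1L) {
  set.seed(seed)
  n <- stats::rpois(1, depth)
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  len_c <- classes$end - classes$start
  res <- vector("list", diff(length_range) + 1L)
  for (Lf in length_range[1]:length_range[2]) {
    nL <- sum(lens == Lf)
    if (nL == 0) next
    w <- classes$amount * (len_c + Lf - 1)
    idx <- sample.int(nrow(classes), nL, replace = TRUE, prob = w)
    u <- classes$start[idx] - Lf + 1L +
      floor(stats::runif(nL) * (len_c[idx] + Lf - 1))
    s <- pmax(u, classes$start[idx])
    e <- pmin(u + Lf, classes$end[idx])
    keep <- (e - s) >= 2L   # boundary tags >= 2 nt are retained
    res[[Lf - length_range[1] + 1L]] <- data.frame(
      reference_id = classes$reference_id[idx][keep],
      start = as.integer(s[keep]), end = as.integer(e[keep]),
      strand = classes$strand[idx][keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("aligned_fragments", "data.frame")
  out
}

#' Background genome gene set
#'
#' Draws a tandem array of background genes with log-normally distributed
#' expression and ribosome density, molecular weights uniform over a
#' plausible protein range, and optional planted repressor-responsive genes
#' with a specified fold-repression (for the off-target screen).
#'
#' @param n_genes Number of genes.
#' @param meanlog,sdlog Log-normal parameters of relative expression.
#' @param seed Integer seed.
#' @param responders Optional `data.frame` with columns `gene` (index),
#'   `repressor` (gene name of the repressor) and `fold` (fold-repression
#'   when the repressor is on).
#' @return List with `genes` (`data.frame`: name, start, end, strand,
#'   rel_expr, rel_rd, mw, responder fields) and `reference_length`.
#' @export
generate_genome_background <- function(n_genes = 200L, meanlog = 0,
                                       sdlog = 1, seed = 1L,
                                       responders = NULL) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  lens <- sample(450:900, n_genes, replace = TRUE)
  gap <- 100L
  start <- cumsum(c(200L + gap, lens[-n_genes] + gap))
  genes <- data.frame(
    name = sprintf("g%04d", seq_len(n_genes)),
    reference_id = "genome",
    start = as.integer(start), end = as.integer(start + lens),
    strand = "+",
    rel_expr = stats::rlnorm(n_genes, meanlog, sdlog),
    rel_rd = NA_real_,
    mw = stats::runif(n_genes, 2e4, 1.2e5),
    responder_repressor = NA_character_,
    responder_fold = NA_real_,
    stringsAsFactors = FALSE)
  genes$rel_rd <- genes$rel_expr * stats::rlnorm(n_genes, 0, 0.3)
  if (!is.null(responders)) {
    genes$responder_repressor[responders$gene] <- responders$repressor
    genes$responder_fold[responders$gene] <- responders$fold
  }
  list(genes = genes,
       reference_length = as.integer(max(genes$end) + 200L))
}

#' Generate a complete synthetic sequencing bundle for one circuit state
#'
#' Runs the forward model end to end: solves the circuit steady state for
#' the induction state, lays the resulting promoter activities onto the
#' annotation, builds noise-free molecule/flux profiles and transcript
#' classes, adds the background genome (scaled so the grand molecule total
#' matches the pipeline's 1e9 normalization exactly) and a masked tRNA
#' region, samples RNA-seq fragments and ribosome footprints, and returns
#' everything together with the ground-truth manifest.
#'
#' @param state Logical induction triple `c(IPTG, aTc, Ara)`.
#' @param depth Expected RNA-seq fragment count.
#' @param depth_fp Expected footprint count.
#' @param seed Integer seed (all randomness derives from it).
#' @param topo,params,consts Model configuration; defaults are the shipped
#'   nominal circuit.
#' @param annotation Optional annotation; default
#'   [synthetic_circuit_annotation()].
#' @param genome Optional [generate_genome_background()] result.
#' @param decay 5'-elevation decay `c(a, lambda)` planted on all
#'   occupancy profiles (`NULL` for none).
#' @param trna_fraction Fraction of all molecules placed in the masked
#'   tRNA region of the genome.
#' @return List of class `synthetic_bundle`.
#' @export
synthesize_bundle <- function(state, depth = 1e6, depth_fp = 3e5, seed = 1L,
                              topo = circuit_topology(),
                              params = circuit_params(),
                              consts = calibration_constants(),
                              annotation = NULL, genome = NULL,
                              decay = c(a = 2, lambda = 60),
                              trna_fraction = 0.3) {
  if (is.null(annotation)) annotation <- synthetic_circuit_annotation(topo)
  if (is.null(genome)) genome <- generate_genome_background(seed = seed)
  ss <- circuit_steady_state(topo, params, state)
  sens <- sensor_activities(params, state, topo)
  activities <- c(ss$y, sens)
  ff <- forward_flux(annotation, activities, params, consts)
  ref_len <- c(attr(annotation, "reference_lengths"),
               genome = genome$reference_length)

  # --- molecule budget: genome absorbs the remainder of the 1e9 total ---
  circuit_total <- sum(ff$classes$amount *
                         (ff$classes$end - ff$classes$start))
  if (circuit_total >= 0.95 * M_BUDGET) {
    stop("circuit molecule total exceeds the normalization budget")
  }
  g <- genome$genes
  on_states <- repressor_on(topo, params, state)
  mod <- rep(1, nrow(g))
  resp <- !is.na(g$responder_repressor)
  if (any(resp)) {
    on <- on_states[g$responder_repressor[resp]]
    mod[resp] <- ifelse(on, 1 / g$responder_fold[resp], 1)
  }
  glen <- g$end - g$start
  g_amount <- g$rel_expr * mod
  g_amount <- g_amount * (M_BUDGET - circuit_total) / sum(g_amount * glen)
  genome_classes <- data.frame(
    start = g$start, end = g$end, amount = g_amount,
    reference_id = "genome", strand = "+", stringsAsFactors = FALSE)
  trna_iv <- c(0L, 200L)
  all_m <- M_BUDGET
  trna_amount <- trna_fraction / (1 - trna_fraction) * all_m / 200
  trna_class <- data.frame(start = trna_iv[1], end = trna_iv[2],
                           amount = trna_amount, reference_id = "genome",
                           strand = "+", stringsAsFactors = FALSE)
  classes <- rbind(ff$classes, genome_classes, trna_class)

  fragments <- sample_fragments(classes, depth, seed = seed + 1L)

  # --- ribosome occupancy: circuit genes from TE, genome fills to pool ---
  cds <- annotation[annotation$class == "cds", , drop = FALSE]
  occ_classes <- list()
  te_truth <- list()
  for (i in seq_len(nrow(cds))) {
    gene <- cds$gene[i]
    Jp <- ff$J[[cds$reference_id[i]]]$sense
    j_end <- mean(Jp$values[interval_idx(cds$end[i] - 10L, cds$end[i])])
    m_ss <- j_end / params$gamma
    base <- params$alpha[[gene]] * m_ss / translation_constants()$omega
    occ_classes[[length(occ_classes) + 1L]] <- data.frame(
      reference_id = cds$reference_id[i], strand = "+",
      start = cds$start[i], end = cds$end[i], base = base,
      stringsAsFactors = FALSE)
    te_truth[[length(te_truth) + 1L]] <- data.frame(
      gene = gene, alpha = params$alpha[[gene]], m_ss = m_ss,
      occ_per_nt = base, stringsAsFactors = FALSE)
  }
  occ_circ <- do.call(rbind, occ_classes)
  decay_f <- if (is.null(decay)) function(d) rep(1, length(d)) else
    function(d) 1 + decay[["a"]] * exp(-d / decay[["lambda"]])
  mean_f <- function(len) mean(decay_f(seq_len(len) - 1))
  circ_occ_total <- sum(occ_circ$base * (occ_circ$end - occ_circ$start) *
                          vapply(occ_circ$end - occ_circ$start, mean_f,
                                 numeric(1)))
  pool <- consts$total_active_ribosomes
  if (circ_occ_total >= 0.95 * pool) {
    stop("circuit ribosome usage exceeds the active-ribosome pool")
  }
  g_occ <- g$rel_rd * mod
  gshape <- vapply(glen, mean_f, numeric(1))
  g_occ <- g_occ * (pool - circ_occ_total) / sum(g_occ * glen * gshape)
  occ_genome <- data.frame(reference_id = "genome", strand = "+",
                           start = g$start, end = g$end, base = g_occ,
                           stringsAsFactors = FALSE)
  occ_all <- rbind(occ_circ, occ_genome)
  occ_profiles <- occupancy_profiles(occ_all, ref_len, decay_f)
  footprints <- sample_footprints(occ_profiles, depth_fp, seed = seed + 2L)

  structure(list(
    state = state, seed = seed, depth = depth, depth_fp = depth_fp,
    annotation = annotation, genome_genes = g, params = params,
    reference_lengths = ref_len,
    masked_regions = list(genome = list(trna_iv)),
    activities = activities, steady = ss,
    classes = classes, fragments = fragments, footprints = footprints,
    M_analytic = ff$M, J_analytic = ff$J,
    occupancy_analytic = occ_profiles,
    te_truth = do.call(rbind, te_truth),
    decay = decay
  ), class = "synthetic_bundle")
}

# which repressor genes are "on" (expressed) in a state: steady-state
# protein count exceeds the gate's binding constant k
repressor_on <- function(topo, params, state) {
  ss <- circuit_steady_state(topo, params, state)
  proms <- names(topo$gate_of_promoter)
  genes <- unname(topo$gate_of_promoter[proms])
  on <- ss$R[genes] > params$k[proms]
  stats::setNames(on, genes)
}

occupancy_profiles <- function(occ_classes, ref_len, decay_f) {
  out <- list()
  for (ref in names(ref_len)) {
    for (strand in c("sense", "antisense")) {
      bed_strand <- if (strand == "sense") "+" else "-"
      v <- numeric(ref_len[[ref]])
      oc <- occ_classes[occ_classes$reference_id == ref &
                          occ_classes$strand == bed_strand, , drop = FALSE]
      for (i in seq_len(nrow(oc))) {
        len <- oc$end[i] - oc$start[i]
        d <- seq_len(len) - 1
        v[interval_idx(oc$start[i], oc$end[i])] <-
          v[interval_idx(oc$start[i], oc$end[i])] + oc$base[i] * decay_f(d)
      }
      out[[paste(ref, strand)]] <- stranded_profile(ref, strand, v,
                                                    "ribosomes")
    }
  }
  out
}

#' Sample ribosome footprints from occupancy profiles
#'
#' P-site nucleotides are drawn with probability proportional to the
#' occupancy, a footprint length is drawn uniform in `[23, 42]` nt, and the
#' footprint is placed so the P-site falls uniformly within its center
#' region; center-weighted remapping of the sampled footprints then
#' reconstructs the occupancy in expectation (up to a <= 20 nt boxcar at
#' sharp edges). The total count is Poisson.
#'
#' @param occ_profiles Named list of [stranded_profile()]s.
#' @param depth Expected footprint count.
#' @param seed Integer seed.
#' @param length_range Footprint length range.
#' @return An [aligned_fragments()] table.
#' @export
sample_footprints <- function(occ_profiles, depth, seed = 1L,
                              length_range = c(23L, 42L)) {
  set.seed(seed)
  keys <- names(occ_profiles)
  totals <- vapply(occ_profiles, function(p) sum(p$values), numeric(1))
  n <- stats::rpois(1, depth)
  if (n == 0 || sum(totals) == 0) {
    return(aligned_fragments(character(), integer(), integer(), character()))
  }
  n_per <- stats::rmultinom(1, n, prob = totals / sum(totals))[, 1]
  res <- list()
  for (i in seq_along(keys)) {
    if (n_per[i] == 0) next
    p <- occ_profiles[[i]]
    L <- length(p$values)
    x <- sample.int(L, n_per[i], replace = TRUE, prob = p$values) - 1L
    fl <- sample(length_range[1]:length_range[2], n_per[i], replace = TRUE)
    j <- floor(stats::runif(n_per[i]) * (fl - 22L))
    start <- x - 11L - j
    start <- pmax(0L, pmin(start, L - fl))
    res[[length(res) + 1L]] <- data.frame(
      reference_id = p$reference_id, start = as.integer(start),
      end = as.integer(start + fl),
      strand = if (p$strand == "sense") "+" else "-",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("aligned_fragments", "data.frame")
  out
}

#' Planted occupancy with a TE-consistent expectation for one gene
#'
#' Convenience wrapper used in tests: expected occupancy per nucleotide of
#' a CDS translated with efficiency alpha from `m_ss` transcripts is
#' `alpha * m_ss / omega`.
#'
#' @param alpha Translation efficiency, proteins/s/mRNA.
#' @param m_ss Steady-state transcript count.
#' @param omega Ribosome elongation rate, 1/s.
#' @return Expected ribosomes per nucleotide.
#' @export
expected_occupancy_per_nt <- function(alpha, m_ss, omega = 15) {
  alpha * m_ss / omega
}
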