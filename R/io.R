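# File formats (BedGraph profiles, BED fragments, GFF3 annotations, TSV
# tables, JSON config) and the command-line entry point.

PART_CLASSES <- c("promoter", "ribozyme", "rbs", "cds", "terminator")

#' Write a stranded profile as 4-column BedGraph
#'
#' Runs of equal value are compressed; one file per strand is the
#' convention (the strand is not encoded in BedGraph).
#'
#' @param profile A [stranded_profile()].
#' @param path Output path.
#' @export
write_profile_bedgraph <- function(profile, path) {
  v <- profile$values
  v[is.na(v)] <- 0
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = rep(profile$reference_id, sum(keep)),
    ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a BedGraph file into a stranded profile
#'
#' @param path BedGraph path.
#' @param reference_id,strand,reference_length,units Profile metadata (the
#'   format does not carry them).
#' @return A [stranded_profile()].
#' @export
read_profile_bedgraph <- function(path, reference_id, strand,
                                  reference_length, units = "arb_mrna") {
  gr <- rtracklayer::import.bedGraph(path)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == reference_id]
  v <- numeric(reference_length)
  if (length(gr)) {
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    sc <- S4Vectors::mcols(gr)$score
    for (i in seq_along(gr)) v[st[i]:en[i]] <- sc[i]
  }
  stranded_profile(reference_id, strand, v, units)
}

#' Write aligned fragments as BED6
#'
#' @param fragments An [aligned_fragments()] table.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = fragments$reference_id,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end),
    strand = fragments$strand)
  S4Vectors::mcols(gr)$name <- "."
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read BED6 fragments
#'
#' @param path BED path.
#' @param reference_length Optional named lengths for validation.
#' @return An [aligned_fragments()] table.
#' @export
read_fragments_bed <- function(path, reference_length = NULL) {
  gr <- rtracklayer::import.bed(path)
  aligned_fragments(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr),
                    as.character(GenomicRanges::strand(gr)),
                    reference_length = reference_length)
}

#' Write a circuit annotation as GFF3
#'
#' Reference lengths are carried as one `region` feature per reference.
#' Coordinates are converted from the package's 0-based half-open
#' convention to GFF3's 1-based inclusive intervals.
#'
#' @param annotation A `circuit_annotation` table.
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  ref_len <- attr(annotation, "reference_lengths")
  regions <- GenomicRanges::GRanges(
    seqnames = names(ref_len),
    ranges = IRanges::IRanges(start = 1L, end = unname(ref_len)),
    strand = "+", type = "region", Name = names(ref_len),
    gene = NA_character_, site = NA_integer_, param_id = NA_character_)
  parts <- GenomicRanges::GRanges(
    seqnames = annotation$reference_id,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand, type = annotation$class,
    Name = annotation$part, gene = annotation$gene,
    site = annotation$site, param_id = annotation$param_id)
  rtracklayer::export.gff3(c(regions, parts), path)
  invisible(path)
}

#' Read and validate a circuit annotation from GFF3
#'
#' Accepts the GFF3 layout written by [write_annotation_gff3()] (part type
#' in the `type` column, reference lengths as `region` features). Errors,
#' with the offending feature, on unknown part types, out-of-bounds
#' intervals, or overlapping CDS features on the same strand.
#'
#' @param path GFF3 path.
#' @return A `circuit_annotation` table with the `reference_lengths`
#'   attribute.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  type <- as.character(S4Vectors::mcols(gr)$type)
  reg <- gr[type == "region"]
  if (!length(reg)) stop("annotation lacks region features (reference lengths)")
  ref_len <- stats::setNames(GenomicRanges::end(reg),
                             as.character(GenomicRanges::seqnames(reg)))
  parts <- gr[type != "region"]
  ptype <- as.character(S4Vectors::mcols(parts)$type)
  bad <- which(!ptype %in% PART_CLASSES)
  if (length(bad)) {
    stop("unknown part type '", ptype[bad[1]], "' at feature ", bad[1])
  }
  start0 <- GenomicRanges::start(parts) - 1L
  end0 <- GenomicRanges::end(parts)
  refs <- as.character(GenomicRanges::seqnames(parts))
  oob <- which(start0 < 0 | end0 > ref_len[refs])
  if (length(oob)) stop("feature ", oob[1], " out of reference bounds")
  mc <- S4Vectors::mcols(parts)
  ann <- data.frame(
    part = as.character(mc$Name), class = ptype, reference_id = refs,
    start = start0, end = end0,
    strand = as.character(GenomicRanges::strand(parts)),
    gene = as.character(mc$gene),
    site = as.integer(mc$site), param_id = as.character(mc$param_id),
    stringsAsFactors = FALSE)
  cds <- ann[ann$class == "cds", , drop = FALSE]
  if (nrow(cds) > 1) {
    o <- order(cds$reference_id, cds$strand, cds$start)
    cds <- cds[o, ]
    same <- cds$reference_id[-1] == cds$reference_id[-nrow(cds)] &
      cds$strand[-1] == cds$strand[-nrow(cds)]
    if (any(same & cds$start[-1] < cds$end[-nrow(cds)])) {
      stop("overlapping CDS features")
    }
  }
  class(ann) <- c("circuit_annotation", "data.frame")
  attr(ann, "reference_lengths") <- ref_len
  ann
}

#' Write a synthetic bundle to a directory
#'
#' Plain-text only: BED fragments/footprints, GFF3 annotation (including
#' the genome background genes), BedGraph analytic profiles, TSV gene
#' table, and a JSON manifest with the state, seed and masked regions.
#'
#' @param bundle A [synthesize_bundle()] result.
#' @param dir Output directory (created).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fragments_bed(bundle$fragments, file.path(dir, "fragments.bed"))
  write_fragments_bed(bundle$footprints, file.path(dir, "footprints.bed"))
  ann <- bundle$annotation
  attr(ann, "reference_lengths") <- bundle$reference_lengths
  write_annotation_gff3(ann, file.path(dir, "annotation.gff3"))
  utils::write.table(bundle$genome_genes,
                     file.path(dir, "genome_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ref in names(bundle$J_analytic)) {
    for (strand in c("sense", "antisense")) {
      write_profile_bedgraph(
        bundle$J_analytic[[ref]][[strand]],
        file.path(dir, sprintf("flux_%s_%s.bedgraph", ref, strand)))
    }
  }
  jsonlite::write_json(
    list(state = as.logical(bundle$state), seed = bundle$seed,
         depth = bundle$depth, depth_fp = bundle$depth_fp,
         reference_lengths = as.list(bundle$reference_lengths),
         masked_regions = bundle$masked_regions),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the analysis pipeline from a configuration
#'
#' The configuration (JSON file or list) names a bundle directory and an
#' output directory; every referenced file is checked before any
#' computation. The pipeline re-reads fragments, footprints and the
#' annotation, runs [analyze_bundle()]-style estimation, evaluates the
#' kinetic model truth table and circuit score with the shipped nominal
#' parameters, and writes part-estimate and gene-metric TSVs plus a JSON
#' report.
#'
#' @param config Path to a JSON config or an equivalent list with entries
#'   `bundle_dir` and `out_dir` (optional `seed`).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (key in c("bundle_dir", "out_dir")) {
    if (is.null(config[[key]])) stop("config missing required key: ", key)
  }
  needed <- file.path(config$bundle_dir,
                      c("fragments.bed", "footprints.bed",
                        "annotation.gff3", "genome_genes.tsv",
                        "manifest.json"))
  missing <- needed[!file.exists(needed)]
  if (length(missing)) {
    stop("bundle is missing required files: ",
         paste(basename(missing), collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(config$bundle_dir,
                                            "manifest.json"),
                                  simplifyVector = TRUE)
  ann <- read_annotation_gff3(file.path(config$bundle_dir,
                                        "annotation.gff3"))
  ref_len <- attr(ann, "reference_lengths")
  genome_genes <- utils::read.delim(file.path(config$bundle_dir,
                                              "genome_genes.tsv"))
  masked <- lapply(manifest$masked_regions, function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (is.list(x)) lapply(x, unlist)
    else list(unlist(x))
  })
  bundle <- structure(list(
    state = manifest$state,
    annotation = ann, genome_genes = genome_genes,
    params = circuit_params(),
    reference_lengths = unlist(ref_len),
    masked_regions = masked,
    activities = NULL,
    fragments = read_fragments_bed(file.path(config$bundle_dir,
                                             "fragments.bed")),
    footprints = read_fragments_bed(file.path(config$bundle_dir,
                                              "footprints.bed"))
  ), class = "synthetic_bundle")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  topo <- circuit_topology()
  params <- circuit_params()
  res <- run_pipeline_estimates(bundle)
  tt <- circuit_truth_table(topo)
  sc <- circuit_score(topo, params, method = "steady")
  utils::write.table(res$parts, file.path(config$out_dir,
                                          "part_estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$genes, file.path(config$out_dir,
                                          "gene_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(state = manifest$state,
                 n_tss = nrow(res$tss), n_tts = nrow(res$tts),
                 truth_table = tt, score = sc$score)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# estimation stages shared with analyze_bundle but tolerant of a bundle
# re-read from disk (no analytic profiles available)
run_pipeline_estimates <- function(bundle, cfg = window_config(),
                                   consts = calibration_constants()) {
  profs <- bundle_flux_profiles(bundle$fragments, bundle$reference_lengths,
                                bundle$masked_regions, consts)
  ann <- bundle$annotation
  ribo <- ann[ann$class == "ribozyme", , drop = FALSE]
  calls_tss <- list(); calls_tts <- list()
  for (ref in names(profs)) {
    rsites <- ribo$site[ribo$reference_id == ref]
    for (strand in c("sense", "antisense")) {
      fx <- profs[[ref]]$flux[[strand]]
      ct <- call_tss(fx, cfg, ribozyme_sites = rsites)
      if (nrow(ct)) { ct$reference_id <- ref
        calls_tss[[paste(ref, strand)]] <- ct }
      tt <- call_tts(fx, cfg)
      if (nrow(tt)) { tt$reference_id <- ref
        calls_tts[[paste(ref, strand)]] <- tt }
    }
  }
  tss <- if (length(calls_tss)) do.call(rbind, calls_tss) else
    empty_site_calls()
  tts <- if (length(calls_tts)) do.call(rbind, calls_tts) else
    empty_site_calls()
  parts <- list()
  for (i in seq_len(nrow(tss))) {
    s <- tss[i, ]
    fx <- profs[[s$reference_id]]$flux[[s$strand]]
    parts[[length(parts) + 1L]] <- data.frame(
      kind = "TSS", reference_id = s$reference_id, strand = s$strand,
      position = s$position, score = s$score,
      value = promoter_strength(fx, s, cfg),
      ribozyme_coincident = s$ribozyme_coincident, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tts))) {
    s <- tts[i, ]
    fx <- profs[[s$reference_id]]$flux[[s$strand]]
    parts[[length(parts) + 1L]] <- data.frame(
      kind = "TTS", reference_id = s$reference_id, strand = s$strand,
      position = s$position, score = s$score,
      value = terminator_strength(fx, s, cfg),
      ribozyme_coincident = FALSE, stringsAsFactors = FALSE)
  }
  parts <- if (length(parts)) do.call(rbind, parts) else
    data.frame(kind = character())

  occ_pairs <- list()
  for (ref in names(bundle$reference_lengths)) {
    mp <- map_psites_center_weighted(
      bundle$footprints[bundle$footprints$reference_id == ref, ,
                        drop = FALSE],
      bundle$reference_lengths[[ref]], reference_id = ref)
    occ_pairs[[paste(ref, "sense")]] <- mp$sense
    occ_pairs[[paste(ref, "antisense")]] <- mp$antisense
  }
  occ_abs <- normalize_occupancy_absolute(occ_pairs, consts)
  dm <- tryCatch(fit_decay_model(occ_abs, bundle$genome_genes),
                 error = function(e) identity_decay_model())
  cds <- ann[ann$class == "cds", , drop = FALSE]
  genes <- lapply(seq_len(nrow(cds)), function(i) {
    g <- cds[i, ]
    rd <- compute_rd(occ_abs, g, dm)
    m_ss <- steady_state_mrna(profs[[g$reference_id]]$flux, g, consts$gamma)
    data.frame(gene = g$gene, rd = rd, m_ss = m_ss,
               te = translation_efficiency(
                 rd, m_ss, translation_constants(gamma = consts$gamma)),
               usage = ribosome_usage(occ_abs, g), stringsAsFactors = FALSE)
  })
  list(tss = tss, tts = tts, parts = parts,
       genes = do.call(rbind, genes))
}

#' Command-line interface
#'
#' Subcommands: `synth` (write a synthetic bundle), `pipeline` (run the
#' analysis on a bundle), `truth-table`, `score`, `simulate`, `steady`,
#' `scan`. Global options: `--seed`, `--out`, `--config`, `--state` (like
#' `+/-/-`), `--parameter` (for `scan`).
#'
#' @param args Character vector, default `commandArgs(TRUE)`.
#' @return Invisibly, the subcommand's result.
#' @export
circuitflux_cli <- function(args = commandArgs(TRUE)) {
  if (!length(args)) stop("usage: circuitflux <subcommand> [options]")
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  seed <- as.integer(opts$seed %||% 1L)
  topo <- circuit_topology()
  params <- circuit_params()
  result <- switch(
    cmd,
    "synth" = {
      state <- parse_state(opts$state %||% "+/-/-")
      b <- synthesize_bundle(state, seed = seed,
                             depth = as.numeric(opts$depth %||% 1e5),
                             depth_fp = as.numeric(opts$depth_fp %||% 3e4))
      write_bundle(b, opts$out %||% "bundle")
    },
    "pipeline" = run_pipeline(opts$config),
    "truth-table" = {
      tt <- circuit_truth_table(topo)
      emit_json(tt, opts$out)
    },
    "score" = {
      sc <- circuit_score(topo, params, method = opts$method %||% "steady")
      emit_json(list(score = sc$score, r_yfp = as.list(sc$r_yfp)),
                opts$out)
    },
    "simulate" = {
      st0 <- parse_state(opts$`initial-state` %||% "+/+/-")
      st1 <- parse_state(opts$state %||% "+/-/+")
      sim <- simulate_circuit(topo, params, st0, st1)
      out <- opts$out %||% "trajectory.tsv"
      utils::write.table(
        data.frame(time = sim$time, sim$R, check.names = FALSE),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
      out
    },
    "steady" = {
      st <- parse_state(opts$state %||% "+/-/-")
      ss <- circuit_steady_state(topo, params, st)
      emit_json(list(m = as.list(ss$m), R = as.list(ss$R),
                     y = as.list(ss$y)), opts$out)
    },
    "scan" = {
      if (is.null(opts$parameter)) stop("scan requires --parameter")
      sc <- sensitivity_scan(topo, params, opts$parameter,
                             n_points = as.integer(opts$n_points %||% 101))
      out <- opts$out %||% "scan.tsv"
      utils::write.table(sc$curve, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

parse_state <- function(s) {
  bits <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(bits) != 3 || !all(bits %in% c("+", "-"))) {
    stop("state must look like +/-/-")
  }
  bits == "+"
}

emit_json <- function(x, out) {
  if (is.null(out)) {
    cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
        "\n")
    invisible(x)
  } else {
    jsonlite::write_json(x, out, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    invisible(out)
  }
}
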