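# shared fixtures and independent oracles

mk_profile <- function(values, strand = "sense", units = "flux_arb",
                       ref = "chr") {
  stranded_profile(ref, strand, values, units)
}

mk_frags <- function(start, end, strand = "+", ref = "chr") {
  aligned_fragments(ref, start, end, strand)
}

# brute-force per-nucleotide coverage oracle (independent of the
# difference-accumulation implementation)
oracle_coverage <- function(start, end, len) {
  v <- numeric(len)
  for (i in seq_along(start)) {
    for (p in start[i]:(end[i] - 1L)) v[p + 1L] <- v[p + 1L] + 1
  }
  v
}

# exhaustive neighbor-ratio scan oracle for TSS detection (sense strand)
oracle_tss_scan <- function(J, thr, eps) {
  hits <- integer(); scores <- numeric()
  for (x in seq_len(length(J) - 1L)) {
    r <- J[x + 1L] / (J[x] + eps)
    if (r > thr) { hits <- c(hits, x); scores <- c(scores, r) }
  }
  data.frame(position = hits, score = scores)  # 0-based TSS = x (R idx x+1 -1)
}

# brute-force AWR oracle (sense strand), 0-based positions n..L-n
oracle_awr <- function(J, n) {
  L <- length(J)
  xs <- n:(L - n)
  vapply(xs, function(x) {
    mean(J[(x - n + 1L):x]) / mean(J[(x + 1L):(x + n)])
  }, numeric(1))
}

# literal, term-by-term transcription of the circuit rate equations,
# independent of the package's topology machinery
oracle_circuit_derivs <- function(m, R, sens, p) {
  hill <- function(prom, Rg) {
    p$ymin[[prom]] + (p$ymax[[prom]] - p$ymin[[prom]]) *
      p$k[[prom]]^p$n[[prom]] / (p$k[[prom]]^p$n[[prom]] + Rg^p$n[[prom]])
  }
  y_PhlF <- hill("PhlF", R[["phlF"]]);  y_SrpR <- hill("SrpR", R[["srpR"]])
  y_BM3R1 <- hill("BM3R1", R[["bm3R1"]]); y_BetI <- hill("BetI", R[["betI"]])
  y_AmeR <- hill("AmeR", R[["ameR"]]); y_HlyIIR <- hill("HlyIIR", R[["hlyIIR"]])
  y_AmtR <- hill("AmtR", R[["amtR"]])
  g <- p$gamma; b <- p$b; mu <- p$mu
  loss <- function(eta) g * (eta * (1 - b) + b)
  J_phlF <- y_SrpR + y_BetI
  J_srpR <- sens[["BAD1"]] + sens[["Tet1"]] + J_phlF / p$Tread[["T37"]]
  J_bm3R1 <- y_PhlF + y_HlyIIR + J_srpR / p$Tread[["T00"]]
  J_betI <- y_AmtR + y_AmeR + J_bm3R1 / p$Tread[["T2P11"]]
  J_ameR <- sens[["Tet2"]] + J_betI / p$Tread[["T3P11"]]
  J_hlyIIR <- sens[["Tac"]] + J_ameR / p$Tread[["T31"]]
  J_amtR <- sens[["BAD2"]] + J_hlyIIR / p$Tread[["T36"]]
  dm <- c(
    phlF = J_phlF - loss(p$eta[["phlF"]]) * m[["phlF"]],
    srpR = J_srpR - loss(p$eta[["srpR"]]) * m[["srpR"]],
    bm3R1 = J_bm3R1 - loss(p$eta[["bm3R1"]]) * m[["bm3R1"]],
    betI = J_betI - loss(p$eta[["betI"]]) * m[["betI"]],
    ameR = J_ameR - loss(p$eta[["ameR"]]) * m[["ameR"]],
    hlyIIR = J_hlyIIR - loss(p$eta[["hlyIIR"]]) * m[["hlyIIR"]],
    amtR = J_amtR - loss(p$eta[["amtR"]]) * m[["amtR"]],
    yfp = y_BM3R1 - loss(p$eta[["yfp"]]) * m[["yfp"]])
  dR <- c(
    phlF = p$alpha[["phlF"]] * m[["phlF"]] - mu * R[["phlF"]],
    srpR = p$alpha[["srpR"]] * m[["srpR"]] - mu * R[["srpR"]],
    bm3R1 = p$alpha[["bm3R1"]] * m[["bm3R1"]] - mu * R[["bm3R1"]],
    betI = p$alpha[["betI"]] * m[["betI"]] - mu * R[["betI"]],
    ameR = p$alpha[["ameR"]] * m[["ameR"]] - mu * R[["ameR"]],
    hlyIIR = p$alpha[["hlyIIR"]] * m[["hlyIIR"]] - mu * R[["hlyIIR"]],
    amtR = p$alpha[["amtR"]] * m[["amtR"]] - mu * R[["amtR"]],
    yfp = p$alpha[["yfp"]] * m[["yfp"]] - mu * R[["yfp"]])
  list(dm = dm, dR = dR)
}

nominal_topology <- function() circuit_topology()
nominal_params <- function() circuit_params()

state_list <- function() {
  st <- circuit_states()
  lapply(seq_len(nrow(st)), function(i) st[i, ])
}
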