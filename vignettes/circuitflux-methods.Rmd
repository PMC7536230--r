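---
title: "Methods: inferring RNAP flux, part parameters and circuit dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring RNAP flux, part parameters and circuit dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(circuitflux)
```

# The measurement model

A repressor-based logic circuit carries its computational state as a
pattern of RNA-polymerase (RNAP) flux along the circuit DNA. The package
treats a promoter as a continuous source of polymerases, so that at
steady state the flux at nucleotide x and the transcript level obey
`J(x) = γ·M(x)`, with a single mRNA degradation rate `γ = 0.0067 s⁻¹`
shared by all circuit mRNAs (they are similar in length and UTR
structure). All coordinates in the package are 0-based, half-open;
annotation I/O converts explicitly from 1-based formats.

**From fragments to profiles.** Per-nucleotide fragment coverage on each
strand is normalized by the total number of mapped nucleotides in the
sample (the summed lengths of all retained fragments, both strands, all
references) and scaled by 1e9. tRNA regions dominate end-enriched
libraries unevenly between samples, so any fragment overlapping a masked
region by one nucleotide or more is removed before the normalizer is
computed. A gene's transcript abundance (the FPKM proxy) is the mean
profile height over the gene.

**Absolute units.** Two calibrations connect arbitrary profile heights to
RNAP/s: the single-molecule reference `1 RPU = 0.019 RNAP/s per promoter`
(times the plasmid copy number, 9, for per-cell totals: 0.171 RNAP/s at
1 RPU), and the empirical power law

    J_abs(x) = 2.25 × 0.019 × 5.05e-5 · (γM(x))^1.64  RNAP/s per promoter,

whose composite coefficient (2.16e-6) is always computed from its three
factors. The 2.25 is the copy-number ratio between the circuit and output
plasmids, through which the fluorescence-calibrated output promoter
anchors the RNA-seq scale. Because the map is pointwise and profiles are
piecewise constant over the averaging windows, window differences and
ratios taken after conversion are exact in flux space.

**Ribosome occupancy.** Footprints of 23–42 nt are center-weighted: 11 nt
are removed from either end and each nucleotide of the remaining center
gets `1/(len−22)`, so every retained footprint contributes exactly one
ribosome. Occupancies are normalized to the actively translating pool,
20,000 ribosomes at a 45-min doubling time, by dividing by the grand
total over circuit and genome.

# Part quantification

* **TSS**: neighbor ratio `J(x+1)/J(x) > 5` (inverse on the minus
  strand). A pseudo-flux of `1e-12·max(J)` keeps zero-coverage positions
  finite; calls whose denominator was at the floor are flagged, and in
  merging of super-threshold steps within 10 nt a floored ratio never
  outranks a genuine one (floored ratios measure the floor, not the
  step). A call at a known ribozyme cleavage site is kept separate from
  the adjacent promoter's residual step rather than merged.
* **TTS**: the averaged-window ratio `AWR(x) = mean J[x−n,x) / mean
  J[x,x+n)` with `n = 10`; contiguous super-threshold runs collapse to
  the maximum-AWR position (ties break toward the 5'-most position in
  transcription direction, the earliest plausible release point).
* **Promoter strength** `δJ`: mean over `[TSS+10, TSS+20)` minus mean
  over `[TSS−20, TSS−10)`, sign-corrected on the minus strand. Windows
  that would leave the profile produce no estimate rather than a
  truncated one, keeping window semantics identical everywhere.
* **Terminator strength** `T_S`: the same windows around the TTS,
  upstream over downstream.
* **Ribozyme cleavage efficiency**: `CE = F_cut/(F_cut+F_uncut)` where
  `F_cut` counts fragments *beginning at* the cleavage site (the
  downstream cut pieces) and `F_uncut` the fragments spanning it.
  Counting the upstream end-at-site pieces as well would tally every
  cleaved read-through molecule twice and inflate CE by roughly
  η × (read-through share); the estimator therefore uses the downstream
  count only and reports the upstream count separately.

For a promoter sitting immediately upstream of its ribozyme insulator,
the released 5' leader is ~10 nt and is lost in library preparation, so
the observable start is the cleavage site; the measured δJ there equals
the promoter's absolute activity exactly (the suppressed leader lies
inside the 10-nt gap the windows skip). When the ribozyme is weak
(cleavage step ratio `(1/(1−η))^1.64` below the calling threshold, as for
the shipped η = 0.48 insulator), the promoter's own TSS remains the
apparent start. Tandem promoters share a cleavage-site step; their
individual TSS steps are suppressed by `(1−η)` and can be masked entirely
by terminator read-through — a genuine limitation of the method that the
recovery suite respects by asserting each site in the state where the
noise-free caller finds it most detectable.

# Gene-level metrics

Ribosome density excludes the first and last five codons (15 nt each
end), divides each position by a fitted 5'-elevation correction
`f(d) = 1 + a·exp(−d/λ)` (fitted to a genome-wide metagene over the first
300 nt with a free baseline, then rescaled so `f(∞) = 1`; a fitted
elevation `a ≤ 1e-6` falls back to the identity with a warning), and
clips the top and bottom 5% of values (90% winsorization) when the raw
mean density exceeds one. Clipping rather than dropping keeps the
estimator deterministic on short genes; the two differ by <5% on uniform
noise. `m_ss` is the mean absolute flux over the last 10 nt of the gene
divided by γ (the window can be shifted into the gene to dodge internal
cryptic promoters), and `TE = RD·ω/m_ss` with `ω = 15 s⁻¹`. Proteome
fractions are `RD·MW` normalized over the gene set. The off-target screen
divides mean RD over repressor-off states by mean RD over repressor-on
states and flags genes above 5-fold; "on" means the kinetic steady-state
repressor count exceeds its binding constant.

# Gate response fitting

`y_min`/`y_max` are fixed at the observed extremes, never fitted. `K` and
`n` minimize the Poisson negative log-likelihood of the outputs scaled to
pseudo-counts (exposure 1e6 by default — the study does not state its
exposure, so fitted values depend weakly on this documented, configurable
choice), by Nelder–Mead from a multistart grid (K at the input quartiles,
n in {1, 2, 4}) with a final polish, reltol 1e-14. Outliers are excluded
only when flagged by the user. The flux-space threshold converts to a
protein-number binding constant through the steady-state chain
`k = α·K/(γ·μ·(η(1−b)+b))`, which for the uncleaved-degradation factor
`b = 2` is `α·K/(γμ(2−η))`.

# The kinetic circuit model

The shipped configuration wires seven gates (phlF, srpR, bm3R1, betI,
ameR, hlyIIR, amtR in physical DNA order, plus yfp on the output plasmid)
with sensor promoters Tac, Tet1/2 and BAD1/2. Fluxes into a gene sum its
input promoter activities plus read-through of the upstream gene's flux
divided by the intervening terminator strength; mRNA decays at
`γ(η(1−b)+b) = γ(2−η)` at `b = 2` (uncleaved mRNA degrades faster);
proteins are produced at `α·m` and diluted at `μ = 0.00026 s⁻¹`. At load
time per-DNA promoter strengths are multiplied by the plasmid copy number
(9; 4 for the output promoter on the lower-copy plasmid) so all fluxes
are per-cell totals, consistent with the sensor activities; printed
binding constants (k × 10³) are scaled by 10³.

Simulation is forward Euler at `dt = 10 s` with a pre-run under the
initial inputs (steady when the relative change over a 1000-s window
drops below 1e-9, capped at 24 simulated hours; the protein-dilution
cascade approaches its fixed point at ~×0.8 per 1000 s, so the cap can
be reached first — the returned flag reports it honestly and the endpoint
is converged to ~1e-7 relative). The analytic steady state solves the
same fixed point by damped iteration; terminator read-through introduces
weak cycles on top of the acyclic Boolean wiring, but attenuation by
`T ≥ 15` makes the iteration contract. Euler endpoints and the analytic
solution agree to better than 0.1% across all states and random
parameter perturbations.

The circuit score is min(ON)/max(OFF) steady-state YFP protein count,
with ON/OFF taken from Boolean propagation of the designed topology,
never from data. Sensitivity scans vary one parameter at a time (default
four log-spaced decades around the nominal value; the source ranges are
not printed) with warm-started steady-state solves, and report the
regions with score < 1.

# The synthetic-data generator

The generator is the package's substitute for the deposited sequencing
data: it produces inputs whose ground truth is known exactly, so every
estimator is validated by parameter recovery.

* The world is defined in transcript-molecule space. A promoter's planted
  absolute activity y is converted to a molecule step through the inverse
  power-law at the local flux level, so the pipeline's measured absolute
  δJ equals y in expectation by construction; a terminator's planted
  flux-fold `T_S` is a molecule fold `T_S^(1/1.64)`; a ribozyme cleaves
  the stated fraction of crossing molecules, with released 5' pieces
  shorter than 50 nt lost and longer (read-through) pieces retained.
* Global totals are built so the pipeline's fixed normalizers hold
  exactly in expectation: the background genome absorbs the remainder of
  the 1e9 mapped-nucleotide scale and of the 20,000-ribosome pool. A
  masked tRNA region carries a configurable share of molecules.
* Fragments: Poisson total; lengths uniform 10–45 nt; placements uniform
  over each molecule with truncation at molecule ends, retaining
  boundary tags ≥ 2 nt. That threshold gives begin-at-boundary,
  end-at-boundary and interior spanning fragments exactly `L−1` effective
  placements each — the discrete analogue of "one fragment per molecule
  covers the site" in a true fragmentation partition, and the property
  the cut/uncut CE estimator needs to be unbiased. The ~1% of tags below
  the library minimum sit within 10 nt of molecule ends, inside the gaps
  the window estimators skip. With no cleavage the estimator still shows
  a chance-abutment floor of roughly 2/mean-fragment-length rather than
  exactly zero; this floor exists in real libraries too.
* Terminator release is jittered geometrically over an 8-nt poly-T
  window, so a unique single-nucleotide termination site does not exist
  in the stated world; the planted TTS is defined as the AWR argmax of
  the noise-free profile.
* Footprints: P-site positions drawn from the occupancy (uniform per CDS
  at `α·m_ss/ω`, times the planted 5' decay `1 + 2·exp(−d/60)`), lengths
  uniform 23–42 nt, the P-site uniform within the center region; the
  center-weighted remapping reconstructs occupancy in expectation up to a
  ≤20-nt boxcar at sharp edges, which the 5-codon trims absorb.
* Determinism: a bundle is a pure function of its seed.

What a green recovery suite establishes: that the estimators recover the
planted world's parameters at realistic depth under Poisson counting
noise. What it does not establish: robustness to features the generator
omits — sequence-dependent coverage bias, RNase footprints of
fragmentation, partial ribozyme-leader degradation, ribosome pausing,
or mapping artifacts.

# Numerical choices and limitations

* Pseudo-flux floor `1e-12·max(J)`; floored calls flagged and outranked
  in merging.
* Windows are n-length and half-open on both sides of a site; sites too
  close to the profile edge get `NA` estimates.
* The CE chance-abutment floor (~0.07 at η = 0) and the +`(1−η)²/L`
  chance-start contamination are inherent to count-based CE estimation;
  both are inside the binomial 99% CI at the depths the acceptance suite
  uses.
* Off-state promoter steps are physically undetectable (ratio below
  threshold); parts are therefore quantified in their most highly
  transcribed state, as on real data.
* The model excludes resource competition between gates, growth-rate
  feedback, attenuation and stochastic single-cell effects.
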