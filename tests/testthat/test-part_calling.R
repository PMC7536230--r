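cfg <- window_config()

test_that("call_tss finds single steps and ignores flat profiles", {
  J <- c(rep(1, 30), rep(10, 30))
  calls <- call_tss(mk_profile(J), cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 30)
  expect_equal(calls$score, 10, tolerance = 1e-9)
  expect_false(calls$eps_dominated)
  expect_equal(nrow(call_tss(mk_profile(rep(3, 50)), cfg)), 0)
})

test_that("call_tss agrees with an exhaustive ratio-scan oracle", {
  # three planted jumps with ratios 2, 6 and 100: only two clear the
  # threshold
  J <- c(rep(1, 30), rep(2, 30), rep(12, 30), rep(1200, 30))
  calls <- call_tss(mk_profile(J), cfg)
  eps <- cfg$pseudo_flux_frac * max(J)
  oracle <- oracle_tss_scan(J, cfg$ratio_threshold, eps)
  expect_equal(calls$position, oracle$position)
  expect_equal(calls$score, oracle$score)
  expect_equal(nrow(calls), 2)
})

test_that("call_tss flags ribozyme-coincident sites and keeps them unmerged", {
  # promoter step at 40 and cleavage-site step at 48 (within n nt)
  J <- c(rep(0.01, 40), rep(1, 8), rep(10, 40))
  calls <- call_tss(mk_profile(J), cfg, ribozyme_sites = 48L)
  expect_true(48 %in% calls$position)
  expect_true(calls$ribozyme_coincident[calls$position == 48])
  expect_true(40 %in% calls$position)  # promoter step survives separately
})

test_that("TSS strand symmetry: mirrored profile gives mirrored calls", {
  set.seed(10)
  J <- c(rep(0.5, 25), rep(9, 25), runif(30, 8, 10))
  f <- mk_profile(J)
  r <- mk_profile(rev(J), strand = "antisense")
  cf <- call_tss(f, cfg)
  cr <- call_tss(r, cfg)
  expect_equal(sort(length(J) - 1 - cr$position), sort(cf$position))
  expect_equal(cr$score[order(length(J) - 1 - cr$position)],
               cf$score[order(cf$position)])
})

test_that("call_tts collapses the run to the AWR maximum", {
  J <- c(rep(100, 40), rep(1, 40))
  calls <- call_tts(mk_profile(J), cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 40)
  expect_equal(calls$score, 100, tolerance = 1e-9)
  expect_equal(nrow(call_tts(mk_profile(rep(5, 60)), cfg)), 0)
})

test_that("call_tts matches the brute-force AWR argmax on a gradual drop", {
  # 20-nt geometric decline
  J <- c(rep(200, 40), 200 * 0.8^(1:20), rep(200 * 0.8^20, 40))
  calls <- call_tts(mk_profile(J), cfg)
  awr <- oracle_awr(J, cfg$n)
  xs <- cfg$n:(length(J) - cfg$n)
  expect_equal(calls$position, xs[which.max(awr)])
  expect_equal(max(calls$score), max(awr), tolerance = 1e-6)
})

test_that("TTS strand symmetry holds", {
  # the TTS marks the boundary between the two averaging windows, so the
  # mirror of position x on a length-L profile is L - x
  J <- c(rep(80, 30), 80 * 0.7^(1:10), rep(80 * 0.7^10, 30))
  cf <- call_tts(mk_profile(J), cfg)
  cr <- call_tts(mk_profile(rev(J), strand = "antisense"), cfg)
  expect_equal(length(J) - cr$position, cf$position)
  expect_equal(cr$score, cf$score)
})

test_that("promoter_strength implements the gap-window difference", {
  h <- 3.4
  J <- c(rep(0, 50), rep(h, 50))
  tss <- list(position = 50, strand = "sense")
  expect_equal(promoter_strength(mk_profile(J), tss, cfg), h)
  expect_equal(promoter_strength(mk_profile(rep(2, 100)), tss, cfg), 0)
  # antisense result is sign-corrected
  Ja <- rev(J)
  tssa <- list(position = 49, strand = "antisense")
  expect_equal(promoter_strength(mk_profile(Ja, strand = "antisense"),
                                 tssa, cfg), h)
  # out-of-bounds windows yield NA, not an error
  expect_true(is.na(promoter_strength(mk_profile(J),
                                      list(position = 5, strand = "sense"),
                                      cfg)))
})

test_that("terminator_strength is the window fold-decrease", {
  J <- c(rep(100, 50), rep(1, 50))
  tts <- list(position = 50, strand = "sense")
  expect_equal(terminator_strength(mk_profile(J), tts, cfg), 100,
               tolerance = 1e-9)
  expect_equal(terminator_strength(mk_profile(rep(7, 100)), tts, cfg), 1,
               tolerance = 1e-9)
  tta <- list(position = 49, strand = "antisense")
  expect_equal(terminator_strength(mk_profile(rev(J), strand = "antisense"),
                                   tta, cfg), 100, tolerance = 1e-9)
})

test_that("delta-J scales linearly and T_S is scale invariant", {
  set.seed(11)
  J <- c(runif(40, 90, 110), runif(40, 8, 12))
  tss <- list(position = 40, strand = "sense")
  a <- 6.3
  dj1 <- promoter_strength(mk_profile(J), tss, cfg)
  dj2 <- promoter_strength(mk_profile(a * J), tss, cfg)
  expect_equal(dj2, a * dj1)
  ts1 <- terminator_strength(mk_profile(J), tss, cfg)
  ts2 <- terminator_strength(mk_profile(a * J), tss, cfg)
  expect_equal(ts2, ts1, tolerance = 1e-9)
})

test_that("noise-free forward model is recovered exactly", {
  topo <- nominal_topology()
  params <- nominal_params()
  state <- c(TRUE, FALSE, FALSE)
  ss <- circuit_steady_state(topo, params, state)
  activities <- c(ss$y, sensor_activities(params, state, topo))
  ann <- synthetic_circuit_annotation(topo)
  ff <- forward_flux(ann, activities, params)
  term <- ann[ann$class == "terminator", ]
  for (i in seq_len(nrow(term))) {
    fx <- ff$J[[term$reference_id[i]]]$sense
    calls <- call_tts(fx, cfg)
    near <- calls[abs(calls$position - term$start[i]) <= 20, ]
    expect_equal(nrow(near), 1)
    planted <- params$parts_table$value[
      params$parts_table$part == term$part[i] &
        params$parts_table$class == "terminator"]
    # "exact" up to the documented pseudo-flux floor in the denominator
    est <- terminator_strength(fx, near, cfg)
    expect_equal(est, planted, tolerance = 1e-5)
  }
  # single-input transcription units: measured delta-J at the cleavage
  # site equals the planted absolute promoter activity exactly
  prom <- ann[ann$class == "promoter", ]
  ribo <- ann[ann$class == "ribozyme", ]
  single <- names(which(table(prom$gene) == 1))
  for (g in single) {
    p <- prom[prom$gene == g, ]
    r <- ribo[ribo$gene == g, ]
    fx <- ff$J[[p$reference_id]]$sense
    dj <- promoter_strength(fx, list(position = r$site, strand = "sense"),
                            cfg)
    expect_equal(dj, unname(activities[p$param_id]), tolerance = 1e-9)
  }
})

test_that("ribozyme_ce counts downstream cut and spanning uncut fragments", {
  site <- 100L
  # 9 fragments beginning at the site, 1 spanning it, 5 ending at it
  fr <- mk_frags(c(rep(100, 9), 90, rep(80, 5)),
                 c(rep(120, 9), 110, rep(100, 5)))
  ce <- ribozyme_ce(fr, site)
  expect_equal(ce$f_cut, 9)
  expect_equal(ce$f_uncut, 1)
  expect_equal(ce$f_cut_upstream, 5)   # reported, not counted
  expect_equal(ce$ce, 0.9)
  fr0 <- mk_frags(rep(95, 5), rep(105, 5))
  expect_equal(ribozyme_ce(fr0, site)$ce, 0)
  expect_true(is.na(ribozyme_ce(mk_frags(0, 10), site)$ce))
})

test_that("CE estimator recovers a Bernoulli cleavage rate within its CI", {
  eta <- 0.89
  site <- 50L
  set.seed(12)
  n <- 2000
  cut <- runif(n) < eta
  start <- ifelse(cut, site, site - sample(5:20, n, TRUE))
  end <- site + sample(5:20, n, TRUE)
  ce <- ribozyme_ce(mk_frags(start, end), site)
  half <- 2.576 * sqrt(eta * (1 - eta) / n)
  expect_lt(abs(ce$ce - eta), half)
})

test_that("CE estimator is unbiased under the Bernoulli fragment model", {
  eta <- 0.89
  site <- 50L
  set.seed(13)
  est <- vapply(1:200, function(i) {
    n <- 2000
    cut <- runif(n) < eta
    start <- ifelse(cut, site, site - sample(5:20, n, TRUE))
    end <- site + sample(5:20, n, TRUE)
    ribozyme_ce(mk_frags(start, end), site)$ce
  }, numeric(1))
  expect_lt(abs(mean(est) - eta), 0.01)
})
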