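mk_gene <- function(start, end, strand = "+", ref = "chr") {
  data.frame(reference_id = ref, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("compute_rd trims, corrects and winsorizes", {
  h <- 0.4
  occ <- mk_profile(rep(h, 300), units = "ribosomes")
  g <- mk_gene(0, 300)
  expect_equal(compute_rd(occ, g), h)
  # self-normalization: occupancy equal to the decay curve gives RD = 1
  dm <- structure(list(a = 2, lambda = 60,
                       correction = function(d) 1 + 2 * exp(-d / 60)),
                  class = "decay_model")
  occ2 <- mk_profile(1 + 2 * exp(-(0:299) / 60), units = "ribosomes")
  expect_equal(compute_rd(occ2, g, dm), 1, tolerance = 1e-12)
  expect_error(compute_rd(occ, mk_gene(0, 30)), "too short")
})

test_that("winsorization equals a brute-force percentile clip", {
  set.seed(20)
  v <- runif(300, 1.5, 2.5)
  v[100] <- 150   # one outlier; mean raw density > 1 triggers winsorization
  occ <- mk_profile(v, units = "ribosomes")
  g <- mk_gene(0, 300)
  rd <- compute_rd(occ, g)
  trimmed <- v[16:285]
  q <- quantile(trimmed, c(0.05, 0.95), names = FALSE)
  expect_equal(rd, mean(pmin(pmax(trimmed, q[1]), q[2])))
  expect_lt(rd, mean(trimmed))
  # no winsorization when the density is below one
  low <- v / 10
  rd_low <- compute_rd(mk_profile(low, units = "ribosomes"), g)
  expect_equal(rd_low, mean(low[16:285]))
})

test_that("compute_rd with identity model equals the trimmed mean", {
  set.seed(21)
  for (i in 1:100) {
    len <- sample(40:400, 1)
    v <- runif(len, 0, 0.9)   # below winsorization trigger
    occ <- mk_profile(v, units = "ribosomes")
    rd <- compute_rd(occ, mk_gene(0, len))
    expect_equal(rd, mean(v[16:(len - 15)]))
  }
})

test_that("fit_decay_model recovers planted parameters and degenerates safely", {
  a <- 2; lambda <- 60
  genes <- mk_gene(start = (0:29) * 420, end = (0:29) * 420 + 400)
  L <- 30 * 420
  v <- numeric(L)
  for (i in 1:30) {
    d <- 0:399
    v[(genes$start[i] + 1):(genes$end[i])] <-
      (0.5 + i / 30) * (1 + a * exp(-d / lambda))
  }
  occ <- list(mk_profile(v, units = "ribosomes"))
  dm <- fit_decay_model(occ, genes)
  expect_lt(abs(dm$a - a) / a, 0.1)
  expect_lt(abs(dm$lambda - lambda) / lambda, 0.1)
  expect_equal(dm$correction(0), 1 + dm$a)
  # flat metagene -> identity model with a warning
  vflat <- numeric(L)
  for (i in 1:30) vflat[(genes$start[i] + 1):(genes$end[i])] <- 1
  expect_warning(dmf <- fit_decay_model(list(mk_profile(vflat,
                                                        units = "ribosomes")),
                                        genes), "degenerate")
  expect_equal(dmf$correction(c(0, 100)), c(1, 1))
  expect_error(fit_decay_model(occ, genes[1:5, ]), ">= 20 genes")
})

test_that("steady_state_mrna averages the 3'-end window over gamma", {
  gamma <- 0.0067
  flux <- mk_profile(rep(gamma, 100), units = "rnap_per_s_total")
  g <- mk_gene(0, 100)
  expect_equal(steady_state_mrna(flux, g, gamma), 1)
  expect_equal(steady_state_mrna(mk_profile(rep(0, 100),
                                            units = "rnap_per_s_total"),
                                 g, gamma), 0)
  ramp <- mk_profile(seq_len(100) / 100, units = "rnap_per_s_total")
  expect_equal(steady_state_mrna(ramp, g, gamma),
               mean((91:100) / 100) / gamma)
  # shifted window (e.g. to dodge an internal cryptic promoter)
  expect_equal(steady_state_mrna(ramp, g, gamma, window_shift = 20),
               mean((71:80) / 100) / gamma)
  expect_error(steady_state_mrna(ramp, g, gamma, window_shift = 95),
               "outside gene")
})

test_that("translation efficiency and its round trip", {
  tc <- translation_constants()
  expect_equal(translation_efficiency(1, 15, tc), 1)
  expect_equal(translation_efficiency(0, 3, tc), 0)
  expect_true(is.na(translation_efficiency(1, 0, tc)))
  # the strongest RBS of the part table: RD 0.9667 over one transcript
  expect_equal(translation_efficiency(0.9667, 1, tc), 14.5,
               tolerance = 1e-3)
  set.seed(22)
  rd <- runif(20, 0.01, 5); m <- runif(20, 0.1, 100)
  te <- vapply(seq_along(rd), function(i)
    translation_efficiency(rd[i], m[i], tc), numeric(1))
  expect_equal(te * m / tc$omega, rd)
})

test_that("ribosome_usage sums occupancy without trimming", {
  occ <- mk_profile(rep(0.1, 400), units = "ribosomes")
  expect_equal(ribosome_usage(occ, mk_gene(50, 350)), 30)
  expect_equal(ribosome_usage(mk_profile(rep(0, 400), units = "ribosomes"),
                              mk_gene(50, 350)), 0)
  set.seed(23)
  v <- runif(400)
  expect_equal(ribosome_usage(mk_profile(v, units = "ribosomes"),
                              mk_gene(17, 311)), sum(v[18:311]))
})

test_that("proteome fractions normalize to one", {
  one <- proteome_fraction(data.frame(rd = 2, mw = 5e4))
  expect_equal(one$proteome_fraction, 1)
  two <- proteome_fraction(data.frame(rd = c(1, 2), mw = c(4e4, 2e4)))
  expect_equal(two$proteome_fraction, c(0.5, 0.5))
  set.seed(24)
  g <- data.frame(rd = runif(100, 0, 3), mw = runif(100, 2e4, 1.2e5))
  out <- proteome_fraction(g)
  expect_equal(out$proteome_fraction, g$rd * g$mw / sum(g$rd * g$mw))
  expect_lt(abs(sum(out$proteome_fraction) - 1), 1e-12)
  expect_error(proteome_fraction(data.frame(rd = 0, mw = 0)), "zero")
})

test_that("offtarget_screen flags genes above the fold threshold", {
  rd <- matrix(1, nrow = 4, ncol = 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  rd["g1", c("s1", "s2")] <- 0.1   # 10-fold repressed in ON states
  rd["g2", c("s1", "s2")] <- 0.5   # 2-fold: below threshold
  rd["g3", c("s1", "s2")] <- 0     # infinite fold
  out <- offtarget_screen(rd, c("s1", "s2"))
  expect_setequal(out$gene, c("g1", "g3"))
  expect_equal(out$gene[1], "g3")  # sorted descending, Inf first
  expect_equal(out$fold_repression[out$gene == "g1"], 10)
  expect_error(offtarget_screen(rd, colnames(rd)), "non-empty")
})

test_that("planted sigmoidal responders are exactly recovered among 500 genes", {
  set.seed(25)
  n <- 500
  base <- rlnorm(n, 0, 0.5)
  states <- paste0("s", 1:8)
  on <- states[1:4]
  rd <- matrix(rep(base, 8), nrow = n,
               dimnames = list(sprintf("g%03d", 1:n), states))
  rd <- rd * matrix(rlnorm(n * 8, 0, 0.02), nrow = n)  # measurement noise
  planted <- c(37, 201, 449)
  rd[planted, on] <- rd[planted, on] / 10
  out <- offtarget_screen(rd, on)
  expect_setequal(out$gene, rownames(rd)[planted])
})
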