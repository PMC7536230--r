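topo <- nominal_topology()
params <- nominal_params()

test_that("parameter loading applies the printed unit conventions", {
  # per-DNA promoter strengths times copy number (9; 4 for the output
  # promoter on the lower-copy plasmid), k times 1e3
  expect_equal(unname(params$ymax["PhlF"]), 0.8e-3 * 9)
  expect_equal(unname(params$ymax["BM3R1"]), 9.3e-3 * 4)
  expect_equal(unname(params$k["SrpR"]), 60)
  expect_equal(unname(params$Tread["T37"]), 124)
  expect_equal(unname(params$eta["betI"]), 0.48)
  expect_equal(unname(params$alpha["hlyIIR"]), 14.5)
  expect_equal(params$b, 2)
  # output promoter copy correction 4/9 = 0.44
  expect_equal(round(params$n_output_copies / params$n_circuit_copies, 2),
               0.44)
})

test_that("derivatives match a literal term-by-term transcription", {
  set.seed(40)
  states <- state_list()
  for (i in 1:20) {
    m <- stats::setNames(runif(8, 0, 500), topo$genes)
    R <- stats::setNames(runif(8, 0, 2e4), topo$genes)
    inputs <- states[[sample(8, 1)]]
    d <- circuit_derivatives(list(m = m, R = R), topo, params, inputs)
    o <- oracle_circuit_derivs(m, R,
                               sensor_activities(params, inputs, topo),
                               params)
    expect_equal(d$dm[names(o$dm)], o$dm, tolerance = 1e-12)
    expect_equal(d$dR[names(o$dR)], o$dR, tolerance = 1e-12)
  }
})

test_that("Hill limits drive every gate promoter to its extremes", {
  big <- stats::setNames(rep(1e12, 8), topo$genes)
  d <- circuit_derivatives(list(m = big * 0, R = big), topo, params,
                           c(FALSE, FALSE, FALSE))
  expect_equal(unname(d$y), unname(params$ymin[names(d$y)]),
               tolerance = 1e-6)
  zero <- stats::setNames(rep(0, 8), topo$genes)
  d0 <- circuit_derivatives(list(m = zero, R = zero), topo, params,
                            c(FALSE, FALSE, FALSE))
  expect_equal(unname(d0$y), unname(params$ymax[names(d0$y)]))
})

test_that("steady state is a fixed point of the rate equations", {
  for (inputs in state_list()[c(2, 7)]) {
    ss <- circuit_steady_state(topo, params, inputs)
    d <- circuit_derivatives(list(m = ss$m, R = ss$R), topo, params, inputs)
    expect_lt(max(abs(d$dm) / (params$gamma * ss$m + 1e-12)), 1e-8)
    expect_lt(max(abs(d$dR) / (params$mu * ss$R + 1e-12)), 1e-8)
    # m* = J / (gamma (2 - eta)) for b = 2
    expect_equal(ss$m, ss$J / (params$gamma * (2 - params$eta[names(ss$J)])),
                 tolerance = 1e-12)
  }
})

test_that("Euler endpoint matches the analytic steady state", {
  for (inputs in state_list()[c(2, 5)]) {
    sim <- simulate_circuit(topo, params, inputs, inputs)
    ss <- circuit_steady_state(topo, params, inputs)
    end <- sim$R[nrow(sim$R), ]
    expect_lt(max(abs(end - ss$R) / (abs(ss$R) + 1e-12)), 1e-3)
    # steady start: trajectories essentially flat
    expect_lt(max(abs(sim$R[nrow(sim$R), ] - sim$R[1, ]) /
                    (abs(sim$R[1, ]) + 1e-12)), 1e-3)
  }
})

test_that("a dt above the stability bound is rejected", {
  expect_error(simulate_circuit(topo, params, c(TRUE, FALSE, FALSE),
                                dt = 1000), "stability")
})

test_that("boolean propagation reproduces the designed logic", {
  expect_true(boolean_propagate(topo, c(TRUE, FALSE, FALSE))$output)
  expect_true(boolean_propagate(topo, c(TRUE, TRUE, TRUE))$output)
  expect_false(boolean_propagate(topo, c(FALSE, FALSE, FALSE))$output)
  tt <- circuit_truth_table(topo)
  expect_equal(sum(tt$output), 2)
  expect_setequal(rownames(tt)[tt$output], c("+/-/-", "+/+/+"))
  # forced failure pinning: pinning the output promoter low kills YFP
  ttf <- circuit_truth_table(topo, failures = list(BM3R1 = 0))
  expect_equal(sum(ttf$output), 0)
  # pinning an internal wire propagates
  w <- boolean_propagate(topo, c(TRUE, FALSE, FALSE),
                         failures = list(PhlF = 1))
  expect_false(w$output)
})

test_that("the input switch +/+/- to +/-/+ produces a YFP glitch", {
  sim <- simulate_circuit(topo, params, c(TRUE, TRUE, FALSE),
                          c(TRUE, FALSE, TRUE))
  ry <- sim$R[, "yfp"]
  expect_gt(max(ry), 2 * ry[1])
  expect_gt(max(ry), 2 * ry[length(ry)])
  expect_lt(which.max(ry), length(ry))   # transient, not monotone
})

test_that("circuit score from the printed parameters rounds to 2", {
  sc <- circuit_score(topo, params, method = "steady")
  expect_gte(sc$score, 1.5)
  expect_lte(sc$score, 2.5)
  expect_equal(sum(sc$on), 2)
})

test_that("weakening a repressor never lowers its gate output", {
  inputs <- c(TRUE, TRUE, FALSE)
  base <- circuit_steady_state(topo, params, inputs)
  for (prom in names(topo$gate_of_promoter)) {
    p2 <- set_circuit_param(params, paste0("k.", prom),
                            2 * params$k[[prom]])
    up <- circuit_steady_state(topo, p2, inputs)
    expect_gte(up$y[[prom]], base$y[[prom]] * (1 - 1e-12))
  }
})

test_that("thresholded kinetic truth table equals the Boolean one", {
  sc <- circuit_score(topo, params, method = "steady")
  thr <- sqrt(min(sc$r_yfp[sc$on]) * max(sc$r_yfp[!sc$on]))
  expect_equal(unname(sc$r_yfp > thr), unname(sc$on))
})

test_that("sensitivity scan is consistent and reports failure regions", {
  scan <- sensitivity_scan(topo, params, "k.PhlF", n_points = 41)
  nominal_score <- circuit_score(topo, params, method = "steady")$score
  i_nom <- which.min(abs(scan$curve$value - params$k[["PhlF"]]))
  # spot checks against an independent recomputation
  set.seed(41)
  for (i in sample(nrow(scan$curve), 5)) {
    p2 <- set_circuit_param(params, "k.PhlF", scan$curve$value[i])
    expect_equal(scan$curve$score[i],
                 circuit_score(topo, p2, method = "steady")$score,
                 tolerance = 1e-6)
  }
  expect_error(sensitivity_scan(topo, params, "k.PhlF",
                                range = c(2, 1)), "invalid range")
  # per-DNA reporting divides promoter values by the copy number
  scan2 <- sensitivity_scan(topo, params, "ymax.BM3R1", n_points = 5,
                            per_dna = TRUE)
  expect_equal(scan2$copy_divisor, 4)
  expect_equal(scan2$nominal, params$ymax[["BM3R1"]] / 4)
})

test_that("a cyclic wiring is rejected by the steady-state solver", {
  cyc <- topo
  cyc$inputs$srpR <- c("BAD1", "Tet1", "PhlF")   # phlF <-> srpR loop
  expect_error(circuit_steady_state(cyc, params, c(TRUE, FALSE, FALSE)),
               "cyclic")
})
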