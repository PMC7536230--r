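# Kinetic ODE model of the 7-gate NOT/NOR logic circuit: derivatives,
# forward-Euler simulation, analytic steady states, Boolean propagation,
# circuit score and parameter sensitivity scans.

#' Nominal circuit topology
#'
#' Wiring of the seven NOT/NOR repressor gates plus the yfp output gene:
#' which promoters feed each gene, which repressor gates each promoter, the
#' physical order of the gates on the circuit DNA, and the terminator
#' read-through chain that follows that order. Read from the shipped JSON
#' config by default.
#'
#' @param path JSON config path; defaults to the config shipped with the
#'   package.
#' @return List of class `circuit_topology`.
#' @export
circuit_topology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "circuit_config.json",
                        package = "circuitflux")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- cfg$topology
  topo$genes <- as.character(topo$genes)
  topo$inputs <- lapply(topo$inputs, as.character)
  topo$gate_of_promoter <- unlist(topo$gate_of_promoter)
  topo$sensors <- as.character(topo$sensors)
  topo$sensor_of_inducer <- lapply(topo$sensor_of_inducer, as.character)
  topo$readthrough <- lapply(topo$readthrough, function(x) {
    list(from = x$from, terminator = x$terminator)
  })
  structure(topo, class = "circuit_topology")
}

#' Nominal circuit parameters
#'
#' Loads the part-parameter table (promoter strengths per DNA, terminator
#' folds, ribozyme cleavage efficiencies, RBS translation efficiencies), the
#' gate response table (binding constants, cooperativities) and the model
#' constants (gamma, b, mu, sensor on/off activities, plasmid copy numbers)
#' from the shipped files, and applies the load-time unit conventions:
#' promoter strengths are stored per cell (per-DNA values multiplied by the
#' circuit plasmid copy number, 9, or by 4 for the output promoter carried
#' on the lower-copy output plasmid), and the binding constants printed as
#' k x 10^3 are multiplied by 10^3.
#'
#' @param part_path,gate_path,config_path Optional overrides of the shipped
#'   TSV/JSON files.
#' @return List of class `circuit_params` with named vectors `ymax`, `ymin`,
#'   `k`, `n` (by gate promoter), `eta`, `alpha` (by gene), `Tread` (by
#'   terminator label), `sensor_on`, `sensor_off`, and globals `gamma`, `b`,
#'   `mu`.
#' @export
circuit_params <- function(part_path = NULL, gate_path = NULL,
                           config_path = NULL) {
  sf <- function(x, f) if (is.null(x)) system.file("extdata", f,
                                                   package = "circuitflux") else x
  parts <- utils::read.delim(sf(part_path, "part_parameters.tsv"))
  gates <- utils::read.delim(sf(gate_path, "gate_parameters.tsv"))
  cfg <- jsonlite::read_json(sf(config_path, "circuit_config.json"),
                             simplifyVector = TRUE)
  cn <- cfg$constants
  prom <- parts[parts$class == "promoter", ]
  gate_prom <- prom$part[prom$part %in% names(cfg$topology$gate_of_promoter)]
  copies <- ifelse(gate_prom == cfg$constants$output_promoter,
                   cn$n_output_copies, cn$n_circuit_copies)
  pick <- function(df, cls, param) {
    d <- df[df$class == cls & df$parameter == param, ]
    stats::setNames(d$value, d$part)
  }
  ymax_dna <- pick(parts, "promoter", "y_max_e3_per_dna")[gate_prom]
  ymin_dna <- pick(parts, "promoter", "y_min_e3_per_dna")[gate_prom]
  eta_all <- pick(parts, "ribozyme", "cleavage_efficiency")
  alpha_all <- pick(parts, "rbs", "translation_efficiency")
  tterm <- pick(parts, "terminator", "strength")
  genes <- cfg$topology$genes
  gene_parts <- cfg$topology$gene_parts
  eta <- vapply(genes, function(g) eta_all[[gene_parts[[g]]$ribozyme]],
                numeric(1))
  alpha <- vapply(genes, function(g) alpha_all[[gene_parts[[g]]$rbs]],
                  numeric(1))
  term_label <- vapply(gene_parts, function(p) p$terminator_label,
                       character(1))
  term_name <- vapply(gene_parts, function(p) p$terminator, character(1))
  Tread <- stats::setNames(tterm[term_name], term_label)
  structure(list(
    ymax = stats::setNames(ymax_dna * 1e-3 * copies, gate_prom),
    ymin = stats::setNames(ymin_dna * 1e-3 * copies, gate_prom),
    k = stats::setNames(gates$binding_constant_e3 * 1e3, gates$promoter),
    n = stats::setNames(gates$cooperativity, gates$promoter),
    eta = eta, alpha = alpha, Tread = Tread,
    sensor_on = unlist(cn$sensor_on), sensor_off = unlist(cn$sensor_off),
    gamma = cn$gamma, b = cn$b, mu = cn$mu,
    n_circuit_copies = cn$n_circuit_copies,
    n_output_copies = cn$n_output_copies,
    output_promoter = cn$output_promoter,
    parts_table = parts
  ), class = "circuit_params")
}

#' Sensor promoter activities for an induction state
#'
#' @param params A [circuit_params()].
#' @param inputs Logical triple `c(IPTG, aTc, Ara)` (named or positional).
#' @param topo A [circuit_topology()].
#' @return Named vector of sensor promoter activities, RNAP/s (per cell).
#' @export
sensor_activities <- function(params, inputs, topo = circuit_topology()) {
  inputs <- as.logical(inputs)
  sens <- params$sensor_off
  for (i in seq_along(topo$sensor_of_inducer)) {
    if (inputs[i]) {
      s <- topo$sensor_of_inducer[[i]]
      sens[s] <- params$sensor_on[s]
    }
  }
  sens
}

# Hill repression activities for the 7 gate promoters, given repressor
# protein counts R (named by gene)
gate_promoter_activities <- function(topo, params, R) {
  proms <- names(topo$gate_of_promoter)
  genes <- unname(topo$gate_of_promoter[proms])
  kp <- unname(params$k[proms]); np <- unname(params$n[proms])
  ymin <- unname(params$ymin[proms]); ymax <- unname(params$ymax[proms])
  kn <- kp^np
  stats::setNames(ymin + (ymax - ymin) * kn / (kn + unname(R[genes])^np),
                  proms)
}

# RNAP flux into every gene: sum of input promoter activities plus
# read-through of the upstream gene's flux divided by the intervening
# terminator strength. Evaluated in DNA order so the chain is well defined.
circuit_fluxes <- function(topo, params, y, sens) {
  J <- stats::setNames(numeric(length(topo$genes)), topo$genes)
  act <- c(y, sens)
  for (g in topo$genes) {
    J[g] <- sum(act[topo$inputs[[g]]])
    rt <- topo$readthrough[[g]]
    if (!is.null(rt)) J[g] <- J[g] + J[[rt$from]] / params$Tread[[rt$terminator]]
  }
  J
}

#' Time derivatives of the circuit state
#'
#' For every gene i: `dm_i/dt = J_i - gamma (eta_i (1-b) + b) m_i` and
#' `dR_i/dt = alpha_i m_i - mu R_i`, with the flux `J_i` the sum of the
#' gene's input promoter activities (each a Hill function of its cognate
#' repressor count) plus terminator read-through from the upstream gene.
#'
#' @param state List with named numeric vectors `m` and `R` (one entry per
#'   gene).
#' @param topo A [circuit_topology()].
#' @param params A [circuit_params()].
#' @param inputs Logical induction triple `c(IPTG, aTc, Ara)`.
#' @return List with `dm`, `dR`, and the evaluated `J` and `y`.
#' @export
circuit_derivatives <- function(state, topo, params, inputs) {
  sens <- sensor_activities(params, inputs, topo)
  y <- gate_promoter_activities(topo, params, state$R)
  J <- circuit_fluxes(topo, params, y, sens)
  loss <- params$gamma * (params$eta * (1 - params$b) + params$b)
  dm <- J - loss[names(J)] * state$m[names(J)]
  dR <- params$alpha[names(J)] * state$m[names(J)] - params$mu * state$R[names(J)]
  list(dm = dm, dR = dR, J = J, y = y)
}

zero_state <- function(topo) {
  z <- stats::setNames(numeric(length(topo$genes)), topo$genes)
  list(m = z, R = z)
}

# index-based view of the model for the integrator inner loop
compile_circuit <- function(topo, params) {
  genes <- topo$genes
  proms <- names(topo$gate_of_promoter)
  act_names <- c(proms, names(params$sensor_on))
  list(
    genes = genes, proms = proms, act_names = act_names,
    prom_gene = match(unname(topo$gate_of_promoter[proms]), genes),
    ymin = unname(params$ymin[proms]), ymax = unname(params$ymax[proms]),
    kn = unname(params$k[proms])^unname(params$n[proms]),
    np = unname(params$n[proms]),
    loss = unname(params$gamma *
                    (params$eta[genes] * (1 - params$b) + params$b)),
    alpha = unname(params$alpha[genes]),
    mu = params$mu,
    input_idx = lapply(genes, function(g)
      match(topo$inputs[[g]], act_names)),
    rt_from = vapply(genes, function(g) {
      rt <- topo$readthrough[[g]]
      if (is.null(rt)) NA_integer_ else match(rt$from, genes)
    }, integer(1)),
    rt_T = vapply(genes, function(g) {
      rt <- topo$readthrough[[g]]
      if (is.null(rt)) NA_real_ else params$Tread[[rt$terminator]]
    }, numeric(1))
  )
}

cc_fluxes <- function(cc, R, sens) {
  y <- cc$ymin + (cc$ymax - cc$ymin) * cc$kn / (cc$kn + R[cc$prom_gene]^cc$np)
  act <- c(y, sens)
  ng <- length(cc$genes)
  J <- numeric(ng)
  for (i in seq_len(ng)) {
    J[i] <- sum(act[cc$input_idx[[i]]])
    if (!is.na(cc$rt_from[i])) J[i] <- J[i] + J[cc$rt_from[i]] / cc$rt_T[i]
  }
  list(J = J, y = y)
}

#' Simulate the circuit through an input step change
#'
#' The equations are first pre-run to steady state under the initial inputs
#' (forward Euler; steady when the maximum relative state change over a
#' 1000-s window drops below `steady_tol`, capped at 24 simulated hours).
#' At t = 0 the sensors switch to the final inputs and the trajectory is
#' recorded with time step `dt` out to `t_end`.
#'
#' @param topo A [circuit_topology()].
#' @param params A [circuit_params()].
#' @param initial_inputs,final_inputs Logical induction triples.
#' @param dt Euler step, s.
#' @param t_end Simulated time after the switch, s.
#' @param steady_tol Relative-change tolerance for the pre-run.
#' @return List of class `simulation_result` with `time`, matrices `m`,
#'   `R`, `y` (rows = time points), and `steady` flag for the pre-run.
#' @export
simulate_circuit <- function(topo, params, initial_inputs,
                             final_inputs = initial_inputs, dt = 10,
                             t_end = 12 * 3600, steady_tol = 1e-9) {
  loss <- params$gamma * (params$eta * (1 - params$b) + params$b)
  if (dt * max(c(loss, params$mu)) >= 1) {
    stop("dt exceeds the Euler stability bound")
  }
  cc <- compile_circuit(topo, params)
  sens0 <- unname(sensor_activities(params, initial_inputs, topo))
  sens1 <- unname(sensor_activities(params, final_inputs, topo))
  ng <- length(cc$genes)
  m <- numeric(ng); R <- numeric(ng)
  # pre-run under initial inputs
  chunk <- max(1L, round(1000 / dt))
  steady <- FALSE
  for (rep in seq_len(ceiling(24 * 3600 / (chunk * dt)))) {
    m0 <- m; R0 <- R
    for (i in seq_len(chunk)) {
      fx <- cc_fluxes(cc, R, sens0)
      m <- m + dt * (fx$J - cc$loss * m)
      R <- R + dt * (cc$alpha * m - cc$mu * R)
    }
    rel <- max(abs(c(m - m0, R - R0)) / (abs(c(m, R)) + 1e-30))
    if (rel < steady_tol) { steady <- TRUE; break }
  }
  nstep <- ceiling(t_end / dt)
  m_tr <- matrix(NA_real_, nstep + 1L, ng, dimnames = list(NULL, cc$genes))
  R_tr <- m_tr
  y_tr <- matrix(NA_real_, nstep + 1L, length(cc$proms),
                 dimnames = list(NULL, cc$proms))
  fx <- cc_fluxes(cc, R, sens1)
  m_tr[1, ] <- m; R_tr[1, ] <- R; y_tr[1, ] <- fx$y
  for (i in seq_len(nstep)) {
    fx <- cc_fluxes(cc, R, sens1)
    m <- m + dt * (fx$J - cc$loss * m)
    R <- R + dt * (cc$alpha * m - cc$mu * R)
    if (!all(is.finite(m)) || !all(is.finite(R)) ||
        any(m < 0) || any(R < 0)) {
      check_state_finite(stats::setNames(m, cc$genes),
                         stats::setNames(R, cc$genes), i * dt)
    }
    m_tr[i + 1L, ] <- m; R_tr[i + 1L, ] <- R
    y_tr[i + 1L, ] <- fx$y
  }
  structure(list(time = seq(0, by = dt, length.out = nstep + 1L),
                 m = m_tr, R = R_tr, y = y_tr, steady = steady),
            class = "simulation_result")
}

check_state_finite <- function(m, R, t) {
  bad <- c(m, R)
  names(bad) <- c(paste0("m_", names(m)), paste0("R_", names(R)))
  idx <- which(!is.finite(bad) | bad < 0)
  if (length(idx)) {
    stop("unstable simulation at t = ", t, " s: ", names(bad)[idx[1]],
         " = ", bad[idx[1]])
  }
  invisible(TRUE)
}

#' Analytic steady state of the circuit
#'
#' Because the Boolean wiring is acyclic and terminator read-through is
#' strongly attenuated, the steady state is the fixed point of
#' `m* = J/(gamma (eta (1-b) + b))`, `R* = alpha m*/mu`, with `J` evaluated
#' from the Hill responses at `R*`. It is found by (damped) fixed-point
#' iteration and agrees with the Euler endpoint to well under 0.1%.
#'
#' @inheritParams circuit_derivatives
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @param warm_start Optional previous solution (list with `R`) used to
#'   initialize the iteration.
#' @return List with `m`, `R`, `y`, `J` at steady state.
#' @export
circuit_steady_state <- function(topo, params, inputs, tol = 1e-12,
                                 max_iter = 10000, warm_start = NULL) {
  check_acyclic(topo)
  sens <- sensor_activities(params, inputs, topo)
  loss <- params$gamma * (params$eta * (1 - params$b) + params$b)
  R <- if (is.null(warm_start)) zero_state(topo)$R else warm_start$R
  damp <- 1
  for (it in seq_len(max_iter)) {
    y <- gate_promoter_activities(topo, params, R)
    J <- circuit_fluxes(topo, params, y, sens)
    m <- J / loss[names(J)]
    Rn <- params$alpha[names(m)] * m / params$mu
    Rn <- damp * Rn + (1 - damp) * R
    if (max(abs(Rn - R) / (abs(Rn) + 1e-30)) < tol) {
      R <- Rn
      y <- gate_promoter_activities(topo, params, R)
      J <- circuit_fluxes(topo, params, y, sens)
      m <- J / loss[names(J)]
      return(list(m = m, R = R, y = y, J = J, iterations = it))
    }
    R <- Rn
    if (it == 200) damp <- 0.5   # damp late to break potential oscillation
  }
  stop("steady-state iteration did not converge")
}

check_acyclic <- function(topo) {
  gates <- topo$genes
  color <- stats::setNames(rep(0L, length(gates)), gates)
  visit <- function(g) {
    if (color[[g]] == 1L) stop("cyclic gate wiring at gene '", g, "'")
    if (color[[g]] == 2L) return(invisible())
    color[[g]] <<- 1L
    for (p in topo$inputs[[g]]) {
      up <- topo$gate_of_promoter[p]
      if (!is.na(up)) visit(unname(up))
    }
    color[[g]] <<- 2L
  }
  for (g in gates) visit(g)
  invisible(TRUE)
}

#' Boolean logic propagation through the circuit
#'
#' Sensors map the induction bits to promoter bits and every NOT/NOR gate
#' outputs `NOT(OR(inputs))`, with optional forced failures pinning a
#' gate's output promoter to 0 or 1 (to model experimentally observed
#' failed states).
#'
#' @param topo A [circuit_topology()].
#' @param inputs Logical triple `c(IPTG, aTc, Ara)`.
#' @param failures Optional named list/vector pinning gate promoters (by
#'   promoter name) to 0 or 1.
#' @return List with `output` (the yfp bit) and `wires` (named promoter
#'   bits).
#' @export
boolean_propagate <- function(topo, inputs, failures = NULL) {
  inputs <- as.logical(inputs)
  bits <- stats::setNames(rep(NA, length(topo$sensors)), topo$sensors)
  for (i in seq_along(topo$sensor_of_inducer)) {
    bits[topo$sensor_of_inducer[[i]]] <- inputs[i]
  }
  # promoter bit of a gate = NOT(OR of that gate's gene inputs)
  prom_bit <- function(p) {
    if (!is.null(failures) && p %in% names(failures)) {
      return(as.logical(failures[[p]]))
    }
    g <- topo$gate_of_promoter[[p]]
    in_bits <- vapply(topo$inputs[[g]], function(q) {
      if (!is.na(bits[q])) bits[[q]] else prom_bit(q)
    }, logical(1))
    !any(in_bits)
  }
  wires <- vapply(names(topo$gate_of_promoter), prom_bit, logical(1))
  out_prom <- topo$inputs$yfp
  list(output = unname(wires[out_prom]), wires = c(bits, wires))
}

#' All eight induction states
#'
#' @return Logical matrix with columns IPTG, aTc, Ara, one row per state,
#'   labelled like `+/-/-`.
#' @export
circuit_states <- function() {
  g <- expand.grid(IPTG = c(FALSE, TRUE), aTc = c(FALSE, TRUE),
                   Ara = c(FALSE, TRUE))
  m <- as.matrix(g)
  rownames(m) <- apply(m, 1, function(r) paste(ifelse(r, "+", "-"),
                                               collapse = "/"))
  m
}

#' Designed Boolean truth table
#'
#' @param topo A [circuit_topology()].
#' @param failures Passed to [boolean_propagate()].
#' @return `data.frame` of the 8 states with the designed yfp output bit.
#' @export
circuit_truth_table <- function(topo = circuit_topology(), failures = NULL) {
  st <- circuit_states()
  out <- apply(st, 1, function(r) boolean_propagate(topo, r, failures)$output)
  data.frame(st, output = out)
}

#' Circuit score
#'
#' The minimum steady-state YFP protein count over the designed ON states
#' divided by the maximum over the designed OFF states; a score below 1
#' means the circuit no longer performs its intended logic. ON/OFF
#' assignments come from Boolean propagation on the designed topology,
#' never from data.
#'
#' @param topo A [circuit_topology()].
#' @param params A [circuit_params()].
#' @param method `"steady"` (analytic fixed point, fast) or `"euler"`
#'   (forward-Euler endpoint, the reference procedure).
#' @param dt,t_end Euler settings when `method = "euler"`.
#' @return List with `score`, per-state `r_yfp`, and the ON mask.
#' @export
circuit_score <- function(topo, params, method = c("steady", "euler"),
                          dt = 10, t_end = 12 * 3600) {
  method <- match.arg(method)
  st <- circuit_states()
  on <- apply(st, 1, function(r) boolean_propagate(topo, r)$output)
  r_yfp <- apply(st, 1, function(r) {
    if (method == "steady") {
      circuit_steady_state(topo, params, r)$R[["yfp"]]
    } else {
      sim <- simulate_circuit(topo, params, r, r, dt = dt, t_end = t_end)
      sim$R[nrow(sim$R), "yfp"]
    }
  })
  mx_off <- max(r_yfp[!on])
  score <- if (mx_off == 0) Inf else min(r_yfp[on]) / mx_off
  list(score = score, r_yfp = r_yfp, on = on)
}

#' One-at-a-time parameter sensitivity scan
#'
#' Varies a single named parameter over a range (by default four decades,
#' log-spaced, centered on its nominal value), recomputes the eight steady
#' states and the circuit score at each value, and reports the regions in
#' which the score falls below 1. Promoter strengths can be reported per
#' DNA (`y/N`) with `per_dna = TRUE`.
#'
#' @param topo A [circuit_topology()].
#' @param params A [circuit_params()].
#' @param parameter Parameter address, e.g. `"ymax.PhlF"`, `"k.AmeR"`,
#'   `"eta.phlF"`, `"T.T37"`, `"alpha.hlyIIR"`, `"sensor_on.Tac"`.
#' @param range `c(lo, hi)`; default nominal x `10^(+/-2)`.
#' @param n_points Number of scan values.
#' @param log_spaced Log- or linearly spaced values.
#' @param per_dna Report promoter values divided by their plasmid copy
#'   number.
#' @return List with `curve` (`data.frame` value/score), `nominal`,
#'   `nonfunctional` (logical vector, score < 1), and `copy_divisor`.
#' @export
sensitivity_scan <- function(topo, params, parameter, range = NULL,
                             n_points = 1000, log_spaced = TRUE,
                             per_dna = FALSE) {
  nominal <- get_circuit_param(params, parameter)
  if (is.null(range)) {
    if (nominal <= 0) stop("cannot derive a default range for a zero nominal")
    range <- c(nominal / 100, nominal * 100)
  }
  if (range[2] <= range[1]) stop("invalid range")
  vals <- if (log_spaced) exp(seq(log(range[1]), log(range[2]),
                                  length.out = n_points))
          else seq(range[1], range[2], length.out = n_points)
  st <- circuit_states()
  on <- apply(st, 1, function(r) boolean_propagate(topo, r)$output)
  warm <- vector("list", nrow(st))
  scores <- vapply(vals, function(v) {
    p2 <- set_circuit_param(params, parameter, v)
    ry <- numeric(nrow(st))
    for (i in seq_len(nrow(st))) {
      ss <- circuit_steady_state(topo, p2, st[i, ], warm_start = warm[[i]])
      warm[[i]] <<- ss
      ry[i] <- ss$R[["yfp"]]
    }
    mx <- max(ry[!on])
    if (mx == 0) Inf else min(ry[on]) / mx
  }, numeric(1))
  divisor <- 1
  if (per_dna && grepl("^y(max|min)\\.", parameter)) {
    prom <- sub("^y(max|min)\\.", "", parameter)
    divisor <- if (identical(prom, params$output_promoter))
      params$n_output_copies else params$n_circuit_copies
  }
  list(curve = data.frame(value = vals / divisor, score = scores),
       nominal = nominal / divisor, nonfunctional = scores < 1,
       copy_divisor = divisor)
}

#' @rdname sensitivity_scan
#' @export
get_circuit_param <- function(params, parameter) {
  a <- parse_param_address(parameter)
  if (is.na(a$name)) params[[a$field]] else params[[a$field]][[a$name]]
}

#' @rdname sensitivity_scan
#' @param value Replacement value.
#' @export
set_circuit_param <- function(params, parameter, value) {
  a <- parse_param_address(parameter)
  if (is.na(a$name)) params[[a$field]] <- value
  else params[[a$field]][[a$name]] <- value
  params
}

parse_param_address <- function(parameter) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  field <- switch(parts[1], T = "Tread", parts[1])
  if (length(parts) == 1) return(list(field = field, name = NA_character_))
  list(field = field, name = parts[2])
}
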