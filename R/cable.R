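#' Passive cable parameters
#'
#' @param specific_capacitance membrane capacitance, uF/cm^2.
#' @param axial_resistivity cytoplasmic resistivity, Ohm cm (the sweep
#'   variable of the robustness analysis).
#' @param leak_conductance_density passive leak density, S/cm^2.
#' @param leak_reversal leak reversal potential, mV; the passive resting
#'   potential (-60 mV).
#' @return A list of class `cable_params`.
#' @export
cable_params <- function(specific_capacitance = 1,
                         axial_resistivity = 130,
                         leak_conductance_density = 5e-5,
                         leak_reversal = -60) {
  if (specific_capacitance <= 0 || axial_resistivity <= 0 ||
      leak_conductance_density <= 0)
    stop("capacitance, resistivity and leak density must be positive")
  if (!is.finite(leak_reversal)) stop("leak_reversal must be finite")
  structure(list(specific_capacitance = specific_capacitance,
                 axial_resistivity = axial_resistivity,
                 leak_conductance_density = leak_conductance_density,
                 leak_reversal = leak_reversal),
            class = "cable_params")
}

#' Voltage-gated channel set for the active bipolar cell model
#'
#' Hodgkin-Huxley-style single-gate formulations of the three conductances
#' of the active membrane: an L-type Ca channel (low-threshold activation,
#' ohmic with fixed Ca reversal), a delayed-rectifier Kv channel, and an
#' HCN2 channel (activated by hyperpolarization). Steady-state activation
#' is `1 / (1 + exp(sign * (v - vhalf) / slope))` with `sign = -1` for
#' depolarization-activated gates; time constants are voltage-independent.
#' Densities and kinetics are configurable; the defaults place the
#' operating point so that Kv is the dominant active conductance between
#' the dark (-45 mV) and light (-30 mV) membrane potentials.
#'
#' @param gbar_cal,gbar_kv,gbar_hcn2 maximal conductance densities, S/cm^2.
#' @return A list of channel specifications (class `channel_specs`), each
#'   with fields `name`, `density`, `e_rev`, `vhalf`, `slope`, `sign`,
#'   `tau`.
#' @export
channel_specs <- function(gbar_cal = 3e-5, gbar_kv = 5e-4,
                          gbar_hcn2 = 1.5e-4) {
  specs <- list(
    list(name = "CaL",  density = gbar_cal, e_rev = 45,  vhalf = -40,
         slope = 7,   sign = -1, tau = 1),
    list(name = "Kv",   density = gbar_kv,  e_rev = -77, vhalf = -30,
         slope = 9.5, sign = -1, tau = 5),
    list(name = "HCN2", density = gbar_hcn2, e_rev = -30, vhalf = -87.6,
         slope = 8.1, sign = 1,  tau = 250)
  )
  specs <- Filter(function(s) s$density > 0, specs)
  structure(specs, class = "channel_specs")
}

#' Two-state kinetic synapse specification
#'
#' Difference-of-exponentials conductance normalized to unit peak; each
#' Poisson event adds `unitary_conductance` at the peak. Excitatory
#' synapses: rise 10 ms, decay 100 ms, reversal 10.1 mV. Inhibitory:
#' rise 1.8 ms, decay 100 ms, reversal -50.4 mV.
#'
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param tau_rise,tau_decay kinetics, ms (`tau_rise < tau_decay`).
#' @param reversal synaptic reversal potential, mV.
#' @param unitary_conductance peak conductance per event, nS.
#' @return A list of class `synapse_spec`.
#' @export
synapse_spec <- function(kind = c("excitatory", "inhibitory"),
                         tau_rise = NULL, tau_decay = 100, reversal = NULL,
                         unitary_conductance = NULL) {
  kind <- match.arg(kind)
  tau_rise <- tau_rise %||% if (kind == "excitatory") 10 else 1.8
  reversal <- reversal %||% if (kind == "excitatory") 10.1 else -50.4
  unitary_conductance <- unitary_conductance %||%
    if (kind == "excitatory") 0.02 else 0.05
  if (!(tau_rise < tau_decay)) stop("tau_rise must be < tau_decay")
  structure(list(kind = kind, tau_rise = tau_rise, tau_decay = tau_decay,
                 reversal = reversal,
                 unitary_conductance = unitary_conductance),
            class = "synapse_spec")
}

#' Simulation configuration
#'
#' @param dt time step, ms.
#' @param settle_time settling period before the stimulus, ms (500).
#' @param stim_time stimulus duration, ms (1000).
#' @param seed integer seed for the Poisson synaptic event draws.
#' @param compartment_max_length maximal compartment length, um.
#' @return A list of class `sim_config`. The measurement window used by the
#'   analysis is the final 500 ms of the stimulus (excluding the synaptic
#'   onset transient), reported in the `window` field.
#' @export
sim_config <- function(dt = 0.025, settle_time = 500, stim_time = 1000,
                       seed = 1L, compartment_max_length = 3) {
  if (dt <= 0) stop("dt must be positive")
  if (settle_time < 0) stop("settle_time must be >= 0")
  w0 <- settle_time + max(stim_time - 500, stim_time / 2)
  structure(list(dt = dt, settle_time = settle_time, stim_time = stim_time,
                 seed = as.integer(seed),
                 compartment_max_length = compartment_max_length,
                 t_stop = settle_time + stim_time,
                 window = c(w0, settle_time + stim_time)),
            class = "sim_config")
}

#' Total membrane area of a morphology
#'
#' Sum of frustum lateral areas over all edges plus the soma sphere.
#'
#' @param m a [tree_morphology()].
#' @return Area in um^2.
#' @export
morphology_area <- function(m) {
  nodes <- m$nodes
  pos <- match(nodes$parent, nodes$id)
  keep <- !is.na(pos)
  L <- sqrt((nodes$x[keep] - nodes$x[pos[keep]])^2 +
            (nodes$y[keep] - nodes$y[pos[keep]])^2 +
            (nodes$z[keep] - nodes$z[pos[keep]])^2)
  r0 <- nodes$radius[pos[keep]]; r1 <- nodes$radius[keep]
  frustum <- pi * (r0 + r1) * sqrt(L^2 + (r1 - r0)^2)
  soma <- nodes$label[is.na(nodes$parent)] == "soma"
  sum(frustum) + if (soma) 4 * pi * nodes$radius[is.na(nodes$parent)]^2 else 0
}

#' Discretize a morphology into cable compartments
#'
#' Splits every edge into segments no longer than `max_len`, computes
#' per-segment membrane area (frustum with linearly interpolated radii) and
#' axial conductances (series half-segment resistances), and preserves the
#' tree topology. The root node becomes a dedicated root compartment (soma
#' sphere area when the root is a soma).
#'
#' @param m a [tree_morphology()].
#' @param max_len maximal segment length, um.
#' @return An object of class `compartment_graph` with fields `parent`
#'   (index, NA for root), `length`, `radius` (um), `area_cm2`, `label`,
#'   `node2comp` (map from node id to compartment index), `n` and
#'   `n_segments` (cable segments, excluding the root compartment).
#' @export
build_compartments <- function(m, max_len) {
  if (max_len <= 0) stop("max_len must be positive")
  nodes <- m$nodes
  pos <- match(nodes$parent, nodes$id)
  root <- which(is.na(pos))
  n_nodes <- nrow(nodes)
  # topological node order (parents first)
  idx <- m$index %||% .tree_index(nodes)
  node_order <- order(idx$depth)

  parent <- NA_integer_; len <- 0; rad <- nodes$radius[root]
  area <- if (nodes$label[root] == "soma") 4 * pi * rad^2 else 0
  label <- nodes$label[root]
  node2comp <- integer(n_nodes); node2comp[root] <- 1L
  cnt <- 1L
  parent <- c(NA_integer_); lens <- c(0); rads <- c(rad); areas <- c(area)
  labels <- c(label)
  for (i in node_order) {
    p <- pos[i]
    if (is.na(p)) next
    dx <- nodes$x[i] - nodes$x[p]; dy <- nodes$y[i] - nodes$y[p]
    dz <- nodes$z[i] - nodes$z[p]
    L <- sqrt(dx^2 + dy^2 + dz^2)
    k <- max(1L, ceiling(L / max_len))
    r0 <- nodes$radius[p]; r1 <- nodes$radius[i]
    prev <- node2comp[p]
    for (j in seq_len(k)) {
      ra <- r0 + (j - 1) / k * (r1 - r0)
      rb <- r0 + j / k * (r1 - r0)
      seg_len <- L / k
      cnt <- cnt + 1L
      parent[cnt] <- prev
      lens[cnt] <- seg_len
      rads[cnt] <- (ra + rb) / 2
      areas[cnt] <- pi * (ra + rb) * sqrt(seg_len^2 + (rb - ra)^2)
      labels[cnt] <- nodes$label[i]
      prev <- cnt
    }
    node2comp[i] <- prev
  }
  names(node2comp) <- nodes$id
  structure(list(parent = parent, length = lens, radius = rads,
                 area_um2 = areas, area_cm2 = areas * 1e-8,
                 label = labels, node2comp = node2comp,
                 n = cnt, n_segments = cnt - 1L),
            class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat("compartment_graph:", x$n, "compartments (", x$n_segments,
      "cable segments ), total area",
      sprintf("%.1f um^2\n", sum(x$area_um2)))
  invisible(x)
}

# Draw sorted Poisson event times for one synapse activation window.
.poisson_events <- function(rate, t_start, t_end) {
  if (rate <= 0 || t_end <= t_start) return(numeric(0))
  n <- stats::rpois(1, rate * (t_end - t_start) / 1000)
  sort(stats::runif(n, t_start, t_end))
}

#' Run a compartmental cable simulation
#'
#' Backward-Euler integration with an exact per-step solution of the
#' tree-structured linear system (leaf-to-root elimination). Synaptic
#' events are drawn from seeded Poisson processes, so identical inputs and
#' seed give identical traces.
#'
#' @param graph a [build_compartments()] graph.
#' @param cp [cable_params()].
#' @param channels a [channel_specs()] list, or `NULL`/empty for a passive
#'   model.
#' @param synapses list of active synapses; each element a list with
#'   `comp` (compartment index) or `node` (node id), `spec`
#'   ([synapse_spec()]), `rate` (events/s), and optional `t_start`/`t_end`
#'   (ms, default the whole simulation).
#' @param cfg [sim_config()].
#' @param injections list of current injections; each a list with `comp`
#'   or `node`, `amp` (nA), `freq` (Hz, 0 = constant), optional
#'   `t_start`/`t_end`.
#' @param record_nodes node ids to record (mapped through the graph), or
#' @param record_comps compartment indices to record.
#' @param v_init initial voltage, mV (default the leak reversal).
#' @param seed overrides `cfg$seed` for the event draw.
#' @param channel_comps optional logical/integer subset of compartments
#'   carrying the voltage-gated channels (default: all).
#' @param record_mean record only the window-mean voltage per site (one
#'   row) instead of the full trace; the statistics of the CSR analysis
#'   need only the means, and this keeps long sweeps light.
#' @return An object of class `cable_sim`: `time` (ms), `v` (matrix, one
#'   column per recorded site), `conductance` (time-averaged summed
#'   conductance per mechanism over the measurement window, nS), `window`,
#'   and the configuration used.
#' @export
simulate_cable <- function(graph, cp, channels = NULL, synapses = list(),
                           cfg = sim_config(), injections = list(),
                           record_nodes = NULL, record_comps = NULL,
                           v_init = NULL, seed = NULL,
                           channel_comps = NULL, record_mean = FALSE) {
  stopifnot(inherits(graph, "compartment_graph"))
  v_init <- v_init %||% cp$leak_reversal
  seed <- seed %||% cfg$seed
  n <- graph$n

  cm_nF <- cp$specific_capacitance * graph$area_cm2 * 1e3      # uF/cm2 * cm2 -> uF -> nF... (1 uF = 1000 nF)
  g_leak <- cp$leak_conductance_density * graph$area_cm2 * 1e6 # S -> uS
  half_res <- cp$axial_resistivity / pi *
    (graph$length * 1e-4 / 2) / (graph$radius * 1e-4)^2        # Ohm
  g_axial <- numeric(n)
  for (i in seq_len(n)) {
    p <- graph$parent[i]
    if (!is.na(p)) g_axial[i] <- 1e6 / (half_res[i] + half_res[p])  # uS
  }

  chan_mask <- rep(1, n)
  if (!is.null(channel_comps)) {
    chan_mask <- rep(0, n)
    chan_mask[channel_comps] <- 1
  }
  chan_list <- lapply(channels %||% list(), function(ch) {
    list(name = ch$name,
         gbar = ch$density * graph$area_cm2 * 1e6 * chan_mask,  # uS
         e_rev = ch$e_rev, vhalf = ch$vhalf, slope = ch$slope,
         sign = ch$sign, tau = ch$tau)
  })

  .resolve_comp <- function(entry) {
    if (!is.null(entry$comp)) return(as.integer(entry$comp))
    if (!is.null(entry$node)) {
      key <- as.character(entry$node)
      if (!key %in% names(graph$node2comp))
        stop("node ", entry$node, " is not on the compartment graph")
      return(graph$node2comp[[key]])
    }
    stop("synapse/injection entry needs `comp` or `node`")
  }

  syn_list <- with_seed(seed, lapply(synapses, function(sy) {
    comp <- .resolve_comp(sy)
    spec <- sy$spec
    t0 <- sy$t_start %||% 0
    t1 <- sy$t_end %||% cfg$t_stop
    list(comp = comp - 1L, e_rev = spec$reversal,
         tau_rise = spec$tau_rise, tau_decay = spec$tau_decay,
         unitary = spec$unitary_conductance * 1e-3,   # nS -> uS
         events = .poisson_events(sy$rate, t0, t1),
         cls = if (spec$kind == "excitatory") 0L else 1L)
  }))

  inj_list <- lapply(injections, function(inj) {
    list(comp = .resolve_comp(inj) - 1L, amp = inj$amp,
         freq = inj$freq %||% 0,
         t_start = inj$t_start %||% 0, t_end = inj$t_end %||% cfg$t_stop)
  })

  if (is.null(record_comps)) {
    if (is.null(record_nodes)) record_comps <- seq_len(n)
    else record_comps <- vapply(record_nodes, function(nd)
      .resolve_comp(list(node = nd)), integer(1))
  }

  res <- .simulate_cable_cpp(
    parent = ifelse(is.na(graph$parent), -1L, graph$parent - 1L),
    cm = cm_nF, g_axial = g_axial, g_leak = g_leak,
    e_leak = cp$leak_reversal, channels = chan_list, synapses = syn_list,
    injections = inj_list, dt = cfg$dt, t_stop = cfg$t_stop,
    v_init = v_init, record_comp = as.integer(record_comps - 1L),
    acct_start = cfg$window[1], record_mean = record_mean)

  v <- res$v
  colnames(v) <- if (!is.null(record_nodes)) as.character(record_nodes)
                 else as.character(record_comps)
  tgrid <- if (record_mean) mean(cfg$window)
           else seq(0, cfg$t_stop, by = cfg$dt)
  structure(list(time = tgrid, v = v,
                 conductance = res$conductance * 1e3,   # uS -> nS
                 window = cfg$window, dt = cfg$dt, cfg = cfg,
                 record_comps = record_comps,
                 record_nodes = record_nodes),
            class = "cable_sim")
}

#' @export
print.cable_sim <- function(x, ...) {
  cat("cable_sim:", nrow(x$v), "time points x", ncol(x$v), "sites;",
      sprintf("window [%g, %g] ms\n", x$window[1], x$window[2]))
  mv <- mean_voltage(x)
  cat(sprintf("  window-mean voltage: %.2f mV (range %.2f to %.2f)\n",
              mean(mv), min(mv), max(mv)))
  invisible(x)
}

#' @export
plot.cable_sim <- function(x, sites = seq_len(min(ncol(x$v), 8)), ...) {
  graphics::matplot(x$time, x$v[, sites, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "voltage (mV)", ...)
  invisible(x)
}

#' Write recorded voltage traces as CSV
#'
#' One `time_ms` column plus one column per recorded site.
#'
#' @param sim a [simulate_cable()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(sim, path) {
  d <- data.frame(time_ms = sim$time, sim$v, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Window-averaged voltage per recorded site
#'
#' @param sim a [simulate_cable()] result.
#' @param window time interval, ms (default the simulation's measurement
#'   window, the final 500 ms of the stimulus).
#' @return Named numeric vector of mean voltages, mV.
#' @export
mean_voltage <- function(sim, window = sim$window) {
  sel <- sim$time >= window[1] & sim$time <= window[2]
  colMeans(sim$v[sel, , drop = FALSE])
}

#' Frequency-dependent length constants from a sinusoidal soma probe
#'
#' Injects a small sinusoidal current at the soma, extracts the voltage
#' oscillation amplitude at the soma and at each ribbon site as the
#' discrete Fourier coefficient at the drive frequency over an integer
#' number of cycles (after discarding the settling transient), and converts
#' per-ribbon attenuation into a length constant
#' `lambda = -d / log(A_ribbon / A_soma)` with `d` the soma-to-ribbon path
#' distance. Ribbons with no attenuation report `Inf`.
#'
#' @param m the [tree_morphology()] underlying `graph`.
#' @param graph a [build_compartments()] graph of `m`.
#' @param cp,channels,cfg model components as in [simulate_cable()].
#' @param freq drive frequency, Hz.
#' @param soma_node node id of the injection site.
#' @param ribbons `synapse_sites` table of ribbon sites.
#' @param amp current amplitude, nA (small, quasi-linear regime).
#' @param synapses optional active synapse list (see [simulate_cable()]);
#'   with synapses active the probe measures the shunted cable.
#' @param cycles number of drive cycles to analyze (default: enough for
#'   at least 500 ms, minimum 1).
#' @param discard transient discard, ms.
#' @param seed RNG seed for synaptic events.
#' @return data frame with columns `site_id`, `distance_um`, `amplitude_mv`
#'   and `lambda_um`.
#' @export
sinusoidal_length_constants <- function(m, graph, cp, channels = NULL,
                                        cfg = sim_config(), freq,
                                        soma_node, ribbons, amp = 0.002,
                                        synapses = list(), cycles = NULL,
                                        discard = 500, seed = 1L) {
  if (freq <= 0) stop("freq must be positive")
  cycles <- cycles %||% max(1, ceiling(freq * 0.5))
  period <- 1000 / freq
  t_stop <- discard + cycles * period
  cfg2 <- cfg
  cfg2$settle_time <- discard
  cfg2$stim_time <- cycles * period
  cfg2$t_stop <- t_stop
  cfg2$window <- c(discard, t_stop)
  record <- c(soma_node, ribbons$node_id)
  sim <- simulate_cable(graph, cp, channels = channels, synapses = synapses,
                        cfg = cfg2,
                        injections = list(list(node = soma_node, amp = amp,
                                               freq = freq, t_start = 0,
                                               t_end = t_stop)),
                        record_nodes = record, seed = seed)
  sel <- sim$time > discard + 1e-9
  tt <- sim$time[sel]
  ph <- exp(-2i * pi * freq * tt / 1000)
  amps <- apply(sim$v[sel, , drop = FALSE], 2, function(v)
    2 * Mod(sum((v - mean(v)) * ph)) / length(v))
  if (any(amps <= 0)) stop("zero oscillation amplitude at a recorded site")
  a_soma <- amps[1]
  a_rib <- amps[-1]
  d <- path_distances(m, soma_node, ribbons$node_id)
  lambda <- ifelse(a_rib >= a_soma, Inf, -d / log(a_rib / a_soma))
  data.frame(site_id = ribbons$site_id, distance_um = d,
             amplitude_mv = a_rib, lambda_um = lambda)
}
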