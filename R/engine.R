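#' Run a network simulation
#'
#' Advances the full network on a fixed time grid: piecewise-constant noise
#' currents are refreshed on 1 ms boundaries, due spike deliveries are added
#' to the synaptic currents, all membranes are advanced with the exact
#' propagator, threshold crossings are detected at step boundaries, and each
#' emission updates the neuron's outbound plastic synapses event-wise in
#' closed form before scheduling deliveries at `t + delay`. The run is
#' reproducible: identical (network, protocol, parameters, seed) give an
#' identical raster.
#'
#' @param network a [build_network()] result.
#' @param protocol a [wm_protocol()].
#' @param neuron_E,neuron_I [neuron_params()] for excitatory / inhibitory
#'   neurons.
#' @param stp an [stp_params()] object (applies to all E-to-E synapses).
#' @param sim a [sim_params()] object.
#' @param variant efficacy-modulation ordering, `"post_u"` (default) or
#'   `"pre_u"`; see [modulated_efficacy()].
#' @param forced_spikes optional data.frame (`time`, `neuron`) of emissions
#'   injected regardless of the membrane state (test instrumentation).
#' @param return_stp_state also return the final per-connection STP state.
#' @param V0 initial membrane potentials (default: uniform on
#'   `[0, V_th)` per neuron, drawn under the run seed).
#' @return An object of class `"wm_sim"`: list with `spikes` (data.frame
#'   `time`, `id`), `n_spikes` (per-neuron counts), `traces` (named list of
#'   data.frames `time`, `mean_u`, `mean_x` per traced population),
#'   `stp_state` (optional data.frame `src`, `u`, `x`, `t_last`), `V_final`,
#'   and `meta` (seed, dt, T_total, variant, protocol).
#' @export
run_simulation <- function(network, protocol,
                           neuron_E = neuron_params(),
                           neuron_I = neuron_params(tau_m = 10),
                           stp = stp_params(), sim = sim_params(),
                           variant = c("post_u", "pre_u"),
                           forced_spikes = NULL,
                           return_stp_state = FALSE, V0 = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(network, "wm_network"), inherits(protocol, "wm_protocol"))
  cfg <- network$cfg
  conn <- network$connections
  popmap <- network$popmap
  N_E <- cfg$N_E; N_I <- cfg$N_I; N <- N_E + N_I
  if (is.unsorted(conn$src))
    stop("connection table must be grouped by source neuron", call. = FALSE)
  if (neuron_E$tau_exc != neuron_I$tau_exc ||
      neuron_E$tau_inh != neuron_I$tau_inh)
    stop("synaptic time constants must agree across neuron types",
         call. = FALSE)

  set.seed(sim$seed)
  compiled <- compile_protocol(protocol, popmap)
  if (is.null(V0)) {
    V_th_of <- c(rep(neuron_E$V_th, N_E), rep(neuron_I$V_th, N_I))
    V0 <- stats::runif(N, 0, V_th_of)
  }

  # precomputed current jumps: alpha(target membrane) * J / tau_syn(source)
  a_E_exc <- as.numeric(alpha_factor(neuron_E, neuron_E$tau_exc))
  a_I_exc <- as.numeric(alpha_factor(neuron_I, neuron_I$tau_exc))
  a_E_inh <- as.numeric(alpha_factor(neuron_E, neuron_E$tau_inh))
  a_I_inh <- as.numeric(alpha_factor(neuron_I, neuron_I$tau_inh))
  src_exc <- conn$src <= N_E
  tgt_exc <- conn$tgt <= N_E
  fac <- ifelse(src_exc,
                ifelse(tgt_exc, a_E_exc, a_I_exc) / neuron_E$tau_exc,
                ifelse(tgt_exc, a_E_inh, a_I_inh) / neuron_E$tau_inh)
  jump <- fac * conn$J

  delay_steps <- pmax(1L, as.integer(ceiling(conn$delay / sim$dt - 1e-9)))
  plastic_id <- rep(-1L, length(conn$src))
  plastic_id[conn$plastic] <- seq_len(sum(conn$plastic)) - 1L
  n_plastic <- sum(conn$plastic)

  out_ptr <- c(0L, cumsum(tabulate(conn$src, nbins = N)))

  traced <- sim$traced_pops
  trace_ids <- lapply(traced, function(p) {
    if (p < 1 || p > popmap$n_pops)
      stop("untraced/unknown population id: ", p, call. = FALSE)
    idx <- which(conn$plastic & conn$src %in% popmap$members[[p]])
    if (length(idx) > sim$trace_max_connections)
      idx <- sort(sample(idx, sim$trace_max_connections))
    plastic_id[idx]
  })
  trace_every <- if (length(traced)) {
    max(1L, as.integer(round(sim$trace_dt / sim$dt)))
  } else 0L

  n_steps <- as.integer(round(sim$T_total / sim$dt))
  if (is.null(forced_spikes)) {
    fs_step <- integer(0); fs_id <- integer(0)
  } else {
    o <- order(forced_spikes$time)
    fs_step <- as.integer(round(forced_spikes$time[o] / sim$dt))
    fs_id <- as.integer(forced_spikes$neuron[o]) - 1L
  }

  res <- .engine_run(
    N_E, N_I,
    c(neuron_E$tau_m, neuron_I$tau_m), c(neuron_E$R_m, neuron_I$R_m),
    c(neuron_E$V_th, neuron_I$V_th), c(neuron_E$V_reset, neuron_I$V_reset),
    c(neuron_E$t_ref, neuron_I$t_ref),
    neuron_E$tau_exc, neuron_E$tau_inh,
    out_ptr, conn$tgt - 1L, jump, delay_steps, plastic_id, n_plastic,
    stp$U, stp$tau_f, stp$tau_d, variant == "post_u",
    compiled$t_start, compiled$t_end, compiled$mu, compiled$sigma,
    lapply(compiled$members, function(m) as.integer(m) - 1L),
    sim$dt, n_steps, sim$seed, V0, sim$record_spikes,
    trace_ids, trace_every, fs_step, fs_id, return_stp_state)

  traces <- res$traces
  names(traces) <- as.character(traced)
  out <- list(
    spikes = data.frame(time = res$spike_time, id = res$spike_id),
    n_spikes = res$n_spikes,
    traces = traces,
    V_final = res$V_final,
    meta = list(seed = sim$seed, dt = sim$dt, T_total = sim$T_total,
                variant = variant, protocol = as.data.frame(protocol),
                N_E = N_E, N_I = N_I, network_seed = network$seed))
  if (return_stp_state)
    out$stp_state <- data.frame(src = conn$src[conn$plastic],
                                u = res$stp_u, x = res$stp_x,
                                t_last = res$stp_t_last)
  class(out) <- "wm_sim"
  out
}

#' @export
print.wm_sim <- function(x, ...) {
  cat(sprintf("wm_sim: %g ms at dt = %g ms, %d spikes from %d neurons (seed %d)\n",
              x$meta$T_total, x$meta$dt, nrow(x$spikes),
              x$meta$N_E + x$meta$N_I, x$meta$seed))
  invisible(x)
}

#' Mean STP variables of a population's outbound synapses
#'
#' Averages the analytically decayed left-side limits `u(t-)`, `x(t-)` over
#' the plastic connections whose source neuron belongs to the given
#' selective population, from a final-state snapshot returned by
#' [run_simulation()] with `return_stp_state = TRUE`. Pure query; no state
#' is mutated.
#'
#' @param result a `"wm_sim"` with an `stp_state` component.
#' @param popmap the network's [assign_populations()] result.
#' @param pop selective-population id.
#' @param t query time (ms), `>=` every connection's last update time.
#' @param stp the [stp_params()] used in the run.
#' @return list with `mean_u` and `mean_x`.
#' @export
stp_population_average <- function(result, popmap, pop, t,
                                   stp = stp_params()) {
  if (is.null(result$stp_state))
    stop("run_simulation() must be called with return_stp_state = TRUE",
         call. = FALSE)
  if (pop < 1 || pop > popmap$n_pops)
    stop("unknown population id: ", pop, call. = FALSE)
  sel <- result$stp_state$src %in% popmap$members[[pop]]
  if (!any(sel)) stop("population has no outbound plastic connections",
                      call. = FALSE)
  dec <- stp_decay(result$stp_state[sel, ], t, stp)
  list(mean_u = mean(dec$u), mean_x = mean(dec$x))
}
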