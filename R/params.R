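#' Membrane and synaptic-current constants of a LIF neuron
#'
#' Bundles the constants of the leaky integrate-and-fire neuron with
#' exponential postsynaptic currents. The membrane potential is expressed
#' relative to rest (rest = 0 mV), so the sub-threshold dynamics carry no
#' explicit leak reversal term. With the default `R_m = 1` external and
#' synaptic currents are expressed directly in mV of steady-state
#' depolarization, the convention used throughout the package.
#'
#' @param tau_m membrane time constant (ms).
#' @param R_m membrane resistance (input resistance; with `R_m = 1` currents
#'   are read in mV).
#' @param V_th firing threshold (mV above rest).
#' @param V_reset post-spike reset potential (mV above rest); must be below
#'   `V_th`.
#' @param t_ref absolute refractory period (ms); the membrane is clamped at
#'   `V_reset` while refractory, synaptic currents keep evolving.
#' @param tau_exc,tau_inh time constants of the excitatory and inhibitory
#'   exponential postsynaptic currents (ms).
#' @return An object of class `"neuron_params"` (a named list).
#' @examples
#' neuron_params()                      # excitatory defaults
#' neuron_params(tau_m = 10)            # inhibitory membrane
#' @export
neuron_params <- function(tau_m = 15, R_m = 1, V_th = 20, V_reset = 16,
                          t_ref = 2, tau_exc = 2, tau_inh = 2) {
  stopifnot(is.numeric(tau_m), is.numeric(R_m), is.numeric(V_th))
  if (tau_m <= 0 || tau_exc <= 0 || tau_inh <= 0)
    stop("all time constants must be positive", call. = FALSE)
  if (R_m <= 0) stop("R_m must be positive", call. = FALSE)
  if (t_ref < 0) stop("t_ref must be non-negative", call. = FALSE)
  if (V_reset >= V_th) stop("V_reset must lie below V_th", call. = FALSE)
  structure(list(tau_m = tau_m, R_m = R_m, V_th = V_th, V_reset = V_reset,
                 t_ref = t_ref, tau_exc = tau_exc, tau_inh = tau_inh),
            class = "neuron_params")
}

#' Short-term plasticity parameters
#'
#' Constants of the phenomenological facilitation/depression model: `U` is
#' the baseline utilization (the fraction of available resources released by
#' a spike arriving at a fully rested synapse), `tau_f` the facilitation
#' (residual-calcium removal) time constant and `tau_d` the depression
#' (neurotransmitter recovery) time constant. The defaults
#' (`U = 0.19`, `tau_f = 1500`, `tau_d = 200`) put the synapse deep in the
#' facilitation-dominated regime (`tau_f > tau_d`) used for synaptic working
#' memory; `U = 0.19` is the value at which the analytic limit-cycle period
#' [tmax_estimate()] equals 445.1 ms.
#'
#' @param U baseline utilization, in (0, 1].
#' @param tau_f facilitation time constant (ms).
#' @param tau_d depression time constant (ms).
#' @return An object of class `"stp_params"`.
#' @examples
#' stp_params()
#' stp_params(tau_f = 3000)   # slower calcium removal: larger capacity
#' @export
stp_params <- function(U = 0.19, tau_f = 1500, tau_d = 200) {
  if (!is.numeric(U) || U <= 0 || U > 1)
    stop("U must lie in (0, 1]", call. = FALSE)
  if (tau_f <= 0 || tau_d <= 0)
    stop("tau_f and tau_d must be positive", call. = FALSE)
  structure(list(U = U, tau_f = tau_f, tau_d = tau_d), class = "stp_params")
}

#' Simulation-loop parameters
#'
#' @param dt integration step (ms). Must divide the 1 ms noise interval
#'   evenly.
#' @param T_total total simulated time (ms).
#' @param seed integer seed controlling noise sampling inside the engine.
#' @param record_spikes keep the full spike raster.
#' @param trace_dt sampling period (ms) of the averaged STP traces.
#' @param traced_pops integer vector of selective-population ids whose
#'   outbound synapses are traced (empty = no traces).
#' @param trace_max_connections per-population cap on the number of plastic
#'   connections averaged for the trace (a random subset; the full set is
#'   millions of synapses and the subset mean is statistically
#'   indistinguishable).
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(dt = 0.05, T_total = 1000, seed = 1,
                       record_spikes = TRUE, trace_dt = 10,
                       traced_pops = integer(0),
                       trace_max_connections = 10000L) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  steps_per_ms <- 1 / dt
  if (abs(steps_per_ms - round(steps_per_ms)) > 1e-9)
    stop("dt must divide the 1 ms noise interval evenly", call. = FALSE)
  if (T_total < 0) stop("T_total must be non-negative", call. = FALSE)
  structure(list(dt = dt, T_total = T_total, seed = as.integer(seed),
                 record_spikes = isTRUE(record_spikes), trace_dt = trace_dt,
                 traced_pops = as.integer(traced_pops),
                 trace_max_connections = as.integer(trace_max_connections)),
            class = "sim_params")
}
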