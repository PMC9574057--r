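#' Exact one-step propagator of the LIF + exponential-current dynamics
#'
#' The sub-threshold system — membrane potential driven by excitatory and
#' inhibitory exponential postsynaptic currents and a piecewise-constant
#' external current — is linear, so a time step of width `dt` can be
#' advanced exactly by precomputed coefficients instead of an approximate
#' scheme (exact integration on a fixed grid). For `tau_m == tau_syn` the
#' degenerate `t * exp(-t/tau)` limit form is used.
#'
#' @param params a [neuron_params()] object.
#' @param dt step width (ms), > 0 (0 is allowed and yields the identity).
#' @return An object of class `"lif_propagator"`: decay factors `dV`
#'   (membrane), `dE`, `dI` (currents), cross couplings `cE`, `cI`
#'   (current-to-voltage over one step) and `cX` (constant external current
#'   to voltage, `R_m * (1 - dV)`).
#' @examples
#' p <- lif_propagator(neuron_params(), dt = 0.05)
#' p$dE  # exp(-0.05/2)
#' @export
lif_propagator <- function(params, dt) {
  if (dt < 0) stop("dt must be non-negative", call. = FALSE)
  tm <- params$tau_m
  cross <- function(ts) {
    if (abs(tm - ts) < 1e-12) {
      params$R_m * (dt / tm) * exp(-dt / tm)
    } else {
      params$R_m * (ts / (tm - ts)) * (exp(-dt / tm) - exp(-dt / ts))
    }
  }
  structure(list(dV = exp(-dt / tm),
                 dE = exp(-dt / params$tau_exc),
                 dI = exp(-dt / params$tau_inh),
                 cE = cross(params$tau_exc),
                 cI = cross(params$tau_inh),
                 cX = params$R_m * (1 - exp(-dt / tm)),
                 dt = dt),
            class = "lif_propagator")
}

#' Advance one neuron by one step, with threshold, reset and refractoriness
#'
#' Sub-threshold state is advanced with an exact propagator; threshold is
#' checked at the step boundary (no sub-step interpolation). On a crossing
#' the membrane is reset and clamped for the absolute refractory period,
#' while synaptic currents keep evolving.
#'
#' @param state list with `V`, `I_exc`, `I_inh`, `refractory_until` (ms).
#' @param prop a [lif_propagator()] for the step width in use.
#' @param I_ext external current held constant over the step.
#' @param params the [neuron_params()] the propagator was built from.
#' @param t time at the beginning of the step (ms).
#' @return list with `state` (after the step) and `spiked` (logical).
#' @export
lif_step <- function(state, prop, I_ext, params, t) {
  if (!all(is.finite(c(state$V, state$I_exc, state$I_inh))))
    stop(sprintf("numerical failure: non-finite neuron state at t = %g ms", t),
         call. = FALSE)
  t_next <- t + prop$dt
  refractory <- state$refractory_until > t + 1e-12
  V <- if (refractory) params$V_reset else
    prop$dV * state$V + prop$cE * state$I_exc + prop$cI * state$I_inh +
      prop$cX * I_ext
  I_exc <- prop$dE * state$I_exc
  I_inh <- prop$dI * state$I_inh
  spiked <- !refractory && V >= params$V_th
  if (spiked) {
    V <- params$V_reset
    state$refractory_until <- t_next + params$t_ref
  }
  state$V <- V
  state$I_exc <- I_exc
  state$I_inh <- I_inh
  list(state = state, spiked = spiked)
}

#' Simulate a single LIF neuron on a fixed grid (reference implementation)
#'
#' Plain-R single-neuron loop used for contracts and oracles (PSP peak
#' measurement, inter-spike-interval checks, propagator validation). Current
#' jumps are applied at the beginning of their step, before propagation, the
#' same ordering as the network engine.
#'
#' @param params a [neuron_params()] object.
#' @param dt step (ms).
#' @param n_steps number of steps.
#' @param I_ext external current: scalar or length-`n_steps` vector.
#' @param exc_jumps,inh_jumps current jumps added to the respective synaptic
#'   current at the beginning of each step (scalar 0 or length `n_steps`).
#' @param V0 initial membrane potential.
#' @return list with vectors `V`, `I_exc`, `I_inh` (state at the end of each
#'   step) and `spike_steps` (1-based indices of spiking steps).
#' @export
simulate_lif <- function(params, dt, n_steps, I_ext = 0,
                         exc_jumps = 0, inh_jumps = 0, V0 = 0) {
  prop <- lif_propagator(params, dt)
  I_ext <- rep_len(I_ext, n_steps)
  exc_jumps <- rep_len(exc_jumps, n_steps)
  inh_jumps <- rep_len(inh_jumps, n_steps)
  state <- list(V = V0, I_exc = 0, I_inh = 0, refractory_until = -Inf)
  V <- Ie <- Ii <- numeric(n_steps)
  spikes <- integer(0)
  for (k in seq_len(n_steps)) {
    state$I_exc <- state$I_exc + exc_jumps[k]
    state$I_inh <- state$I_inh + inh_jumps[k]
    res <- lif_step(state, prop, I_ext[k], params, (k - 1) * dt)
    state <- res$state
    if (res$spiked) spikes <- c(spikes, k)
    V[k] <- state$V; Ie[k] <- state$I_exc; Ii[k] <- state$I_inh
  }
  list(V = V, I_exc = Ie, I_inh = Ii, spike_steps = spikes)
}

#' Sample a piecewise-constant Gaussian noise current
#'
#' The external drive is approximated by a current held constant over 1 ms
#' intervals; interval `k` carries `mu + sigma * G_k` with `G_k` standard
#' normal. Sampling uses R's global RNG stream.
#'
#' @param mu mean current.
#' @param sigma standard deviation, >= 0.
#' @param n_intervals number of 1 ms intervals, >= 0.
#' @return numeric vector of per-interval current values.
#' @export
sample_noise <- function(mu, sigma, n_intervals) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (n_intervals < 0) stop("n_intervals must be non-negative", call. = FALSE)
  mu + sigma * stats::rnorm(n_intervals)
}

#' Current-per-mV conversion factor for spike deliveries
#'
#' Synaptic efficacies are expressed in mV of peak postsynaptic-potential
#' deflection, while a delivered spike enters the dynamics as a jump of the
#' exponential synaptic current. `alpha_factor` returns the factor `alpha`
#' such that a jump `alpha * J / tau_syn` produces a peak membrane
#' deflection of exactly `J` mV from rest. The peak occurs at
#' `t_peak = tau_m * tau_syn / (tau_m - tau_syn) * log(tau_m / tau_syn)`;
#' for `tau_syn == tau_m` the `t e^{-t/tau}` limit form applies
#' (`t_peak = tau_m`). `alpha` scales as `1 / R_m`.
#'
#' @param params a [neuron_params()] object (the *target* neuron's
#'   membrane).
#' @param tau_syn synaptic-current time constant (ms).
#' @return `alpha` (current units per mV, times ms via the `J/tau_syn`
#'   convention), with attribute `t_peak` (ms).
#' @examples
#' alpha_factor(neuron_params(), 2)   # tau_m = 15: t_peak = 30/13*log(7.5)
#' @export
alpha_factor <- function(params, tau_syn = params$tau_exc) {
  tm <- params$tau_m
  if (abs(tm - tau_syn) < 1e-12) {
    peak1 <- params$R_m * exp(-1) / tm  # jump 1/tau_syn, peak at t = tau_m
    t_peak <- tm
  } else {
    t_peak <- tm * tau_syn / (tm - tau_syn) * log(tm / tau_syn)
    # V(t) for unit jump h = 1/tau_syn into the synaptic current:
    peak1 <- params$R_m * (1 / (tm - tau_syn)) *
      (exp(-t_peak / tm) - exp(-t_peak / tau_syn))
  }
  structure(1 / peak1, t_peak = t_peak)
}
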