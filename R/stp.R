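#' Relax STP variables between presynaptic spikes
#'
#' Closed-form decay of the utilization `u` toward its baseline `U` (time
#' constant `tau_f`) and recovery of the resources `x` toward 1 (time
#' constant `tau_d`) over a spike-free interval. This is the inter-event
#' half of the event-driven update: synapse state is stored only at
#' presynaptic spike times and relaxed analytically on demand.
#'
#' @param state list (or data.frame row set) with numeric fields `u`, `x`,
#'   `t_last` (ms); vectors are accepted and relaxed elementwise.
#' @param t_now query time (ms), must be `>= t_last`.
#' @param params an [stp_params()] object.
#' @return list with fields `u` and `x`: the left-side limits u(t_now-),
#'   x(t_now-). Pure function; `state` is not modified.
#' @examples
#' p <- stp_params()
#' stp_decay(list(u = 0.3439, x = 0.6561, t_last = 0), t_now = 1500, p)
#' @export
stp_decay <- function(state, t_now, params) {
  dt <- t_now - state$t_last
  if (any(dt < 0))
    stop("causality error: t_now precedes t_last", call. = FALSE)
  list(u = params$U + (state$u - params$U) * exp(-dt / params$tau_f),
       x = 1 + (state$x - 1) * exp(-dt / params$tau_d))
}

#' Apply the presynaptic-spike jump to the STP variables
#'
#' The spike first facilitates: `u` jumps by `U * (1 - u)` (right-side
#' limit), then a fraction `u_plus` of the available resources `x` is
#' released. Inputs are the left-side limits returned by [stp_decay()].
#'
#' @param u_minus,x_minus left-side limits of `u` and `x` at the spike time.
#' @param params an [stp_params()] object.
#' @return list with fields `u` (u(t+)) and `x` (x(t+)), both in \[0, 1\].
#' @examples
#' stp_spike_update(0.19, 1, stp_params())   # first spike from rest
#' @export
stp_spike_update <- function(u_minus, x_minus, params) {
  u_plus <- u_minus + params$U * (1 - u_minus)
  list(u = u_plus, x = x_minus - u_plus * x_minus)
}

#' Modulated efficacy of a plastic synapse at a presynaptic spike
#'
#' Combines [stp_decay()] and [stp_spike_update()] into the full event
#' update and returns the short-term-plasticity-modulated efficacy used for
#' the postsynaptic current. Two orderings of the `u` modulation are
#' supported: `"post_u"` (the default) modulates with the facilitated value
#' `u(t+) * x(t-)` — the spike's own calcium influx contributes to its
#' release probability — while `"pre_u"` uses `u(t-) * x(t-)`. For
#' identical spike trains `post_u` never yields a smaller efficacy, the
#' difference being largest at low firing rates.
#'
#' @param J_abs absolute (unmodulated) synaptic efficacy, mV.
#' @param state list with `u`, `x`, `t_last` as in [stp_decay()].
#' @param t_spike presynaptic spike time (ms), `>= state$t_last`.
#' @param params an [stp_params()] object.
#' @param variant `"post_u"` or `"pre_u"`.
#' @return list with `J_eff` (modulated efficacy, mV) and `state` (the
#'   post-spike state: fields `u`, `x`, `t_last = t_spike`).
#' @examples
#' s0 <- list(u = 0.19, x = 1, t_last = 0)
#' modulated_efficacy(0.45, s0, 0, stp_params())$J_eff   # 0.45*0.3439
#' @export
modulated_efficacy <- function(J_abs, state, t_spike, params,
                               variant = c("post_u", "pre_u")) {
  variant <- match.arg(variant)
  minus <- stp_decay(state, t_spike, params)
  plus <- stp_spike_update(minus$u, minus$x, params)
  u_mod <- if (variant == "post_u") plus$u else minus$u
  list(J_eff = J_abs * u_mod * minus$x,
       state = list(u = plus$u, x = plus$x, t_last = t_spike))
}

#' Fixed point of the STP map under a periodic spike train
#'
#' One cycle of the event-driven dynamics (decay over one inter-spike
#' interval, then the spike jump) is an affine map in `u` and in `x`
#' separately; its unique fixed point gives the steady-state facilitation
#' and depression under periodic firing at interval `isi`. Iterating the
#' cycle from any admissible start converges to it geometrically with
#' ratios `(1-U) exp(-isi/tau_f)` and `(1-u*) exp(-isi/tau_d)`.
#'
#' @param params an [stp_params()] object.
#' @param isi inter-spike interval (ms), > 0 (may be `Inf`).
#' @return list with `u_plus` (post-spike utilization u*(+)) and `x_minus`
#'   (pre-spike resources x*(-)) at the fixed point, the pair whose product
#'   with `J_abs` is the steady-state released efficacy under `post_u`
#'   modulation.
#' @examples
#' stp_fixed_point(stp_params(), isi = 100)
#' @export
stp_fixed_point <- function(params, isi) {
  if (isi <= 0) stop("isi must be positive", call. = FALSE)
  U <- params$U
  ef <- exp(-isi / params$tau_f)
  ed <- exp(-isi / params$tau_d)
  # u cycle: u+' = f(u+) with f affine: decay then jump
  # u- = U + (u+ - U) ef ; u+' = u- + U (1 - u-)
  # => u+' = (1-U) ef u+ + [U(1-ef)(1-U) + U]
  a_u <- (1 - U) * ef
  b_u <- U * (1 - ef) * (1 - U) + U
  u_plus <- b_u / (1 - a_u)
  u_minus <- U + (u_plus - U) * ef
  # x cycle in terms of x- (pre-spike value), release fraction u_plus:
  # x+ = (1 - u+) x- ; x-' = 1 + (x+ - 1) ed = (1-u+) ed x- + (1 - ed)
  a_x <- (1 - u_plus) * ed
  x_minus <- (1 - ed) / (1 - a_x)
  list(u_plus = u_plus, x_minus = x_minus, u_minus = u_minus)
}
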