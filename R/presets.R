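#' Default configuration bundle
#'
#' The full parameter set of the working-memory network, grouped the way
#' the configuration file is laid out. Every value carries a provenance
#' tag: `"paper"` (stated for this model), `"derived"` (computed from a
#' stated quantity), `"reference"` (adopted from the reference model family
#' this network reproduces) or `"calibrated"` (found by the package's own
#' calibration against the stated regime anchors: 0.7 Hz spontaneous rate;
#' autonomous periodic reactivation; asynchronous elevated activity).
#'
#' The three excitatory background-current levels select the memory
#' regime: `mu_bg_E` (spontaneous / externally-cued, regime A),
#' `mu_bg_E_B` (autonomous synchronous reactivation, regime B) and
#' `mu_bg_E_C` (asynchronous elevated activity, regime C).
#'
#' @return nested named list with components `network`, `neuron_E`,
#'   `neuron_I`, `stp`, `sim`, `background`, `stimulus`, `analysis` and
#'   `provenance`.
#' @export
wm_defaults <- function() {
  list(
    network = list(N_E = 8000, N_I = 2000, n_pops = 5, pop_size = 800,
                   overlap = FALSE, c = 0.2, J_p = 0.305, J_b = 0.10,
                   J_EI = 0.135, J_IE = -0.25, J_II = -0.20,
                   frac_potentiated_background = 0.10,
                   delay_range = c(0.1, 1.0),
                   allow_multapses = TRUE, allow_autapses = TRUE,
                   J_p_overlap_factor = 1.05),
    neuron_E = list(tau_m = 15, R_m = 1, V_th = 20, V_reset = 16, t_ref = 2,
                    tau_exc = 2, tau_inh = 2),
    neuron_I = list(tau_m = 10, R_m = 1, V_th = 20, V_reset = 16, t_ref = 2,
                    tau_exc = 2, tau_inh = 2),
    stp = list(U = 0.19, tau_f = 1500, tau_d = 200),
    sim = list(dt = 0.05, trace_dt = 10, trace_max_connections = 10000),
    background = list(mu_bg_E = 23.0, mu_bg_E_spont = 24.50,
                      mu_bg_E_B = 24.75, mu_bg_E_C = 26.2,
                      sigma_bg_E = 2.0, mu_bg_I = 21.0, sigma_bg_I = 1.0),
    stimulus = list(load_mu = 3.0, load_sigma = 1.0, load_duration = 350,
                    readout_mu = 1.5, readout_sigma = 0.5,
                    readout_duration = 100, readout_period = 300,
                    noise_frac = 0.15),
    analysis = list(ps_bin = 5, ps_threshold_factor = 10,
                    ps_min_separation = 50, ps_abs_floor = 10,
                    min_participation = 0.25, gap_factor = 2),
    provenance = list(
      paper = c("network.N_E", "network.N_I", "network.n_pops",
                "network.pop_size", "network.frac_potentiated_background",
                "network.delay_range", "network.allow_multapses",
                "network.allow_autapses", "neuron_E.tau_exc",
                "neuron_E.tau_inh", "stp.tau_f", "stp.tau_d", "sim.dt",
                "stimulus.load_duration", "stimulus.readout_period",
                "stimulus.noise_frac"),
      derived = c("stp.U"),
      reference = c("network.c", "network.J_b",
                    "network.J_EI", "network.J_IE", "network.J_II",
                    "neuron_E.tau_m", "neuron_I.tau_m", "neuron_E.V_th",
                    "neuron_E.V_reset", "neuron_E.t_ref"),
      calibrated = c("network.J_p", "background.sigma_bg_E",
                     "background.mu_bg_E", "background.mu_bg_E_spont",
                     "background.mu_bg_E_B", "background.mu_bg_E_C",
                     "background.mu_bg_I",
                     "stimulus.load_mu", "stimulus.readout_mu"),
      assumed = c("background.sigma_bg_I",
                  "stimulus.load_sigma", "stimulus.readout_sigma",
                  "network.J_p_overlap_factor",
                  "analysis.ps_threshold_factor",
                  "analysis.ps_min_separation", "analysis.gap_factor")))
}

.cfg_network <- function(cfg) do.call(network_config, cfg$network)
.cfg_neuron_E <- function(cfg) do.call(neuron_params, cfg$neuron_E)
.cfg_neuron_I <- function(cfg) do.call(neuron_params, cfg$neuron_I)
.cfg_stp <- function(cfg) do.call(stp_params, cfg$stp)

#' Background-only protocol at a given excitatory drive
#'
#' @param cfg a configuration bundle ([wm_defaults()] shape).
#' @param T_total duration (ms).
#' @param mu_E excitatory background mean; defaults to the regime-A level.
#' @return a [wm_protocol()] with the two background epochs.
#' @export
background_protocol <- function(cfg, T_total, mu_E = cfg$background$mu_bg_E) {
  wm_protocol(data.frame(
    t_start = c(0, 0), t_end = c(T_total, T_total),
    target = c("exc", "inh"),
    mu = c(mu_E, cfg$background$mu_bg_I),
    sigma = c(cfg$background$sigma_bg_E, cfg$background$sigma_bg_I)))
}

#' Item-loading / memory protocols for the standard experiments
#'
#' Builds the full stimulation timeline for a run in one of the three
#' regimes: the excitatory background sits at the regime's level until
#' `t_release` (when it falls back to the spontaneous regime-A level, the
#' manipulation the raster figures mark) and item-loading epochs of
#' `load_duration` ms target the selected populations in turn.
#'
#' @param cfg configuration bundle.
#' @param regime `"A"`, `"B"` or `"C"`.
#' @param load_times numeric vector of item-loading onsets (ms).
#' @param load_pops population ids loaded at those times (recycled).
#' @param T_total run length (ms).
#' @param t_release time at which the background returns to the regime-A
#'   level (`NULL`: never, background keeps its regime level throughout).
#' @param readout if `TRUE`, adds the periodic nonspecific readout input
#'   (all excitatory neurons) used in the externally-cued regime, starting
#'   `readout_period` ms after the first load.
#' @param noise_epoch optional length-2 numeric: an epoch in which the
#'   item-loading signal is sent to a random `noise_frac` of all excitatory
#'   neurons (robustness probe).
#' @return a [wm_protocol()].
#' @export
memory_protocol <- function(cfg, regime = "B", load_times = 3000,
                            load_pops = seq_along(load_times),
                            T_total = 6000, t_release = NULL,
                            readout = FALSE, noise_epoch = NULL) {
  bg <- cfg$background
  st <- cfg$stimulus
  mu_E <- switch(regime, A = bg$mu_bg_E, B = bg$mu_bg_E_B, C = bg$mu_bg_E_C,
                 stop("regime must be A, B or C", call. = FALSE))
  if (is.null(t_release)) t_release <- T_total
  ep <- data.frame(t_start = 0, t_end = t_release, target = "exc",
                   mu = mu_E, sigma = bg$sigma_bg_E)
  if (t_release < T_total)
    ep <- rbind(ep, data.frame(t_start = t_release, t_end = T_total,
                               target = "exc", mu = bg$mu_bg_E,
                               sigma = bg$sigma_bg_E))
  ep <- rbind(ep, data.frame(t_start = 0, t_end = T_total, target = "inh",
                             mu = bg$mu_bg_I, sigma = bg$sigma_bg_I))
  load_pops <- rep_len(load_pops, length(load_times))
  for (i in seq_along(load_times))
    ep <- rbind(ep, data.frame(t_start = load_times[i],
                               t_end = load_times[i] + st$load_duration,
                               target = paste0("pop:", load_pops[i]),
                               mu = st$load_mu, sigma = st$load_sigma))
  if (readout) {
    starts <- seq(min(load_times) + st$load_duration + st$readout_period,
                  T_total - 1, by = st$readout_period)
    for (s in starts)
      ep <- rbind(ep, data.frame(t_start = s,
                                 t_end = min(s + st$readout_duration, T_total),
                                 target = "exc", mu = st$readout_mu,
                                 sigma = st$readout_sigma))
  }
  if (!is.null(noise_epoch))
    ep <- rbind(ep, data.frame(t_start = noise_epoch[1], t_end = noise_epoch[2],
                               target = paste0("frac:", st$noise_frac),
                               mu = st$load_mu, sigma = st$load_sigma))
  wm_protocol(ep)
}

#' Experiment presets
#'
#' Self-contained, seedable bundles reproducing the standard experiments:
#' \describe{
#'   \item{fig2a}{regime A: one item, memory silent until a single
#'     nonspecific readout pulse.}
#'   \item{fig2b}{regime B: one item, autonomous periodic population
#'     spikes; background released at 5200 ms.}
#'   \item{fig2c}{regime C: one item, asynchronous elevated activity;
#'     background released at 5200 ms.}
#'   \item{fig3a}{regime A: two items, periodic readout, noise probe on
#'     15\% of the excitatory neurons.}
#'   \item{fig3b}{regime B: two items, autonomous alternation, noise
#'     probe.}
#'   \item{fig4}{regime B: three items loaded at 3000/6000/9000 ms.}
#'   \item{fig5}{as fig3b with overlapping selective populations.}
#' }
#'
#' @param name preset name.
#' @param cfg configuration bundle (defaults to [wm_defaults()]).
#' @return list with `name`, `cfg`, `protocol`, `T_total`, `loaded_pops`,
#'   `windows` (list with `spontaneous` and `delay`, ms) and `traced_pops`.
#' @export
wm_preset <- function(name = c("fig2a", "fig2b", "fig2c", "fig3a", "fig3b",
                               "fig4", "fig5"),
                      cfg = wm_defaults()) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset '", name, "'; available: fig2a, ",
                          "fig2b, fig2c, fig3a, fig3b, fig4, fig5",
                          call. = FALSE))
  ld <- cfg$stimulus$load_duration
  out <- switch(name,
    fig2a = {
      T_total <- 7000
      proto <- memory_protocol(cfg, "A", load_times = 3000, load_pops = 1,
                               T_total = T_total)
      proto <- protocol_epoch(proto, 6000, 6000 + cfg$stimulus$readout_duration,
                              "exc", cfg$stimulus$readout_mu,
                              cfg$stimulus$readout_sigma)
      list(protocol = proto, T_total = T_total, loaded_pops = 1L,
           windows = list(spontaneous = c(1000, 3000),
                          delay = c(3000 + ld, 6000)))
    },
    fig2b = list(protocol = memory_protocol(cfg, "B", 3000, 1, 6000,
                                            t_release = 5200),
                 T_total = 6000, loaded_pops = 1L,
                 windows = list(spontaneous = c(1000, 3000),
                                delay = c(3000 + ld, 5200))),
    fig2c = list(protocol = memory_protocol(cfg, "C", 3000, 1, 6000,
                                            t_release = 5200),
                 T_total = 6000, loaded_pops = 1L,
                 windows = list(spontaneous = c(1000, 3000),
                                delay = c(3000 + ld, 5200))),
    fig3a = {
      T_total <- 8000
      proto <- memory_protocol(cfg, "A", c(3000, 4500), 1:2, T_total,
                               readout = TRUE, noise_epoch = c(6000, 6350))
      list(protocol = proto, T_total = T_total, loaded_pops = 1:2,
           windows = list(spontaneous = c(1000, 3000),
                          delay = c(4500 + ld, T_total)))
    },
    fig3b = list(protocol = memory_protocol(cfg, "B", c(3000, 4500), 1:2,
                                            8000, noise_epoch = c(6000, 6350)),
                 T_total = 8000, loaded_pops = 1:2,
                 windows = list(spontaneous = c(1000, 3000),
                                delay = c(4850, 8000))),
    fig4 = list(protocol = memory_protocol(cfg, "B", c(3000, 6000, 9000), 1:3,
                                           13000),
                T_total = 13000, loaded_pops = 1:3,
                windows = list(spontaneous = c(1000, 3000),
                               delay = c(9000 + ld, 13000))),
    fig5 = {
      cfg$network$overlap <- TRUE
      list(protocol = memory_protocol(cfg, "B", c(3000, 4500), 1:2, 8000,
                                      noise_epoch = c(6000, 6350)),
           T_total = 8000, loaded_pops = 1:2,
           windows = list(spontaneous = c(1000, 3000),
                          delay = c(4850, 8000)))
    })
  c(list(name = name, cfg = cfg), out,
    list(traced_pops = out$loaded_pops))
}

#' Scale a network configuration down for fast tests
#'
#' Shrinks the neuron counts while preserving the per-neuron in-degrees
#' (and hence the input statistics each neuron sees), the 4:1 E:I ratio and
#' the population structure. Intended for CI-speed qualitative runs of the
#' engine and analysis chain, not for quantitative reproduction.
#'
#' @param cfg a configuration bundle ([wm_defaults()] shape).
#' @param scale factor in (0, 1].
#' @return the scaled bundle (network section modified; in-degrees pinned
#'   via `K_E`, `K_I`).
#' @export
make_fixture <- function(cfg = wm_defaults(), scale = 0.1) {
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]", call. = FALSE)
  nw <- cfg$network
  K_E <- if (is.null(nw$K_E)) round(nw$c * nw$N_E) else nw$K_E
  K_I <- if (is.null(nw$K_I)) round(nw$c * nw$N_I) else nw$K_I
  nw$N_E <- as.integer(round(nw$N_E * scale))
  nw$N_I <- as.integer(round(nw$N_I * scale))
  nw$pop_size <- as.integer(round(nw$pop_size * scale))
  if (nw$pop_size < 1)
    stop("scale too small: a selective population would be empty",
         call. = FALSE)
  nw$K_E <- as.integer(min(K_E, if (nw$allow_multapses) K_E else nw$N_E))
  nw$K_I <- as.integer(min(K_I, if (nw$allow_multapses) K_I else nw$N_I))
  cfg$network <- nw
  cfg
}

#' Calibrate the excitatory background drive against a target rate
#'
#' Bisection on the mean excitatory background current so that the
#' background-only network fires at the target spontaneous rate. The rate
#' is the mean spike-count rate of all excitatory neurons over the run,
#' discarding a settle-in interval.
#'
#' @param network a [build_network()] result.
#' @param cfg configuration bundle (for the remaining background fields).
#' @param target_rate target mean excitatory rate (Hz).
#' @param bounds length-2 search interval for `mu_bg_E`.
#' @param n_iter bisection iterations.
#' @param T_sim simulated time per evaluation (ms).
#' @param t_settle discarded initial interval (ms).
#' @param seed run seed.
#' @return list with `mu_E` (calibrated level), `rate` (achieved, Hz) and
#'   `trace` (data.frame of the bisection path).
#' @export
calibrate_background <- function(network, cfg = wm_defaults(),
                                 target_rate = 0.7,
                                 bounds = cfg$background$mu_bg_E_spont +
                                   c(-1, 1),
                                 n_iter = 8,
                                 T_sim = 2000, t_settle = 500, seed = 1) {
  nE <- .cfg_neuron_E(cfg); nI <- .cfg_neuron_I(cfg); sp <- .cfg_stp(cfg)
  eval_rate <- function(mu) {
    proto <- background_protocol(cfg, T_sim, mu_E = mu)
    sim <- sim_params(dt = cfg$sim$dt, T_total = T_sim, seed = seed,
                      record_spikes = TRUE)
    r <- run_simulation(network, proto, nE, nI, sp, sim)
    sel <- r$spikes$time >= t_settle & r$spikes$id <= network$cfg$N_E
    sum(sel) / network$cfg$N_E / ((T_sim - t_settle) / 1000)
  }
  lo <- bounds[1]; hi <- bounds[2]
  trace <- data.frame(mu = numeric(0), rate = numeric(0))
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    r <- eval_rate(mid)
    trace <- rbind(trace, data.frame(mu = mid, rate = r))
    if (r > target_rate) hi <- mid else lo <- mid
  }
  mu_final <- (lo + hi) / 2
  list(mu_E = mu_final, rate = eval_rate(mu_final), trace = trace)
}
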