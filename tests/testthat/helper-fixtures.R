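# Shared fixture builders. Everything is generated in code at test time.

# A micro-network with explicit in-degrees, used for engine-level contracts.
micro_network <- function(N_E = 4, N_I = 2, n_pops = 1, pop_size = 2,
                          K_E = 2, K_I = 1, seed = 42, ...) {
  cfg <- network_config(N_E = N_E, N_I = N_I, n_pops = n_pops,
                        pop_size = pop_size, c = 0.5, K_E = K_E, K_I = K_I,
                        ...)
  build_network(cfg, seed = seed)
}

# A scaled-down copy of the full model preserving per-neuron in-degrees.
fixture_network <- function(scale = 0.1, seed = 7, cfg = wm_defaults()) {
  cfg <- make_fixture(cfg, scale)
  list(cfg = cfg, net = build_network(do.call(network_config, cfg$network),
                                      seed = seed))
}

# Silent protocol (no external drive) over T ms.
silent_protocol <- function(T_total) {
  wm_protocol(data.frame(t_start = 0, t_end = T_total, target = "all",
                         mu = 0, sigma = 0))
}

# Event-driven STP reference: iterate the closed-form update along a train.
stp_chain <- function(spike_times, params, variant = "post_u") {
  state <- list(u = params$U, x = 1, t_last = 0)
  J <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    m <- modulated_efficacy(1, state, spike_times[i], params, variant)
    J[i] <- m$J_eff
    state <- m$state
  }
  list(J = J, state = state)
}

# Dense-grid Euler oracle for the continuous STP dynamics: between spikes
# u' = -(u-U)/tau_f, x' = (1-x)/tau_d stepped at `h`; the affine Euler
# recursion is accumulated in closed form (identical to looping, without
# the 1e6-iteration cost), and the spike jumps are applied discretely.
stp_euler_oracle <- function(spike_times, params, h = 1e-3,
                             variant = "post_u") {
  U <- params$U
  u <- U; x <- 1; t_prev <- 0
  J <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    n <- round((spike_times[i] - t_prev) / h)
    au <- (1 - h / params$tau_f)^n
    ax <- (1 - h / params$tau_d)^n
    um <- U + (u - U) * au
    xm <- 1 + (x - 1) * ax
    up <- um + U * (1 - um)
    J[i] <- (if (variant == "post_u") up else um) * xm
    u <- up
    x <- xm - up * xm
    t_prev <- spike_times[i]
  }
  list(J = J, u = u, x = x)
}

# Poisson spike train on [0, T] at `rate` Hz, sorted, distinct grid times.
poisson_train <- function(rate_hz, T_ms) {
  n <- stats::rpois(1, rate_hz * T_ms / 1000)
  sort(stats::runif(n, 0, T_ms))
}

# A raster with synchronized volleys of `pop` at given times over a sparse
# Poisson background, for exercising the population-spike detector.
volley_raster <- function(pop, volley_times, T_ms, bg_rate_hz = 1,
                          participation = 1) {
  n_bg <- stats::rpois(1, bg_rate_hz * length(pop) * T_ms / 1000)
  sp <- data.frame(time = stats::runif(n_bg, 0, T_ms),
                   id = sample(pop, n_bg, replace = TRUE))
  for (tv in volley_times) {
    who <- sample(pop, round(participation * length(pop)))
    sp <- rbind(sp, data.frame(time = tv + stats::runif(length(who), 0, 2),
                               id = who))
  }
  sp[order(sp$time), ]
}
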