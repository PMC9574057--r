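test_that("a silent network stays silent", {
  net <- micro_network(N_E = 10, N_I = 4, K_E = 3, K_I = 2)
  res <- run_simulation(net, silent_protocol(200),
                        sim = sim_params(T_total = 200, seed = 1),
                        V0 = rep(0, 14))
  expect_equal(nrow(res$spikes), 0)
  expect_true(all(res$V_final == 0))
})

test_that("forced two-neuron chain reproduces the closed-form STP cascade", {
  # one excitatory pair inside a minimal selective population
  cfg <- network_config(N_E = 2, N_I = 2, n_pops = 1, pop_size = 2,
                        c = 0.5, K_E = 1, K_I = 1, allow_autapses = FALSE)
  net <- build_network(cfg, seed = 2)
  stp <- stp_params()
  times <- c(10, 60)
  res <- run_simulation(net, silent_protocol(100),
                        sim = sim_params(T_total = 100, seed = 1),
                        forced_spikes = data.frame(time = times, neuron = 1),
                        return_stp_state = TRUE, V0 = rep(0, 4))
  # chain the event update by hand through both spikes
  ref <- stp_chain(times, stp)
  got <- res$stp_state[res$stp_state$src == 1, ][1, ]
  expect_equal(got$u, ref$state$u, tolerance = 1e-12)
  expect_equal(got$x, ref$state$x, tolerance = 1e-12)
  expect_equal(got$t_last, 60)
  # untouched synapses stay at baseline
  rest <- res$stp_state[res$stp_state$src == 2, ]
  if (nrow(rest)) {
    expect_true(all(rest$u == stp$U))
    expect_true(all(rest$x == 1))
  }
})

test_that("second delivery of a facilitating pair is scaled by u_plus * x_minus", {
  cfg <- network_config(N_E = 2, N_I = 2, n_pops = 1, pop_size = 2,
                        c = 0.5, K_E = 1, K_I = 1, allow_autapses = FALSE)
  net <- build_network(cfg, seed = 2)
  np <- neuron_params()
  stp <- stp_params()
  conn <- net$connections
  ee <- which(conn$plastic & conn$src == 1)
  expect_length(ee, 1)
  J_abs <- conn$J[ee]
  for (variant in c("post_u", "pre_u")) {
    res <- run_simulation(net, silent_protocol(120),
                          sim = sim_params(T_total = 120, seed = 1),
                          variant = variant,
                          forced_spikes = data.frame(time = c(10, 60),
                                                     neuron = 1),
                          V0 = rep(0, 4))
    # the target's V peaks at J_eff after each delivery (alpha contract)
    ref <- stp_chain(c(10, 60), stp, variant)
    # measure via a fine single-neuron replay of the two jumps
    a <- alpha_factor(np, np$tau_exc)
    dt <- 0.05
    delay_steps <- ceiling(conn$delay[ee] / dt - 1e-9)
    jumps <- numeric(2400)
    jumps[10 / dt + delay_steps + 1] <- as.numeric(a) * J_abs * ref$J[1] / 2
    jumps[60 / dt + delay_steps + 1] <- as.numeric(a) * J_abs * ref$J[2] / 2
    rep_sim <- simulate_lif(np, dt, 2400, exc_jumps = jumps)
    expect_equal(max(res$V_final[conn$tgt[ee]], 0), max(0, rep_sim$V[2400]),
                 tolerance = 1e-9)
  }
})

test_that("post_u spikes arrive stronger than pre_u on a driven pair", {
  # first spike from rest: post_u releases J * 0.3439, pre_u J * 0.19;
  # J = 70 mV puts the threshold (20 mV) between the two peaks
  cfg <- network_config(N_E = 2, N_I = 2, n_pops = 1, pop_size = 2,
                        c = 0.5, K_E = 1, K_I = 1, J_p = 70,
                        allow_autapses = FALSE)
  net <- build_network(cfg, seed = 2)
  run <- function(variant) {
    res <- run_simulation(net, silent_protocol(50),
                          sim = sim_params(T_total = 50, seed = 1),
                          variant = variant,
                          forced_spikes = data.frame(time = 5, neuron = 1),
                          V0 = rep(0, 4))
    res$spikes[res$spikes$id == 2, "time"]
  }
  expect_gt(length(run("post_u")), 0)  # 70 * 0.3439 = 24 mV > 20
  expect_length(run("pre_u"), 0)       # 70 * 0.19 = 13.3 mV < 20
})

test_that("spikes are delivered after exactly the synaptic delay", {
  cfg <- network_config(N_E = 2, N_I = 2, n_pops = 1, pop_size = 2,
                        c = 0.5, K_E = 1, K_I = 1, J_p = 80,
                        allow_autapses = FALSE)
  net <- build_network(cfg, seed = 2)
  ee <- which(net$connections$plastic & net$connections$src == 1)
  base_delay <- net$connections$delay[ee]
  spike_time_with_delay <- function(d) {
    net$connections$delay[ee] <- d
    res <- run_simulation(net, silent_protocol(30),
                          sim = sim_params(T_total = 30, seed = 1),
                          forced_spikes = data.frame(time = 5, neuron = 1),
                          V0 = rep(0, 4))
    res$spikes[res$spikes$id == 2, "time"][1]
  }
  t1 <- spike_time_with_delay(0.2)
  t2 <- spike_time_with_delay(0.8)
  expect_equal(t2 - t1, 0.6, tolerance = 0.05 + 1e-9)
  expect_gte(t1, 5 + 0.2)
})

test_that("identical seeds give byte-identical rasters, different seeds differ", {
  fx <- fixture_network(scale = 0.05, seed = 9)
  proto <- background_protocol(fx$cfg, 500)
  run <- function(seed) run_simulation(
    fx$net, proto, sim = sim_params(T_total = 500, seed = seed))
  a <- run(4); b <- run(4); c <- run(5)
  expect_identical(a$spikes, b$spikes)
  expect_gt(nrow(a$spikes), 0)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("overlapping constant epochs add their currents", {
  # one isolated neuron (no recurrence): firing follows the summed drive
  cfg <- network_config(N_E = 2, N_I = 1, n_pops = 0, pop_size = 0,
                        c = 0.5, K_E = 1, K_I = 1, J_b = 0, J_EI = 0,
                        J_IE = 0, J_II = 0, frac_potentiated_background = 0)
  net <- build_network(cfg, seed = 3)
  np <- neuron_params()
  proto <- wm_protocol(data.frame(
    t_start = c(0, 0), t_end = c(1000, 1000), target = "exc",
    mu = c(14, 11), sigma = 0))
  res <- run_simulation(net, proto, sim = sim_params(T_total = 1000, seed = 1),
                        V0 = rep(0, 3))
  isi <- diff(res$spikes$time[res$spikes$id == 1])
  theo <- np$t_ref + np$tau_m * log((25 - np$V_reset) / (25 - np$V_th))
  expect_lt(max(abs(isi - theo)), 0.1)
  # neither epoch alone reaches threshold: remove one and the firing stops
  res1 <- run_simulation(net, wm_protocol(data.frame(
    t_start = 0, t_end = 1000, target = "exc", mu = 14, sigma = 0)),
    sim = sim_params(T_total = 1000, seed = 1), V0 = rep(0, 3))
  expect_equal(nrow(res1$spikes), 0)
})

test_that("item-loading epochs reach only the selected population", {
  cfg <- network_config(N_E = 40, N_I = 10, n_pops = 2, pop_size = 10,
                        c = 0.2, K_E = 2, K_I = 1, J_b = 0, J_p = 0,
                        J_EI = 0, J_IE = 0, J_II = 0,
                        frac_potentiated_background = 0)
  net <- build_network(cfg, seed = 4)
  proto <- wm_protocol(data.frame(t_start = 100, t_end = 200,
                                  target = "pop:1", mu = 30, sigma = 0))
  res <- run_simulation(net, proto, sim = sim_params(T_total = 300, seed = 1),
                        V0 = rep(0, 50))
  fired <- unique(res$spikes$id)
  expect_true(all(fired %in% net$popmap$members[[1]]))
  expect_gt(length(fired), 0)
  expect_true(all(res$spikes$time >= 100))
})

test_that("STP traces start at baseline and follow the event state", {
  cfg <- network_config(N_E = 4, N_I = 1, n_pops = 1, pop_size = 4,
                        c = 0.5, K_E = 2, K_I = 1)
  net <- build_network(cfg, seed = 5)
  res <- run_simulation(net, silent_protocol(100),
                        sim = sim_params(T_total = 100, seed = 1, trace_dt = 5,
                                         traced_pops = 1L),
                        forced_spikes = data.frame(time = 20, neuron = 1),
                        return_stp_state = TRUE, V0 = rep(0, 5))
  tr <- res$traces[["1"]]
  expect_equal(tr$mean_u[tr$time <= 20], rep(0.19, sum(tr$time <= 20)))
  expect_equal(tr$mean_x[tr$time <= 20], rep(1, sum(tr$time <= 20)))
  expect_true(all(tr$mean_u >= 0.19 - 1e-12 & tr$mean_u <= 1))
  expect_true(all(tr$mean_x >= 0 & tr$mean_x <= 1 + 1e-12))
  # the queried average equals the analytic decay of the stored state
  last <- tr[nrow(tr), ]
  q <- stp_population_average(res, net$popmap, 1, last$time)
  expect_equal(q$mean_u, last$mean_u, tolerance = 1e-6)
  expect_error(stp_population_average(res, net$popmap, 7, 100), "unknown")
})

test_that("refractory clamp and NaN diagnostics hold inside the engine", {
  # a neuron driven far above threshold fires at the refractory limit
  cfg <- network_config(N_E = 2, N_I = 1, n_pops = 0, pop_size = 0,
                        c = 0.5, K_E = 1, K_I = 1, J_b = 0, J_EI = 0,
                        J_IE = 0, J_II = 0, frac_potentiated_background = 0)
  net <- build_network(cfg, seed = 6)
  proto <- wm_protocol(data.frame(t_start = 0, t_end = 100, target = "exc",
                                  mu = 2000, sigma = 0))
  res <- run_simulation(net, proto, sim = sim_params(T_total = 100, seed = 1),
                        V0 = rep(0, 4))
  isi <- diff(res$spikes$time[res$spikes$id == 1])
  expect_true(all(isi >= 2))          # t_ref = 2 ms
  expect_true(all(isi <= 2 + 0.1))
})
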