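test_that("inter-spike decay follows the closed form and its limits", {
  p <- stp_params(U = 0.19, tau_f = 1500, tau_d = 200)
  s <- list(u = 0.3439, x = 0.6561, t_last = 0)

  same <- stp_decay(s, 0, p)
  expect_equal(same$u, s$u)
  expect_equal(same$x, s$x)

  far <- stp_decay(s, 1e9, p)
  expect_equal(far$u, p$U, tolerance = 1e-12)
  expect_equal(far$x, 1, tolerance = 1e-12)

  # one facilitation time constant after a first spike from rest
  d <- stp_decay(s, 1500, p)
  expect_equal(d$u, 0.19 + 0.1539 * exp(-1), tolerance = 1e-6)
  expect_equal(d$x, 1 - 0.3439 * exp(-7.5), tolerance = 1e-6)
  expect_equal(round(d$u, 5), 0.24662)
  expect_equal(round(d$x, 5), 0.99981)

  expect_error(stp_decay(s, -1, p), "causality")
})

test_that("spike update facilitates then depletes, with saturation", {
  p <- stp_params(U = 0.19)
  r <- stp_spike_update(0.19, 1, p)
  expect_equal(r$u, 0.3439)
  expect_equal(r$x, 0.6561)

  sat <- stp_spike_update(0.5, 0.8, stp_params(U = 1))
  expect_equal(sat$u, 1)

  empty <- stp_spike_update(0.4, 0, p)
  expect_equal(empty$x, 0)
})

test_that("modulated efficacy matches hand substitution for both orderings", {
  p <- stp_params()
  s0 <- list(u = 0.19, x = 1, t_last = 0)
  post <- modulated_efficacy(0.45, s0, 0, p, "post_u")
  expect_equal(post$J_eff, 0.45 * 0.3439, tolerance = 1e-12)
  expect_equal(round(post$J_eff, 5), 0.15476)
  pre <- modulated_efficacy(0.45, s0, 0, p, "pre_u")
  expect_equal(pre$J_eff, 0.45 * 0.19, tolerance = 1e-12)
  # states advance identically; only the released efficacy differs
  expect_equal(post$state, pre$state)
})

test_that("facilitated ordering never releases less than the baseline one", {
  p <- stp_params()
  set.seed(11)
  for (i in 1:200) {
    train <- poisson_train(stats::runif(1, 1, 50), 2000)
    if (length(train) < 2) next
    post <- stp_chain(train, p, "post_u")
    pre <- stp_chain(train, p, "pre_u")
    expect_true(all(post$J >= pre$J - 1e-14))
  }
})

test_that("u and x stay inside their physical bounds on random trains", {
  set.seed(4)
  for (i in 1:50) {
    p <- stp_params(U = stats::runif(1, 0.05, 1), tau_f = stats::runif(1, 100, 3000),
                    tau_d = stats::runif(1, 50, 1000))
    state <- list(u = p$U, x = 1, t_last = 0)
    for (t in poisson_train(20, 1000)) {
      minus <- stp_decay(state, t, p)
      expect_true(minus$u >= p$U - 1e-12 && minus$u <= 1 + 1e-12)
      expect_true(minus$x >= -1e-12 && minus$x <= 1 + 1e-12)
      plus <- stp_spike_update(minus$u, minus$x, p)
      expect_true(plus$u >= p$U - 1e-12 && plus$u <= 1 + 1e-12)
      expect_true(plus$x >= -1e-12 && plus$x <= 1 + 1e-12)
      state <- list(u = plus$u, x = plus$x, t_last = t)
    }
  }
})

test_that("event-driven updates agree with dense Euler integration", {
  p <- stp_params()
  set.seed(21)
  for (i in 1:20) {
    train <- poisson_train(stats::runif(1, 1, 50), 2000)
    if (length(train) < 1) next
    train <- round(train, 3)  # align to the Euler grid
    train <- train[train > 0]
    got <- stp_chain(train, p)
    oracle <- stp_euler_oracle(train, p, h = 1e-3)
    expect_lt(max(abs(got$J - oracle$J)), 1e-5)
  }
  # the accumulated power form equals a literal Euler loop
  u <- 0.5
  for (k in 1:2000) u <- u + 1e-3 * (-(u - p$U) / p$tau_f)
  expect_equal(u, p$U + (0.5 - p$U) * (1 - 1e-3 / p$tau_f)^2000,
               tolerance = 1e-12)
})

test_that("periodic-train fixed point matches brute-force iteration", {
  p <- stp_params()
  for (isi in c(10, 100, 445)) {
    fp <- stp_fixed_point(p, isi)
    u <- 0.9; x <- 0.1  # arbitrary admissible start
    for (k in 1:10000) {
      um <- p$U + (u - p$U) * exp(-isi / p$tau_f)
      xm <- 1 + (x - 1) * exp(-isi / p$tau_d)
      u <- um + p$U * (1 - um)
      x <- xm - u * xm
      if (k == 10000) x_minus_final <- xm
    }
    expect_equal(fp$u_plus, u, tolerance = 1e-12)
    expect_equal(fp$x_minus, x_minus_final, tolerance = 1e-12)
  }

  # infinite recovery between spikes
  fp_inf <- stp_fixed_point(p, Inf)
  expect_equal(fp_inf$u_plus, p$U * (2 - p$U))
  expect_equal(fp_inf$x_minus, 1)
  expect_equal(stp_fixed_point(stp_params(U = 1), 50)$u_plus, 1)
})

test_that("facilitation dominates at 10 Hz for small U", {
  for (U in c(0.1, 0.15, 0.2)) {
    p <- stp_params(U = U, tau_f = 1500, tau_d = 200)
    fp <- stp_fixed_point(p, 100)  # 10 Hz periodic train
    first <- stp_spike_update(p$U, 1, p)
    expect_gt(fp$u_plus * fp$x_minus, first$u * 1 * 0.999)
  }
})

test_that("the efficacy-variant ratio is u_plus/u_minus and at least one", {
  p <- stp_params()
  set.seed(33)
  for (i in 1:20) {
    train <- poisson_train(10, 3000)
    if (length(train) < 2) next
    state <- list(u = p$U, x = 1, t_last = 0)
    for (t in train) {
      minus <- stp_decay(state, t, p)
      plus <- stp_spike_update(minus$u, minus$x, p)
      ratio <- plus$u / minus$u
      expect_gte(ratio, 1)
      state <- list(u = plus$u, x = plus$x, t_last = t)
    }
  }
  # equality holds only at saturation
  sat <- stp_spike_update(1, 0.5, p)
  expect_equal(sat$u / 1, 1)
})

test_that("alpha conversion delivers the advertised peak deflection", {
  np <- neuron_params()
  a <- alpha_factor(np, np$tau_exc)
  expect_equal(attr(a, "t_peak"), 30 / 13 * log(7.5), tolerance = 1e-12)
  expect_equal(round(attr(a, "t_peak"), 3), 4.650)

  for (J in c(0.45, 1)) {
    sim <- simulate_lif(np, dt = 0.001, n_steps = 30000,
                        exc_jumps = c(as.numeric(a) * J / np$tau_exc,
                                      rep(0, 29999)))
    expect_equal(max(sim$V), J, tolerance = 1e-4)
    expect_equal(which.max(sim$V) * 0.001, attr(a, "t_peak"),
                 tolerance = 2e-3)
  }

  # halving the membrane resistance doubles the required current
  half <- alpha_factor(neuron_params(R_m = 0.5), 2)
  expect_equal(as.numeric(half), 2 * as.numeric(a), tolerance = 1e-12)

  # degenerate tau_syn = tau_m limit form peaks at tau_m
  deg <- alpha_factor(neuron_params(tau_m = 2), 2)
  expect_equal(attr(deg, "t_peak"), 2)
  sim <- simulate_lif(neuron_params(tau_m = 2), dt = 0.001, n_steps = 10000,
                      exc_jumps = c(as.numeric(deg) / 2, rep(0, 9999)))
  expect_equal(max(sim$V), 1, tolerance = 1e-3)
})
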