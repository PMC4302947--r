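small_cfg <- function(dt = 1, n_inputs = 20L, n_mcus = 5L)
  hcu_config(n_inputs = n_inputs, n_mcus = n_mcus, dt = dt,
             params = bcpnn_params(dt = dt))

test_that("soft-WTA normalises exactly when the exponential mass exceeds one", {
  o <- soft_wta(rep(2, 100), gamma_m = 1)
  expect_equal(o, rep(1 / 100, 100))
  set.seed(21)
  m <- rnorm(50, 1, 2)
  o2 <- soft_wta(m, gamma_m = 1.5)
  expect_equal(sum(o2), 1, tolerance = 1e-12)
  # below the threshold the activations stay unnormalised
  m_low <- rep(-10, 10)
  expect_equal(soft_wta(m_low, 1), exp(m_low))
})

test_that("MCU rates never exceed the hypercolumn ceiling", {
  cfg <- small_cfg()
  st <- mcu_step(s_syn = rep(0, 5), m = rep(50, 5), weighted_input = rep(0, 5),
                 beta = rep(0, 5), I = rep(0, 5), cfg, rand = rep(0.5, 5))
  expect_true(all(st$r <= cfg$r_max_hcu + 1e-12))
  expect_true(all(st$o >= 0))
  expect_error(mcu_step(rep(0, 3), rep(0, 5), rep(0, 5), rep(0, 5),
                        rep(0, 5), cfg), "length")
  # quiescent fixed point: no input, beta = I = 0, m stays 0
  st0 <- mcu_step(rep(0, 5), rep(0, 5), rep(0, 5), rep(0, 5), rep(0, 5),
                  cfg, rand = rep(1, 5))
  expect_equal(st0$m, rep(0, 5))
  expect_equal(st0$r, rep(soft_wta(rep(0, 5), 1)[1] * cfg$r_max_hcu, 5))
})

test_that("memory footprint matches the array layout", {
  full <- hcu_config()
  expect_gt(memory_footprint(full, 4), 12e6)        # full scale exceeds 12 MB
  expect_equal(memory_footprint(full, 4),
               (1e4 * 100 * 3 + 1e4 * 3 + 100 * 3) * 4)
  one <- hcu_config(n_inputs = 1L, n_mcus = 1L)
  expect_equal(memory_footprint(one, 4), 9 * 4)
  expect_equal(memory_footprint(full, 2), memory_footprint(full, 4) / 2)
})

test_that("silent inputs produce zero synaptic events", {
  cfg <- small_cfg()
  ins <- lapply(1:20, function(u) spike_train(dt = 1, unit_id = u))
  outs <- lapply(1:5, function(u) spike_train(dt = 1, unit_id = u))
  h <- hcu_run(cfg, ins, duration = 0.2, engine = "analytical2",
               clamp_output = outs)
  expect_equal(h$n_syn_events, 0)
})

test_that("synaptic event count equals spikes times the array dimension", {
  cfg <- small_cfg(n_inputs = 50L, n_mcus = 8L)
  ins <- lapply(1:50, function(u) poisson_train(2, 1, seed = 300 + u, unit_id = u))
  outs <- lapply(1:8, function(u) poisson_train(2, 1, seed = 400 + u, unit_id = u))
  h <- hcu_run(cfg, ins, duration = 1, engine = "analytical2",
               clamp_output = outs)
  n_pre <- sum(vapply(ins, length, 1L))
  n_post <- sum(vapply(outs, length, 1L))
  expect_equal(h$n_syn_events, n_pre * 8 + n_post * 50)
})

test_that("a 1x1 array reproduces the single-synapse engine", {
  dt <- 1
  cfg <- hcu_config(n_inputs = 1L, n_mcus = 1L, dt = dt,
                    params = bcpnn_params(dt = dt))
  pre <- poisson_train(8, 5, seed = 501)
  post <- poisson_train(8, 5, seed = 502)
  h <- hcu_run(cfg, list(pre), duration = 5, engine = "analytical2",
               clamp_output = list(post), record_beta = TRUE)
  r <- run_synapse(pre, post, cfg$params, duration = 5, engine = "analytical2")
  # bias at the synapse-run sample times equals the recorded per-step bias
  idx <- r$samples$time_ms / dt
  expect_equal(h$beta[idx, 1], r$samples$beta, tolerance = 1e-9)
  # final weight: both decayed to the end of the run
  fw <- bcpnn_weight(r$final$P_i, r$final$P_j, r$final$P_ij, cfg$params$eps)
  expect_equal(h$weights[1, 1], fw, tolerance = 1e-9)
})

test_that("the Euler hypercolumn converges to the event-driven one at first order", {
  # identical spikes refined onto finer grids: the gap must halve with dt
  ins0 <- lapply(1:10, function(u) poisson_train(20, 0.2, dt = 0.2,
                                                 seed = 600 + u, unit_id = u))
  outs0 <- lapply(1:5, function(u) poisson_train(10, 0.2, dt = 0.2,
                                                 seed = 700 + u, unit_id = u))
  errs <- vapply(c(1L, 2L, 4L), function(mult) {
    dt <- 0.2 / mult
    cfg <- hcu_config(n_inputs = 10L, n_mcus = 5L, dt = dt,
                      params = bcpnn_params(dt = dt))
    ins <- lapply(ins0, function(t) spike_train(t$steps * mult, dt, t$unit_id))
    outs <- lapply(outs0, function(t) spike_train(t$steps * mult, dt, t$unit_id))
    h2 <- hcu_run(cfg, ins, duration = 0.2, engine = "analytical2",
                  clamp_output = outs)
    he <- hcu_run(cfg, ins, duration = 0.2, engine = "euler",
                  clamp_output = outs)
    max(abs(h2$weights - he$weights))
  }, 1.0)
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.15)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.15)
})

test_that("a fine-step Euler hypercolumn matches the event-driven biases", {
  dt <- 1e-3; mult <- 200L
  ins0 <- lapply(1:10, function(u) poisson_train(40, 0.05, dt = 0.2,
                                                 seed = 600 + u, unit_id = u))
  outs0 <- lapply(1:5, function(u) poisson_train(20, 0.05, dt = 0.2,
                                                 seed = 700 + u, unit_id = u))
  cfg <- hcu_config(n_inputs = 10L, n_mcus = 5L, dt = dt,
                    params = bcpnn_params(dt = dt))
  ins <- lapply(ins0, function(t) spike_train(t$steps * mult, dt, t$unit_id))
  outs <- lapply(outs0, function(t) spike_train(t$steps * mult, dt, t$unit_id))
  h2 <- hcu_run(cfg, ins, duration = 0.05, engine = "analytical2",
                clamp_output = outs, record_beta = TRUE)
  he <- hcu_run(cfg, ins, duration = 0.05, engine = "euler",
                clamp_output = outs, record_beta = TRUE)
  expect_lt(max(abs(h2$beta - he$beta)), 1e-4)
  expect_lt(max(abs(h2$weights - he$weights)), 1e-3)
})

test_that("stochastic output spiking is seed-reproducible", {
  cfg <- small_cfg()
  ins <- lapply(1:20, function(u) poisson_train(30, 0.5, seed = 800 + u,
                                                unit_id = u))
  h1 <- hcu_run(cfg, ins, duration = 0.5, engine = "analytical2",
                I = 2, seed = 42)
  h2 <- hcu_run(cfg, ins, duration = 0.5, engine = "analytical2",
                I = 2, seed = 42)
  expect_identical(lapply(h1$output, function(t) t$steps),
                   lapply(h2$output, function(t) t$steps))
})
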