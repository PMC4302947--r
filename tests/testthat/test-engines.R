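p1 <- tab1()
co1 <- derive_coefficients(p1)

test_that("the quiescent state is a fixed point of the Euler scheme", {
  st <- canonical_state()
  for (k in 1:5) st <- euler_step(st, 0, 0, p1)
  expect_equal(unlist(st[1:8]), unlist(canonical_state()[1:8]))
  r <- run_synapse(spike_train(), spike_train(), p1, duration = 0.05,
                   engine = "euler", init = canonical_state())
  expect_equal(unlist(r$final[1:8]), unlist(canonical_state()[1:8]))
})

test_that("compiled Euler equals the single-step R implementation", {
  pre <- poisson_train(30, 0.2, seed = 21)
  post <- poisson_train(30, 0.2, seed = 22)
  r <- run_synapse(pre, post, p1, duration = 0.2, engine = "euler",
                   record = "steps")
  st <- initial_canonical_state(p1)
  n_steps <- nrow(r$samples)
  for (n in seq_len(n_steps))
    st <- euler_step(st, as.integer(n %in% pre$steps),
                     as.integer(n %in% post$steps), p1)
  last <- r$samples[n_steps, ]
  for (v in c("Z_i", "Z_j", "E_ij", "P_i", "P_ij"))
    expect_equal(st[[v]], last[[v]], tolerance = 1e-12)
})

test_that("Euler converges to the exact solution at first order in dt", {
  # single pre spike at 10 ms, free decay; compare P_i at 50 ms
  exact <- decay_canonical_pre(canonical_state(Z_i = 1), 40L, co1)
  errs <- vapply(c(1, 0.5, 0.25, 0.125), function(h) {
    ph <- bcpnn_params(dt = h)
    mult <- as.integer(round(1 / h))
    r <- run_synapse(spike_train(10L * mult, dt = h), spike_train(dt = h),
                     ph, duration = 0.05, engine = "euler", record = "steps",
                     init = canonical_state())
    abs(r$samples$P_i[nrow(r$samples)] - exact$P_i)
  }, 1.0)
  fit <- stats::lm(log(errs) ~ log(c(1, 0.5, 0.25, 0.125)))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("both event-driven engines match a dense-Euler oracle trajectory", {
  pre <- poisson_train(10, 1.5, seed = 31)
  post <- poisson_train(10, 1.5, seed = 32)
  h <- 1e-3
  mult <- as.integer(round(1 / h))
  pf <- bcpnn_params(dt = h)
  n_fine <- as.integer(1.5 * 1000 / h)
  oracle <- dense_euler(pre$steps * mult, post$steps * mult, n_fine, pf)
  for (eng in c("analytical1", "analytical2")) {
    r <- run_synapse(pre, post, p1, duration = 1.5, engine = eng)
    idx <- r$samples$time_ms / h
    for (v in c("P_i", "P_j", "P_ij", "E_ij", "Z_i"))
      expect_rel_equal(r$samples[[v]], oracle[idx, v], 1e-4,
                       scale = max(abs(oracle[, v])))
  }
})

test_that("analytical engines agree at every spike time over many Poisson pairs", {
  set.seed(41)
  worst_w <- 0; worst_b <- 0
  for (k in 1:100) {
    rate <- runif(1, 1, 20)
    pre <- poisson_train(rate, 100, seed = 4000 + k)
    post <- poisson_train(rate, 100, seed = 8000 + k)
    if (!length(pre$steps) || !length(post$steps)) next
    r1 <- run_synapse(pre, post, p1, duration = 100, engine = "analytical1")
    r2 <- run_synapse(pre, post, p1, duration = 100, engine = "analytical2")
    sc_w <- max(abs(r1$samples$w), 1); sc_b <- max(abs(r1$samples$beta), 1)
    worst_w <- max(worst_w, max(abs(r1$samples$w - r2$samples$w)) / sc_w)
    worst_b <- max(worst_b, max(abs(r1$samples$beta - r2$samples$beta)) / sc_b)
  }
  expect_lt(worst_w, 1e-9)
  expect_lt(worst_b, 1e-9)
})

test_that("event-driven state updates equal the number of spikes", {
  pre <- poisson_train(5, 20, seed = 51)
  post <- poisson_train(5, 20, seed = 52)
  n_spk <- length(pre$steps) + length(post$steps)
  for (eng in c("analytical1", "analytical2")) {
    r <- run_synapse(pre, post, p1, duration = 20, engine = eng)
    # coincident pre/post spikes share one event
    n_coinc <- length(intersect(pre$steps, post$steps))
    expect_equal(r$n_events, n_spk - n_coinc)
    expect_equal(r$n_updates, r$n_events)
  }
  # Euler updates every step regardless of activity
  re <- run_synapse(pre, post, p1, duration = 20, engine = "euler")
  expect_equal(re$n_updates, 20000L)
})

test_that("a LUT covering all gaps reproduces the plain run bit for bit", {
  pre <- poisson_train(2, 30, seed = 61)
  post <- poisson_train(2, 30, seed = 62)
  gaps <- diff(sort(unique(c(pre$steps, post$steps))))
  plain <- run_synapse(pre, post, p1, duration = 30, engine = "analytical2")
  lut <- run_synapse(pre, post, p1, duration = 30,
                     engine = engine_config("analytical2", use_lut = TRUE,
                                            lut_size = max(gaps)))
  expect_identical(plain$samples$w, lut$samples$w)
  expect_identical(plain$samples$P_ij, lut$samples$P_ij)
  # short LUT with on-demand fallback beyond L: still identical by design
  lut2 <- run_synapse(pre, post, p1, duration = 30,
                      engine = engine_config("analytical2", use_lut = TRUE,
                                             lut_size = 10L))
  expect_identical(plain$samples$w, lut2$samples$w)
})

test_that("a zero learning rate freezes P, w and beta in all engines", {
  p0 <- bcpnn_params(kappa = 0)
  pre <- poisson_train(8, 5, seed = 71)
  post <- poisson_train(8, 5, seed = 72)
  for (eng in c("euler", "analytical1", "analytical2")) {
    r <- run_synapse(pre, post, p0, duration = 5, engine = eng)
    expect_equal(r$samples$P_i, rep(p0$eps, nrow(r$samples)), tolerance = 1e-12)
    expect_equal(r$samples$P_ij, rep(p0$eps^2, nrow(r$samples)), tolerance = 1e-12)
    expect_lt(diff(range(r$samples$w)), 1e-12)
    expect_lt(diff(range(r$samples$beta)), 1e-12)
    # the Z traces still move
    expect_gt(diff(range(r$samples$Z_i)), 0.01)
  }
})

test_that("P_ij stays zero until pre/post activity has overlapped", {
  pre <- spike_train(c(10L, 25L))
  post <- spike_train(15L)
  r <- run_synapse(pre, post, p1, duration = 0.05, engine = "analytical1",
                   init = canonical_state())
  # E_ij is sourced only by the Z_i * Z_j overlap, which starts at the
  # post spike; P_ij becomes positive at the following event
  expect_equal(r$samples$P_ij[r$samples$time_ms == 10], 0)
  expect_equal(r$samples$P_ij[r$samples$time_ms == 15], 0)
  expect_gt(r$samples$P_ij[r$samples$time_ms == 25], 0)
})

test_that("the R per-event functions reproduce the compiled engines", {
  pre <- poisson_train(6, 4, seed = 81)
  post <- poisson_train(6, 4, seed = 82)
  r1 <- run_synapse(pre, post, p1, duration = 4, engine = "analytical1")
  r2 <- run_synapse(pre, post, p1, duration = 4, engine = "analytical2")
  cs <- initial_canonical_state(p1)
  es <- canonical_to_exp(cs, co1)
  events <- sort(unique(c(pre$steps, post$steps)))
  for (k in seq_along(events)) {
    n <- events[k]
    si <- as.integer(n %in% pre$steps); sj <- as.integer(n %in% post$steps)
    cs <- analytical1_process_event(cs, n, si, sj, co1)$state
    out2 <- analytical2_process_event(es, n, si, sj, co1)
    es <- out2$state
    expect_equal(cs$P_ij, r1$samples$P_ij[k], tolerance = 1e-12)
    if (sj > 0)
      expect_equal(out2$output$beta, r2$samples$beta[k], tolerance = 1e-12)
    if (si > 0)
      expect_equal(out2$output$w, r2$samples$w[k], tolerance = 1e-10)
  }
  expect_error(analytical1_process_event(cs, events[1], 1, 0, co1),
               "out-of-order")
})

test_that("run plumbing validates inputs and handles empty runs", {
  expect_equal(nrow(run_synapse(spike_train(), spike_train(), p1,
                                duration = 0)$samples), 0)
  expect_error(run_synapse(spike_train(5000L), spike_train(), p1,
                           duration = 1), "beyond")
  expect_error(run_synapse(spike_train(1L, dt = 0.1), spike_train(), p1,
                           duration = 1), "grid")
  r <- run_synapse(poisson_train(50, 0.5, seed = 1), spike_train(), p1,
                   duration = 0.5)
  # weight is defined at presynaptic spikes, bias available at every sample
  expect_true(all(is.finite(r$samples$w)))
  expect_true(all(is.finite(r$samples$beta)))
})

test_that("stationary Poisson drive gives mean P close to rate * tau_z", {
  pre <- poisson_train(5, 400, seed = 91)
  post <- poisson_train(5, 400, seed = 92)
  r <- run_synapse(pre, post, p1, duration = 400, engine = "analytical2")
  # discard the initial transient (~3 tau_p*)
  s <- r$samples[r$samples$time_ms > 5000, ]
  expect_equal(mean(s$P_i), 5 * p1$tau_zi / 1000, tolerance = 0.15)
  expect_equal(mean(s$P_j), 5 * p1$tau_zj / 1000, tolerance = 0.15)
})
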