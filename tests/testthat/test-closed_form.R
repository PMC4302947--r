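co1 <- derive_coefficients(tab1())

test_that("canonical decay reproduces the single-spike kernels and the dense oracle", {
  st <- canonical_state(Z_i = 1)
  expect_identical(decay_canonical_pre(st, 0L, co1), st)
  expect_error(decay_canonical_pre(st, -1L, co1), "backward")
  # from (Z=1, E=0, P=0) the decay equals the spike-response kernels
  for (dt_ms in c(1, 10, 37)) {
    r <- decay_canonical_pre(st, as.integer(dt_ms), co1)
    expect_equal(r$Z_i, kernel_value("zeta", dt_ms, co1), tolerance = 1e-12)
    expect_equal(r$E_i, kernel_value("alpha", dt_ms, co1), tolerance = 1e-12)
    expect_equal(r$P_i, kernel_value("pi", dt_ms, co1), tolerance = 1e-12)
  }
  # hand-checked values at 10 ms
  r10 <- decay_canonical_pre(st, 10L, co1)
  expect_equal(r10$Z_i, 0.3679, tolerance = 1e-4)
  expect_equal(r10$E_i, 0.2387, tolerance = 1e-3)
  expect_equal(r10$P_i, 0.001541, tolerance = 1e-3)
  # dense-Euler oracle at h = 1e-4 ms
  o <- oracle_decay(st, 10, tab1())
  expect_equal(r10$Z_i, o[["Z_i"]], tolerance = 1e-5)
  expect_equal(r10$E_i, o[["E_i"]], tolerance = 1e-4)
  expect_equal(r10$P_i, o[["P_i"]], tolerance = 1e-3)
})

test_that("synaptic decay matches kernels and the dense oracle on random states", {
  st <- canonical_state(Z_i = 1, Z_j = 1)
  expect_identical(decay_canonical_syn(st, 0L, co1), st)
  r <- decay_canonical_syn(st, 25L, co1)
  expect_equal(r$E_ij, kernel_value("alpha_ij", 25, co1), tolerance = 1e-12)
  expect_equal(r$P_ij, kernel_value("pi_ij", 25, co1), tolerance = 1e-12)

  set.seed(11)
  for (k in 1:5) {
    st <- random_canonical()
    full <- decay_canonical(st, 37L, co1)
    o <- oracle_decay(st, 37, tab1())
    for (v in c("E_ij", "P_ij", "Z_i", "E_i", "P_i"))
      expect_rel_equal(full[[v]], o[[v]], 1e-3)
  }
})

test_that("exact closed forms agree with a fine-step Euler oracle to first order", {
  # halving the oracle step halves its deviation from the closed form
  st <- canonical_state(Z_i = 1, Z_j = 0.5, E_ij = 0.2, P_ij = 0.01)
  exact <- decay_canonical(st, 20L, co1)$P_ij
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(h)
    abs(oracle_decay(st, 20, tab1(), h = h)[["P_ij"]] - exact), 1.0)
  expect_true(all(diff(errs) < 0))
  ratio <- errs[1] / errs[3]
  expect_gt(ratio, 3); expect_lt(ratio, 5)  # ~4 for first order
})

test_that("exponential state decay is elementwise with the right constants", {
  es <- exp_state(Zs_i = 1, Zs_j = 1, Es_i = 1, Es_j = 1, Ps_i = 1,
                  Ps_j = 1, Es_ij = 1, Ps_ij = 1)
  expect_identical(decay_exp(es, 0L, co1), es)
  expect_error(decay_exp(es, -2L, co1), "backward")
  r <- decay_exp(es, 10L, co1)
  expect_equal(r$Zs_i, exp(-1), tolerance = 1e-15)
  expect_equal(r$Zs_j, exp(-10 / 15), tolerance = 1e-15)
  expect_equal(r$Es_ij, exp(-0.5), tolerance = 1e-15)
  expect_equal(r$Ps_ij, exp(-0.01), tolerance = 1e-15)
  # semigroup property: decay(a+b) == decay(a) then decay(b)
  set.seed(2)
  es2 <- exp_state(Zs_i = runif(1), Zs_j = runif(1), Es_i = runif(1),
                   Es_j = runif(1), Ps_i = runif(1), Ps_j = runif(1),
                   Es_ij = runif(1), Ps_ij = runif(1))
  once <- decay_exp(es2, 13L, co1)
  twice <- decay_exp(decay_exp(es2, 5L, co1), 8L, co1)
  expect_equal(once, twice, tolerance = 1e-14)
})

test_that("spike application increments the exponential variables correctly", {
  es <- exp_state()
  r <- apply_pre_spike(es, Z_other = 0)
  expect_equal(unlist(r[c("Zs_i", "Es_i", "Ps_i")]), c(Zs_i = 1, Es_i = 1, Ps_i = 1))
  expect_equal(r$Es_ij, 0); expect_equal(r$Ps_ij, 0)
  r2 <- apply_pre_spike(es, Z_other = 0.5)
  expect_equal(r2$Es_ij, 0.5); expect_equal(r2$Ps_ij, 0.5)
  # one spike per side per step is enforced at the train level
  expect_error(spike_train(c(5L, 5L)), "strictly increasing")
})

test_that("synchronous and consecutive coincidence increments are identical", {
  expect_equal(coincident_increment(0.5, 0.2, 1, 1), 1.7)
  expect_equal(coincident_increment(0.5, 0.2, 1, 0), 0.2)
  expect_equal(coincident_increment(0.5, 0.2, 0, 1), 0.5)
  expect_equal(coincident_increment(0.5, 0.2, 0, 0), 0)
  expect_error(coincident_increment(0.5, 0.2, 2, 0), "0 or 1")
  set.seed(3)
  for (k in 1:20) {
    zi <- runif(1, 0, 3); zj <- runif(1, 0, 3)
    si <- rbinom(1, 1, 0.5); sj <- rbinom(1, 1, 0.5)
    sync <- si * zj + sj * zi + si * sj                 # synchronous form
    consec <- si * zj + sj * (zi + si)                  # pre first, then post
    expect_equal(coincident_increment(zi, zj, si, sj), sync, tolerance = 1e-15)
    expect_equal(sync, consec, tolerance = 1e-15)
  }
})

test_that("representation transforms are exact inverses", {
  expect_equal(exp_to_canonical(exp_state(), co1), canonical_state())
  # immediately after one isolated pre spike the E and P kernels vanish
  es <- apply_pre_spike(exp_state(), Z_other = 0)
  cs <- exp_to_canonical(es, co1)
  expect_equal(cs$Z_i, 1); expect_equal(cs$E_i, 0, tolerance = 1e-15)
  expect_equal(cs$P_i, 0, tolerance = 1e-15)
  # direct nested-coefficient evaluation vs the lambda form
  set.seed(4)
  for (k in 1:20) {
    es <- exp_state(Zs_i = runif(1, 0, 3), Zs_j = runif(1, 0, 3),
                    Es_i = runif(1, 0, 3), Es_j = runif(1, 0, 3),
                    Ps_i = runif(1, 0, 3), Ps_j = runif(1, 0, 3),
                    Es_ij = runif(1, 0, 3), Ps_ij = runif(1, 0, 3))
    cs <- exp_to_canonical(es, co1)
    direct <- co1$ai * (co1$bi * (es$Zs_i - es$Ps_i) +
                          co1$c * (es$Ps_i - es$Es_i))
    expect_rel_equal(cs$P_i, direct, 1e-12)
    direct_ij <- co1$aij * (co1$bij * (es$Zs_i * es$Zs_j - es$Ps_ij) +
                              co1$c * (es$Ps_ij - es$Es_ij))
    expect_rel_equal(cs$P_ij, direct_ij, 1e-12)
  }
  # round trip on many random canonical states
  set.seed(5)
  worst <- 0
  for (k in 1:1000) {
    st <- random_canonical()
    back <- exp_to_canonical(canonical_to_exp(st, co1), co1)
    for (v in c("Z_i", "Z_j", "E_i", "E_j", "E_ij", "P_i", "P_j", "P_ij"))
      worst <- max(worst, abs(back[[v]] - st[[v]]) / max(abs(st[[v]]), 1e-12))
  }
  expect_lt(worst, 1e-9)
})

test_that("a state built from spike history transforms onto the directly simulated one", {
  set.seed(6)
  pre <- sort(sample(1:300, 12)); post <- sort(sample(1:300, 12))
  events <- sort(unique(c(pre, post)))
  cs <- canonical_state(); es <- exp_state()
  for (n in events) {
    si <- as.integer(n %in% pre); sj <- as.integer(n %in% post)
    cs <- analytical1_process_event(cs, n, si, sj, co1)$state
    es <- analytical2_process_event(es, n, si, sj, co1)$state
  }
  from_cs <- canonical_to_exp(cs, co1)
  for (v in c("Zs_i", "Zs_j", "Es_i", "Es_j", "Ps_i", "Ps_j", "Es_ij", "Ps_ij"))
    expect_rel_equal(from_cs[[v]], es[[v]], 1e-9)
})

test_that("kernels are Heaviside-gated with unit DC gain through the cascade", {
  expect_equal(kernel_value("pi", -5, co1), 0)
  expect_equal(kernel_value("alpha_ij", -0.001, co1), 0)
  expect_equal(kernel_value("zeta", 0, co1), 1)
  expect_equal(kernel_value("alpha", 0, co1), 0)
  expect_equal(kernel_value("pi", 0, co1), 0, tolerance = 1e-15)
  # integral of the P kernel equals tau_z (unit DC gain of both filters)
  q <- stats::integrate(function(t) kernel_value("pi", t, co1), 0, Inf,
                        rel.tol = 1e-10)
  expect_equal(q$value, co1$tau_zi, tolerance = 1e-6)
  qj <- stats::integrate(function(t) kernel_value("pi", t, co1, side = "post"),
                         0, Inf, rel.tol = 1e-10)
  expect_equal(qj$value, co1$tau_zj, tolerance = 1e-6)
})

test_that("sequential closed-form updates equal the kernel superposition", {
  set.seed(7)
  for (rep in 1:4) {
    pre <- sort(sample(1:400, sample(3:10, 1)))
    post <- sort(sample(1:400, sample(3:10, 1)))
    events <- sort(unique(c(pre, post)))
    cs <- canonical_state()   # zero initial state, as the superposition assumes
    for (n in events) {
      cs <- analytical1_process_event(cs, n, as.integer(n %in% pre),
                                      as.integer(n %in% post), co1)$state
    }
    t_end <- max(events)
    srm <- srm_traces(t_end, pre, post, co1)
    for (v in names(srm))
      expect_rel_equal(cs[[v]], srm[[v]], 1e-9, scale = max(abs(srm[[v]]), 1e-9))
  }
})

test_that("decay-only evolution never increases the exponential state variables", {
  set.seed(8)
  st <- random_canonical()
  es <- canonical_to_exp(st, co1)
  vars <- c("Zs_i", "Zs_j", "Es_i", "Es_j", "Ps_i", "Ps_j", "Es_ij", "Ps_ij")
  prev <- es
  for (d in c(1L, 2L, 5L, 10L, 50L)) {
    cur <- decay_exp(prev, d, co1)
    for (v in vars) expect_lte(abs(cur[[v]]), abs(prev[[v]]) + 1e-15)
    prev <- cur
  }
  # canonical Z traces share that property (pure decay between spikes)
  dec <- decay_canonical(st, 25L, co1)
  expect_lte(dec$Z_i, st$Z_i)
  expect_lte(dec$Z_j, st$Z_j)
})
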