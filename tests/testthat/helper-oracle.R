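# Test helpers: an independent dense-Euler oracle for the trace cascade
# (vectorised first-order recursions via stats::filter, a different code
# path from the package engines), spike-time bookkeeping, and shared
# fixtures.

tab1 <- function(dt = 1) bcpnn_params(dt = dt)

# explicit Euler on the canonical cascade, vectorised: returns a matrix of
# all eight traces after each step (step h = params$dt)
dense_euler <- function(pre_steps, post_steps, n_steps, params, init = NULL) {
  h <- params$dt
  if (is.null(init)) init <- initial_canonical_state(params)
  Si <- numeric(n_steps); Si[pre_steps] <- 1
  Sj <- numeric(n_steps); Sj[post_steps] <- 1
  lag1 <- function(x, x0) c(x0, x[-length(x)])
  rec <- function(x, a, y0) as.numeric(stats::filter(x, a, "recursive", init = y0))
  Zi <- rec(Si, 1 - h / params$tau_zi, init$Z_i)
  Zj <- rec(Sj, 1 - h / params$tau_zj, init$Z_j)
  ke <- h / params$tau_e
  kp <- h * params$kappa / params$tau_p
  Ei <- rec(ke * lag1(Zi, init$Z_i), 1 - ke, init$E_i)
  Ej <- rec(ke * lag1(Zj, init$Z_j), 1 - ke, init$E_j)
  Eij <- rec(ke * lag1(Zi, init$Z_i) * lag1(Zj, init$Z_j), 1 - ke, init$E_ij)
  Pi <- rec(kp * lag1(Ei, init$E_i), 1 - kp, init$P_i)
  Pj <- rec(kp * lag1(Ej, init$E_j), 1 - kp, init$P_j)
  Pij <- rec(kp * lag1(Eij, init$E_ij), 1 - kp, init$P_ij)
  cbind(Z_i = Zi, Z_j = Zj, E_i = Ei, E_j = Ej, E_ij = Eij,
        P_i = Pi, P_j = Pj, P_ij = Pij)
}

# oracle decay of a single state over dt_ms with no spikes, on a fine grid
oracle_decay <- function(state, dt_ms, params, h = 1e-4) {
  pf <- params; pf$dt <- h
  n <- as.integer(round(dt_ms / h))
  tr <- dense_euler(integer(), integer(), n, pf, init = state)
  tr[n, ]
}

# random canonical state with traces on realistic scales
random_canonical <- function() {
  canonical_state(Z_i = runif(1, 0, 2), Z_j = runif(1, 0, 2),
                  E_i = runif(1, 0, 1), E_j = runif(1, 0, 1),
                  E_ij = runif(1, 0, 1), P_i = runif(1, 0, 0.2),
                  P_j = runif(1, 0, 0.2), P_ij = runif(1, 0, 0.1))
}

expect_rel_equal <- function(x, y, tol, scale = NULL) {
  s <- if (is.null(scale)) pmax(abs(x), abs(y), 1e-12) else scale
  expect_lt(max(abs(x - y) / s), tol)
}

# kernel-superposition evaluation of all traces at time t (ms) for given
# spike times (ms): the spike-response-model route (independent of the
# sequential closed-form updates)
srm_traces <- function(t, pre_ms, post_ms, co) {
  pre_ms <- pre_ms[pre_ms <= t]; post_ms <- post_ms[post_ms <= t]
  zi <- function(tt) sum(kernel_value("zeta", tt - pre_ms, co, side = "pre"))
  zj <- function(tt) sum(kernel_value("zeta", tt - post_ms, co, side = "post"))
  # Z sampled after the spikes at each spike time (consecutive, pre first)
  Zj_at_pre <- vapply(pre_ms, function(tf)
    sum(kernel_value("zeta", tf - post_ms[post_ms < tf], co, side = "post")),
    1.0)
  Zi_at_post <- vapply(post_ms, function(tf)
    sum(kernel_value("zeta", tf - pre_ms[pre_ms <= tf], co, side = "pre")),
    1.0)
  list(
    Z_i = zi(t), Z_j = zj(t),
    E_i = sum(kernel_value("alpha", t - pre_ms, co, side = "pre")),
    E_j = sum(kernel_value("alpha", t - post_ms, co, side = "post")),
    P_i = sum(kernel_value("pi", t - pre_ms, co, side = "pre")),
    P_j = sum(kernel_value("pi", t - post_ms, co, side = "post")),
    E_ij = sum(Zj_at_pre * kernel_value("alpha_ij", t - pre_ms, co)) +
      sum(Zi_at_post * kernel_value("alpha_ij", t - post_ms, co)),
    P_ij = sum(Zj_at_pre * kernel_value("pi_ij", t - pre_ms, co)) +
      sum(Zi_at_post * kernel_value("pi_ij", t - post_ms, co))
  )
}
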