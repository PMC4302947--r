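# Reduced cortical hypercolumn model: M stochastic minicolumn units (MCUs)
# competing through soft winner-take-all normalisation, fed by an array of
# plastic BCPNN synapses (n_inputs x M). The synapse array is updated by
# the configured plasticity engine (event-driven by default); the MCU
# dynamics run clock-driven on the dt grid, with the bias available at
# every step.

#' Hypercolumn configuration
#'
#' @param n_inputs Number of presynaptic input units (full-scale: 10000).
#' @param n_mcus Number of minicolumn units `M` (full-scale: 100).
#' @param tau_m Membrane time constant of the MCU leaky integrators (ms).
#' @param gamma_m Soft-WTA gain on the membrane potentials.
#' @param r_max_hcu Maximum firing rate per HCU (Hz); an MCU's rate is its
#'   activation times this ceiling.
#' @param dt Grid step (ms).
#' @param params Synapse [bcpnn_params()] (its `dt` must match).
#' @return An object of class `hcu_config`.
#' @export
hcu_config <- function(n_inputs = 10000L, n_mcus = 100L, tau_m = 10,
                       gamma_m = 1, r_max_hcu = 100, dt = 1,
                       params = bcpnn_params(dt = dt)) {
  if (n_inputs < 1L || n_mcus < 1L) stop("array sizes must be >= 1")
  if (tau_m <= 0 || r_max_hcu <= 0 || dt <= 0)
    stop("tau_m, r_max_hcu and dt must be > 0")
  if (abs(params$dt - dt) > 1e-12) stop("params$dt must equal the HCU dt")
  structure(list(n_inputs = as.integer(n_inputs), n_mcus = as.integer(n_mcus),
                 tau_m = tau_m, gamma_m = gamma_m, r_max_hcu = r_max_hcu,
                 dt = dt, params = params),
            class = "hcu_config")
}

#' Soft winner-take-all activation
#'
#' Maps membrane potentials to activations: `o_j = exp(gamma_m * m_j)`,
#' normalised by the sum whenever the sum exceeds 1 (so activations then
#' sum to exactly 1 and on average at most one MCU is active); left
#' unnormalised otherwise.
#'
#' @param m Membrane potentials (vector over MCUs).
#' @param gamma_m Soft-WTA gain.
#' @return Activation vector `o`.
#' @export
soft_wta <- function(m, gamma_m) {
  e <- exp(gamma_m * m)
  s <- sum(e)
  if (s > 1) e / s else e
}

#' One clock step of the minicolumn units
#'
#' Advances all M MCUs by one grid step: the synaptic current decays with
#' `tau_zi` and jumps by the summed weights of arriving presynaptic spikes;
#' the support is bias + synaptic current + external input; the membrane
#' potential follows the support by explicit Euler with `tau_m`; the
#' activation is the soft-WTA of the potentials; the firing rate is
#' `o * r_max_hcu`; a spike is emitted when a uniform draw falls below
#' `min(rate * dt, 1)`.
#'
#' @param s_syn Synaptic current vector (length M).
#' @param m Membrane potential vector (length M).
#' @param weighted_input Summed synaptic weight of this step's presynaptic
#'   spikes, per MCU (length M).
#' @param beta Bias vector (length M).
#' @param I External input vector (length M).
#' @param cfg An [hcu_config()].
#' @param rand Optional uniform draws (length M), for deterministic tests.
#' @return A list with updated `s_syn`, `m`, plus `o`, `r` (Hz) and logical
#'   `spikes`.
#' @export
mcu_step <- function(s_syn, m, weighted_input, beta, I, cfg, rand = NULL) {
  M <- cfg$n_mcus
  stopifnot(length(s_syn) == M, length(m) == M, length(weighted_input) == M,
            length(beta) == M, length(I) == M)
  s_syn <- s_syn * exp(-cfg$dt / cfg$params$tau_zi) + weighted_input
  s <- beta + s_syn + I
  m <- m + cfg$dt / cfg$tau_m * (s - m)
  o <- soft_wta(m, cfg$gamma_m)
  r <- o * cfg$r_max_hcu
  p <- pmin(r * cfg$dt / 1000, 1)
  if (is.null(rand)) rand <- stats::runif(M)
  list(s_syn = s_syn, m = m, o = o, r = r, spikes = rand < p)
}

#' Memory footprint of a hypercolumn's BCPNN state
#'
#' Storage for the synaptic array (`E_ij`, `P_ij`, `w_ij` per synapse) plus
#' the marginal traces (`Z`, `E`, `P` per input and per MCU).
#'
#' @param cfg An [hcu_config()].
#' @param bytes_per_variable Bytes per stored variable (4 for single
#'   precision floats).
#' @return Total bytes.
#' @examples
#' memory_footprint(hcu_config()) / 1e6  # > 12 MB at full scale
#' @export
memory_footprint <- function(cfg, bytes_per_variable = 4) {
  n_syn <- as.numeric(cfg$n_inputs) * cfg$n_mcus
  (n_syn * 3 + cfg$n_inputs * 3 + cfg$n_mcus * 3) * bytes_per_variable
}

#' Simulate a hypercolumn unit
#'
#' Drives the synapse array with the given input spike trains and advances
#' the MCU dynamics every step. The plastic weights are applied to the
#' synaptic currents at presynaptic spike arrival (using the value after
#' that spike's plasticity update) and the biases are refreshed every step
#' from the postsynaptic `P` traces.
#'
#' The synapse array is simulated with the reduced-operation event-driven
#' scheme (`engine = "analytical2"`, margins and array updated only at
#' spikes) or with the clock-driven Euler scheme (`engine = "euler"`).
#' Postsynaptic spikes are the MCUs' own stochastic output unless
#' `clamp_output` provides fixed output trains (then the MCU dynamics are
#' still computed but their stochastic spikes are ignored, which makes runs
#' deterministic and engine comparisons exact — the setup used by the
#' synapse-array benchmarks).
#'
#' @param cfg An [hcu_config()].
#' @param input_trains List of `n_inputs` [spike_train()]s.
#' @param duration Duration (s).
#' @param engine `"analytical2"` or `"euler"`.
#' @param I External input: vector of length `n_mcus` (constant) or
#'   function(step) returning one.
#' @param clamp_output Optional list of `n_mcus` [spike_train()]s used as
#'   the postsynaptic spikes.
#' @param record_beta Record the bias matrix (steps x M)?
#' @param seed Optional seed for the stochastic MCU spiking.
#' @return A list with `output` (list of [spike_train()]s), `beta`
#'   (matrix or NULL), `weights` (final n_inputs x M weight matrix),
#'   `traces` (final marginal/synaptic `P` traces), `n_syn_events`
#'   (synaptic event updates processed) and `n_steps`.
#' @export
hcu_run <- function(cfg, input_trains, duration, engine = c("analytical2", "euler"),
                    I = 0, clamp_output = NULL, record_beta = FALSE,
                    seed = NULL) {
  engine <- match.arg(engine)
  if (length(input_trains) != cfg$n_inputs)
    stop("need one input train per input unit")
  n_steps <- as.integer(round(duration * 1000 / cfg$dt))
  p <- cfg$params
  co <- engine_coefficients(p)
  M <- cfg$n_mcus; Ni <- cfg$n_inputs
  I_fun <- if (is.function(I)) I else function(step) rep_len(I, M)

  # spike rasters as step lists
  pre_at <- vector("list", n_steps)
  for (u in seq_len(Ni)) for (s in input_trains[[u]]$steps)
    if (s <= n_steps) pre_at[[s]] <- c(pre_at[[s]], u)
  clamp_at <- NULL
  if (!is.null(clamp_output)) {
    if (length(clamp_output) != M) stop("need one clamp train per MCU")
    clamp_at <- vector("list", n_steps)
    for (u in seq_len(M)) for (s in clamp_output[[u]]$steps)
      if (s <= n_steps) clamp_at[[s]] <- c(clamp_at[[s]], u)
  }

  # margins: exponential state variables per input (rows) and per MCU
  marg_pre <- matrix(0, Ni, 3)   # Zs, Es, Ps with tau_zi, tau_e, tau_p*
  marg_post <- matrix(0, M, 3)
  # initial P = eps on the margins, P_ij = eps^2 in the array
  marg_pre[, 3] <- p$eps / co$lam_pi
  marg_post[, 3] <- p$eps / co$lam_pj
  Es_ij <- matrix(0, Ni, M)
  Ps_ij <- matrix(p$eps^2 / co$lam_pij, Ni, M)
  t_last_pre <- integer(Ni)           # margins' last update step
  t_last_post <- integer(M)
  t_last_syn <- matrix(0L, Ni, M)     # per-synapse last update step

  # Euler state (canonical), used when engine == "euler"
  if (engine == "euler") {
    Zi <- numeric(Ni); Ei <- numeric(Ni); Pi <- rep(p$eps, Ni)
    Zj <- numeric(M); Ej <- numeric(M); Pj <- rep(p$eps, M)
    Eij <- matrix(0, Ni, M); Pij <- matrix(p$eps^2, Ni, M)
  }

  s_syn <- numeric(M); m <- numeric(M)
  out_steps <- vector("list", M)
  beta_rec <- if (record_beta) matrix(NA_real_, n_steps, M) else NULL
  n_syn_events <- 0

  dec <- function(mat, taus, dn) {    # decay margin matrix columns
    mat[, 1] <- mat[, 1] * exp(-dn * cfg$dt / taus[1])
    mat[, 2] <- mat[, 2] * exp(-dn * cfg$dt / taus[2])
    mat[, 3] <- mat[, 3] * exp(-dn * cfg$dt / taus[3])
    mat
  }

  run_with_seed <- function(expr) with_local_seed(seed, expr)
  run_with_seed({
    kz_i <- 1 - cfg$dt / p$tau_zi; kz_j <- 1 - cfg$dt / p$tau_zj
    ke <- cfg$dt / p$tau_e; kp <- cfg$dt * p$kappa / p$tau_p
    fzi1 <- exp(-cfg$dt / co$tau_zi); fzj1 <- exp(-cfg$dt / co$tau_zj)
    fe1 <- exp(-cfg$dt / co$tau_e); fp1 <- exp(-cfg$dt / co$tau_p_star)

    for (n in seq_len(n_steps)) {
      pre_ids <- pre_at[[n]]

      if (engine == "euler") {
        Zi0 <- Zi; Zj0 <- Zj; Ei0 <- Ei; Ej0 <- Ej; Eij0 <- Eij
        Si <- numeric(Ni); if (length(pre_ids)) Si[pre_ids] <- 1
        Zi <- Zi0 * kz_i + Si
        Zj <- Zj0 * kz_j   # post increments added at spike emission below
        Ei <- Ei0 + ke * (Zi0 - Ei0)
        Ej <- Ej0 + ke * (Zj0 - Ej0)
        Pi <- Pi + kp * (Ei0 - Pi)
        Pj <- Pj + kp * (Ej0 - Pj)
        Eij <- Eij0 + ke * (outer(Zi0, Zj0) - Eij0)
        Pij <- Pij + kp * (Eij0 - Pij)
        beta <- bcpnn_bias(Pj, p$eps)
        w_now <- function(ids)
          bcpnn_weight(matrix(Pi[ids], length(ids), M),
                       matrix(Pj, length(ids), M, byrow = TRUE),
                       Pij[ids, , drop = FALSE], p$eps)
      } else {
        # advance postsynaptic margins one step (bias needed every step)
        marg_post[, 1] <- marg_post[, 1] * fzj1
        marg_post[, 2] <- marg_post[, 2] * fe1
        marg_post[, 3] <- marg_post[, 3] * fp1
        t_last_post <- rep(n, M)
        Pj_now <- co$lam_zj * marg_post[, 1] + co$lam_ej * marg_post[, 2] +
          co$lam_pj * marg_post[, 3]
        beta <- bcpnn_bias(pmax(Pj_now, 0), p$eps)
        if (length(pre_ids)) {
          # presynaptic margins of the spiking inputs: decay + increment
          dn <- n - t_last_pre[pre_ids]
          for (k in 1:3) {
            tauk <- c(co$tau_zi, co$tau_e, co$tau_p_star)[k]
            marg_pre[pre_ids, k] <-
              marg_pre[pre_ids, k] * exp(-dn * cfg$dt / tauk) + 1
          }
          t_last_pre[pre_ids] <- n
          # synapse rows of the spiking inputs: decay + Z_j-sampled jump
          dn_syn <- n - t_last_syn[pre_ids, , drop = FALSE]
          Zj_now <- marg_post[, 1]
          Zj_mat <- matrix(Zj_now, length(pre_ids), M, byrow = TRUE)
          Es_ij[pre_ids, ] <- Es_ij[pre_ids, , drop = FALSE] *
            exp(-dn_syn * cfg$dt / co$tau_e) + Zj_mat
          Ps_ij[pre_ids, ] <- Ps_ij[pre_ids, , drop = FALSE] *
            exp(-dn_syn * cfg$dt / co$tau_p_star) + Zj_mat
          t_last_syn[pre_ids, ] <- n
          n_syn_events <- n_syn_events + length(pre_ids) * M
        }
      }

      # weighted input to the MCUs: sum of w_ij over this step's pre spikes
      weighted <- numeric(M)
      if (length(pre_ids)) {
        if (engine == "euler") {
          weighted <- colSums(w_now(pre_ids))
        } else {
          Pi_now <- co$lam_zi * marg_pre[pre_ids, 1] +
            co$lam_ei * marg_pre[pre_ids, 2] + co$lam_pi * marg_pre[pre_ids, 3]
          Pj_now2 <- co$lam_zj * marg_post[, 1] + co$lam_ej * marg_post[, 2] +
            co$lam_pj * marg_post[, 3]
          G <- outer(marg_pre[pre_ids, 1], marg_post[, 1])
          Pij_now <- co$lam_zij * G +
            co$lam_eij * Es_ij[pre_ids, , drop = FALSE] +
            co$lam_pij * Ps_ij[pre_ids, , drop = FALSE]
          wmat <- bcpnn_weight(
            matrix(pmax(Pi_now, 0), length(pre_ids), M),
            matrix(pmax(Pj_now2, 0), length(pre_ids), M, byrow = TRUE),
            pmax(Pij_now, 0), p$eps)
          weighted <- colSums(wmat)
        }
      }

      st <- mcu_step(s_syn, m, weighted, beta, I_fun(n), cfg)
      s_syn <- st$s_syn; m <- st$m
      if (record_beta) beta_rec[n, ] <- beta

      post_ids <- if (!is.null(clamp_at)) clamp_at[[n]]
                  else which(st$spikes)
      if (length(post_ids)) {
        if (engine == "euler") {
          Zj[post_ids] <- Zj[post_ids] + 1
        } else {
          # margins already at step n; apply increments
          marg_post[post_ids, ] <- marg_post[post_ids, , drop = FALSE] + 1
          # synapse columns: decay + Z_i-sampled jump
          dn_syn <- n - t_last_syn[, post_ids, drop = FALSE]
          dn_pre <- n - t_last_pre
          Zi_now <- marg_pre[, 1] * exp(-dn_pre * cfg$dt / co$tau_zi)
          Zi_mat <- matrix(Zi_now, Ni, length(post_ids))
          Es_ij[, post_ids] <- Es_ij[, post_ids, drop = FALSE] *
            exp(-dn_syn * cfg$dt / co$tau_e) + Zi_mat
          Ps_ij[, post_ids] <- Ps_ij[, post_ids, drop = FALSE] *
            exp(-dn_syn * cfg$dt / co$tau_p_star) + Zi_mat
          t_last_syn[, post_ids] <- n
          n_syn_events <- n_syn_events + length(post_ids) * Ni
        }
        for (u in post_ids) out_steps[[u]] <- c(out_steps[[u]], n)
      }
    }

    # final weight matrix
    if (engine == "euler") {
      W <- bcpnn_weight(matrix(Pi, Ni, M), matrix(Pj, Ni, M, byrow = TRUE),
                        Pij, p$eps)
    } else {
      dn_pre <- n_steps - t_last_pre
      marg_pre <- dec(marg_pre, c(co$tau_zi, co$tau_e, co$tau_p_star), dn_pre)
      dn_post <- n_steps - t_last_post
      marg_post <- dec(marg_post, c(co$tau_zj, co$tau_e, co$tau_p_star), dn_post)
      dn_syn <- n_steps - t_last_syn
      Es_ij <- Es_ij * exp(-dn_syn * cfg$dt / co$tau_e)
      Ps_ij <- Ps_ij * exp(-dn_syn * cfg$dt / co$tau_p_star)
      Pi_f <- pmax(co$lam_zi * marg_pre[, 1] + co$lam_ei * marg_pre[, 2] +
                     co$lam_pi * marg_pre[, 3], 0)
      Pj_f <- pmax(co$lam_zj * marg_post[, 1] + co$lam_ej * marg_post[, 2] +
                     co$lam_pj * marg_post[, 3], 0)
      Pij_f <- pmax(co$lam_zij * outer(marg_pre[, 1], marg_post[, 1]) +
                      co$lam_eij * Es_ij + co$lam_pij * Ps_ij, 0)
      W <- bcpnn_weight(matrix(Pi_f, Ni, M), matrix(Pj_f, Ni, M, byrow = TRUE),
                        Pij_f, p$eps)
    }

    traces <- if (engine == "euler")
      list(P_i = Pi, P_j = Pj, P_ij = Pij)
    else list(P_i = Pi_f, P_j = Pj_f, P_ij = Pij_f)
    list(output = lapply(seq_len(M), function(u)
           spike_train(out_steps[[u]], cfg$dt, u)),
         beta = beta_rec, weights = W, traces = traces,
         n_syn_events = n_syn_events, n_steps = n_steps)
  })
}
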