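# Engine interface: one contract, three interchangeable engines.
#
# `run_synapse()` drives a single BCPNN synapse over pre/post spike trains
# and records the canonical traces plus the weight and bias readouts at
# every spike time (after processing the spike). The fixed-step Euler
# engine additionally supports recording at every grid step.
#
# The per-event R functions (`euler_step()`, `analytical1_process_event()`,
# `analytical2_process_event()`) expose single updates for inspection and
# testing; the compiled loops produce identical trajectories.

# coefficient set for a frozen learning rate: tau_p* -> Inf makes every
# P decay factor 1 and every P source coefficient 0, so P stays put
derive_coefficients_frozen <- function(params) {
  p2 <- params
  p2$kappa <- 1
  co <- derive_coefficients(p2)
  co$kappa <- 0
  co$tau_p_star <- Inf
  co$bi <- 0; co$bj <- 0; co$bij <- 0; co$c <- 0
  co$aibi <- 0; co$ajbj <- 0
  co$lam_zi <- 0; co$lam_ei <- 0; co$lam_pi <- 0
  co$lam_zj <- 0; co$lam_ej <- 0; co$lam_pj <- 0
  co$lam_zij <- 0; co$lam_eij <- 0; co$lam_pij <- 0
  co
}

engine_coefficients <- function(params) {
  if (params$kappa == 0) derive_coefficients_frozen(params)
  else derive_coefficients(params)
}

coef_vector <- function(co) {
  unlist(co[c("dt", "eps", "tau_zi", "tau_zj", "tau_e", "tau_p_star",
              "tau_zij", "ai", "aj", "c", "aibi", "ajbj", "aij", "bij",
              "lam_zi", "lam_ei", "lam_pi", "lam_zj", "lam_ej", "lam_pj",
              "lam_zij", "lam_eij", "lam_pij")])
}

#' Engine configuration
#'
#' @param method One of `"analytical2"` (event-driven, exponential state
#'   variables, the default), `"analytical1"` (event-driven, canonical
#'   traces) or `"euler"` (fixed-step explicit Euler).
#' @param use_lut Serve decay factors from pre-computed look-up tables
#'   (event-driven engines only).
#' @param lut_size Entries per look-up table.
#' @param frac_bits If non-`NULL`, emulate fixed-point storage of the
#'   exponential state variables with this many fractional bits
#'   (`analytical2` only).
#' @param int_bits Integer bits of the emulated storage format.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(method = c("analytical2", "analytical1", "euler"),
                          use_lut = FALSE, lut_size = 3000L,
                          frac_bits = NULL, int_bits = 10L) {
  method <- match.arg(method)
  if (use_lut && lut_size < 1L) stop("lut_size must be >= 1 when use_lut")
  if (!is.null(frac_bits) && method != "analytical2")
    stop("fixed-point storage emulation applies to the analytical2 engine")
  structure(list(method = method, use_lut = use_lut,
                 lut_size = as.integer(lut_size),
                 frac_bits = if (is.null(frac_bits)) NULL else as.integer(frac_bits),
                 int_bits = as.integer(int_bits)),
            class = "engine_config")
}

validate_trains <- function(pre, post, params, n_steps) {
  for (tr in list(pre, post)) {
    if (!inherits(tr, "spike_train")) stop("pre/post must be spike_train objects")
    if (abs(tr$dt - params$dt) > 1e-12)
      stop("spike train grid step does not match params$dt")
    if (length(tr$steps) && tr$steps[length(tr$steps)] > n_steps)
      stop("spikes beyond the simulation duration")
  }
}

#' Simulate one BCPNN synapse
#'
#' Runs the configured engine over a pair of spike trains and returns the
#' canonical traces and readouts sampled at every pre-/postsynaptic spike
#' step (after the spike's update). With `record = "steps"` the Euler
#' engine records every grid step instead.
#'
#' @param pre,post [spike_train()]s on the `params$dt` grid.
#' @param params A [bcpnn_params()] object.
#' @param duration Duration (s); defaults to the last spike time.
#' @param engine An [engine_config()] (or a method name).
#' @param init Initial [canonical_state()]; defaults to
#'   [initial_canonical_state()].
#' @param record `"spikes"` (default) or `"steps"` (Euler only).
#' @return A list of class `synapse_run` with `samples` (data.frame:
#'   `time_ms`, `S_i`, `S_j`, traces, `w`, `beta`), `final`
#'   (final [canonical_state()]), `n_events`, `n_updates` and the
#'   configuration used.
#' @export
run_synapse <- function(pre, post, params, duration = NULL,
                        engine = engine_config(), init = NULL,
                        record = c("spikes", "steps")) {
  record <- match.arg(record)
  if (is.character(engine)) engine <- engine_config(method = engine)
  if (is.null(duration)) {
    last <- max(c(0L, pre$steps, post$steps))
    duration <- last * params$dt / 1000
  }
  n_steps <- as.integer(round(duration * 1000 / params$dt))
  validate_trains(pre, post, params, n_steps)
  if (is.null(init)) init <- initial_canonical_state(params)
  init_can <- as.numeric(init[c("Z_i", "Z_j", "E_i", "E_j", "E_ij",
                                "P_i", "P_j", "P_ij")])

  method <- engine$method
  if (method == "analytical2" && params$kappa == 0) method <- "analytical1"

  if (method == "euler") {
    par <- c(dt = params$dt, tau_zi = params$tau_zi, tau_zj = params$tau_zj,
             tau_e = params$tau_e, tau_p = params$tau_p,
             kappa = params$kappa, eps = params$eps)
    res <- .cpp_run_euler(pre$steps, post$steps, n_steps, par, init_can,
                          record_all = (record == "steps"))
    final <- do.call(new_canonical_state,
                     c(as.list(stats::setNames(res$final, names(init)[1:8])),
                       list(t_last = n_steps)))
  } else {
    if (record == "steps")
      stop("per-step recording is only available for the euler engine")
    co <- engine_coefficients(params)
    m <- if (method == "analytical1") 1L else 2L
    st0 <- if (m == 1L) init_can
           else {
             e <- canonical_to_exp(init, co)
             as.numeric(e[c("Zs_i", "Zs_j", "Es_i", "Es_j",
                            "Ps_i", "Ps_j", "Es_ij", "Ps_ij")])
           }
    res <- .cpp_run_event(pre$steps, post$steps, coef_vector(co), st0, m,
                          lut_L = if (engine$use_lut) engine$lut_size else 0L,
                          frac_bits = if (is.null(engine$frac_bits)) -1L
                                      else engine$frac_bits,
                          int_bits = engine$int_bits)
    tail_steps <- n_steps - res$t_last   # final state reported at `duration`
    if (m == 1L) {
      final <- do.call(new_canonical_state,
                       c(as.list(stats::setNames(res$final, names(init)[1:8])),
                         list(t_last = res$t_last)))
      final <- decay_canonical(final, tail_steps, co)
    } else {
      fe <- do.call(exp_state,
                    c(as.list(stats::setNames(res$final,
                        c("Zs_i", "Zs_j", "Es_i", "Es_j", "Ps_i", "Ps_j",
                          "Es_ij", "Ps_ij"))),
                      list(t_last = res$t_last)))
      final <- exp_to_canonical(decay_exp(fe, tail_steps, co), co)
    }
  }

  s <- as.data.frame(res$samples)
  names(s) <- c("step", "S_i", "S_j", "Z_i", "Z_j", "E_i", "E_j", "E_ij",
                "P_i", "P_j", "P_ij", "w", "beta")
  s$time_ms <- s$step * params$dt
  s <- s[, c("time_ms", "S_i", "S_j", "Z_i", "Z_j", "E_i", "E_j", "E_ij",
             "P_i", "P_j", "P_ij", "w", "beta")]
  structure(list(samples = s, final = final, n_events = res$n_events,
                 n_updates = res$n_updates, engine = engine, params = params,
                 duration = duration),
            class = "synapse_run")
}

#' @export
print.synapse_run <- function(x, ...) {
  cat(sprintf("BCPNN synapse run: %s engine, %g s, %d spike events, %d state updates\n",
              x$engine$method, x$duration, x$n_events, x$n_updates))
  if (nrow(x$samples)) {
    last <- x$samples[nrow(x$samples), ]
    cat(sprintf("  last sample (t = %g ms): w = %.4f, beta = %.4f\n",
                last$time_ms, last$w, last$beta))
  }
  invisible(x)
}

#' Single explicit Euler step on the canonical traces
#'
#' One step of the fixed-step reference scheme: all right-hand sides use
#' start-of-step values; `Z` decays by `(1 - dt/tau_z)` and receives the
#' spike increment within the step; `E` relaxes towards `Z` (the synaptic
#' `E_ij` towards `Z_i Z_j`) with `tau_e`; `P` relaxes towards `E` with
#' `tau_p / kappa` (frozen for `kappa = 0`).
#'
#' @param state A [canonical_state()].
#' @param S_i,S_j Spike indicators for this step (0 or 1).
#' @param params A [bcpnn_params()] object.
#' @return The updated [canonical_state()].
#' @export
euler_step <- function(state, S_i, S_j, params) {
  if (params$dt <= 0) stop("dt must be > 0")
  dt <- params$dt
  old <- state
  state$Z_i <- old$Z_i * (1 - dt / params$tau_zi) + S_i
  state$Z_j <- old$Z_j * (1 - dt / params$tau_zj) + S_j
  state$E_i <- old$E_i + dt / params$tau_e * (old$Z_i - old$E_i)
  state$E_j <- old$E_j + dt / params$tau_e * (old$Z_j - old$E_j)
  state$E_ij <- old$E_ij + dt / params$tau_e * (old$Z_i * old$Z_j - old$E_ij)
  kp <- dt * params$kappa / params$tau_p
  state$P_i <- old$P_i + kp * (old$E_i - old$P_i)
  state$P_j <- old$P_j + kp * (old$E_j - old$P_j)
  state$P_ij <- old$P_ij + kp * (old$E_ij - old$P_ij)
  state$t_last <- old$t_last + 1L
  state
}

#' Process one event with the canonical event-driven scheme
#'
#' Decays the canonical state to the event step with the exact closed
#' forms, applies the spike increments to the `Z` traces, and computes the
#' readout: the weight on a presynaptic spike, the bias on a postsynaptic
#' spike.
#'
#' @param state A [canonical_state()].
#' @param step Event grid step, `>= state$t_last`.
#' @param S_i,S_j Spike indicators (0/1).
#' @param coeffs Coefficients from [derive_coefficients()].
#' @return A list with `state` and `output` (list with `w` and/or `beta`,
#'   `NULL` entries when not computed at this event).
#' @export
analytical1_process_event <- function(state, step, S_i, S_j, coeffs) {
  dsteps <- step - state$t_last
  if (dsteps < 0) stop("out-of-order event (step < t_last)")
  state <- decay_canonical(state, dsteps, coeffs)
  state$Z_i <- state$Z_i + S_i
  state$Z_j <- state$Z_j + S_j
  out <- list(w = NULL, beta = NULL)
  if (S_i > 0)
    out$w <- bcpnn_weight(state$P_i, state$P_j, state$P_ij, coeffs$eps)
  if (S_j > 0) out$beta <- bcpnn_bias(state$P_j, coeffs$eps)
  list(state = state, output = out)
}

#' Process one event with the reduced-operation event-driven scheme
#'
#' Decays all exponential state variables (optionally via a decay LUT set),
#' applies the spike increments with consecutive evaluation (presynaptic
#' first), and reconstructs the `P` traces only when a readout is needed.
#'
#' @param state An [exp_state()].
#' @param step Event grid step, `>= state$t_last`.
#' @param S_i,S_j Spike indicators (0/1).
#' @param coeffs Coefficients from [derive_coefficients()].
#' @param luts Optional LUT set from [build_engine_luts()].
#' @return A list with `state` and `output` as in
#'   [analytical1_process_event()].
#' @export
analytical2_process_event <- function(state, step, S_i, S_j, coeffs,
                                      luts = NULL) {
  dsteps <- step - state$t_last
  if (dsteps < 0) stop("out-of-order event (step < t_last)")
  if (dsteps > 0) {
    if (is.null(luts)) state <- decay_exp(state, dsteps, coeffs)
    else {
      state$Zs_i <- state$Zs_i * lookup_decay(luts$zi, dsteps)
      state$Zs_j <- state$Zs_j * lookup_decay(luts$zj, dsteps)
      fe <- lookup_decay(luts$e, dsteps); fp <- lookup_decay(luts$p, dsteps)
      state$Es_i <- state$Es_i * fe; state$Es_j <- state$Es_j * fe
      state$Es_ij <- state$Es_ij * fe
      state$Ps_i <- state$Ps_i * fp; state$Ps_j <- state$Ps_j * fp
      state$Ps_ij <- state$Ps_ij * fp
      state$t_last <- state$t_last + as.integer(dsteps)
    }
  }
  if (S_i > 0) state <- apply_pre_spike(state)
  if (S_j > 0) state <- apply_post_spike(state)
  out <- list(w = NULL, beta = NULL)
  if (S_i > 0 || S_j > 0) {
    # reconstructed probabilities clamped at zero (roundoff guard)
    P_j <- max(retrieve_P_margin(state$Zs_j, state$Es_j, state$Ps_j,
                                 coeffs$lam_zj, coeffs$lam_ej, coeffs$lam_pj), 0)
    if (S_i > 0) {
      P_i <- max(retrieve_P_margin(state$Zs_i, state$Es_i, state$Ps_i,
                                   coeffs$lam_zi, coeffs$lam_ei, coeffs$lam_pi), 0)
      P_ij <- max(retrieve_P_syn(state$Zs_i, state$Zs_j, state$Es_ij,
                                 state$Ps_ij, coeffs), 0)
      out$w <- bcpnn_weight(P_i, P_j, P_ij, coeffs$eps)
    }
    if (S_j > 0) out$beta <- bcpnn_bias(P_j, coeffs$eps)
  }
  list(state = state, output = out)
}
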