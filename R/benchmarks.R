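# Accuracy and runtime benchmark protocols.
#
# The accuracy protocol stimulates a single synapse with correlated Poisson
# pairs (11 correlation factors 0..1, several seeds each, 1 Hz, 1000 s,
# 5 ms jitter on the shared postsynaptic spikes), simulates the same
# stimuli with the exact event-driven solution (the reference) and with an
# approximate engine (fixed-step Euler or fixed-point storage), and pools
# absolute errors of the state variables sampled at every pre-/postsynaptic
# spike time over all runs. The normalized mean absolute error (NMAE) is
# the pooled mean absolute error divided by the pooled range of the
# reference values.

acc_vars <- c("P_i", "P_j", "P_ij", "w", "beta")

#' Stimulus set of the accuracy protocol
#'
#' Generates one correlated Poisson pair per (correlation, seed)
#' combination; correlations are equally spaced on `[0, 1]`. Run seeds are
#' drawn reproducibly from the master seed.
#'
#' @param n_correlations Number of correlation factors (11 covers 0 to 1 in
#'   steps of 0.1).
#' @param seeds_per_c Independent stimulus seeds per correlation factor.
#' @param rate Average rate per side (Hz).
#' @param duration Duration of each run (s).
#' @param dt Grid step (ms).
#' @param jitter_sigma Gaussian jitter of shared postsynaptic spikes (ms).
#' @param master_seed Master seed for the whole stimulus set.
#' @return List of runs, each with `pre`, `post`, `c`, `seed`.
#' @export
accuracy_stimuli <- function(n_correlations = 11, seeds_per_c = 10, rate = 1,
                             duration = 1000, dt = 1, jitter_sigma = 5,
                             master_seed = 1) {
  cs <- seq(0, 1, length.out = n_correlations)
  n_runs <- n_correlations * seeds_per_c
  run_seeds <- with_local_seed(master_seed,
                               sample.int(.Machine$integer.max, n_runs))
  runs <- vector("list", n_runs)
  k <- 0
  for (cc in cs) for (s in seq_len(seeds_per_c)) {
    k <- k + 1
    pair <- correlated_pair(rate, cc, duration, dt, jitter_sigma,
                            seed = run_seeds[k])
    runs[[k]] <- list(pre = pair$pre, post = pair$post, c = cc,
                      seed = run_seeds[k])
  }
  attr(runs, "duration") <- duration
  attr(runs, "dt") <- dt
  runs
}

# pooled error/range accumulator over runs
acc_new <- function() {
  list(abs_sum = stats::setNames(numeric(length(acc_vars)), acc_vars),
       abs_max = stats::setNames(numeric(length(acc_vars)), acc_vars),
       ref_sum = stats::setNames(numeric(length(acc_vars)), acc_vars),
       ref_min = stats::setNames(rep(Inf, length(acc_vars)), acc_vars),
       ref_max = stats::setNames(rep(-Inf, length(acc_vars)), acc_vars),
       n = 0)
}

acc_add <- function(acc, ref_samples, approx_samples) {
  for (v in acc_vars) {
    x <- ref_samples[[v]]
    e <- abs(x - approx_samples[[v]])
    acc$abs_sum[v] <- acc$abs_sum[v] + sum(e)
    acc$abs_max[v] <- max(acc$abs_max[v], if (length(e)) max(e) else 0)
    acc$ref_sum[v] <- acc$ref_sum[v] + sum(x)
    acc$ref_min[v] <- min(acc$ref_min[v], if (length(x)) min(x) else Inf)
    acc$ref_max[v] <- max(acc$ref_max[v], if (length(x)) max(x) else -Inf)
  }
  acc$n <- acc$n + nrow(ref_samples)
  acc
}

acc_finish <- function(acc) {
  rng <- acc$ref_max - acc$ref_min
  if (any(rng <= 0)) stop("zero reference range: NMAE undefined")
  mean_abs <- acc$abs_sum / acc$n
  data.frame(variable = acc_vars,
             mean_abs_err = as.numeric(mean_abs),
             nmae = as.numeric(mean_abs / rng),
             max_abs_err = as.numeric(acc$abs_max),
             ref_mean = as.numeric(acc$ref_sum / acc$n),
             ref_min = as.numeric(acc$ref_min),
             ref_max = as.numeric(acc$ref_max),
             n_samples = acc$n,
             row.names = NULL)
}

#' Accuracy benchmark against the exact event-driven solution
#'
#' Runs the accuracy protocol for one or more approximate engine settings.
#' The reference is the exact canonical event-driven solution in double
#' precision; errors of `P_i`, `P_j`, `P_ij`, `w` and `beta` are sampled at
#' every pre-/postsynaptic spike time (after that spike's update) and
#' pooled over all runs.
#'
#' @param approx An [engine_config()] or a named list of them (a sweep
#'   evaluated on the same stimuli and reference).
#' @param stimuli A stimulus set from [accuracy_stimuli()]; alternatively
#'   pass `...` to generate one here.
#' @param params Synapse parameters; `dt` is overridden by the stimulus
#'   grid.
#' @param ... Passed to [accuracy_stimuli()] when `stimuli` is `NULL`.
#' @return For a single setting, a data.frame (class
#'   `bcpnn_accuracy`) with one row per variable: `mean_abs_err`, `nmae`,
#'   `max_abs_err`, and pooled reference statistics (`ref_mean`, `ref_min`,
#'   `ref_max`). For a sweep, a named list of such data.frames.
#' @export
accuracy_benchmark <- function(approx = engine_config("euler"),
                               stimuli = NULL, params = bcpnn_params(), ...) {
  single <- inherits(approx, "engine_config")
  settings <- if (single) list(approx) else approx
  if (is.null(stimuli)) stimuli <- accuracy_stimuli(...)
  dt <- attr(stimuli, "dt")
  duration <- attr(stimuli, "duration")
  params$dt <- dt
  validate_bcpnn_params(params)

  accs <- lapply(settings, function(s) acc_new())
  for (run in stimuli) {
    ref <- run_synapse(run$pre, run$post, params, duration,
                       engine = engine_config("analytical1"))$samples
    for (k in seq_along(settings)) {
      ap <- run_synapse(run$pre, run$post, params, duration,
                        engine = settings[[k]])$samples
      accs[[k]] <- acc_add(accs[[k]], ref, ap)
    }
  }
  res <- lapply(accs, function(a) {
    r <- acc_finish(a)
    class(r) <- c("bcpnn_accuracy", class(r))
    r
  })
  names(res) <- names(settings)
  if (single) res[[1]] else res
}

#' @export
print.bcpnn_accuracy <- function(x, ...) {
  cat("accuracy vs exact solution (pooled over runs, sampled at spikes)\n")
  y <- x
  class(y) <- "data.frame"
  y$nmae <- sprintf("%.3e", y$nmae)
  y$mean_abs_err <- sprintf("%.3e", y$mean_abs_err)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

nmae_of <- function(acc_df, variable) {
  acc_df$nmae[match(variable, acc_df$variable)]
}

#' Fractional bits matching a given Euler accuracy
#'
#' Sweeps the fixed-point storage word length of the event-driven engine
#' and returns the smallest number of fractional bits whose NMAE is equal
#' to or better than the fixed-step Euler NMAE (at step `dt_euler`) for
#' both readout variables `w` and `beta`, on identical stimuli.
#'
#' @param dt_euler Euler step size (ms); also the stimulus grid step.
#' @param bits Candidate fractional bit counts (increasing).
#' @param int_bits Integer bits of the emulated format.
#' @param stimuli Optional stimulus set from [accuracy_stimuli()].
#' @param params Synapse parameters.
#' @param ... Passed to [accuracy_stimuli()] when `stimuli` is `NULL`
#'   (e.g. `duration`, `seeds_per_c`, `master_seed`).
#' @return List with `bits` (smallest sufficient count), `euler`
#'   (reference accuracy data.frame) and `sweep` (per-bit accuracy).
#' @export
equal_error_bits <- function(dt_euler = 1, bits = 8:20, int_bits = 10L,
                             stimuli = NULL, params = bcpnn_params(), ...) {
  if (is.null(stimuli)) stimuli <- accuracy_stimuli(dt = dt_euler, ...)
  settings <- c(list(euler = engine_config("euler")),
                stats::setNames(
                  lapply(bits, function(b)
                    engine_config("analytical2", frac_bits = b,
                                  int_bits = int_bits)),
                  paste0("b", bits)))
  res <- accuracy_benchmark(settings, stimuli = stimuli, params = params)
  ew <- nmae_of(res$euler, "w"); eb <- nmae_of(res$euler, "beta")
  ok <- vapply(bits, function(b) {
    r <- res[[paste0("b", b)]]
    nmae_of(r, "w") <= ew && nmae_of(r, "beta") <= eb
  }, logical(1))
  if (!any(ok)) stop("search range exhausted: no bit count matches the Euler accuracy")
  list(bits = bits[which(ok)[1]], euler = res$euler, sweep = res[-1],
       bits_tested = bits, ok = ok)
}

#' Runtime and event-count report for the synapse array
#'
#' Mirrors the hypercolumn benchmark setup: pre- and postsynaptic units
#' driven by pre-generated independent Poisson trains (the stochastic MCU
#' outputs are clamped to the generated trains, so identical spikes reach
#' every engine), sweeping the Poisson rate. Reports wall-clock time per
#' simulated second and the number of synaptic state updates per engine.
#' Wall-clock numbers are hardware-dependent and informational only; the
#' structural quantities are the update counts: event-driven updates scale
#' with the spike count, clock-driven updates with `steps x array size`.
#'
#' @param rates Poisson rates to sweep (Hz).
#' @param duration Simulated duration per run (s).
#' @param n_runs Averaging runs with different seeds.
#' @param n_inputs,n_mcus Synapse-array dimensions.
#' @param engines Engines to time (subset of `"analytical2"`, `"euler"`).
#' @param dt Grid step (ms).
#' @param master_seed Seed for the stimulus generation.
#' @return Data.frame with columns `rate`, `engine`, `run`,
#'   `wall_s_per_sim_s`, `n_syn_updates`, `n_spikes` and `speedup_vs_euler`
#'   (NA when Euler is not timed).
#' @export
runtime_benchmark <- function(rates = c(0.1, 1, 10), duration = 2,
                              n_runs = 2, n_inputs = 100L, n_mcus = 10L,
                              engines = c("analytical2", "euler"), dt = 1,
                              master_seed = 1) {
  cfg <- hcu_config(n_inputs = n_inputs, n_mcus = n_mcus, dt = dt,
                    params = bcpnn_params(dt = dt))
  seeds <- with_local_seed(master_seed,
                           sample.int(.Machine$integer.max,
                                      length(rates) * n_runs))
  out <- list(); k <- 0; si <- 0
  for (r in rates) for (run in seq_len(n_runs)) {
    si <- si + 1
    seed <- seeds[si]
    ins <- lapply(seq_len(n_inputs), function(u)
      poisson_train(r, duration, dt, seed = seed + u, unit_id = u))
    outs <- lapply(seq_len(n_mcus), function(u)
      poisson_train(r, duration, dt, seed = seed + n_inputs + u, unit_id = u))
    n_spikes <- sum(vapply(ins, length, 1L)) + sum(vapply(outs, length, 1L))
    for (eng in engines) {
      tm <- system.time(
        h <- hcu_run(cfg, ins, duration, engine = eng, clamp_output = outs)
      )[["elapsed"]]
      n_upd <- if (eng == "euler")
        as.numeric(h$n_steps) * n_inputs * n_mcus else h$n_syn_events
      k <- k + 1
      out[[k]] <- data.frame(rate = r, engine = eng, run = run,
                             wall_s_per_sim_s = tm / duration,
                             n_syn_updates = n_upd, n_spikes = n_spikes)
    }
  }
  df <- do.call(rbind, out)
  if ("euler" %in% engines) {
    base <- df[df$engine == "euler", c("rate", "run", "wall_s_per_sim_s")]
    names(base)[3] <- "euler_time"
    df <- merge(df, base, by = c("rate", "run"), sort = FALSE)
    df$speedup_vs_euler <- df$euler_time / df$wall_s_per_sim_s
    df$euler_time <- NULL
  } else df$speedup_vs_euler <- NA_real_
  df[order(df$rate, df$engine, df$run), , drop = FALSE]
}
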