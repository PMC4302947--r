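# Synthetic stimulus generation: homogeneous Poisson trains (per-step
# Bernoulli on the dt grid), correlated Poisson pairs with Gaussian jitter
# on the shared spikes, and regular trains for worst-case bounds.

#' Spike train on a fixed time grid
#'
#' A spike train is a strictly increasing vector of positive integer grid
#' step indices (spike times are `steps * dt` ms); at most one spike per
#' unit per grid step.
#'
#' @param steps Integer vector of grid step indices, strictly increasing,
#'   `>= 1`.
#' @param dt Grid step (ms).
#' @param unit_id Integer unit identifier.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(steps = integer(), dt = 1, unit_id = 1L) {
  steps <- as.integer(steps)
  if (length(steps) && (any(steps < 1L) || any(diff(steps) <= 0L)))
    stop("steps must be strictly increasing integers >= 1 (one spike per step)")
  structure(list(steps = steps, dt = dt, unit_id = as.integer(unit_id)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train (unit %d): %d spikes on a %g ms grid",
              x$unit_id, length(x$steps), x$dt))
  if (length(x$steps))
    cat(sprintf(", t in [%g, %g] ms", x$steps[1] * x$dt,
                x$steps[length(x$steps)] * x$dt))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$steps)

#' Spike times in milliseconds
#' @param train A [spike_train()].
#' @return Numeric vector of spike times (ms).
#' @export
spike_times <- function(train) train$steps * train$dt

# run the generator body with a locally seeded RNG, leaving the caller's
# RNG stream untouched when a seed is given
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# k spikes ~ Binomial(n_steps, p) placed uniformly on distinct steps:
# identical in distribution to independent per-step Bernoulli draws
bernoulli_grid_steps <- function(n_steps, p) {
  if (p == 0 || n_steps == 0L) return(integer())
  k <- stats::rbinom(1L, n_steps, p)
  if (k == 0L) integer() else sort(sample.int(n_steps, k))
}

#' Homogeneous Poisson spike train
#'
#' Grid-restricted Poisson process: each grid step carries a spike with
#' probability `rate * dt` (at most one spike per step), so the empirical
#' rate converges to `rate` for `rate * dt << 1`.
#'
#' @param rate Firing rate (Hz), `>= 0`; `rate * dt` must not exceed 1.
#' @param duration Duration (s).
#' @param dt Grid step (ms).
#' @param seed Optional integer seed (local to this call).
#' @param unit_id Unit identifier.
#' @return A [spike_train()].
#' @export
poisson_train <- function(rate, duration, dt = 1, seed = NULL, unit_id = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  p <- rate * dt / 1000
  if (p > 1) stop("rate * dt exceeds one spike per grid step")
  n_steps <- as.integer(round(duration * 1000 / dt))
  steps <- with_local_seed(seed, bernoulli_grid_steps(n_steps, p))
  spike_train(steps, dt, unit_id)
}

#' Correlated Poisson spike-train pair
#'
#' Pre- and postsynaptic Poisson trains of rate `rate` sharing a fraction
#' `c` of spike times: one shared train of rate `c*rate` plus two
#' independent trains of rate `(1-c)*rate`. The shared spikes of the
#' postsynaptic side are jittered by Gaussian noise (sd `jitter_sigma`,
#' rounded to the grid) to avoid a systematic zero-lag; jittered spikes
#' falling outside the duration are dropped and collisions on one grid step
#' are merged.
#'
#' @param rate Average rate per side (Hz).
#' @param c Correlation fraction in `[0, 1]`.
#' @param duration Duration (s).
#' @param dt Grid step (ms).
#' @param jitter_sigma Jitter standard deviation (ms).
#' @param seed Optional integer seed (local to this call).
#' @return A list with elements `pre` and `post` ([spike_train()]s) and
#'   `shared` (the unjittered shared step indices).
#' @export
correlated_pair <- function(rate, c, duration, dt = 1, jitter_sigma = 5,
                            seed = NULL) {
  if (c < 0 || c > 1) stop("c must be in [0, 1]")
  if (rate <= 0 || duration <= 0) stop("rate and duration must be > 0")
  n_steps <- as.integer(round(duration * 1000 / dt))
  with_local_seed(seed, {
    shared <- bernoulli_grid_steps(n_steps, c * rate * dt / 1000)
    ind_pre <- bernoulli_grid_steps(n_steps, (1 - c) * rate * dt / 1000)
    ind_post <- bernoulli_grid_steps(n_steps, (1 - c) * rate * dt / 1000)
    jit <- as.integer(round(shared + stats::rnorm(length(shared), 0,
                                                  jitter_sigma / dt)))
    jit <- jit[jit >= 1L & jit <= n_steps]
    pre_steps <- sort(unique(c(ind_pre, shared)))
    post_steps <- sort(unique(c(ind_post, jit)))
    list(pre = spike_train(pre_steps, dt, 1L),
         post = spike_train(post_steps, dt, 2L),
         shared = shared)
  })
}

#' Regular spike train
#'
#' Evenly spaced spikes at `rate` Hz (period rounded to the nearest grid
#' step), used for worst-case value-range analysis.
#'
#' @param rate Firing rate (Hz), `> 0`.
#' @param duration Duration (s).
#' @param dt Grid step (ms).
#' @param unit_id Unit identifier.
#' @return A [spike_train()].
#' @export
regular_train <- function(rate, duration, dt = 1, unit_id = 1L) {
  if (rate <= 0) stop("rate must be > 0")
  period <- max(1L, as.integer(round(1000 / (rate * dt))))
  n_steps <- as.integer(round(duration * 1000 / dt))
  steps <- if (period > n_steps) integer() else seq.int(period, n_steps, by = period)
  spike_train(steps, dt, unit_id)
}

#' Regrid a spike train to a coarser (or finer) time grid
#'
#' Snaps spike times to the nearest step of the new grid, merging
#' collisions. Used to generate stimuli at fine resolution and simulate on
#' a coarser engine grid.
#'
#' @param train A [spike_train()].
#' @param dt_new New grid step (ms).
#' @return A [spike_train()] on the new grid.
#' @export
regrid_train <- function(train, dt_new) {
  t_ms <- spike_times(train)
  steps <- as.integer(round(t_ms / dt_new))
  steps <- sort(unique(steps[steps >= 1L]))
  spike_train(steps, dt_new, train$unit_id)
}
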