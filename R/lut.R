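# Pre-computed look-up tables for exponential decay factors on the integer
# step grid. With spike times restricted to multiples of dt, every decay
# factor has the form exp(-N*dt/tau) for an integer step gap N, so the
# frequent exponentials can be tabulated once per time constant.

#' Build a decay look-up table
#'
#' Tabulates `exp(-N*dt/tau)` for `N = 1...L`. Gaps larger than `L` steps
#' fall back to computing the same expression on demand, so the table is an
#' exact cache, not an approximation.
#'
#' @param tau Time constant (ms), `> 0`.
#' @param dt Grid step (ms), `> 0`.
#' @param L Number of entries, integer `>= 1`. The default 3000 at
#'   `dt = 1` ms covers update gaps up to 3 s, which handles about 95% of
#'   the inter-spike intervals of a 1 Hz Poisson input.
#' @return An object of class `decay_lut`.
#' @examples
#' lut <- build_lut(tau = 20, dt = 1, L = 3000)
#' lookup_decay(lut, 1)  # exp(-0.05)
#' @export
build_lut <- function(tau, dt = 1, L = 3000L) {
  if (tau <= 0 || dt <= 0) stop("tau and dt must be > 0")
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be an integer >= 1")
  structure(list(tau = tau, dt = dt, L = L,
                 table = exp(-(seq_len(L) * dt) / tau)),
            class = "decay_lut")
}

#' Look up (or compute) a decay factor
#'
#' Returns `exp(-N*dt/tau)`: 1 for `N = 0`, the tabulated value for
#' `1 <= N <= L`, and the directly computed exponential for `N > L`
#' (identical formula and routine, so LUT-backed simulations are
#' bit-identical to direct ones).
#'
#' @param lut A [build_lut()] object.
#' @param N Elapsed grid steps, integer `>= 0` (vectorised).
#' @return Decay factor(s) in `(0, 1]`.
#' @export
lookup_decay <- function(lut, N) {
  if (any(N < 0)) stop("N must be >= 0")
  out <- numeric(length(N))
  out[N == 0] <- 1
  inside <- N >= 1 & N <= lut$L
  out[inside] <- lut$table[N[inside]]
  beyond <- N > lut$L
  if (any(beyond)) out[beyond] <- exp(-(N[beyond] * lut$dt) / lut$tau)
  out
}

#' Fraction of Poisson inter-spike intervals covered by a LUT
#'
#' For a homogeneous Poisson process at `rate`, the probability that an
#' inter-spike interval does not exceed the table span `L*dt` is
#' `1 - exp(-rate * L * dt)`; update gaps inside the span are served from
#' the table.
#'
#' @param rate Firing rate (Hz), `> 0`.
#' @param L Number of LUT entries.
#' @param dt Grid step (ms).
#' @return Coverage fraction in `[0, 1)`.
#' @examples
#' lut_coverage(1, 3000, 1)  # 1 - exp(-3) ~ 0.95
#' @export
lut_coverage <- function(rate, L = 3000L, dt = 1) {
  if (rate <= 0) stop("rate must be > 0")
  1 - exp(-rate * L * dt / 1000)
}

#' Look-up table set for the engine time constants
#'
#' Builds one [build_lut()] table per engine time constant (`tau_zi`,
#' `tau_zj`, `tau_e`, `tau_p_star`), as used by the event-driven engines.
#'
#' @param coeffs Coefficients from [derive_coefficients()].
#' @param L Entries per table.
#' @return Named list of `decay_lut`s (`zi`, `zj`, `e`, `p`).
#' @export
build_engine_luts <- function(coeffs, L = 3000L) {
  list(zi = build_lut(coeffs$tau_zi, coeffs$dt, L),
       zj = build_lut(coeffs$tau_zj, coeffs$dt, L),
       e = build_lut(coeffs$tau_e, coeffs$dt, L),
       p = build_lut(coeffs$tau_p_star, coeffs$dt, L))
}
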