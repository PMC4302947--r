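# Exact closed-form updates of the BCPNN trace cascade, in both
# representations (canonical Z/E/P traces and purely exponential state
# variables), plus the transforms between them and the spike-response
# kernels. These R kernels are written against a pluggable arithmetic
# backend: the default backend is plain arithmetic; a counting backend
# (see opcount.R) tallies ADD/MUL/EXP/LOG on exactly the same code path.

# plain backend: real arithmetic, no bookkeeping
arith_plain <- list(
  add = function(a, b) a + b,
  sub = function(a, b) a - b,
  mul = function(a, b) a * b,
  div = function(a, b) a / b,
  exp = function(x) exp(x),
  log = function(x) log(x)
)

# decay factor exp(-(dsteps*dt)/tau); the elapsed-time product dsteps*dt is
# event bookkeeping and is not counted, the division by tau and the
# exponential are. A decay LUT may stand in for the whole factor.
decay_factor <- function(dsteps, tau, dt, b = arith_plain, lut = NULL) {
  if (!is.null(lut)) return(lookup_decay(lut, dsteps))
  b$exp(-b$div(dsteps * dt, tau))
}

#' Canonical BCPNN state
#'
#' The eight canonical traces of one BCPNN synapse: the fast `Z` traces
#' (jump by 1 at a spike, decay with `tau_z`), the eligibility `E` traces
#' (low-pass of `Z`, with `E_ij` tracking the product `Z_i Z_j`), and the
#' slow probability `P` traces, plus the grid step of the last update.
#'
#' @param Z_i,Z_j,E_i,E_j,E_ij,P_i,P_j,P_ij Trace values, `>= 0`.
#' @param t_last Grid step index of the last update (integer, `>= 0`).
#' @return An object of class `canonical_state`.
#' @export
canonical_state <- function(Z_i = 0, Z_j = 0, E_i = 0, E_j = 0, E_ij = 0,
                            P_i = 0, P_j = 0, P_ij = 0, t_last = 0L) {
  s <- new_canonical_state(Z_i, Z_j, E_i, E_j, E_ij, P_i, P_j, P_ij, t_last)
  if (any(unlist(s[1:8]) < 0)) stop("canonical traces must be >= 0")
  if (s$t_last < 0) stop("t_last must be >= 0")
  s
}

# internal constructor without the non-negativity check (results computed
# from quantized storage can sit a rounding error below zero)
new_canonical_state <- function(Z_i = 0, Z_j = 0, E_i = 0, E_j = 0, E_ij = 0,
                                P_i = 0, P_j = 0, P_ij = 0, t_last = 0L) {
  structure(list(Z_i = Z_i, Z_j = Z_j, E_i = E_i, E_j = E_j, E_ij = E_ij,
                 P_i = P_i, P_j = P_j, P_ij = P_ij,
                 t_last = as.integer(t_last)),
            class = "canonical_state")
}

#' Exponential (reduced-operation) BCPNN state
#'
#' The state variables of the reduced-operation representation: every
#' variable decays purely exponentially with its own time constant
#' (`tau_zi`, `tau_zj`, `tau_e` or `tau_p_star`) and is only incremented at
#' spikes (+1 on the pre/post side, +Z of the opposite side for the synaptic
#' pair). The canonical traces are linear combinations of these variables.
#'
#' @param Zs_i,Zs_j,Es_i,Es_j,Ps_i,Ps_j,Es_ij,Ps_ij State variable values.
#' @param t_last Grid step index of the last update.
#' @return An object of class `exp_state`.
#' @export
exp_state <- function(Zs_i = 0, Zs_j = 0, Es_i = 0, Es_j = 0,
                      Ps_i = 0, Ps_j = 0, Es_ij = 0, Ps_ij = 0, t_last = 0L) {
  s <- list(Zs_i = Zs_i, Zs_j = Zs_j, Es_i = Es_i, Es_j = Es_j,
            Ps_i = Ps_i, Ps_j = Ps_j, Es_ij = Es_ij, Ps_ij = Ps_ij,
            t_last = as.integer(t_last))
  if (s$t_last < 0) stop("t_last must be >= 0")
  class(s) <- "exp_state"
  s
}

#' Default initial state
#'
#' Default initialisation of a BCPNN synapse: `Z = E = 0`,
#' `P_i = P_j = eps`, `P_ij = eps^2`, i.e. the probability estimates start
#' at the assumed minimum activity so that the initial weight is
#' `ln(2 eps^2 / (2 eps)^2) = ln(1/2)` and the initial bias `ln(2 eps)`.
#'
#' @param params A [bcpnn_params()] object.
#' @return A [canonical_state()].
#' @export
initial_canonical_state <- function(params) {
  canonical_state(P_i = params$eps, P_j = params$eps, P_ij = params$eps^2)
}

#' @rdname initial_canonical_state
#' @param coeffs Coefficients from [derive_coefficients()].
#' @return `initial_exp_state`: the same state in the exponential
#'   representation.
#' @export
initial_exp_state <- function(params, coeffs = derive_coefficients(params)) {
  canonical_to_exp(initial_canonical_state(params), coeffs)
}

# one Z/E/P cascade: pure decay over dsteps plus optional unit spike
# increment on Z. `a` and `ab` are the partial-fraction coefficients
# (ab = a*b precomputed), `cc` the shared E/P coefficient.
zep_decay <- function(Z, E, P, dsteps, tau_z, a, ab, cc, co, b, luts = NULL,
                      spike = FALSE) {
  fz <- decay_factor(dsteps, tau_z, co$dt, b, luts$z)
  fe <- decay_factor(dsteps, co$tau_e, co$dt, b, luts$e)
  fp <- decay_factor(dsteps, co$tau_p_star, co$dt, b, luts$p)
  AZ <- b$mul(a, Z)
  Z_new <- b$mul(Z, fz)
  if (spike) Z_new <- b$add(Z_new, 1)
  E_new <- b$add(b$mul(E, fe), b$mul(AZ, b$sub(fz, fe)))
  P_new <- b$add(b$add(b$mul(P, fp),
                       b$mul(b$mul(ab, Z), b$sub(fz, fp))),
                 b$mul(b$mul(b$sub(E, AZ), cc), b$sub(fe, fp)))
  list(Z = Z_new, E = E_new, P = P_new)
}

#' Closed-form decay of the presynaptic (or postsynaptic) canonical traces
#'
#' Advances `Z_i`, `E_i`, `P_i` (or the `j` analogues with `side = "post"`)
#' by `dsteps` grid steps assuming no spike in the interval, using the exact
#' solution of the linear cascade. `t_last` is advanced accordingly.
#'
#' @param state A [canonical_state()].
#' @param dsteps Number of elapsed grid steps, integer `>= 0`.
#' @param coeffs Coefficients from [derive_coefficients()].
#' @param side `"pre"` advances `Z_i, E_i, P_i`; `"post"` advances
#'   `Z_j, E_j, P_j`.
#' @return The updated [canonical_state()] (only the chosen side and
#'   `t_last` change).
#' @export
decay_canonical_pre <- function(state, dsteps, coeffs, side = c("pre", "post")) {
  side <- match.arg(side)
  if (dsteps < 0) stop("dsteps must be >= 0 (no backward evolution)")
  if (dsteps == 0) return(state)
  if (side == "pre") {
    r <- zep_decay(state$Z_i, state$E_i, state$P_i, dsteps, coeffs$tau_zi,
                   coeffs$ai, coeffs$aibi, coeffs$c, coeffs, arith_plain)
    state$Z_i <- r$Z; state$E_i <- r$E; state$P_i <- r$P
  } else {
    r <- zep_decay(state$Z_j, state$E_j, state$P_j, dsteps, coeffs$tau_zj,
                   coeffs$aj, coeffs$ajbj, coeffs$c, coeffs, arith_plain)
    state$Z_j <- r$Z; state$E_j <- r$E; state$P_j <- r$P
  }
  state$t_last <- state$t_last + as.integer(dsteps)
  state
}

# Synaptic pair decay (E_ij, P_ij), sourced by the product of the Z traces
# at the start of the interval. The coefficient product aij*bij is formed
# inline (the compound synaptic coefficient is not pre-tabulated).
syn_decay <- function(E_ij, P_ij, Zi_last, Zj_last, dsteps, co, b,
                      luts = NULL) {
  fzij <- decay_factor(dsteps, co$tau_zij, co$dt, b, luts$zij)
  fe <- decay_factor(dsteps, co$tau_e, co$dt, b, luts$e)
  fp <- decay_factor(dsteps, co$tau_p_star, co$dt, b, luts$p)
  G <- b$mul(Zi_last, Zj_last)
  AG <- b$mul(co$aij, G)
  E_new <- b$add(b$mul(E_ij, fe), b$mul(AG, b$sub(fzij, fe)))
  P_new <- b$add(b$add(b$mul(P_ij, fp),
                       b$mul(b$mul(b$mul(co$aij, co$bij), G), b$sub(fzij, fp))),
                 b$mul(b$mul(b$sub(E_ij, AG), co$c), b$sub(fe, fp)))
  list(E_ij = E_new, P_ij = P_new)
}

#' Closed-form decay of the synaptic canonical traces
#'
#' Advances `E_ij` and `P_ij` by `dsteps` grid steps using the exact
#' solution, with the product `Z_i(t_last) * Z_j(t_last)` as the source term.
#' The `Z` traces themselves are not modified here (use
#' [decay_canonical_pre()] for the margins); `t_last` is not advanced so the
#' three decay calls of one event can share the same reference time.
#'
#' @inheritParams decay_canonical_pre
#' @return The updated [canonical_state()] (only `E_ij`, `P_ij` change).
#' @export
decay_canonical_syn <- function(state, dsteps, coeffs) {
  if (dsteps < 0) stop("dsteps must be >= 0 (no backward evolution)")
  if (dsteps == 0) return(state)
  r <- syn_decay(state$E_ij, state$P_ij, state$Z_i, state$Z_j, dsteps,
                 coeffs, arith_plain)
  state$E_ij <- r$E_ij; state$P_ij <- r$P_ij
  state
}

#' Advance a full canonical state over a spike-free interval
#'
#' Applies [decay_canonical_syn()] (which must see the `Z` traces at the
#' start of the interval) and then [decay_canonical_pre()] for both sides.
#'
#' @inheritParams decay_canonical_pre
#' @return The updated [canonical_state()].
#' @export
decay_canonical <- function(state, dsteps, coeffs) {
  if (dsteps < 0) stop("dsteps must be >= 0 (no backward evolution)")
  if (dsteps == 0) return(state)
  state <- decay_canonical_syn(state, dsteps, coeffs)
  state <- decay_canonical_pre(state, dsteps, coeffs, side = "pre")
  state$t_last <- state$t_last - as.integer(dsteps)   # pre call advanced it
  decay_canonical_pre(state, dsteps, coeffs, side = "post")
}

#' Decay the exponential state variables over a spike-free interval
#'
#' Every variable is multiplied by `exp(-dsteps*dt/tau)` for its own time
#' constant; nothing else changes. This is the whole between-spike update of
#' the reduced-operation representation.
#'
#' @param state An [exp_state()].
#' @inheritParams decay_canonical_pre
#' @return The updated [exp_state()].
#' @export
decay_exp <- function(state, dsteps, coeffs) {
  if (dsteps < 0) stop("dsteps must be >= 0 (no backward evolution)")
  if (dsteps == 0) return(state)
  fzi <- exp(-dsteps * coeffs$dt / coeffs$tau_zi)
  fzj <- exp(-dsteps * coeffs$dt / coeffs$tau_zj)
  fe <- exp(-dsteps * coeffs$dt / coeffs$tau_e)
  fp <- exp(-dsteps * coeffs$dt / coeffs$tau_p_star)
  state$Zs_i <- state$Zs_i * fzi
  state$Zs_j <- state$Zs_j * fzj
  state$Es_i <- state$Es_i * fe
  state$Es_j <- state$Es_j * fe
  state$Ps_i <- state$Ps_i * fp
  state$Ps_j <- state$Ps_j * fp
  state$Es_ij <- state$Es_ij * fe
  state$Ps_ij <- state$Ps_ij * fp
  state$t_last <- state$t_last + as.integer(dsteps)
  state
}

#' Apply a presynaptic (or postsynaptic) spike to an exponential state
#'
#' The state must already be decayed to the spike time. A presynaptic spike
#' adds 1 to `Zs_i`, `Es_i`, `Ps_i` and the current value of the opposite
#' `Z` trace to the synaptic pair `Es_ij`, `Ps_ij` (that is how the synaptic
#' variables track the overlap of pre- and postsynaptic activity).
#'
#' @param state An [exp_state()], decayed to the spike time.
#' @param Z_other Sampled value of the opposite side's `Z` trace at the
#'   spike time; defaults to the corresponding trace in `state`. For
#'   simultaneous pre+post spikes evaluated consecutively (pre first), the
#'   defaults implement the consecutive coincidence rule exactly.
#' @return The updated [exp_state()].
#' @export
apply_pre_spike <- function(state, Z_other = state$Zs_j) {
  state$Zs_i <- state$Zs_i + 1
  state$Es_i <- state$Es_i + 1
  state$Ps_i <- state$Ps_i + 1
  state$Es_ij <- state$Es_ij + Z_other
  state$Ps_ij <- state$Ps_ij + Z_other
  state
}

#' @rdname apply_pre_spike
#' @export
apply_post_spike <- function(state, Z_other = state$Zs_i) {
  state$Zs_j <- state$Zs_j + 1
  state$Es_j <- state$Es_j + 1
  state$Ps_j <- state$Ps_j + 1
  state$Es_ij <- state$Es_ij + Z_other
  state$Ps_ij <- state$Ps_ij + Z_other
  state
}

#' Coincidence increment of the synaptic variables
#'
#' The jump of the product `Z_i Z_j` (and hence of `Es_ij`, `Ps_ij`) when a
#' presynaptic and/or postsynaptic spike arrives:
#' `Delta_ij = S_i Z_j^- + S_j Z_i^- + S_i S_j`, where `Z^-` are the trace
#' values before the spikes. The synchronous form and the consecutive form
#' (`S_i Z_j^- + S_j Z_i^+`, pre evaluated first) are algebraically
#' identical.
#'
#' @param Z_i_minus,Z_j_minus `Z` trace values before spike evaluation.
#' @param S_i,S_j Spike indicators, 0 or 1.
#' @return The increment `Delta_ij`.
#' @export
coincident_increment <- function(Z_i_minus, Z_j_minus, S_i, S_j) {
  if (!all(c(S_i, S_j) %in% c(0, 1))) stop("S_i, S_j must be 0 or 1")
  S_i * Z_j_minus + S_j * Z_i_minus + S_i * S_j
}

# lambda-form retrieval of canonical P traces from exponential variables,
# backend-parameterised (these are the "retrieve" tasks of the op count).
retrieve_P_margin <- function(Zs, Es, Ps, lam_z, lam_e, lam_p, b = arith_plain) {
  b$add(b$add(b$mul(lam_z, Zs), b$mul(lam_e, Es)), b$mul(lam_p, Ps))
}

retrieve_P_syn <- function(Zs_i, Zs_j, Es_ij, Ps_ij, co, b = arith_plain) {
  G <- b$mul(Zs_i, Zs_j)
  b$add(b$add(b$mul(co$lam_zij, G), b$mul(co$lam_eij, Es_ij)),
        b$mul(co$lam_pij, Ps_ij))
}

#' Transform an exponential state to canonical traces
#'
#' `Z_i = Zs_i`, `E_i = ai (Zs_i - Es_i)`,
#' `P_i = lam_zi Zs_i + lam_ei Es_i + lam_pi Ps_i` (analogously for `j`),
#' `E_ij = aij (Zs_i Zs_j - Es_ij)`,
#' `P_ij = lam_zij Zs_i Zs_j + lam_eij Es_ij + lam_pij Ps_ij`.
#'
#' @param state An [exp_state()].
#' @param coeffs Coefficients from [derive_coefficients()].
#' @return A [canonical_state()].
#' @export
exp_to_canonical <- function(state, coeffs) {
  G <- state$Zs_i * state$Zs_j
  new_canonical_state(
    Z_i = state$Zs_i,
    Z_j = state$Zs_j,
    E_i = coeffs$ai * (state$Zs_i - state$Es_i),
    E_j = coeffs$aj * (state$Zs_j - state$Es_j),
    E_ij = coeffs$aij * (G - state$Es_ij),
    P_i = retrieve_P_margin(state$Zs_i, state$Es_i, state$Ps_i,
                            coeffs$lam_zi, coeffs$lam_ei, coeffs$lam_pi),
    P_j = retrieve_P_margin(state$Zs_j, state$Es_j, state$Ps_j,
                            coeffs$lam_zj, coeffs$lam_ej, coeffs$lam_pj),
    P_ij = retrieve_P_syn(state$Zs_i, state$Zs_j, state$Es_ij, state$Ps_ij,
                          coeffs),
    t_last = state$t_last
  )
}

#' Transform canonical traces to the exponential representation
#'
#' Inverse of [exp_to_canonical()]; the assignments must be performed in
#' order (`Zs` first, then `Es` which uses `Zs`, then `Ps` which uses both).
#'
#' @param state A [canonical_state()].
#' @param coeffs Coefficients from [derive_coefficients()].
#' @return An [exp_state()].
#' @export
canonical_to_exp <- function(state, coeffs) {
  if (abs(coeffs$lam_pi) < 1e-300 || abs(coeffs$lam_pj) < 1e-300 ||
      abs(coeffs$lam_pij) < 1e-300)
    stop("degenerate parameters: a lambda_p coefficient is zero")
  Zs_i <- state$Z_i
  Zs_j <- state$Z_j
  Es_i <- -state$E_i / coeffs$ai + Zs_i
  Es_j <- -state$E_j / coeffs$aj + Zs_j
  Ps_i <- (state$P_i - coeffs$lam_zi * Zs_i - coeffs$lam_ei * Es_i) / coeffs$lam_pi
  Ps_j <- (state$P_j - coeffs$lam_zj * Zs_j - coeffs$lam_ej * Es_j) / coeffs$lam_pj
  G <- Zs_i * Zs_j
  Es_ij <- -state$E_ij / coeffs$aij + G
  Ps_ij <- (state$P_ij - coeffs$lam_zij * G - coeffs$lam_eij * Es_ij) / coeffs$lam_pij
  exp_state(Zs_i = Zs_i, Zs_j = Zs_j, Es_i = Es_i, Es_j = Es_j,
            Ps_i = Ps_i, Ps_j = Ps_j, Es_ij = Es_ij, Ps_ij = Ps_ij,
            t_last = state$t_last)
}

#' Spike-response kernels of the BCPNN traces
#'
#' Evaluates the stereotyped single-spike response of each trace:
#' `zeta(t) = exp(-t/tau_z)` (Heaviside-gated), `alpha` the eligibility
#' kernel, `pi` the probability kernel, and the `_ij` analogues with the
#' combined time constant `tau_zij`. Every canonical trace is a superposition
#' of these kernels over past spikes (with `Z`-sampled amplitudes for the
#' synaptic pair).
#'
#' @param kind One of `"zeta"`, `"alpha"`, `"pi"`, `"zeta_ij"`,
#'   `"alpha_ij"`, `"pi_ij"` (the marginal kernels use the presynaptic time
#'   constant; pass `side = "post"` for the postsynaptic ones).
#' @param t Time since the spike (ms), vectorised; kernels vanish for
#'   `t < 0`.
#' @param coeffs Coefficients from [derive_coefficients()].
#' @param side `"pre"` or `"post"` for the marginal kernels.
#' @return Kernel value(s).
#' @export
kernel_value <- function(kind = c("zeta", "alpha", "pi", "zeta_ij",
                                  "alpha_ij", "pi_ij"),
                         t, coeffs, side = c("pre", "post")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  if (side == "pre") {
    tz <- coeffs$tau_zi; a <- coeffs$ai; bb <- coeffs$bi
  } else {
    tz <- coeffs$tau_zj; a <- coeffs$aj; bb <- coeffs$bj
  }
  if (kind %in% c("zeta_ij", "alpha_ij", "pi_ij")) {
    tz <- coeffs$tau_zij; a <- coeffs$aij; bb <- coeffs$bij
  }
  theta <- as.numeric(t >= 0)
  ez <- exp(-t / tz); ee <- exp(-t / coeffs$tau_e)
  ep <- exp(-t / coeffs$tau_p_star)
  v <- switch(sub("_ij$", "", kind),
    zeta = ez,
    alpha = a * (ez - ee),
    pi = a * (bb * (ez - ep) + coeffs$c * (ep - ee))
  )
  v * theta
}
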