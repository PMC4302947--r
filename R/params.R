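#' BCPNN model parameters
#'
#' Bundles the parameters of the spike-based BCPNN synapse: the time constants
#' of the three low-pass filtering stages, the learning rate, the minimum
#' activity and the simulation grid step. Defaults are the benchmark parameter
#' set used throughout the package: fast receptor-scale `Z` traces (10/15 ms),
#' an eligibility `E` stage (20 ms) and a slow probability `P` stage (1000 ms).
#'
#' While the learning rate `kappa` is constant and non-zero the `P` stage
#' behaves as a first-order low-pass with effective time constant
#' `tau_p_star = tau_p / kappa`. `kappa = 0` freezes the `P` traces (no
#' learning); this is handled by the engines, not by the coefficients.
#'
#' @param tau_zi Presynaptic `Z` trace time constant (ms).
#' @param tau_zj Postsynaptic `Z` trace time constant (ms).
#' @param tau_e Eligibility (`E`) trace time constant (ms).
#' @param tau_p Probability (`P`) trace time constant (ms).
#' @param kappa Learning rate, unitless, `>= 0`.
#' @param eps Minimum activity epsilon, unitless, `> 0`; regularises the
#'   logarithms in the weight and bias readout.
#' @param dt Simulation grid step (ms); spike times are restricted to
#'   multiples of `dt`.
#' @return An object of class `bcpnn_params` (named list).
#' @examples
#' p <- bcpnn_params()
#' p$tau_zi
#' @export
bcpnn_params <- function(tau_zi = 10, tau_zj = 15, tau_e = 20, tau_p = 1000,
                         kappa = 1, eps = 0.001, dt = 1) {
  p <- list(tau_zi = as.numeric(tau_zi), tau_zj = as.numeric(tau_zj),
            tau_e = as.numeric(tau_e), tau_p = as.numeric(tau_p),
            kappa = as.numeric(kappa), eps = as.numeric(eps),
            dt = as.numeric(dt))
  validate_bcpnn_params(p)
  class(p) <- "bcpnn_params"
  p
}

validate_bcpnn_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("tau_zi", "tau_zj", "tau_e", "tau_p", "kappa", "eps", "dt"))
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite numeric scalar")
  if (p$tau_zi <= 0 || p$tau_zj <= 0 || p$tau_e <= 0 || p$tau_p <= 0)
    stop("all time constants must be strictly positive")
  if (p$kappa < 0) stop("kappa must be >= 0")
  if (p$eps <= 0) stop("eps must be > 0")
  if (p$dt <= 0) stop("dt must be > 0")
  invisible(p)
}

#' @export
print.bcpnn_params <- function(x, ...) {
  cat("BCPNN parameters\n")
  cat(sprintf("  tau_zi = %g ms, tau_zj = %g ms, tau_e = %g ms, tau_p = %g ms\n",
              x$tau_zi, x$tau_zj, x$tau_e, x$tau_p))
  cat(sprintf("  kappa = %g, eps = %g, dt = %g ms\n", x$kappa, x$eps, x$dt))
  invisible(x)
}

#' Derived coefficients of the closed-form BCPNN updates
#'
#' Computes every constant needed by the exact event-driven updates: the
#' effective `P` time constant `tau_p_star = tau_p / kappa`, the partial
#' fraction coefficients
#' `ai = tau_zi / (tau_zi - tau_e)`, `bi = tau_zi / (tau_zi - tau_p_star)`,
#' `c = tau_e / (tau_e - tau_p_star)` (and the `j` analogues), the combined
#' coincidence time constant `tau_zij = (1/tau_zi + 1/tau_zj)^-1` with its
#' coefficients `aij`, `bij`, and the linear-combination coefficients
#' `lam_zi = ai*bi`, `lam_ei = -ai*c`, `lam_pi = ai*(c - bi)` (plus `j` and
#' `ij` analogues) that map the exponential state variables back to the
#' canonical traces.
#'
#' The closed forms require the three time constants of each cascade
#' (`tau_z*`, `tau_e`, `tau_p_star`) to be pairwise distinct; `tau_zi` may
#' equal `tau_zj`. Degenerate (equal) time constants raise an error.
#'
#' @param params A [bcpnn_params()] object. `kappa` must be `> 0` here
#'   (a zero learning rate is handled by the engines, which freeze the `P`
#'   traces instead of deriving coefficients).
#' @return An object of class `bcpnn_coefficients`.
#' @examples
#' co <- derive_coefficients(bcpnn_params())
#' co$tau_zij  # 6 ms for tau_zi = 10, tau_zj = 15
#' @export
derive_coefficients <- function(params) {
  validate_bcpnn_params(params)
  if (params$kappa <= 0)
    stop("derive_coefficients requires kappa > 0 (kappa = 0 freezes the P traces)")
  tau_p_star <- params$tau_p / params$kappa
  tau_zij <- 1 / (1 / params$tau_zi + 1 / params$tau_zj)

  rel_equal <- function(a, b) abs(a - b) <= 1e-9 * max(abs(a), abs(b))
  check_distinct <- function(taus, lab) {
    cmb <- utils::combn(length(taus), 2)
    for (k in seq_len(ncol(cmb)))
      if (rel_equal(taus[cmb[1, k]], taus[cmb[2, k]]))
        stop("degenerate time constants: ", lab,
             " must be pairwise distinct (equal time-constant case unsupported)")
  }
  check_distinct(c(params$tau_zi, params$tau_e, tau_p_star), "tau_zi, tau_e, tau_p*")
  check_distinct(c(params$tau_zj, params$tau_e, tau_p_star), "tau_zj, tau_e, tau_p*")
  check_distinct(c(tau_zij, params$tau_e, tau_p_star), "tau_zij, tau_e, tau_p*")

  ai <- params$tau_zi / (params$tau_zi - params$tau_e)
  aj <- params$tau_zj / (params$tau_zj - params$tau_e)
  bi <- params$tau_zi / (params$tau_zi - tau_p_star)
  bj <- params$tau_zj / (params$tau_zj - tau_p_star)
  cc <- params$tau_e / (params$tau_e - tau_p_star)
  aij <- tau_zij / (tau_zij - params$tau_e)
  bij <- tau_zij / (tau_zij - tau_p_star)

  co <- list(
    tau_zi = params$tau_zi, tau_zj = params$tau_zj, tau_e = params$tau_e,
    tau_p_star = tau_p_star, tau_zij = tau_zij,
    dt = params$dt, eps = params$eps, kappa = params$kappa,
    ai = ai, aj = aj, bi = bi, bj = bj, c = cc,
    aibi = ai * bi, ajbj = aj * bj,
    aij = aij, bij = bij,
    lam_zi = ai * bi, lam_ei = -ai * cc, lam_pi = ai * (cc - bi),
    lam_zj = aj * bj, lam_ej = -aj * cc, lam_pj = aj * (cc - bj),
    lam_zij = aij * bij, lam_eij = -aij * cc, lam_pij = aij * (cc - bij)
  )
  class(co) <- "bcpnn_coefficients"
  co
}

#' @export
print.bcpnn_coefficients <- function(x, ...) {
  cat("BCPNN derived coefficients\n")
  cat(sprintf("  tau_p* = %g ms, tau_zij = %g ms\n", x$tau_p_star, x$tau_zij))
  cat(sprintf("  ai = %.6g, aj = %.6g, bi = %.6g, bj = %.6g, c = %.6g\n",
              x$ai, x$aj, x$bi, x$bj, x$c))
  cat(sprintf("  lam_zi = %.6g, lam_ei = %.6g, lam_pi = %.6g\n",
              x$lam_zi, x$lam_ei, x$lam_pi))
  invisible(x)
}

#' Postsynaptic bias readout
#'
#' `beta_j = ln(P_j + eps)`: the log prior probability of the postsynaptic
#' unit being active, regularised by the minimum activity `eps`.
#'
#' @param P_j Postsynaptic probability trace (vectorised), `>= 0`.
#' @param eps Minimum activity, `> 0`.
#' @return Bias value(s), natural log scale.
#' @examples
#' bcpnn_bias(0.001, 0.001)  # ln(0.002) ~ -6.215
#' @export
bcpnn_bias <- function(P_j, eps) {
  if (any(P_j < 0)) stop("P_j must be >= 0")
  if (eps <= 0) stop("eps must be > 0")
  log(P_j + eps)
}

#' Synaptic weight readout
#'
#' `w_ij = ln((P_ij + eps^2) / ((P_i + eps) (P_j + eps)))`: the log odds of
#' co-activation relative to independence. Positive for correlated pre/post
#' activity, negative for anti-correlated, and zero under statistical
#' independence (`P_ij = P_i * P_j` for `P >> eps`). The epsilon terms keep
#' the logarithm finite for silent units.
#'
#' @param P_i,P_j,P_ij Probability traces (vectorised), `>= 0`.
#' @param eps Minimum activity, `> 0`.
#' @return Weight value(s), natural log scale.
#' @examples
#' bcpnn_weight(0.05, 0.05, 0.0025, 0.001)  # ~ 0 (independence)
#' @export
bcpnn_weight <- function(P_i, P_j, P_ij, eps) {
  if (any(P_i < 0) || any(P_j < 0) || any(P_ij < 0))
    stop("P traces must be >= 0")
  if (eps <= 0) stop("eps must be > 0")
  log((P_ij + eps^2) / ((P_i + eps) * (P_j + eps)))
}

#' Read BCPNN parameters from a config file
#'
#' Reads a YAML (or JSON) file with keys `tau_zi`, `tau_zj`, `tau_e`,
#' `tau_p`, `kappa`, `eps`, `dt`; missing keys fall back to the defaults of
#' [bcpnn_params()].
#'
#' @param path Path to a YAML or JSON file.
#' @return A [bcpnn_params()] object.
#' @export
read_bcpnn_params <- function(path) {
  cfg <- read_config(path)
  keys <- c("tau_zi", "tau_zj", "tau_e", "tau_p", "kappa", "eps", "dt")
  unknown <- setdiff(names(cfg), keys)
  if (length(unknown))
    warning("ignoring unknown parameter keys: ", paste(unknown, collapse = ", "))
  do.call(bcpnn_params, cfg[intersect(names(cfg), keys)])
}
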