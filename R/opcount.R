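# Arithmetic-operation instrumentation. A counting backend performs the
# real arithmetic while tallying ADD (additions and subtractions), MUL
# (multiplications and divisions), EXP and LOG; the counted code paths are
# the same closed-form kernels used by the R reference implementation, so
# the counts are measured, not transcribed. Only state math is counted:
# event bookkeeping (elapsed-step products, control flow) is not.

# counting backend over a shared environment
op_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$ADD <- 0L; env$MUL <- 0L; env$EXP <- 0L; env$LOG <- 0L
  backend <- list(
    add = function(a, b) { env$ADD <- env$ADD + 1L; a + b },
    sub = function(a, b) { env$ADD <- env$ADD + 1L; a - b },
    mul = function(a, b) { env$MUL <- env$MUL + 1L; a * b },
    div = function(a, b) { env$MUL <- env$MUL + 1L; a / b },
    exp = function(x) { env$EXP <- env$EXP + 1L; exp(x) },
    log = function(x) { env$LOG <- env$LOG + 1L; log(x) }
  )
  list(env = env, backend = backend)
}

op_count_result <- function(env) {
  structure(list(ADD = env$ADD, MUL = env$MUL, EXP = env$EXP, LOG = env$LOG),
            class = "op_count")
}

#' @export
print.op_count <- function(x, ...) {
  cat(sprintf("ADD %d, MUL %d, EXP %d, LOG %d\n", x$ADD, x$MUL, x$EXP, x$LOG))
  invisible(x)
}

# counted task bodies ------------------------------------------------------

# presynaptic margin update at a spike (analytical I): closed-form decay of
# Z_i, E_i, P_i plus the +S increment on Z
counted_pre_update_a1 <- function(st, dsteps, co, b, spike = TRUE) {
  zep_decay(st$Z, st$E, st$P, dsteps, co$tau_zi, co$ai, co$aibi, co$c, co, b,
            spike = spike)
}

# synaptic pair update (analytical I): closed-form decay of E_ij, P_ij
counted_syn_update_a1 <- function(st, dsteps, co, b) {
  syn_decay(st$E_ij, st$P_ij, st$Z_i, st$Z_j, dsteps, co, b)
}

# presynaptic margin update at a spike (analytical II): three exponential
# decays plus three unit increments
counted_pre_update_a2 <- function(st, dsteps, co, b, spike = TRUE) {
  fz <- decay_factor(dsteps, co$tau_zi, co$dt, b)
  fe <- decay_factor(dsteps, co$tau_e, co$dt, b)
  fp <- decay_factor(dsteps, co$tau_p_star, co$dt, b)
  Zs <- b$mul(st$Zs, fz); Es <- b$mul(st$Es, fe); Ps <- b$mul(st$Ps, fp)
  if (spike) {
    Zs <- b$add(Zs, 1); Es <- b$add(Es, 1); Ps <- b$add(Ps, 1)
  }
  list(Zs = Zs, Es = Es, Ps = Ps)
}

# synaptic pair update at a presynaptic spike (analytical II): two
# exponential decays plus the sampled-Z increment S*Z_j
counted_syn_update_a2 <- function(st, dsteps, co, b) {
  fe <- decay_factor(dsteps, co$tau_e, co$dt, b)
  fp <- decay_factor(dsteps, co$tau_p_star, co$dt, b)
  inc <- b$mul(1, st$Z_other)
  list(Es_ij = b$add(b$mul(st$Es_ij, fe), inc),
       Ps_ij = b$add(b$mul(st$Ps_ij, fp), inc))
}

counted_weight <- function(P_i, P_j, P_ij, eps, eps2, b) {
  b$log(b$div(b$add(P_ij, eps2), b$mul(b$add(P_i, eps), b$add(P_j, eps))))
}

counted_bias <- function(P_j, eps, b) b$log(b$add(P_j, eps))

# representative operands from a short simulated spike history (counts are
# data-independent, but a physically consistent state keeps the readouts in
# the domain of the logarithm)
op_demo_state <- function() {
  list(Z = 0.660404, E = 0.405454, P = 0.015833,
       Z_i = 0.660404, Z_j = 0.553002, E_ij = 0.305233, P_ij = 0.008550,
       Zs = 0.660404, Es = 1.065859, Ps = 2.999293, Z_other = 0.553002,
       Es_ij = 1.077416, Ps_ij = 2.764728)
}

#' Count arithmetic operations per update task
#'
#' Runs the R closed-form kernels for one task under a counting arithmetic
#' backend and reports the number of ADD (additions/subtractions), MUL
#' (multiplications/divisions), EXP and LOG operations. Composite tasks
#' (`update_w_at_pre`, `update_beta_at_post`) chain the margin update, the
#' synaptic update, the trace retrievals needed by the readout, and the
#' readout formula itself.
#'
#' For the retrieval tasks the canonical engine needs no arithmetic (the
#' `P` traces are stored directly), while the reduced-operation engine
#' reconstructs them as linear combinations of the exponential state
#' variables.
#'
#' @param task One of `"pre_update"`, `"syn_update"`, `"retrieve_Pi"`,
#'   `"retrieve_Pij"`, `"update_w_at_pre"`, `"update_beta_at_post"`.
#' @param method `"analytical1"` or `"analytical2"`.
#' @param params A [bcpnn_params()] object (counts do not depend on the
#'   values, only on the kernel structure).
#' @param dsteps Elapsed steps used for the demo update.
#' @return An `op_count` (list with `ADD`, `MUL`, `EXP`, `LOG`).
#' @examples
#' count_ops("retrieve_Pi", "analytical2")  # 2 ADD, 3 MUL
#' @export
count_ops <- function(task = c("pre_update", "syn_update", "retrieve_Pi",
                               "retrieve_Pij", "update_w_at_pre",
                               "update_beta_at_post"),
                      method = c("analytical1", "analytical2"),
                      params = bcpnn_params(), dsteps = 7L) {
  task <- match.arg(task)
  method <- match.arg(method)
  co <- derive_coefficients(params)
  eps2 <- params$eps^2   # constant, prepared once with the coefficients
  ctr <- op_counter()
  b <- ctr$backend
  st <- op_demo_state()

  a1 <- method == "analytical1"
  switch(task,
    pre_update = {
      if (a1) counted_pre_update_a1(st, dsteps, co, b)
      else counted_pre_update_a2(st, dsteps, co, b)
    },
    syn_update = {
      if (a1) counted_syn_update_a1(st, dsteps, co, b)
      else counted_syn_update_a2(st, dsteps, co, b)
    },
    retrieve_Pi = {
      if (!a1) retrieve_P_margin(st$Zs, st$Es, st$Ps, co$lam_zi, co$lam_ei,
                                 co$lam_pi, b)
    },
    retrieve_Pij = {
      if (!a1) retrieve_P_syn(st$Zs, st$Z_other, st$Es_ij, st$Ps_ij, co, b)
    },
    update_w_at_pre = {
      if (a1) {
        r_syn <- counted_syn_update_a1(st, dsteps, co, b)
        r_pre <- counted_pre_update_a1(st, dsteps, co, b, spike = TRUE)
        r_post <- counted_pre_update_a1(st, dsteps, co, b, spike = FALSE)
        counted_weight(r_pre$P, r_post$P, r_syn$P_ij, params$eps, eps2, b)
      } else {
        r_pre <- counted_pre_update_a2(st, dsteps, co, b, spike = TRUE)
        r_post <- counted_pre_update_a2(st, dsteps, co, b, spike = FALSE)
        r_syn <- counted_syn_update_a2(st, dsteps, co, b)
        P_i <- retrieve_P_margin(r_pre$Zs, r_pre$Es, r_pre$Ps, co$lam_zi,
                                 co$lam_ei, co$lam_pi, b)
        P_j <- retrieve_P_margin(r_post$Zs, r_post$Es, r_post$Ps, co$lam_zj,
                                 co$lam_ej, co$lam_pj, b)
        P_ij <- retrieve_P_syn(r_pre$Zs, r_post$Zs, r_syn$Es_ij, r_syn$Ps_ij,
                               co, b)
        counted_weight(P_i, P_j, P_ij, params$eps, eps2, b)
      }
    },
    update_beta_at_post = {
      if (a1) {
        r_post <- counted_pre_update_a1(st, dsteps, co, b, spike = TRUE)
        counted_bias(r_post$P, params$eps, b)
      } else {
        r_post <- counted_pre_update_a2(st, dsteps, co, b, spike = TRUE)
        P_j <- retrieve_P_margin(r_post$Zs, r_post$Es, r_post$Ps, co$lam_zj,
                                 co$lam_ej, co$lam_pj, b)
        counted_bias(P_j, params$eps, b)
      }
    }
  )
  op_count_result(ctr$env)
}

#' Operation-count table for all tasks and both event-driven methods
#'
#' @inheritParams count_ops
#' @return A data.frame with one row per task/method and columns
#'   `ADD`, `MUL`, `EXP`, `LOG`.
#' @export
count_ops_table <- function(params = bcpnn_params()) {
  tasks <- c("pre_update", "syn_update", "retrieve_Pi", "retrieve_Pij",
             "update_w_at_pre", "update_beta_at_post")
  methods <- c("analytical1", "analytical2")
  rows <- do.call(rbind, lapply(tasks, function(tk) {
    do.call(rbind, lapply(methods, function(m) {
      cnt <- count_ops(tk, m, params)
      data.frame(task = tk, method = m, ADD = cnt$ADD, MUL = cnt$MUL,
                 EXP = cnt$EXP, LOG = cnt$LOG)
    }))
  }))
  rownames(rows) <- NULL
  rows
}
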