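# Fixed-point storage emulation and analytic value-range bounds. The
# emulation follows the storage-quantisation model: arithmetic runs at
# floating-point precision, but every value written back to a state
# variable is rounded to b fractional bits (round-to-nearest, ties to
# even) and saturated to the representable range. Quantisation then acts
# as a noise source of amplitude 2^-b on the stored state.

#' Fixed-point number format
#'
#' Describes a `Qi.f` fixed-point format with `int_bits` integer bits and
#' `frac_bits` fractional bits (resolution `2^-frac_bits`). Values outside
#' the representable range saturate.
#'
#' @param int_bits Integer bits (excluding sign), `>= 0`.
#' @param frac_bits Fractional bits `b`, `>= 0`.
#' @param signed Whether a sign bit is present.
#' @return An object of class `fixed_point_format`.
#' @examples
#' fixed_point_format(10, 12)
#' parse_fixed_point_format("Q10.12")
#' @export
fixed_point_format <- function(int_bits, frac_bits, signed = TRUE) {
  int_bits <- as.integer(int_bits); frac_bits <- as.integer(frac_bits)
  if (int_bits < 0 || frac_bits < 0) stop("bit counts must be >= 0")
  if (int_bits + frac_bits < 1) stop("int_bits + frac_bits must be >= 1")
  res <- 2^-frac_bits
  hi <- 2^int_bits - res
  lo <- if (signed) -2^int_bits else 0
  structure(list(int_bits = int_bits, frac_bits = frac_bits, signed = signed,
                 resolution = res, min = lo, max = hi),
            class = "fixed_point_format")
}

#' @rdname fixed_point_format
#' @param spec A specification string `"Qi.f"`, e.g. `"Q10.12"`.
#' @export
parse_fixed_point_format <- function(spec) {
  m <- regmatches(spec, regexec("^Q([0-9]+)\\.([0-9]+)$", spec))[[1]]
  if (length(m) != 3L) stop("fixed-point format must look like 'Q10.12'")
  fixed_point_format(as.integer(m[2]), as.integer(m[3]))
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("fixed-point format Q%d.%d (%ssigned), resolution 2^-%d, range [%g, %g]\n",
              x$int_bits, x$frac_bits, if (x$signed) "" else "un",
              x$frac_bits, x$min, x$max))
  invisible(x)
}

#' Quantize values to a fixed-point format
#'
#' Rounds to the nearest multiple of `2^-frac_bits` (ties to even) and
#' saturates at the format bounds. The per-write error of an in-range value
#' is at most `2^-(frac_bits+1)`.
#'
#' @param x Numeric vector.
#' @param fmt A [fixed_point_format()].
#' @return Quantized values.
#' @export
quantize <- function(x, fmt) {
  q <- round(x * 2^fmt$frac_bits) / 2^fmt$frac_bits
  pmin(pmax(q, fmt$min), fmt$max)
}

#' Worst-case value bound of an exponential trace
#'
#' Equilibrium maximum of a purely exponentially decaying trace with unit
#' (or `increment`-sized) jumps, driven by a regular spike train at the
#' maximum rate `r_max`: decay over one inter-spike interval and the jump
#' balance at `bound = increment / (1 - exp(-1/(r_max*tau)))`. For
#' `r_max*tau >> 1` this approaches `r_max * tau * increment`, which is the
#' convenient bound for sizing integer bits.
#'
#' @param r_max Maximum sustained firing rate (Hz), e.g. the inverse
#'   refractory period.
#' @param tau Trace time constant (ms).
#' @param increment Jump size per spike (1 for the `Z`-type variables).
#' @return A list with `exact` (equilibrium bound) and `approx`
#'   (`r_max * tau * increment`).
#' @examples
#' value_range_bound(1000, 1000)  # approx 1000, exact ~1000.5
#' @export
value_range_bound <- function(r_max, tau, increment = 1) {
  if (r_max <= 0 || tau <= 0) stop("r_max and tau must be > 0")
  rt <- r_max * tau / 1000  # rate in Hz, tau in ms
  list(exact = increment / (1 - exp(-1 / rt)),
       approx = rt * increment)
}

#' Integer bits needed to represent a bound
#'
#' Smallest `n` with `2^n >= bound`. A magnitude bounded by 1 needs no
#' integer bits beyond the sign.
#'
#' @param bound Positive value bound.
#' @return Integer bit count.
#' @examples
#' integer_bits_required(1000.5)  # 10
#' @export
integer_bits_required <- function(bound) {
  if (bound <= 0) stop("bound must be > 0")
  max(0L, as.integer(ceiling(log2(bound) - 1e-12)))
}

# quantize derived coefficients to the "highest available" fixed-point
# precision (32 fractional bits), used when emulating fixed-point storage
quantize_coefficients <- function(coeffs, coef_frac_bits = 32L) {
  fmt <- fixed_point_format(30L, as.integer(coef_frac_bits))
  for (f in c("ai", "aj", "bi", "bj", "c", "aibi", "ajbj", "aij", "bij",
              "lam_zi", "lam_ei", "lam_pi", "lam_zj", "lam_ej", "lam_pj",
              "lam_zij", "lam_eij", "lam_pij"))
    coeffs[[f]] <- quantize(coeffs[[f]], fmt)
  coeffs
}
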