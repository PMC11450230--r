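#' Elementary rate constants of the four-state symport cycle
#'
#' Container for the eight elementary rate constants of the four-state
#' K+/H+ symport cycle plus the transporter count N.  The cycle is
#' C1 (outward-open, empty) -> C2 (H+ bound) -> C3 (H+ and K+ bound) ->
#' C4 (inward-open, empty) -> C1.  External binding steps are second order
#' (\code{k12_0} in M^-1 s^-1 for H+, \code{k23_0} in M^-1 s^-1 for K+);
#' the reverse conformational step lumps internal release and is third
#' order (\code{k43_0} in M^-2 s^-1, multiplied by [H+]i [K+]i); the
#' C1 <-> C4 conformational step carries the voltage dependence
#' (\code{k14_0}, \code{k41_0} at V = 0).
#'
#' Microscopic reversibility constrains the constants:
#' \deqn{k41_0 k12_0 k23_0 k34 = k14_0 k21 k32 k43_0}
#' so only seven rates are free.  One constant (named by
#' \code{derived_constant}, default \code{"k43_0"}) is always recomputed
#' from the identity rather than taken from the user.
#'
#' @param k12_0 external H+ binding constant (M^-1 s^-1)
#' @param k21 H+ debinding rate (s^-1)
#' @param k23_0 external K+ binding constant (M^-1 s^-1)
#' @param k32 K+ debinding rate (s^-1)
#' @param k34 forward conformational rate (s^-1)
#' @param k43_0 reverse composite constant (M^-2 s^-1); ignored (recomputed)
#'   when \code{derived_constant = "k43_0"}
#' @param k14_0 outward conformational rate at V = 0 (s^-1)
#' @param k41_0 inward conformational rate at V = 0 (s^-1)
#' @param N total number of transporters in the membrane
#' @param derived_constant which single constant is derived from the
#'   microscopic-reversibility identity (one of the eight rate names)
#' @return an object of class \code{kinetic_params}
#' @examples
#' p <- kinetic_params(k12_0 = 1e7, k21 = 10, k23_0 = 1e6, k32 = 100,
#'                     k34 = 100, k14_0 = 1e5, k41_0 = 0.1, N = 1e10)
#' p$k43_0 # derived
#' @export
kinetic_params <- function(k12_0, k21, k23_0, k32, k34, k43_0 = NULL,
                           k14_0, k41_0, N = 1e10,
                           derived_constant = "k43_0") {
  rate_names <- c("k12_0", "k21", "k23_0", "k32", "k34", "k43_0",
                  "k14_0", "k41_0")
  derived_constant <- match.arg(derived_constant, rate_names)
  vals <- list(k12_0 = k12_0, k21 = k21, k23_0 = k23_0, k32 = k32,
               k34 = k34, k43_0 = k43_0, k14_0 = k14_0, k41_0 = k41_0)
  supplied <- rate_names[rate_names != derived_constant]
  for (nm in supplied) {
    v <- vals[[nm]]
    if (is.null(v) || !is.finite(v) || length(v) != 1L || v <= 0)
      stop("rate constant '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (!is.finite(N) || N < 1)
    stop("N must be a finite count >= 1", call. = FALSE)
  vals[[derived_constant]] <- .derive_rate(vals, derived_constant)
  obj <- structure(c(vals, list(N = N, derived_constant = derived_constant)),
                   class = "kinetic_params")
  stopifnot(abs(reversibility_gap(obj)) < 1e-10)
  obj
}

## forward product k41_0 k12_0 k23_0 k34, reverse product k14_0 k21 k32 k43_0;
## solve the identity for the designated constant.
.derive_rate <- function(vals, which) {
  fwd <- c("k41_0", "k12_0", "k23_0", "k34")
  rev <- c("k14_0", "k21", "k32", "k43_0")
  prod_except <- function(nms) prod(vapply(setdiff(nms, which), function(n)
    vals[[n]], numeric(1)))
  if (which %in% fwd) prod(vapply(rev, function(n) vals[[n]], numeric(1))) /
    prod_except(fwd)
  else prod(vapply(fwd, function(n) vals[[n]], numeric(1))) / prod_except(rev)
}

#' Relative departure from microscopic reversibility
#'
#' Relative difference between the forward and reverse cycle products
#' \code{k41_0 k12_0 k23_0 k34} and \code{k14_0 k21 k32 k43_0}; zero for any
#' thermodynamically consistent parameter set.
#'
#' @param params a \code{kinetic_params} object
#' @return a dimensionless relative gap
#' @export
reversibility_gap <- function(params) {
  fwd <- params$k41_0 * params$k12_0 * params$k23_0 * params$k34
  rev <- params$k14_0 * params$k21 * params$k32 * params$k43_0
  (fwd - rev) / fwd
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Four-state K+/H+ symport cycle parameters\n")
  for (nm in c("k12_0", "k21", "k23_0", "k32", "k34", "k43_0", "k14_0",
               "k41_0"))
    cat(sprintf("  %-6s %12.6g %s\n", nm, x[[nm]],
                if (nm == x$derived_constant) " (derived)" else ""))
  cat(sprintf("  N      %12.6g transporters\n", x$N))
  invisible(x)
}

#' Experimental conditions for the kinetic model
#'
#' Membrane voltage, temperature, and the four ion concentrations seen by
#' the transporter.  Convenience arguments \code{pH_out}/\code{pH_in}
#' override \code{H_out}/\code{H_in} when given.
#'
#' @param V membrane voltage (mV, cytosol minus bath)
#' @param T_K absolute temperature (K)
#' @param K_out,K_in external/internal K+ (mol/L)
#' @param H_out,H_in external/internal H+ (mol/L)
#' @param pH_out,pH_in optional pH shorthand; H = 10^-pH
#' @return an object of class \code{conditions}
#' @examples
#' conditions(V = -120, pH_out = 4.5, K_out = 20e-6)
#' @export
conditions <- function(V = -120, T_K = DEFAULT_TEMPERATURE,
                       K_out = 200e-6, H_out = 10^-4.5,
                       K_in = 0.1, H_in = 10^-7.1,
                       pH_out = NULL, pH_in = NULL) {
  if (!is.null(pH_out)) H_out <- 10^(-pH_out)
  if (!is.null(pH_in)) H_in <- 10^(-pH_in)
  conc <- c(K_out = K_out, H_out = H_out, K_in = K_in, H_in = H_in)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (!is.finite(T_K) || T_K <= 0)
    stop("temperature must be > 0 K", call. = FALSE)
  if (!is.finite(V)) stop("voltage must be finite", call. = FALSE)
  structure(list(V = V, T_K = T_K, K_out = K_out, H_out = H_out,
                 K_in = K_in, H_in = H_in),
            class = "conditions")
}

#' @export
print.conditions <- function(x, ...) {
  cat(sprintf(
    "Conditions: V = %g mV, T = %g K\n  [K+]o = %g M, [H+]o = %g M (pH %.2f)\n  [K+]i = %g M, [H+]i = %g M (pH %.2f)\n",
    x$V, x$T_K, x$K_out, x$H_out, -log10(x$H_out), x$K_in, x$H_in,
    -log10(x$H_in)))
  invisible(x)
}

#' Effective first-order rates under given conditions
#'
#' Multiplies binding constants by their substrate concentrations and
#' applies the symmetric Eyring voltage factors to the C1 <-> C4 step:
#' \deqn{k14 = k14_0 e^{FV/RT}, \quad k41 = k41_0 e^{-FV/RT}}
#' \deqn{k12 = k12_0 [H+]_o, \quad k23 = k23_0 [K+]_o, \quad
#'       k43 = k43_0 [H+]_i [K+]_i}
#' The product \code{k14 * k41} is voltage independent (symmetric barrier).
#'
#' @param params a \code{kinetic_params} object
#' @param cond a \code{conditions} object
#' @return an object of class \code{resolved_rates}: the eight effective
#'   rates (s^-1) plus the voltage factor \code{u = FV/RT} and copies of
#'   \code{params}/\code{cond}
#' @export
resolve_rates <- function(params, cond) {
  stopifnot(inherits(params, "kinetic_params"), inherits(cond, "conditions"))
  u <- .FARADAY * (cond$V / 1000) / (.GAS_R * cond$T_K)
  structure(list(
    k12 = params$k12_0 * cond$H_out,
    k21 = params$k21,
    k23 = params$k23_0 * cond$K_out,
    k32 = params$k32,
    k34 = params$k34,
    k43 = params$k43_0 * cond$H_in * cond$K_in,
    k14 = params$k14_0 * exp(u),
    k41 = params$k41_0 * exp(-u),
    u = u, params = params, cond = cond),
    class = "resolved_rates")
}
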