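## Reduced Michaelis-Menten description of the full cycle: closed-form
## apparent affinities and maximal currents, voltage scans, and the
## K+-site mutant scenario.

## shared denominator factor: coefficient of [K+]o in the King-Altman
## denominator, divided by k23_0
.kk_denom <- function(r, k12H) {
  r$k34 * r$k41 + r$k14 * (r$k43 + r$k34) +
    k12H * (r$k41 + r$k43 + r$k34)
}

#' Apparent K+ affinity and maximal K+ current (closed form)
#'
#' At fixed voltage and external H+, the inward branch of the full
#' steady-state current is exactly Michaelis-Menten in [K+]o.  This
#' evaluates the closed-form half-saturation constant K_K and maximal
#' current I_Kmax (inward, hence <= 0) of that reduction.
#'
#' @param params a \code{kinetic_params} object
#' @param V membrane voltage (mV)
#' @param H_out external H+ (mol/L); must be > 0
#' @param internal a \code{conditions} object supplying temperature and the
#'   internal concentrations (its V, K_out, H_out are ignored)
#' @return a list of class \code{reduced_params}: \code{substrate = "K"},
#'   \code{K_X} (mol/L), \code{I_Xmax} (A, signed), \code{V},
#'   \code{co_substrate_conc}
#' @export
km_imax_potassium <- function(params, V, H_out, internal = conditions()) {
  if (!is.finite(H_out) || H_out <= 0)
    stop("H_out must be > 0", call. = FALSE)
  cond <- conditions(V = V, T_K = internal$T_K, K_out = 0, H_out = H_out,
                     K_in = internal$K_in, H_in = internal$H_in)
  r <- resolve_rates(params, cond)
  k12H <- params$k12_0 * H_out
  B <- .kk_denom(r, k12H)
  if (B <= 0) stop("degenerate system: zero saturation denominator",
                   call. = FALSE)
  I_Kmax <- -(2 * .E_CHARGE * params$N * params$k41_0 * params$k12_0 *
                params$k23_0 * params$k34 * H_out * exp(-r$u)) /
    (params$k23_0 * B)
  K_K <- (r$k32 * (
    r$k41 * r$k21 * (1 + r$k34 / r$k32) +
      r$k43 * r$k21 +
      r$k14 * (r$k43 + r$k21 * (1 + (r$k43 + r$k34) / r$k32)) +
      k12H * (r$k41 * (1 + r$k34 / r$k32) + r$k43))) /
    (params$k23_0 * B)
  structure(list(substrate = "K", K_X = K_K, I_Xmax = I_Kmax, V = V,
                 co_substrate_conc = H_out),
            class = "reduced_params")
}

#' Apparent H+ affinity (closed form)
#'
#' Half-saturation constant K_H of the current with respect to external
#' H+ at fixed voltage and external K+, from the closed-form reduction of
#' the full cycle.  The companion maximal current is obtained from the
#' large-[H+] limit of the same decomposition.
#'
#' @param params a \code{kinetic_params} object
#' @param V membrane voltage (mV)
#' @param K_out external K+ (mol/L); must be > 0
#' @param internal a \code{conditions} object supplying temperature and the
#'   internal concentrations
#' @return a list of class \code{reduced_params}: \code{substrate = "H"},
#'   \code{K_X} (mol/L), \code{I_Xmax} (A, signed), \code{V},
#'   \code{co_substrate_conc}
#' @export
km_proton <- function(params, V, K_out, internal = conditions()) {
  if (!is.finite(K_out) || K_out <= 0)
    stop("K_out must be > 0", call. = FALSE)
  cond <- conditions(V = V, T_K = internal$T_K, K_out = K_out, H_out = 0,
                     K_in = internal$K_in, H_in = internal$H_in)
  r <- resolve_rates(params, cond)
  k23K <- params$k23_0 * K_out
  D <- r$k41 * (r$k34 + r$k32) + r$k32 * r$k43 +
    k23K * (r$k41 + r$k43 + r$k34)
  if (D <= 0) stop("degenerate system: zero saturation denominator",
                   call. = FALSE)
  K_H <- (r$k21 * (
    r$k41 * (r$k34 + r$k32) +
      r$k43 * r$k32 +
      r$k14 * (r$k43 * (1 + r$k32 / r$k21) + r$k34 + r$k32) +
      k23K * (r$k41 * r$k34 + r$k14 * r$k43 + r$k34 * r$k14) / r$k21)) /
    (params$k12_0 * D)
  I_Hmax <- -(2 * .E_CHARGE * params$N * params$k41_0 * params$k12_0 *
                params$k23_0 * params$k34 * K_out * exp(-r$u)) /
    (params$k12_0 * D)
  structure(list(substrate = "H", K_X = K_H, I_Xmax = I_Hmax, V = V,
                 co_substrate_conc = K_out),
            class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf(
    "Reduced Michaelis parameters (%s+): K_%s = %.4g uM, I_max = %.4g nA at %g mV\n",
    x$substrate, x$substrate, x$K_X * 1e6, x$I_Xmax * 1e9, x$V))
  invisible(x)
}

#' Voltage scan of the apparent Michaelis parameters
#'
#' Evaluates \code{\link{km_imax_potassium}} and \code{\link{km_proton}}
#' on a grid of voltages at fixed external concentrations.
#'
#' @param params a \code{kinetic_params} object
#' @param V_grid numeric vector of voltages (mV); nonempty
#' @param H_out external H+ used for the K+ scan (mol/L)
#' @param K_out external K+ used for the H+ scan (mol/L)
#' @param internal a \code{conditions} object with internal settings
#' @return a data.frame with columns \code{V_mV}, \code{K_K_M},
#'   \code{I_Kmax_A}, \code{K_H_M}
#' @export
voltage_scan <- function(params, V_grid, H_out = 10^-4.5, K_out = 200e-6,
                         internal = conditions()) {
  if (length(V_grid) == 0) stop("V_grid must be nonempty", call. = FALSE)
  rows <- lapply(V_grid, function(v) {
    kk <- km_imax_potassium(params, v, H_out, internal)
    kh <- km_proton(params, v, K_out, internal)
    data.frame(V_mV = v, K_K_M = kk$K_X, I_Kmax_A = kk$I_Xmax,
               K_H_M = kh$K_X)
  })
  do.call(rbind, rows)
}

#' Rescale the external K+ binding step (mutant scenario)
#'
#' Emulates a K+-site mutation by dividing the external K+ binding
#' constant k23_0 by \code{factor} (mode \code{"k23_down"}) or multiplying
#' the debinding constant k32 by \code{factor} (mode \code{"k32_up"}).
#' The designated derived constant is recomputed so the
#' microscopic-reversibility identity still holds on the result.
#'
#' @param params a \code{kinetic_params} object
#' @param factor positive scale factor (default 1000)
#' @param mode \code{"k23_down"} or \code{"k32_up"}
#' @return a new \code{kinetic_params} object
#' @export
apply_mutant_scaling <- function(params, factor = 1000,
                                 mode = c("k23_down", "k32_up")) {
  mode <- match.arg(mode)
  if (!is.finite(factor) || factor <= 0)
    stop("factor must be > 0", call. = FALSE)
  k23_0 <- params$k23_0
  k32 <- params$k32
  if (mode == "k23_down") k23_0 <- k23_0 / factor else k32 <- k32 * factor
  kinetic_params(k12_0 = params$k12_0, k21 = params$k21, k23_0 = k23_0,
                 k32 = k32, k34 = params$k34, k43_0 = params$k43_0,
                 k14_0 = params$k14_0, k41_0 = params$k41_0, N = params$N,
                 derived_constant = params$derived_constant)
}
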