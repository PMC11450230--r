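## Closed-form King-Altman solution of the four-state cycle and its
## numeric null-space oracle.

#' The sixteen King-Altman directed-tree terms
#'
#' Each term C[i, j] is a product of three effective rate constants; the
#' sum over j of row i is proportional to the steady-state occupancy of
#' state Ci.  The terms are the directed spanning trees of the four-state
#' cycle rooted at each state.
#'
#' @param rates a \code{resolved_rates} object, or any list with elements
#'   k12, k21, k23, k32, k34, k43, k14, k41 (all >= 0)
#' @return a 4 x 4 numeric matrix of tree terms
#' @export
king_altman_terms <- function(rates) {
  r <- rates
  with(r, matrix(c(
    k23 * k34 * k41,  k34 * k41 * k21,  k41 * k21 * k32,  k21 * k32 * k43,
    k34 * k41 * k12,  k41 * k12 * k32,  k12 * k32 * k43,  k32 * k43 * k14,
    k41 * k12 * k23,  k12 * k23 * k43,  k23 * k43 * k14,  k43 * k14 * k21,
    k12 * k23 * k34,  k23 * k34 * k14,  k34 * k14 * k21,  k14 * k21 * k32),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("C", 1:4), paste0("tree", 1:4))))
}

#' Steady-state occupancies by the King-Altman closed form
#'
#' Occupancy of state Ci is the i-th row sum of the sixteen directed-tree
#' terms divided by their grand total.
#'
#' @inheritParams king_altman_terms
#' @return a list with \code{occupancy} (named numeric, sums to 1),
#'   \code{terms} (the 4 x 4 matrix) and \code{denominator} (their sum)
#' @export
king_altman_occupancies <- function(rates) {
  k <- unlist(rates[c("k12", "k21", "k23", "k32", "k34", "k43", "k14", "k41")])
  if (any(!is.finite(k)) || any(k < 0))
    stop("all effective rates must be finite and >= 0", call. = FALSE)
  terms <- king_altman_terms(rates)
  denom <- sum(terms)
  if (denom <= 0)
    stop("degenerate system: all King-Altman terms are zero", call. = FALSE)
  occ <- rowSums(terms) / denom
  list(occupancy = occ, terms = terms, denominator = denom)
}

#' Stationary distribution by direct linear solve (numeric oracle)
#'
#' Solves the four-state master equation dC/dt = Q C = 0 with the
#' normalisation sum(C) = 1 by replacing one balance row with the
#' normalisation row.  Makes no use of the King-Altman closed form; used
#' to cross-check it.
#'
#' @inheritParams king_altman_terms
#' @return named numeric vector of occupancies C1..C4
#' @export
numeric_occupancy_oracle <- function(rates) {
  r <- rates
  Q <- matrix(0, 4, 4)
  ## column j holds outflows from state j; Q[i, j] = rate j -> i
  Q[2, 1] <- r$k12; Q[4, 1] <- r$k14
  Q[1, 2] <- r$k21; Q[3, 2] <- r$k23
  Q[2, 3] <- r$k32; Q[4, 3] <- r$k34
  Q[3, 4] <- r$k43; Q[1, 4] <- r$k41
  diag(Q) <- -colSums(Q)
  A <- rbind(Q[1:3, ], rep(1, 4))
  b <- c(0, 0, 0, 1)
  occ <- tryCatch(solve(A, b), error = function(e)
    stop("degenerate system: stationary distribution is not unique",
         call. = FALSE))
  if (max(abs(Q %*% occ)) > 1e-8 * max(abs(Q)))
    stop("degenerate system: stationary distribution is not unique",
         call. = FALSE)
  names(occ) <- paste0("C", 1:4)
  occ
}

#' Steady-state transport current of the symport cycle
#'
#' Net current carried by the 2-charge conformational step, computed two
#' ways that must agree: the occupancy form \code{I = 2 e N (k14 C1 - k41 C4)}
#' and the factored King-Altman closed form whose numerator is
#' \code{2 e N k41_0 k12_0 k23_0 k34 ([H]i [K]i e^u - [H]o [K]o e^-u)} with
#' \code{u = FV/RT}.  Negative current means net K+/H+ entry into the
#' cytosol (physiological uptake).  The current splits exactly into an
#' outward component \code{I_plus >= 0} and an inward component
#' \code{I_minus <= 0} with \code{I = I_plus + I_minus}.
#'
#' @param params a \code{kinetic_params} object
#' @param cond a \code{conditions} object
#' @return an object of class \code{steady_state_solution}: fields
#'   \code{occupancy}, \code{terms}, \code{I}, \code{I_plus},
#'   \code{I_minus} (A), \code{I_occupancy_form} (A, the Eq.-6 route) and
#'   \code{rates}
#' @examples
#' p <- kinetic_params(k12_0 = 1e7, k21 = 10, k23_0 = 1e6, k32 = 100,
#'                     k34 = 100, k14_0 = 1e5, k41_0 = 0.1, N = 1e10)
#' s <- steady_state_current(p, conditions(V = -120, pH_out = 4.5,
#'                                         K_out = 20e-6))
#' s$I < 0  # inward under physiological gradients
#' @export
steady_state_current <- function(params, cond) {
  r <- resolve_rates(params, cond)
  ka <- king_altman_occupancies(r)
  pref <- 2 * .E_CHARGE * params$N *
    params$k41_0 * params$k12_0 * params$k23_0 * params$k34
  I_plus <- pref * cond$H_in * cond$K_in * exp(r$u) / ka$denominator
  I_minus <- -pref * cond$H_out * cond$K_out * exp(-r$u) / ka$denominator
  I <- I_plus + I_minus
  I_occ <- 2 * .E_CHARGE * params$N *
    (r$k14 * ka$occupancy[["C1"]] - r$k41 * ka$occupancy[["C4"]])
  structure(list(occupancy = ka$occupancy, terms = ka$terms,
                 I = I, I_plus = I_plus, I_minus = I_minus,
                 I_occupancy_form = I_occ, rates = r),
            class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat("Steady-state symport solution\n")
  cat("  occupancies:",
      paste(sprintf("%s=%.4f", names(x$occupancy), x$occupancy),
            collapse = ", "), "\n")
  cat(sprintf("  I = %.6g nA (I+ = %.6g, I- = %.6g)\n",
              x$I * 1e9, x$I_plus * 1e9, x$I_minus * 1e9))
  invisible(x)
}

#' Reversal potential of 1:1 K+/H+ symport
#'
#' Voltage at which the net transport current vanishes.  Zeroing the
#' factored numerator of the closed-form current gives
#' \deqn{V_rev = (RT / 2F) \ln([H+]_o [K+]_o / ([H+]_i [K+]_i))}
#' independent of the rate constants; two elementary charges move per
#' cycle, hence the factor 2.
#'
#' @param cond a \code{conditions} object (all four concentrations > 0)
#' @return reversal potential in mV
#' @examples
#' reversal_potential(conditions(V = 0, K_out = 1e-3, K_in = 1e-3,
#'                               pH_out = 7, pH_in = 7)) # 0 mV
#' @export
reversal_potential <- function(cond) {
  conc <- c(cond$K_out, cond$H_out, cond$K_in, cond$H_in)
  if (any(conc <= 0))
    stop("reversal potential undefined: all four concentrations must be > 0",
         call. = FALSE)
  1000 * (.GAS_R * cond$T_K / (2 * .FARADAY)) *
    log((cond$H_out * cond$K_out) / (cond$H_in * cond$K_in))
}
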