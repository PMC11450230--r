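## Equilibrium uptake limits: how low an external K+ concentration can
## still be accumulated by a K+ channel versus an n:1 H+-coupled symporter.

#' Thermodynamic uptake scenario
#'
#' @param K_in cytosolic K+ concentration (mol/L), > 0
#' @param V membrane voltage (mV)
#' @param delta_pH external-minus-internal pH difference (pH units;
#'   negative when the outside is more acidic)
#' @param n_H protons co-transported per K+ (integer >= 0; 0 = uncoupled
#'   channel)
#' @param slope decadic Nernst slope (mV per tenfold concentration change);
#'   60 mV by default, or use \code{nernst_slope(T_K)} for a
#'   temperature-derived value
#' @return an object of class \code{thermo_scenario}
#' @export
thermo_scenario <- function(K_in = 0.150, V = -180, delta_pH = -2,
                            n_H = 1, slope = 60) {
  if (!is.finite(K_in) || K_in <= 0) stop("K_in must be > 0", call. = FALSE)
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (!is.finite(n_H) || n_H < 0 || n_H != round(n_H))
    stop("n_H must be an integer >= 0", call. = FALSE)
  structure(list(K_in = K_in, V = V, delta_pH = delta_pH, n_H = n_H,
                 slope = slope), class = "thermo_scenario")
}

#' Temperature-derived decadic Nernst slope
#'
#' \code{RT ln(10) / F} in mV (59.16 mV at 25 degrees C).
#'
#' @param T_K absolute temperature (K)
#' @return slope in mV per tenfold
#' @export
nernst_slope <- function(T_K = DEFAULT_TEMPERATURE) {
  1000 * .GAS_R * T_K * log(10) / .FARADAY
}

#' Minimal external K+ for net uptake through a K+ channel
#'
#' An uncoupled channel equilibrates at the K+ Nernst potential; net
#' influx requires \code{[K+]o >= K_in * 10^(V / slope)}.
#'
#' @param s a \code{thermo_scenario} (its \code{n_H} is ignored; a channel
#'   moves K+ alone)
#' @return limiting external K+ concentration (mol/L)
#' @examples
#' # 150 mM internal K+, -180 mV, 60 mV/decade -> 150 uM
#' channel_uptake_limit(thermo_scenario(K_in = 0.150, V = -180))
#' @export
channel_uptake_limit <- function(s) {
  stopifnot(inherits(s, "thermo_scenario"))
  s$K_in * 10^(s$V / s$slope)
}

#' Minimal external K+ for net uptake through an n_H:1 H+/K+ symporter
#'
#' Each cycle moves one K+ plus \code{n_H} protons down a combined
#' electrochemical gradient, so the equilibrium condition gains the proton
#' gradient and an extra charge per coupled proton:
#' \deqn{[K+]_o^{lim} = K_{in} 10^{n_H \Delta pH} 10^{(1 + n_H) V / slope}}
#' with \code{delta_pH = pH_out - pH_in}.  With \code{n_H = 0} this reduces
#' to the channel limit.
#'
#' @param s a \code{thermo_scenario}
#' @return limiting external K+ concentration (mol/L)
#' @examples
#' # 2 pH units more acidic outside, -180 mV: 1.5 nM
#' symport_uptake_limit(thermo_scenario(K_in = 0.150, V = -180,
#'                                      delta_pH = -2, n_H = 1))
#' @export
symport_uptake_limit <- function(s) {
  stopifnot(inherits(s, "thermo_scenario"))
  s$K_in * 10^(s$n_H * s$delta_pH) * 10^((1 + s$n_H) * s$V / s$slope)
}

#' Accumulation advantage of coupled over uncoupled uptake
#'
#' Ratio of the channel uptake limit to the symport uptake limit for
#' scenarios sharing \code{K_in} and \code{V}; equals
#' \code{10^(-n_H delta_pH - n_H V / slope)} algebraically.
#'
#' @param s_channel scenario for the channel (n_H ignored)
#' @param s_symport scenario for the symporter
#' @return dimensionless ratio (> 1 when coupling helps)
#' @export
accumulation_advantage <- function(s_channel, s_symport = s_channel) {
  if (s_channel$K_in != s_symport$K_in || s_channel$V != s_symport$V)
    stop("scenarios must share K_in and V", call. = FALSE)
  channel_uptake_limit(s_channel) / symport_uptake_limit(s_symport)
}
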