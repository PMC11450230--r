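## Seeded synthetic-data generator: noisy dose-response datasets and
## TEVC-like concentration-step current traces with the statistical
## structure the fitting layer assumes.

#' Measurement noise model for synthetic recordings
#'
#' @param cv multiplicative coefficient of variation (dimensionless, >= 0)
#' @param additive_sd additive noise SD (A, >= 0)
#' @param leak_mean,leak_sd background/leak current mean and SD (A); the
#'   defaults are the magnitude of K+ control-oocyte leak currents
#'   (about -85 +/- 7 nA)
#' @param seed integer RNG seed; mandatory so every synthetic dataset is
#'   reproducible
#' @return an object of class \code{noise_model}
#' @export
noise_model <- function(cv = 0.05, additive_sd = 0, leak_mean = -84.55e-9,
                        leak_sd = 7.2e-9, seed) {
  if (missing(seed)) stop("noise_model requires an explicit seed",
                          call. = FALSE)
  if (cv < 0 || additive_sd < 0 || leak_sd < 0)
    stop("cv and SDs must be >= 0", call. = FALSE)
  structure(list(cv = cv, additive_sd = additive_sd, leak_mean = leak_mean,
                 leak_sd = leak_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Concentration-step TEVC protocol
#'
#' An ordered sequence of solution-application segments at a constant
#' holding voltage.  The canonical protocol holds at -120 mV, records a
#' zero-substrate baseline, then applies one test concentration for 120 s.
#'
#' @param holding_mV holding voltage (mV)
#' @param segments data.frame with columns \code{duration_s} (> 0),
#'   \code{substrate}, \code{conc_M} (>= 0) and \code{pH}
#' @param sampling_Hz sampling rate (Hz, > 0)
#' @return an object of class \code{step_protocol}
#' @export
step_protocol <- function(holding_mV = -120,
                          segments = data.frame(
                            duration_s = c(10, 120),
                            substrate = "K",
                            conc_M = c(0, 200e-6),
                            pH = 4.5),
                          sampling_Hz = 10) {
  stopifnot(is.data.frame(segments),
            all(c("duration_s", "substrate", "conc_M", "pH") %in%
                  names(segments)))
  if (any(segments$duration_s <= 0) || sampling_Hz <= 0)
    stop("durations and sampling rate must be > 0", call. = FALSE)
  structure(list(holding_mV = holding_mV, segments = segments,
                 sampling_Hz = sampling_Hz), class = "step_protocol")
}

## run code under a private RNG stream, restoring the caller's stream
.with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Generate a noisy dose-response dataset from a known truth
#'
#' Responses are \code{model(conc) * (1 + cv * z) + additive_sd * z'} with
#' z, z' standard normal, drawn from a private seeded stream.  The
#' generating truth is attached to the result for round-trip tests.
#'
#' @param truth either a function \code{conc -> response magnitude} or a
#'   list with elements \code{I_max}, \code{K_m} and optionally \code{h}
#'   (Hill coefficient, default 1)
#' @param concs concentrations (mol/L), nonempty
#' @param noise a \code{\link{noise_model}}
#' @param n_replicates number of replicate "oocytes" (>= 1)
#' @param substrate substrate tag stored on the dataset
#' @return a \code{\link{dose_response_dataset}} with a \code{truth}
#'   attribute
#' @examples
#' nm <- noise_model(cv = 0.05, seed = 42)
#' d <- generate_dose_response(list(I_max = 1, K_m = 23.56e-6),
#'                             c(10, 20, 50, 100, 200, 500, 1000, 2000) * 1e-6,
#'                             nm, n_replicates = 5)
#' @export
generate_dose_response <- function(truth, concs, noise, n_replicates = 1L,
                                   substrate = "K") {
  if (!length(concs)) stop("concs must be nonempty", call. = FALSE)
  stopifnot(inherits(noise, "noise_model"), n_replicates >= 1)
  model <- if (is.function(truth)) truth else {
    h <- if (is.null(truth$h)) 1 else truth$h
    function(conc) truth$I_max * conc^h / (conc^h + truth$K_m^h)
  }
  clean <- model(concs)
  d <- .with_seed(noise$seed, {
    rows <- lapply(seq_len(n_replicates), function(rep) {
      z <- stats::rnorm(length(concs))
      z2 <- stats::rnorm(length(concs))
      resp <- clean * (1 + noise$cv * z) + noise$additive_sd * z2
      data.frame(conc_M = concs, response = pmax(resp, 0), replicate = rep)
    })
    do.call(rbind, rows)
  })
  out <- dose_response_dataset(d$conc_M, d$response, substrate = substrate,
                               replicate = d$replicate)
  attr(out, "truth") <- list(model = model, clean = clean, concs = concs,
                             truth = if (!is.function(truth)) truth)
  out
}

#' Phenomenological peak/steady-state preset for trace simulation
#'
#' Encodes the concentration- and pH-graded behaviour of wild-type-like
#' K+/H+ symport currents:
#' \itemize{
#'   \item peak magnitude: Michaelis-Menten in [K+] times a Hill factor in
#'     [H+] (K_m 23.56 uM at pH 4.5, K_H 4.81 uM, h 1.67);
#'   \item the apparent K_m tightens with external alkalinisation in
#'     proportion to proton-site occupancy, so a fixed [K+] sits further
#'     above K_m at higher pH;
#'   \item steady-state magnitude: the bell-shaped curve (scale
#'     \code{r_ss}, offset \code{s_leakfree}) sharing the same pH factor,
#'     capped at the peak.  High [K+]/K_m ratios therefore inactivate
#'     nearly completely, low ratios not at all.
#' }
#'
#' @param I_peak_max saturating peak magnitude (A)
#' @param K_m_ref apparent K+ half-saturation at the reference pH (mol/L)
#' @param K_H H+ half-activation (mol/L)
#' @param h Hill coefficient of proton activation
#' @param pH_ref reference pH at which \code{K_m_ref} applies
#' @param r_ss steady-state bell scale relative to \code{I_peak_max}
#' @param s_offset steady-state offset relative to \code{I_peak_max}
#' @return a list of class \code{trace_preset} with functions
#'   \code{peak(conc, pH)} and \code{ss(conc, pH)} returning magnitudes (A)
#' @export
hak5_trace_preset <- function(I_peak_max = 1e-6, K_m_ref = 23.56e-6,
                              K_H = 4.81e-6, h = 1.67, pH_ref = 4.5,
                              r_ss = 1.2, s_offset = 0.05) {
  g <- function(H) H / (H + K_H)
  km_of_pH <- function(pH) K_m_ref * g(10^-pH) / g(10^-pH_ref)
  hill <- function(H) H^h / (H^h + K_H^h)
  peak <- function(conc, pH) {
    km <- km_of_pH(pH)
    I_peak_max * hill(10^-pH) * conc / (conc + km)
  }
  ss <- function(conc, pH) {
    km <- km_of_pH(pH)
    bell <- conc * km / (conc + km)^2
    pmin(peak(conc, pH),
         hill(10^-pH) * I_peak_max * (r_ss * bell + s_offset))
  }
  structure(list(peak = peak, ss = ss, km_of_pH = km_of_pH,
                 I_peak_max = I_peak_max, K_H = K_H, h = h),
            class = "trace_preset")
}

#' Simulate a TEVC concentration-step current trace
#'
#' Per segment, the substrate-induced current rises mono-exponentially
#' with \code{tau_act} toward the peak level and simultaneously relaxes
#' with \code{tau_inact} toward the bell-shaped steady-state level for
#' that concentration and pH:
#' \deqn{\Delta I(t) = (1 - e^{-t/\tau_{act}})
#'       (I_{ss} + (I_{peak} - I_{ss}) e^{-t/\tau_{inact}})}
#' A leak current (drawn once per trace), a per-trace multiplicative gain
#' of CV \code{cv}, and additive white noise are applied on top.  The
#' noiseless per-segment peak and steady-state magnitudes actually realized
#' at the sample times are stored as the truth record.
#'
#' @param model a \code{\link{hak5_trace_preset}}, or a
#'   \code{kinetic_params} object (peak levels then come from
#'   \code{\link{steady_state_current}} at the holding voltage and the
#'   steady-state level from the bell curve at the model's own apparent
#'   K_m, with the preset's default relative scale and offset)
#' @param protocol a \code{\link{step_protocol}}
#' @param tau_act activation time constant (s)
#' @param tau_inact inactivation time constant (s)
#' @param noise a \code{\link{noise_model}}; use \code{cv = 0,
#'   additive_sd = 0, leak_sd = 0} for a noiseless trace
#' @param internal a \code{conditions} object used when \code{model} is a
#'   \code{kinetic_params} (internal concentrations, temperature)
#' @return an object of class \code{tevc_trace}: a list with
#'   \code{time_s}, \code{current_A}, attached \code{protocol} and a
#'   \code{truth} attribute (per-segment realized dI_peak, dI_ss, leak,
#'   seed)
#' @export
simulate_tevc_trace <- function(model, protocol = step_protocol(),
                                tau_act = 0.7, tau_inact = 20,
                                noise = noise_model(seed = 1),
                                internal = conditions()) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (inherits(model, "kinetic_params")) {
    params <- model
    V <- protocol$holding_mV
    peak_fun <- function(conc, pH) {
      if (conc <= 0) return(0)
      cond <- conditions(V = V, T_K = internal$T_K, K_out = conc,
                         H_out = 10^-pH, K_in = internal$K_in,
                         H_in = internal$H_in)
      abs(steady_state_current(params, cond)$I)
    }
    ss_fun <- function(conc, pH) {
      if (conc <= 0) return(0)
      red <- km_imax_potassium(params, V, 10^-pH, internal)
      km <- red$K_X
      bell <- conc * km / (conc + km)^2
      pmin(peak_fun(conc, pH),
           abs(red$I_Xmax) * (1.2 * bell + 0.05))
    }
  } else if (inherits(model, "trace_preset")) {
    peak_fun <- function(conc, pH) if (conc <= 0) 0 else model$peak(conc, pH)
    ss_fun <- function(conc, pH) if (conc <= 0) 0 else model$ss(conc, pH)
  } else stop("model must be a trace_preset or kinetic_params",
              call. = FALSE)

  segs <- protocol$segments
  dt <- 1 / protocol$sampling_Hz
  bounds <- cumsum(c(0, segs$duration_s))
  time_s <- seq(0, sum(segs$duration_s) - dt, by = dt)
  seg_of <- findInterval(time_s, bounds, rightmost.closed = FALSE)
  dI <- numeric(length(time_s))
  truth <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    idx <- which(seg_of == i)
    t <- time_s[idx] - bounds[i]
    p <- peak_fun(segs$conc_M[i], segs$pH[i])
    s <- ss_fun(segs$conc_M[i], segs$pH[i])
    wave <- (1 - exp(-t / tau_act)) * (s + (p - s) * exp(-t / tau_inact))
    dI[idx] <- wave
    ss_window <- t >= 0.95 * segs$duration_s[i]
    truth[[i]] <- data.frame(
      segment = i, conc_M = segs$conc_M[i], pH = segs$pH[i],
      dI_peak_A = if (length(wave)) max(wave) else 0,
      dI_ss_A = if (any(ss_window)) mean(wave[ss_window]) else NA_real_,
      target_peak_A = p, target_ss_A = s)
  }
  truth <- do.call(rbind, truth)
  out <- .with_seed(noise$seed, {
    leak <- noise$leak_mean + noise$leak_sd * stats::rnorm(1)
    gain <- 1 + noise$cv * stats::rnorm(1)
    current <- leak - gain * dI +
      noise$additive_sd * stats::rnorm(length(dI))
    list(leak = leak, current = current)
  })
  trace <- structure(list(time_s = time_s, current_A = out$current),
                     class = "tevc_trace")
  attr(trace, "protocol") <- protocol
  attr(trace, "truth") <- list(segments = truth, leak_A = out$leak,
                               tau_act = tau_act, tau_inact = tau_inact,
                               seed = noise$seed)
  trace
}

#' @export
print.tevc_trace <- function(x, ...) {
  cat(sprintf("TEVC trace: %d samples over %.1f s, current %.4g..%.4g nA\n",
              length(x$time_s), max(x$time_s),
              min(x$current_A) * 1e9, max(x$current_A) * 1e9))
  invisible(x)
}
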