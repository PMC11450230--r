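## Dose-response fitting layer for TEVC peak and steady-state currents:
## Michaelis-Menten and Hill fits of |dI_peak|, the bell-shaped
## steady-state fit with fixed Km, and inactivation metrics.

#' Dose-response dataset
#'
#' A table of (concentration, response-magnitude) points.  Responses are
#' magnitudes |dI| (A, or normalized), so they are >= 0; the inward sign
#' convention of the kinetic layer is dropped here, matching how TEVC
#' dose-response plots report positive peak-current changes.
#'
#' @param conc_M concentrations (mol/L), strictly positive
#' @param response response magnitudes, >= 0 (A or normalized)
#' @param substrate substrate tag, e.g. "K" or "H"
#' @param replicate optional replicate id per point
#' @param V_mV,pH optional metadata
#' @return a data.frame of class \code{dose_response_dataset}, sorted by
#'   concentration within replicate
#' @export
dose_response_dataset <- function(conc_M, response, substrate = "K",
                                  replicate = 1L, V_mV = NA_real_,
                                  pH = NA_real_) {
  if (length(conc_M) != length(response))
    stop("conc_M and response lengths differ", call. = FALSE)
  if (any(!is.finite(conc_M)) || any(conc_M <= 0))
    stop("concentrations must be finite and > 0", call. = FALSE)
  if (any(!is.finite(response)) || any(response < 0))
    stop("responses must be finite and >= 0", call. = FALSE)
  d <- data.frame(conc_M = conc_M, response = response,
                  replicate = rep_len(replicate, length(conc_M)))
  if (anyDuplicated(d[c("conc_M", "replicate")]))
    stop("concentrations must be distinct within each replicate",
         call. = FALSE)
  d <- d[order(d$replicate, d$conc_M), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, substrate = substrate, V_mV = V_mV, pH = pH,
            class = c("dose_response_dataset", "data.frame"))
}

## log-interpolated concentration at half the largest response: robust
## starting value for Km
.km_start <- function(conc, resp) {
  half <- max(resp) / 2
  i <- which.min(abs(resp - half))
  above <- which(resp >= half)
  if (length(above) && min(above) > 1) {
    j <- min(above)
    lo <- conc[j - 1]; hi <- conc[j]
    rlo <- resp[j - 1]; rhi <- resp[j]
    if (rhi > rlo)
      return(exp(log(lo) + (half - rlo) / (rhi - rlo) * (log(hi) - log(lo))))
  }
  conc[i]
}

.fit_result <- function(kind, estimate, se, residuals, converged,
                        fitted_fun, fit = NULL) {
  structure(list(kind = kind, estimate = estimate, se = se,
                 residuals = residuals,
                 residual_norm = sqrt(sum(residuals^2)),
                 converged = converged, fitted = fitted_fun, fit = fit),
            class = "hak5_fit")
}

#' @export
print.hak5_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s)\n", x$kind,
              if (x$converged) "converged" else "NOT converged"))
  est <- x$estimate
  for (nm in names(est))
    cat(sprintf("  %-10s %.6g  (se %.3g)\n", nm, est[[nm]],
                if (nm %in% names(x$se)) x$se[[nm]] else NA))
  cat(sprintf("  residual norm %.4g on %d points\n", x$residual_norm,
              length(x$residuals)))
  invisible(x)
}

.as_dr <- function(data) {
  if (!inherits(data, "dose_response_dataset"))
    stop("data must be a dose_response_dataset", call. = FALSE)
  data
}

#' Michaelis-Menten fit of peak currents
#'
#' Least-squares fit of \code{response = I_max [X] / ([X] + K_m)} by
#' Levenberg-Marquardt.  K_m is initialized at the (log-interpolated)
#' concentration nearest half the largest response.
#'
#' @param data a \code{\link{dose_response_dataset}} with >= 3 points
#'   spanning at least a factor 10 in concentration
#' @param weights optional per-point weights (e.g. 1/se^2)
#' @return a \code{hak5_fit} with estimates \code{I_max}, \code{K_m}
#' @export
fit_michaelis_menten <- function(data, weights = NULL) {
  data <- .as_dr(data)
  if (nrow(data) < 3)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  if (max(data$conc_M) / min(data$conc_M) < 10)
    stop("concentrations must span at least a factor 10", call. = FALSE)
  start <- list(I_max = max(data$response),
                K_m = .km_start(data$conc_M, data$response))
  args <- list(response ~ I_max * conc_M / (conc_M + K_m),
               data = data, start = start,
               lower = c(I_max = 0, K_m = .Machine$double.xmin),
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) stop("Michaelis-Menten fit failed: ",
                             conditionMessage(e), call. = FALSE))
  co <- summary(fit)$coefficients
  est <- as.list(co[, "Estimate"])
  f <- function(conc) est$I_max * conc / (conc + est$K_m)
  .fit_result("Michaelis-Menten", est, as.list(co[, "Std. Error"]),
              residuals(fit), fit$convInfo$isConv, f, fit)
}

#' Hill fit of dose-response data
#'
#' Least-squares fit of
#' \code{response = I_max [X]^h / ([X]^h + K_m^h)} with the Hill
#' coefficient h free (initialized at 1, reducing to Michaelis-Menten).
#'
#' @param data a \code{\link{dose_response_dataset}} with >= 4 points
#' @param weights optional per-point weights
#' @param h_init starting value for the Hill coefficient
#' @return a \code{hak5_fit} with estimates \code{I_max}, \code{K_m},
#'   \code{h}
#' @export
fit_hill <- function(data, weights = NULL, h_init = 1) {
  data <- .as_dr(data)
  if (nrow(data) < 4)
    stop("insufficient data: need at least 4 points", call. = FALSE)
  start <- list(I_max = max(data$response),
                K_m = .km_start(data$conc_M, data$response), h = h_init)
  args <- list(response ~ I_max * conc_M^h / (conc_M^h + K_m^h),
               data = data, start = start,
               lower = c(I_max = 0, K_m = .Machine$double.xmin, h = 1e-3),
               upper = c(I_max = Inf, K_m = Inf, h = 20),
               control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) stop("Hill fit failed: ", conditionMessage(e),
                             call. = FALSE))
  co <- summary(fit)$coefficients
  est <- as.list(co[, "Estimate"])
  f <- function(conc) est$I_max * conc^est$h / (conc^est$h + est$K_m^est$h)
  .fit_result("Hill", est, as.list(co[, "Std. Error"]),
              residuals(fit), fit$convInfo$isConv, f, fit)
}

#' Bell-shaped steady-state current fit with fixed Km
#'
#' Fits the steady-state magnitude
#' \deqn{I_{ss}([K]) = \frac{[K]}{[K]+K_m}\frac{I_{max}}{[K]/K_m+1} + I_s
#'     = I_{max}\frac{[K] K_m}{([K]+K_m)^2} + I_s}
#' with K_m held at the value obtained from the peak-current fit.  The
#' model is linear in (I_max, I_s), so ordinary least squares is exact.
#'
#' @param data a \code{\link{dose_response_dataset}} of steady-state
#'   magnitudes with >= 3 points
#' @param K_m_fixed the fixed half-saturation constant (mol/L), > 0
#' @return a \code{hak5_fit} with estimates \code{I_max}, \code{I_s} and
#'   the fixed \code{K_m}
#' @export
fit_steady_state_bell <- function(data, K_m_fixed) {
  data <- .as_dr(data)
  if (!is.finite(K_m_fixed) || K_m_fixed <= 0)
    stop("K_m_fixed must be > 0", call. = FALSE)
  if (nrow(data) < 3)
    stop("insufficient data: need at least 3 points", call. = FALSE)
  x <- data$conc_M * K_m_fixed / (data$conc_M + K_m_fixed)^2
  fit <- stats::lm(data$response ~ x)
  # summary.lm warns on exact (noiseless) data; the coefficients are fine
  co <- suppressWarnings(summary(fit))$coefficients
  est <- list(I_max = unname(co["x", "Estimate"]),
              I_s = unname(co["(Intercept)", "Estimate"]), K_m = K_m_fixed)
  se <- list(I_max = unname(co["x", "Std. Error"]),
             I_s = unname(co["(Intercept)", "Std. Error"]))
  f <- function(conc)
    est$I_max * conc * K_m_fixed / (conc + K_m_fixed)^2 + est$I_s
  .fit_result("steady-state bell", est, se, stats::residuals(fit), TRUE, f,
              fit)
}

#' Concentration at which the bell-shaped steady-state current peaks
#'
#' The concentration-dependent part of the steady-state bell curve,
#' \code{[K] K_m / ([K]+K_m)^2}, is maximal exactly at \code{[K] = K_m};
#' the scale I_max and offset I_s do not move the argmax.
#'
#' @param K_m half-saturation constant (mol/L), > 0
#' @return the argmax concentration (= K_m)
#' @export
bell_argmax <- function(K_m) {
  if (any(!is.finite(K_m)) || any(K_m <= 0))
    stop("K_m must be > 0", call. = FALSE)
  K_m
}

#' Percentage of current inactivation
#'
#' \code{100 * (dI_peak - dI_ss) / dI_peak}: 0 when the current does not
#' decay from its peak, 100 when it vanishes entirely.
#'
#' @param dI_peak peak current change magnitude (> 0)
#' @param dI_ss steady-state current change magnitude (>= 0)
#' @return percentage
#' @export
percent_inactivation <- function(dI_peak, dI_ss) {
  if (any(!is.finite(dI_peak)) || any(dI_peak <= 0))
    stop("undefined metric: dI_peak must be > 0", call. = FALSE)
  if (any(!is.finite(dI_ss)) || any(dI_ss < 0))
    stop("dI_ss must be >= 0", call. = FALSE)
  100 * (dI_peak - dI_ss) / dI_peak
}

#' Extract peak and steady-state features from a TEVC trace
#'
#' The baseline is the median current over the pre-step (zero-substrate)
#' window.  Within each substrate-application segment, the peak change is
#' \code{max |I - baseline|} and the steady-state change is the mean of
#' \code{|I - baseline|} over the final 5 percent of the segment.
#'
#' @param trace a \code{\link{tevc_trace}}
#' @param protocol the \code{\link{step_protocol}} the trace was recorded
#'   under (defaults to the one attached to the trace)
#' @return a data.frame with one row per substrate segment: columns
#'   \code{segment}, \code{conc_M}, \code{pH}, \code{dI_peak_A},
#'   \code{dI_ss_A}, \code{t_peak_s}, \code{pct_inactivation}
#' @export
extract_trace_features <- function(trace, protocol = attr(trace, "protocol")) {
  if (is.null(protocol))
    stop("feature extraction requires the step protocol", call. = FALSE)
  segs <- protocol$segments
  bounds <- cumsum(c(0, segs$duration_s))
  if (segs$conc_M[1] != 0)
    stop("feature extraction requires a zero-substrate baseline segment ",
         "before the first step", call. = FALSE)
  in_seg <- function(i) trace$time_s >= bounds[i] & trace$time_s < bounds[i + 1]
  if (!any(in_seg(1)))
    stop("trace does not cover the baseline window", call. = FALSE)
  baseline <- stats::median(trace$current_A[in_seg(1)])
  steps <- which(segs$conc_M > 0)
  rows <- lapply(steps, function(i) {
    idx <- which(in_seg(i))
    if (!length(idx))
      stop("trace does not cover segment ", i, call. = FALSE)
    t <- trace$time_s[idx] - bounds[i]
    dI <- abs(trace$current_A[idx] - baseline)
    ss_window <- t >= 0.95 * segs$duration_s[i]
    if (!any(ss_window)) ss_window[length(t)] <- TRUE
    peak_i <- which.max(dI)
    dI_peak <- dI[peak_i]
    dI_ss <- mean(dI[ss_window])
    data.frame(segment = i, conc_M = segs$conc_M[i], pH = segs$pH[i],
               dI_peak_A = dI_peak, dI_ss_A = dI_ss, t_peak_s = t[peak_i],
               pct_inactivation = if (dI_peak > 0)
                 percent_inactivation(dI_peak, min(dI_ss, dI_peak)) else 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_A") <- baseline
  out
}
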