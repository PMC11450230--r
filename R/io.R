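## JSON/CSV round-tripping of parameter sets, conditions, dose-response
## tables and traces.  CSV dialect: comma-separated, '.' decimal, header
## row mandatory, UTF-8; '#'-prefixed provenance comment lines are
## ignored by the readers.

#' Write and read kinetic parameters as JSON
#'
#' Keys: \code{k12_0, k21, k23_0, k32, k34, k43_0, k14_0, k41_0, N,
#' derived_constant}.  On reading, the designated derived constant is
#' recomputed from the microscopic-reversibility identity.
#'
#' @param params a \code{kinetic_params} object
#' @param path file path
#' @return \code{read_kinetic_params} returns a \code{kinetic_params}
#' @export
write_kinetic_params <- function(params, path) {
  jsonlite::write_json(unclass(params)[c("k12_0", "k21", "k23_0", "k32",
                                         "k34", "k43_0", "k14_0", "k41_0",
                                         "N", "derived_constant")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinetic_params
#' @export
read_kinetic_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_params(k12_0 = x$k12_0, k21 = x$k21, k23_0 = x$k23_0,
                 k32 = x$k32, k34 = x$k34, k43_0 = x$k43_0,
                 k14_0 = x$k14_0, k41_0 = x$k41_0,
                 N = if (is.null(x$N)) 1e10 else x$N,
                 derived_constant = if (is.null(x$derived_constant))
                   "k43_0" else x$derived_constant)
}

#' Write and read experimental conditions as JSON
#'
#' Keys: \code{V_mV, T_K, K_out_M, H_out_M, K_in_M, H_in_M}; the
#' convenience keys \code{pH_out}/\code{pH_in} are accepted on reading and
#' converted as H = 10^-pH mol/L.
#'
#' @param cond a \code{conditions} object
#' @param path file path
#' @return \code{read_conditions} returns a \code{conditions} object
#' @export
write_conditions <- function(cond, path) {
  jsonlite::write_json(list(V_mV = cond$V, T_K = cond$T_K,
                            K_out_M = cond$K_out, H_out_M = cond$H_out,
                            K_in_M = cond$K_in, H_in_M = cond$H_in),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_conditions
#' @export
read_conditions <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(key, default) if (is.null(x[[key]])) default else x[[key]]
  conditions(V = pick("V_mV", -120), T_K = pick("T_K", DEFAULT_TEMPERATURE),
             K_out = pick("K_out_M", 200e-6),
             H_out = pick("H_out_M", 10^-4.5),
             K_in = pick("K_in_M", 0.1), H_in = pick("H_in_M", 10^-7.1),
             pH_out = x$pH_out, pH_in = x$pH_in)
}

## provenance comment block written at the top of every output CSV
.provenance_header <- function(seed = NA, extra = NULL) {
  ver <- as.character(utils::packageVersion("hak5kin"))
  c(sprintf("# hak5kin %s", ver),
    sprintf("# seed: %s", seed),
    if (!is.null(extra)) paste0("# ", extra))
}

.write_csv <- function(df, path, seed = NA, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_header(seed, extra), con)
  utils::write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  out <- tryCatch(
    utils::read.table(path, sep = ",", dec = ".", header = TRUE,
                      comment.char = "#", encoding = "UTF-8"),
    error = function(e)
      stop("parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE))
  out
}

#' Write and read dose-response tables as CSV
#'
#' Columns \code{conc_M}, \code{dI_A} (or \code{dI_norm}) and
#' \code{replicate}.
#'
#' @param data a \code{\link{dose_response_dataset}}
#' @param path file path
#' @param seed seed recorded in the provenance header
#' @param normalized write the response column as \code{dI_norm} instead
#'   of \code{dI_A}
#' @return \code{read_dose_response} returns a
#'   \code{dose_response_dataset}
#' @export
write_dose_response <- function(data, path, seed = NA, normalized = FALSE) {
  df <- data.frame(conc_M = data$conc_M, resp = data$response,
                   replicate = data$replicate)
  names(df)[2] <- if (normalized) "dI_norm" else "dI_A"
  .write_csv(df, path, seed = seed,
             extra = sprintf("substrate: %s", attr(data, "substrate")))
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  df <- .read_csv(path)
  resp_col <- intersect(c("dI_A", "dI_norm", "response"), names(df))
  if (!("conc_M" %in% names(df)) || !length(resp_col))
    stop("parse error in '", path,
         "': need columns conc_M and dI_A/dI_norm", call. = FALSE)
  dose_response_dataset(df$conc_M, df[[resp_col[1]]],
                        replicate = if ("replicate" %in% names(df))
                          df$replicate else 1L)
}

#' Write a TEVC trace as CSV (with a truth sidecar JSON)
#'
#' Columns \code{time_s}, \code{current_A}.  When the trace carries a
#' generator truth record it is written to \code{<path>.truth.json}.
#'
#' @param trace a \code{\link{tevc_trace}}
#' @param path file path
#' @param seed seed recorded in the provenance header
#' @return \code{read_tevc_trace} returns a \code{tevc_trace} (without
#'   protocol/truth attributes unless the sidecar is present)
#' @export
write_tevc_trace <- function(trace, path, seed = NA) {
  .write_csv(data.frame(time_s = trace$time_s, current_A = trace$current_A),
             path, seed = seed)
  truth <- attr(trace, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_tevc_trace
#' @export
read_tevc_trace <- function(path) {
  df <- .read_csv(path)
  if (!all(c("time_s", "current_A") %in% names(df)))
    stop("parse error in '", path, "': need columns time_s, current_A",
         call. = FALSE)
  structure(list(time_s = df$time_s, current_A = df$current_A),
            class = "tevc_trace")
}
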