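#' Configuration for the steady-state BLI simulator
#'
#' Parameters of the synthetic biolayer-interferometry concentration series.
#' The default ladder reproduces the published titration design: nine
#' twofold dilutions from 34 uM down to about 0.133 uM, plus a buffer-only
#' zero point. Responses follow the one-site saturation model
#' `R(C) = rmax_true * C / (kd_true + C)` with additive Gaussian noise and
#' an optional linear drift along the dilution series.
#'
#' @param seed Integer seed.
#' @param kd_true True dissociation constant (uM).
#' @param rmax_true Saturating response (nm).
#' @param top_concentration Highest analyte concentration (uM, default 34).
#' @param n_dilutions Number of twofold dilution steps including the top
#'   concentration (default 9, spanning 34 down to 34/2^8 ~ 0.133 uM).
#' @param noise_sd Gaussian response noise SD (nm).
#' @param drift_slope Linear drift in nm per concentration index (default 0;
#'   index 0 at the top concentration).
#'
#' @return An object of class `bli_sim_config`.
#' @seealso [gen_bli_series()], [fit_one_site()]
#' @export
bli_sim_config <- function(seed,
                           kd_true,
                           rmax_true = 1,
                           top_concentration = 34,
                           n_dilutions = 9L,
                           noise_sd = 0.02,
                           drift_slope = 0) {
  check_scalar_num(seed, "seed", integer = TRUE)
  check_scalar_num(kd_true, "kd_true", positive = TRUE)
  check_scalar_num(rmax_true, "rmax_true", positive = TRUE)
  check_scalar_num(top_concentration, "top_concentration", positive = TRUE)
  check_scalar_num(n_dilutions, "n_dilutions", min = 2, integer = TRUE)
  check_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar_num(drift_slope, "drift_slope")
  structure(list(seed = as.integer(seed), kd_true = kd_true,
                 rmax_true = rmax_true,
                 top_concentration = top_concentration,
                 n_dilutions = as.integer(n_dilutions),
                 noise_sd = noise_sd, drift_slope = drift_slope),
            class = "bli_sim_config")
}

#' Construct a binding series
#'
#' Holds a steady-state concentration-response series: strictly positive
#' analyte concentrations (uM) with one binding response (nm) each, and an
#' optional buffer-only response expected near zero.
#'
#' @param concentrations Strictly positive numeric vector (uM).
#' @param responses Numeric vector, same length (nm). A matrix with one
#'   column per technical replicate is also accepted; replicates are kept
#'   and averaged at fit time.
#' @param buffer_response Optional scalar buffer-only (zero-concentration)
#'   response.
#' @return An object of class `binding_series`.
#' @export
binding_series <- function(concentrations, responses, buffer_response = NULL) {
  if (!is.numeric(concentrations) || any(concentrations <= 0)) {
    stop_field("concentrations", "must be strictly positive")
  }
  if (is.matrix(responses)) {
    if (nrow(responses) != length(concentrations)) {
      stop_field("responses", "must have one row per concentration")
    }
  } else if (length(responses) != length(concentrations)) {
    stop_field("responses", "must match concentrations in length")
  }
  if (!is.null(buffer_response)) {
    check_scalar_num(buffer_response, "buffer_response")
  }
  structure(list(concentrations = as.numeric(concentrations),
                 responses = responses,
                 buffer_response = buffer_response),
            class = "binding_series")
}

#' Simulate a steady-state BLI concentration series
#'
#' @param config A [bli_sim_config()].
#' @return A [binding_series()] with concentrations in descending twofold
#'   steps from `top_concentration` and noisy one-site responses; the
#'   buffer-only point carries noise (and no specific signal).
#' @examples
#' ser <- gen_bli_series(bli_sim_config(seed = 1, kd_true = 1.4))
#' round(ser$concentrations, 3)
#' @export
gen_bli_series <- function(config) {
  if (!inherits(config, "bli_sim_config")) {
    stop_field("config", "must be a bli_sim_config")
  }
  set.seed(config$seed)
  conc <- config$top_concentration / 2^(seq_len(config$n_dilutions) - 1)
  idx <- seq_along(conc) - 1
  resp <- config$rmax_true * conc / (config$kd_true + conc) +
    config$drift_slope * idx +
    stats::rnorm(length(conc), 0, config$noise_sd)
  buffer <- stats::rnorm(1, 0, config$noise_sd)
  binding_series(conc, resp, buffer_response = buffer)
}
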