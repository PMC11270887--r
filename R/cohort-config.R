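#' Observation-mechanism specification
#'
#' Defines the conditional law of the per-lab observation indicators given the
#' patient state: the mechanism class (MCAR, MAR or NMAR in the Little-Rubin
#' sense) together with its parameter vector. Each lab has a base log-odds of
#' being observed in a block; under NMAR the log-odds additionally increase
#' with latent illness severity (sicker patients are measured more — the
#' informative-missingness signature), and under MAR they depend only on the
#' patient's most recent \emph{observed} value of the same lab. Under MCAR all
#' severity and lag coefficients are forced to zero; under MAR all severity
#' coefficients are forced to zero, so the declared class always matches the
#' realised mechanism.
#'
#' Default base log-odds are calibrated (jointly with the default severity
#' process) so that under NMAR the five regular labs are missing in about half
#' of all blocks and the seven informative labs in about nine tenths.
#'
#' @param mechanism One of "mcar", "mar", "nmar".
#' @param labs A \code{\link{lab_config}} data frame.
#' @param base_logodds Named numeric, per-lab base log-odds of observation.
#'   Defaults to the calibrated values for the requested mechanism.
#' @param severity_coef Named numeric, per-lab coefficient on latent severity
#'   (NMAR only; ignored and zeroed otherwise).
#' @param lag_coef Named numeric, per-lab coefficient on the standardised most
#'   recent observed value of the lab (MAR only; zeroed otherwise).
#' @return An object of class \code{mechanism_spec}.
#' @export
mechanism_spec <- function(mechanism = c("nmar", "mar", "mcar"),
                           labs = lab_config(),
                           base_logodds = NULL,
                           severity_coef = NULL,
                           lag_coef = NULL) {
  mechanism <- match.arg(mechanism)
  nm <- labs$name
  if (is.null(severity_coef)) {
    severity_coef <- ifelse(labs$regular, 0.6, 1.0)
    names(severity_coef) <- nm
  }
  if (is.null(lag_coef)) {
    lag_coef <- stats::setNames(rep(0.6, nrow(labs)), nm)
  }
  if (is.null(base_logodds)) {
    # Calibrated so the marginal block-level observation probability is ~0.50
    # for regular labs and ~0.10 for informative labs under each mechanism
    # (the severity/lag terms shift the marginal mean, hence the per-mechanism
    # intercepts).
    base_logodds <- switch(mechanism,
      nmar = ifelse(labs$regular, -0.015, -2.566),
      mar  = ifelse(labs$regular, -0.28, -2.344),
      mcar = ifelse(labs$regular, 0.000, -2.197))
    names(base_logodds) <- nm
  }
  base_logodds <- base_logodds[nm]
  severity_coef <- severity_coef[nm]
  lag_coef <- lag_coef[nm]
  if (anyNA(base_logodds)) stop("base_logodds must name every lab")
  if (mechanism %in% c("mcar", "mar")) severity_coef[] <- 0
  if (mechanism %in% c("mcar")) lag_coef[] <- 0
  if (mechanism == "nmar") lag_coef[] <- 0
  structure(list(mechanism = mechanism,
                 base_logodds = base_logodds,
                 severity_coef = severity_coef,
                 lag_coef = lag_coef),
            class = "mechanism_spec")
}

#' Cohort generator configuration
#'
#' All constants of the synthetic inpatient cohort generator: cohort size,
#' the 12-hour block structure with 7-day censoring (14 blocks), the latent
#' severity process (a stationary first-order autoregression), the lab
#' measurement model, the per-block deterioration and discharge hazards, and
#' the observation mechanism. The shipped defaults are calibrated so that the
#' generated cohorts match the descriptives of the motivating early-warning
#' -score setting: a patient-level deterioration rate near 4.7%, a block-level
#' event rate near 0.6%, a median of about 8 blocks (4 hospital days) per
#' patient, and block-level missingness near 50% for regular labs and 90% for
#' informative labs.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed and config.
#' @param mechanism A \code{\link{mechanism_spec}}, or a string passed to
#'   \code{mechanism_spec()}.
#' @param labs A \code{\link{lab_config}}.
#' @param max_blocks Maximum blocks per patient (14 = 7 days of 12-hour
#'   blocks).
#' @param block_hours Block length in hours (12).
#' @param discharge_hazard Per-block probability of discharge, constant across
#'   blocks; calibrated to a median stay of ~8 blocks.
#' @param event_intercept,event_slope Per-block deterioration probability is
#'   \code{plogis(event_intercept + event_slope * severity)}.
#' @param severity_rho AR(1) persistence of latent severity.
#' @param severity_innovation_sd Innovation SD; the default pair (0.8, 0.6)
#'   gives a stationary severity SD of 1.
#' @param lab_loading_scale Lab severity loading, in units of the lab's
#'   normal-range half-width per severity SD.
#' @param lab_noise_scale Lab measurement noise SD, in half-width units.
#' @param debug_severity Emit the latent severity as a \code{severity} column
#'   (ground truth for diagnostics; never a predictor).
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 1000,
                          seed = 1L,
                          mechanism = "nmar",
                          labs = lab_config(),
                          max_blocks = 14L,
                          block_hours = 12,
                          discharge_hazard = 0.080,
                          event_intercept = -6.38,
                          event_slope = 1.5,
                          severity_rho = 0.8,
                          severity_innovation_sd = 0.6,
                          lab_loading_scale = 0.8,
                          lab_noise_scale = 0.5,
                          debug_severity = TRUE) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive count")
  }
  if (discharge_hazard <= 0 || discharge_hazard > 1) {
    stop("discharge_hazard must lie in (0, 1]")
  }
  if (max_blocks < 1) stop("max_blocks must be >= 1")
  if (abs(severity_rho) >= 1) stop("severity_rho must lie in (-1, 1)")
  if (is.character(mechanism)) mechanism <- mechanism_spec(mechanism, labs = labs)
  stopifnot(inherits(mechanism, "mechanism_spec"))
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 mechanism = mechanism,
                 labs = labs,
                 max_blocks = as.integer(max_blocks),
                 block_hours = block_hours,
                 discharge_hazard = discharge_hazard,
                 event_intercept = event_intercept,
                 event_slope = event_slope,
                 severity_rho = severity_rho,
                 severity_innovation_sd = severity_innovation_sd,
                 lab_loading_scale = lab_loading_scale,
                 lab_noise_scale = lab_noise_scale,
                 debug_severity = isTRUE(debug_severity)),
            class = "cohort_config")
}
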