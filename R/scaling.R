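#' Fit the relative-voltage reference
#'
#' The voltage feature is converted to a relative value by dividing by the
#' highest output voltage observed in the fitted data set; this suppresses
#' session-to-session variation of the raw output. The reference is stored
#' and reused on new data (new sessions are *not* rescaled by their own
#' maximum, so relative values above 1 may occur on held-out data).
#'
#' @param features feature data frame with a `voltage` column (see
#'   [extract_features()]).
#' @return The reference voltage in volts: `max(features$voltage)`.
#' @export
fit_voltage_reference <- function(features) {
  v <- features$voltage
  if (is.null(v) || !length(v))
    stop_respstage("features must contain at least one voltage",
                   "respstage_invalid_input")
  check_finite(v, "voltage")
  if (max(v) <= 0)
    stop_respstage("all voltages are zero: cannot fit a reference",
                   "respstage_invalid_input")
  max(v)
}

#' Scaling configuration
#'
#' The two scaling steps applied before centroid distances are computed:
#' the respiration rate (x-axis) is multiplied by the weight `W`, and the
#' voltage (y-axis) is divided by the stored reference. `W = 0.1` brings
#' the two axes to a similar order of magnitude, which is where nearest-
#' centroid accuracy peaks.
#'
#' @param weight positive weight `W` multiplied onto the respiration rate.
#' @param voltage_reference positive reference voltage in volts.
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(weight = 0.1, voltage_reference) {
  if (!is.finite(weight) || weight <= 0)
    stop_respstage("weight must be positive", "respstage_invalid_config")
  if (!is.finite(voltage_reference) || voltage_reference <= 0)
    stop_respstage("voltage_reference must be positive", "respstage_invalid_config")
  structure(list(weight = weight, voltage_reference = voltage_reference),
            class = "scaling_config")
}

#' @export
print.scaling_config <- function(x, ...) {
  cat(sprintf("<scaling_config> W = %g, voltage reference = %g V\n",
              x$weight, x$voltage_reference))
  invisible(x)
}

#' Apply feature scaling
#'
#' Maps each feature vector (rate, voltage) to the classification plane
#' point `(x, y) = (W * rate_bpm, voltage / voltage_reference)`. Stage
#' labels are preserved. A voltage equal to the reference maps to exactly
#' 1.
#'
#' @param features feature data frame (see [extract_features()]).
#' @param scaling a [scaling_config()].
#' @return Data frame with columns `x` (weighted rate), `y` (relative
#'   voltage) and `stage`.
#' @export
#' @examples
#' f <- data.frame(rate_bpm = 16.32, voltage = 7.89, stage = "AWAKE")
#' apply_scaling(f, scaling_config(0.1, 7.89))
apply_scaling <- function(features, scaling) {
  if (!inherits(scaling, "scaling_config"))
    stop_respstage("scaling must be a scaling_config", "respstage_invalid_config")
  data.frame(x = scaling$weight * features$rate_bpm,
             y = features$voltage / scaling$voltage_reference,
             stage = if ("stage" %in% names(features)) as_stage(features$stage)
                     else as_stage(rep(NA_character_, nrow(features))))
}

# Inverse of apply_scaling, used in round-trip tests.
unapply_scaling <- function(scaled, scaling) {
  data.frame(rate_bpm = scaled$x / scaling$weight,
             voltage = scaled$y * scaling$voltage_reference,
             stage = scaled$stage)
}
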