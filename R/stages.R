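#' Sleep stage levels
#'
#' The five sleep stages used throughout the package, in reporting order:
#' wake, the three non-REM depths, and REM. Ground truth for staging is
#' conventionally EEG-derived; here stages label 30-s analysis windows of
#' the respiration signal.
#'
#' @return Character vector `c("AWAKE", "N1", "N2", "N3", "REM")`.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("AWAKE", "N1", "N2", "N3", "REM")

#' Coerce to a sleep-stage factor
#'
#' @param x character or factor of stage names.
#' @return Factor with levels [stage_levels()].
#' @export
as_stage <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% stage_levels())
  if (any(bad))
    stop_respstage(sprintf("unknown sleep stage(s): %s",
                           paste(unique(x[bad]), collapse = ", ")),
                   "respstage_parse_error")
  factor(x, levels = stage_levels())
}
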