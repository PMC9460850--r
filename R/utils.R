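# Internal helpers: condition classes and seeded evaluation.

stop_respstage <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "respstage_error"), call = call))
}

#' @noRd
check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_respstage(sprintf("%s must be finite numeric", what), "respstage_invalid_input")
  invisible(x)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. A NULL seed runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# MD5 of an arbitrary serializable object, via its YAML text. Used to stamp
# output files with the producing configuration.
config_hash <- function(x) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}
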