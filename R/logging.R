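# Lightweight leveled logging. Every filter/override decision in the pipeline
# goes through ka_log() so manual exceptions stay auditable.

.ka_levels <- c(debug = 10L, info = 20L, warn = 30L, quiet = 90L)

#' Set or query the package log level
#'
#' Messages at or above the chosen level are emitted with [message()].
#' The pipeline logs every filtering and override decision (removed
#' sequences, tie-breaks, threshold overrides) at `"info"` level so that
#' manual exceptions remain auditable.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return The previous level, invisibly.
#' @export
ka_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- getOption("kvancestry.log_level", "info")
  options(kvancestry.log_level = level)
  invisible(old)
}

ka_log <- function(msg, level = "info") {
  cur <- getOption("kvancestry.log_level", "info")
  if (.ka_levels[[level]] >= .ka_levels[[cur]]) {
    message(sprintf("[kvancestry %s] %s", level, msg))
  }
  invisible(NULL)
}
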