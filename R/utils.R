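# Minimal leveled logging so solver statuses and filter decisions are
# auditable; controlled by options(upfinder.log_level = "quiet"|"info"|"debug").

.log_level <- function() {
  lev <- getOption("upfinder.log_level", "info")
  match(lev, c("quiet", "info", "debug"), nomatch = 2L)
}

.log_info <- function(...) {
  if (.log_level() >= 2L) message(...)
  invisible(NULL)
}

.log_debug <- function(...) {
  if (.log_level() >= 3L) message(...)
  invisible(NULL)
}
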