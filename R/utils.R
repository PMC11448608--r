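#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join distinct n
#' @importFrom generics tidy glance
#' @useDynLib clickdosim
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Logging goes to stderr and is silenced unless options(clickdosim.verbose)
# is TRUE; validation failures are errors, never log lines.
cd_log <- function(...) {
  if (isTRUE(getOption("clickdosim.verbose", FALSE))) {
    message("[clickdosim] ", sprintf(...))
  }
  invisible(NULL)
}

# Seed streams: derive per-task seeds from one master seed, staying < 2^31.
derive_seed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L) %% 2147483647L
}
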