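#' @keywords internal
"_PACKAGE"

#' @importFrom stats approxfun coef lm median nls optimize predict qt quantile
#'   rbinom rlnorm rnorm runif sd setNames uniroot
#' @importFrom utils modifyList read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("'%s' must be a finite numeric scalar", name)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain("'%s' = %g out of range %s%g, %g%s", name, x,
                if (lower_open) "(" else "[", lower, upper,
                if (upper_open) ")" else "]")
  invisible(x)
}

#' Locate a file bundled with the package
#'
#' Thin wrapper around [system.file()] for the configuration files shipped
#' under `inst/extdata` (compound files, physiology table, scenarios).
#'
#' @param ... path components below `extdata`.
#' @return Absolute path to the bundled file.
#' @export
vincpbpk_file <- function(...) {
  path <- system.file("extdata", ..., package = "vincpbpk", mustWork = FALSE)
  if (!nzchar(path))
    stop_domain("bundled file not found: %s", file.path(...))
  path
}
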