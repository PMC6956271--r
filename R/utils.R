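# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
stop_ocunano <- function(msg, class) {
  stop(structure(
    class = c(class, "ocunano_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_ocunano <- function(msg, class) {
  warning(structure(
    class = c(class, "ocunano_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ocunano(sprintf("`%s` must be a single finite number", name),
                 "ocunano_domain_error")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_ocunano(sprintf("`%s` = %g is outside its valid range", name, x),
                 "ocunano_domain_error")
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Boltzmann constant, J/K
.kB <- 1.380649e-23
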