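#' Specify an environmental regime
#'
#' The environmental parameter `p(t)` is deterministic (no environmental
#' stochasticity) and changes only between discrete generations. Three
#' regimes are supported:
#' \describe{
#'   \item{constant}{`p(t) = p0`,}
#'   \item{periodic}{`p(t) = p0 + A * sin(2*pi*t / period)`,}
#'   \item{directional}{`p(t) = p0 + eta * t`.}
#' }
#' `t` is the integer generation index, starting at 1 for the first selected
#' generation; `t = 0` is the initialization state, where all regimes return
#' `p0` (default 0, matching founders centred at trait 0).
#'
#' @param regime One of `"constant"`, `"periodic"`, `"directional"`.
#' @param p0 Initial state (default 0).
#' @param A Amplitude of periodic cycling.
#' @param period Period of cycling in generations (> 0).
#' @param eta Rate of directional change per generation.
#' @return An object of class `"environment_spec"`.
#' @export
environment_spec <- function(regime = c("constant", "periodic", "directional"),
                             p0 = 0, A = 1, period = 200, eta = 0.001) {
  regime <- match.arg(regime)
  if (regime == "periodic" && (!is.finite(period) || period <= 0)) {
    stop("period must be > 0 for the periodic regime", call. = FALSE)
  }
  structure(
    list(regime = regime, p0 = p0, A = A, period = period, eta = eta),
    class = "environment_spec"
  )
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(switch(x$regime,
    constant = sprintf("<environment_spec> constant, p = %g\n", x$p0),
    periodic = sprintf(
      "<environment_spec> periodic, p(t) = %g + %g sin(2 pi t / %g)\n",
      x$p0, x$A, x$period),
    directional = sprintf(
      "<environment_spec> directional, p(t) = %g + %g t\n", x$p0, x$eta)
  ))
  invisible(x)
}

#' Environmental parameter at generation t
#'
#' @param spec An [environment_spec()].
#' @param t Non-negative integer generation index (vectorized).
#' @return Numeric `p(t)` values.
#' @examples
#' env_value(environment_spec("periodic", A = 1, period = 200), 50)   # p0 + 1
#' env_value(environment_spec("directional", eta = 0.001), 1000)      # p0 + 1
#' @export
env_value <- function(spec, t) {
  stopifnot(inherits(spec, "environment_spec"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  switch(spec$regime,
    constant    = rep(spec$p0, length(t)),
    periodic    = spec$p0 + spec$A * sin(2 * pi * t / spec$period),
    directional = spec$p0 + spec$eta * t
  )
}
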