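# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Conversion factor between mmHg and Pa (1 mmHg = 133.322 Pa).
MMHG_TO_PA <- 133.322

stop_invalid <- function(msg, class = "capfit_invalid_input") {
  stop(errorCondition(msg, class = c(class, "capfit_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("capfit_config_error", "capfit_error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("'%s' must be a single finite positive number", name))
  }
  invisible(x)
}

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}

## Trapezoidal integral of y over (possibly non-uniform) grid t.
trapz_integral <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

## Round to k significant figures, as the printed tables do.
signif_sf <- function(x, k) signif(x, k)

is_uniform_grid <- function(times, rel_tol = 1e-6) {
  n <- length(times)
  if (n < 2L) return(TRUE)
  dt <- diff(times)
  if (any(dt <= 0)) return(FALSE)
  max(abs(dt - dt[1L])) <= rel_tol * dt[1L]
}
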