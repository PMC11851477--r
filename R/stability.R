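# Routh-Hurwitz tabulation, pole extraction, and second-order transient
# characteristics (damping ratio, natural frequency, damping classification).

#' Routh-Hurwitz stability tabulation
#'
#' Builds the standard Routh array for a characteristic polynomial given by
#' its coefficients in descending powers, and counts sign changes in the
#' first column: the polynomial has all roots in the open left half-plane iff
#' there are none. A zero first-column pivot (with a nonzero remainder of the
#' row) is replaced by a small epsilon of magnitude
#' `1e-9 * max(|coefficients|)`, the classical perturbation device.
#'
#' @param den_coeffs Numeric coefficients, descending powers, length >= 2
#'   (degree >= 1), leading coefficient nonzero.
#' @return A list with `first_column`, `sign_changes`, `stable`, and the full
#'   `array`.
#' @export
#' @examples
#' routh_hurwitz(c(1, 9.028, 108.2))$stable  # TRUE
routh_hurwitz <- function(den_coeffs) {
  co <- as.numeric(den_coeffs)
  if (length(co) < 2L || co[1] == 0 || !all(is.finite(co))) {
    stop_invalid("'den_coeffs' must be finite, degree >= 1, nonzero leading coefficient")
  }
  n <- length(co) - 1L                     # polynomial degree
  eps <- 1e-9 * max(abs(co))
  ncols <- ceiling((n + 1L) / 2)
  tab <- matrix(0, nrow = n + 1L, ncol = ncols)
  r1 <- co[seq(1L, n + 1L, by = 2L)]
  r2 <- co[seq(2L, n + 1L, by = 2L)]
  tab[1L, seq_along(r1)] <- r1
  if (length(r2)) tab[2L, seq_along(r2)] <- r2
  if (n >= 2L) {
    for (i in 3L:(n + 1L)) {
      pivot <- tab[i - 1L, 1L]
      if (pivot == 0) {
        if (all(tab[i - 1L, ] == 0)) {
          # full zero row: differentiate the auxiliary polynomial of the row above
          ord <- n + 1L - (i - 2L)         # highest power in row i-2
          aux <- tab[i - 2L, ]
          powers <- seq(ord, by = -2, length.out = ncols)
          deriv <- aux * powers
          deriv[powers < 0] <- 0
          tab[i - 1L, ] <- c(deriv[powers >= 1], rep(0, sum(powers < 1)))[1:ncols]
          pivot <- tab[i - 1L, 1L]
          if (pivot == 0) pivot <- eps
        } else {
          pivot <- eps
        }
        tab[i - 1L, 1L] <- pivot
      }
      for (j in 1L:(ncols - 1L)) {
        tab[i, j] <- (pivot * tab[i - 2L, j + 1L] -
                      tab[i - 2L, 1L] * tab[i - 1L, j + 1L]) / pivot
      }
    }
  }
  first_col <- tab[, 1L]
  # signs relative to the leading coefficient; count strict changes
  signs <- sign(first_col)
  signs[signs == 0] <- sign(eps)
  sign_changes <- sum(diff(signs[signs != 0]) != 0)
  list(first_column = first_col,
       sign_changes = as.integer(sign_changes),
       stable = sign_changes == 0L && all(first_col != 0),
       array = tab)
}

#' Poles of a transfer function
#'
#' Roots of the (monic, degree-2) denominator, sorted by increasing real part
#' with conjugates adjacent (the member with positive imaginary part first).
#'
#' @param tf A [transfer_function()].
#' @return Complex vector of length 2.
#' @export
#' @examples
#' tf_poles(transfer_function(89.38, c(1, 9.028, 108.2)))
tf_poles <- function(tf) {
  if (!inherits(tf, "transfer_function")) {
    stop_invalid("'tf' must be a transfer_function")
  }
  r <- polyroot(rev(tf$den))
  r <- r[order(Re(r), -Im(r))]
  # scrub numerically-zero imaginary parts on real roots
  re_scale <- max(1, Mod(r))
  r[abs(Im(r)) < 1e-10 * re_scale] <-
    complex(real = Re(r[abs(Im(r)) < 1e-10 * re_scale]), imaginary = 0)
  r
}

#' Second-order transient characteristics
#'
#' For a monic quadratic denominator `s^2 + a1 s + a0` with `a0 > 0`:
#' natural frequency `wn = sqrt(a0)`, damping ratio `zeta = a1 / (2 wn)`, and
#' the damping classification (`zeta < 1` underdamped, `= 1` critically
#' damped, `> 1` overdamped). An underdamped system has a complex-conjugate
#' pole pair and an oscillatory transient.
#'
#' @param tf A [transfer_function()].
#' @param tol Relative tolerance for the critically-damped boundary.
#' @return A list with `damping_ratio`, `natural_frequency`, `classification`.
#' @export
second_order_characteristics <- function(tf, tol = 1e-9) {
  if (!inherits(tf, "transfer_function")) {
    stop_invalid("'tf' must be a transfer_function")
  }
  a1 <- tf$den[2]; a0 <- tf$den[3]
  if (a0 <= 0) stop_invalid("constant denominator coefficient must be positive")
  wn <- sqrt(a0)
  zeta <- a1 / (2 * wn)
  classification <- if (abs(zeta - 1) <= tol) "critically_damped"
    else if (zeta < 1) "underdamped" else "overdamped"
  list(damping_ratio = zeta, natural_frequency = wn,
       classification = classification)
}

#' Full stability report
#'
#' Combines Routh-Hurwitz tabulation, pole extraction and second-order
#' characteristics, cross-checking that the Routh verdict agrees with the
#' pole locations.
#'
#' @param x A [transfer_function()], [state_space_model()] or
#'   [circuit_params()] object.
#' @return An object of class `stability_report`: list with `poles`, `stable`,
#'   `routh_first_column`, `sign_changes`, `damping_ratio`,
#'   `natural_frequency`, `classification`.
#' @export
#' @examples
#' stability_report(reference_circuit_params())
stability_report <- function(x) {
  tf <- if (inherits(x, "transfer_function")) x
    else if (inherits(x, "state_space_model")) to_transfer_function(x)
    else if (inherits(x, "circuit_params")) {
      to_transfer_function(assemble_state_space(x))
    } else stop_invalid("cannot build a stability report from this object")
  rh <- routh_hurwitz(tf$den)
  p <- tf_poles(tf)
  pole_stable <- all(Re(p) < 0)
  if (rh$stable != pole_stable) {
    warning("Routh-Hurwitz verdict disagrees with pole locations (borderline system)")
  }
  ch <- second_order_characteristics(tf)
  structure(
    list(poles = p, stable = rh$stable && pole_stable,
         routh_first_column = rh$first_column,
         sign_changes = rh$sign_changes,
         damping_ratio = ch$damping_ratio,
         natural_frequency = ch$natural_frequency,
         classification = ch$classification,
         tf = tf),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report\n")
  cat("  poles:", paste(format(x$poles, digits = 6), collapse = ", "), "\n")
  cat("  stable:", x$stable,
      sprintf("(Routh first column sign changes: %d)\n", x$sign_changes))
  cat(sprintf("  zeta = %.4g, wn = %.4g rad/s, %s\n",
              x$damping_ratio, x$natural_frequency, x$classification))
  invisible(x)
}

#' Pole trajectories under a numerator gain sweep
#'
#' Reports closed-loop pole locations of `1 + k G(s) = 0` for a grid of gains
#' `k`, the tabular counterpart of a root-locus diagram.
#'
#' @param tf A [transfer_function()].
#' @param k_min,k_max Gain range (k >= 0).
#' @param n Number of gain samples.
#' @return A data.frame with columns `k`, `re`, `im` (two rows per gain).
#' @export
gain_sweep_poles <- function(tf, k_min = 0, k_max = 10, n = 50L) {
  if (!inherits(tf, "transfer_function")) {
    stop_invalid("'tf' must be a transfer_function")
  }
  ks <- seq(k_min, k_max, length.out = n)
  out <- lapply(ks, function(k) {
    num <- if (length(tf$num) == 1L) c(0, tf$num) else tf$num
    cl <- tf$den + c(0, k * num)
    r <- polyroot(rev(cl))
    data.frame(k = k, re = Re(r), im = Im(r))
  })
  do.call(rbind, out)
}
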