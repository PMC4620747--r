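#' Monotone step curve of GDT fractions
#'
#' Container for the Hubbard function H(theta): a non-decreasing step
#' function from cutoffs (Angstrom) to fractions of residues in (0, 1].
#' The curve holds `base_value` on `[0, step_thetas[1])` and jumps to
#' `step_values[j]` at `step_thetas[j]`. Evaluation at a jump returns the
#' post-jump value, because H(theta) is attained at theta (the defining
#' maximum uses a closed inequality).
#'
#' @param step_thetas strictly increasing jump locations in (0, theta_max].
#'   May be empty for a constant curve.
#' @param step_values post-jump values, same length, non-decreasing, each in
#'   (0, 1].
#' @param theta_max right end of the domain (Angstrom).
#' @param base_value value on `[0, step_thetas[1])`.
#' @return An object of class `step_curve`.
#' @export
step_curve <- function(step_thetas, step_values, theta_max, base_value) {
  step_thetas <- as.numeric(step_thetas)
  step_values <- as.numeric(step_values)
  stopifnot(length(step_thetas) == length(step_values),
            theta_max > 0, base_value > 0, base_value <= 1)
  if (length(step_thetas)) {
    if (any(diff(step_thetas) <= 0)) stop("step_thetas must be strictly increasing")
    if (step_thetas[1] <= 0 || step_thetas[length(step_thetas)] > theta_max)
      stop("step_thetas must lie in (0, theta_max]")
    if (any(diff(c(base_value, step_values)) < 0))
      stop("step_values must be non-decreasing from base_value")
    if (any(step_values <= 0 | step_values > 1)) stop("values must be in (0, 1]")
  }
  structure(list(step_thetas = step_thetas, step_values = step_values,
                 theta_max = theta_max, base_value = base_value),
            class = "step_curve")
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("step_curve on [0, %g]: base %.4g, %d steps\n",
              x$theta_max, x$base_value, length(x$step_thetas)))
  if (length(x$step_thetas))
    print(data.frame(theta = x$step_thetas, value = x$step_values))
  invisible(x)
}

#' Evaluate a step curve
#'
#' @param curve a `step_curve`.
#' @param theta cutoff(s) in `[0, theta_max]` (vectorized).
#' @return The curve value(s): the value of the step region containing
#'   theta, post-jump at jump points.
#' @export
evaluate_step_curve <- function(curve, theta) {
  stopifnot(inherits(curve, "step_curve"))
  if (any(theta < 0 | theta > curve$theta_max))
    stop("theta outside [0, theta_max]")
  vals <- c(curve$base_value, curve$step_values)
  idx <- findInterval(theta, curve$step_thetas) + 1L  # closed at jumps
  vals[idx]
}

#' Area under a step curve
#'
#' Exact area of the step region: `sum H(theta_i) (theta_i - theta_{i-1})`
#' with `theta_0 = 0` and the final partition point at `theta_max`.
#'
#' @param curve a `step_curve`.
#' @return Area in Angstrom x fraction, in `[theta_max/n, theta_max]` for a
#'   curve coming from an n-residue pair.
#' @export
step_curve_area <- function(curve) {
  stopifnot(inherits(curve, "step_curve"))
  if (is.null(curve$base_value)) stop("no steps")
  breaks <- c(0, curve$step_thetas, curve$theta_max)
  vals <- c(curve$base_value, curve$step_values)   # value on each cell
  sum(vals * pmax(0, diff(breaks)))
}
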