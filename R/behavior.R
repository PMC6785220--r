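# Psychophysics of grasp choices: the probability of an overhand grasp
# follows a sine law of cylinder orientation, p = a*sin(theta + phi0) + c,
# with one over/underhand alternation per full rotation.

#' Sine-law psychometric fit
#'
#' Least-squares fit of `p(overhand) = a * sin(theta + phi0) + c` with a
#' fixed 360-degree period.  The model is linear in
#' `(sin theta, cos theta, 1)`, so the global optimum is found in closed
#' form; `a >= 0` and `phi0` in `(-180, 180]` by convention.
#'
#' @param orientations cylinder orientations, degrees (>= 4 distinct).
#' @param p_overhand observed proportion of overhand choices per
#'   orientation.
#' @return list of class `psychometric_fit`: a, phi0 (degrees), c,
#'   r_squared, fitted, orientations.
#' @export
fit_sine_psychometric <- function(orientations, p_overhand) {
  if (length(unique(orientations)) < 4)
    stop_invalid("need >= 4 distinct orientations")
  if (length(orientations) != length(p_overhand))
    stop_invalid("orientations and p_overhand differ in length")
  th <- orientations * pi / 180
  X <- cbind(sin(th), cos(th), 1)
  if (stats::sd(p_overhand) == 0) {
    warning("constant choice proportions: zero-amplitude fit")
    fitc <- mean(p_overhand)
    return(structure(list(a = 0, phi0 = 0, c = fitc, r_squared = 0,
                          fitted = rep(fitc, length(orientations)),
                          orientations = orientations),
                     class = "psychometric_fit"))
  }
  cf <- stats::lm.fit(X, p_overhand)$coefficients
  # A*sin(th) + B*cos(th) = a*sin(th + phi0) with a = sqrt(A^2+B^2)
  a <- sqrt(cf[1]^2 + cf[2]^2)
  phi0 <- atan2(cf[2], cf[1]) * 180 / pi
  fitted <- as.vector(X %*% cf)
  ss_res <- sum((p_overhand - fitted)^2)
  ss_tot <- sum((p_overhand - mean(p_overhand))^2)
  structure(list(a = unname(a), phi0 = unname(phi0), c = unname(cf[3]),
                 r_squared = 1 - ss_res / ss_tot, fitted = fitted,
                 orientations = orientations),
            class = "psychometric_fit")
}

#' Orientation switch points of a psychometric fit
#'
#' Solves `a * sin(theta + phi0) + c = 0.5`: the orientations at which
#' the preferred grasp flips (50% crossings), two per 360-degree cycle.
#'
#' @param fit a [fit_sine_psychometric()] result.
#' @return numeric length 2, degrees in `[0, 360)`, sorted.
#' @export
find_switch_points <- function(fit) {
  q <- (0.5 - fit$c) / fit$a
  if (!is.finite(q) || abs(q) > 1)
    ecog_error("ecog_no_switch_point",
               "fitted curve does not cross 50%: no switch points")
  s <- asin(q) * 180 / pi
  sort(c((s - fit$phi0) %% 360, (180 - s - fit$phi0) %% 360))
}

#' Demand labels from switch-point proximity
#'
#' Trials whose cylinder orientation lies within +/- `half_range`
#' degrees of a switch point are high-demand (both grasps afforded);
#' orientations in the equivalent range around `switch point + 90`
#' degrees are low-demand; everything else is `neither`.
#'
#' @param orientations trial orientations, degrees.
#' @param switch_points the two switch points, degrees.
#' @param half_range half-width of each demand bin, degrees (default 24,
#'   i.e. three orientation bins per switch point).
#' @return character vector in `{high, low, neither}`.
#' @export
label_demand <- function(orientations, switch_points, half_range = 24) {
  circ_dist <- function(a, b) {
    d <- abs((a - b) %% 360)
    pmin(d, 360 - d)
  }
  near <- function(targets) {
    Reduce(`|`, lapply(targets, function(s)
      circ_dist(orientations, s) <= half_range))
  }
  out <- rep("neither", length(orientations))
  out[near(switch_points + 90)] <- "low"
  out[near(switch_points)] <- "high"   # high wins on overlap
  out
}
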