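#' Linear-up/log-down trapezoidal area of one segment
#'
#' The declining branch (`c2 < c1`, both positive) uses the exact integral of
#' the exponential interpolant, `(c1 - c2) * (t2 - t1) / log(c1/c2)`; rising,
#' flat or zero-bounded segments use the arithmetic trapezoid
#' `(c1 + c2)/2 * (t2 - t1)`.
#'
#' @param t1,t2 Segment endpoints in hours, `t2 > t1`. Vectorised.
#' @param c1,c2 Concentrations at the endpoints, >= 0.
#' @return Segment area(s), ng.h/mL, always >= 0.
#' @examples
#' auc_segment(0, 0, 1, 2)      # 1.0, linear
#' auc_segment(1, 2, 2, 1)      # 1/log(2), log-down
#' @export
auc_segment <- function(t1, c1, t2, c2) {
  if (any(t2 <= t1)) stop("segment times must satisfy t2 > t1")
  stopifnot(all(c1 >= 0), all(c2 >= 0))
  dt <- t2 - t1
  logdown <- c2 < c1 & c2 > 0
  area <- (c1 + c2) / 2 * dt
  if (any(logdown)) {
    area[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
      log(c1[logdown] / c2[logdown])
  }
  area
}

#' First-moment (AUMC) area of one segment
#'
#' Companion of [auc_segment()] for the moment curve `t * C(t)`. On the
#' log-down branch the exact integral of `t * c1 * exp(-k (t - t1))` with
#' `k = log(c1/c2)/(t2 - t1)` is `(t1 c1 - t2 c2)/k + (c1 - c2)/k^2`. On the
#' rising/flat/zero branch the moment curve itself is interpolated linearly,
#' giving the moment trapezoid `(t1 c1 + t2 c2)/2 * (t2 - t1)`.
#'
#' @inheritParams auc_segment
#' @return Segment moment area(s), ng.h^2/mL.
#' @export
aumc_segment <- function(t1, c1, t2, c2) {
  if (any(t2 <= t1)) stop("segment times must satisfy t2 > t1")
  stopifnot(all(c1 >= 0), all(c2 >= 0))
  dt <- t2 - t1
  logdown <- c2 < c1 & c2 > 0
  area <- (t1 * c1 + t2 * c2) / 2 * dt
  if (any(logdown)) {
    k <- log(c1[logdown] / c2[logdown]) / dt[logdown]
    area[logdown] <- (t1[logdown] * c1[logdown] - t2[logdown] * c2[logdown]) / k +
      (c1[logdown] - c2[logdown]) / k^2
  }
  area
}
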