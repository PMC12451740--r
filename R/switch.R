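#' Switching-function parameters
#'
#' Parameters of the rational switching function
#' \deqn{s(r) = \frac{1 - x^n}{1 - x^m}, \qquad x = \frac{r - d_0}{r_0},}
#' the PLUMED `RATIONAL` form.  At the removable singularity \eqn{x = 1}
#' the value is \eqn{n/m}; for \eqn{r \le d_0} the value is 1.  An optional
#' hard outer cutoff `d_max` (PLUMED `D_MAX`) truncates the switch to
#' exactly 0 beyond `d_max`, with the inner part rescaled ("stretched") so
#' the function remains continuous: \eqn{s'(r) = (s(r) - s(d_{max})) / (1 -
#' s(d_{max}))}.  A finite `d_max` is what makes feature values strictly
#' local, so that periodic-image ambiguities far away cannot perturb them.
#'
#' @param r0 Reference distance (Angstrom for distances; unitless when the
#'   switch is applied to an angular coordinate). Must be > 0.
#' @param n,m Integer exponents, `0 < n < m`.
#' @param d0 Offset (same units as `r0`), default 0.
#' @param d_max Hard cutoff; `Inf` (default) disables truncation.
#' @return A list of class `fcv_switch`.
#' @export
#' @examples
#' p <- switch_params(r0 = 3.0, n = 6, m = 10)
#' rational_switch(c(0, 3, 6), p)
switch_params <- function(r0, n = 6L, m = 10L, d0 = 0, d_max = Inf) {
  if (!is.finite(r0) || r0 <= 0) .stopf("r0 must be > 0")
  n <- as.integer(n); m <- as.integer(m)
  if (!(n > 0L && m > n)) .stopf("exponents must satisfy 0 < n < m")
  if (d_max <= d0 && is.finite(d_max)) .stopf("d_max must exceed d0")
  structure(list(r0 = r0, n = n, m = m, d0 = d0, d_max = d_max), class = "fcv_switch")
}

#' Rational switching function
#'
#' Evaluates the PLUMED `RATIONAL` switch (see [switch_params()]).  The
#' function is total on `r >= 0`: continuous, monotonically non-increasing,
#' 1 at `r <= d0`, `n/m` at the removable singularity `x = 1`, and decaying
#' to 0 (exactly 0 beyond `d_max` when finite).
#'
#' @param r Numeric vector of distances (>= 0).
#' @param params An `fcv_switch` from [switch_params()].
#' @return Numeric vector of switch values in `[0, 1]`.
#' @export
rational_switch <- function(r, params) {
  x <- (r - params$d0) / params$r0
  n <- params$n; m <- params$m
  val <- numeric(length(x))
  lo <- x <= 0
  val[lo] <- 1
  near <- !lo & abs(x - 1) < 1e-6
  if (any(near)) {
    ## second-order expansion around the removable singularity:
    ## s(1+h) = (n/m) (1 + (n-m) h / 2 + O(h^2))
    h <- x[near] - 1
    val[near] <- (n / m) * (1 + (n - m) * h / 2)
  }
  rest <- !lo & !near
  if (any(rest)) {
    xr <- x[rest]
    val[rest] <- (1 - xr^n) / (1 - xr^m)
  }
  if (is.finite(params$d_max)) {
    sdm <- .rational_core((params$d_max - params$d0) / params$r0, n, m)
    val <- (val - sdm) / (1 - sdm)
    val[r >= params$d_max] <- 0
    val[val < 0] <- 0
  }
  val
}

## bare rational form, used to compute the stretch constant
.rational_core <- function(x, n, m) {
  if (x <= 0) return(1)
  if (abs(x - 1) < 1e-6) return((n / m) * (1 + (n - m) * (x - 1) / 2))
  (1 - x^n) / (1 - x^m)
}

#' Hydrogen-bond angular term
#'
#' A smooth, chirality-free term in `[0, 1]` for the donor-hydrogen-acceptor
#' angle \eqn{\theta} (measured at the hydrogen): 1 for a collinear
#' D-H...A arrangement (\eqn{\theta = \pi}) and decaying to ~0 for bent
#' geometries.  Implemented as a rational switch on the bounded coordinate
#' \eqn{u = (1 + \cos\theta)/2 \in [0, 1]} (0 when collinear), so the term
#' is differentiable everywhere and usable for biasing.  With the default
#' parameters the value is 0.6 at \eqn{\theta = 150^\circ} and below 0.01
#' at \eqn{\theta = 120^\circ}.
#'
#' @param donor_heavy,hydrogen,acceptor Length-3 numeric coordinates
#'   (Angstrom) of the donor heavy atom, the shared hydrogen, and the
#'   acceptor.
#' @param params An `fcv_switch` over `u`; default [angular_params()].
#' @return Scalar in `[0, 1]`.
#' @export
angular_term <- function(donor_heavy, hydrogen, acceptor, params = angular_params()) {
  v1 <- donor_heavy - hydrogen
  v2 <- acceptor - hydrogen
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-8 || n2 < 1e-8) .stopf("coincident points in angular_term")
  cth <- sum(v1 * v2) / (n1 * n2)
  cth <- min(1, max(-1, cth))
  rational_switch((1 + cth) / 2, params)
}

#' Default angular switch parameters
#'
#' `r0 = (1 + cos 150 deg)/2`, `n = 6`, `m = 10`: the angular term is 0.6 at
#' a 150 degree D-H...A angle and ~0.005 at 120 degrees.
#'
#' @return An `fcv_switch` over the angular coordinate `u = (1+cos theta)/2`.
#' @export
angular_params <- function() {
  switch_params(r0 = (1 + cos(150 * pi / 180)) / 2, n = 6L, m = 10L, d0 = 0, d_max = Inf)
}

## vectorised over frames: D, H, A are 3 x nframes matrices (min-image is
## irrelevant for bonded geometry at these scales; raw vectors are used)
.angular_frames <- function(D, H, A, params) {
  v1 <- D - H
  v2 <- A - H
  n1 <- sqrt(colSums(v1^2)); n2 <- sqrt(colSums(v2^2))
  cth <- colSums(v1 * v2) / pmax(n1 * n2, 1e-12)
  cth <- pmin(1, pmax(-1, cth))
  rational_switch((1 + cth) / 2, params)
}
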