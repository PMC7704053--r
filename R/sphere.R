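#' Concentric-spheres continuum reference model
#'
#' Closed forms for diffusion between concentric spheres: an absorbing
#' nuclear membrane at radius `a`, a reflecting cell membrane at radius
#' `R`, start radius `r0`, diffusivity `D`.  These are the continuum
#' counterparts of the voxelized computations and serve as independent
#' oracles.
#'
#' @param a nucleus radius, um.
#' @param R cell radius, um.
#' @param r0 start radius, um (`a <= r0 <= R`).
#' @param D diffusivity, um^2/s.
#' @return an object of class `sphere_model`.
#' @export
sphere_model <- function(a, R, r0 = R, D = 10) {
  if (!(a > 0 && a <= r0 && r0 <= R && a < R))
    stop("need 0 < a <= r0 <= R with a < R", call. = FALSE)
  structure(list(a = a, R = R, r0 = r0, D = D), class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat("<sphere_model> a = ", format(x$a), ", R = ", format(x$R),
      ", r0 = ", format(x$r0), " um, D = ", format(x$D), " um^2/s\n", sep = "")
  invisible(x)
}

#' Continuum MFPT between concentric spheres
#'
#' Radial integration of `D Laplacian u = -1` with `u(a) = 0`, `u'(R) = 0`
#' gives `u(r0) = (1 / 3D) [R^3 (1/a - 1/r0) - (r0^2 - a^2) / 2]`.
#'
#' @param m a [sphere_model()].
#' @return MFPT in seconds.
#' @export
sphere_mfpt <- function(m) {
  stopifnot(inherits(m, "sphere_model"))
  (m$R^3 * (1 / m$a - 1 / m$r0) - (m$r0^2 - m$a^2) / 2) / (3 * m$D)
}

# log of v(r) = alpha R cosh(X) - sinh(X) with X = alpha (R - r), evaluated
# stably for large X (v ~ e^X (alpha R - 1) / 2)
.log_v <- function(X, aR) {
  small <- X < 30
  out <- numeric(length(X))
  out[small] <- log(aR * cosh(X[small]) - sinh(X[small]))
  big <- !small
  out[big] <- X[big] + log((aR - 1) / 2 + (aR + 1) / 2 * exp(-2 * X[big]))
  out
}

# log splitting probability at start radius r0
.sphere_log_Z <- function(m, lambda) {
  if (lambda == 0) return(0)
  alpha <- sqrt(lambda / m$D)
  log(m$a / m$r0) +
    .log_v(alpha * (m$R - m$r0), alpha * m$R) -
    .log_v(alpha * (m$R - m$a), alpha * m$R)
}

#' Continuum splitting probability between concentric spheres
#'
#' The probability `z(r0)` of reaching the absorbing inner sphere before a
#' rate-`lambda` inactivation, solving
#' `D (z'' + 2 z' / r) - lambda z = 0`, `z(a) = 1`, `z'(R) = 0`.  The
#' substitution `v = r z` reduces this to `D v'' = lambda v`, giving
#' `z(r0) = (a / r0) v(r0) / v(a)` with
#' `v(r) = alpha R cosh(alpha (R - r)) - sinh(alpha (R - r))`,
#' `alpha = sqrt(lambda / D)`, evaluated in log space so strong
#' inactivation does not overflow.  `lambda = 0` gives 1 (diffusion in a
#' bounded shell is recurrent).
#'
#' @param m a [sphere_model()].
#' @param lambda inactivation rate(s), s^-1 (each >= 0).
#' @return numeric vector of probabilities.
#' @export
sphere_Z <- function(m, lambda) {
  stopifnot(inherits(m, "sphere_model"), all(lambda >= 0))
  exp(vapply(lambda, function(l) .sphere_log_Z(m, l), numeric(1)))
}

#' Continuum conditional MFPT between concentric spheres
#'
#' `<T_lambda> = -d/dlambda log Z_lambda`, computed by Richardson-
#' extrapolated central differences of the log splitting probability with
#' step scaled to `lambda * 1e-4`.  Numerical differentiation keeps this
#' oracle independent of the algebra of any closed-form derivative.  At
#' strong inactivation the mean scales as `lambda^{-1/2}` -- the continuum
#' signature, distinct from the `lambda^{-1}` scaling of the voxelized
#' model.
#'
#' @inheritParams sphere_Z
#' @param lambda positive rate(s), s^-1; for `lambda = 0` use
#'   [sphere_mfpt()].
#' @return conditional mean arrival times, s.
#' @export
sphere_conditional_mean <- function(m, lambda) {
  stopifnot(inherits(m, "sphere_model"))
  if (any(lambda <= 0))
    stop("lambda must be positive; the lambda = 0 limit is sphere_mfpt()",
         call. = FALSE)
  vapply(lambda, function(l) {
    d1 <- function(u) (.sphere_log_Z(m, l + u) - .sphere_log_Z(m, l - u)) / (2 * u)
    u <- l * 1e-4
    -(4 * d1(u / 2) - d1(u)) / 3
  }, numeric(1))
}
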