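#' First-passage-time density to the nuclear membrane
#'
#' Converts a density trajectory into the first-passage-time (FPT) density
#' `f_h(t)` and survival probability `S_h(t)`.  The FPT density is the
#' probability flux into the nucleus,
#' `f_h(t) = D h sum_i n_i p_h(x_i, t)` (s^-1), where `n_i` counts nucleus
#' face-neighbors -- the unique scaling for which `f_h = -dS_h/dt` holds
#' exactly when `p_h` is a density per um^3.  Survival is exposed two ways:
#' from the probability mass (`S`) and from the cumulative trapezoidal
#' integral of `f` (`S_quad`); their agreement is a quadrature diagnostic.
#' If the trajectory carries an eigen tail, the density continues beyond
#' `T_switch` as the closed form `f(t) = sum_k a_k exp(mu_k t)`.
#'
#' @param traj a [evolve_density()] or [hybrid_trajectory()] result.
#' @return an object of class `fpt_density` with fields `times`, `f`, `S`,
#'   `S_quad`, `T_switch`, `tail` (`mu`, `a` flux amplitudes), `h`, `D`,
#'   `absorbed` (total probability of ever reaching the nucleus accounted
#'   for by samples plus tail), and `connected_mass` (source mass on the
#'   nucleus-connected component).
#' @export
fpt_density <- function(traj) {
  stopifnot(inherits(traj, "density_trajectory"))
  op <- traj$op
  h <- op$h
  f <- op$D * h * as.numeric(crossprod(traj$p, op$n_adj))
  S <- survival_mass(traj)
  cum_f <- .cumtrapz(traj$times, f)
  S_quad <- 1 - cum_f
  tail <- NULL
  tail_mass <- 0
  if (!is.null(traj$tail) && length(traj$tail$mu)) {
    a <- op$D * h * as.numeric(crossprod(traj$tail$modes, op$n_adj)) * traj$tail$coef
    tail <- list(mu = traj$tail$mu, a = a)
    tail_mass <- sum(-a / tail$mu * exp(tail$mu * traj$T_switch))
  }
  conn <- sum(traj$init$values[op$connected_rows]) * h^3
  structure(
    list(times = traj$times, f = f, S = S, S_quad = S_quad,
         T_switch = traj$T_switch, tail = tail, h = h, D = op$D,
         absorbed = cum_f[length(cum_f)] + tail_mass,
         connected_mass = conn),
    class = "fpt_density"
  )
}

#' @export
print.fpt_density <- function(x, ...) {
  cat("<fpt_density> ", length(x$times), " samples on [0, ",
      format(max(x$times)), "] s", sep = "")
  if (!is.null(x$tail)) cat(" + ", length(x$tail$mu), "-mode eigen tail", sep = "")
  cat("\n  absorbed probability = ", format(x$absorbed),
      " (source mass on connected component = ", format(x$connected_mass), ")\n",
      sep = "")
  invisible(x)
}

#' @describeIn fpt_density tidy the sampled density into a tibble with
#'   columns `time`, `f`, `survival`.
#' @param x an `fpt_density`.
#' @param ... unused.
#' @export
tidy.fpt_density <- function(x, ...) {
  tibble::tibble(time = x$times, f = x$f, survival = x$S)
}

#' @describeIn fpt_density one-row summary: absorbed probability, mean FPT
#'   (at lambda = 0), switch time, number of tail modes.
#' @export
glance.fpt_density <- function(x, ...) {
  tibble::tibble(
    absorbed = x$absorbed,
    mean_fpt = tryCatch(conditional_mean(x, 0), error = function(e) NA_real_),
    T_switch = x$T_switch,
    n_modes = if (is.null(x$tail)) 0L else length(x$tail$mu)
  )
}

# cumulative trapezoid with a leading zero
.cumtrapz <- function(t, y) {
  if (length(t) == 1L) return(0)
  as.numeric(pracma::cumtrapz(t, y))
}

# ---- hybrid quadrature of int_0^inf t^m exp(-lambda t) f(t) dt -------------
# sampled part: trapezoid on the stored grid; tail part: exact integrals of
# a_k exp((mu_k - lambda) t) from T_switch to infinity.
.fpt_moment <- function(fpt, lambda, m = 0L) {
  t <- fpt$times
  w <- exp(-lambda * t) * t^m * fpt$f
  if (m > 0L) w[t == 0] <- 0
  out <- pracma::trapz(t, w)
  if (!is.null(fpt$tail)) {
    s <- lambda - fpt$tail$mu      # > 0 for decaying modes
    Tt <- fpt$T_switch
    e <- exp(-s * Tt)
    out <- out + switch(as.character(m),
      "0" = sum(fpt$tail$a * e / s),
      "1" = sum(fpt$tail$a * e * (Tt / s + 1 / s^2)),
      "2" = sum(fpt$tail$a * e * (Tt^2 / s + 2 * Tt / s^2 + 2 / s^3)),
      stop("moment order must be 0, 1 or 2", call. = FALSE)
    )
  }
  out
}

#' Splitting probability by Laplace-transform quadrature
#'
#' `Z_lambda = int_0^inf exp(-lambda t) f_h(t) dt`: the probability of
#' reaching the nucleus before a rate-`lambda` inactivation clock fires.
#' Cumulative trapezoidal quadrature on the sampled times plus exact
#' integration of the eigen tail.  At `lambda = 0` this is the total
#' absorption probability (1 on fully connected geometries).
#'
#' @param fpt an [fpt_density()].
#' @param lambda inactivation rate(s), s^-1 (vectorized).
#' @return numeric vector of probabilities.
#' @export
laplace_Z <- function(fpt, lambda) {
  stopifnot(inherits(fpt, "fpt_density"), all(lambda >= 0))
  vapply(lambda, function(l) .fpt_moment(fpt, l, 0L), numeric(1))
}

#' Conditional mean and variance of the arrival time under inactivation
#'
#' For inactivation rate `lambda`, conditioning on arrival before
#' inactivation weights the FPT density by `exp(-lambda t)`:
#' the conditional mean is
#' `<T_lambda> = int t e^{-lambda t} f dt / int e^{-lambda t} f dt`
#' and the conditional variance is
#' `int (t^2 - <T>^2) e^{-lambda t} f dt / Z`.
#' Both use the hybrid sampled-plus-tail quadrature.  For rates above
#' ~1e3 s^-1 the integrand underflows the sampled grid and the resolvent
#' route ([resolvent_stats()]) is the recommended computation.
#'
#' @inheritParams laplace_Z
#' @return numeric vector (s, or s^2 for the variance).
#' @export
conditional_mean <- function(fpt, lambda) {
  stopifnot(inherits(fpt, "fpt_density"), all(lambda >= 0))
  vapply(lambda, function(l) {
    Z <- .fpt_moment(fpt, l, 0L)
    if (!is.finite(Z) || Z < 1e-300)
      stop("Z underflow at lambda = ", format(l),
           "; use the resolvent route (resolvent_stats)", call. = FALSE)
    .fpt_moment(fpt, l, 1L) / Z
  }, numeric(1))
}

#' @rdname conditional_mean
#' @export
conditional_variance <- function(fpt, lambda) {
  stopifnot(inherits(fpt, "fpt_density"), all(lambda >= 0))
  vapply(lambda, function(l) {
    Z <- .fpt_moment(fpt, l, 0L)
    if (!is.finite(Z) || Z < 1e-300)
      stop("Z underflow at lambda = ", format(l),
           "; use the resolvent route (resolvent_stats)", call. = FALSE)
    m1 <- .fpt_moment(fpt, l, 1L) / Z
    .fpt_moment(fpt, l, 2L) / Z - m1^2
  }, numeric(1))
}

#' Conditional CDF and median of the arrival time
#'
#' `conditional_cdf()` returns the function
#' `F_lambda(t) = int_0^t e^{-lambda s} f ds / Z_lambda`, evaluated by
#' interpolating the cumulative trapezoid on the sampled grid and
#' analytically beyond the eigen-tail switch time.  `conditional_median()`
#' solves `F_lambda(t) = 1/2` by bisection on a bracket grown geometrically
#' from the conditional mean, to 1e-8 relative tolerance.
#'
#' @inheritParams laplace_Z
#' @param lambda a single inactivation rate, s^-1.
#' @return `conditional_cdf()`: a vectorized function of time;
#'   `conditional_median()`: the median arrival time in seconds
#'   (vectorized over `lambda`).
#' @export
conditional_cdf <- function(fpt, lambda) {
  stopifnot(inherits(fpt, "fpt_density"), length(lambda) == 1L, lambda >= 0)
  Z <- .fpt_moment(fpt, lambda, 0L)
  if (!is.finite(Z) || Z <= 0) stop("Z_lambda is zero; CDF undefined", call. = FALSE)
  t_s <- fpt$times
  cum <- .cumtrapz(t_s, exp(-lambda * t_s) * fpt$f)
  cum_end <- cum[length(cum)]
  interp <- stats::approxfun(t_s, cum, rule = 2L)
  tail <- fpt$tail
  Tt <- fpt$T_switch
  function(t) {
    v <- interp(pmin(t, max(t_s)))
    if (!is.null(tail)) {
      beyond <- t > Tt
      if (any(beyond)) {
        s <- lambda - tail$mu
        add <- vapply(t[beyond], function(tt)
          sum(tail$a / s * (exp(-s * Tt) - exp(-s * tt))), numeric(1))
        v[beyond] <- cum_end + add
      }
    }
    pmin(v / Z, 1)
  }
}

#' @rdname conditional_cdf
#' @export
conditional_median <- function(fpt, lambda) {
  stopifnot(inherits(fpt, "fpt_density"))
  vapply(lambda, function(l) {
    Fl <- conditional_cdf(fpt, l)
    m <- conditional_mean(fpt, l)
    lo <- m; hi <- m
    for (it in 1:200) { if (Fl(lo) <= 0.5) break; lo <- lo / 2 }
    for (it in 1:200) { if (Fl(hi) >= 0.5) break; hi <- hi * 2 }
    stats::uniroot(function(t) Fl(t) - 0.5, lower = lo, upper = hi,
                   tol = 1e-8 * m)$root
  }, numeric(1))
}

#' Signal curve: arrival rate at the nucleus for fixed delivered signal
#'
#' The number of molecules per second reaching the nuclear membrane when
#' the total number that ultimately arrive is held at `N`:
#' `N e^{-lambda t} f_h(t) / Z_lambda`.  Holding `N` fixed as `lambda`
#' grows requires releasing `N0 = N / Z_lambda` molecules at the membrane;
#' `N0` is attached as an attribute.  With `N = 1` the curve is the
#' conditional arrival-time density.
#'
#' @inheritParams conditional_cdf
#' @param N number of molecules that reach the nucleus.
#' @return a tibble (class `signal_curve`) with columns `time`, `signal`
#'   (molecules/s), and attributes `lambda`, `N`, `N0`.
#' @export
signal_curve <- function(fpt, lambda, N = 1) {
  stopifnot(inherits(fpt, "fpt_density"), length(lambda) == 1L, lambda >= 0, N >= 1)
  Z <- .fpt_moment(fpt, lambda, 0L)
  if (!is.finite(Z) || Z <= 0) stop("Z_lambda is zero; signal undefined", call. = FALSE)
  t_s <- fpt$times
  sig <- N * exp(-lambda * t_s) * fpt$f / Z
  out <- tibble::tibble(time = t_s, signal = sig)
  if (!is.null(fpt$tail)) {
    mu1 <- max(fpt$tail$mu)
    t_ext_end <- fpt$T_switch + log(1e8) / (lambda - mu1)  # mu1 < 0
    if (t_ext_end > fpt$T_switch * (1 + 1e-9)) {
      t_ext <- seq(fpt$T_switch, t_ext_end, length.out = 200L)[-1L]
      f_ext <- as.numeric(exp(outer(t_ext, fpt$tail$mu)) %*% fpt$tail$a)
      out <- dplyr::bind_rows(out, tibble::tibble(
        time = t_ext, signal = N * exp(-lambda * t_ext) * f_ext / Z))
    }
  }
  attr(out, "lambda") <- lambda
  attr(out, "N") <- N
  attr(out, "N0") <- N / Z
  class(out) <- c("signal_curve", class(out))
  out
}

#' Arrival-number statistics for independent molecules
#'
#' With `N0` molecules released independently and each reaching the nucleus
#' with probability `Z`, the number that arrive is binomial `B(N0, Z)`:
#' mean `N0 Z` and coefficient of variation `sqrt((1 - Z) / (N0 Z))`, which
#' for strong inactivation (`Z -> 0`) approaches `1 / sqrt(E[N])`.
#'
#' @param N0 number of molecules released at the membrane (>= 1).
#' @param Z per-molecule splitting probability in (0, 1].
#' @return one-row tibble: `N0`, `Z`, `mean`, `cv`, `cv_large_lambda`.
#' @export
arrival_number_stats <- function(N0, Z) {
  stopifnot(all(N0 >= 1), all(Z > 0), all(Z <= 1))
  m <- N0 * Z
  tibble::tibble(
    N0 = N0, Z = Z, mean = m,
    cv = sqrt((1 - Z) / m),
    cv_large_lambda = 1 / sqrt(m)
  )
}
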