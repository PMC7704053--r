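#' Conditional statistics by the resolvent route
#'
#' Computes the splitting probability and conditional moments without time
#' integration, from sparse linear solves against the resolvent
#' `(lambda I - D Delta_h)^{-1}`:
#' * `z = (lambda I - D Delta_h)^{-1} (D / h^2) n` gives the per-voxel
#'   probability `z_i` of reaching the nucleus before inactivation
#'   (0 <= z_i <= 1), and `Z = h^3 sum_i g_i z_i`;
#' * one further solve gives the conditional mean
#'   `<T> = (g . w) / (g . z)` with `w = (lambda I - D Delta_h)^{-1} z`;
#' * a third gives the conditional second moment
#'   `2 (g . (lambda I - D Delta_h)^{-1} w) / (g . z)`.
#'
#' This route is exact in lambda (no quadrature) and is the recommended
#' computation for strong inactivation (lambda above ~1e3 s^-1), where
#' `exp(-lambda t) f(t)` underflows sampled time grids.  At `lambda = 0`
#' the system is restricted to the nucleus-connected component and requires
#' the source to live there.
#'
#' @param op a [diffusion_operator()].
#' @param g an initial density on the same masks.
#' @param lambda inactivation rates, s^-1 (vectorized; each >= 0).
#' @param moments if `FALSE`, skip the mean/variance solves.
#' @param solver `"chol"` (sparse Cholesky, default) or `"cg"` (Jacobi-
#'   preconditioned conjugate gradient, for grids too large to factor).
#' @return a tibble with columns `lambda`, `Z`, `mean_s`, `var_s2`, and
#'   `method = "resolvent"`.
#' @export
resolvent_stats <- function(op, g, lambda, moments = TRUE,
                            solver = c("chol", "cg")) {
  .check_density_for(op, g)
  solver <- match.arg(solver)
  stopifnot(all(lambda >= 0))
  h <- op$h
  rhs_full <- (op$D / h^2) * op$n_adj
  rows <- purrr::map(lambda, function(l) {
    if (l == 0) {
      cc <- op$connected_rows
      if (any(g$values[-cc] != 0) && length(cc) < nrow(op$A))
        stop("lambda = 0 with source mass off the nucleus-connected component; ",
             "use laplace_Z on a trajectory instead", call. = FALSE)
      M <- -op$A[cc, cc, drop = FALSE]
      gv <- g$values[cc]
      rhs <- rhs_full[cc]
    } else {
      M <- Matrix::Diagonal(nrow(op$A), l) - op$A
      gv <- g$values
      rhs <- rhs_full
    }
    lin_solve <- if (solver == "chol") {
      Ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
      function(b) as.numeric(Matrix::solve(Ch, b))
    } else {
      function(b) .pcg(M, b, tol = 1e-12)
    }
    z <- lin_solve(rhs)
    Z <- h^3 * sum(gv * z)
    if (!moments)
      return(tibble::tibble(lambda = l, Z = Z, mean_s = NA_real_, var_s2 = NA_real_))
    w <- lin_solve(z)
    gz <- sum(gv * z)
    m1 <- sum(gv * w) / gz
    v <- lin_solve(w)
    m2 <- 2 * sum(gv * v) / gz
    tibble::tibble(lambda = l, Z = Z, mean_s = m1, var_s2 = m2 - m1^2)
  })
  out <- dplyr::bind_rows(rows)
  out$method <- "resolvent"
  out
}

#' @rdname resolvent_stats
#' @details `resolvent_Z()` returns just the splitting probabilities; with
#'   `per_voxel = TRUE` it instead returns the full per-voxel splitting
#'   probability vector `z` for a single rate.
#' @param per_voxel return the per-voxel splitting probabilities.
#' @export
resolvent_Z <- function(op, g, lambda, per_voxel = FALSE) {
  if (per_voxel) {
    stopifnot(length(lambda) == 1L, lambda > 0)
    M <- Matrix::Diagonal(nrow(op$A), lambda) - op$A
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
    return(as.numeric(Matrix::solve(Ch, (op$D / op$h^2) * op$n_adj)))
  }
  resolvent_stats(op, g, lambda, moments = FALSE)$Z
}

#' Conditional-statistics table across an inactivation-rate grid
#'
#' Tabulates `Z_lambda`, the conditional mean, variance, and median of the
#' arrival time over a grid of inactivation rates, choosing per rate
#' between the time-domain (Laplace quadrature of the sampled FPT density)
#' and resolvent routes.  Under `method = "auto"`, rates up to
#' `lambda_switch` use the time-domain route (which also yields the
#' median); stronger rates use the resolvent route (median `NA`: it has no
#' Laplace-domain expression).
#'
#' @param lambda inactivation-rate grid, s^-1.
#' @param fpt an [fpt_density()] (required for the time-domain route).
#' @param op,g operator and initial density (required for the resolvent
#'   route).
#' @param method `"auto"`, `"time_domain"`, or `"resolvent"`.
#' @param lambda_switch route cross-over under `"auto"` (default 1e3 s^-1).
#' @return a tibble (class `conditional_stats`) with columns `lambda`, `Z`,
#'   `mean_s`, `var_s2`, `median_s`, `method`.
#' @export
conditional_stats <- function(lambda, fpt = NULL, op = NULL, g = NULL,
                              method = c("auto", "time_domain", "resolvent"),
                              lambda_switch = 1e3) {
  method <- match.arg(method)
  use_td <- switch(method,
    auto = if (is.null(fpt)) rep(FALSE, length(lambda)) else lambda <= lambda_switch,
    time_domain = rep(TRUE, length(lambda)),
    resolvent = rep(FALSE, length(lambda))
  )
  if (any(use_td) && is.null(fpt))
    stop("time-domain route requested but no fpt density supplied", call. = FALSE)
  if (any(!use_td) && (is.null(op) || is.null(g)))
    stop("resolvent route requested but op/g not supplied", call. = FALSE)
  parts <- list()
  if (any(use_td)) {
    l_td <- lambda[use_td]
    parts$td <- tibble::tibble(
      lambda = l_td,
      Z = laplace_Z(fpt, l_td),
      mean_s = conditional_mean(fpt, l_td),
      var_s2 = conditional_variance(fpt, l_td),
      median_s = conditional_median(fpt, l_td),
      method = "time_domain"
    )
  }
  if (any(!use_td)) {
    rs <- resolvent_stats(op, g, lambda[!use_td])
    rs$median_s <- NA_real_
    parts$rs <- rs[, c("lambda", "Z", "mean_s", "var_s2", "median_s", "method")]
  }
  out <- dplyr::arrange(dplyr::bind_rows(parts), lambda)
  class(out) <- c("conditional_stats", class(out))
  out
}

#' @describeIn conditional_stats one-row summary across the rate grid.
#' @param x a `conditional_stats` table.
#' @param ... unused.
#' @export
glance.conditional_stats <- function(x, ...) {
  tibble::tibble(
    n_lambda = nrow(x), lambda_min = min(x$lambda), lambda_max = max(x$lambda),
    Z_min = min(x$Z), mean_min_s = min(x$mean_s),
    monotone_Z = !is.unsorted(rev(x$Z), strictly = TRUE),
    monotone_mean = !is.unsorted(rev(x$mean_s), strictly = TRUE)
  )
}
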