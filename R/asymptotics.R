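#' Graph distance to the nucleus
#'
#' Breadth-first search over the face-adjacency graph of the cytosol,
#' started simultaneously from every nucleus-adjacent cytosol voxel
#' (distance 1, matching the convention that a source with a nucleus
#' face-neighbor has distance 1).  Voxels in components with no nucleus
#' contact get infinite distance.  When a `source` is supplied, the source
#' distance `d_g = d(G_h, N_h)` is the minimum over its voxels; it governs
#' the strong-inactivation asymptotics of the conditional arrival time.
#'
#' @param masks a [build_masks()] result.
#' @param source optional source: an `init_density` (its support is used) or
#'   linear voxel indices within the cytosol.
#' @return an object of class `distance_field`: integer-valued `d` per
#'   cytosol voxel (`Inf` where unreachable), `voxels`, `dims`, and `d_g`
#'   (`NA` when no source was given).
#' @export
graph_distance <- function(masks, source = NULL) {
  stopifnot(inherits(masks, "geometry_masks"))
  n <- length(masks$cytosol)
  d <- rep(Inf, n)
  frontier <- which(masks$n_adj > 0L)
  d[frontier] <- 1
  lev <- 1
  nb <- masks$nb
  while (length(frontier)) {
    nxt <- unique(as.vector(nb[frontier, , drop = FALSE]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[!is.finite(d[nxt])]
    lev <- lev + 1
    d[nxt] <- lev
    frontier <- nxt
  }
  d_g <- NA_real_
  if (!is.null(source)) {
    rows <- if (inherits(source, "init_density")) source$support
            else .rows_of(masks, as.integer(source))
    if (length(rows) == 0L) stop("empty source", call. = FALSE)
    d_g <- min(d[rows])
  }
  structure(list(d = d, voxels = masks$cytosol, dims = masks$dims, d_g = d_g),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  fin <- x$d[is.finite(x$d)]
  cat("<distance_field> ", length(x$d), " voxels, d in [",
      min(fin), ", ", max(fin), "]", sep = "")
  if (!is.na(x$d_g)) cat(", d_g = ", x$d_g, sep = "")
  cat("\n")
  invisible(x)
}

#' @describeIn graph_distance tidy into a tibble of 0-based voxel indices
#'   and hop counts.
#' @param x a `distance_field`.
#' @param ... unused.
#' @export
tidy.distance_field <- function(x, ...) {
  ijk <- .vox_ijk(x$voxels, x$dims)
  tibble::tibble(i = ijk[, 1L] - 1L, j = ijk[, 2L] - 1L, k = ijk[, 3L] - 1L,
                 d = x$d)
}

#' Power sums of the discrete Laplacian applied to the initial density
#'
#' `sum_i (Delta_h^k g)(x_i)` for `k = 0..k_max`, computed by repeated
#' sparse application of the bare Laplacian `Delta_h` (the diffusivity is
#' factored out).  By the support-propagation argument these sums vanish
#' exactly for `1 <= k < d(G_h, N_h)`: each application of the Laplacian
#' moves probability mass within the cytosol until the support first
#' borders the nucleus, so mass is conserved.  The first nonzero sum (at
#' `k = d_g`) sets the leading coefficient of the short-time expansion of
#' the FPT density.  Cancellation is the point here, so the running maximum
#' magnitude of the summed field is reported for scaling tolerances.
#'
#' @param op a [diffusion_operator()].
#' @param g an initial density on the same masks.
#' @param k_max highest power (>= 1).
#' @return a tibble with columns `k`, `sum` (units um^-3 h^-2k), and
#'   `max_abs` (largest voxel magnitude of `Delta_h^k g`).
#' @export
laplacian_power_sums <- function(op, g, k_max) {
  .check_density_for(op, g)
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1L)
  L <- op$A / op$D
  v <- g$values
  out <- vector("list", k_max + 1L)
  out[[1L]] <- tibble::tibble(k = 0L, sum = sum(v), max_abs = max(abs(v)))
  for (k in seq_len(k_max)) {
    v <- as.numeric(L %*% v)
    out[[k + 1L]] <- tibble::tibble(k = k, sum = sum(v), max_abs = max(abs(v)))
  }
  dplyr::bind_rows(out)
}

#' Strong-inactivation asymptotics
#'
#' For inactivation rate `lambda -> infinity`, the splitting probability is
#' dominated by the shortest nearest-neighbor paths to the nucleus:
#' `Z ~ -h^3 D^{d_g} lambda^{-d_g} sum_i (Delta_h^{d_g} g)(x_i)`
#' (`asymptotic_Z()`), the conditional mean approaches `d_g / lambda`
#' (`asymptotic_mean()`), and the ratio of conditional means between two
#' geometries sharing a source approaches the ratio of their graph
#' distances (`ratio_limit()`).  The `Z` formula is derived for
#' `d_g > 1` but agrees with the closed form at `d_g = 1`, so it is applied
#' for all `d_g >= 1`.
#'
#' @param op a [diffusion_operator()].
#' @param g an initial density on the same masks.
#' @param d_g graph distance from the source support to the nucleus (see
#'   [graph_distance()]).
#' @param lambda inactivation rate(s), s^-1.
#' @return `asymptotic_Z()` and `asymptotic_mean()`: numeric vectors along
#'   `lambda`; `ratio_limit()`: a single dimensionless ratio.
#' @export
asymptotic_Z <- function(op, g, d_g, lambda) {
  stopifnot(is.finite(d_g), d_g >= 1)
  if (!is.finite(d_g)) stop("d_g must be finite", call. = FALSE)
  ps <- laplacian_power_sums(op, g, k_max = as.integer(d_g))
  s_d <- ps$sum[ps$k == as.integer(d_g)]
  -op$h^3 * op$D^d_g * lambda^(-d_g) * s_d
}

#' @rdname asymptotic_Z
#' @export
asymptotic_mean <- function(d_g, lambda) {
  stopifnot(d_g >= 1, all(lambda > 0))
  d_g / lambda
}

#' @rdname asymptotic_Z
#' @param masks_ref,masks_alt geometry masks for the two variants (e.g.
#'   physiological and no-organelles), sharing the source voxels.
#' @param source common source voxels (linear indices, cytosol in both).
#' @export
ratio_limit <- function(masks_ref, masks_alt, source) {
  d_ref <- graph_distance(masks_ref, source)$d_g
  d_alt <- graph_distance(masks_alt, source)$d_g
  if (!is.finite(d_ref) || !is.finite(d_alt))
    stop("source cannot reach the nucleus in one of the geometries", call. = FALSE)
  d_ref / d_alt
}

#' Fit a power-law scaling exponent
#'
#' Least-squares slope of `log(value)` against `log(lambda)`; returns the
#' absolute slope.  Used to distinguish the semi-discrete strong-
#' inactivation scaling (conditional mean ~ `lambda^-1`) from the continuum
#' one (~ `lambda^-1/2`).
#'
#' @param lambda positive rates (>= 3 points).
#' @param values positive values to fit.
#' @return absolute value of the fitted log-log slope.
#' @export
scaling_exponent_fit <- function(lambda, values) {
  if (length(lambda) < 3L || length(values) != length(lambda))
    stop("need at least 3 (lambda, value) pairs", call. = FALSE)
  if (any(values <= 0) || any(lambda <= 0))
    stop("scaling fit requires positive values", call. = FALSE)
  abs(unname(stats::coef(stats::lm(log(values) ~ log(lambda)))[2L]))
}
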