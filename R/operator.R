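#' Assemble the discrete diffusion operator
#'
#' Builds the sparse symmetric operator `D * Delta_h` acting on the cytosol
#' voxels.  The stencil couples face-adjacent cytosol voxels with rate
#' `D / h^2`; reflecting boundaries (organelles, cell membrane, exterior)
#' appear simply as absent couplings, and absorption at the nuclear membrane
#' enters as a sink `-(D / h^2) * n_i` on the diagonal, where `n_i` counts
#' the nucleus face-neighbors of voxel i.  The diagonal is therefore
#' `-(D / h^2) * (#cytosol neighbors + n_i)` and all eigenvalues are
#' non-positive, strictly negative on the nucleus-connected component.
#'
#' @param masks a [build_masks()] result.
#' @param D diffusivity, um^2/s (default 10, a typical cytosolic protein).
#' @return an object of class `diffusion_operator`: the sparse matrix `A`
#'   (s^-1, class `dgCMatrix`), nucleus-adjacency counts `n_adj`, `D`, `h`,
#'   the linear voxel indices `voxels` mapping rows back to the grid,
#'   `connected_rows` (rows on the nucleus-connected component), and `dims`.
#' @export
diffusion_operator <- function(masks, D = 10) {
  stopifnot(inherits(masks, "geometry_masks"))
  if (length(masks$cytosol) == 0L) stop("empty cytosol", call. = FALSE)
  if (!(D > 0)) stop("D must be positive", call. = FALSE)
  n <- length(masks$cytosol)
  h <- masks$h
  w <- D / h^2
  nb <- masks$nb
  deg <- rowSums(nb > 0L)
  ii <- rep(seq_len(n), times = 6L)
  jj <- as.vector(nb)
  keep <- jj > 0L
  A <- Matrix::sparseMatrix(
    i = c(ii[keep], seq_len(n)),
    j = c(jj[keep], seq_len(n)),
    x = c(rep(w, sum(keep)), -w * (deg + masks$n_adj)),
    dims = c(n, n)
  )
  structure(
    list(A = A, n_adj = masks$n_adj, D = D, h = h,
         voxels = masks$cytosol,
         connected_rows = match(masks$connected, masks$cytosol),
         dims = masks$dims),
    class = "diffusion_operator"
  )
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat("<diffusion_operator> ", nrow(x$A), " cytosol voxels, D = ", format(x$D),
      " um^2/s, h = ", format(x$h), " um\n", sep = "")
  cat(sprintf("  nucleus-adjacent voxels: %d; nucleus-connected rows: %d/%d\n",
              sum(x$n_adj > 0L), length(x$connected_rows), nrow(x$A)))
  invisible(x)
}

.check_density_for <- function(op, g) {
  stopifnot(inherits(op, "diffusion_operator"), inherits(g, "init_density"))
  if (length(g$values) != nrow(op$A) || !identical(g$voxels, op$voxels))
    stop("initial density was built on different masks than the operator",
         call. = FALSE)
  invisible(TRUE)
}

#' Integrate the semi-discrete diffusion equation
#'
#' Solves `dp/dt = D * Delta_h p` (optionally with a uniform inactivation
#' sink `- lambda p`) from the initial density `g` with a stiff sparse ODE
#' integrator (`deSolve::lsodes`) at absolute and relative tolerances 1e-8.
#' Output is sampled on a dense log-spaced time grid (plus t = 0) spanning
#' nine decades below `t_end`, dense enough for the trapezoidal quadratures
#' downstream.
#'
#' @param op a [diffusion_operator()].
#' @param g an [shell_init()]/[patch_init()]/[point_init()] density.
#' @param t_end final time, s.
#' @param times optional explicit output times (must start at 0, increasing).
#' @param n_out number of log-spaced output points when `times` is `NULL`.
#' @param lambda uniform inactivation rate added as `-lambda p` (default 0).
#' @param atol,rtol integrator tolerances.
#' @return an object of class `density_trajectory`: `times`, matrix `p`
#'   (voxels x times, um^-3), the operator, `tail = NULL`, `T_switch = Inf`.
#' @export
evolve_density <- function(op, g, t_end, times = NULL, n_out = 1000L,
                           lambda = 0, atol = 1e-8, rtol = 1e-8) {
  .check_density_for(op, g)
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- c(0, exp(seq(log(t_end) - 9 * log(10), log(t_end), length.out = n_out)))
  }
  if (times[1L] != 0 || is.unsorted(times, strictly = TRUE))
    stop("output times must start at 0 and increase strictly", call. = FALSE)
  A <- op$A
  if (lambda > 0) A <- A - Matrix::Diagonal(nrow(A), lambda)
  s <- Matrix::summary(methods::as(A, "TsparseMatrix"))  # sparsity for lsodes
  inz <- unique(rbind(cbind(s$i, s$j), cbind(seq_len(nrow(A)), seq_len(nrow(A)))))
  inz <- inz[order(inz[, 2L], inz[, 1L]), , drop = FALSE]
  n <- nrow(A)
  nnz <- nrow(inz)
  # lsodes workspace needs room for the sparse LU factors, whose fill-in is
  # geometry dependent; retry with a larger workspace if the first guess is
  # too small
  lrw <- 200 + 20 * n + 60 * nnz
  sol <- NULL
  for (attempt in 1:5) {
    sparse_args <- if (nnz >= 2L) {
      list(sparsetype = "sparseusr", inz = inz,
           lrw = as.integer(min(lrw, 2^31 - 1)),
           liw = as.integer(min(100 + 3 * n + nnz, 2^31 - 1)))
    } else {
      list(sparsetype = "sparseint")
    }
    sol <- tryCatch(
      do.call(deSolve::lsodes, c(list(
        y = g$values, times = times,
        func = function(t, y, parms) list(as.numeric(A %*% y)),
        atol = atol, rtol = rtol, maxsteps = 10000L), sparse_args)),
      error = function(e) e)
    if (!inherits(sol, "error")) break
    if (!grepl("illegal input", conditionMessage(sol))) stop(sol)
    lrw <- lrw * 3
  }
  if (inherits(sol, "error")) stop(sol)
  if (attr(sol, "istate")[1L] < 0)
    stop("stiff integrator failed; last accepted time ",
         format(max(sol[, 1L])), call. = FALSE)
  structure(
    list(times = sol[, 1L], p = t(unname(sol[, -1L, drop = FALSE])),
         op = op, init = g, tail = NULL, T_switch = Inf, lambda = lambda),
    class = "density_trajectory"
  )
}

#' @export
print.density_trajectory <- function(x, ...) {
  cat("<density_trajectory> ", nrow(x$p), " voxels x ", length(x$times),
      " times, t in [0, ", format(max(x$times)), "] s", sep = "")
  if (is.finite(x$T_switch))
    cat(", eigen tail beyond T_switch = ", format(x$T_switch), " s", sep = "")
  cat("\n")
  invisible(x)
}

#' Survival probability along a trajectory
#'
#' `sum_i p_h(x_i, t) h^3` at each stored time.
#'
#' @param traj a [evolve_density()] or [hybrid_trajectory()] result.
#' @return numeric vector of survival probabilities.
#' @export
survival_mass <- function(traj) {
  stopifnot(inherits(traj, "density_trajectory"))
  colSums(traj$p) * traj$op$h^3
}

#' Eigenvector-expansion tail of the diffusion operator
#'
#' Computes the eigenpairs of `D * Delta_h` with small-magnitude eigenvalues
#' (default retention: |mu| < 1 s^-1) and the expansion coefficients of the
#' initial density, giving the closed form
#' `p(t) = sum_k c_k exp(mu_k t) v_k` valid once faster modes have decayed.
#' Modes are orthonormal under the h^3-weighted inner product and
#' `c_k = h^3 <v_k, g>`.
#'
#' Small operators are decomposed densely with `eigen()`; large ones use
#' ARPACK (via igraph) in shift-invert mode on a sparse Cholesky
#' factorization, which targets the smallest-magnitude end of the spectrum.
#'
#' @param op a [diffusion_operator()].
#' @param g an initial density on the same masks.
#' @param cutoff eigenvalue magnitude retention cutoff, s^-1.
#' @param max_modes cap on the number of retained modes; a warning is issued
#'   if the cutoff set is truncated.
#' @param method `"auto"`, `"dense"`, or `"arpack"`.
#' @param dense_limit largest size decomposed densely under `"auto"`.
#' @return an object of class `eigen_tail`: `mu` (eigenvalues, s^-1),
#'   `modes` (voxels x modes, um^-3/2 normalization), `coef`, `h`.
#' @export
eigen_tail <- function(op, g, cutoff = 1, max_modes = 200L,
                       method = c("auto", "dense", "arpack"),
                       dense_limit = 3000L) {
  .check_density_for(op, g)
  method <- match.arg(method)
  n <- nrow(op$A)
  if (method == "auto") method <- if (n <= dense_limit) "dense" else "arpack"
  if (method == "dense") {
    E <- eigen(as.matrix(op$A), symmetric = TRUE)
    mu <- E$values
    keep <- which(abs(mu) < cutoff)
    truncated <- length(keep) > max_modes
    keep <- keep[order(abs(mu[keep]))][seq_len(min(length(keep), max_modes))]
    vecs <- E$vectors[, keep, drop = FALSE]
    mu <- mu[keep]
  } else {
    nev <- min(max_modes + 1L, n - 1L)
    sigma <- max(1e-10, 1e-8 * op$D / op$h^2)
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(
      Matrix::Diagonal(n, sigma) - op$A), LDL = FALSE)
    res <- igraph::arpack(
      function(x, extra) as.numeric(Matrix::solve(Ch, x)),
      sym = TRUE,
      options = list(n = n, nev = nev, ncv = min(n, max(4L * nev, 20L)),
                     which = "LA", maxiter = 5000L)
    )
    mu_all <- sigma - 1 / res$values
    keep <- which(abs(mu_all) < cutoff)
    truncated <- length(keep) >= nev  # may not have seen the whole cutoff set
    keep <- keep[order(abs(mu_all[keep]))][seq_len(min(length(keep), max_modes))]
    vecs <- res$vectors[, keep, drop = FALSE]
    mu <- mu_all[keep]
  }
  if (isTRUE(truncated))
    warning("eigen tail truncated at max_modes = ", max_modes,
            " before exhausting |mu| < ", format(cutoff), call. = FALSE)
  h <- op$h
  modes <- vecs / h^1.5                       # orthonormal under h^3 weights
  coef <- as.numeric(h^3 * crossprod(modes, g$values))
  structure(list(mu = mu, modes = modes, coef = coef, h = h),
            class = "eigen_tail")
}

#' @export
print.eigen_tail <- function(x, ...) {
  cat("<eigen_tail> ", length(x$mu), " mode(s)", sep = "")
  if (length(x$mu))
    cat("; slowest mu = ", format(max(x$mu)), " s^-1, fastest retained mu = ",
        format(min(x$mu)), " s^-1", sep = "")
  cat("\n")
  invisible(x)
}

# density reconstructed from the tail at times t (voxels x times)
.tail_density <- function(tail, t) {
  if (length(tail$mu) == 0L) stop("empty eigen tail", call. = FALSE)
  tail$modes %*% (exp(outer(tail$mu, t)) * tail$coef)
}

# survival from the tail: S(t) = h^3 sum_i p_i(t)
.tail_survival <- function(tail, t) {
  b <- tail$h^3 * colSums(tail$modes) * tail$coef
  as.numeric(exp(outer(t, tail$mu)) %*% b)
}

#' Hybrid trajectory: stiff integrator early, eigen expansion late
#'
#' Runs the stiff integrator up to the end of the scan window and attaches
#' the eigenvector-expansion tail from the first time in the window where
#' the integrator and expansion survival probabilities agree to an absolute
#' error below `abs_tol` and a relative error below `rel_tol` (times where
#' both values are below `abs_tol` count as agreeing).  Stored samples are
#' truncated at the switch time; the tail covers all later times in closed
#' form.  If the tail is empty or the criteria are never met, the full
#' integrator trajectory is returned with a warning.
#'
#' @inheritParams evolve_density
#' @param window scan window (s) for the switch time; default `c(1, 10)`.
#' @param abs_tol,rel_tol agreement thresholds (defaults 1e-5 and 0.01).
#' @param cutoff,max_modes,eigen_method passed to [eigen_tail()].
#' @return a `density_trajectory` with `tail` and finite `T_switch` on
#'   success.
#' @export
hybrid_trajectory <- function(op, g, window = c(1, 10), n_out = 1000L,
                              times = NULL, abs_tol = 1e-5, rel_tol = 0.01,
                              cutoff = 1, max_modes = 200L,
                              eigen_method = "auto",
                              atol = 1e-8, rtol = 1e-8) {
  stopifnot(length(window) == 2L, window[1L] > 0, window[2L] > window[1L])
  traj <- evolve_density(op, g, t_end = window[2L], times = times,
                         n_out = n_out, atol = atol, rtol = rtol)
  tail <- eigen_tail(op, g, cutoff = cutoff, max_modes = max_modes,
                     method = eigen_method)
  if (length(tail$mu) == 0L) {
    warning("eigen tail empty under cutoff |mu| < ", format(cutoff),
            " s^-1; returning integrator-only trajectory", call. = FALSE)
    return(traj)
  }
  in_win <- which(traj$times >= window[1L] & traj$times <= window[2L])
  S_int <- survival_mass(traj)[in_win]
  S_tail <- .tail_survival(tail, traj$times[in_win])
  adiff <- abs(S_int - S_tail)
  rdiff <- adiff / pmax(abs(S_int), abs(S_tail), .Machine$double.xmin)
  ok <- adiff < abs_tol & (rdiff < rel_tol | (abs(S_int) < abs_tol & abs(S_tail) < abs_tol))
  if (!any(ok)) {
    warning("integrator and eigen expansion never agreed in the scan window; ",
            "returning integrator-only trajectory", call. = FALSE)
    return(traj)
  }
  sw <- in_win[which(ok)[1L]]
  traj$times <- traj$times[seq_len(sw)]
  traj$p <- traj$p[, seq_len(sw), drop = FALSE]
  traj$tail <- tail
  traj$T_switch <- traj$times[sw]
  traj
}
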