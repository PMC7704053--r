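#' Mean first-passage-time field
#'
#' Solves the discrete MFPT system `D * Delta_h u = -1` on the nucleus-
#' connected component of the cytosol: `u_i` is the expected time for a
#' molecule started at voxel i to first reach the nucleus.  Voxels with no
#' path to the nucleus have infinite MFPT and are flagged unreachable
#' rather than raising an error.
#'
#' The connected-component system is symmetric positive definite; it is
#' solved by sparse Cholesky up to `chol_limit` unknowns and by Jacobi-
#' preconditioned conjugate gradient beyond that.
#'
#' @param op a [diffusion_operator()].
#' @param method `"auto"`, `"chol"`, or `"cg"`.
#' @param chol_limit size threshold for the automatic choice.
#' @param cg_tol relative residual tolerance for the CG route.
#' @return an object of class `mfpt_field`: `u` (s, `Inf` on unreachable
#'   voxels), logical `reachable`, `voxels`, `dims`, `h`.
#' @export
mfpt_field <- function(op, method = c("auto", "chol", "cg"),
                       chol_limit = 60000L, cg_tol = 1e-10) {
  stopifnot(inherits(op, "diffusion_operator"))
  method <- match.arg(method)
  n <- nrow(op$A)
  cc <- op$connected_rows
  if (method == "auto") method <- if (length(cc) <= chol_limit) "chol" else "cg"
  B <- -op$A[cc, cc, drop = FALSE]
  b <- rep(1, length(cc))
  u_cc <- if (method == "chol") {
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(B), LDL = FALSE), b))
  } else {
    .pcg(B, b, tol = cg_tol)
  }
  u <- rep(Inf, n)
  u[cc] <- u_cc
  reachable <- logical(n)
  reachable[cc] <- TRUE
  structure(
    list(u = u, reachable = reachable, voxels = op$voxels,
         dims = op$dims, h = op$h, D = op$D),
    class = "mfpt_field"
  )
}

#' @export
print.mfpt_field <- function(x, ...) {
  fin <- x$u[is.finite(x$u)]
  cat("<mfpt_field> ", length(x$u), " voxels (", sum(!x$reachable),
      " unreachable)\n", sep = "")
  if (length(fin))
    cat(sprintf("  u: min %.4g, median %.4g, max %.4g s\n",
                min(fin), stats::median(fin), max(fin)))
  invisible(x)
}

#' @describeIn mfpt_field tidy into a tibble with 0-based voxel indices,
#'   `u_s`, and `reachable`.
#' @param x an `mfpt_field`.
#' @param ... unused.
#' @export
tidy.mfpt_field <- function(x, ...) {
  ijk <- .vox_ijk(x$voxels, x$dims)
  tibble::tibble(i = ijk[, 1L] - 1L, j = ijk[, 2L] - 1L, k = ijk[, 3L] - 1L,
                 u_s = x$u, reachable = x$reachable)
}

#' @describeIn mfpt_field one-row summary of the reachable MFPTs.
#' @export
glance.mfpt_field <- function(x, ...) {
  fin <- x$u[is.finite(x$u)]
  tibble::tibble(n_voxels = length(x$u), n_unreachable = sum(!x$reachable),
                 mean_s = mean(fin), median_s = stats::median(fin),
                 sd_s = stats::sd(fin), cv = stats::sd(fin) / mean(fin))
}

#' Shell-resolved MFPT comparison between geometry variants
#'
#' For every membrane-shell voxel of the reference (physiological) geometry,
#' pairs the MFPT in the reference field with the MFPT in an alternative
#' (barrier-reduced) field and their ratio -- the per-release-site measure
#' of how much organelle barriers slow the search.  Shell voxels
#' unreachable in either field are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param field_ref MFPT field of the reference (barrier-rich) variant.
#' @param field_alt MFPT field of the alternative variant; its cytosol must
#'   contain the reference cytosol.
#' @param shell linear voxel indices of the release shell (defaults must be
#'   supplied, typically `membrane_shell(masks_ref)`).
#' @return a tibble (class `mfpt_shell_summary`) with 0-based voxel indices,
#'   `u_ref`, `u_alt` (s), `ratio`.
#' @export
shell_mfpt_summary <- function(field_ref, field_alt, shell) {
  stopifnot(inherits(field_ref, "mfpt_field"), inherits(field_alt, "mfpt_field"))
  r_ref <- match(shell, field_ref$voxels)
  r_alt <- match(shell, field_alt$voxels)
  if (anyNA(r_ref) || anyNA(r_alt))
    stop("shell voxels must be cytosol in both fields (reference cytosol must embed)",
         call. = FALSE)
  u_ref <- field_ref$u[r_ref]
  u_alt <- field_alt$u[r_alt]
  ok <- is.finite(u_ref) & is.finite(u_alt)
  ijk <- .vox_ijk(shell[ok], field_ref$dims)
  out <- tibble::tibble(
    i = ijk[, 1L] - 1L, j = ijk[, 2L] - 1L, k = ijk[, 3L] - 1L,
    u_ref = u_ref[ok], u_alt = u_alt[ok], ratio = u_ref[ok] / u_alt[ok]
  )
  attr(out, "n_excluded") <- sum(!ok)
  class(out) <- c("mfpt_shell_summary", class(out))
  out
}
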