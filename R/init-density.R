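#' Initial densities for the diffusing signal
#'
#' An `init_density` is a probability density (per um^3) over the cytosol
#' voxels: values are stored in the cytosol ordering of the masks it was
#' built from and satisfy sum(values) * h^3 = 1 to 1e-12.
#'
#' * `shell_init()` starts the molecule uniformly within the membrane shell
#'   `dC_h`, the semi-discrete stand-in for a release uniformly distributed
#'   over the inner cell membrane: value 1 / (|dC_h| h^3) on each shell
#'   voxel.
#' * `patch_init()` restricts the release to the shell voxels whose centers
#'   lie within `radius` (um) of the center voxel's center, emulating
#'   activation within a small membrane patch.
#' * `point_init()` releases at a single cytosol voxel (value 1 / h^3).
#'
#' @param masks a [build_masks()] result.
#' @param center shell voxel (linear index or (i, j, k) 1-based triple).
#' @param radius patch radius in um.
#' @param voxel cytosol voxel (linear index or triple).
#' @return an object of class `init_density` with fields `values` (length
#'   |C_h|), `support` (cytosol row indices of nonzero values), and `h`.
#' @export
shell_init <- function(masks) {
  shell <- membrane_shell(masks)
  .make_init(masks, .rows_of(masks, shell))
}

#' @rdname shell_init
#' @export
patch_init <- function(masks, center, radius) {
  shell <- membrane_shell(masks)
  center <- .as_lin(center, masks$dims)
  if (!(center %in% shell))
    stop("patch center must be a membrane-shell voxel", call. = FALSE)
  ctr <- .vox_centers(center, masks$dims, masks$h)
  pts <- .vox_centers(shell, masks$dims, masks$h)
  d <- sqrt(rowSums((pts - matrix(ctr, nrow(pts), 3L, byrow = TRUE))^2))
  keep <- shell[d <= radius]
  if (length(keep) == 0L)
    stop("no shell voxel within radius ", format(radius), " um of the patch center",
         call. = FALSE)
  .make_init(masks, .rows_of(masks, keep))
}

#' @rdname shell_init
#' @export
point_init <- function(masks, voxel) {
  lin <- .as_lin(voxel, masks$dims)
  .make_init(masks, .rows_of(masks, lin))
}

.make_init <- function(masks, support_rows) {
  n <- length(masks$cytosol)
  h <- masks$h
  values <- numeric(n)
  values[support_rows] <- 1 / (length(support_rows) * h^3)
  structure(
    list(values = values, support = sort(support_rows), h = h,
         dims = masks$dims, voxels = masks$cytosol),
    class = "init_density"
  )
}

#' @export
print.init_density <- function(x, ...) {
  cat("<init_density> support ", length(x$support), " voxel(s), h = ",
      format(x$h), " um, mass = ", format(sum(x$values) * x$h^3), "\n", sep = "")
  invisible(x)
}
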