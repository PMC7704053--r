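# Voxel index bookkeeping.
#
# Internally voxels are addressed by 1-based linear indices into an array of
# dim c(nx, ny, nz); R's column-major layout makes x the fastest-varying
# direction, matching the x-fastest ordering documented for file I/O (where
# indices are reported 0-based).  Voxel (i, j, k) (1-based) has its center at
# ((i - 1/2) h, (j - 1/2) h, (k - 1/2) h).

# face-neighbor offsets: +x, -x, +y, -y, +z, -z
.nb_offsets <- rbind(
  c(1L, 0L, 0L), c(-1L, 0L, 0L),
  c(0L, 1L, 0L), c(0L, -1L, 0L),
  c(0L, 0L, 1L), c(0L, 0L, -1L)
)

.vox_lin <- function(ijk, dims) {
  ijk[, 1L] + dims[1L] * (ijk[, 2L] - 1L) + dims[1L] * dims[2L] * (ijk[, 3L] - 1L)
}

.vox_ijk <- function(lin, dims) arrayInd(lin, .dim = dims)

# centers in um for linear indices
.vox_centers <- function(lin, dims, h) (.vox_ijk(lin, dims) - 0.5) * h

# linear indices of the face neighbors of `lin` in direction `dir` (1..6);
# NA where the neighbor would leave the grid
.vox_neighbor <- function(lin, dims, dir) {
  ijk <- .vox_ijk(lin, dims)
  off <- .nb_offsets[dir, ]
  i <- ijk[, 1L] + off[1L]
  j <- ijk[, 2L] + off[2L]
  k <- ijk[, 3L] + off[3L]
  ok <- i >= 1L & i <= dims[1L] & j >= 1L & j <= dims[2L] & k >= 1L & k <= dims[3L]
  out <- rep(NA_integer_, length(lin))
  out[ok] <- i[ok] + dims[1L] * (j[ok] - 1L) + dims[1L] * dims[2L] * (k[ok] - 1L)
  out
}

# accept a voxel given as a single linear index or an (i, j, k) triple
.as_lin <- function(voxel, dims) {
  if (length(voxel) == 3L) {
    ijk <- matrix(as.integer(voxel), nrow = 1L)
    if (any(ijk < 1L) || any(ijk > dims))
      stop("voxel (", paste(voxel, collapse = ","), ") is outside the grid", call. = FALSE)
    .vox_lin(ijk, dims)
  } else if (length(voxel) == 1L) {
    v <- as.integer(voxel)
    if (is.na(v) || v < 1L || v > prod(dims))
      stop("linear voxel index out of range", call. = FALSE)
    v
  } else {
    stop("voxel must be a linear index or an (i, j, k) triple", call. = FALSE)
  }
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems, used where
# a Cholesky factorization would be too memory-hungry (large MFPT fields).
.pcg <- function(A, b, tol = 1e-10, maxiter = 20000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  if (b2 == 0) return(x)
  for (it in seq_len(maxiter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b2) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning("conjugate gradient reached maxiter; residual ",
          format(sqrt(sum(r^2)) / b2), call. = FALSE)
  x
}
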