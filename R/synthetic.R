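#' Concentric-sphere label grid
#'
#' Nucleus and cell membranes as concentric spheres centered on the grid:
#' a voxel whose center lies within `R_nuc` of the origin is nucleus, within
#' `R_cell` cytosol, otherwise exterior.  No organelles.  This is the
#' geometry for which continuum closed forms exist (see [sphere_model()]),
#' so it anchors most numerical cross-checks.
#'
#' @param R_nuc nucleus radius, um.
#' @param R_cell cell radius, um; requires `0 < R_nuc < R_cell` and
#'   `h < (R_cell - R_nuc) / 2` so at least two voxel layers of cytosol fit.
#' @param h voxel edge, um.
#' @return a [label_grid()] (labels: 0 exterior, 1 cytosol, 2 nucleus).
#' @export
concentric_spheres_grid <- function(R_nuc, R_cell, h) {
  if (!(R_nuc > 0 && R_cell > R_nuc))
    stop("need 0 < R_nuc < R_cell", call. = FALSE)
  if (!(h > 0 && h < (R_cell - R_nuc) / 2))
    stop("need 0 < h < (R_cell - R_nuc) / 2", call. = FALSE)
  nhalf <- ceiling(R_cell / h) + 2L
  n <- 2L * nhalf
  ax <- ((seq_len(n)) - 0.5 - nhalf) * h  # voxel centers, origin at grid center
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  labels <- array(0L, dim = c(n, n, n))
  labels[r2 <= R_cell^2] <- 1L
  labels[r2 <= R_nuc^2] <- 2L
  map <- label_map(0:2, c("exterior", "cytosol", "nucleus"),
                   c("exterior", "cytosol", "nucleus"))
  label_grid(labels, h, map)
}

#' Corridor label grid
#'
#' A minimal geometry with a known graph distance: a straight line of `L`
#' cytosol voxels capped by a single nucleus voxel at one end.  The sides
#' and the nucleus-end cap are reflecting wall voxels so that only the far
#' end borders the exterior -- the membrane shell is exactly the far voxel,
#' and the graph distance from it to the nucleus is exactly `L`.
#'
#' @param L corridor length in voxels (>= 1).
#' @param h voxel edge, um (default 0.1).
#' @return a [label_grid()] using [default_label_map()] labels
#'   (cytosol 1, heterochromatin 2 as the nucleus voxel, wall 7).
#' @export
corridor_grid <- function(L, h = 0.1) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  nx <- L + 3L
  labels <- array(7L, dim = c(nx, 3L, 3L))       # wall everywhere...
  labels[1L, , ] <- 7L                            # cap behind the nucleus
  labels[2L, 2L, 2L] <- 2L                        # nucleus voxel
  labels[3L:(L + 2L), 2L, 2L] <- 1L               # corridor cytosol
  labels[nx, , ] <- 0L                            # exterior beyond the far end
  label_grid(labels, h, default_label_map())
}

#' Parameters for a synthetic cell
#'
#' Describes an ellipsoidal cell containing an ellipsoidal nucleus and
#' randomly placed ellipsoidal organelle blobs, emulating the gross
#' structure of tomographic reconstructions: closed nucleus, connected
#' cytosol, organelle occlusions at a target volume fraction, and a thin
#' cytosol shell adjacent to the exterior.  Defaults give a compact test-
#' scale cell (~9000 cytosol voxels at h = 0.05 um).
#'
#' @param cell_semi,nucleus_semi ellipsoid semi-axes, um.
#' @param nucleus_offset nucleus center offset from the cell center, um.
#' @param organelle_fraction target organelle volume fraction of the
#'   organelle-free cytosol, in [0, 1).
#' @param blob_semi_range range of blob semi-axes, um.
#' @param max_attempts placement attempts before giving up.
#' @param h voxel edge, um.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return a list of class `synthetic_cell_params`.
#' @export
synthetic_cell_params <- function(cell_semi = c(0.75, 0.65, 0.60),
                                  nucleus_semi = c(0.30, 0.28, 0.25),
                                  nucleus_offset = c(0.08, 0, 0),
                                  organelle_fraction = 0.25,
                                  blob_semi_range = c(0.06, 0.14),
                                  max_attempts = 500L,
                                  h = 0.05,
                                  seed = 1L) {
  stopifnot(length(cell_semi) == 3L, length(nucleus_semi) == 3L,
            length(nucleus_offset) == 3L)
  if (!(organelle_fraction >= 0 && organelle_fraction < 1))
    stop("organelle_fraction must be in [0, 1)", call. = FALSE)
  if (h <= 0) stop("h must be positive", call. = FALSE)
  if (any(abs(nucleus_offset) + nucleus_semi >= 0.95 * cell_semi))
    stop("nucleus must lie strictly inside the cell", call. = FALSE)
  structure(
    list(cell_semi = cell_semi, nucleus_semi = nucleus_semi,
         nucleus_offset = nucleus_offset,
         organelle_fraction = organelle_fraction,
         blob_semi_range = blob_semi_range,
         max_attempts = as.integer(max_attempts),
         h = h, seed = as.integer(seed)),
    class = "synthetic_cell_params"
  )
}

#' Generate a random synthetic cell
#'
#' Builds the ellipsoidal cell and nucleus of `params`, then places random
#' axis-aligned ellipsoidal organelle blobs by rejection sampling: a blob is
#' kept only if, after carving it out, every remaining cytosol voxel is
#' still 6-connected to a nucleus-adjacent voxel.  Blobs never occupy the
#' membrane shell or nucleus-adjacent voxels, so the release surface and the
#' absorbing interface survive.  Placement stops once the achieved organelle
#' fraction is within the target band; if `max_attempts` placements cannot
#' reach 80% of the target, an error reports the achieved fraction.
#'
#' @param params a [synthetic_cell_params()].
#' @return a [label_grid()] with attributes `params` and
#'   `achieved_fraction` (organelle voxels / organelle-free cytosol voxels).
#' @export
random_cell <- function(params = synthetic_cell_params()) {
  stopifnot(inherits(params, "synthetic_cell_params"))
  h <- params$h
  half <- params$cell_semi
  dims <- as.integer(2L * (ceiling(half / h) + 2L))
  ctr <- dims / 2
  ax <- lapply(1:3, function(d) ((seq_len(dims[d])) - 0.5 - ctr[d]) * h)

  sq <- function(semi, off) {
    x2 <- ((ax[[1L]] - off[1L]) / semi[1L])^2
    y2 <- ((ax[[2L]] - off[2L]) / semi[2L])^2
    z2 <- ((ax[[3L]] - off[3L]) / semi[3L])^2
    outer(outer(x2, y2, `+`), z2, `+`)
  }

  cell_q <- sq(params$cell_semi, c(0, 0, 0))
  nuc_q <- sq(params$nucleus_semi, params$nucleus_offset)

  labels <- array(0L, dim = dims)
  labels[cell_q <= 1] <- 1L
  labels[nuc_q <= 1] <- 3L            # euchromatin rim
  labels[nuc_q <= 0.5] <- 2L          # heterochromatin core
  grid <- label_grid(labels, h, default_label_map())

  base_masks <- build_masks(grid, "physiological")
  n_cyt0 <- length(base_masks$cytosol)
  target <- params$organelle_fraction * n_cyt0
  if (target == 0) {
    attr(grid, "params") <- params
    attr(grid, "achieved_fraction") <- 0
    return(grid)
  }

  # voxels a blob may occupy: cytosol minus shell minus nucleus-adjacent
  protected <- logical(prod(dims))
  protected[base_masks$shell] <- TRUE
  protected[base_masks$cytosol[base_masks$n_adj > 0L]] <- TRUE

  organelle_classes <- c(4L, 5L, 6L)  # ER, mitochondria, Golgi
  withr::with_seed(params$seed, {
    placed <- 0L
    blob_i <- 0L
    for (attempt in seq_len(params$max_attempts)) {
      if (placed >= 0.95 * target) break
      cyt <- which(labels == 1L)
      free <- cyt[!protected[cyt]]
      if (!length(free)) break
      c_lin <- free[sample.int(length(free), 1L)]
      c_ijk <- .vox_ijk(c_lin, dims)
      c_pos <- c(ax[[1L]][c_ijk[1L]], ax[[2L]][c_ijk[2L]], ax[[3L]][c_ijk[3L]])
      semi <- stats::runif(3L, params$blob_semi_range[1L], params$blob_semi_range[2L])
      q <- sq(semi, c_pos)
      blob <- which(q <= 1 & labels == 1L & !protected)
      if (!length(blob)) next
      if (placed + length(blob) > 1.2 * target) next
      # connectivity check: carve tentatively, flood fill from nucleus-adjacent
      labels_try <- labels
      labels_try[blob] <- organelle_classes[(blob_i %% 3L) + 1L]
      if (.cytosol_connected(labels_try, dims, grid$map)) {
        labels <- labels_try
        placed <- placed + length(blob)
        blob_i <- blob_i + 1L
      }
    }
  })

  achieved <- placed / n_cyt0
  if (achieved < 0.8 * params$organelle_fraction)
    stop(sprintf(
      "could not reach target organelle fraction %.3f after %d attempts (achieved %.3f)",
      params$organelle_fraction, params$max_attempts, achieved), call. = FALSE)

  out <- label_grid(labels, h, grid$map)
  attr(out, "params") <- params
  attr(out, "achieved_fraction") <- achieved
  out
}

# TRUE when every cytosol voxel is 6-connected to some nucleus-adjacent voxel
.cytosol_connected <- function(labels, dims, map) {
  g <- label_grid(labels, 1, map)
  m <- tryCatch(build_masks(g, "physiological"), error = function(e) NULL)
  !is.null(m) && length(m$connected) == length(m$cytosol)
}
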