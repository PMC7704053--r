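#' Geometry variants: reopening organelles to diffusion
#'
#' Returns a copy of `grid` in which organelle voxels are relabeled as
#' cytosol according to the variant: `"physiological"` keeps every organelle
#' as a reflecting barrier, `"no_ER"` opens only ER-labeled voxels, and
#' `"no_organelles"` opens every organelle so the cytosol fills all space
#' between the cell and nuclear membranes.
#'
#' @param grid a [label_grid()].
#' @param variant `"physiological"`, `"no_ER"` or `"no_organelles"`.
#' @return a relabeled [label_grid()].
#' @export
apply_variant <- function(grid, variant = c("physiological", "no_ER", "no_organelles")) {
  variant <- match.arg(variant)
  if (variant == "physiological") return(grid)
  map <- grid$map
  cyt_label <- map$label[map$category == "cytosol"][1L]
  if (is.na(cyt_label)) stop("label map has no cytosol class", call. = FALSE)
  open <- if (variant == "no_ER") {
    map$label[map$category == "organelle" &
                tolower(map$name) %in% c("er", "endoplasmic reticulum")]
  } else {
    map$label[map$category == "organelle"]
  }
  labels <- grid$labels
  labels[labels %in% open] <- cyt_label
  label_grid(labels, grid$h, map)
}

#' Classify a label grid into the model's voxel sets
#'
#' Partitions the voxels into cytosol `C_h`, nucleus `N_h` (the union of all
#' nucleus-component classes), organelles `O_h`, and exterior; finds the
#' membrane shell (cytosol voxels bordering the exterior), the per-voxel
#' count of nucleus face-neighbors, and the subset of the cytosol that is
#' 6-connected to a nucleus-adjacent voxel.  All adjacency is face (6-
#' neighbor) adjacency, matching the diffusion stencil.  Voxels beyond the
#' grid boundary count as exterior when deciding shell membership.
#'
#' @param grid a [label_grid()].
#' @param variant geometry variant, see [apply_variant()].
#' @return an object of class `geometry_masks`: linear voxel index sets
#'   `cytosol`, `nucleus`, `organelle`, `exterior`, `shell`, `connected`
#'   (all sorted), per-cytosol-voxel nucleus-adjacency counts `n_adj`, the
#'   cytosol face-neighbor table `nb` (|C_h| x 6 of cytosol row indices, 0
#'   where no cytosol neighbor), `dims`, `h`, and `variant`.
#' @export
build_masks <- function(grid, variant = c("physiological", "no_ER", "no_organelles")) {
  variant <- match.arg(variant)
  grid <- apply_variant(grid, variant)
  dims <- dim(grid$labels)
  cat_f <- .category_field(grid)

  cytosol   <- which(cat_f == "cytosol")
  nucleus   <- which(cat_f == "nucleus")
  organelle <- which(cat_f == "organelle")
  exterior  <- which(cat_f == "exterior")

  if (length(nucleus) == 0L) stop("empty nucleus", call. = FALSE)
  if (length(cytosol) == 0L) stop("empty cytosol", call. = FALSE)

  n_cyt <- length(cytosol)
  # row index of each cytosol voxel in the sorted cytosol ordering
  row_of <- integer(prod(dims))
  row_of[cytosol] <- seq_len(n_cyt)

  is_nuc <- logical(prod(dims)); is_nuc[nucleus] <- TRUE
  is_ext <- logical(prod(dims)); is_ext[exterior] <- TRUE

  nb <- matrix(0L, nrow = n_cyt, ncol = 6L)
  n_adj <- integer(n_cyt)
  ext_adj <- logical(n_cyt)
  for (dir in 1:6) {
    nbr <- .vox_neighbor(cytosol, dims, dir)
    off_grid <- is.na(nbr)
    nbr_safe <- ifelse(off_grid, 1L, nbr)
    nb[, dir] <- ifelse(off_grid, 0L, row_of[nbr_safe])
    n_adj <- n_adj + as.integer(!off_grid & is_nuc[nbr_safe])
    ext_adj <- ext_adj | off_grid | (!off_grid & is_ext[nbr_safe])
  }
  if (!any(n_adj > 0L)) stop("nucleus unreachable: no cytosol voxel borders the nucleus",
                             call. = FALSE)
  shell <- cytosol[ext_adj]

  # flood fill (BFS over the face-adjacency graph) from nucleus-adjacent voxels
  visited <- logical(n_cyt)
  frontier <- which(n_adj > 0L)
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- unique(as.vector(nb[frontier, , drop = FALSE]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }

  structure(
    list(
      dims = dims, h = grid$h, variant = variant,
      cytosol = cytosol, nucleus = nucleus, organelle = organelle,
      exterior = exterior, shell = shell,
      connected = cytosol[visited],
      n_adj = n_adj, nb = nb,
      map = grid$map
    ),
    class = "geometry_masks"
  )
}

#' @export
print.geometry_masks <- function(x, ...) {
  cat("<geometry_masks> variant = ", x$variant,
      ", h = ", format(x$h), " um\n", sep = "")
  cat(sprintf("  |C_h| = %d, |N_h| = %d, |O_h| = %d, exterior = %d\n",
              length(x$cytosol), length(x$nucleus), length(x$organelle),
              length(x$exterior)))
  cat(sprintf("  shell |dC_h| = %d voxels (%.4g um^3); connected cytosol = %d/%d\n",
              length(x$shell), length(x$shell) * x$h^3,
              length(x$connected), length(x$cytosol)))
  invisible(x)
}

#' Membrane shell of a geometry
#'
#' The shell is the set of cytosol voxels with at least one exterior face
#' neighbor (grid boundary counts as exterior): the model's stand-in for the
#' inner surface of the cell membrane.  Computed during [build_masks()];
#' this accessor validates non-emptiness.
#'
#' @param masks a [build_masks()] result.
#' @return sorted linear voxel indices of the shell.
#' @export
membrane_shell <- function(masks) {
  stopifnot(inherits(masks, "geometry_masks"))
  if (length(masks$shell) == 0L)
    stop("empty membrane shell: the cell does not border the exterior", call. = FALSE)
  masks$shell
}

#' @export
as_tibble.geometry_masks <- function(x, ...) {
  cats <- c(rep("cytosol", length(x$cytosol)), rep("nucleus", length(x$nucleus)),
            rep("organelle", length(x$organelle)), rep("exterior", length(x$exterior)))
  lin <- c(x$cytosol, x$nucleus, x$organelle, x$exterior)
  ijk <- .vox_ijk(lin, x$dims)
  shell_set <- logical(prod(x$dims)); shell_set[x$shell] <- TRUE
  conn_set <- logical(prod(x$dims)); conn_set[x$connected] <- TRUE
  tibble::tibble(
    i = ijk[, 1L] - 1L, j = ijk[, 2L] - 1L, k = ijk[, 3L] - 1L,
    category = cats, shell = shell_set[lin], connected = conn_set[lin]
  ) |> dplyr::arrange(.data$k, .data$j, .data$i)
}

# row indices (cytosol ordering) for linear voxel ids; error if not cytosol
.rows_of <- function(masks, lin) {
  r <- match(lin, masks$cytosol)
  if (anyNA(r)) stop("voxel(s) not in the cytosol of these masks", call. = FALSE)
  r
}
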