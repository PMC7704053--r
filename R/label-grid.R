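#' Label maps: which integer label means what
#'
#' A label map ties the integer values stored in a segmented volume to named
#' tissue classes, and each class to one of four categories the diffusion
#' model distinguishes: `exterior` (outside the cell), `cytosol` (free
#' diffusion), `nucleus` (absorbing target; possibly several components such
#' as heterochromatin and euchromatin), and `organelle` (reflecting barrier,
#' e.g. ER, mitochondria, Golgi).
#'
#' @param label integer label values as stored in the volume.
#' @param name class name per label (e.g. `"ER"`).
#' @param category one of `"exterior"`, `"cytosol"`, `"nucleus"`,
#'   `"organelle"` per label.
#' @return a tibble with columns `label`, `name`, `category`.
#' @examples
#' label_map(0:2, c("exterior", "cytosol", "nucleus"),
#'           c("exterior", "cytosol", "nucleus"))
#' @export
label_map <- function(label, name, category) {
  label <- as.integer(label)
  category <- as.character(category)
  name <- as.character(name)
  stopifnot(length(label) == length(name), length(label) == length(category))
  if (anyDuplicated(label)) stop("duplicate integer labels in label map", call. = FALSE)
  bad <- setdiff(unique(category), c("exterior", "cytosol", "nucleus", "organelle"))
  if (length(bad))
    stop("unknown label categories: ", paste(bad, collapse = ", "), call. = FALSE)
  tibble::tibble(label = label, name = name, category = category)
}

#' @rdname label_map
#' @details `default_label_map()` is the convention used by the synthetic
#'   generators: 0 exterior, 1 cytosol, 2 heterochromatin, 3 euchromatin
#'   (both nucleus components), 4 ER, 5 mitochondria, 6 Golgi, 7 wall (a
#'   generic reflecting barrier used by corridor geometries).
#' @export
default_label_map <- function() {
  label_map(
    0:7,
    c("exterior", "cytosol", "heterochromatin", "euchromatin",
      "ER", "mitochondria", "Golgi", "wall"),
    c("exterior", "cytosol", "nucleus", "nucleus",
      "organelle", "organelle", "organelle", "organelle")
  )
}

#' Segmented label volumes on cubic voxels
#'
#' A `label_grid` holds a 3D integer label field, the cubic voxel edge length
#' `h` (um), and the [label_map()] interpreting the labels.  Voxel (i, j, k)
#' (0-based in all file formats, 1-based inside R) has its center at
#' ((i + 1/2) h, (j + 1/2) h, (k + 1/2) h) with 0-based indices, and linear
#' storage is x-fastest.
#'
#' @param labels integer 3D array of labels.
#' @param h voxel edge length in um; must be positive.
#' @param map a [label_map()]; defaults to [default_label_map()].
#' @return an object of class `label_grid`.
#' @export
label_grid <- function(labels, h, map = default_label_map()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("h must be a positive voxel edge length in um", call. = FALSE)
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(present, map$label)
  if (length(missing))
    stop("labels absent from label map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(
    list(labels = labels, h = as.numeric(h), map = map),
    class = "label_grid"
  )
}

#' @export
print.label_grid <- function(x, ...) {
  d <- dim(x$labels)
  cat("<label_grid> ", paste(d, collapse = " x "),
      " voxels, h = ", format(x$h), " um\n", sep = "")
  tab <- table(factor(x$map$category[match(as.vector(x$labels), x$map$label)],
                      levels = c("exterior", "cytosol", "nucleus", "organelle")))
  cat("  voxels by category:",
      paste(names(tab), format(as.integer(tab), big.mark = ","), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.label_grid <- function(x) dim(x$labels)

#' Tidy a label grid into a voxel table
#'
#' @param x a [label_grid()].
#' @param ... unused.
#' @return tibble with 0-based voxel indices `i`, `j`, `k`, the integer
#'   `label`, its class `name` and model `category`.
#' @export
as_tibble.label_grid <- function(x, ...) {
  dims <- dim(x$labels)
  ijk <- arrayInd(seq_along(x$labels), .dim = dims)
  m <- match(as.vector(x$labels), x$map$label)
  tibble::tibble(
    i = ijk[, 1L] - 1L, j = ijk[, 2L] - 1L, k = ijk[, 3L] - 1L,
    label = as.vector(x$labels),
    name = x$map$name[m],
    category = x$map$category[m]
  )
}

.category_field <- function(grid) {
  m <- match(as.vector(grid$labels), grid$map$label)
  array(grid$map$category[m], dim = dim(grid$labels))
}

#' Read and write segmented label volumes
#'
#' Two on-disk representations are supported, picked by file extension:
#' * **NIfTI** (`.nii` / `.nii.gz`, via RNifti): the label field with cubic
#'   voxel spacing in `pixdim`; the label map travels in a JSON sidecar
#'   `<path>.labels.json` written alongside.
#' * **Raw + JSON sidecar** (`.raw`): little-endian int32 voxels in x-fastest
#'   order plus `<path stem>.json` holding
#'   `{dims, h_um, dtype, order: "x-fastest", label_map}`.
#'
#' Round trips are bit exact.  Anisotropic voxel spacing is an error: the
#' diffusion stencil assumes cubes.
#'
#' @param path file to read or write.
#' @param map optional [label_map()]; when `NULL`, read from the sidecar.
#' @param grid a [label_grid()] to write.
#' @return `read_label_volume()` returns a [label_grid()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
read_label_volume <- function(path, map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (diff(range(pd)) > 1e-8 * max(pd))
      stop("anisotropic voxels (pixdim ", paste(format(pd), collapse = " x "),
           "); cubic voxels are required", call. = FALSE)
    if (is.null(map)) {
      sidecar <- paste0(path, ".labels.json")
      map <- if (file.exists(sidecar)) .read_label_map_json(sidecar) else default_label_map()
    }
    arr <- array(as.integer(img), dim = dim(img))
    label_grid(arr, h = pd[1L], map = map)
  } else if (grepl("\\.raw$", path)) {
    meta_path <- sub("\\.raw$", ".json", path)
    if (!file.exists(meta_path)) stop("missing JSON sidecar: ", meta_path, call. = FALSE)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!identical(meta$order, "x-fastest"))
      stop("raw volume sidecar must declare order \"x-fastest\"", call. = FALSE)
    dims <- as.integer(meta$dims)
    n <- prod(dims)
    con <- file(path, "rb"); on.exit(close(con))
    vals <- readBin(con, what = "integer", n = n, size = 4L, endian = "little")
    if (length(vals) != n) stop("raw volume truncated: expected ", n, " voxels", call. = FALSE)
    if (is.null(map)) map <- label_map(meta$label_map$label, meta$label_map$name,
                                       meta$label_map$category)
    label_grid(array(vals, dim = dims), h = meta$h_um, map = map)
  } else {
    stop("unsupported volume format: ", path,
         " (use .nii, .nii.gz, or .raw with JSON sidecar)", call. = FALSE)
  }
}

#' @rdname read_label_volume
#' @export
write_label_volume <- function(grid, path) {
  stopifnot(inherits(grid, "label_grid"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- grid$labels
    attr(arr, "pixdim") <- rep(grid$h, 3L)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), path)
    .write_label_map_json(grid$map, paste0(path, ".labels.json"))
  } else if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    writeBin(as.integer(grid$labels), con, size = 4L, endian = "little")
    close(con)
    meta <- list(
      dims = dim(grid$labels), h_um = grid$h, dtype = "int32",
      order = "x-fastest",
      label_map = as.list(grid$map)
    )
    jsonlite::write_json(meta, sub("\\.raw$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

.write_label_map_json <- function(map, path) {
  jsonlite::write_json(as.list(map), path, auto_unbox = TRUE, digits = NA)
}

.read_label_map_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  label_map(m$label, m$name, m$category)
}
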