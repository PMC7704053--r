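# Geometry: label volumes, masks, shells, initial densities.

test_that("label volumes round-trip bit-exactly through both formats", {
  grid <- concentric_spheres_grid(1, 2, 0.25)
  for (ext in c(".nii.gz", ".raw")) {
    path <- tempfile(fileext = ext)
    write_label_volume(grid, path)
    back <- read_label_volume(path)
    expect_identical(back$labels, grid$labels)
    expect_equal(back$h, grid$h, tolerance = 1e-12)
    expect_equal(back$map, grid$map)
  }
})

test_that("voxel edge lengths survive I/O at tomographic precision", {
  # the reconstruction voxel size used by the source imaging: 0.03515625 um
  labels <- array(0L, dim = c(3L, 3L, 3L))
  labels[2L, 2L, 2L] <- 2L
  labels[2L, 2L, 1L] <- 1L
  grid <- label_grid(labels, h = 0.03515625)
  path <- tempfile(fileext = ".raw")
  write_label_volume(grid, path)
  expect_identical(read_label_volume(path)$h, 0.03515625)
})

test_that("unknown labels and anisotropic voxels are rejected with details", {
  labels <- array(c(0L, 99L), dim = c(2L, 1L, 1L))
  expect_error(label_grid(labels, 0.1), "99")
  img <- RNifti::asNifti(array(0L, dim = c(2L, 2L, 2L)))
  attr(img, "pixdim") <- c(0.1, 0.1, 0.2)
  path <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, path)
  expect_error(read_label_volume(path), "anisotropic")
})

test_that("degenerate volumes fail mask construction informatively", {
  all_ext <- label_grid(array(0L, dim = c(3L, 3L, 3L)), 0.1)
  expect_error(build_masks(all_ext), "empty nucleus")
  no_cyt <- label_grid(array(2L, dim = c(3L, 3L, 3L)), 0.1)
  expect_error(build_masks(no_cyt), "empty cytosol")
  # nucleus sealed away from the cytosol by walls
  labels <- array(7L, dim = c(5L, 3L, 3L))
  labels[2L, 2L, 2L] <- 2L
  labels[4L, 2L, 2L] <- 1L
  expect_error(build_masks(label_grid(labels, 0.1)), "nucleus unreachable")
})

test_that("corridor masks have the constructed counts and connectivity", {
  fx <- fx_corridor(3)
  expect_length(fx$masks$cytosol, 3L)
  expect_length(fx$masks$nucleus, 1L)
  expect_identical(fx$masks$connected, fx$masks$cytosol)
  expect_length(membrane_shell(fx$masks), 1L)
})

test_that("voxel categories partition the grid for every variant", {
  grids <- list(corridor_grid(4), concentric_spheres_grid(0.5, 1, 0.2),
                fx_random_cell()$grid)
  for (grid in grids) {
    for (v in c("physiological", "no_ER", "no_organelles")) {
      m <- build_masks(grid, v)
      expect_identical(
        length(m$cytosol) + length(m$nucleus) + length(m$organelle) +
          length(m$exterior),
        prod(dim(grid$labels)) |> as.integer())
      expect_false(any(duplicated(c(m$cytosol, m$nucleus, m$organelle,
                                    m$exterior))))
    }
  }
})

test_that("variants nest: opening barriers only grows the cytosol", {
  grid <- fx_random_cell()$grid
  m_phys <- build_masks(grid, "physiological")
  m_noer <- build_masks(grid, "no_ER")
  m_none <- build_masks(grid, "no_organelles")
  expect_true(all(m_phys$cytosol %in% m_noer$cytosol))
  expect_true(all(m_noer$cytosol %in% m_none$cytosol))
  expect_length(m_none$organelle, 0L)
  # no_organelles cytosol is exactly physiological cytosol plus organelles
  expect_setequal(m_none$cytosol, c(m_phys$cytosol, m_phys$organelle))
  # strict growth whenever organelles exist
  expect_gt(length(m_none$cytosol), length(m_phys$cytosol))
})

test_that("build_masks is idempotent under a pre-applied variant", {
  grid <- fx_random_cell()$grid
  direct <- build_masks(grid, "no_organelles")
  pre <- build_masks(apply_variant(grid, "no_organelles"), "physiological")
  for (f in c("cytosol", "nucleus", "organelle", "exterior", "shell", "connected"))
    expect_identical(direct[[f]], pre[[f]])
})

test_that("sphere-grid classification matches brute-force center distances", {
  grid <- concentric_spheres_grid(1, 2, 0.25)
  m <- build_masks(grid)
  dims <- dim(grid$labels)
  ctr <- dims[1L] / 2
  lin <- seq_len(prod(dims))
  r <- sqrt(rowSums((arrayInd(lin, dims) - 0.5 - ctr)^2)) * grid$h
  expect_setequal(m$nucleus, lin[r <= 1])
  expect_setequal(m$cytosol, lin[r > 1 & r <= 2])
  expect_setequal(m$exterior, lin[r > 2])
})

test_that("membrane shell is exactly the exterior-adjacent cytosol", {
  # solid 3x3x3 cytosol cube around a nucleus, surrounded by exterior:
  # all 26 outer voxels are shell, the center is nucleus
  labels <- array(0L, dim = c(5L, 5L, 5L))
  labels[2:4, 2:4, 2:4] <- 1L
  labels[3L, 3L, 3L] <- 2L
  m <- build_masks(label_grid(labels, 0.1))
  expect_length(m$shell, 26L)
  expect_setequal(m$shell, setdiff(m$cytosol, integer(0)))
  # sphere fixture: every shell voxel borders exterior, no other does
  fx <- fx_sphere()
  dims <- fx$masks$dims
  is_ext <- logical(prod(dims)); is_ext[fx$masks$exterior] <- TRUE
  borders_ext <- vapply(fx$masks$cytosol, function(v) {
    nb <- vapply(1:6, function(d) fptcell:::.vox_neighbor(v, dims, d), integer(1))
    any(is.na(nb)) || any(is_ext[nb[!is.na(nb)]])
  }, logical(1))
  expect_setequal(fx$masks$shell, fx$masks$cytosol[borders_ext])
})

test_that("initial densities are normalized probability densities", {
  fx <- fx_sphere()
  h <- fx$masks$h
  g <- shell_init(fx$masks)
  K <- length(membrane_shell(fx$masks))
  expect_equal(sum(g$values) * h^3, 1, tolerance = 1e-12)
  expect_equal(unique(g$values[g$support]), 1 / (K * h^3), tolerance = 1e-12)
  expect_true(all(g$values[-g$support] == 0))
  # single-voxel shell: density 1/h^3
  c1 <- fx_corridor(1)
  g1 <- shell_init(c1$masks)
  expect_equal(g1$values[g1$support], 1 / c1$masks$h^3)
})

test_that("patch initial conditions interpolate between point and shell", {
  fx <- fx_sphere()
  shell <- membrane_shell(fx$masks)
  center <- shell[1L]
  # radius below h/2 keeps only the center voxel
  g_pt <- patch_init(fx$masks, center, fx$masks$h / 4)
  expect_length(g_pt$support, 1L)
  expect_equal(g_pt$values[g_pt$support], 1 / fx$masks$h^3)
  # huge radius reproduces the uniform shell release
  g_all <- patch_init(fx$masks, center, 1e6)
  expect_equal(g_all$values, shell_init(fx$masks)$values)
  # moderate radius: support equals the brute-force distance-filtered shell
  radius <- 0.5
  g_r <- patch_init(fx$masks, center, radius)
  ctr <- fptcell:::.vox_centers(center, fx$masks$dims, fx$masks$h)
  pts <- fptcell:::.vox_centers(shell, fx$masks$dims, fx$masks$h)
  d <- sqrt(rowSums((pts - matrix(ctr, nrow(pts), 3L, byrow = TRUE))^2))
  expect_setequal(fx$masks$cytosol[g_r$support], shell[d <= radius])
  expect_equal(sum(g_r$values) * fx$masks$h^3, 1, tolerance = 1e-12)
  # errors: off-shell center
  interior <- setdiff(fx$masks$cytosol, shell)[1L]
  expect_error(patch_init(fx$masks, interior, 1), "shell")
})
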