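# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# corridor of length L with operator, far-end point source, and an FPT
# density whose eigen tail is complete (all modes retained), so Laplace-
# domain integrals are exact beyond the switch time
fx_corridor <- function(L, D = 10) {
  fx_cached(paste0("corridor", L, "_", D), function() {
    grid <- corridor_grid(L)
    masks <- build_masks(grid)
    op <- diffusion_operator(masks, D = D)
    far <- membrane_shell(masks)  # single far-end voxel by construction
    g <- point_init(masks, far)
    traj <- hybrid_trajectory(op, g, window = c(5e-4, 0.05), n_out = 4000L,
                              cutoff = 1e4, max_modes = 100L)
    list(grid = grid, masks = masks, op = op, g = g, far = far,
         fpt = fpt_density(traj))
  })
}

# small concentric-spheres fixture: a = 0.5, R = 1, h = 0.2 (~500 voxels)
fx_sphere <- function() {
  fx_cached("sphere_small", function() {
    grid <- concentric_spheres_grid(0.5, 1, 0.2)
    masks <- build_masks(grid)
    op <- diffusion_operator(masks, D = 10)
    list(grid = grid, masks = masks, op = op, g = shell_init(masks))
  })
}

# hybrid trajectory + fpt density for the small sphere
fx_sphere_fpt <- function() {
  fx_cached("sphere_small_fpt", function() {
    fx <- fx_sphere()
    traj <- hybrid_trajectory(fx$op, fx$g, window = c(0.05, 1), cutoff = 500)
    fpt_density(traj)
  })
}

# seeded random cell with physiological and no-organelles masks
fx_random_cell <- function() {
  fx_cached("random_cell", function() {
    grid <- random_cell(synthetic_cell_params(seed = 42L))
    list(grid = grid,
         phys = build_masks(grid, "physiological"),
         none = build_masks(grid, "no_organelles"))
  })
}

# a two-chamber geometry: nucleus + corridor in one chamber, an isolated
# cytosol pocket in the other (for unreachable-source behavior)
fx_two_chamber <- function() {
  fx_cached("two_chamber", function() {
    labels <- array(7L, dim = c(9L, 3L, 3L))
    labels[2L, 2L, 2L] <- 2L             # nucleus
    labels[3:4, 2L, 2L] <- 1L            # connected corridor (L = 2)
    labels[5L, 2L, 2L] <- 7L             # wall separating the chambers
    labels[6:7, 2L, 2L] <- 1L            # isolated pocket
    labels[9L, , ] <- 0L                 # exterior past the far end
    labels[8L, 2L, 2L] <- 1L             # pocket voxel bordering exterior
    grid <- label_grid(labels, 0.1, default_label_map())
    masks <- build_masks(grid)
    list(grid = grid, masks = masks, op = diffusion_operator(masks, 10))
  })
}

# dense matrix-exponential survival oracle (independent of the ODE solver)
expm_survival <- function(op, g, times) {
  A <- as.matrix(op$A)
  vapply(times, function(t) {
    p <- as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% g$values)
    sum(p) * op$h^3
  }, numeric(1))
}

expect_strictly_decreasing <- function(x, label = "sequence") {
  expect_true(all(diff(x) < 0),
              label = paste(label, "strictly decreasing"))
}
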