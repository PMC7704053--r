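# Discrete Laplacian assembly and the semi-discrete solvers.

test_that("corridor operators realize the hand-computed stencil", {
  # single voxel: only the absorbing sink, -(D/h^2) * 1 = -1000 /s
  c1 <- fx_corridor(1)
  expect_equal(as.matrix(c1$op$A), matrix(-1000), ignore_attr = TRUE)
  expect_identical(c1$op$n_adj, 1L)
  # corridor(3): tridiagonal, off-diagonals D/h^2, sink on the nucleus end
  c3 <- fx_corridor(3)
  A <- as.matrix(c3$op$A)
  w <- 10 / 0.1^2
  nuc_row <- which(c3$op$n_adj == 1L)
  far_row <- setdiff(which(rowSums(A != 0) == 2L), nuc_row)
  expect_equal(sort(Matrix::diag(c3$op$A)), c(-2 * w, -2 * w, -w))
  expect_equal(A[nuc_row, nuc_row], -2 * w)  # one neighbor + one sink
  expect_equal(A[far_row, far_row], -w)      # one neighbor, reflecting end
  expect_equal(sum(A[upper.tri(A)] != 0), 2) # chain topology
  expect_true(all(A[A != 0 & row(A) != col(A)] == w))
})

test_that("the assembled operator is exactly symmetric", {
  for (op in list(fx_corridor(4)$op, fx_sphere()$op,
                  diffusion_operator(fx_random_cell()$phys, 10))) {
    expect_identical(Matrix::nnzero(op$A - Matrix::t(op$A)), 0L)
  }
})

test_that("single-voxel decay follows the analytic exponential", {
  c1 <- fx_corridor(1)
  tr <- evolve_density(c1$op, c1$g, t_end = 0.02)
  expect_equal(tr$p[1L, ], 1000 * exp(-1000 * tr$times), tolerance = 1e-6)
})

test_that("mass is conserved exactly when no voxel touches the nucleus", {
  fx <- fx_two_chamber()
  # start in the isolated pocket: no flux can ever leave it
  pocket <- setdiff(fx$masks$cytosol, fx$masks$connected)
  g <- point_init(fx$masks, pocket[1L])
  tr <- evolve_density(fx$op, g, t_end = 0.05)
  expect_equal(survival_mass(tr), rep(1, length(tr$times)), tolerance = 1e-7)
  expect_equal(fpt_density(tr)$f, rep(0, length(tr$times)))
})

test_that("densities stay nonnegative up to solver tolerance", {
  fp <- fx_sphere_fpt()
  expect_true(all(fp$f >= -1e-7))
  expect_true(all(fp$S >= -1e-7))
})

test_that("eigen tails obey the retention rule and weighted orthonormality", {
  c1 <- fx_corridor(1)
  # sole eigenvalue is -1000 /s: excluded under the default |mu| < 1 cutoff
  tl_default <- eigen_tail(c1$op, c1$g)
  expect_length(tl_default$mu, 0L)
  # raising the cutoff captures it and reproduces the solution exactly
  tl <- eigen_tail(c1$op, c1$g, cutoff = 2000)
  expect_equal(tl$mu, -1000)
  t_check <- c(1e-4, 1e-3, 1e-2)
  expect_equal(as.numeric(fptcell:::.tail_density(tl, t_check)),
               1000 * exp(-1000 * t_check), tolerance = 1e-12)
  # h^3-weighted orthonormality on a multi-voxel fixture
  fx <- fx_sphere()
  tl_s <- eigen_tail(fx$op, fx$g, cutoff = 500)
  G <- fx$op$h^3 * crossprod(tl_s$modes)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
})

test_that("shift-invert ARPACK agrees with the dense eigensolver", {
  fx <- fx_sphere()
  tl_d <- eigen_tail(fx$op, fx$g, cutoff = 120, method = "dense")
  tl_a <- eigen_tail(fx$op, fx$g, cutoff = 120, method = "arpack",
                     max_modes = 50L)
  expect_equal(sort(tl_a$mu), sort(tl_d$mu), tolerance = 1e-7)
  t_check <- c(0.05, 0.2)
  expect_equal(fptcell:::.tail_survival(tl_a, t_check),
               fptcell:::.tail_survival(tl_d, t_check), tolerance = 1e-8)
})

test_that("hybrid trajectories switch to the tail where the solutions agree", {
  c1 <- fx_corridor(1)
  # complete expansion: agreement from the first scan point
  expect_silent(ht <- hybrid_trajectory(c1$op, c1$g, window = c(1e-3, 1e-2),
                                        cutoff = 2000))
  expect_equal(ht$T_switch, min(ht$times[ht$times >= 1e-3]))
  S_tail <- fptcell:::.tail_survival(ht$tail, c(2e-3, 5e-3))
  expect_equal(S_tail, exp(-1000 * c(2e-3, 5e-3)), tolerance = 1e-10)
  # empty tail: warning and integrator-only fallback
  expect_warning(ht0 <- hybrid_trajectory(c1$op, c1$g, window = c(1e-3, 1e-2)),
                 "tail")
  expect_identical(ht0$T_switch, Inf)
  expect_null(ht0$tail)
})

test_that("hybrid and integrator-only survival agree on their overlap", {
  grid <- concentric_spheres_grid(0.5, 1, 0.15)
  masks <- build_masks(grid)
  op <- diffusion_operator(masks, 10)
  g <- shell_init(masks)
  full <- evolve_density(op, g, t_end = 1)
  hyb <- hybrid_trajectory(op, g, window = c(0.05, 1), cutoff = 500)
  expect_true(is.finite(hyb$T_switch))
  S_full <- survival_mass(full)
  keep <- full$times > hyb$T_switch
  S_tail <- fptcell:::.tail_survival(hyb$tail, full$times[keep])
  expect_lt(max(abs(S_full[keep] - S_tail)), 1e-5)
})

test_that("integrator survival matches the dense matrix-exponential oracle", {
  for (fx in list(fx_corridor(5), fx_sphere())) {
    tr <- evolve_density(fx$op, fx$g, t_end = 0.5)
    t_check_idx <- round(seq(2L, length(tr$times), length.out = 8L))
    S_int <- survival_mass(tr)[t_check_idx]
    S_oracle <- expm_survival(fx$op, fx$g, tr$times[t_check_idx])
    expect_lt(max(abs(S_int - S_oracle)), 1e-6)
  }
})

test_that("adding uniform inactivation equals exponential damping", {
  c3 <- fx_corridor(3)
  tr0 <- evolve_density(c3$op, c3$g, t_end = 0.05)
  for (lam in c(1, 10, 100)) {
    tr_l <- evolve_density(c3$op, c3$g, t_end = 0.05, lambda = lam)
    expect_equal(tr_l$p, tr0$p * rep(exp(-lam * tr0$times), each = nrow(tr0$p)),
                 tolerance = 1e-6)
  }
})
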