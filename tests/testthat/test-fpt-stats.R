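# FPT densities, conditional statistics, MFPT fields.

test_that("single-voxel FPT density and conditional laws are exponential", {
  c1 <- fx_corridor(1)
  tr <- evolve_density(c1$op, c1$g, t_end = 0.02)
  fp <- fpt_density(tr)
  # f(t) = 1000 exp(-1000 t); total absorbed probability 1
  expect_equal(fp$f, 1000 * exp(-1000 * fp$times), tolerance = 1e-6)
  expect_equal(fp$absorbed, 1, tolerance = 1e-4)
  # exponential conditional laws at lambda = 1000: rate doubles
  fph <- c1$fpt  # complete eigen tail: Laplace integrals near exact
  expect_equal(laplace_Z(fph, 1000), 0.5, tolerance = 1e-5)
  expect_equal(conditional_mean(fph, 1000), 1 / 2000, tolerance = 1e-5)
  expect_equal(conditional_variance(fph, 1000), 1 / 2000^2, tolerance = 1e-5)
  expect_equal(conditional_median(fph, 1000), log(2) / 2000, tolerance = 1e-4)
  # CDF endpoints
  Fl <- conditional_cdf(fph, 1000)
  expect_equal(Fl(0), 0)
  expect_equal(Fl(1), 1, tolerance = 1e-6)
})

test_that("the two survival computations agree (discrete -dS/dt = f)", {
  for (fp in list(fx_sphere_fpt(),
                  fpt_density(evolve_density(fx_corridor(3)$op, fx_corridor(3)$g,
                                             t_end = 0.05, n_out = 4000L)))) {
    expect_lt(max(abs(fp$S - fp$S_quad)), 1e-5)
  }
})

test_that("absorption is total on connected geometries", {
  fp <- fx_sphere_fpt()
  expect_equal(fp$absorbed, 1, tolerance = 1e-4)
  expect_equal(laplace_Z(fp, 0), 1, tolerance = 1e-4)
})

test_that("laplace and resolvent routes agree across the rate grid", {
  fixtures <- list(
    list(fpt = fx_sphere_fpt(), op = fx_sphere()$op, g = fx_sphere()$g),
    list(fpt = fx_corridor(3)$fpt, op = fx_corridor(3)$op, g = fx_corridor(3)$g))
  for (fx in fixtures) {
    for (lam in c(0.1, 1, 10, 100, 1000)) {
      rs <- resolvent_stats(fx$op, fx$g, lam)
      expect_equal(laplace_Z(fx$fpt, lam), rs$Z, tolerance = 1e-4)
      expect_equal(conditional_mean(fx$fpt, lam), rs$mean_s, tolerance = 1e-4)
      expect_equal(conditional_variance(fx$fpt, lam), rs$var_s2, tolerance = 1e-3)
    }
  }
})

test_that("per-voxel splitting probabilities are probabilities", {
  fx <- fx_sphere()
  for (lam in c(1, 100, 1e4)) {
    z <- resolvent_Z(fx$op, fx$g, lam, per_voxel = TRUE)
    expect_true(all(z >= 0 & z <= 1 + 1e-12))
  }
  # hand-checked scalar case: (lambda + D/h^2) z = D/h^2
  c1 <- fx_corridor(1)
  expect_equal(resolvent_Z(c1$op, c1$g, 1000, per_voxel = TRUE), 0.5,
               tolerance = 1e-12)
  expect_equal(resolvent_Z(c1$op, c1$g, 1000), 0.5, tolerance = 1e-12)
})

test_that("MFPT fields solve the discrete system and respect reachability", {
  # single voxel: u = h^2 / D
  c1 <- fx_corridor(1)
  expect_equal(mfpt_field(c1$op)$u, 1e-3, tolerance = 1e-12)
  # unreachable pocket flagged infinite, not an error
  fx2 <- fx_two_chamber()
  fld <- mfpt_field(fx2$op)
  pocket_rows <- match(setdiff(fx2$masks$cytosol, fx2$masks$connected),
                       fx2$op$voxels)
  expect_true(all(is.infinite(fld$u[pocket_rows])))
  expect_true(all(is.finite(fld$u[-pocket_rows])))
  # Cholesky and CG routes agree
  fx <- fx_sphere()
  u_chol <- mfpt_field(fx$op, method = "chol")$u
  u_cg <- mfpt_field(fx$op, method = "cg")$u
  expect_equal(u_cg, u_chol, tolerance = 1e-8)
})

test_that("conditional mean at lambda = 0 equals the source-averaged MFPT", {
  fx <- fx_sphere()
  fp <- fx_sphere_fpt()
  u <- mfpt_field(fx$op)$u
  u_src <- sum(fx$g$values * u) * fx$op$h^3
  expect_equal(conditional_mean(fp, 0), u_src, tolerance = 1e-3)
  rs0 <- resolvent_stats(fx$op, fx$g, 0)
  expect_equal(rs0$mean_s, u_src, tolerance = 1e-10)
  expect_equal(rs0$Z, 1, tolerance = 1e-10)
})

test_that("conditional mean is the negative log-derivative of Z", {
  fp <- fx_sphere_fpt()
  for (lam in c(1, 10, 100)) {
    eps <- lam * 1e-3
    dlnZ <- (log(laplace_Z(fp, lam + eps)) - log(laplace_Z(fp, lam - eps))) /
      (2 * eps)
    expect_equal(conditional_mean(fp, lam), -dlnZ, tolerance = 1e-3)
  }
})

test_that("identical geometries give unit MFPT ratios; detours scale them", {
  fx <- fx_sphere()
  fld <- mfpt_field(fx$op)
  tbl <- shell_mfpt_summary(fld, fld, membrane_shell(fx$masks))
  expect_true(all(tbl$ratio == 1))
  # forced detour: a wall doubles the graph distance (4 hops vs 2)
  labels <- array(7L, dim = c(6L, 4L, 3L))
  labels[2L, 2L, 2L] <- 2L                      # nucleus
  labels[cbind(c(4L, 4L, 3L, 2L), c(2L, 3L, 3L, 3L), 2L)] <- 1L  # open voxels
  labels[3L, 2L, 2L] <- 7L                      # blocking wall
  grid <- label_grid(labels, 0.1, default_label_map())
  m_block <- build_masks(grid, "physiological")
  m_open <- build_masks(grid, "no_organelles")
  source <- fptcell:::.vox_lin(cbind(4L, 2L, 2L), dim(labels))
  expect_identical(graph_distance(m_block, source)$d_g, 4)
  expect_identical(graph_distance(m_open, source)$d_g, 2)
  expect_equal(ratio_limit(m_block, m_open, source), 2, tolerance = 1e-12)
  expect_identical(ratio_limit(m_block, m_block, source), 1)
})

test_that("signal curves integrate to the delivered molecule count", {
  fp <- fx_sphere_fpt()
  for (lam in c(0, 10, 100)) {
    sc <- signal_curve(fp, lam, N = 500)
    total <- pracma::trapz(sc$time, sc$signal)
    expect_equal(total, 500, tolerance = 1e-3)
    expect_equal(attr(sc, "N0"), 500 / laplace_Z(fp, lam), tolerance = 1e-10)
  }
  # lambda = 0: the curve is N f(t) on the sampled grid
  sc0 <- signal_curve(fp, 0, N = 2)
  n_grid <- length(fp$times)
  expect_equal(sc0$signal[seq_len(n_grid)], 2 * fp$f / fp$absorbed,
               tolerance = 1e-10)
  # sharpening: the peak time decreases with the inactivation rate
  peaks <- vapply(c(0, 100, 1e4), function(l) {
    sc <- signal_curve(fp, l, N = 1)
    sc$time[which.max(sc$signal)]
  }, numeric(1))
  expect_strictly_decreasing(peaks, "signal peak time")
})

test_that("arrival-number statistics are binomial", {
  expect_equal(arrival_number_stats(100, 1)$cv, 0)
  st <- arrival_number_stats(1e4, 0.01)
  expect_equal(st$mean, 100)
  expect_equal(st$cv, sqrt(0.99 / 100), tolerance = 1e-12)
  expect_equal(st$cv_large_lambda, 0.1)
  # Monte-Carlo oracle: binomial draws reproduce the CV
  withr::with_seed(11L, {
    draws <- stats::rbinom(1e5, size = 200L, prob = 0.3)
    cv_mc <- stats::sd(draws) / mean(draws)
  })
  st2 <- arrival_number_stats(200, 0.3)
  se <- st2$cv / sqrt(2 * 1e5)  # rough SE of a CV estimate
  expect_lt(abs(cv_mc - st2$cv), 3 * se + 3e-4)
})

test_that("route selection in the conditional-stats table is seamless", {
  fx <- fx_sphere()
  fp <- fx_sphere_fpt()
  lam <- 10^seq(0, 5, length.out = 6L)
  tbl <- conditional_stats(lam, fpt = fp, op = fx$op, g = fx$g)
  expect_identical(tbl$method, c(rep("time_domain", 4L), rep("resolvent", 2L)))
  expect_true(all(is.na(tbl$median_s) == (tbl$method == "resolvent")))
  expect_strictly_decreasing(tbl$Z, "Z across routes")
  expect_strictly_decreasing(tbl$mean_s, "mean across routes")
  gl <- glance(tbl)
  expect_true(gl$monotone_Z && gl$monotone_mean)
})
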