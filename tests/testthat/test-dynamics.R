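# Rigid-body Langevin dynamics engine: initialization, forces, integration,
# diffusion.

test_that("random initialization is reproducible and non-overlapping", {
  st1 <- initialize_random(20, 60, tpl_dodeca, seed = 5)
  st2 <- initialize_random(20, 60, tpl_dodeca, seed = 5)
  expect_identical(st1$centers, st2$centers)
  expect_identical(st1$orientations, st2$orientations)
  expect_identical(st1$velocities, st2$velocities)
  st3 <- initialize_random(20, 60, tpl_dodeca, seed = 6)
  expect_false(identical(st1$centers, st3$centers))

  st <- initialize_random(2, 1000, tpl_dodeca, seed = 1)
  d <- sqrt(sum((st$centers[1, ] - st$centers[2, ])^2))
  expect_gt(d, 2 * tpl_dodeca$circumradius)

  # pairwise non-overlap under minimum image for a denser case
  stn <- initialize_random(40, 30, tpl_dodeca, seed = 2)
  dd <- as.matrix(dist(stn$centers))
  diag(dd) <- Inf
  # minimum image not needed for the check to be conservative here: wrapology
  expect_true(all(condcap:::site_pair_dists(stn$centers, stn$centers, 30)
                  [upper.tri(dd)] > 2 * tpl_dodeca$circumradius - 1e-9))
  expect_error(initialize_random(1000, 10, tpl_dodeca, seed = 1),
               "infeasible")
})

test_that("forces vanish beyond cutoffs and obey Newton's third law", {
  st <- system_state(rbind(c(-10, 0, 0), c(10, 0, 0)),
                     rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), 60, tpl_dodeca)
  fr <- compute_forces(st, tab_dodeca6)
  expect_equal(fr$energy, 0)
  expect_true(all(fr$forces == 0))

  set.seed(31)
  st2 <- initialize_random(20, 18, tpl_dodeca, seed = 31)
  fr2 <- compute_forces(st2, tab_dodeca6)
  expect_lt(max(abs(colSums(fr2$forces))), 1e-10)
})

test_that("neighbor-list forces match the all-pairs oracle", {
  for (s in 1:6) {
    st <- initialize_random(20, 16, tpl_dodeca, seed = 100 + s)
    fr <- compute_forces(st, tab_dodeca6)
    or <- brute_forces(st, tab_dodeca6)
    expect_lt(max(abs(fr$forces - or$forces)), 1e-10)
    expect_lt(max(abs(fr$torques - or$torques)), 1e-10)
    expect_lt(abs(fr$energy - or$energy), 1e-10)
  }
  # with the condensate field
  spec <- condensate_spec(R_c = 4, eps_c = 3)
  st <- initialize_random(10, 20, tpl_dodeca, seed = 9)
  fr <- compute_forces(st, tab_dodeca6, spec)
  or <- brute_forces(st, tab_dodeca6, spec)
  expect_lt(max(abs(fr$forces - or$forces)), 1e-10)
  expect_lt(abs(fr$energy - or$energy), 1e-10)
})

test_that("zero-length runs return exactly the initial state", {
  st <- initialize_random(5, 40, tpl_dodeca, seed = 3)
  cfg <- run_config(t_F = 0, seed = 3)
  tr <- run_dynamics(st, cfg, tab_dodeca6)
  expect_identical(length(tr$times), 1L)
  expect_equal(t(tr$x[, , 1]), st$centers, tolerance = 1e-14)
})

test_that("NVE limit conserves energy and preserves quaternion norms", {
  st <- system_state(ref_dodeca$centers[1:2, ], ref_dodeca$orientations[1:2, ],
                     30, tpl_dodeca)
  set.seed(2)
  st$velocities <- matrix(rnorm(6), 2, 3)
  st$angmom <- matrix(rnorm(6, sd = 0.3), 2, 3)
  cfg <- run_config(dt = 1e-3, gamma = 0, gamma_rot = 0, t_F = 10,
                    snapshot_every = 0.1, seed = 3)
  tr <- run_dynamics(st, cfg, tab_dodeca6)
  E <- tr$epot + tr$ekin
  expect_lt(max(abs(E - E[1])), 1e-3)
  qn <- apply(tr$q[, , length(tr$times)], 2, function(q) abs(sum(q^2) - 1))
  expect_lt(max(qn), 1e-8)
})

test_that("trajectories are deterministic given seed and config", {
  st <- initialize_random(10, 40, tpl_dodeca, seed = 77)
  cfg <- run_config(t_F = 5, snapshot_every = 1, seed = 77)
  tr1 <- run_dynamics(st, cfg, tab_dodeca6)
  tr2 <- run_dynamics(st, cfg, tab_dodeca6)
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$q, tr2$q)
  cfg2 <- run_config(t_F = 5, snapshot_every = 1, seed = 78)
  tr3 <- run_dynamics(st, cfg2, tab_dodeca6)
  expect_false(identical(tr1$x, tr3$x))
})

test_that("thermostat equipartitions kinetic energy", {
  st <- initialize_random(50, 80, tpl_dodeca, seed = 12)
  cfg <- run_config(t_F = 60, snapshot_every = 1, seed = 12)
  tab_free <- tab_dodeca0
  tr <- run_dynamics(st, cfg, tab_free)
  keep <- tr$times > 10
  ek_dof <- tr$ekin[keep] / (50 * 6)
  sem <- sd(ek_dof) / sqrt(sum(keep))
  expect_lt(abs(mean(ek_dof) - 0.5), max(2 * sem, 0.02))
})

test_that("translational diffusion follows the Einstein relation", {
  tab_free <- tab_dodeca0
  tab_free$rules <- list()
  st <- initialize_random(100, 120, tpl_dodeca, seed = 8)
  cfg <- run_config(gamma = 1, t_F = 500, snapshot_every = 5, seed = 8)
  tr <- run_dynamics(st, cfg, tab_free)
  D1 <- measure_translational_diffusion(tr)
  expect_equal(D1, 1, tolerance = 0.05)
  cfg2 <- run_config(gamma = 2, t_F = 500, snapshot_every = 5, seed = 8)
  tr2 <- run_dynamics(st, cfg2, tab_free)
  D2 <- measure_translational_diffusion(tr2)
  expect_equal(D2, 0.5, tolerance = 0.1)
  expect_lt(D2 / D1, 0.6)
  expect_gt(D2 / D1, 0.4)
  short <- run_dynamics(st, run_config(t_F = 2, snapshot_every = 1, seed = 1),
                        tab_free)
  expect_error(measure_translational_diffusion(short), "insufficient")
})

test_that("extended-XYZ trajectories round-trip", {
  st <- initialize_random(6, 30, tpl_dodeca, seed = 4)
  cfg <- run_config(t_F = 2, snapshot_every = 0.5, seed = 4)
  tr <- run_dynamics(st, cfg, tab_dodeca6)
  path <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, path)
  tr2 <- read_trajectory_xyz(path, tpl_dodeca)
  expect_equal(tr2$times, tr$times, tolerance = 1e-9)
  expect_equal(tr2$x, tr$x, tolerance = 1e-9)
  expect_equal(tr2$q, tr$q, tolerance = 1e-9)
  expect_identical(tr2$image, tr$image)
  expect_equal(tr2$box_L, tr$box_L, tolerance = 1e-9)
})
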