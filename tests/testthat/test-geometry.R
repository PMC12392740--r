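# Subunit templates, interaction rules and reference capsids.

test_that("dodecahedron subunit has the prescribed pentagon geometry", {
  tpl <- tpl_dodeca
  expect_identical(sum(tpl$atoms$role == "A"), 5L)
  expect_identical(sum(tpl$atoms$role == "T"), 1L)
  expect_identical(sum(tpl$atoms$role == "B"), 1L)
  A <- tpl$atoms$pos[tpl$atoms$role == "A", ]
  # all A atoms at distance exactly l0 = 1 from the symmetry axis
  expect_equal(sqrt(rowSums(A[, 1:2]^2)), rep(1, 5), tolerance = 1e-12)
  # adjacent-vertex chord length 2 sin(pi/5)
  d <- sqrt(sum((A[1, ] - A[2, ])^2))
  expect_equal(d, 2 * sin(pi / 5), tolerance = 1e-12)
  # mass 1, SPD inertia
  expect_identical(tpl$mass, 1)
  ev <- eigen(tpl$inertia, symmetric = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(tpl$inertia, t(tpl$inertia))
})

test_that("geometry scales linearly with l0 and inertia quadratically", {
  t1 <- build_dodecahedron_subunit(1)
  t2 <- build_dodecahedron_subunit(2)
  expect_equal(t2$atoms$pos, 2 * t1$atoms$pos, tolerance = 1e-12)
  expect_equal(t2$inertia, 4 * t1$inertia, tolerance = 1e-12)
  expect_error(build_dodecahedron_subunit(0), "positive")
  expect_error(build_dodecahedron_subunit(-1), "positive")
})

test_that("icosahedron subunit has 45 excluders, 6 attractors, diameter ~3", {
  tpl <- tpl_icosa
  expect_identical(sum(tpl$atoms$role == "EXCLUDER"), 45L)
  expect_identical(sum(tpl$atoms$role %in% c("Aa", "Ab")), 6L)
  expect_gt(2 * tpl$circumradius, 2.9)
  expect_lt(2 * tpl$circumradius, 3.1)
  # centroid of pseudoatom positions at the body origin
  expect_equal(colMeans(tpl$atoms$pos), c(0, 0, 0), tolerance = 1e-12)
  expect_error(build_icosahedron_subunit(-0.5), "positive")
})

test_that("interaction table carries eps_ss only on attractor pairs", {
  expect_equal(tab_dodeca6$rules[["A|A"]]$eps, 6)
  expect_false(grepl("A", names(tab_dodeca6$rules)[2], fixed = TRUE) &&
               tab_dodeca6$rules[["T|T"]]$eps == 6)
  # repulsive rules do not depend on eps_ss
  expect_equal(tab_dodeca0$rules[["T|T"]], tab_dodeca6$rules[["T|T"]])
  # eps_ss = 0: attraction is <= 0 everywhere and exactly 0 beyond cutoff
  r <- seq(0.01, 2, by = 0.01)
  e0 <- pair_energy(tab_dodeca0, "A", "A", r)
  expect_true(all(e0 <= 1e-14))
  expect_true(all(e0[r >= tab_dodeca0$rules[["A|A"]]$r_cut] == 0))
  expect_error(build_interaction_table("dodecahedron", eps_ss = -1), "negative")
})

test_that("non-complementary icosahedron attractor pairs carry no attraction", {
  r <- seq(0.05, 3, by = 0.01)
  expect_true(all(pair_energy(tab_icosa6, "Aa", "Aa", r) == 0))
  expect_true(all(pair_energy(tab_icosa6, "Ab", "Ab", r) == 0))
  expect_true(any(pair_energy(tab_icosa6, "Aa", "Ab", r) < -1))
})

test_that("pair energies are symmetric, continuous at cutoff, zero beyond", {
  pairs <- list(c("A", "A"), c("T", "T"), c("B", "T"), c("T", "B"))
  r <- seq(0.05, 3, by = 0.037)
  for (p in pairs) {
    expect_equal(pair_energy(tab_dodeca6, p[1], p[2], r),
                 pair_energy(tab_dodeca6, p[2], p[1], r), tolerance = 0)
  }
  for (nm in names(tab_dodeca6$rules)) {
    rc <- tab_dodeca6$rules[[nm]]$r_cut
    roles <- strsplit(nm, "|", fixed = TRUE)[[1]]
    # cut-and-shifted potentials are continuous at the cutoff: the residual
    # just inside is O(slope * delta), with slopes of a few kT per length
    e_in <- pair_energy(tab_dodeca6, roles[1], roles[2], rc - 1e-6)
    slope <- abs(pair_energy(tab_dodeca6, roles[1], roles[2], rc - 1e-4) -
                 pair_energy(tab_dodeca6, roles[1], roles[2], rc - 2e-4)) / 1e-4
    expect_lt(abs(e_in), (slope + 1) * 2e-6)
    expect_identical(pair_energy(tab_dodeca6, roles[1], roles[2], 10 * rc), 0)
  }
  # Morse minimum (r_eq -> 0 limit) approaches the cut-shifted well depth
  rl <- tab_dodeca6$rules[["A|A"]]
  expect_equal(pair_energy(tab_dodeca6, "A", "A", 1e-12),
               -6 - rl$shift, tolerance = 1e-9)
  # WCA is zero at and beyond 2^(1/6) sigma
  sg <- tab_dodeca6$rules[["T|T"]]$sigma
  expect_equal(pair_energy(tab_dodeca6, "T", "T", 2^(1 / 6) * sg), 0,
               tolerance = 1e-12)
  expect_error(pair_energy(tab_dodeca6, "A", "A", -0.3), "positive")
})

test_that("reference capsids close with the full bond complement", {
  st <- system_state(ref_dodeca$centers, ref_dodeca$orientations, 50,
                     tpl_dodeca)
  g <- detect_bonds(st)
  expect_identical(nrow(g$edges), 30L)
  expect_equal(tabulate(c(g$edges), 12), rep(5, 12))

  sti <- system_state(ref_icosa$centers, ref_icosa$orientations, 60,
                      tpl_icosa)
  gi <- detect_bonds(sti)
  expect_identical(nrow(gi$edges), 30L)
  expect_equal(tabulate(c(gi$edges), 20), rep(3, 20))
})

test_that("reference capsid attraction energy equals 30 bonds at the pair minimum", {
  st <- system_state(ref_dodeca$centers, ref_dodeca$orientations, 50,
                     tpl_dodeca)
  fr <- compute_forces(st, tab_dodeca6)
  per_bond <- 2 * pair_energy(tab_dodeca6, "A", "A", 1e-12)
  expect_equal(fr$energy, 30 * per_bond, tolerance = 0.05)
  # dodecahedron reference is exactly at the minimum: forces vanish
  expect_lt(max(abs(fr$forces)), 1e-9)

  sti <- system_state(ref_icosa$centers, ref_icosa$orientations, 60,
                      tpl_icosa)
  fri <- compute_forces(sti, tab_icosa6)
  rl <- tab_icosa6$rules[["Aa|Ab"]]
  per_bond_i <- 2 * pair_energy(tab_icosa6, "Aa", "Ab", 2^(1 / 6) * rl$sigma)
  expect_equal(fri$energy, 30 * per_bond_i, tolerance = 0.05)
})

test_that("capsid circumscribed diameter is near the effective size 5.1", {
  expect_equal(capsid_diameter(ref_dodeca), 5.1, tolerance = 0.08)
})

test_that("templates serialize to JSON and round-trip", {
  path <- tempfile(fileext = ".json")
  template_to_json(tpl_dodeca, path)
  tpl2 <- template_from_json(path)
  expect_equal(tpl2$atoms$pos, tpl_dodeca$atoms$pos, tolerance = 1e-10)
  expect_identical(tpl2$model, "dodecahedron")
})
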