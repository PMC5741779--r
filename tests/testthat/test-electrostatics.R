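test_that("point-charge and point-dipole potentials match closed forms", {
  k <- field_constants()
  m <- molecule("H", matrix(0, 1, 3))

  # unit charge at 1 Å: hartree->kcal times bohr->Å
  v <- potential_at_point(m, multipole_set(q = 1), c(1, 0, 0))
  expect_equal(v, k$hartree_to_kcalmol * k$bohr_to_angstrom, tolerance = 1e-12)
  expect_equal(round(v, 4), 332.0637)

  # axial point dipole mu=(0,0,1) e*bohr at 2 bohr: V = mu/R^2 = 1/4 hartree/e
  md <- multipole_set(q = 0, mu = matrix(c(0, 0, 1), 1), order = 1)
  vz <- potential_at_point(m, md, c(0, 0, 2 * k$bohr_to_angstrom))
  expect_equal(vz, k$hartree_to_kcalmol / 4, tolerance = 1e-10)
  expect_equal(round(vz, 4), 156.8774)

  # points inside the 0.3 bohr guard fail loudly, naming the atom
  expect_error(potential_at_point(m, multipole_set(q = 1), c(0.05, 0, 0)),
               "atom 1.*guard")
})

test_that("order-2 expansion matches an explicit finite-charge cluster", {
  # every multipole set has an equivalent point-charge cluster; at long range
  # the two potentials must agree (acceptance runs 100 seeds; spot-check here)
  for (s in 1:10) {
    cl <- make_random_multipole_cloud(6, order = 2, seed = 4000 + s)
    cluster <- multipole_charge_cluster(cl$mol, cl$mps)
    centroid <- colMeans(cl$mol$xyz)
    u <- withr::with_seed(s, { v <- rnorm(3); v / sqrt(sum(v^2)) })
    pt <- centroid + 20 * .k$bohr_to_angstrom * u
    v_mp <- potential_at_point(cl$mol, cl$mps, pt)
    v_cl <- coulomb_sum(cluster$xyz, cluster$q, pt)
    expect_lt(abs(v_mp - v_cl) / max(abs(v_cl), 1e-12), 1e-4)
  }
})

test_that("grid evaluation is bitwise the per-point evaluation", {
  cl <- make_random_multipole_cloud(5, order = 2, seed = 77)
  pts <- withr::with_seed(78, matrix(rnorm(300, sd = 3), 100, 3) +
                            matrix(colMeans(cl$mol$xyz), 100, 3, byrow = TRUE))
  pts <- pts + 10   # push points safely outside the cloud
  g <- potential_on_grid(cl$mol, cl$mps, pts)
  per <- vapply(seq_len(nrow(pts)),
                function(i) potential_at_point(cl$mol, cl$mps, pts[i, ]),
                numeric(1))
  expect_identical(g$V, per)
  expect_equal(nrow(potential_on_grid(cl$mol, cl$mps,
                                      matrix(numeric(0), 0, 3))), 0L)

  # summed potential of a 3-charge system over a grid vs a direct double loop
  tri <- molecule(rep("C", 3), rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  qs <- c(0.5, -0.3, -0.2)
  mps <- multipole_set(qs)
  grid <- as.matrix(expand.grid(x = seq(5, 8, length.out = 10),
                                y = seq(5, 8, length.out = 10),
                                z = seq(5, 8, length.out = 10)))
  total <- sum(potential_on_grid(tri, mps, grid)$V)
  direct <- 0
  for (i in seq_len(nrow(grid)))
    direct <- direct + coulomb_sum(tri$xyz, qs, grid[i, ])
  expect_equal(total, direct, tolerance = 1e-10)
})

test_that("potential is linear in the source and odd under sign flip", {
  mol <- random_test_molecule(5, seed = 91)
  q1 <- withr::with_seed(92, rnorm(5, 0, 0.3))
  q2 <- withr::with_seed(93, rnorm(5, 0, 0.3))
  pt <- c(12, 12, 12)
  v1 <- potential_at_point(mol, multipole_set(q1), pt)
  v2 <- potential_at_point(mol, multipole_set(q2), pt)
  v12 <- potential_at_point(mol, multipole_set(q1 + q2), pt)
  expect_equal(v12, v1 + v2, tolerance = 1e-12 * max(1, abs(v12)))

  cl <- make_random_multipole_cloud(5, order = 2, seed = 94)
  neg <- multipole_set(-cl$mps$q, mu = -cl$mps$mu, theta = -cl$mps$theta,
                       order = 2)
  expect_equal(potential_at_point(cl$mol, neg, pt),
               -potential_at_point(cl$mol, cl$mps, pt), tolerance = 1e-12)
})

test_that("single-centre expansion of a dipolar pair converges monotonically", {
  # exact source: +/-0.5 e separated by d=0.8 Å; expansion: one centre with
  # the equivalent mu (quadrupole vanishes by symmetry) -> error ~ (d/R)^2
  d <- 0.8
  pair_xyz <- rbind(c(d / 2, 0, 0), c(-d / 2, 0, 0))
  pair_q <- c(0.5, -0.5)
  centre <- molecule("C", matrix(0, 1, 3))
  mu <- matrix(c(0.5 * d * .k$angstrom_to_bohr, 0, 0), 1)
  exp_set <- multipole_set(q = 0, mu = mu, order = 1)
  Rs <- d * seq(5, 50, by = 5)
  rel <- vapply(Rs, function(R) {
    pt <- c(R / sqrt(2), R / sqrt(2), 0)
    ve <- coulomb_sum(pair_xyz, pair_q, pt)
    vm <- potential_at_point(centre, exp_set, pt)
    abs(vm - ve) / abs(ve)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[length(rel)], 1e-3)
})

test_that("molecular moments obey textbook definitions and shift identities", {
  k <- field_constants()
  # +/-1 e, 1 Å apart, origin at midpoint: Q=0, |D| = 1 Å in e*bohr, along -x
  two <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  mm <- molecular_moments(two, multipole_set(c(1, -1)), origin = c(0.5, 0, 0))
  expect_equal(mm$Q, 0)
  expect_equal(mm$D, c(-k$angstrom_to_bohr, 0, 0), tolerance = 1e-12)

  # neutral set: dipole independent of origin
  cl <- make_random_multipole_cloud(6, order = 1, seed = 101)
  d1 <- molecular_moments(cl$mol, cl$mps, origin = c(0, 0, 0))$D
  d2 <- molecular_moments(cl$mol, cl$mps, origin = c(3, -2, 1))$D
  expect_equal(d1, d2, tolerance = 1e-10)

  # charged set: D(o2) - D(o1) = -Q * (o2 - o1) in bohr
  q <- withr::with_seed(102, rnorm(6, 0.2, 0.3))
  mol <- random_test_molecule(6, seed = 103)
  chg <- multipole_set(q)
  o1 <- c(0, 0, 0); o2 <- c(1, 2, -1)
  m1 <- molecular_moments(mol, chg, o1)
  m2 <- molecular_moments(mol, chg, o2)
  expect_equal(m2$D - m1$D, -m1$Q * (o2 - o1) * k$angstrom_to_bohr,
               tolerance = 1e-10)

  # point-charge-only quadrupole agrees with an independent direct loop
  # (detraced-second-moment convention: theta = sum q (r r' - r^2 I / 3))
  Th <- matrix(0, 3, 3)
  for (i in 1:6) {
    r <- unname(mol$xyz[i, ]) * k$angstrom_to_bohr
    Th <- Th + q[i] * (outer(r, r) - (sum(r^2) / 3) * diag(3))
  }
  expect_equal(m1$Theta, Th, tolerance = 1e-10)
  expect_lt(abs(sum(diag(m1$Theta))), 1e-10)
})
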