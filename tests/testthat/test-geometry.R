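make_traj <- function(xyz) direct_topology(xyz)$trajectory

test_that("distance, angle and torsion match construction and oracles", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 2), c(1, 0, 2), c(1, 1, 2))
  tr <- make_traj(xyz)
  expect_equal(series_values(distance_series(tr, 1, 2)), 2)
  expect_equal(series_values(distance_series(tr, 1, 1)), 0)
  expect_equal(series_values(angle_series(tr, 1, 2, 3)), 90)
  # angle symmetry
  expect_equal(series_values(angle_series(tr, 3, 2, 1)), 90)

  # planar cis chain -> 0; trans -> 180
  cis <- make_traj(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(series_values(torsion_series(cis, 1, 2, 3, 4)), 0)
  trans <- make_traj(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  expect_equal(abs(series_values(torsion_series(trans, 1, 2, 3, 4))), 180)

  # butane-like: rotate the last atom about the bc axis by a known angle;
  # independent rotation-matrix oracle fixes the expected torsion
  set.seed(11)
  for (phi in c(-150, -60, 30, 120)) {
    base <- rbind(c(0, 1.2, 0), c(0, 0, 0), c(1.5, 0, 0))
    d0 <- c(1.5, 1.2, 0)  # cis position of atom d
    R <- fpgtraj:::rot_about_axis(c(1, 0, 0), phi)
    d1 <- as.numeric((d0 - c(1.5, 0, 0)) %*% t(R)) + c(1.5, 0, 0)
    tr2 <- make_traj(rbind(base, d1))
    got <- series_values(torsion_series(tr2, 1, 2, 3, 4))
    expect_equal(abs(got), abs(phi), tolerance = 1e-8)
  }

  # reversal identity of the IUPAC convention: reading the chain
  # backwards leaves the signed torsion unchanged
  xyz <- matrix(rnorm(12), 4)
  tr3 <- make_traj(xyz)
  expect_equal(series_values(torsion_series(tr3, 1, 2, 3, 4)),
               series_values(torsion_series(tr3, 4, 3, 2, 1)))

  # degenerate b-c axis is masked, not an error
  dg <- make_traj(rbind(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)))
  expect_false(torsion_series(dg, 1, 2, 3, 4)$mask[1])

  # random pair vs independent norm computation
  set.seed(2)
  xyz <- matrix(rnorm(30), 10)
  tr4 <- make_traj(xyz)
  expect_equal(series_values(distance_series(tr4, 3, 7)),
               sqrt(sum((xyz[3, ] - xyz[7, ])^2)), tolerance = 1e-12)
})

test_that("glycosidic chi reads back planted values and classifies domains", {
  for (target in c(30, -64, 101, 27, -55)) {
    x <- set_chi(toy$topology, toy$coords, 0, "B", target)
    got <- series_values(glycosidic_chi(new_trajectory(toy$topology, x), 0, "B"))
    expect_equal(got, target, tolerance = 1e-6)
  }
  # pyrimidine path works too
  expect_silent(glycosidic_chi(toy_traj, 1, "B"))

  expect_equal(classify_chi(27), "syn")
  expect_equal(classify_chi(101), "anti")
  expect_equal(classify_chi(-55), "syn")
  expect_equal(classify_chi(90), "anti")    # half-open boundary
  expect_equal(classify_chi(-90), "syn")
  expect_equal(classify_chi(-64, sub_labels = TRUE), "high_anti")
  expect_equal(classify_chi(101, sub_labels = TRUE), "high_syn")
  expect_true(is.na(classify_chi(150, sub_labels = TRUE)))
  # totality over the wrapped circle
  grid <- seq(-179.5, 180, by = 0.5)
  expect_false(anyNA(classify_chi(grid)))

  expect_error(glycosidic_chi(toy_traj, 3, "A"), "chi-defining")
})

test_that("Kabsch superposition is exact on rigid copies and bounded on defects", {
  set.seed(3)
  ref <- matrix(rnorm(60), 20)
  expect_equal(superpose_kabsch(ref, ref)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation()
  mob <- ref %*% t(R) + matrix(c(3, -2, 5), 20, 3, byrow = TRUE)
  k <- superpose_kabsch(ref, mob)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)

  # one atom displaced by d among n atoms: optimal rmsd <= d/sqrt(n)
  mob2 <- ref
  mob2[1, ] <- mob2[1, ] + c(0.9, 0, 0)
  k2 <- superpose_kabsch(ref, mob2)
  expect_lte(k2$rmsd, 0.9 / sqrt(20) + 1e-9)

  expect_error(superpose_kabsch(ref[1:2, ], ref[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_kabsch(line, line), "rank")
})

test_that("rmsd_series: zero on identity, closed form under noise, rigid invariance", {
  tr <- traj_of(toy$topology, toy$coords, toy$coords, toy$coords)
  expect_equal(series_values(rmsd_series(tr, 1)), rep(0, 3), tolerance = 1e-9)

  set.seed(4)
  sig <- 0.25
  n <- 12
  ref <- toy$coords
  arr <- array(rep(ref, n), dim = c(nrow(ref), 3, n)) +
    stats::rnorm(nrow(ref) * 3 * n, sd = sig)
  trn <- new_trajectory(toy$topology, arr)
  rs <- series_values(rmsd_series(trn, ref))
  expect_equal(mean(rs), sig * sqrt(3), tolerance = 0.05 * sig * sqrt(3))
  # Kabsch-fitted rmsd never exceeds the unfitted rmsd
  unfit <- vapply(seq_len(n), function(m)
    sqrt(mean(rowSums((arr[, , m] - ref)^2))), 0)
  expect_true(all(rs <= unfit + 1e-12))

  trR <- transform_traj(trn, random_rotation(), c(5, -1, 2))
  expect_equal(series_values(rmsd_series(trR, ref)), rs, tolerance = 1e-6)

  expect_error(rmsd_series(trn, ref, fit_selection = "none"), "empty")
})

test_that("radius of gyration: closed forms and direct-sum oracle", {
  two <- direct_topology(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(series_values(radius_of_gyration(two$trajectory)), 1)
  one <- direct_topology(matrix(c(1, 2, 3), 1))
  expect_equal(series_values(radius_of_gyration(one$trajectory)), 0)
  set.seed(5)
  xyz <- matrix(rnorm(300), 100)
  cl <- direct_topology(xyz)
  direct <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  expect_equal(series_values(radius_of_gyration(cl$trajectory)), direct,
               tolerance = 1e-12)
})

test_that("DNA kink angle: collinear arms give 0, constructed bends read back", {
  arm <- function(d, o) t(vapply(0:5, function(k) o + k * 3.4 * d, numeric(3)))
  for (bend in c(0, 30, 60, 120)) {
    d1 <- c(0, 0, 1)
    d2 <- c(sin(bend * pi / 180), 0, cos(bend * pi / 180))
    pts <- rbind(arm(d1, c(0, 0, 0)), arm(d2, c(0, 0, 17) + 3.4 * d2))
    pdb <- direct_topology(pts, name = "P", resname = "DA", elem = "P", chain = "B")
    got <- series_values(dna_kink_angle(pdb$trajectory, 1:6, 7:12))
    expect_equal(got, bend, tolerance = 0.1)
  }
  # independent SVD-line-fit oracle on a noisy bent pair of arms
  set.seed(6)
  d1 <- c(0, 0, 1); d2 <- c(sin(1), 0, cos(1))
  pts <- rbind(arm(d1, c(0, 0, 0)), arm(d2, c(0, 0, 17) + 3.4 * d2)) +
    stats::rnorm(36, sd = 0.3)
  pdb <- direct_topology(pts, name = "P", resname = "DA", elem = "P", chain = "B")
  fitdir <- function(x) {
    v <- svd(sweep(x, 2, colMeans(x)))$v[, 1]
    if (sum((x[nrow(x), ] - x[1, ]) * v) < 0) -v else v
  }
  oracle <- acos(sum(fitdir(pts[1:6, ]) * fitdir(pts[7:12, ]))) * 180 / pi
  expect_equal(series_values(dna_kink_angle(pdb$trajectory, 1:6, 7:12)),
               oracle, tolerance = 1e-9)
  expect_error(dna_kink_angle(pdb$trajectory, 1:2, 7:12), "3 P atoms")
})

test_that("propeller twist: coplanar 0, planted values read back with + sign", {
  tr0 <- new_trajectory(toy$topology, toy$coords)
  flat <- series_values(propeller_twist(tr0, list(c(-3, "B"), c(-3, "C"))))
  expect_equal(flat, 0, tolerance = 1e-6)
  for (omega in c(13, 15)) {
    cxp <- suppressWarnings(build_toy_complex(propeller_deg = omega))
    trp <- new_trajectory(cxp$topology, cxp$coords)
    got <- series_values(propeller_twist(trp, list(c(-3, "B"), c(-3, "C"))))
    expect_equal(got, omega, tolerance = 0.2)
  }
  expect_error(propeller_twist(tr0, list(c(1, "A"), c(-3, "C"))), "ring")
})

test_that("eversion pseudo-dihedral: rigid invariance and swap oracle", {
  ev <- eversion_angle(toy_traj, 0, "B")
  expect_true(ev$mask[1])
  trR <- transform_traj(toy_traj, random_rotation(), c(-4, 2, 9))
  expect_equal(series_values(eversion_angle(trR, 0, "B")),
               series_values(ev), tolerance = 1e-6)

  # swapping the last two points equals the torsion oracle on swapped points
  top <- toy$topology
  b <- fpgtraj:::base_ring_indices(top, 0, "B")
  c1 <- fpgtraj:::find_in_residue(top, b$ai, "C1'")
  p0 <- fpgtraj:::find_in_residue(top, b$ai, "P")
  p3 <- fpgtraj:::find_in_residue(top, fpgtraj:::residue_atoms(top, 1, "B"), "P")
  swapped <- eversion_angle(toy_traj, 0, "B", points = list(b$idx, c1, p3, p0))
  ctr <- colMeans(toy$coords[b$idx, ])
  oracle <- fpgtraj:::torsion_from_tracks(
    matrix(ctr), matrix(toy$coords[c1, ]),
    matrix(toy$coords[p3, ]), matrix(toy$coords[p0, ]))
  expect_equal(series_values(swapped), oracle, tolerance = 1e-9)

  expect_error(eversion_angle(toy_traj, 6, "B"), "eversion")  # no 3' neighbour
})

test_that("moving average: identity, constants, masks and circular seam", {
  const <- geom_series(rep(3.2, 100), unit = "A")
  expect_equal(series_values(moving_average(const, 50)), rep(3.2, 100))
  s <- geom_series(rnorm(60), unit = "A")
  expect_equal(series_values(moving_average(s, 1)), series_values(s))

  # alternating +-179 torsions average to +-180, never 0
  alt <- geom_series(rep(c(179, -179), 30), unit = "degree", wrap = TRUE)
  ma <- series_values(moving_average(alt, 10))
  expect_true(all(abs(abs(ma) - 180) < 1.5))

  # masked positions are excluded; all-masked window propagates the mask
  v <- c(NA, NA, 5, 5, NA)
  m <- moving_average(geom_series(v, unit = "A"), 2)
  expect_false(m$mask[1])
  expect_equal(series_values(m)[3], 5)

  expect_warning(moving_average(geom_series(1:3, unit = "A"), 10), "masked")
})

test_that("descriptors are invariant under global rigid-body motion", {
  set.seed(7)
  R <- random_rotation(); tv <- c(12, -7, 3)
  trR <- transform_traj(toy_traj, R, tv)
  pairs <- list(
    list(distance_series, list(5, 80)),
    list(angle_series, list(5, 80, 200)),
    list(torsion_series, list(5, 80, 200, 300))
  )
  for (p in pairs) {
    a <- series_values(do.call(p[[1]], c(list(toy_traj), p[[2]])))
    b <- series_values(do.call(p[[1]], c(list(trR), p[[2]])))
    expect_equal(a, b, tolerance = 1e-6)
  }
  expect_equal(series_values(radius_of_gyration(trR)),
               series_values(radius_of_gyration(toy_traj)), tolerance = 1e-6)
  expect_equal(series_values(glycosidic_chi(trR, 0, "B")),
               series_values(glycosidic_chi(toy_traj, 0, "B")),
               tolerance = 1e-6)
})
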