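test_that("hbond energy: parameter anchor, decay, and closed-form grid", {
  expect_equal(hbond_energy(2.9, 0), 2.8)            # maximum by construction
  expect_lt(hbond_energy(6.0, 0), 0.1)               # decayed below thresholds
  # independent evaluation of the closed form on a grid
  d <- seq(2.5, 6, length.out = 100)
  th <- seq(0, 80, length.out = 100)
  x <- 2.9 / d
  ref <- pmax(0, 2.8 * (6 * x^10 - 5 * x^12)) * cos(th * pi / 180)^4
  expect_equal(hbond_energy(d, th), ref, tolerance = 1e-12)
  # angular factor vanishes for bent arrangements
  expect_equal(hbond_energy(2.9, 95), 0)
})

test_that("detection: ideal bond found, far pair not, brute-force set equality", {
  ideal <- suppressWarnings(read_pdb(paste(
    pdb_text(c("N", "H", "CA", "C", "O"),
             rbind(c(0, 0, 0), c(1, 0, 0), c(-1.46, 0, 0), c(-2.98, 0, 0),
                   c(-3.6, 0, 1)), resname = "GLY", resnum = rep(1, 5)),
    pdb_text(c("O", "C", "CA", "N", "H"),
             rbind(c(2.9, 0, 0), c(2.9, 1.23, 0), c(2.9, 2.75, 0),
                   c(2.9, 4.21, 0), c(2.9, 4.5, 1)),
             resname = "GLY", resnum = rep(2, 5)),
    sep = "\n")))
  hb <- detect_hbonds(snapshot(ideal$trajectory, 1), ideal$topology)
  expect_true(any(ideal$topology$atoms$name[hb$donor] == "N" &
                    ideal$topology$atoms$name[hb$acceptor] == "O" &
                    ideal$topology$atoms$resnum[hb$acceptor] == 2))

  far <- ideal
  shift <- ideal$topology$atoms$resnum == 2
  xyz <- snapshot(far$trajectory, 1)
  xyz[shift, 1] <- xyz[shift, 1] + 2.6   # N...O becomes 5.5
  hb2 <- detect_hbonds(xyz, far$topology)
  expect_false(any(far$topology$atoms$resnum[hb2$acceptor] == 2 &
                     far$topology$atoms$name[hb2$acceptor] == "O"))

  # brute-force equivalence on jittered complex snapshots
  set.seed(9)
  for (rep in 1:3) {
    xyz <- toy$coords + stats::rnorm(length(toy$coords), sd = 0.25)
    got <- detect_hbonds(xyz, toy$topology)
    want <- brute_force_hbonds(xyz, toy$topology)
    expect_identical(hb_set(got), hb_set(want))
  }
})

test_that("geometric fallback criterion agrees with the energy rule on planted bonds", {
  cx <- suppressWarnings(build_toy_complex(n_hbond_stations = 10))
  plan <- plant_spec(hbond_occurrence = rep(0.5, 10), noise_sigma = 0.03, tau = 1)
  sim <- simulate_trajectory(cx, plan, n_snapshots = 60, seed = 21)
  keys <- sim$manifest$hbonds$key
  agree <- 0; total <- 0
  for (s in seq_len(60)) {
    xyz <- sim$trajectory$coords[, , s]
    e <- detect_hbonds(xyz, cx$topology, criterion = "energy")
    g <- detect_hbonds(xyz, cx$topology, criterion = "geometric")
    ek <- hbond_key(cx$topology, e$donor, e$acceptor)
    gk <- hbond_key(cx$topology, g$donor, g$acceptor)
    agree <- agree + sum((keys %in% ek) == (keys %in% gk))
    total <- total + length(keys)
  }
  expect_gte(agree / total, 0.9)
})

test_that("occurrence table: planted fractions, floor rule, model comparability", {
  cx <- suppressWarnings(build_toy_complex(n_hbond_stations = 3))
  plan <- plant_spec(hbond_occurrence = c(1.0, 0.40, 0.005), noise_sigma = 0,
                     tau = 1)
  sim <- simulate_trajectory(cx, plan, n_snapshots = 400, seed = 5)
  ot <- occurrence_table(sim$trajectory)
  mf <- sim$manifest$hbonds
  expect_equal(unname(ot$occurrence[mf$key[1], 1]), 1.0)
  expect_lt(abs(ot$occurrence[mf$key[2], 1] - 0.40),
            3 * sqrt(0.4 * 0.6 / 400))   # binomial 3 sigma
  # the 1% existence floor keys off the realized occupancy: the sparse
  # plant is present iff it was realized above the floor
  expect_equal(mf$key[3] %in% rownames(ot$occurrence), mf$realized[3] > 0.01)
  # deterministically below-floor occurrences are dropped
  ot0 <- occurrence_table(sim$trajectory, floor = 0.5)
  expect_false(mf$key[2] %in% rownames(ot0$occurrence))  # 0.4 < 0.5 floor

  # mismatched topologies are refused
  other <- suppressWarnings(build_toy_complex(n_bp = 8))
  sim2 <- simulate_trajectory(other, plant_spec(noise_sigma = 0),
                              n_snapshots = 2, seed = 1)
  expect_error(occurrence_table(list(sim$trajectory, sim2$trajectory)),
               "mismatched")
})

test_that("stability classes partition occurrences with inclusive boundaries", {
  occ <- c(0.95, 0.905, 0.90, 0.50, 0.25, 0.251, 0.01)
  got <- classify_stability(occ)
  expect_equal(got, c("stable", "stable", "intermediate", "intermediate",
                      "fluctuating", "intermediate", "fluctuating"))
  # partition: every bond in exactly one category
  expect_true(all(got %in% c("stable", "intermediate", "fluctuating")))
})

test_that("phi coefficient: identity, formula case, independence, degenerate margins", {
  occ <- runif(80)
  expect_equal(phi_coefficient(occ, occ, split = 0.5), 1)

  # (a,b,c,d) = (30,10,10,30) -> phi = 0.5, via direct construction
  a_cat <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 10, 30))
  b_cat <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  expect_equal(phi_coefficient(as.numeric(a_cat), as.numeric(b_cat), split = 0.5),
               0.5)

  set.seed(10)
  x <- as.numeric(runif(1e4) > 0.5)
  y <- as.numeric(runif(1e4) > 0.5)
  expect_lt(abs(phi_coefficient(x, y, split = 0.5)), 0.03)

  z <- rep(1, 50)
  ph <- phi_coefficient(z, runif(50), split = 0.5)
  expect_equal(as.numeric(ph), 0)
  expect_true(attr(ph, "degenerate"))
  expect_error(phi_coefficient(numeric(0), numeric(0)), "empty")
})

test_that("group-specific bonds: planted differences selected, noise rejected", {
  set.seed(12)
  n_bg <- 120
  occ <- matrix(runif(n_bg * 8, 0.3, 0.5) +
                  rep(rnorm(n_bg, sd = 0.01), 8), n_bg, 8)
  occ[1, ] <- c(0.92, 0.95, 0.90, 0.93, 0.10, 0.15, 0.12, 0.08)  # planted
  occ[2, ] <- c(0.55, 0.25, 0.85, 0.15, 0.35, 0.65, 0.05, 0.95)  # wide spread
  occ <- pmin(pmax(occ, 0), 1)
  tab <- synthetic_occurrence_table(occ, paste0("m", 1:8))
  grouping <- setNames(rep(c("C", "A"), each = 4), paste0("m", 1:8))
  dm <- group_specific_bonds(tab, grouping, k = 3, abs_floor = 0.10)
  expect_true(dm$selected[1])
  expect_false(dm$selected[2])   # delta small relative to the spread

  # identical occurrences select nothing
  same <- synthetic_occurrence_table(matrix(0.4, 50, 4), paste0("m", 1:4))
  g2 <- setNames(rep(c("C", "A"), each = 2), paste0("m", 1:4))
  expect_false(any(group_specific_bonds(same, g2)$selected))

  # monotone in k; k = 0 with floor 0 selects every bond with delta != 0
  sel3 <- sum(group_specific_bonds(tab, grouping, k = 3)$selected)
  sel1 <- sum(group_specific_bonds(tab, grouping, k = 1)$selected)
  sel0 <- group_specific_bonds(tab, grouping, k = 0, abs_floor = 0)
  selinf <- group_specific_bonds(tab, grouping, k = 1e9)
  expect_lte(sel3, sel1)
  expect_equal(sum(sel0$selected), sum(abs(sel0$diff) > 0))
  expect_false(any(selinf$selected))

  # single-model group warns and borrows sigma
  g3 <- setNames(c("C", rep("A", 7)), paste0("m", 1:8))
  expect_warning(group_specific_bonds(tab, g3), "single model")
})

test_that("replicate reproducibility: zero CV on identical runs, direct formula", {
  occ4 <- matrix(rep(c(0.9, 0.5, 0.2), 4), ncol = 4)
  tab <- synthetic_occurrence_table(occ4, paste0("rep", 1:4))
  rr <- replicate_reproducibility(tab)
  expect_equal(rr$per_bond$cv, rep(0, 3))
  expect_equal(rr$frac_stable, 0)

  # one bond absent in one replicate, 1.0 in the others
  occ <- matrix(c(1, 1, 1, 0), 1, 4)
  tab2 <- synthetic_occurrence_table(occ, paste0("rep", 1:4))
  rr2 <- replicate_reproducibility(tab2)
  v <- c(1, 1, 1, 0)
  expect_equal(rr2$per_bond$cv, sd(v) / mean(v))
  expect_error(replicate_reproducibility(
    synthetic_occurrence_table(matrix(1, 2, 1), "only")), "2 replicates")
})

test_that("reference-bond recovery by class at the 90% cutoff", {
  occ <- matrix(c(0.98, 0.97, 0.96, 0.95, 0.5, 0.5), ncol = 1)
  tab <- synthetic_occurrence_table(occ, "m1")
  ref_all <- data.frame(key = tab$bonds$key[1:4],
                        class = rep("watson_crick", 4))
  got <- compare_to_reference(tab, ref_all)
  expect_equal(unname(got$by_class["watson_crick"]), 1)

  ref_half <- data.frame(key = tab$bonds$key[c(1, 2, 5, 6)],
                         class = rep("main_chain", 4))
  got2 <- compare_to_reference(tab, ref_half)
  expect_equal(unname(got2$by_class["main_chain"]), 0.5)

  bad <- data.frame(key = c(tab$bonds$key[1], "nonsense"),
                    class = c("wc", "wc"))
  expect_warning(got3 <- compare_to_reference(tab, bad), "unresolvable")
  expect_equal(got3$unresolved, "nonsense")
  expect_error(compare_to_reference(tab, data.frame()), "empty")
})
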