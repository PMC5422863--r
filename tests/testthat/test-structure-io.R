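test_that("a one-line ATOM record parses to 1 atom, 1 residue, 1 snapshot", {
  txt <- "ATOM      1  O   HOH W 101      1.000   2.000   3.000  1.00  0.00           O"
  pdb <- read_pdb(txt)
  expect_equal(n_atoms(pdb$topology), 1)
  expect_equal(nrow(pdb$topology$residues), 1)
  expect_equal(n_snapshots(pdb$trajectory), 1)
  expect_equal(unname(snapshot(pdb$trajectory, 1)[1, ]), c(1, 2, 3))
})

test_that("MODEL blocks give one snapshot each; duplicated models are identical", {
  one <- pdb_text(c("N", "CA", "C"), matrix(rnorm(9), 3), resnum = c(1, 1, 1))
  txt <- paste("MODEL        1", one, "ENDMDL",
               "MODEL        2", one, "ENDMDL", sep = "\n")
  pdb <- suppressWarnings(read_pdb(txt))
  expect_equal(n_snapshots(pdb$trajectory), 2)
  expect_equal(snapshot(pdb$trajectory, 1), snapshot(pdb$trajectory, 2))
})

test_that("inconsistent atom counts across models fail naming the model", {
  a <- pdb_text(c("N", "CA"), matrix(0, 2, 3), resnum = c(1, 1))
  b <- pdb_text("N", matrix(0, 1, 3), resnum = 1)
  txt <- paste("MODEL        1", a, "ENDMDL", "MODEL        2", b, "ENDMDL",
               sep = "\n")
  expect_error(suppressWarnings(read_pdb(txt)), "model 2")
})

test_that("unparseable coordinates fail with the line number", {
  txt <- paste(
    "ATOM      1  O   HOH W 101      1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  O   HOH W 102      xx.000   2.000   3.000  1.00  0.00           O",
    sep = "\n")
  expect_error(read_pdb(txt), "line 2")
})

test_that("alt-loc keeps the highest-occupancy conformer, ties go to A", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    sep = "\n")
  pdb <- suppressWarnings(suppressMessages(read_pdb(txt)))
  expect_equal(n_atoms(pdb$topology), 2)
  xyz <- snapshot(pdb$trajectory, 1)
  expect_equal(xyz[pdb$topology$atoms$name == "CA", 1], 9)  # occupancy 0.6 wins
  expect_equal(xyz[pdb$topology$atoms$name == "CB", 1], 1)  # tie -> A
})

test_that("element inference handles primes, digits and two-letter ions", {
  expect_equal(infer_element(c("C1'", "O4'", "N9", "H21", "OE2"),
                             rep("XXX", 5)),
               c("C", "O", "N", "H", "O"))
  expect_equal(infer_element("ZN", "ZN"), "ZN")
})

test_that("classification is total and matches the templates", {
  # water: 1 acceptor O, donor with both hydrogens
  w <- read_pdb(pdb_text(c("O", "H1", "H2"),
                         rbind(c(0, 0, 0), c(0.95, 0, 0), c(-0.24, 0.92, 0)),
                         resname = "HOH", resnum = c(1, 1, 1)))
  expect_equal(w$topology$residues$class, "water")
  expect_equal(nrow(w$topology$donors), 2)   # one per hydrogen
  expect_equal(length(w$topology$acceptors), 1)

  # adenine template content: N6 donor; N1/N3/N7 acceptors
  ai <- which(toy$topology$atoms$resname == "DA")[1]
  res <- toy$topology$atoms$res_index[ai]
  ridx <- which(toy$topology$atoms$res_index == res)
  don_names <- toy$topology$atoms$name[
    intersect(toy$topology$donors$donor, ridx)]
  acc_names <- toy$topology$atoms$name[
    intersect(toy$topology$acceptors, ridx)]
  expect_true("N6" %in% don_names)
  expect_true(all(c("N1", "N3", "N7") %in% acc_names))

  # unknown residue -> other with a warning, no annotations
  expect_warning(
    u <- read_pdb(pdb_text("X1", matrix(0, 1, 3), resname = "XYZ")),
    "other")
  expect_equal(u$topology$residues$class, "other")
  expect_equal(nrow(u$topology$donors), 0)

  # totality on the toy complex
  expect_true(all(toy$topology$residues$class %in%
                    c("protein", "dna", "water", "ion")))
})

test_that("user template tables extend classification", {
  tf <- system.file("extdata", "residue_templates_example.tsv", package = "fpgtraj")
  extra <- read_residue_templates(tf)
  expect_true(all(c("resname", "class", "atom", "role") %in% names(extra)))
  txt <- pdb_text(c("N9", "H9"), rbind(c(0, 0, 0), c(1, 0, 0)),
                  resname = "CFG", resnum = c(5, 5))
  pdb <- suppressWarnings(read_pdb(txt, templates = residue_templates(extra)))
  expect_equal(pdb$topology$residues$class, "dna")
  expect_equal(nrow(pdb$topology$donors), 1)
})

test_that("write/read round-trip reproduces names, numbering and coordinates", {
  txt <- write_pdb(toy$topology, toy_traj)
  rt <- suppressWarnings(read_pdb(paste(txt, collapse = "\n")))
  expect_identical(rt$topology$atoms$name, toy$topology$atoms$name)
  expect_identical(rt$topology$atoms$resnum, toy$topology$atoms$resnum)
  expect_identical(rt$topology$atoms$chain, toy$topology$atoms$chain)
  expect_identical(rt$topology$residues$class, toy$topology$residues$class)
  expect_lt(max(abs(snapshot(rt$trajectory, 1) - toy$coords)), 1e-3)
  # fixed point: a second round trip is exact
  txt2 <- write_pdb(rt$topology, rt$trajectory)
  rt2 <- suppressWarnings(read_pdb(paste(txt2, collapse = "\n")))
  expect_identical(snapshot(rt2$trajectory, 1), snapshot(rt$trajectory, 1))
})

test_that("write_pdb dialect and error cases", {
  one <- write_pdb(toy$topology, new_trajectory(toy$topology, toy$coords))
  expect_false(any(startsWith(one, "MODEL")))   # single snapshot: no MODEL
  two <- write_pdb(toy$topology,
                   new_trajectory(toy$topology,
                                  array(rep(toy$coords, 2),
                                        dim = c(nrow(toy$coords), 3, 2))))
  expect_equal(sum(startsWith(two, "MODEL")), 2)
  big <- toy$coords; big[1, 1] <- 1e5
  expect_error(write_pdb(toy$topology, coords = big), "overflow")
  expect_error(new_trajectory(toy$topology,
                              array(0, dim = c(nrow(toy$coords), 3, 0))))
})

test_that("selection terms, algebra and within-distance behave", {
  top <- toy$topology
  w <- resolve_selection(top, "resname HOH")
  expect_equal(length(w), 3 * sum(top$residues$resname == "HOH"))
  expect_equal(resolve_selection(top, "water"), w)

  # empty numeric range selects nothing
  expect_length(resolve_selection(top, "chain A and resnum 1-0"), 0)

  a <- resolve_selection(top, "protein")
  b <- resolve_selection(top, "elem O")
  expect_equal(resolve_selection(top, "protein or elem O"), sort(union(a, b)))
  expect_equal(resolve_selection(top, "protein and elem O"),
               sort(intersect(a, b)))
  expect_equal(resolve_selection(top, "not protein"),
               setdiff(seq_len(n_atoms(top)), a))

  # within R: boundary by construction on a two-atom system
  two <- suppressWarnings(read_pdb(pdb_text(c("O1", "O2"),
                                            rbind(c(0, 0, 0), c(3.9, 0, 0)),
                                            resname = c("XXA"),
                                            resnum = c(1, 2))))
  expect_length(resolve_selection(two$topology, "within 4.0 of resnum 1",
                                  snapshot(two$trajectory, 1)), 2)
  two2 <- suppressWarnings(read_pdb(pdb_text(c("O1", "O2"),
                                             rbind(c(0, 0, 0), c(4.1, 0, 0)),
                                             resname = c("XXA"),
                                             resnum = c(1, 2))))
  expect_length(resolve_selection(two2$topology, "within 4.0 of resnum 1",
                                  snapshot(two2$trajectory, 1)), 1)

  # within is symmetric to the brute-force pairwise check
  sub <- resolve_selection(top, "resname 8OG")
  ref <- toy$coords[sub, , drop = FALSE]
  bf <- which(apply(toy$coords, 1, function(p)
    min(sqrt(colSums((t(ref) - p)^2))) <= 4))
  expect_equal(resolve_selection(top, "within 4 of resname 8OG", toy$coords), bf)

  expect_error(resolve_selection(top, "within 4 of resname 8OG"), "snapshot")
  expect_error(resolve_selection(top, "resname"), "syntax")
  expect_error(resolve_selection(top, "protein and (dna"), "syntax")
})

test_that("parsing and r.m.s.d. agree with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  tf <- tempfile(fileext = ".pdb")
  write_pdb(toy$topology, toy_traj, file = tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(nrow(ref$atom), n_atoms(toy$topology))
  expect_equal(trimws(ref$atom$elety), toy$topology$atoms$name)
  expect_equal(unname(matrix(ref$xyz, ncol = 3, byrow = TRUE)),
               unname(snapshot(toy_traj, 1)), tolerance = 1e-3)

  # Kabsch r.m.s.d. against bio3d's superposition on a perturbed copy
  set.seed(24)
  a <- matrix(rnorm(90), 30)
  b <- a + rnorm(90, sd = 0.4)
  ours <- superpose_kabsch(a, b)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
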