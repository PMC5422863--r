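#' @title Per-snapshot structural descriptors
#' @description Distances, angles, torsions, glycosidic chi with conformer
#'   classification, Kabsch superposition and r.m.s.d., radius of gyration,
#'   DNA kink angle, propeller twist and base-eversion pseudo-dihedral over
#'   a trajectory.
#' @name geometry-descriptors
NULL

# --- low-level vector math over the snapshot axis -------------------------
# atom coordinates across snapshots as a 3 x n_snap matrix
atom_track <- function(traj, i) {
  x <- traj$coords[i, , , drop = FALSE]
  dim(x) <- c(3, dim(traj$coords)[3])
  x
}

cross3 <- function(u, v) {
  rbind(u[2, ] * v[3, ] - u[3, ] * v[2, ],
        u[3, ] * v[1, ] - u[1, ] * v[3, ],
        u[1, ] * v[2, ] - u[2, ] * v[1, ])
}

vnorm <- function(u) sqrt(colSums(u^2))

#' Distance between two atoms over a trajectory
#' @param traj A `trajectory`.
#' @param atom_a,atom_b Atom indices (see [atom_index()]).
#' @param name Series name.
#' @return `geom_series` in Angstrom.
#' @export
distance_series <- function(traj, atom_a, atom_b, name = "distance") {
  d <- vnorm(atom_track(traj, atom_a) - atom_track(traj, atom_b))
  geom_series(d, name = name, unit = "A")
}

#' Three-point angle over a trajectory
#'
#' Angle a-b-c at vertex b, in `[0, 180]` degrees.
#' @inheritParams distance_series
#' @param atom_c Third atom index (vertex is `atom_b`).
#' @return `geom_series` in degrees.
#' @export
angle_series <- function(traj, atom_a, atom_b, atom_c, name = "angle") {
  u <- atom_track(traj, atom_a) - atom_track(traj, atom_b)
  v <- atom_track(traj, atom_c) - atom_track(traj, atom_b)
  ang <- atan2(vnorm(cross3(u, v)), colSums(u * v)) * 180 / pi
  geom_series(ang, name = name, unit = "degree")
}

#' Torsion (dihedral) angle over a trajectory
#'
#' Signed IUPAC torsion a-b-c-d in `(-180, 180]` degrees: looking along
#' b->c, the angle from the a-b-c plane to the b-c-d plane, clockwise
#' positive.  Snapshots with a degenerate b-c axis (norm < 1e-9) are
#' masked rather than raising an error.
#' @inheritParams angle_series
#' @param atom_d Fourth atom index.
#' @return `geom_series` in degrees with `wrap = TRUE`.
#' @export
torsion_series <- function(traj, atom_a, atom_b, atom_c, atom_d, name = "torsion") {
  pa <- atom_track(traj, atom_a); pb <- atom_track(traj, atom_b)
  pc <- atom_track(traj, atom_c); pd <- atom_track(traj, atom_d)
  tor <- torsion_from_tracks(pa, pb, pc, pd)
  geom_series(tor, name = name, unit = "degree",
              mask = is.finite(tor), wrap = TRUE)
}

torsion_from_tracks <- function(pa, pb, pc, pd) {
  b1 <- pb - pa; b2 <- pc - pb; b3 <- pd - pc
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  m1 <- cross3(n1, sweep(b2, 2, pmax(nb2, .Machine$double.eps), "/"))
  tor <- atan2(colSums(m1 * n2), colSums(n1 * n2)) * 180 / pi
  tor[nb2 < 1e-9] <- NA_real_
  tor[!is.na(tor) & tor <= -180] <- 180
  tor
}

# ring-atom name sets used for chi, propeller twist and eversion centroids
PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

residue_atoms <- function(top, resnum, chain = NULL) {
  hit <- top$atoms$resnum == resnum
  if (!is.null(chain)) hit <- hit & top$atoms$chain == chain
  which(hit)
}

find_in_residue <- function(top, ai, names) {
  for (nm in names) {
    j <- ai[top$atoms$name[ai] == nm]
    if (length(j)) return(j[1])
  }
  NA_integer_
}

#' Glycosidic torsion chi of a nucleotide
#'
#' Computes the torsion about the base-sugar bond: O4'-C1'-N9-C4 for
#' purines, O4'-C1'-N1-C2 for pyrimidines.  For carbacyclic lesion
#' analogs, whose ring carbon replaces O4', alternative names for the
#' isosteric atom can be supplied.
#'
#' @param traj A `trajectory`.
#' @param resnum Residue number of the nucleotide.
#' @param chain Optional chain identifier.
#' @param o4_names Candidate names for the O4'-isosteric atom, tried in
#'   order.
#' @return `geom_series` in degrees (`wrap = TRUE`).
#' @export
glycosidic_chi <- function(traj, resnum, chain = NULL,
                           o4_names = c("O4'", "O4*", "C4X", "C7'")) {
  top <- traj$topology
  ai <- residue_atoms(top, resnum, chain)
  if (length(ai) == 0) stop(sprintf("residue %s not found", resnum))
  o4 <- find_in_residue(top, ai, o4_names)
  c1 <- find_in_residue(top, ai, c("C1'", "C1*"))
  n9 <- find_in_residue(top, ai, "N9")
  if (!is.na(n9)) {
    n_at <- n9
    ref <- find_in_residue(top, ai, "C4")
  } else {
    n_at <- find_in_residue(top, ai, "N1")
    ref <- find_in_residue(top, ai, "C2")
  }
  miss <- c("O4'(iso)", "C1'", "N9/N1", "C4/C2")[is.na(c(o4, c1, n_at, ref))]
  if (length(miss))
    stop(sprintf("residue %s lacks chi-defining atom(s): %s",
                 resnum, paste(miss, collapse = ", ")))
  s <- torsion_series(traj, o4, c1, n_at, ref,
                      name = sprintf("chi(%s)", resnum))
  s
}

#' Conformer domain boundaries for chi classification
#'
#' The primary partition follows the half-open convention
#' `syn = [-90, 90)` degrees with `anti` as the remainder of the circle,
#' matching the field's usage that chi near 0 is syn and chi near 180 (or
#' -120) is anti.  Two border sub-ranges are reported alongside the
#' primary label: `high_anti = (-90, -30]` and `high_syn = (60, 120]`,
#' the loosely-defined transition vocabulary used when a structure
#' straddles the syn/anti border.  All boundaries are configurable.
#'
#' @param syn Length-2 numeric, `[lo, hi)` of the syn domain in degrees.
#' @param high_anti,high_syn Length-2 numeric sub-range boundaries
#'   (`(lo, hi]`).
#' @return A `conformer_domains` list.
#' @export
conformer_domains <- function(syn = c(-90, 90),
                              high_anti = c(-90, -30),
                              high_syn = c(60, 120)) {
  structure(list(syn = syn, high_anti = high_anti, high_syn = high_syn),
            class = "conformer_domains")
}

#' Classify chi values into syn/anti conformer domains
#'
#' @param chi Numeric chi values in degrees (or a `geom_series`).
#' @param domains A [conformer_domains()] object.
#' @param sub_labels If `TRUE`, return the border sub-label
#'   (`"high_syn"`/`"high_anti"`) where applicable and `NA` elsewhere,
#'   instead of the primary label.
#' @return Character vector of labels (`"syn"`/`"anti"`, or sub-labels).
#' @export
classify_chi <- function(chi, domains = conformer_domains(), sub_labels = FALSE) {
  chi <- series_values(chi)
  x <- ((chi + 180) %% 360) - 180  # wrap into (-180, 180]
  x[x <= -180] <- 180
  if (sub_labels) {
    out <- rep(NA_character_, length(x))
    out[x > domains$high_anti[1] & x <= domains$high_anti[2]] <- "high_anti"
    out[x > domains$high_syn[1] & x <= domains$high_syn[2]] <- "high_syn"
    return(out)
  }
  ifelse(is.na(x), NA_character_,
         ifelse(x >= domains$syn[1] & x < domains$syn[2], "syn", "anti"))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` via singular
#' value decomposition of the weighted covariance, with the determinant
#' correction guaranteeing a proper rotation.
#'
#' @param reference,mobile `n x 3` coordinate matrices (equal n, n >= 3,
#'   not collinear).
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3;
#'   the fitted mobile is `mobile %*% rotation + translation`), and
#'   `rmsd` (weighted, Angstrom).
#' @export
superpose_kabsch <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n != nrow(mobile)) stop("coordinate sets differ in length")
  if (n < 3) stop("need at least 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cr <- colSums(reference * w); cm <- colSums(mobile * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("rank-deficient (collinear) coordinates: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = cr - cm %*% R, rmsd = rmsd)
}

resolve_sel_arg <- function(traj, sel, snapshot_coords = NULL) {
  if (is.character(sel))
    resolve_selection(traj$topology, sel,
                      context_snapshot = if (is.null(snapshot_coords))
                        snapshot(traj, 1) else snapshot_coords)
  else as.integer(sel)
}

#' Per-snapshot r.m.s.d. after superposition
#'
#' For each snapshot: superpose on `fit_selection` against the reference,
#' then report the r.m.s.d. over `measure_selection` under that fit.  The
#' conventional backbone r.m.s.d. trace uses the same selection for both.
#'
#' @param traj A `trajectory`.
#' @param reference Reference coordinates: a snapshot index into `traj` or
#'   an `n_atoms x 3` matrix.
#' @param fit_selection,measure_selection Selection strings or atom index
#'   vectors; `measure_selection` defaults to `fit_selection`.
#' @return `geom_series` in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1, fit_selection = "all",
                        measure_selection = NULL) {
  ref <- if (is.matrix(reference)) reference else snapshot(traj, reference)
  fit <- resolve_sel_arg(traj, fit_selection, ref)
  mea <- if (is.null(measure_selection)) fit
         else resolve_sel_arg(traj, measure_selection, ref)
  if (length(fit) == 0 || length(mea) == 0) stop("empty selection")
  ns <- n_snapshots(traj)
  out <- numeric(ns)
  for (m in seq_len(ns)) {
    xyz <- traj$coords[, , m]
    k <- superpose_kabsch(ref[fit, , drop = FALSE], xyz[fit, , drop = FALSE])
    fitted <- sweep(xyz[mea, , drop = FALSE] %*% k$rotation, 2,
                    -as.numeric(k$translation), "-")
    out[m] <- sqrt(mean(rowSums((fitted - ref[mea, , drop = FALSE])^2)))
  }
  geom_series(out, name = "rmsd", unit = "A")
}

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                  S = 32.06, ZN = 65.38, NA. = 22.99, MG = 24.305, CL = 35.45,
                  K = 39.098, FE = 55.845, MN = 54.938, CA = 40.078)

element_mass <- function(elem) {
  m <- ELEMENT_MASS[toupper(elem)]
  m[toupper(elem) == "NA"] <- 22.99
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Radius of gyration over a trajectory
#'
#' `sqrt(sum(w_i * |r_i - rbar|^2) / sum(w_i))`, optionally mass-weighted.
#' @param traj A `trajectory`.
#' @param selection Selection string or atom indices (default all atoms).
#' @param mass_weighted Use atomic masses as weights.
#' @return `geom_series` in Angstrom.
#' @export
radius_of_gyration <- function(traj, selection = "all", mass_weighted = FALSE) {
  sel <- resolve_sel_arg(traj, selection)
  if (length(sel) == 0) stop("empty selection")
  w <- if (mass_weighted) element_mass(traj$topology$atoms$elem[sel])
       else rep(1, length(sel))
  w <- w / sum(w)
  ns <- n_snapshots(traj)
  out <- numeric(ns)
  for (m in seq_len(ns)) {
    xyz <- traj$coords[sel, , m, drop = FALSE]
    dim(xyz) <- c(length(sel), 3)
    ctr <- colSums(xyz * w)
    out[m] <- sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
  }
  geom_series(out, name = "radius_of_gyration", unit = "A")
}

principal_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(axis = sv$v[, 1], spread = sv$d[1], center = ctr)
}

#' DNA kink angle from two phosphate arms
#'
#' Fits a principal axis through the P atoms of each helix arm, orients
#' each axis along its arm's 5'->3' atom order, and reports the angular
#' deviation from a straight axis: collinear, consistently oriented arms
#' give 0 degrees; a sharply bent glycosylase-bound duplex gives values
#' around 55-65 degrees.  The arm definition (which phosphates belong to
#' which arm) is the caller's: kink values are comparable only within one
#' arm convention.
#'
#' @param traj A `trajectory`.
#' @param arm1_selection,arm2_selection Selections of >= 3 P atoms each,
#'   ordered 5'->3' when given as index vectors (selection strings resolve
#'   in file order).
#' @return `geom_series` in degrees; degenerate arms give masked values.
#' @export
dna_kink_angle <- function(traj, arm1_selection, arm2_selection) {
  a1 <- resolve_sel_arg(traj, arm1_selection)
  a2 <- resolve_sel_arg(traj, arm2_selection)
  if (length(a1) < 3 || length(a2) < 3)
    stop("each arm needs at least 3 P atoms")
  ns <- n_snapshots(traj)
  out <- rep(NA_real_, ns)
  for (m in seq_len(ns)) {
    x1 <- traj$coords[a1, , m]; x2 <- traj$coords[a2, , m]
    p1 <- principal_axis(x1); p2 <- principal_axis(x2)
    if (p1$spread < 1e-9 || p2$spread < 1e-9) next
    v1 <- p1$axis; v2 <- p2$axis
    # orient along the arm's atom order (5'->3')
    if (sum((x1[nrow(x1), ] - x1[1, ]) * v1) < 0) v1 <- -v1
    if (sum((x2[nrow(x2), ] - x2[1, ]) * v2) < 0) v2 <- -v2
    out[m] <- acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
  }
  geom_series(out, name = "dna_kink", unit = "degree", mask = is.finite(out))
}

base_ring_indices <- function(top, resnum, chain = NULL) {
  ai <- residue_atoms(top, resnum, chain)
  if (length(ai) == 0) stop(sprintf("residue %s not found", resnum))
  is_purine <- any(top$atoms$name[ai] == "N9")
  ring <- if (is_purine) PURINE_RING else PYRIMIDINE_RING
  idx <- ai[top$atoms$name[ai] %in% ring]
  if (length(idx) < 3)
    stop(sprintf("residue %s: unrecognized base ring atoms", resnum))
  list(idx = idx, purine = is_purine, ai = ai)
}

#' Propeller twist of a base pair
#'
#' The counter-rotation omega of the two bases of a pair about the pair's
#' long axis.  Base normals are normals of the least-squares plane
#' through the ring atoms (oriented consistently); the long axis is the
#' C8(purine) -> C6(pyrimidine) direction for purine-pyrimidine pairs,
#' falling back to the centroid-centroid direction otherwise.  The sign
#' convention makes canonical B-DNA constructions with the usual
#' propeller come out positive around +13 degrees; absolute signs are
#' convention-relative across programs.
#'
#' @param traj A `trajectory`.
#' @param base_pair Length-2 list/vector of residue numbers (optionally
#'   `list(c(resnum, chain), c(resnum, chain))`).
#' @return `geom_series` in degrees (signed, `wrap = TRUE`).
#' @export
propeller_twist <- function(traj, base_pair) {
  top <- traj$topology
  getres <- function(b) {
    if (length(b) == 2) base_ring_indices(top, as.integer(b[1]), b[2])
    else base_ring_indices(top, as.integer(b))
  }
  b1 <- getres(base_pair[[1]]); b2 <- getres(base_pair[[2]])
  ns <- n_snapshots(traj)
  out <- numeric(ns)
  # long-axis anchors
  lax <- function(bp, bq, xyz) {
    if (bp$purine && !bq$purine) {
      c8 <- find_in_residue(top, bp$ai, "C8"); c6 <- find_in_residue(top, bq$ai, "C6")
      if (!is.na(c8) && !is.na(c6)) return(xyz[c6, ] - xyz[c8, ])
    }
    colMeans(xyz[bq$idx, , drop = FALSE]) - colMeans(xyz[bp$idx, , drop = FALSE])
  }
  plane_normal <- function(xyz, idx) {
    sv <- svd(sweep(xyz[idx, , drop = FALSE], 2, colMeans(xyz[idx, , drop = FALSE])))
    sv$v[, 3]
  }
  for (m in seq_len(ns)) {
    xyz <- traj$coords[, , m]
    n1 <- plane_normal(xyz, b1$idx); n2 <- plane_normal(xyz, b2$idx)
    if (sum(n1 * n2) < 0) n2 <- -n2
    L <- lax(b1, b2, xyz); L <- L / sqrt(sum(L^2))
    # fix the global normal orientation relative to the long axis so the
    # sign is reproducible: n1 chosen with positive component along L x n1ref
    refz <- n1 + n2
    if (sum(cross3(matrix(L), matrix(refz))^2) < 1e-12) { out[m] <- 0; next }
    p1 <- n1 - sum(n1 * L) * L; p2 <- n2 - sum(n2 * L) * L
    # sign fixed so the canonical B-DNA propeller sense comes out positive
    out[m] <- -atan2(sum(cross3(matrix(p1), matrix(p2)) * L), sum(p1 * p2)) * 180 / pi
  }
  geom_series(out, name = "propeller_twist", unit = "degree", wrap = TRUE)
}

#' Base-eversion pseudo-dihedral of a lesion nucleotide
#'
#' Pseudo-torsion over four reference points that tracks how far a
#' damaged nucleotide has flipped out of the helix into the enzyme's
#' pocket.  Default points: the lesion base-ring centroid, C1' of the
#' lesion, P of the lesion, and P of the 3' neighbour.  Values are
#' comparable only within one point definition; fully everted
#' glycosylase-bound lesions typically measure far from the intrahelical
#' value.
#'
#' @param traj A `trajectory`.
#' @param resnum Lesion residue number.
#' @param chain Optional chain.
#' @param points Optional list of 4 atom-index vectors overriding the
#'   default definition (each point is the centroid of its indices).
#' @return `geom_series` in degrees (`wrap = TRUE`).
#' @export
eversion_angle <- function(traj, resnum, chain = NULL, points = NULL) {
  top <- traj$topology
  if (is.null(points)) {
    b <- base_ring_indices(top, resnum, chain)
    c1 <- find_in_residue(top, b$ai, c("C1'", "C1*"))
    p0 <- find_in_residue(top, b$ai, "P")
    ai3 <- residue_atoms(top, resnum + 1, chain)
    p3 <- if (length(ai3)) find_in_residue(top, ai3, "P") else NA_integer_
    if (is.na(c1) || is.na(p0) || is.na(p3))
      stop(sprintf("residue %s: missing eversion reference atoms (C1'/P/3'-P)", resnum))
    points <- list(b$idx, c1, p0, p3)
  }
  if (length(points) != 4) stop("eversion definition needs exactly 4 points")
  tracks <- lapply(points, function(idx) {
    if (length(idx) == 1) atom_track(traj, idx)
    else {
      x <- traj$coords[idx, , , drop = FALSE]
      apply(x, c(2, 3), mean)
    }
  })
  tor <- torsion_from_tracks(tracks[[1]], tracks[[2]], tracks[[3]], tracks[[4]])
  geom_series(tor, name = "eversion", unit = "degree",
              mask = is.finite(tor), wrap = TRUE)
}
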