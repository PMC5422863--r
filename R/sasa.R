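#' @title Solvent accessible surface area
#' @description Shrake-Rupley numerical SASA with a deterministic
#'   golden-spiral sphere point set, plus the derived water-burial and
#'   occluded-contact-area descriptors.
#' @name sasa-descriptors
NULL

# Bondi-type van der Waals radii (Angstrom); unmatched elements fall back
# to 1.7.  The same table ships as plain text under inst/extdata.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               ZN = 1.39, MG = 1.73, CL = 1.75, K = 2.75, F = 1.47,
               BR = 1.85, FE = 1.50, MN = 1.50, CA = 2.31)

#' Van der Waals radii for a vector of element symbols
#' @param elem Character vector of element symbols.
#' @param table Named radius table; defaults to the bundled Bondi set.
#' @return Numeric radii in Angstrom.
#' @export
vdw_radii <- function(elem, table = VDW_RADII) {
  r <- table[toupper(elem)]
  r[toupper(elem) == "NA"] <- 2.27
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read a van der Waals radius table from plain text
#'
#' Two whitespace-separated columns: element symbol, radius in Angstrom;
#' `#` comments allowed.
#' @param path File path.
#' @return Named numeric vector usable as the `table` of [vdw_radii()].
#' @export
read_vdw_radii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                  vapply(parts, `[`, "", 1))
}

# deterministic unit-sphere point set (golden-section spiral; no RNG)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Numerical SASA of the `selection` atoms with all atoms of
#' `selection` and `context_selection` acting as occluders.  Each atom's
#' sphere of radius `r_vdw + probe` is sampled at `n_points` deterministic
#' golden-spiral points; the accessible fraction times the sphere area
#' gives the per-atom SASA.
#'
#' @param coords `n_atoms x 3` coordinate matrix.
#' @param radii Per-atom van der Waals radii (Angstrom), length
#'   `nrow(coords)`.
#' @param selection Atom indices whose areas are wanted (default: all).
#' @param context_selection Additional occluding atoms (default: none
#'   beyond `selection`).
#' @param probe Probe radius, Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom (>= 96; default 960).
#' @return Numeric vector of per-atom areas (Angstrom^2), one per
#'   `selection` atom.
#' @export
sasa <- function(coords, radii, selection = seq_len(nrow(coords)),
                 context_selection = integer(0), probe = 1.4, n_points = 960) {
  if (probe < 0) stop("probe radius must be >= 0")
  if (n_points < 96) stop("n_points must be >= 96")
  if (any(radii <= 0)) stop("non-positive van der Waals radius")
  selection <- as.integer(selection)
  occl <- sort(unique(c(selection, as.integer(context_selection))))
  pts <- sphere_points(n_points)
  oc_xyz <- coords[occl, , drop = FALSE]
  oc_r <- radii[occl] + probe
  out <- numeric(length(selection))
  for (k in seq_along(selection)) {
    i <- selection[k]
    ri <- radii[i] + probe
    ci <- coords[i, ]
    # occluders that can reach this atom's expanded sphere
    d2 <- rowSums(sweep(oc_xyz, 2, ci)^2)
    nb <- which(d2 < (ri + oc_r)^2 & occl != i)
    if (length(nb) == 0) {
      out[k] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2, ci, "+")
    # point accessible iff outside every neighbour's expanded sphere
    acc <- rep(TRUE, n_points)
    nxyz <- oc_xyz[nb, , drop = FALSE]
    nr2 <- oc_r[nb]^2
    ord <- order(d2[nb])  # closest neighbours prune fastest
    for (j in ord) {
      if (!any(acc)) break
      dd <- sweep(sp[acc, , drop = FALSE], 2, nxyz[j, ])
      acc[acc] <- rowSums(dd^2) >= nr2[j]
    }
    out[k] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  out
}

topology_radii <- function(top, table = VDW_RADII) vdw_radii(top$atoms$elem, table)

#' Solvent-exposure fraction of a water molecule over a trajectory
#'
#' Exposure = SASA(water within the full complex) / SASA(isolated water);
#' a water is conventionally called buried when its exposure is below
#' 0.10.
#'
#' @param traj A `trajectory`.
#' @param resnum Water residue number.
#' @param chain Optional chain.
#' @param probe Probe radius (default 1.4).
#' @param n_points Sphere points per atom.
#' @return `geom_series` of dimensionless fractions in `[0, 1]`.
#' @export
water_burial <- function(traj, resnum, chain = NULL, probe = 1.4, n_points = 960) {
  top <- traj$topology
  wat <- residue_atoms(top, resnum, chain)
  if (length(wat) == 0) stop(sprintf("water residue %s not found", resnum))
  if (!any(top$atoms$elem[wat] == "O"))
    stop(sprintf("residue %s has no O atom", resnum))
  radii <- topology_radii(top)
  rest <- setdiff(seq_len(n_atoms(top)), wat)
  ns <- n_snapshots(traj)
  out <- numeric(ns)
  for (m in seq_len(ns)) {
    xyz <- traj$coords[, , m]
    a_ctx <- sum(sasa(xyz, radii, selection = wat, context_selection = rest,
                      probe = probe, n_points = n_points))
    a_iso <- sum(sasa(xyz, radii, selection = wat, probe = probe,
                      n_points = n_points))
    out[m] <- a_ctx / a_iso
  }
  geom_series(out, name = sprintf("exposure(%s)", resnum), unit = "dimensionless")
}

#' Occluded contact area between two atom groups
#'
#' Area mutually inaccessible to the probe:
#' `([SASA(A alone) - SASA(A in A+B)] + [SASA(B alone) - SASA(B in A+B)]) / 2`,
#' computed with only the two groups present.  A standard measure of
#' stacking/packing contact, e.g. between an intercalated aromatic side
#' chain and the adjacent base.
#'
#' @param traj A `trajectory`.
#' @param group_a,group_b Disjoint, non-empty selections (strings or
#'   index vectors).
#' @param probe Probe radius (default 1.4).
#' @param n_points Sphere points per atom.
#' @return `geom_series` in Angstrom^2 (non-negative up to quadrature
#'   error, clamped at 0).
#' @export
occluded_area <- function(traj, group_a, group_b, probe = 1.4, n_points = 960) {
  ga <- resolve_sel_arg(traj, group_a)
  gb <- resolve_sel_arg(traj, group_b)
  if (length(ga) == 0 || length(gb) == 0) stop("groups must be non-empty")
  if (length(intersect(ga, gb)) > 0) stop("groups overlap")
  radii <- topology_radii(traj$topology)
  ns <- n_snapshots(traj)
  out <- numeric(ns)
  for (m in seq_len(ns)) {
    xyz <- traj$coords[, , m]
    a_alone <- sum(sasa(xyz, radii, ga, probe = probe, n_points = n_points))
    b_alone <- sum(sasa(xyz, radii, gb, probe = probe, n_points = n_points))
    a_ab <- sum(sasa(xyz, radii, ga, context_selection = gb,
                     probe = probe, n_points = n_points))
    b_ab <- sum(sasa(xyz, radii, gb, context_selection = ga,
                     probe = probe, n_points = n_points))
    out[m] <- max(0, ((a_alone - a_ab) + (b_alone - b_ab)) / 2)
  }
  geom_series(out, name = "occluded_area", unit = "A^2")
}
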