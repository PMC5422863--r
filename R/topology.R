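#' @title Topology and trajectory containers
#' @description Internal constructors and validators for the two core
#'   containers of the package: a `topology` (atoms, residues, residue
#'   classes, hydrogen-bond donor/acceptor annotations) and a `trajectory`
#'   (an ordered ensemble of coordinate snapshots over one topology).
#' @name topology-containers
NULL

RESIDUE_CLASSES <- c("protein", "dna", "water", "ion", "other")

new_topology <- function(atoms, residues, donors = NULL, acceptors = integer()) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  if (is.null(donors)) {
    donors <- data.frame(donor = integer(), hydrogen = integer())
  }
  x <- list(atoms = atoms, residues = residues,
            donors = donors, acceptors = as.integer(acceptors))
  class(x) <- "topology"
  validate_topology(x)
  x
}

validate_topology <- function(top) {
  a <- top$atoms
  r <- top$residues
  need_a <- c("serial", "name", "elem", "alt", "resname", "resnum", "chain", "res_index")
  if (!all(need_a %in% names(a)))
    stop("topology atoms table missing columns: ",
         paste(setdiff(need_a, names(a)), collapse = ", "))
  need_r <- c("res_index", "resname", "resnum", "chain", "class", "first", "last")
  if (!all(need_r %in% names(r)))
    stop("topology residues table missing columns: ",
         paste(setdiff(need_r, names(r)), collapse = ", "))
  if (nrow(a) > 0 && anyNA(a$res_index))
    stop("every atom must belong to exactly one residue")
  if (!all(r$class %in% RESIDUE_CLASSES))
    stop("unknown residue class: ",
         paste(unique(setdiff(r$class, RESIDUE_CLASSES)), collapse = ", "))
  invisible(top)
}

#' Number of atoms in a topology
#' @param top A `topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' @export
print.topology <- function(x, ...) {
  cls <- table(factor(x$residues$class, levels = RESIDUE_CLASSES))
  cat(sprintf("<topology> %d atoms, %d residues (%s)\n",
              nrow(x$atoms), nrow(x$residues),
              paste(sprintf("%s: %d", names(cls), as.integer(cls)), collapse = ", ")))
  cat(sprintf("  donors: %d  acceptors: %d\n", nrow(x$donors), length(x$acceptors)))
  invisible(x)
}

#' Construct a trajectory
#'
#' Bundles a topology with an ordered set of coordinate snapshots.
#'
#' @param topology A `topology`.
#' @param coords Numeric array `n_atoms x 3 x n_snapshots`, or a list of
#'   `n_atoms x 3` matrices, or a single matrix (one snapshot). Angstrom.
#' @param dt_ps Snapshot spacing in picoseconds (default 2, the cadence at
#'   which production MD frames are typically saved).
#' @param label Model identifier, e.g. a protonation-state x opposite-base
#'   tag such as `"PRO-GLH-C"`.
#' @return A `trajectory` object.
#' @export
new_trajectory <- function(topology, coords, dt_ps = 2, label = "model") {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  if (is.matrix(coords))
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[3] < 1) stop("trajectory must contain at least one snapshot")
  if (dim(coords)[1] != n_atoms(topology))
    stop(sprintf("snapshot atom count (%d) does not match topology (%d)",
                 dim(coords)[1], n_atoms(topology)))
  if (!is.numeric(dt_ps) || dt_ps <= 0) stop("dt_ps must be > 0")
  if (any(!is.finite(coords))) stop("trajectory coordinates must be finite")
  x <- list(topology = topology, coords = coords,
            dt_ps = dt_ps, label = label)
  class(x) <- "trajectory"
  x
}

#' Number of snapshots in a trajectory
#' @param traj A `trajectory`.
#' @return Integer snapshot count.
#' @export
n_snapshots <- function(traj) dim(traj$coords)[3]

#' Extract one snapshot as a coordinate matrix
#' @param traj A `trajectory`.
#' @param i Snapshot index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
snapshot <- function(traj, i) {
  x <- traj$coords[, , i, drop = FALSE]
  dim(x) <- dim(traj$coords)[1:2]
  x
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> '%s': %d snapshots x %d atoms, dt = %g ps (%g ps total)\n",
              x$label, n_snapshots(x), n_atoms(x$topology), x$dt_ps,
              x$dt_ps * n_snapshots(x)))
  invisible(x)
}

# Locate one atom index by residue number (+ optional chain) and atom name.
# Used throughout to resolve named atoms like N[Pro1] or C1'[oxoG].
#' Find an atom index
#' @param top A `topology`.
#' @param resnum Residue number as in the file.
#' @param name Atom name (PDB convention, e.g. `"C1'"`).
#' @param chain Optional chain identifier.
#' @return Single integer atom index; error if absent or ambiguous.
#' @export
atom_index <- function(top, resnum, name, chain = NULL) {
  a <- top$atoms
  hit <- a$resnum == resnum & a$name == name
  if (!is.null(chain)) hit <- hit & a$chain == chain
  idx <- which(hit)
  if (length(idx) == 0)
    stop(sprintf("atom %s of residue %s not found", name, resnum))
  if (length(idx) > 1)
    stop(sprintf("atom %s of residue %s is ambiguous; give a chain", name, resnum))
  idx
}
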