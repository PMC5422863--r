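#' Read a single- or multi-model PDB file
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL records into a validated topology plus
#' trajectory (one snapshot per MODEL block; a single snapshot when the file
#' has no MODEL records).  Waters and ions are retained.  Alternate
#' locations are resolved by keeping the highest-occupancy conformer (ties
#' broken in favour of alt-loc 'A'); discarded records are reported via a
#' message.  Blank element fields are inferred from the atom-name column
#' following PDB v3 conventions.
#'
#' @param source Path to a PDB file, or a character scalar/vector of PDB
#'   text lines.
#' @param dt_ps Snapshot spacing to stamp on the returned trajectory (ps).
#' @param label Model label for the trajectory.
#' @param classify If `TRUE` (default) run [classify_residues()] on the
#'   parsed topology before returning.
#' @param templates Residue template table passed on to
#'   [classify_residues()].
#' @return A list with elements `topology` and `trajectory`.
#' @examples
#' txt <- "ATOM      1  O   HOH A   1       0.000   0.000   0.000           O"
#' pdb <- read_pdb(txt)
#' n_atoms(pdb$topology)
#' @export
read_pdb <- function(source, dt_ps = 2, label = "model",
                     classify = TRUE, templates = residue_templates()) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source))
    readLines(source, warn = FALSE)
  else unlist(strsplit(source, "\n", fixed = TRUE))

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  # assign each atom line to a model block
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[!is_atom] <- NA
  atom_lines <- which(is_atom)
  blocks <- split(atom_lines, model_id[atom_lines])

  parse_block <- function(lns) {
    txt <- lines[lns]
    fw <- function(a, b) trimws(substr(txt, a, b))
    x <- suppressWarnings(as.numeric(substr(txt, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(txt, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(txt, 47, 54)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad))
      stop(sprintf("unparseable coordinate field at line %d: '%s'",
                   lns[bad[1]], substr(lines[lns[bad[1]]], 1, 54)))
    occ <- suppressWarnings(as.numeric(substr(txt, 55, 60)))
    occ[!is.finite(occ)] <- 1
    data.frame(
      line = lns,
      serial = suppressWarnings(as.integer(fw(7, 11))),
      name = fw(13, 16),
      alt = substr(txt, 17, 17),
      resname = fw(18, 21),
      chain = substr(txt, 22, 22),
      resnum = suppressWarnings(as.integer(fw(23, 26))),
      x = x, y = y, z = z, occ = occ,
      elem = fw(77, 78),
      stringsAsFactors = FALSE
    )
  }

  resolve_altloc <- function(df) {
    if (all(df$alt %in% c(" ", ""))) return(df)
    key <- paste(df$chain, df$resnum, df$resname, df$name, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(ii) {
      if (length(ii) == 1) return(ii)
      sub <- df[ii, ]
      best <- ii[order(-sub$occ, sub$alt != "A", sub$alt)][1]
      best
    }), use.names = FALSE)
    keep <- sort(keep)
    dropped <- nrow(df) - length(keep)
    if (dropped > 0)
      message(sprintf("read_pdb: discarded %d alternate-location record(s)", dropped))
    df[keep, ]
  }

  parsed <- lapply(blocks, parse_block)
  parsed <- lapply(parsed, resolve_altloc)

  n0 <- nrow(parsed[[1]])
  for (m in seq_along(parsed)) {
    if (nrow(parsed[[m]]) != n0)
      stop(sprintf("inconsistent atom count across models: model %d has %d atoms, model 1 has %d",
                   m, nrow(parsed[[m]]), n0))
  }

  ref <- parsed[[1]]
  elem <- ifelse(ref$elem == "", infer_element(ref$name, ref$resname), ref$elem)
  # residues: contiguous runs of (chain, resnum, resname)
  rkey <- paste(ref$chain, ref$resnum, ref$resname, sep = "\r")
  res_index <- cumsum(c(TRUE, rkey[-1] != rkey[-length(rkey)]))
  atoms <- data.frame(
    serial = ref$serial, name = ref$name, elem = elem,
    alt = ifelse(ref$alt == " ", "", ref$alt),
    resname = ref$resname, resnum = ref$resnum, chain = ref$chain,
    res_index = res_index, stringsAsFactors = FALSE
  )
  first <- which(!duplicated(res_index))
  residues <- data.frame(
    res_index = res_index[first],
    resname = ref$resname[first], resnum = ref$resnum[first],
    chain = ref$chain[first], class = "other",
    first = first,
    last = c(first[-1] - 1L, nrow(ref)),
    stringsAsFactors = FALSE
  )
  top <- new_topology(atoms, residues)

  coords <- array(NA_real_, dim = c(n0, 3, length(parsed)))
  for (m in seq_along(parsed))
    coords[, , m] <- as.matrix(parsed[[m]][, c("x", "y", "z")])
  traj <- new_trajectory(top, coords, dt_ps = dt_ps, label = label)
  if (classify) {
    top <- classify_residues(top, templates = templates,
                             reference_coords = coords[, , 1])
    traj$topology <- top
  }
  list(topology = top, trajectory = traj)
}

# PDB v3 element inference from the atom-name columns.  Two-letter ions are
# recognised from common monatomic residue names; otherwise the first
# alphabetic character wins, with names starting in column 13 by a digit
# (e.g. 1H5') read as hydrogens of the following letter.
infer_element <- function(name, resname) {
  two_letter <- c("ZN", "MG", "NA", "CL", "MN", "FE", "CA", "K", "BR", "CU", "NI", "CO")
  out <- character(length(name))
  for (i in seq_along(name)) {
    nm <- name[i]
    if (toupper(resname[i]) %in% two_letter && toupper(nm) %in% two_letter) {
      out[i] <- toupper(nm)
      next
    }
    stripped <- gsub("[^A-Za-z]", "", nm)
    if (nchar(stripped) == 0) stop("cannot infer element for atom name '", nm, "'")
    ch <- toupper(substr(stripped, 1, 1))
    # digit-led names (1H5') and names like HB2 are hydrogens
    if (grepl("^[0-9]", nm)) ch <- toupper(substr(stripped, 1, 1))
    out[i] <- ch
  }
  out
}

#' Write a topology + trajectory as (multi-model) PDB text
#'
#' Inverse of [read_pdb()] up to 3-decimal coordinate quantisation: reading
#' the written text back reproduces atom names, residue numbering and
#' coordinates.  A single-snapshot trajectory is written without MODEL
#' records; multi-snapshot trajectories wrap each snapshot in
#' MODEL/ENDMDL.
#'
#' @param topology A `topology`.
#' @param trajectory A `trajectory` over `topology` (or `NULL` to use a
#'   bare coordinate matrix via `coords`).
#' @param file Output path, or `NULL` to return the text invisibly.
#' @param coords Optional `n_atoms x 3` matrix used when `trajectory` is
#'   `NULL`.
#' @return Character vector of PDB lines (invisibly when `file` given).
#' @export
write_pdb <- function(topology, trajectory = NULL, file = NULL, coords = NULL) {
  if (is.null(trajectory)) {
    if (is.null(coords)) stop("either trajectory or coords must be given")
    trajectory <- new_trajectory(topology, coords)
  }
  ns <- n_snapshots(trajectory)
  if (ns < 1) stop("empty trajectory")
  a <- topology$atoms
  fmt_atom <- function(xyz) {
    if (any(xyz >= 10000 | xyz <= -1000))
      stop("coordinates overflow PDB fixed columns")
    nm <- a$name
    # atom-name column convention: 1-3 char names start at column 14
    nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    sprintf("ATOM  %5d %4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$serial %% 100000, nm4,
            ifelse(a$alt == "", " ", a$alt),
            a$resname, a$chain, a$resnum,
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$elem)
  }
  out <- character(0)
  if (ns == 1) {
    out <- fmt_atom(snapshot(trajectory, 1))
  } else {
    for (m in seq_len(ns)) {
      out <- c(out, sprintf("MODEL %8d", m),
               fmt_atom(snapshot(trajectory, m)), "ENDMDL")
    }
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
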