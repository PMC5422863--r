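#' Residue template table
#'
#' Per-residue-name templates assigning a residue class and listing the
#' hydrogen-bond donor heavy atoms (with the names of their attached
#' hydrogens) and acceptor heavy atoms.  The defaults cover the 20
#' standard amino acids, DNA nucleotides (modern DA/DC/DG/DT and legacy
#' one-letter names), 8-oxoguanine (`8OG`, an oxidised guanine lesion
#' whose N7 carries a hydrogen and whose C8 carries the diagnostic
#' exocyclic O8 acceptor), the protonated-glutamate variant `GLH`, water
#' (`HOH`/`WAT`) and common monatomic ions.  Users can extend the table
#' for modified residues via [read_residue_templates()] or by rbinding
#' rows of the same shape.
#'
#' @param extra Optional data frame of additional template rows (same
#'   columns) appended to the defaults; later rows win on conflict.
#' @return A data frame with columns `resname`, `class`, `atom`, `role`
#'   (`"donor"`, `"acceptor"` or `"both"`) and `hydrogens`
#'   (comma-separated hydrogen names, donors only; a name is matched as a
#'   prefix so `HG` covers `HG1`).
#' @export
residue_templates <- function(extra = NULL) {
  tpl <- function(resname, class, atom, role, hydrogens = "") {
    data.frame(resname = resname, class = class, atom = atom, role = role,
               hydrogens = hydrogens, stringsAsFactors = FALSE)
  }
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "GLH")
  rows <- list()
  for (r in aa) {
    # backbone: amide N donates (except proline), carbonyl O accepts
    if (!r %in% c("PRO"))
      rows[[length(rows) + 1]] <- tpl(r, "protein", "N", "donor", "H,HN,H1,H2,H3,HT")
    else
      # N-terminal (secondary amine) proline can carry H2/H3 when protonated
      rows[[length(rows) + 1]] <- tpl(r, "protein", "N", "donor", "H2,H3,HT")
    rows[[length(rows) + 1]] <- tpl(r, "protein", "O", "acceptor")
    rows[[length(rows) + 1]] <- tpl(r, "protein", "OXT", "acceptor")
    sidechain <- switch(r,
      ARG = rbind(tpl(r, "protein", "NE", "donor", "HE"),
                  tpl(r, "protein", "NH1", "donor", "HH1"),
                  tpl(r, "protein", "NH2", "donor", "HH2")),
      ASN = rbind(tpl(r, "protein", "ND2", "donor", "HD2"),
                  tpl(r, "protein", "OD1", "acceptor")),
      ASP = rbind(tpl(r, "protein", "OD1", "acceptor"),
                  tpl(r, "protein", "OD2", "acceptor")),
      CYS = tpl(r, "protein", "SG", "both", "HG"),
      GLN = rbind(tpl(r, "protein", "NE2", "donor", "HE2"),
                  tpl(r, "protein", "OE1", "acceptor")),
      GLU = rbind(tpl(r, "protein", "OE1", "acceptor"),
                  tpl(r, "protein", "OE2", "acceptor")),
      GLH = rbind(tpl(r, "protein", "OE1", "acceptor"),
                  tpl(r, "protein", "OE2", "both", "HE2")),
      HIS = rbind(tpl(r, "protein", "ND1", "both", "HD1"),
                  tpl(r, "protein", "NE2", "both", "HE2")),
      LYS = tpl(r, "protein", "NZ", "donor", "HZ"),
      SER = tpl(r, "protein", "OG", "both", "HG"),
      THR = tpl(r, "protein", "OG1", "both", "HG1"),
      TRP = tpl(r, "protein", "NE1", "donor", "HE1"),
      TYR = tpl(r, "protein", "OH", "both", "HH"),
      MET = tpl(r, "protein", "SD", "acceptor"),
      NULL)
    if (!is.null(sidechain)) rows[[length(rows) + 1]] <- sidechain
  }
  dna <- function(rn) {
    base <- sub("^D", "", rn)
    bb <- rbind(tpl(rn, "dna", "O1P", "acceptor"), tpl(rn, "dna", "O2P", "acceptor"),
                tpl(rn, "dna", "OP1", "acceptor"), tpl(rn, "dna", "OP2", "acceptor"),
                tpl(rn, "dna", "O5'", "acceptor"), tpl(rn, "dna", "O3'", "acceptor"),
                tpl(rn, "dna", "O4'", "acceptor"))
    side <- switch(base,
      A = rbind(tpl(rn, "dna", "N6", "donor", "H61,H62"),
                tpl(rn, "dna", "N1", "acceptor"), tpl(rn, "dna", "N3", "acceptor"),
                tpl(rn, "dna", "N7", "acceptor")),
      C = rbind(tpl(rn, "dna", "N4", "donor", "H41,H42"),
                tpl(rn, "dna", "O2", "acceptor"), tpl(rn, "dna", "N3", "acceptor")),
      G = rbind(tpl(rn, "dna", "N1", "donor", "H1"),
                tpl(rn, "dna", "N2", "donor", "H21,H22"),
                tpl(rn, "dna", "O6", "acceptor"), tpl(rn, "dna", "N3", "acceptor"),
                tpl(rn, "dna", "N7", "acceptor")),
      T = rbind(tpl(rn, "dna", "N3", "donor", "H3"),
                tpl(rn, "dna", "O2", "acceptor"), tpl(rn, "dna", "O4", "acceptor")),
      NULL)
    rbind(bb, side)
  }
  for (rn in c("DA", "DC", "DG", "DT", "A", "C", "G", "T"))
    rows[[length(rows) + 1]] <- dna(rn)
  # 8-oxoguanine: guanine-like plus protonated N7 (donor) and O8 acceptor
  rows[[length(rows) + 1]] <- rbind(
    tpl("8OG", "dna", "O1P", "acceptor"), tpl("8OG", "dna", "O2P", "acceptor"),
    tpl("8OG", "dna", "O5'", "acceptor"), tpl("8OG", "dna", "O3'", "acceptor"),
    tpl("8OG", "dna", "O4'", "acceptor"),
    tpl("8OG", "dna", "N1", "donor", "H1"),
    tpl("8OG", "dna", "N2", "donor", "H21,H22"),
    tpl("8OG", "dna", "N7", "donor", "H7"),
    tpl("8OG", "dna", "O6", "acceptor"), tpl("8OG", "dna", "N3", "acceptor"),
    tpl("8OG", "dna", "O8", "acceptor"))
  for (w in c("HOH", "WAT"))
    rows[[length(rows) + 1]] <- tpl(w, "water", "O", "both", "H1,H2,H")
  for (ion in c("ZN", "NA", "MG", "CL", "K", "MN", "CA", "FE"))
    rows[[length(rows) + 1]] <- tpl(ion, "ion", ion, "acceptor")
  out <- do.call(rbind, rows)
  if (!is.null(extra)) out <- rbind(out, extra)
  rownames(out) <- NULL
  out
}

#' Read additional residue templates from a plain-text table
#'
#' The format is tab- or whitespace-separated with four or five columns:
#' `resname class atom role [hydrogens]`, `#` comments allowed.  An
#' example covering a modified nucleotide is installed under
#' `system.file("extdata", "residue_templates_example.tsv", package = "fpgtraj")`.
#'
#' @param path Path to the template file.
#' @return Data frame in the shape accepted by `residue_templates(extra=)`.
#' @export
read_residue_templates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad)) stop("template line ", bad[1], " has fewer than 4 fields")
  data.frame(
    resname = vapply(parts, `[`, "", 1),
    class = vapply(parts, `[`, "", 2),
    atom = vapply(parts, `[`, "", 3),
    role = vapply(parts, `[`, "", 4),
    hydrogens = vapply(parts, function(p) if (length(p) >= 5) p[5] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Classify residues and annotate hydrogen-bond donors/acceptors
#'
#' Assigns every residue a class in protein/dna/water/ion/other and
#' populates the topology's donor and acceptor lists from the template
#' table.  Donor hydrogens are matched by name prefix within the residue;
#' when `reference_coords` is supplied, a matched hydrogen must also lie
#' within 1.2 Angstrom of its heavy atom.  Donors whose hydrogens are
#' absent (e.g. crystal structures) are kept in heavy-atom-only mode
#' (hydrogen index `NA`); see [hbond_energy()] for how such donors are
#' scored.  Residues with no template are classed `"other"` with a
#' warning; residues matching a template but missing template-required
#' heavy atoms get a warning and best-effort annotation.
#'
#' @param topology A `topology`.
#' @param templates Template table, see [residue_templates()].
#' @param reference_coords Optional `n_atoms x 3` matrix used to validate
#'   donor-hydrogen covalency.
#' @return The topology with `residues$class`, `donors` and `acceptors`
#'   filled in.
#' @export
classify_residues <- function(topology, templates = residue_templates(),
                              reference_coords = NULL) {
  a <- topology$atoms
  r <- topology$residues
  donors <- list()
  acceptors <- integer(0)
  unknown <- character(0)
  incomplete <- character(0)

  tpl_split <- split(templates, templates$resname)

  for (ri in seq_len(nrow(r))) {
    rn <- r$resname[ri]
    rows <- tpl_split[[rn]]
    if (is.null(rows)) {
      r$class[ri] <- "other"
      unknown <- c(unknown, rn)
      next
    }
    r$class[ri] <- rows$class[1]
    ai <- seq.int(r$first[ri], r$last[ri])
    anames <- a$name[ai]
    missing_heavy <- FALSE
    for (k in seq_len(nrow(rows))) {
      heavy <- which(anames == rows$atom[k])
      if (length(heavy) == 0) {
        # phosphate naming variants (O1P/OP1) and 5'-terminal residues
        # legitimately lack atoms; only warn for non-backbone template atoms
        if (!rows$atom[k] %in% c("O1P", "O2P", "OP1", "OP2", "O5'", "O3'", "OXT", "P"))
          missing_heavy <- TRUE
        next
      }
      heavy <- ai[heavy[1]]
      if (rows$role[k] %in% c("acceptor", "both"))
        acceptors <- c(acceptors, heavy)
      if (rows$role[k] %in% c("donor", "both")) {
        hnames <- strsplit(rows$hydrogens[k], ",", fixed = TRUE)[[1]]
        hs <- integer(0)
        for (hn in hnames) {
          cand <- ai[which(startsWith(anames, hn) & a$elem[ai] == "H")]
          hs <- c(hs, cand)
        }
        hs <- unique(hs)
        if (!is.null(reference_coords) && length(hs)) {
          hx <- reference_coords[heavy, , drop = FALSE]
          d <- sqrt(rowSums((reference_coords[hs, , drop = FALSE] -
                               hx[rep(1, length(hs)), , drop = FALSE])^2))
          hs <- hs[d <= 1.2]
        }
        if (length(hs) == 0)
          donors[[length(donors) + 1]] <- data.frame(donor = heavy, hydrogen = NA_integer_)
        else
          donors[[length(donors) + 1]] <- data.frame(donor = heavy, hydrogen = hs)
      }
    }
    if (missing_heavy)
      incomplete <- c(incomplete, sprintf("%s %d", rn, r$resnum[ri]))
  }
  if (length(unknown))
    warning("unknown residue name(s) classed 'other': ",
            paste(unique(unknown), collapse = ", "))
  if (length(incomplete))
    warning("residue(s) missing template heavy atoms (best-effort annotation): ",
            paste(unique(incomplete), collapse = ", "))
  topology$residues <- r
  topology$donors <- if (length(donors)) do.call(rbind, donors)
                     else data.frame(donor = integer(), hydrogen = integer())
  rownames(topology$donors) <- NULL
  topology$acceptors <- sort(unique(acceptors))
  topology
}
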