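#' @title Synthetic protein-DNA-water complexes with planted ground truth
#' @description Builds a toy glycosylase-DNA complex (a kinked-free 14-bp
#'   duplex with an 8-oxoguanine lesion, a Pro1/Glu2-like catalytic dyad,
#'   Arg/Phe stand-ins, waters, an ion, and optional planting "stations")
#'   and simulates multi-snapshot trajectories in which hydrogen-bond
#'   occupancies, water-bridge frequencies, glycosidic conformer jumps and
#'   the optimal-attack-geometry fraction are all planted with fully known
#'   ground truth, emitted alongside a machine-readable truth manifest.
#' @name synthetic-data
NULL

rot_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th); C <- 1 - c
  matrix(c(
    a[1]^2 * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c
  ), 3, 3, byrow = TRUE)
}

unitv <- function(v) v / sqrt(sum(v^2))

# ---- planar base templates (2D), generated from regular-polygon geometry --
base_template_2d <- function(base) {
  s <- 1.39
  ctr <- c(s, 0)
  hex_ang <- c(180, 240, 300, 0, 60, 120) * pi / 180
  hex <- cbind(ctr[1] + s * cos(hex_ang), ctr[2] + s * sin(hex_ang))
  rownames(hex) <- c("p1", "p2", "p3", "p4", "p5", "p6")
  exo <- function(pos, center, len) pos + len * unitv(pos - center)
  hdir <- function(pos, center, rot = 0) {
    d <- unitv(pos - center)
    R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
    as.numeric(R %*% d)
  }
  add <- function(df, name, pos) rbind(df, data.frame(name = name, u = pos[1], v = pos[2]))
  df <- data.frame(name = character(), u = numeric(), v = numeric())

  if (base %in% c("C", "T")) {
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    for (i in 1:6) df <- add(df, nm[i], hex[i, ])
    if (base == "C") {
      df <- add(df, "O2", exo(hex[2, ], ctr, 1.23))
      df <- add(df, "N4", exo(hex[4, ], ctr, 1.34))
      n4 <- exo(hex[4, ], ctr, 1.34)
      df <- add(df, "H41", n4 + hdir(hex[4, ], ctr, pi / 3))
      df <- add(df, "H42", n4 + hdir(hex[4, ], ctr, -pi / 3))
    } else {
      df <- add(df, "O2", exo(hex[2, ], ctr, 1.23))
      df <- add(df, "O4", exo(hex[4, ], ctr, 1.23))
      df <- add(df, "H3", hex[3, ] + hdir(hex[3, ], ctr))
      df <- add(df, "C5M", exo(hex[5, ], ctr, 1.50))
    }
    attach <- "N1"
    outward <- hdir(hex[1, ], ctr)
  } else {
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    for (i in 1:6) df <- add(df, nm[i], hex[i, ])
    # pentagon fused on the C4-C5 edge, outside the hexagon
    A <- hex[4, ]; B <- hex[5, ]
    M <- (A + B) / 2
    n <- unitv(M - ctr)
    apo <- s / (2 * tan(pi / 5))
    Rp <- s / (2 * sin(pi / 5))
    P <- M + apo * n
    angA <- atan2(A[2] - P[2], A[1] - P[1])
    step <- -2 * pi / 5  # walk from C4 away from C5
    n9 <- P + Rp * c(cos(angA + step), sin(angA + step))
    c8 <- P + Rp * c(cos(angA + 2 * step), sin(angA + 2 * step))
    n7 <- P + Rp * c(cos(angA + 3 * step), sin(angA + 3 * step))
    df <- add(df, "N7", n7); df <- add(df, "C8", c8); df <- add(df, "N9", n9)
    if (base == "A") {
      n6 <- exo(hex[6, ], ctr, 1.34)
      df <- add(df, "N6", n6)
      df <- add(df, "H61", n6 + hdir(hex[6, ], ctr, pi / 3))
      df <- add(df, "H62", n6 + hdir(hex[6, ], ctr, -pi / 3))
    } else {  # G and 8OG share the guanine decoration
      df <- add(df, "O6", exo(hex[6, ], ctr, 1.23))
      n2 <- exo(hex[2, ], ctr, 1.34)
      df <- add(df, "N2", n2)
      df <- add(df, "H1", hex[1, ] + hdir(hex[1, ], ctr))
      df <- add(df, "H21", n2 + hdir(hex[2, ], ctr, pi / 3))
      df <- add(df, "H22", n2 + hdir(hex[2, ], ctr, -pi / 3))
      if (base == "8OG") {
        df <- add(df, "O8", exo(c8, P, 1.23))
        df <- add(df, "H7", n7 + hdir(n7, P))
      }
    }
    attach <- "N9"
    outward <- hdir(n9, P)
  }
  list(atoms = df, attach = attach, outward = outward)
}

BACKBONE_NAMES <- c("P", "O1P", "O2P", "O5'", "C5'", "C4'", "O4'",
                    "C3'", "O3'", "C2'", "C1'")

# place one nucleotide: base in the plane spanned by (e_r, e_t) with
# normal zn; attach nitrogen at `npos`; sugar extends along +e_r (outward)
make_nucleotide <- function(base, npos, e_r, e_t, zn, strand_dir) {
  tpl <- base_template_2d(sub("^D", "", base))
  b2 <- tpl$atoms
  out2 <- tpl$outward
  # rotate 2D so outward -> (1, 0), then map (1,0)->e_r, (0,1)->e_t
  att2 <- as.numeric(b2[b2$name == tpl$attach, c("u", "v")])
  rel <- cbind(b2$u - att2[1], b2$v - att2[2])
  ang <- atan2(out2[2], out2[1])
  R2 <- matrix(c(cos(-ang), -sin(-ang), sin(-ang), cos(-ang)), 2, 2)
  rel <- rel %*% t(R2)
  xyz <- matrix(rep(npos, nrow(rel)), ncol = 3, byrow = TRUE) +
    rel[, 1] %o% e_r + rel[, 2] %o% e_t
  atoms <- data.frame(name = b2$name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  # sugar ring: planar pentagon (side 1.45) in the (e_r, zn) plane
  c1 <- npos + 1.47 * e_r
  Rp <- 1.45 / (2 * sin(pi / 5))
  Q <- c1 + Rp * unitv(0.85 * e_r + 0.53 * zn)
  a0 <- c1 - Q
  # orthonormal frame of the sugar plane
  f1 <- unitv(a0)
  f2 <- unitv(zn - sum(zn * f1) * f1)
  sug <- list()
  nms <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  for (k in 0:4) {
    th <- -k * 2 * pi / 5
    sug[[nms[k + 1]]] <- Q + Rp * (cos(th) * f1 + sin(th) * f2)
  }
  # choose ring walk direction so O4' sits on the +zn side
  if (sum((sug[["O4'"]] - c1) * zn) < 0) {
    for (k in 0:4) {
      th <- k * 2 * pi / 5
      sug[[nms[k + 1]]] <- Q + Rp * (cos(th) * f1 + sin(th) * f2)
    }
  }
  add3 <- function(atoms, name, pos)
    rbind(atoms, data.frame(name = name, x = pos[1], y = pos[2], z = pos[3]))
  for (nm in nms) atoms <- add3(atoms, nm, sug[[nm]])
  o3 <- sug[["C3'"]] + 1.42 * unitv(sug[["C3'"]] - Q - 0.5 * strand_dir)
  atoms <- add3(atoms, "O3'", o3)
  c5 <- sug[["C4'"]] + 1.52 * unitv(unitv(sug[["C4'"]] - Q) + strand_dir)
  atoms <- add3(atoms, "C5'", c5)
  o5 <- c5 + 1.42 * unitv(0.4 * e_r + strand_dir)
  atoms <- add3(atoms, "O5'", o5)
  p <- o5 + 1.60 * unitv(0.5 * e_r + strand_dir)
  atoms <- add3(atoms, "P", p)
  atoms <- add3(atoms, "O1P", p + 1.48 * unitv(e_r + 0.6 * zn))
  atoms <- add3(atoms, "O2P", p + 1.48 * unitv(e_r - 0.6 * zn))
  atoms
}

# a glycine built as a straight chain; `from` = position of the first atom
# in `order`, extending along `dir` with 1.0-1.6 A bonds
make_gly_chain <- function(from, dir, updir = c(0, 0, 1), reverse = FALSE) {
  d <- unitv(dir)
  u <- unitv(updir - sum(updir * d) * d)
  atoms <- list()
  if (!reverse) {
    # H first: H, N, CA, C, O (donor-presenting end at `from`)
    atoms[["H"]] <- from
    atoms[["N"]] <- from + 1.00 * d
    atoms[["CA"]] <- atoms[["N"]] + 1.46 * d
    atoms[["C"]] <- atoms[["CA"]] + 1.52 * d
    atoms[["O"]] <- atoms[["C"]] + 1.23 * unitv(0.5 * d + 0.866 * u)
  } else {
    # O first: O, C, CA, N, H (acceptor-presenting end at `from`)
    atoms[["O"]] <- from
    atoms[["C"]] <- from + 1.23 * d
    atoms[["CA"]] <- atoms[["C"]] + 1.52 * d
    atoms[["N"]] <- atoms[["CA"]] + 1.46 * d
    atoms[["H"]] <- atoms[["N"]] + 1.00 * unitv(0.3 * d + 0.954 * u)
  }
  do.call(rbind, lapply(c("N", "H", "CA", "C", "O"), function(nm)
    data.frame(name = nm, x = atoms[[nm]][1], y = atoms[[nm]][2],
               z = atoms[[nm]][3], stringsAsFactors = FALSE)))
}

#' Build the toy protein-DNA-water complex
#'
#' Constructs a chemically plausible (bonded distances 1.0-1.8 Angstrom)
#' single-snapshot complex: a straight B-DNA-like duplex of `n_bp` base
#' pairs numbered -7..+6 with an 8-oxoguanine lesion at position 0 and
#' either C or A opposite it; a small protein scaffold whose Pro1/Glu2
#' dyad is placed in the ideal nucleophilic-attack pose relative to the
#' lesion (N...C1' = 3.5 A on the O4'-C1' line, C1'...N...Cd = 107
#' degrees, Oe2...O4' = 4.0 A) plus Arg/Phe/Thr stand-ins; `n_waters`
#' waters near the interface; a Zn ion; and optional planting stations
#' for hydrogen bonds and water bridges used by [simulate_trajectory()].
#'
#' @param n_bp Base pairs (>= 6; default 14).
#' @param n_protein Protein scaffold residues (>= 8).
#' @param n_waters Free interface waters (>= 5).
#' @param opposite_base `"DC"` or `"DA"`: the base opposite the lesion.
#' @param n_hbond_stations Number of isolated donor/acceptor pairs whose
#'   geometry the simulator can toggle.
#' @param bridge_sizes Integer vector of partner-set sizes (2 or 3), one
#'   bridge station each.
#' @param propeller_deg Propeller twist planted into every base pair
#'   (degrees; positive values reproduce the canonical B-DNA sense).
#' @param twist,rise Helical twist (degrees/bp) and rise (Angstrom/bp).
#' @return A `toy_complex`: list with `topology`, `coords`
#'   (single-snapshot matrix), and `info` (lesion identity, catalytic
#'   atom map, station tables).
#' @export
build_toy_complex <- function(n_bp = 14, n_protein = 8, n_waters = 7,
                              opposite_base = c("DC", "DA"),
                              n_hbond_stations = 0, bridge_sizes = integer(),
                              propeller_deg = 0, twist = 36, rise = 3.38) {
  opposite_base <- match.arg(opposite_base)
  if (n_bp < 6) stop("need at least a 6-bp duplex")
  if (n_protein < 8) stop("need at least 8 protein residues")
  if (n_waters < 5) stop("need at least 5 waters")
  if (!all(bridge_sizes %in% c(2, 3))) stop("bridge sizes must be 2 or 3")

  positions <- seq(-ceiling(n_bp / 2), length.out = n_bp)
  lesion_pos <- 0
  base1 <- rep(c("DC", "DT", "DG", "DA"), length.out = n_bp)
  base1[positions == lesion_pos] <- "8OG"
  comp <- c(DA = "DT", DT = "DA", DC = "DG", DG = "DC")
  base2 <- ifelse(base1 == "8OG", opposite_base, comp[base1])

  glyc_R <- 4.6
  rows <- list()
  res_counter <- 0
  emit <- function(df, resname, resnum, chain) {
    res_counter <<- res_counter + 1
    df$resname <- resname; df$resnum <- resnum; df$chain <- chain
    rows[[length(rows) + 1]] <<- df
  }

  pair_axis_info <- list()
  for (i in seq_along(positions)) {
    phi <- (i - 1) * twist * pi / 180
    z <- (i - 1) * rise
    e_r1 <- c(cos(phi), sin(phi), 0)
    e_t1 <- c(-sin(phi), cos(phi), 0)
    zn <- c(0, 0, 1)
    n1pos <- glyc_R * e_r1 + c(0, 0, z)
    e_r2 <- -e_r1
    e_t2 <- e_t1   # keeps the second base's walk sense antiparallel
    n2pos <- glyc_R * e_r2 + c(0, 0, z)
    nuc1 <- make_nucleotide(base1[i], n1pos, e_r1, e_t1, zn, unitv(c(0, 0, 1)))
    nuc2 <- make_nucleotide(base2[i], n2pos, e_r2, e_t2, -zn, unitv(c(0, 0, -1)))
    if (propeller_deg != 0) {
      # counter-rotate the two bases' planar atoms about the pair long axis
      L <- unitv(n2pos - n1pos)
      spin <- function(nuc, npos, ang) {
        R <- rot_about_axis(L, ang)
        planar <- !nuc$name %in% BACKBONE_NAMES
        xyz <- as.matrix(nuc[planar, c("x", "y", "z")])
        xyz <- sweep(sweep(xyz, 2, npos) %*% t(R), 2, npos, "+")
        nuc[planar, c("x", "y", "z")] <- xyz
        nuc
      }
      nuc1 <- spin(nuc1, n1pos, +propeller_deg / 2)
      nuc2 <- spin(nuc2, n2pos, -propeller_deg / 2)
    }
    emit(nuc1, base1[i], positions[i], "B")
    emit(nuc2, base2[i], positions[i], "C")
    pair_axis_info[[i]] <- list(n1 = n1pos, n2 = n2pos)
  }

  # ---- protein scaffold ---------------------------------------------------
  # the dyad is placed in the ideal catalytic pose relative to the lesion
  li <- which(positions == lesion_pos)
  phiL <- (li - 1) * twist * pi / 180
  zL <- (li - 1) * rise
  nucL <- rows[[2 * li - 1]]
  gp <- function(df, nm) as.numeric(df[df$name == nm, c("x", "y", "z")])
  c1 <- gp(nucL, "C1'"); o4 <- gp(nucL, "O4'")
  u <- unitv(c1 - o4)
  proN <- c1 + 3.5 * u
  w <- unitv(orth_unit(u))
  cd_dir <- cos(107 * pi / 180) * (-u) + sin(107 * pi / 180) * w
  proCD <- proN + 1.49 * cd_dir
  proCA <- proN + 1.46 * unitv(-u - 0.8 * w)
  proCB <- proCA + 1.52 * unitv(cd_dir + 0.3 * u)
  proCG <- (proCB + proCD) / 2 + 0.45 * u
  proC <- proCA + 1.52 * unitv(u + 2 * w)
  proO <- proC + 1.23 * unitv(w)
  pro <- do.call(rbind, Map(function(nm, p)
    data.frame(name = nm, x = p[1], y = p[2], z = p[3]),
    c("N", "CA", "CB", "CG", "CD", "C", "O"),
    list(proN, proCA, proCB, proCG, proCD, proC, proO)))
  emit(pro, "PRO", 1, "A")

  v2 <- unitv(w - 0.5 * u)
  oe2 <- o4 + 4.0 * v2
  gcd <- oe2 + 1.25 * v2
  oe1 <- gcd + 1.25 * unitv(v2 + 0.9 * u)
  ggam <- gcd + 1.52 * unitv(v2 - 0.9 * u)
  gbet <- ggam + 1.52 * v2
  gca <- gbet + 1.52 * unitv(v2 + 0.5 * u)
  gn <- gca + 1.46 * v2
  gh <- gn + 1.00 * v2
  gc <- gca + 1.52 * unitv(v2 - 0.6 * u)
  go <- gc + 1.23 * unitv(u)
  glu <- do.call(rbind, Map(function(nm, p)
    data.frame(name = nm, x = p[1], y = p[2], z = p[3]),
    c("N", "H", "CA", "CB", "CG", "CD", "OE1", "OE2", "C", "O"),
    list(gn, gh, gca, gbet, ggam, gcd, oe1, oe2, gc, go)))
  emit(glu, "GLU", 2, "A")

  # remaining scaffold residues on an arc outside the duplex
  prot_R <- 13
  extra <- c("GLY", "GLY", "GLU", "ARG", "PHE", "THR",
             rep("GLY", max(0, n_protein - 8)))
  for (j in seq_along(extra)) {
    phj <- phiL + (j - 3) * 0.45
    base_pt <- c(prot_R * cos(phj), prot_R * sin(phj), zL + 2 * (j %% 3) - 2)
    d <- unitv(c(-sin(phj), cos(phj), 0.2))
    upd <- c(0, 0, 1)
    resn <- extra[j]
    at <- make_gly_chain(base_pt, d, upd, reverse = FALSE)
    if (resn == "GLU") {
      cbv <- gp(at, "CA") + 1.52 * upd
      cgv <- cbv + 1.52 * upd
      cdv <- cgv + 1.52 * upd
      at <- rbind(at,
        data.frame(name = "CB", x = cbv[1], y = cbv[2], z = cbv[3]),
        data.frame(name = "CG", x = cgv[1], y = cgv[2], z = cgv[3]),
        data.frame(name = "CD", x = cdv[1], y = cdv[2], z = cdv[3]),
        data.frame(name = "OE1", x = cdv[1] + 1.10, y = cdv[2], z = cdv[3] + 0.62),
        data.frame(name = "OE2", x = cdv[1] - 1.10, y = cdv[2], z = cdv[3] + 0.62))
    } else if (resn == "ARG") {
      nev <- gp(at, "CA") + c(0, 0, 1.8)
      czv <- nev + 1.33 * upd
      at <- rbind(at,
        data.frame(name = "NE", x = nev[1], y = nev[2], z = nev[3]),
        data.frame(name = "HE", x = nev[1] + 0.9, y = nev[2], z = nev[3] - 0.44),
        data.frame(name = "CZ", x = czv[1], y = czv[2], z = czv[3]),
        data.frame(name = "NH1", x = czv[1] + 1.2, y = czv[2], z = czv[3] + 0.6),
        data.frame(name = "HH11", x = czv[1] + 1.9, y = czv[2] + 0.6, z = czv[3] + 0.9),
        data.frame(name = "HH12", x = czv[1] + 1.9, y = czv[2] - 0.6, z = czv[3] + 0.9),
        data.frame(name = "NH2", x = czv[1] - 1.2, y = czv[2], z = czv[3] + 0.6),
        data.frame(name = "HH21", x = czv[1] - 1.9, y = czv[2] + 0.6, z = czv[3] + 0.9),
        data.frame(name = "HH22", x = czv[1] - 1.9, y = czv[2] - 0.6, z = czv[3] + 0.9))
    } else if (resn == "PHE") {
      ctr <- gp(at, "CA") + c(0, 0, 2.4)
      ring <- t(vapply(0:5, function(k) {
        th <- k * pi / 3
        ctr + 1.39 * (cos(th) * c(1, 0, 0) + sin(th) * c(0, 1, 0))
      }, numeric(3)))
      rnm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      at <- rbind(at, data.frame(name = rnm, x = ring[, 1], y = ring[, 2], z = ring[, 3]))
    } else if (resn == "THR") {
      ogv <- gp(at, "CA") + c(0, 0, 1.42)
      at <- rbind(at,
        data.frame(name = "OG1", x = ogv[1], y = ogv[2], z = ogv[3]),
        data.frame(name = "HG1", x = ogv[1], y = ogv[2] + 0.95, z = ogv[3] + 0.31))
    }
    emit(at, resn, j + 2, "A")
  }

  # ---- waters and ion ------------------------------------------------------
  for (k in seq_len(n_waters)) {
    phk <- phiL + 2.2 + 0.5 * k
    pos <- c(8.5 * cos(phk), 8.5 * sin(phk), zL - 4 + 1.6 * k)
    wat <- data.frame(
      name = c("O", "H1", "H2"),
      x = pos[1] + c(0, 0.95, -0.24), y = pos[2] + c(0, 0, 0.92),
      z = pos[3] + c(0, 0.31, 0.31))
    emit(wat, "HOH", 100 + k, "W")
  }
  znpos <- c(prot_R + 4, 0, zL + 8)
  emit(data.frame(name = "ZN", x = znpos[1], y = znpos[2], z = znpos[3]),
       "ZN", 90, "A")

  # ---- planting stations ---------------------------------------------------
  hb_station_rows <- list()
  grid0 <- c(40, 0, 0)
  for (st in seq_len(n_hbond_stations)) {
    g <- grid0 + c(15 * ((st - 1) %% 5), 15 * ((st - 1) %/% 5), 0)
    # donor: H at g+(1,0,0), N at g, chain extends -x
    don <- make_gly_chain(g + c(1.0, 0, 0), c(-1, 0, 0), c(0, 0, 1))
    # acceptor O on the N-H line at 3.05 A: within the flat top of the
    # 10-12 well (E = 2.5 kcal/mol), but clear of its steep compression
    # wall so that coordinate noise cannot push a planted bond under the
    # 1.2 kcal/mol existence threshold; its chain bends off along +y so
    # neighbouring stations stay out of H-bond range
    acc <- make_gly_chain(g + c(3.05, 0, 0), c(0, 1, 0), c(0, 0, 1), reverse = TRUE)
    emit(don, "GLY", 2 * st - 1, "S")
    emit(acc, "GLY", 2 * st, "S")
    hb_station_rows[[st]] <- data.frame(station = st)
  }

  br_station_info <- list()
  for (bs in seq_along(bridge_sizes)) {
    sz <- bridge_sizes[bs]
    g <- c(-40, 15 * (bs - 1), 0)  # water position
    # two acceptor partners along the two O-H directions (104.5 deg apart);
    # 3.0 A sits mid-well of the 10-12 energy term, so coordinate noise
    # cannot push a planted bridge below the existence threshold
    d1 <- c(1, 0, 0)
    d2 <- c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0)
    p1 <- make_gly_chain(g + 3.0 * d1, d1, c(0, 0, 1), reverse = TRUE)
    p2 <- make_gly_chain(g + 3.0 * d2, d2, c(0, 0, 1), reverse = TRUE)
    emit(p1, "GLY", 3 * bs - 2, "T")
    emit(p2, "GLY", 3 * bs - 1, "T")
    partners <- list(c("T", 3 * bs - 2, "O"), c("T", 3 * bs - 1, "O"))
    if (sz == 3) {
      d3 <- unitv(-(d1 + d2))
      # donor partner: N at 3.0 along d3 with H pointing back at the water
      p3 <- make_gly_chain(g + 2.0 * d3, d3, c(0, 0, 1))
      # H at g+1.85*d3, N at g+2.85*d3 -> H on the N->water line
      emit(p3, "GLY", 3 * bs, "T")
      partners[[3]] <- c("T", 3 * bs, "N")
    }
    wat <- data.frame(
      name = c("O", "H1", "H2"),
      x = g[1] + c(0, d1[1], d2[1]), y = g[2] + c(0, d1[2], d2[2]),
      z = g[3] + c(0, d1[3], d2[3]))
    emit(wat, "HOH", 200 + bs, "V")
    br_station_info[[bs]] <- list(size = sz, water = c("V", 200 + bs),
                                  partners = partners)
  }

  # ---- assemble topology ---------------------------------------------------
  all_atoms <- do.call(rbind, rows)
  n <- nrow(all_atoms)
  rkey <- paste(all_atoms$chain, all_atoms$resnum, all_atoms$resname, sep = "\r")
  res_index <- cumsum(c(TRUE, rkey[-1] != rkey[-length(rkey)]))
  atoms <- data.frame(
    serial = seq_len(n), name = all_atoms$name,
    elem = infer_element(all_atoms$name, all_atoms$resname),
    alt = "", resname = all_atoms$resname,
    resnum = as.integer(all_atoms$resnum),
    chain = all_atoms$chain, res_index = res_index, stringsAsFactors = FALSE)
  first <- which(!duplicated(res_index))
  residues <- data.frame(
    res_index = res_index[first], resname = all_atoms$resname[first],
    resnum = as.integer(all_atoms$resnum[first]), chain = all_atoms$chain[first],
    class = "other", first = first, last = c(first[-1] - 1L, n),
    stringsAsFactors = FALSE)
  coords <- as.matrix(all_atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  top <- new_topology(atoms, residues)
  top <- classify_residues(top, reference_coords = coords)

  idx <- function(chain, resnum, name) {
    which(top$atoms$chain == chain & top$atoms$resnum == resnum &
            top$atoms$name == name)[1]
  }
  info <- list(
    lesion = list(chain = "B", resnum = lesion_pos),
    positions = positions, opposite_base = opposite_base,
    catalytic_atoms = list(
      pro_n = idx("A", 1, "N"), pro_cd = idx("A", 1, "CD"),
      glu_oe2 = idx("A", 2, "OE2"),
      c1 = idx("B", lesion_pos, "C1'"), o4 = idx("B", lesion_pos, "O4'"),
      n9 = idx("B", lesion_pos, "N9")),
    hbond_stations = if (n_hbond_stations > 0) data.frame(
      station = seq_len(n_hbond_stations),
      donor = vapply(seq_len(n_hbond_stations), function(s) idx("S", 2 * s - 1, "N"), 0L),
      hydrogen = vapply(seq_len(n_hbond_stations), function(s) idx("S", 2 * s - 1, "H"), 0L),
      acceptor = vapply(seq_len(n_hbond_stations), function(s) idx("S", 2 * s, "O"), 0L)
    ) else NULL,
    bridge_stations = lapply(br_station_info, function(b) {
      list(size = b$size,
           water_res = top$atoms$res_index[idx(b$water[1], as.integer(b$water[2]), "O")],
           water_o = idx(b$water[1], as.integer(b$water[2]), "O"),
           partners = vapply(b$partners, function(p)
             idx(p[1], as.integer(p[2]), p[3]), 0L))
    })
  )
  structure(list(topology = top, coords = coords, info = info),
            class = "toy_complex")
}

# a deterministic unit vector orthogonal to u
orth_unit <- function(u) {
  t <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(t - sum(t * u) * u)
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("<toy_complex> %d atoms; lesion %s%d (%s opposite); %d hbond station(s), %d bridge station(s)\n",
              n_atoms(x$topology), x$info$lesion$chain, x$info$lesion$resnum,
              x$info$opposite_base,
              if (is.null(x$info$hbond_stations)) 0 else nrow(x$info$hbond_stations),
              length(x$info$bridge_stations)))
  invisible(x)
}

#' Rotate a nucleotide base to a target glycosidic angle
#'
#' Rotates the planar base atoms of a nucleotide about its glycosidic
#' bond (C1' -> N9/N1) so that chi equals `target_deg`.  Used to
#' construct nucleotides at prescribed conformer states.
#'
#' @param topology A `topology`.
#' @param coords `n_atoms x 3` matrix (modified copy returned).
#' @param resnum,chain Nucleotide identity.
#' @param target_deg Desired chi (degrees).
#' @return The coordinate matrix with the base rotated.
#' @export
set_chi <- function(topology, coords, resnum, chain = NULL, target_deg) {
  ai <- residue_atoms(topology, resnum, chain)
  if (length(ai) == 0) stop("residue not found")
  traj1 <- new_trajectory(topology, coords)
  chi0 <- as.numeric(glycosidic_chi(traj1, resnum, chain))[1]
  c1 <- find_in_residue(topology, ai, c("C1'", "C1*"))
  natt <- find_in_residue(topology, ai, "N9")
  if (is.na(natt)) natt <- find_in_residue(topology, ai, "N1")
  axis <- coords[natt, ] - coords[c1, ]
  base_atoms <- ai[!topology$atoms$name[ai] %in% BACKBONE_NAMES]
  # rotating the base by +t about the C1'->N axis decreases the measured
  # torsion by t under the IUPAC sign convention used here
  R <- rot_about_axis(axis, chi0 - target_deg)
  pivot <- coords[natt, ]
  coords[base_atoms, ] <- sweep(sweep(coords[base_atoms, , drop = FALSE], 2, pivot) %*% t(R),
                                2, pivot, "+")
  coords
}

#' Plant specification for the trajectory simulator
#'
#' Two-state Markov processes (rather than i.i.d. coin flips) drive every
#' plant, because real MD observables have persistence; the default
#' correlation time is 10 snapshots.  A plant with target occurrence `p`
#' and correlation time `tau` switches off->on with probability `p/tau`
#' and on->off with `(1-p)/tau` per snapshot, giving a stationary
#' occupancy of exactly `p`.
#'
#' @param hbond_occurrence Numeric vector: target occurrence per hydrogen
#'   bond station (complex must have at least that many stations).
#' @param bridge_occurrence Target occurrence per bridge station.
#' @param chi_states Chi state values (degrees) of the lesion conformer
#'   process, or `NULL` for no chi dynamics.
#' @param chi_trans Square transition matrix over `chi_states` (rows sum
#'   to 1); default: stay probability 0.9, uniform otherwise.
#' @param census_fraction Target fraction of snapshots with optimal
#'   catalytic geometry, or `NULL` to leave the dyad static (always
#'   optimal).
#' @param noise_sigma Isotropic Gaussian coordinate noise, Angstrom.
#' @param tau Correlation time (snapshots) for all two-state plants.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(hbond_occurrence = numeric(), bridge_occurrence = numeric(),
                       chi_states = NULL, chi_trans = NULL,
                       census_fraction = NULL, noise_sigma = 0.05, tau = 10) {
  stopifnot(all(hbond_occurrence >= 0 & hbond_occurrence <= 1),
            all(bridge_occurrence >= 0 & bridge_occurrence <= 1),
            noise_sigma >= 0, tau >= 1)
  if (!is.null(chi_states) && is.null(chi_trans)) {
    m <- length(chi_states)
    chi_trans <- matrix(0.1 / max(1, m - 1), m, m)
    diag(chi_trans) <- 0.9
    if (m == 1) chi_trans <- matrix(1, 1, 1)
  }
  if (!is.null(census_fraction))
    stopifnot(census_fraction >= 0, census_fraction <= 1)
  structure(list(hbond_occurrence = hbond_occurrence,
                 bridge_occurrence = bridge_occurrence,
                 chi_states = chi_states, chi_trans = chi_trans,
                 census_fraction = census_fraction,
                 noise_sigma = noise_sigma, tau = tau),
            class = "plant_spec")
}

# two-state Markov chain with stationary probability p
markov_binary <- function(n, p, tau) {
  s <- logical(n)
  if (p <= 0) return(s)
  if (p >= 1) return(rep(TRUE, n))
  q01 <- p / tau; q10 <- (1 - p) / tau
  s[1] <- stats::runif(1) < p
  if (n >= 2) {
    r <- stats::runif(n)
    for (t in 2:n)
      s[t] <- if (s[t - 1]) r[t] >= q10 else r[t] < q01
  }
  s
}

#' Simulate a trajectory with planted ground truth
#'
#' Realizes the plant specification over `n_snapshots` starting from the
#' toy complex's built coordinates: planted hydrogen bonds toggle their
#' acceptor residue between the ideal (2.9 A, linear) and broken (> 7 A)
#' geometry; bridge waters toggle between their trigonometrically placed
#' bridging position and a displaced one; the lesion base rotates about
#' the glycosidic bond through the chi Markov process; the Pro1 residue
#' withdraws from the attack position in non-optimal census snapshots;
#' and isotropic Gaussian noise is added last.  Fully reproducible from
#' the seed.
#'
#' @param complex A [build_toy_complex()] result.
#' @param plan A [plant_spec()].
#' @param n_snapshots Number of snapshots (>= 1).
#' @param seed Integer RNG seed.
#' @param dt_ps Snapshot spacing (ps).
#' @param label Trajectory label.
#' @return List: `trajectory` and `manifest` (a `truth_manifest` with
#'   per-plant realized counts, per-snapshot state labels, the census
#'   mask and the seed).
#' @export
simulate_trajectory <- function(complex, plan = plant_spec(), n_snapshots = 1000,
                                seed = 1, dt_ps = 2, label = "synthetic") {
  stopifnot(inherits(complex, "toy_complex"), n_snapshots >= 1)
  top <- complex$topology
  info <- complex$info
  nh <- length(plan$hbond_occurrence)
  nb <- length(plan$bridge_occurrence)
  if (nh > 0 && (is.null(info$hbond_stations) || nrow(info$hbond_stations) < nh))
    stop(sprintf("plan wants %d hbond plants but the complex has %d stations",
                 nh, if (is.null(info$hbond_stations)) 0 else nrow(info$hbond_stations)))
  if (nb > length(info$bridge_stations))
    stop(sprintf("plan wants %d bridge plants but the complex has %d stations",
                 nb, length(info$bridge_stations)))
  # satisfiability: one water must be able to span each partner set
  for (b in seq_len(nb)) {
    pts <- complex$coords[info$bridge_stations[[b]]$partners, , drop = FALSE]
    if (max(stats::dist(pts)) > 6.0)
      stop(sprintf("bridge plant %d: partners too distant for one water", b))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  hb_states <- if (nh) vapply(seq_len(nh), function(i)
    markov_binary(n_snapshots, plan$hbond_occurrence[i], plan$tau),
    logical(n_snapshots)) else NULL
  br_states <- if (nb) vapply(seq_len(nb), function(i)
    markov_binary(n_snapshots, plan$bridge_occurrence[i], plan$tau),
    logical(n_snapshots)) else NULL
  if (nh == 1) hb_states <- matrix(hb_states, ncol = 1)
  if (nb == 1) br_states <- matrix(br_states, ncol = 1)

  chi_seq <- NULL
  if (!is.null(plan$chi_states)) {
    m <- length(plan$chi_states)
    chi_seq <- integer(n_snapshots)
    # start from the stationary distribution
    ev <- eigen(t(plan$chi_trans))
    st <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    st <- st / sum(st)
    chi_seq[1] <- sample.int(m, 1, prob = st)
    if (n_snapshots >= 2) for (t in 2:n_snapshots)
      chi_seq[t] <- sample.int(m, 1, prob = plan$chi_trans[chi_seq[t - 1], ])
  }

  census_mask <- if (!is.null(plan$census_fraction))
    markov_binary(n_snapshots, plan$census_fraction, plan$tau) else NULL

  # precompute moving groups and off-state shifts
  hb_moves <- if (nh) lapply(seq_len(nh), function(i) {
    acc <- info$hbond_stations$acceptor[i]
    list(atoms = which(top$atoms$res_index == top$atoms$res_index[acc]),
         shift = c(4.5, 0, 0))
  }) else NULL
  br_moves <- if (nb) lapply(seq_len(nb), function(i) {
    b <- info$bridge_stations[[i]]
    list(atoms = which(top$atoms$res_index == b$water_res),
         shift = c(0, 0, 9))
  }) else NULL
  pro_atoms <- which(top$atoms$res_index ==
                       top$atoms$res_index[info$catalytic_atoms$pro_n])
  c1 <- complex$coords[info$catalytic_atoms$c1, ]
  pro_off_shift <- 1.8 * unitv(complex$coords[info$catalytic_atoms$pro_n, ] - c1)

  base0 <- complex$coords
  lesion <- info$lesion
  chi_coords <- NULL
  if (!is.null(chi_seq)) {
    chi_coords <- lapply(plan$chi_states, function(tg)
      set_chi(top, base0, lesion$resnum, lesion$chain, tg))
  }

  n <- nrow(base0)
  coords <- array(NA_real_, dim = c(n, 3, n_snapshots))
  for (t in seq_len(n_snapshots)) {
    x <- if (is.null(chi_seq)) base0 else chi_coords[[chi_seq[t]]]
    if (nh) for (i in seq_len(nh)) if (!hb_states[t, i]) {
      mv <- hb_moves[[i]]
      x[mv$atoms, ] <- sweep(x[mv$atoms, , drop = FALSE], 2, mv$shift, "+")
    }
    if (nb) for (i in seq_len(nb)) if (!br_states[t, i]) {
      mv <- br_moves[[i]]
      x[mv$atoms, ] <- sweep(x[mv$atoms, , drop = FALSE], 2, mv$shift, "+")
    }
    if (!is.null(census_mask) && !census_mask[t])
      x[pro_atoms, ] <- sweep(x[pro_atoms, , drop = FALSE], 2, pro_off_shift, "+")
    coords[, , t] <- x
  }
  if (plan$noise_sigma > 0)
    coords <- coords + stats::rnorm(length(coords), sd = plan$noise_sigma)

  traj <- new_trajectory(top, coords, dt_ps = dt_ps, label = label)
  manifest <- structure(list(
    seed = seed, n_snapshots = n_snapshots,
    hbonds = if (nh) data.frame(
      station = seq_len(nh),
      donor = info$hbond_stations$donor[seq_len(nh)],
      acceptor = info$hbond_stations$acceptor[seq_len(nh)],
      key = hbond_key(top, info$hbond_stations$donor[seq_len(nh)],
                      info$hbond_stations$acceptor[seq_len(nh)]),
      target = plan$hbond_occurrence,
      count = colSums(hb_states), realized = colMeans(hb_states)) else NULL,
    hbond_states = hb_states,
    bridges = if (nb) data.frame(
      station = seq_len(nb),
      size = vapply(info$bridge_stations[seq_len(nb)], function(b) b$size, 0),
      target = plan$bridge_occurrence,
      count = colSums(br_states), realized = colMeans(br_states)) else NULL,
    bridge_states = br_states,
    chi_states = plan$chi_states, chi_seq = chi_seq,
    chi_stationary = if (!is.null(chi_seq)) {
      ev <- eigen(t(plan$chi_trans))
      st <- Re(ev$vectors[, which.min(abs(ev$values - 1))]); st / sum(st)
    } else NULL,
    census_mask = census_mask,
    census_count = if (!is.null(census_mask)) sum(census_mask) else NULL
  ), class = "truth_manifest")
  list(trajectory = traj, manifest = manifest)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("<truth_manifest> seed %d, %d snapshots; %d hbond plant(s), %d bridge plant(s)%s%s\n",
              x$seed, x$n_snapshots,
              if (is.null(x$hbonds)) 0 else nrow(x$hbonds),
              if (is.null(x$bridges)) 0 else nrow(x$bridges),
              if (is.null(x$chi_seq)) "" else ", chi process",
              if (is.null(x$census_mask)) "" else
                sprintf(", census %d/%d", x$census_count, x$n_snapshots)))
  invisible(x)
}

#' Write a truth manifest as delimited text
#' @param manifest A `truth_manifest`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# truth manifest: seed %d, %d snapshots",
                     manifest$seed, manifest$n_snapshots), con)
  if (!is.null(manifest$hbonds)) {
    writeLines("# [hbonds]", con)
    utils::write.table(manifest$hbonds, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(manifest$bridges)) {
    writeLines("# [bridges]", con)
    utils::write.table(manifest$bridges, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(manifest$census_mask)) {
    writeLines(sprintf("# [census] count=%d", manifest$census_count), con)
  }
  invisible(path)
}
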