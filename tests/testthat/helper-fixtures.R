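# shared fixtures, built in code at test time

# a small complex reused by several suites (no stations)
toy <- local({
  suppressWarnings(suppressMessages(build_toy_complex()))
})
toy_traj <- new_trajectory(toy$topology, toy$coords)

# PDB text for a chain of named atoms at given coordinates
pdb_text <- function(names, xyz, resname = "GLY", resnum = NULL,
                     chain = "A", elem = NULL) {
  n <- length(names)
  if (is.null(resnum)) resnum <- seq_len(n)
  if (is.null(elem)) elem <- substr(gsub("[^A-Za-z]", "", names), 1, 1)
  paste(sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                seq_len(n), sprintf("%-3s", names), resname, chain, resnum,
                xyz[, 1], xyz[, 2], xyz[, 3], elem),
        collapse = "\n")
}

# topology of n pseudo-atoms (one residue each) at given coordinates,
# built through the PDB parser (coordinates quantized to 3 decimals)
point_topology <- function(xyz, name = "P", resname = "DA", elem = "P",
                           chain = "B") {
  txt <- pdb_text(rep(name, nrow(xyz)), xyz, resname = resname,
                  chain = chain, elem = elem)
  suppressWarnings(read_pdb(txt))
}

# same, but constructed directly (exact coordinates, for numeric oracles)
direct_topology <- function(xyz, name = "CA", resname = "GLY", elem = "C",
                            chain = "A") {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = name, elem = elem,
                      alt = "", resname = resname, resnum = seq_len(n),
                      chain = chain, res_index = seq_len(n),
                      stringsAsFactors = FALSE)
  residues <- data.frame(res_index = seq_len(n), resname = resname,
                         resnum = seq_len(n), chain = chain, class = "other",
                         first = seq_len(n), last = seq_len(n),
                         stringsAsFactors = FALSE)
  top <- fpgtraj:::new_topology(atoms, residues)
  list(topology = top, trajectory = new_trajectory(top, xyz))
}

# trajectory wrapper around one or more coordinate matrices
traj_of <- function(top, ...) {
  mats <- list(...)
  arr <- array(unlist(mats), dim = c(nrow(mats[[1]]), 3, length(mats)))
  new_trajectory(top, arr)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# apply a rigid-body transform to every snapshot of a trajectory
transform_traj <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  arr <- traj$coords
  for (m in seq_len(dim(arr)[3]))
    arr[, , m] <- arr[, , m] %*% t(R) + matrix(t, nrow(arr), 3, byrow = TRUE)
  new_trajectory(traj$topology, arr, dt_ps = traj$dt_ps, label = traj$label)
}

# a synthetic occurrence_table for statistics-level tests (no trajectories)
synthetic_occurrence_table <- function(occ, labels = colnames(occ)) {
  if (is.null(labels)) labels <- paste0("model", seq_len(ncol(occ)))
  colnames(occ) <- labels
  keys <- sprintf("X:%d:N--Y:%d:O", seq_len(nrow(occ)), seq_len(nrow(occ)))
  rownames(occ) <- keys
  structure(list(
    bonds = data.frame(key = keys, label = keys,
                       donor = seq_len(nrow(occ)), acceptor = seq_len(nrow(occ)),
                       stringsAsFactors = FALSE),
    occurrence = occ,
    n_snapshots = rep(5000L, ncol(occ)),
    params = hbond_params(), floor = 0.01
  ), class = "occurrence_table")
}

# brute-force H-bond reference: all donor x acceptor pairs, no cutoff
brute_force_hbonds <- function(coords, top, params = hbond_params()) {
  don <- top$donors; acc <- top$acceptors
  res <- list()
  for (dh in unique(don$donor)) {
    hs <- don$hydrogen[don$donor == dh]
    hs <- hs[!is.na(hs)]
    for (a in acc) {
      if (a == dh) next
      if (top$atoms$res_index[a] == top$atoms$res_index[dh]) next
      d <- sqrt(sum((coords[dh, ] - coords[a, ])^2))
      if (d > params$cutoff) next  # detection contract includes the cutoff
      if (length(hs) == 0) {
        ant <- fpgtraj:::donor_antecedent(top, coords, dh)
        theta <- if (is.na(ant)) 0 else {
          u <- coords[ant, ] - coords[dh, ]; v <- coords[a, ] - coords[dh, ]
          abs(acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi - 109.5)
        }
        e <- hbond_energy(d, theta, params)
      } else {
        e <- max(vapply(hs, function(h) {
          u <- coords[dh, ] - coords[h, ]; v <- coords[a, ] - coords[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                   sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
          hbond_energy(d, 180 - ang, params)
        }, 0))
      }
      if (e > params$threshold)
        res[[length(res) + 1]] <- c(dh, a)
    }
  }
  if (length(res) == 0) return(data.frame(donor = integer(), acceptor = integer()))
  m <- do.call(rbind, res)
  data.frame(donor = m[, 1], acceptor = m[, 2])
}

hb_set <- function(df) sort(paste(df$donor, df$acceptor))
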