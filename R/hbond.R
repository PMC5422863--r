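#' @title Hydrogen-bond detection and occurrence statistics
#' @description Energy-criterion H-bond detection per snapshot, occurrence
#'   tables across models, stability classes, phi coefficients,
#'   group-difference maps and replicate reproducibility.
#' @name hbond-analysis
NULL

#' Hydrogen-bond energy parameters
#'
#' The radial term is a 10-12 Lennard-Jones-type well with depth
#' `epsilon` at donor-acceptor distance `sigma`, weighted by the fourth
#' power of the cosine of the deviation of D-H...A from linear.  A bond is
#' considered to exist when the stabilization exceeds `threshold`
#' (kcal/mol); candidate pairs are pre-filtered by the donor-acceptor
#' `cutoff` (Angstrom), beyond which the energy is far below any sensible
#' threshold.
#'
#' @param epsilon Well depth, kcal/mol (default 2.8).
#' @param sigma Optimal donor-acceptor distance, Angstrom (default 2.9).
#' @param threshold Existence threshold, kcal/mol (default 1.2).
#' @param cutoff Donor-acceptor neighbour cutoff, Angstrom (default 5.0).
#' @return A parameter list.
#' @export
hbond_params <- function(epsilon = 2.8, sigma = 2.9, threshold = 1.2, cutoff = 5.0) {
  list(epsilon = epsilon, sigma = sigma, threshold = threshold, cutoff = cutoff)
}

#' Hydrogen-bond stabilization energy
#'
#' `E = epsilon * (6 (sigma/d)^10 - 5 (sigma/d)^12) * cos^4(theta)`,
#' clamped at >= 0, where `d` is the donor-acceptor distance and `theta`
#' the deviation of the D-H...A arrangement from linear (0 for an ideal
#' bond; contributions vanish for theta >= 90 degrees).  The maximum is
#' `epsilon` at `d = sigma`, `theta = 0`.
#'
#' @param d Donor-acceptor distance(s), Angstrom.
#' @param theta_deg Angular deviation(s) from linear, degrees.
#' @param params See [hbond_params()].
#' @return Stabilization energy (kcal/mol, >= 0), vectorized.
#' @export
hbond_energy <- function(d, theta_deg = 0, params = hbond_params()) {
  x <- params$sigma / d
  radial <- params$epsilon * (6 * x^10 - 5 * x^12)
  ct <- cos(pmin(abs(theta_deg), 90) * pi / 180)
  pmax(0, radial) * ct^4
}

# per-snapshot antecedent lookup for heavy-atom-mode donors: the nearest
# heavy atom within 1.8 A in the same residue (e.g. C for a backbone N)
donor_antecedent <- function(top, coords, donor) {
  ri <- top$atoms$res_index[donor]
  cand <- which(top$atoms$res_index == ri & top$atoms$elem != "H")
  cand <- setdiff(cand, donor)
  if (length(cand) == 0) return(NA_integer_)
  d <- sqrt(rowSums(sweep(coords[cand, , drop = FALSE], 2, coords[donor, ])^2))
  if (min(d) > 1.8) return(NA_integer_)
  cand[which.min(d)]
}

#' Detect hydrogen bonds in one snapshot
#'
#' Evaluates all annotated donor-acceptor pairs within the neighbour
#' cutoff (equivalent to an all-pairs search) and returns the pairs whose
#' stabilization energy exceeds the threshold.  Donors with several
#' hydrogens are scored with each hydrogen and the maximum energy is
#' taken.  Donors without hydrogens (crystal structures) are scored in
#' heavy-atom mode: the angular factor is computed from the
#' donor-antecedent geometry (deviation of the antecedent-donor-acceptor
#' angle from tetrahedral), or taken as 1 when no antecedent exists.
#' Intra-residue pairs are excluded.
#'
#' With `criterion = "geometric"` the energy model is replaced by the
#' classic geometric rule: donor-acceptor distance <= 3.5 Angstrom and
#' D-H...A angle >= 120 degrees (heavy-atom mode: distance rule only).
#'
#' @param coords `n_atoms x 3` snapshot coordinates.
#' @param topology Annotated `topology` (see [classify_residues()]).
#' @param params See [hbond_params()].
#' @param criterion `"energy"` (default) or `"geometric"`.
#' @return Data frame with columns `donor`, `acceptor` (atom indices) and
#'   `energy`.
#' @export
detect_hbonds <- function(coords, topology, params = hbond_params(),
                          criterion = c("energy", "geometric")) {
  criterion <- match.arg(criterion)
  don <- topology$donors
  acc <- topology$acceptors
  empty <- data.frame(donor = integer(), acceptor = integer(), energy = numeric())
  if (nrow(don) == 0 || length(acc) == 0) return(empty)
  dh <- unique(don$donor)
  dx <- coords[dh, , drop = FALSE]
  ax <- coords[acc, , drop = FALSE]
  d2 <- outer(rowSums(dx^2), rowSums(ax^2), "+") - 2 * dx %*% t(ax)
  d2[d2 < 0] <- 0
  cand <- which(d2 <= params$cutoff^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  di <- dh[cand[, 1]]; aj <- acc[cand[, 2]]
  dvals <- sqrt(d2[cand])
  same_res <- topology$atoms$res_index[di] == topology$atoms$res_index[aj]
  keep <- !same_res & di != aj
  di <- di[keep]; aj <- aj[keep]
  dd <- dvals[keep]
  if (length(di) == 0) return(empty)

  # expand candidate pairs over the hydrogens of each donor (vectorized);
  # the maximum energy over a donor's hydrogens is taken per pair
  has_h <- !is.na(don$hydrogen)
  hmap <- don[has_h, , drop = FALSE]
  hcount <- table(factor(hmap$donor, levels = unique(hmap$donor)))
  nh_per_pair <- as.integer(hcount[as.character(di)])
  nh_per_pair[is.na(nh_per_pair)] <- 0L
  energy <- numeric(length(di))

  withh <- which(nh_per_pair > 0)
  if (length(withh)) {
    rep_p <- rep(withh, nh_per_pair[withh])
    hsplit <- split(hmap$hydrogen, hmap$donor)
    hvec <- unlist(hsplit[as.character(di[withh])], use.names = FALSE)
    hd <- coords[di[rep_p], , drop = FALSE]
    ha <- coords[aj[rep_p], , drop = FALSE]
    hh <- coords[hvec, , drop = FALSE]
    u <- hd - hh; v <- ha - hh
    cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi  # D-H...A angle
    theta <- 180 - ang
    e <- if (criterion == "energy") hbond_energy(dd[rep_p], theta, params)
         else ifelse(dd[rep_p] <= 3.5 & ang >= 120, params$threshold + 1, 0)
    best <- tapply(e, rep_p, max)
    energy[as.integer(names(best))] <- best
  }
  for (p in which(nh_per_pair == 0)) {
    # heavy-atom mode (no hydrogens present for this donor)
    ant <- donor_antecedent(topology, coords, di[p])
    theta <- if (is.na(ant)) 0 else {
      u <- coords[ant, ] - coords[di[p], ]
      v <- coords[aj[p], ] - coords[di[p], ]
      ang <- acos(pmin(1, pmax(-1, sum(u * v) /
               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      abs(ang - 109.5)
    }
    energy[p] <- if (criterion == "energy")
      hbond_energy(dd[p], theta, params)
    else if (dd[p] <= 3.5) params$threshold + 1 else 0
  }
  ok <- energy > params$threshold
  data.frame(donor = di[ok], acceptor = aj[ok], energy = energy[ok])
}

# heavy-atom bond key, comparable across protonation variants of a model
hbond_key <- function(top, donor, acceptor) {
  a <- top$atoms
  paste0(a$chain[donor], ":", a$resnum[donor], ":", a$name[donor], "--",
         a$chain[acceptor], ":", a$resnum[acceptor], ":", a$name[acceptor])
}

#' Human-readable bond label including residue names
#' @param top A `topology`.
#' @param donor,acceptor Atom indices.
#' @return Character labels like `"A:136:THR:N--A:134:GLU:O"`.
#' @export
hbond_label <- function(top, donor, acceptor) {
  a <- top$atoms
  paste0(a$chain[donor], ":", a$resnum[donor], ":", a$resname[donor], ":",
         a$name[donor], "--", a$chain[acceptor], ":", a$resnum[acceptor], ":",
         a$resname[acceptor], ":", a$name[acceptor])
}

#' Hydrogen-bond occurrence table across trajectories
#'
#' For each trajectory (model or replicate run), the fraction of
#' snapshots in which each hydrogen bond exists under the energy
#' criterion.  Bonds are keyed by heavy atoms (chain:resnum:atom) so that
#' tables are comparable across alternative protonation states of the
#' same complex.  Bonds below the existence floor in every model are
#' dropped.
#'
#' @param trajectories A `trajectory` or list of trajectories (names used
#'   as model labels, falling back to each trajectory's `label`).
#' @param params See [hbond_params()].
#' @param floor Existence floor: minimum occurrence fraction in at least
#'   one model for a bond to be retained (default 0.01).
#' @param criterion Passed to [detect_hbonds()].
#' @return An `occurrence_table`: list with `bonds` (data frame: `key`,
#'   `label`, `donor`, `acceptor` from the first model's topology),
#'   `occurrence` (bonds x models matrix of fractions), `n_snapshots`
#'   (per model), `params`, `floor`.
#' @export
occurrence_table <- function(trajectories, params = hbond_params(),
                             floor = 0.01, criterion = "energy") {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < 1) stop("need at least one trajectory")
  labs <- names(trajectories)
  if (is.null(labs))
    labs <- vapply(trajectories, function(t) t$label, "")
  labs[!nzchar(labs)] <- paste0("model", which(!nzchar(labs)))

  ref_res <- trajectories[[1]]$topology$residues
  sig <- function(r) paste(r$chain, r$resnum, collapse = "|")
  for (m in seq_along(trajectories)) {
    if (sig(trajectories[[m]]$topology$residues) != sig(ref_res))
      stop(sprintf("trajectory %d ('%s') has a mismatched topology", m, labs[m]))
  }

  counts <- list()   # key -> per-model count
  firstseen <- list()  # key -> c(donor, acceptor) in that model's topology
  nsnap <- integer(length(trajectories))
  for (m in seq_along(trajectories)) {
    traj <- trajectories[[m]]
    top <- traj$topology
    ns <- n_snapshots(traj)
    nsnap[m] <- ns
    tally <- new.env(parent = emptyenv(), hash = TRUE)
    for (s in seq_len(ns)) {
      hb <- detect_hbonds(traj$coords[, , s], top, params, criterion)
      if (nrow(hb) == 0) next
      keys <- hbond_key(top, hb$donor, hb$acceptor)
      for (q in seq_along(keys)) {
        k <- keys[q]
        tally[[k]] <- if (is.null(tally[[k]])) 1L else tally[[k]] + 1L
        if (is.null(firstseen[[k]]))
          firstseen[[k]] <- c(hb$donor[q], hb$acceptor[q], m)
      }
    }
    for (k in ls(tally)) {
      if (is.null(counts[[k]])) counts[[k]] <- integer(length(trajectories))
      counts[[k]][m] <- tally[[k]]
    }
  }
  if (length(counts) == 0) {
    occ <- matrix(numeric(0), 0, length(trajectories),
                  dimnames = list(NULL, labs))
    bonds <- data.frame(key = character(), label = character(),
                        donor = integer(), acceptor = integer())
  } else {
    keys <- sort(names(counts))
    occ <- do.call(rbind, lapply(keys, function(k) counts[[k]] / nsnap))
    colnames(occ) <- labs
    keep <- apply(occ, 1, max) > floor
    keys <- keys[keep]
    occ <- occ[keep, , drop = FALSE]
    da <- t(vapply(keys, function(k) firstseen[[k]][1:3], numeric(3)))
    labels <- vapply(seq_along(keys), function(i) {
      top_m <- trajectories[[da[i, 3]]]$topology
      hbond_label(top_m, da[i, 1], da[i, 2])
    }, "")
    bonds <- data.frame(key = keys, label = labels,
                        donor = as.integer(da[, 1]), acceptor = as.integer(da[, 2]),
                        stringsAsFactors = FALSE)
    rownames(occ) <- keys
  }
  structure(list(bonds = bonds, occurrence = occ, n_snapshots = nsnap,
                 params = params, floor = floor),
            class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("<occurrence_table> %d bonds x %d models (%s snapshots)\n",
              nrow(x$bonds), ncol(x$occurrence),
              paste(x$n_snapshots, collapse = "/")))
  invisible(x)
}

#' Classify hydrogen bonds by occurrence stability
#'
#' `stable` when occurrence > 0.90, `fluctuating` when occurrence <= 0.25
#' (boundary inclusive), `intermediate` otherwise.  Stable bonds are the
#' candidates for functional importance; fluctuating ones mostly reflect
#' conformational noise.
#'
#' @param occurrence Numeric occurrences in `[0, 1]`, or an
#'   `occurrence_table` (classified per bond and model).
#' @param stable_cut,fluct_cut The two boundaries (defaults 0.90, 0.25).
#' @return Character vector (or bonds x models matrix) of categories.
#' @export
classify_stability <- function(occurrence, stable_cut = 0.90, fluct_cut = 0.25) {
  if (inherits(occurrence, "occurrence_table")) {
    m <- occurrence$occurrence
    out <- apply(m, 2, classify_stability, stable_cut = stable_cut,
                 fluct_cut = fluct_cut)
    if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
    return(out)
  }
  if (length(occurrence) == 0) stop("empty occurrence vector")
  ifelse(occurrence > stable_cut, "stable",
         ifelse(occurrence <= fluct_cut, "fluctuating", "intermediate"))
}

#' Phi (mean square contingency) coefficient between two models
#'
#' Cross-tabulates the bonds of a common universe by membership in a
#' binary category (e.g. stable: occurrence > 0.9) in model A versus
#' model B, and returns `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`.
#' When any margin is zero phi is returned as 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param occ_a,occ_b Numeric occurrence vectors over the same bond
#'   universe.
#' @param split Binary category rule: a numeric threshold `t` (category =
#'   occurrence > t, default 0.9) or a function returning logicals.
#' @return phi in `[-1, 1]`.
#' @export
phi_coefficient <- function(occ_a, occ_b, split = 0.9) {
  if (length(occ_a) == 0) stop("empty bond universe")
  if (length(occ_a) != length(occ_b)) stop("bond universes differ in size")
  f <- if (is.function(split)) split else function(x) x > split
  ca <- f(occ_a); cb <- f(occ_b)
  a <- sum(ca & cb); b <- sum(ca & !cb)
  c <- sum(!ca & cb); d <- sum(!ca & !cb)
  den <- sqrt(prod(c(a + b, c + d, a + c, b + d)))
  if (den == 0) return(structure(0, degenerate = TRUE))
  (a * d - b * c) / den
}

#' Group-specific hydrogen bonds (difference map)
#'
#' Selects the bonds whose mean occurrence differs between two groups of
#' models by more than `k` standard deviations plus an absolute floor.
#' The dispersion estimate is, by default, the pooled within-group
#' standard deviation of the bond's occurrences across models
#' (`sigma_mode = "pooled"`); `sigma_mode = "across_bonds"` instead uses
#' the standard deviation of the difference over all bonds, for the
#' alternative reading of "deviating > k sigma from the mean distance
#' between the models".
#'
#' @param table An `occurrence_table`.
#' @param grouping Named character vector mapping model labels (columns
#'   of the table) to exactly two group labels.
#' @param k Sigma multiple (default 3).
#' @param abs_floor Absolute occurrence-difference floor (default 0.10),
#'   suppressing sparse-bond noise.
#' @param sigma_mode `"pooled"` (default) or `"across_bonds"`.
#' @return A `difference_map` data frame: `key`, `label`, per-group mean
#'   occurrences, `diff`, `sigma`, `selected`, `magnitude` (|diff| for
#'   plotting); attributes `groups`, `k`, `abs_floor`.
#' @export
group_specific_bonds <- function(table, grouping, k = 3, abs_floor = 0.10,
                                 sigma_mode = c("pooled", "across_bonds")) {
  sigma_mode <- match.arg(sigma_mode)
  occ <- table$occurrence
  if (is.null(names(grouping)) || !all(names(grouping) %in% colnames(occ)))
    stop("grouping must be named by the table's model labels")
  gl <- unique(grouping)
  if (length(gl) != 2) stop("need exactly 2 groups")
  g1 <- names(grouping)[grouping == gl[1]]
  g2 <- names(grouping)[grouping == gl[2]]
  m1 <- rowMeans(occ[, g1, drop = FALSE])
  m2 <- rowMeans(occ[, g2, drop = FALSE])
  dif <- m1 - m2
  s1 <- apply(occ[, g1, drop = FALSE], 1, stats::sd)
  s2 <- apply(occ[, g2, drop = FALSE], 1, stats::sd)
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 && n2 < 2)
    stop("at least one group needs >= 2 models for a dispersion estimate")
  if (n1 < 2 || n2 < 2) {
    warning("a group has a single model; sigma taken from the other group")
    sig <- if (n1 < 2) s2 else s1
  } else {
    sig <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  }
  if (sigma_mode == "across_bonds") sig <- rep(stats::sd(dif), length(dif))
  selected <- abs(dif) > k * sig & abs(dif) > abs_floor
  out <- data.frame(key = table$bonds$key, label = table$bonds$label,
                    mean_g1 = m1, mean_g2 = m2, diff = dif, sigma = sig,
                    selected = selected, magnitude = abs(dif),
                    stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("mean_", gl)
  structure(out, groups = gl, k = k, abs_floor = abs_floor,
            class = c("difference_map", "data.frame"))
}

#' Reproducibility of bond occurrences across replicate runs
#'
#' Per bond, the mean occurrence and coefficient of variation over
#' replicate trajectories of the same model, plus the fraction of bonds
#' with mean occurrence above the stability cutoff.
#'
#' @param table An `occurrence_table` whose columns are replicate runs.
#' @param stable_cut Stability cutoff for the summary fraction (0.90).
#' @return List: `per_bond` data frame (`key`, `label`, `mean`, `sd`,
#'   `cv`; `cv` is `NA` where the mean is 0) and `frac_stable`.
#' @export
replicate_reproducibility <- function(table, stable_cut = 0.90) {
  occ <- table$occurrence
  if (ncol(occ) < 2) stop("need >= 2 replicates")
  mu <- rowMeans(occ)
  sdv <- apply(occ, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  list(per_bond = data.frame(key = table$bonds$key, label = table$bonds$label,
                             mean = mu, sd = sdv, cv = cv,
                             stringsAsFactors = FALSE),
       frac_stable = mean(mu > stable_cut))
}

#' Recovery of reference (crystal-structure) bonds at a stability cutoff
#'
#' Given a list of reference bonds observed in a crystal structure,
#' reports the fraction classified stable in the trajectory per bond
#' class (e.g. Watson-Crick, main-chain, other).  Reference bonds whose
#' key is absent from the table count as not recovered; bonds that cannot
#' be resolved against the topology at all are excluded with a warning
#' and reported.
#'
#' @param table An `occurrence_table` (occurrences averaged over models).
#' @param reference Data frame with columns `key` (heavy-atom bond key as
#'   produced by the package, `"chain:resnum:atom--chain:resnum:atom"`)
#'   and `class`.
#' @param stable_cut Stability cutoff (default 0.90).
#' @return List: `by_class` (named recovered fractions), `detail` data
#'   frame, `unresolved` character vector of excluded keys.
#' @export
compare_to_reference <- function(table, reference, stable_cut = 0.90) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("empty reference bond list")
  mu <- rowMeans(table$occurrence)
  names(mu) <- table$bonds$key
  valid_atoms <- function(k) {
    parts <- strsplit(k, "--", fixed = TRUE)[[1]]
    length(parts) == 2 && all(grepl("^[^:]*:-?[0-9]+:.+$", parts))
  }
  resolvable <- vapply(reference$key, valid_atoms, TRUE)
  unresolved <- reference$key[!resolvable]
  if (length(unresolved))
    warning("excluded unresolvable reference bond(s): ",
            paste(unresolved, collapse = ", "))
  ref <- reference[resolvable, , drop = FALSE]
  occ <- mu[ref$key]
  occ[is.na(occ)] <- 0
  recovered <- occ > stable_cut
  by_class <- tapply(recovered, ref$class, mean)
  list(by_class = by_class,
       detail = data.frame(key = ref$key, class = ref$class,
                           occurrence = unname(occ), recovered = recovered,
                           stringsAsFactors = FALSE),
       unresolved = unresolved)
}
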