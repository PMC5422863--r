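#' @title Water-mediated bridge detection and census
#' @description Waters simultaneously hydrogen-bonded to two (pair) or
#'   three (triplet) protein/DNA partners in one snapshot, censused over a
#'   trajectory with quartile-based retention thresholds, and detection of
#'   multi-water bridges between fixed partner pairs.
#' @name water-bridges
NULL

# water <-> non-water hydrogen bonds of one snapshot: returns data frame
# (water res_index, partner atom index)
water_partner_bonds <- function(coords, top, params) {
  hb <- detect_hbonds(coords, top, params)
  if (nrow(hb) == 0)
    return(data.frame(water = integer(), partner = integer()))
  cls <- top$residues$class[match(top$atoms$res_index, top$residues$res_index)]
  dw <- cls[hb$donor] == "water"; aw <- cls[hb$acceptor] == "water"
  keep1 <- dw & !aw   # water donates to a partner
  keep2 <- aw & !dw   # partner donates to water
  rbind(
    data.frame(water = top$atoms$res_index[hb$donor[keep1]],
               partner = hb$acceptor[keep1]),
    data.frame(water = top$atoms$res_index[hb$acceptor[keep2]],
               partner = hb$donor[keep2])
  )
}

# canonical partner-set key; `merge_map` maps atom index -> logical partner id
partner_set_key <- function(ids) paste(sort(unique(ids)), collapse = "+")

# build atom -> logical-partner labels, merging chemically equivalent
# carboxylate / phosphate oxygens into one logical partner
logical_partner_ids <- function(top, merge_equivalent = TRUE,
                                merge_phosphate = FALSE) {
  a <- top$atoms
  id <- paste0(a$chain, ":", a$resnum, ":", a$name)
  if (merge_equivalent) {
    carbox <- list(c("OE1", "OE2"), c("OD1", "OD2"))
    for (grp in carbox) {
      hit <- a$name %in% grp
      id[hit] <- paste0(a$chain[hit], ":", a$resnum[hit], ":",
                        paste(grp, collapse = "/"))
    }
  }
  if (merge_phosphate) {
    grp <- c("O1P", "O2P", "OP1", "OP2")
    hit <- a$name %in% grp
    id[hit] <- paste0(a$chain[hit], ":", a$resnum[hit], ":O1P/O2P")
  }
  id
}

#' Detect water bridges in one snapshot
#'
#' For every water hydrogen-bonded to k >= 2 non-water partners, emits
#' all C(k,2) partner pairs and C(k,3) triplets.  Chemically equivalent
#' acceptor atoms (Glu/Asp carboxylate oxygens by default) collapse to a
#' single logical partner before the combinatorics.
#'
#' @param coords `n_atoms x 3` snapshot coordinates.
#' @param topology Annotated `topology`.
#' @param params See [hbond_params()].
#' @param merge_equivalent Merge Glu/Asp carboxylate oxygen pairs.
#' @param merge_phosphate Also merge non-bridging phosphate oxygens.
#' @return List with `pairs` and `triplets`: data frames of `key`
#'   (canonical sorted logical-partner set) and `water` (water residue
#'   index), one row per (water, set) membership.
#' @export
detect_bridges <- function(coords, topology, params = hbond_params(),
                           merge_equivalent = TRUE, merge_phosphate = FALSE) {
  wp <- water_partner_bonds(coords, topology, params)
  lid <- logical_partner_ids(topology, merge_equivalent, merge_phosphate)
  out_pairs <- list(); out_trip <- list()
  if (nrow(wp)) {
    wp$pid <- lid[wp$partner]
    for (w in unique(wp$water)) {
      ps <- unique(wp$pid[wp$water == w])
      k <- length(ps)
      if (k < 2) next
      cb2 <- utils::combn(sort(ps), 2)
      out_pairs[[length(out_pairs) + 1]] <-
        data.frame(key = apply(cb2, 2, paste, collapse = "+"), water = w,
                   stringsAsFactors = FALSE)
      if (k >= 3) {
        cb3 <- utils::combn(sort(ps), 3)
        out_trip[[length(out_trip) + 1]] <-
          data.frame(key = apply(cb3, 2, paste, collapse = "+"), water = w,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(
    pairs = if (length(out_pairs)) do.call(rbind, out_pairs)
            else data.frame(key = character(), water = integer()),
    triplets = if (length(out_trip)) do.call(rbind, out_trip)
               else data.frame(key = character(), water = integer())
  )
}

#' Census of water bridges over a trajectory
#'
#' Counts, per partner set, the snapshots in which at least one water
#' bridges the full set.  A snapshot counts once per partner set even
#' when several waters bridge it simultaneously; the multiplicity is kept
#' in a per-set histogram of the number of simultaneously bridging
#' waters.
#'
#' @param traj A `trajectory`.
#' @param params See [hbond_params()].
#' @param floor Existence floor as a fraction of snapshots (default 0:
#'   keep everything).
#' @param merge_equivalent,merge_phosphate See [detect_bridges()].
#' @return A `bridge_census`: list with `pairs` and `triplets` data
#'   frames (`key`, `count`, `fraction`, `max_waters`, plus `nw1`,
#'   `nw2`, ... columns of the n-waters histogram) and `n_snapshots`.
#' @export
bridge_census <- function(traj, params = hbond_params(), floor = 0,
                          merge_equivalent = TRUE, merge_phosphate = FALSE) {
  ns <- n_snapshots(traj)
  tallies <- list(pairs = new.env(parent = emptyenv(), hash = TRUE),
                  triplets = new.env(parent = emptyenv(), hash = TRUE))
  for (s in seq_len(ns)) {
    br <- detect_bridges(traj$coords[, , s], traj$topology, params,
                         merge_equivalent, merge_phosphate)
    for (kind in c("pairs", "triplets")) {
      df <- br[[kind]]
      if (nrow(df) == 0) next
      nw <- table(df$key)  # waters per partner set this snapshot
      env <- tallies[[kind]]
      for (k in names(nw)) {
        rec <- env[[k]]
        if (is.null(rec)) rec <- integer(0)
        m <- as.integer(nw[[k]])
        if (m > length(rec)) rec <- c(rec, integer(m - length(rec)))
        rec[m] <- rec[m] + 1L
        env[[k]] <- rec
      }
    }
  }
  to_df <- function(env) {
    keys <- sort(ls(env))
    if (length(keys) == 0)
      return(data.frame(key = character(), count = integer(),
                        fraction = numeric(), max_waters = integer()))
    maxw <- max(vapply(keys, function(k) length(env[[k]]), 1L))
    hist <- do.call(rbind, lapply(keys, function(k) {
      h <- env[[k]]
      c(h, integer(maxw - length(h)))
    }))
    colnames(hist) <- paste0("nw", seq_len(maxw))
    cnt <- rowSums(hist)
    df <- data.frame(key = keys, count = as.integer(cnt), fraction = cnt / ns,
                     max_waters = apply(hist, 1, function(h) max(which(h > 0))),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(hist))
  }
  pairs <- to_df(tallies$pairs)
  trips <- to_df(tallies$triplets)
  if (floor > 0) {
    pairs <- pairs[pairs$fraction > floor, , drop = FALSE]
    trips <- trips[trips$fraction > floor, , drop = FALSE]
  }
  structure(list(pairs = pairs, triplets = trips, n_snapshots = ns),
            class = "bridge_census")
}

#' @export
print.bridge_census <- function(x, ...) {
  cat(sprintf("<bridge_census> %d pair set(s), %d triplet set(s) over %d snapshots\n",
              nrow(x$pairs), nrow(x$triplets), x$n_snapshots))
  invisible(x)
}

#' Retention thresholds for a bridge census
#'
#' Two modes. `"fixed"`: retain pair sets with count > 2000 and triplet
#' sets with count > 1500 on a 5000-snapshot trajectory, rescaled
#' proportionally for other lengths - the conventional cutoffs that
#' discard the lowest quartile of total bridge occurrences.
#' `"quantile"`: find, separately for pairs and triplets, the largest
#' count cutoff such that the retained sets still account for more than
#' `share` (default 0.75) of all occurrences; the threshold is a level
#' set, so every retained record's count is >= every dropped record's
#' count.
#'
#' @param census A `bridge_census`.
#' @param mode `"fixed"` or `"quantile"`.
#' @param pair_threshold,triplet_threshold Fixed-mode counts at 5000
#'   snapshots.
#' @param share Quantile-mode cumulative occurrence share to retain.
#' @return The census with logical `retained` columns added and an
#'   attribute `thresholds` recording the count cutoffs used.
#' @export
apply_thresholds <- function(census, mode = c("fixed", "quantile"),
                             pair_threshold = 2000, triplet_threshold = 1500,
                             share = 0.75) {
  mode <- match.arg(mode)
  scale <- census$n_snapshots / 5000
  th <- c(pairs = NA_real_, triplets = NA_real_)
  for (kind in c("pairs", "triplets")) {
    df <- census[[kind]]
    if (nrow(df) == 0) { census[[kind]]$retained <- logical(0); next }
    if (mode == "fixed") {
      cut <- (if (kind == "pairs") pair_threshold else triplet_threshold) * scale
      df$retained <- df$count > cut
    } else {
      cnt <- sort(df$count, decreasing = TRUE)
      cum <- cumsum(cnt) / sum(cnt)
      need <- which(cum > share)[1]
      cut <- cnt[need]          # retain all records with count >= cut
      df$retained <- df$count >= cut
      cut <- cut - 0.5          # report as a strict threshold between levels
    }
    th[kind] <- cut
    census[[kind]] <- df
  }
  attr(census, "thresholds") <- th
  census
}

#' Multi-water bridging of one partner pair over a trajectory
#'
#' Per snapshot, the number of distinct waters each hydrogen-bonded to
#' both partners, and an indicator of whether at least `min_waters`
#' bridge simultaneously - the signature of a tightly coordinated
#' double-water site.
#'
#' @param traj A `trajectory`.
#' @param partner_a,partner_b Partner atom indices (heavy atoms), or
#'   logical-partner id strings as used in census keys.
#' @param min_waters Minimum simultaneous waters (default 2).
#' @param params See [hbond_params()].
#' @param merge_equivalent,merge_phosphate See [detect_bridges()].
#' @return List: `n_waters` integer vector per snapshot, `indicator`
#'   logical vector, `occurrence` count of indicator-true snapshots.
#' @export
multi_water_bridges <- function(traj, partner_a, partner_b, min_waters = 2,
                                params = hbond_params(),
                                merge_equivalent = TRUE, merge_phosphate = FALSE) {
  top <- traj$topology
  lid <- logical_partner_ids(top, merge_equivalent, merge_phosphate)
  pid <- function(p) if (is.character(p)) p else lid[as.integer(p)]
  pa <- pid(partner_a); pb <- pid(partner_b)
  ns <- n_snapshots(traj)
  nwat <- integer(ns)
  for (s in seq_len(ns)) {
    wp <- water_partner_bonds(traj$coords[, , s], top, params)
    if (nrow(wp) == 0) next
    wp$pid <- lid[wp$partner]
    per_water <- split(wp$pid, wp$water)
    nwat[s] <- sum(vapply(per_water, function(ps) pa %in% ps && pb %in% ps, TRUE))
  }
  ind <- nwat >= min_waters
  list(n_waters = nwat, indicator = ind, occurrence = sum(ind))
}
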