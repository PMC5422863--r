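#' @title Catalytic-geometry census
#' @description Tracks the nucleophilic-attack distances and angles of the
#'   Pro1-Glu2 catalytic dyad relative to the everted lesion, evaluates
#'   the four-criterion "optimal geometry" per snapshot, and summarizes
#'   series distributions (median, 90% range, modality).
#' @name active-site-census
NULL

#' Optimal-geometry criteria
#'
#' The four-parameter definition of a catalytically poised snapshot: the
#' attacking amine close to the anomeric carbon (`d1 = N...C1' <
#' d1_max`), the proton-donor carboxylate close to the ring oxygen
#' (`d2 = Oe2...O4' < d2_max`), and the two attack angles within
#' `angle_tolerance` of their ideals - 107 degrees for C1'...N...Cd
#' (tetrahedral approach of the secondary amine) and 180 degrees for
#' O4'...C1'...N (in-line S_N_2 displacement of O4').
#'
#' @param d1_max N...C1' cutoff, Angstrom (default 4).
#' @param d2_max Oe2...O4' cutoff, Angstrom (default 4.5).
#' @param ideal_angle1 Ideal C1'...N...Cd angle (degrees, 107).
#' @param ideal_angle2 Ideal O4'...C1'...N angle (degrees, 180).
#' @param angle_tolerance Symmetric, boundary-inclusive tolerance
#'   (degrees, 20).
#' @return A `census_criteria` list.
#' @export
census_criteria <- function(d1_max = 4, d2_max = 4.5, ideal_angle1 = 107,
                            ideal_angle2 = 180, angle_tolerance = 20) {
  stopifnot(d1_max > 0, d2_max > 0,
            angle_tolerance > 0, angle_tolerance < 90)
  structure(list(d1_max = d1_max, d2_max = d2_max,
                 ideal_angle1 = ideal_angle1, ideal_angle2 = ideal_angle2,
                 angle_tolerance = angle_tolerance),
            class = "census_criteria")
}

#' Catalytic distance/angle series bundle
#'
#' The five aligned series describing the attack geometry: `d1`
#' (N...C1'), `d2` (Oe2...O4'), `angle1` (C1'...N...Cd), `angle2`
#' (O4'...C1'...N), `angle_n9` (N9...C1'...N).
#'
#' @param traj A `trajectory`.
#' @param atoms Named list/vector of atom indices: `pro_n`, `pro_cd`,
#'   `glu_oe2`, `c1`, `o4`, `n9` (see [atom_index()]).  `n9` may be `NA`
#'   for lesions without it; its series is then masked.
#' @return Named list of `geom_series`.
#' @export
catalytic_series <- function(traj, atoms) {
  need <- c("pro_n", "pro_cd", "glu_oe2", "c1", "o4")
  for (nm in need)
    if (is.null(atoms[[nm]]) || is.na(atoms[[nm]]))
      stop("catalytic atom map missing: ", nm)
  out <- list(
    d1 = distance_series(traj, atoms$pro_n, atoms$c1, name = "d1 N...C1'"),
    d2 = distance_series(traj, atoms$glu_oe2, atoms$o4, name = "d2 Oe2...O4'"),
    angle1 = angle_series(traj, atoms$c1, atoms$pro_n, atoms$pro_cd,
                          name = "angle1 C1'...N...Cd"),
    angle2 = angle_series(traj, atoms$o4, atoms$c1, atoms$pro_n,
                          name = "angle2 O4'...C1'...N")
  )
  out$angle_n9 <- if (!is.null(atoms$n9) && !is.na(atoms$n9))
    angle_series(traj, atoms$n9, atoms$c1, atoms$pro_n,
                 name = "angle_n9 N9...C1'...N")
  else geom_series(rep(NA_real_, n_snapshots(traj)), name = "angle_n9",
                   unit = "degree", mask = rep(FALSE, n_snapshots(traj)))
  out
}

#' Census of snapshots with optimal attack geometry
#'
#' A snapshot is optimal when `d1 < d1_max`, `d2 < d2_max`,
#' `|angle1 - ideal1| <= tol` and `|angle2 - ideal2| <= tol` all hold.
#'
#' @param series Bundle from [catalytic_series()] (or any list with
#'   `d1`, `d2`, `angle1`, `angle2`).
#' @param criteria See [census_criteria()].
#' @return List: `count`, `fraction`, `mask` (per-snapshot logical).
#' @export
optimal_geometry_census <- function(series, criteria = census_criteria()) {
  v <- lapply(series[c("d1", "d2", "angle1", "angle2")], series_values)
  n <- unique(vapply(v, length, 1L))
  if (length(n) != 1) stop("series are not aligned")
  tol <- criteria$angle_tolerance
  mask <- v$d1 < criteria$d1_max &
    v$d2 < criteria$d2_max &
    abs(v$angle1 - criteria$ideal_angle1) <= tol &
    abs(v$angle2 - criteria$ideal_angle2) <= tol
  mask[is.na(mask)] <- FALSE
  list(count = sum(mask), fraction = mean(mask), mask = mask)
}

#' Summary of a per-snapshot series distribution
#'
#' Median, central 90% range (5th-95th percentiles), a Freedman-Diaconis
#' histogram, and a peak count: the number of local maxima of the 3-bin
#' smoothed histogram above 10% of the global maximum.  Two peaks flag a
#' bimodal series, i.e. two stable conformational basins.
#'
#' @param series A `geom_series` or numeric vector (>= 20 valid values
#'   for stable percentiles).
#' @return A `series_summary`: list with `median`, `range90`, `histogram`
#'   (an object from [graphics::hist()], not plotted), `n_peaks`, `n`.
#' @export
summarize_series <- function(series) {
  x <- series_values(series)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("all-masked series cannot be summarized")
  if (length(x) < 20)
    warning("fewer than 20 valid values; percentiles may be unstable")
  med <- stats::median(x)
  rng <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  if (stats::sd(x) == 0) {
    h <- list(breaks = c(x[1] - 0.5, x[1] + 0.5), counts = length(x),
              mids = x[1])
    peaks <- 1L
  } else {
    nb <- max(1, grDevices::nclass.FD(x))
    h <- graphics::hist(x, breaks = nb, plot = FALSE)
    cnt <- as.numeric(h$counts)
    sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- cnt[is.na(sm)]
    sm <- as.numeric(sm)
    lim <- 0.1 * max(sm)
    peaks <- 0L
    k <- length(sm)
    for (i in seq_len(k)) {
      left <- if (i > 1) sm[i - 1] else -Inf
      right <- if (i < k) sm[i + 1] else -Inf
      if (sm[i] > lim && sm[i] > left && sm[i] >= right) peaks <- peaks + 1L
    }
    peaks <- max(peaks, 1L)
  }
  structure(list(median = med, range90 = rng, histogram = h,
                 n_peaks = peaks, n = length(x)),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("median %.3g (90%% range %.3g-%.3g), %d peak(s), n = %d\n",
              x$median, x$range90[1], x$range90[2], x$n_peaks, x$n))
  invisible(x)
}

#' Table-style report of catalytic geometry per model
#'
#' One row per model: median (90% range) of the four catalytic
#' parameters plus the optimal-geometry snapshot count.
#'
#' @param bundles Named list of [catalytic_series()] bundles, one per
#'   model.
#' @param criteria See [census_criteria()].
#' @return Data frame with formatted `median (lo-hi)` cells and the
#'   optimal count/fraction.
#' @export
catalytic_report <- function(bundles, criteria = census_criteria()) {
  fmt <- function(s) {
    z <- summarize_series(s)
    sprintf("%.2f (%.2f-%.2f)", z$median, z$range90[1], z$range90[2])
  }
  rows <- lapply(names(bundles), function(nm) {
    b <- bundles[[nm]]
    cen <- optimal_geometry_census(b, criteria)
    data.frame(model = nm, d1 = fmt(b$d1), d2 = fmt(b$d2),
               angle1 = fmt(b$angle1), angle2 = fmt(b$angle2),
               optimal_count = cen$count, optimal_fraction = cen$fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
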