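#' @title Trajectory comparison statistics
#' @description Moving-window Mann-Whitney Z between two series, variance
#'   F-tests, and Benjamini-Hochberg false-discovery-rate control.
#' @name trajectory-stats
NULL

# tie-corrected Mann-Whitney U -> Z for one pair of bins
mwz_bin <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mU <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  s2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (s2 <= 0) return(c(U = U, Z = 0, p = 1, tied = 1))
  Z <- (U - mU) / sqrt(s2)
  c(U = U, Z = Z, p = 2 * stats::pnorm(-abs(Z)), tied = 0)
}

#' Moving Mann-Whitney Z comparison of two series
#'
#' Splits two aligned series into windows and computes, per window, the
#' Mann-Whitney U between the two series' values in that window, with the
#' tie-corrected normal approximation `Z = (U - m_U) / sigma_U` and a
#' two-sided p-value.  Windows are disjoint bins by default (`floor(n /
#' bin)` of them); `disjoint = FALSE` slides the window by one snapshot.
#' All-tied windows give Z = 0 and are flagged.
#'
#' @param series_a,series_b `geom_series` or numeric vectors of equal
#'   length.
#' @param bin Window size in snapshots (default 50).
#' @param disjoint Disjoint bins (default) or sliding window.
#' @return Data frame: `window`, `start`, `end` (snapshot indices), `U`,
#'   `Z`, `p`, `all_tied`.
#' @export
moving_mwz <- function(series_a, series_b, bin = 50, disjoint = TRUE) {
  a <- series_values(series_a)
  b <- series_values(series_b)
  if (length(a) != length(b)) stop("series must have equal length")
  n <- length(a)
  if (bin > n) stop("bin exceeds series length")
  starts <- if (disjoint) seq(1, n - bin + 1, by = bin)
            else seq(1, n - bin + 1, by = 1)
  out <- t(vapply(starts, function(s) {
    ii <- s:(s + bin - 1)
    mwz_bin(a[ii], b[ii])
  }, numeric(4)))
  data.frame(window = seq_along(starts), start = starts,
             end = starts + bin - 1, U = out[, 1], Z = out[, 2],
             p = out[, 3], all_tied = out[, 4] > 0)
}

#' F-test for a variance difference between two series
#'
#' Ratio of sample variances with the larger variance in the numerator
#' (convention recorded in the output) and a two-sided p-value from the F
#' distribution; delegates to [stats::var.test()].
#'
#' @param series_a,series_b `geom_series` or numeric vectors (n >= 2
#'   each).
#' @return List: `F`, `df` (length-2), `p`, `larger` (`"a"`/`"b"`:
#'   which series supplied the numerator), `flagged` (TRUE when one
#'   variance is zero, giving p = 0).
#' @export
f_test_variance <- function(series_a, series_b) {
  a <- series_values(series_a)
  b <- series_values(series_b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per series")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both series have zero variance")
  if (va == 0 || vb == 0) {
    larger <- if (va >= vb) "a" else "b"
    return(list(F = Inf, df = c(length(a) - 1, length(b) - 1), p = 0,
                larger = larger, flagged = TRUE))
  }
  if (va >= vb) {
    vt <- stats::var.test(a, b); larger <- "a"
  } else {
    vt <- stats::var.test(b, a); larger <- "b"
  }
  list(F = unname(vt$statistic), df = unname(vt$parameter), p = vt$p.value,
       larger = larger, flagged = FALSE)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard FDR control: reject the `k` smallest p-values where `k` is
#' the largest rank with `p_(k) <= k * q / m`.  Adjusted values come from
#' [stats::p.adjust()] and form a monotone envelope.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return List: `rejected` (logical, in input order), `adjusted`
#'   (BH-adjusted p-values), `k` (number of rejections).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0)
    return(list(rejected = logical(0), adjusted = numeric(0), k = 0L))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  rejected <- adj <= q
  list(rejected = rejected, adjusted = adj, k = sum(rejected))
}

#' Family-wise comparison report for named parameter series
#'
#' Runs [f_test_variance()] on each named pair of series and applies
#' Benjamini-Hochberg across the family.  The family composition (which
#' parameters enter) is the caller's declaration.
#'
#' @param pairs Named list; each element a list/pair of two series.
#' @param q Target FDR.
#' @return Data frame: `parameter`, `F`, `p`, `p_adjusted`, `rejected`.
#' @export
compare_parameters <- function(pairs, q = 0.05) {
  res <- lapply(pairs, function(pr) f_test_variance(pr[[1]], pr[[2]]))
  p <- vapply(res, function(r) r$p, 0)
  bh <- benjamini_hochberg(p, q)
  data.frame(parameter = names(pairs),
             F = vapply(res, function(r) r$F, 0),
             p = p, p_adjusted = bh$adjusted, rejected = bh$rejected,
             row.names = NULL, stringsAsFactors = FALSE)
}
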