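#' Per-snapshot scalar series
#'
#' A `geom_series` holds one named scalar per trajectory snapshot
#' (distance, angle, torsion, area, ...), an optional validity mask, and
#' the unit.  Torsion-like series carry `wrap = TRUE` so that averaging
#' operations treat them as circular quantities.
#'
#' @param values Numeric vector.
#' @param name Series name.
#' @param unit One of `"A"`, `"degree"`, `"A^2"`, `"dimensionless"`.
#' @param mask Logical vector, `TRUE` where the value is valid.
#' @param wrap `TRUE` for circular (torsion) series.
#' @return A `geom_series` object.
#' @export
geom_series <- function(values, name = "series",
                        unit = c("A", "degree", "A^2", "dimensionless"),
                        mask = NULL, wrap = FALSE) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(length(mask) == length(values))
  structure(list(values = values, name = name, unit = unit,
                 mask = mask, wrap = wrap),
            class = "geom_series")
}

#' @export
print.geom_series <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<geom_series> '%s' (%s): %d snapshots (%d valid)\n",
              x$name, x$unit, length(x$values), sum(x$mask)))
  if (length(v))
    cat(sprintf("  median %.3f, range [%.3f, %.3f]\n",
                stats::median(v), min(v), max(v)))
  invisible(x)
}

#' @export
length.geom_series <- function(x) length(x$values)

#' @export
as.double.geom_series <- function(x, ...) {
  out <- x$values
  out[!x$mask] <- NA_real_
  out
}

# internal accessor used where dispatch of as.numeric() would be fragile
series_values <- function(x) {
  if (inherits(x, "geom_series")) as.double.geom_series(x) else as.numeric(x)
}

#' Centered moving average of a series
#'
#' Windowed mean over valid values, used to smooth per-snapshot traces
#' before plotting (the conventional 50-snapshot smoothing of MD series).
#' Circular series (torsions) are averaged via the vector (sin/cos) mean so
#' that values straddling the +/-180 degree seam do not collapse to 0.
#'
#' @param series A `geom_series` (or plain numeric vector).
#' @param window Window width in snapshots (odd widths are centered
#'   exactly; even widths take one extra trailing point).
#' @param circular Override the series' `wrap` flag.
#' @return A `geom_series` of the same length; positions whose window
#'   contains no valid value are masked.
#' @export
moving_average <- function(series, window = 50, circular = NULL) {
  if (!inherits(series, "geom_series"))
    series <- geom_series(series, unit = "dimensionless")
  if (window < 1) stop("window must be >= 1")
  n <- length(series$values)
  if (window > n) {
    warning("window longer than series; all values masked")
    return(geom_series(rep(NA_real_, n), name = series$name, unit = series$unit,
                       mask = rep(FALSE, n), wrap = series$wrap))
  }
  circ <- if (is.null(circular)) isTRUE(series$wrap) else circular
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  v <- series$values
  ok <- series$mask & is.finite(v)
  # cumulative sums over (value * valid) give O(n) windowed means
  win_mean <- function(x) {
    x0 <- ifelse(ok, x, 0)
    cs <- cumsum(x0)
    cnt <- cumsum(as.numeric(ok))
    i <- seq_len(n)
    lo <- pmax(1L, i - half_lo)
    hi <- pmin(n, i + half_hi)
    s <- cs[hi] - c(0, cs)[lo]
    m <- cnt[hi] - c(0, cnt)[lo]
    list(sum = s, count = m)
  }
  if (circ) {
    rad <- v * pi / 180
    s1 <- win_mean(sin(rad))
    s2 <- win_mean(cos(rad))
    cnt <- s1$count
    out <- atan2(s1$sum, s2$sum) * 180 / pi
    out[cnt == 0] <- NA_real_
  } else {
    s <- win_mean(v)
    cnt <- s$count
    out <- s$sum / cnt
    out[cnt == 0] <- NA_real_
  }
  geom_series(out, name = paste0(series$name, " (ma", window, ")"),
              unit = series$unit, mask = cnt > 0, wrap = series$wrap)
}
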