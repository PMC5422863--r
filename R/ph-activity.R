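#' @title Two-state ionization model for pH-activity profiles
#' @description A single titratable group controls activity:
#'   `activity(pH) = B + A / (1 + 10^(pKa - pH))` rises from baseline `B`
#'   to `B + A` through one inflection at `pH = pKa`.  Fits report the
#'   pKa with Jacobian-based standard errors.
#' @name ph-activity
NULL

#' Two-state ionization model
#'
#' @param pH Numeric pH values.
#' @param pKa Midpoint of the transition.
#' @param A Amplitude (activity gained on deprotonation).
#' @param B Baseline activity.
#' @return Model activity; equals `B + A/2` at `pH = pKa`, `B` far below
#'   and `B + A` far above the transition.
#' @export
two_state_model <- function(pH, pKa, A, B) {
  B + A / (1 + 10^(pKa - pH))
}

#' Fit the two-state model to a pH-activity curve
#'
#' Levenberg-Marquardt nonlinear least squares
#' (via [minpack.lm::nlsLM()]) with data-driven initialization: `B` from
#' the minimum activity, `A` from the activity range, and `pKa` from the
#' pH at the half-range crossing by linear interpolation.  Standard
#' errors come from the Jacobian-based covariance.  Designs that do not
#' span the transition are flagged (or fail) rather than returning a
#' spuriously confident pKa: the fit is marked non-identifiable when
#' `se["pKa"] > 1` or when the fitted midpoint falls outside the sampled
#' pH range (an extrapolated inflection).
#'
#' @param pH,activity Numeric vectors (>= 4 distinct pH points).
#' @param start Optional named list overriding the automatic starting
#'   values.
#' @return A `two_state_fit`: list with `pKa`, `A`, `B`, `se` (named
#'   standard errors), `residuals`, `fitted`, `rss`, `identifiable`
#'   (FALSE when `se["pKa"] > 1`), and the underlying `fit` object.
#' @export
fit_two_state <- function(pH, activity, start = NULL) {
  if (length(pH) != length(activity)) stop("pH and activity lengths differ")
  if (anyDuplicated(pH)) {
    # replicates are allowed; distinctness is required of the design points
    if (length(unique(pH)) < 4) stop("need >= 4 distinct pH points")
  } else if (length(pH) < 4) stop("need >= 4 points")
  if (any(activity < 0)) stop("activity must be non-negative")
  o <- order(pH)
  pHo <- pH[o]; yo <- activity[o]
  if (is.null(start)) {
    B0 <- min(yo); A0 <- max(yo) - B0
    half <- B0 + A0 / 2
    above <- which(yo >= half)
    pKa0 <- if (length(above) == 0 || above[1] == 1) stats::median(pHo)
    else {
      i <- above[1]
      pHo[i - 1] + (half - yo[i - 1]) / (yo[i] - yo[i - 1]) * (pHo[i] - pHo[i - 1])
    }
    start <- list(pKa = pKa0, A = max(A0, .Machine$double.eps), B = B0)
  }
  dat <- data.frame(pH = pH, activity = activity)
  fit <- tryCatch(
    minpack.lm::nlsLM(activity ~ two_state_model(pH, pKa, A, B),
                      data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("two-state fit failed to converge: ", conditionMessage(e),
           " (best start: pKa=", signif(start$pKa, 4), ")"))
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  structure(list(pKa = unname(est["pKa"]), A = unname(est["A"]),
                 B = unname(est["B"]), se = se,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 rss = sum(stats::residuals(fit)^2),
                 identifiable = is.finite(se["pKa"]) && se["pKa"] <= 1 &&
                   est["pKa"] >= min(pH) && est["pKa"] <= max(pH),
                 fit = fit),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state ionization fit: pKa = %.2f +/- %.2f, A = %.3g, B = %.3g\n",
              x$pKa, x$se["pKa"], x$A, x$B))
  if (!x$identifiable)
    cat("  warning: pKa poorly identified (SE > 1); design may not span the transition\n")
  invisible(x)
}

#' Read a delimited pH-activity table
#'
#' Whitespace- or comma-separated columns `pH`, `activity` and optional
#' `replicate`; `#` comments allowed; a header line is detected
#' automatically.
#'
#' @param path File path.
#' @return Data frame with `pH`, `activity` (and `replicate` if present).
#' @export
read_ph_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#", fill = TRUE)
  if (!all(c("pH", "activity") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#")
    names(df)[1:2] <- c("pH", "activity")
    if (ncol(df) >= 3) names(df)[3] <- "replicate"
  }
  df
}
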