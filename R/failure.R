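#' Cross-sectional area from diameter measurements
#'
#' The smallest of the measured diameters is used to compute CSA assuming a
#' circular cross-section: `csa = pi * d^2 / 4`.
#'
#' @param diameters numeric vector of diameters, mm (all > 0).
#' @param gaugeLength optional gauge length, mm, carried along.
#' @return list with `smallest_diameter` (mm), `csa` (mm^2), `gauge_length`.
#' @examples
#' computeCSA(c(0.52, 0.50, 0.55))$csa  # pi * 0.5^2 / 4
#' @export
computeCSA <- function(diameters, gaugeLength = NA_real_) {
  if (!length(diameters)) stop("validation error: empty diameter list")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("validation error: diameters must all be > 0")
  d <- min(diameters)
  list(smallest_diameter = d, csa = pi * d^2 / 4, gauge_length = gaugeLength)
}

#' Convert a ramp to stress-strain
#'
#' Engineering stress `sigma = F / csa` (N/mm^2 = MPa) and strain
#' `epsilon = 100 * x / gauge_length` (%), at the ramp's sampling.
#'
#' @param force N; `extension` mm.
#' @param extension mm.
#' @param geometry list from [computeCSA()] (needs `csa` and `gauge_length`).
#' @return data frame with `stress_MPa`, `strain_pct`.
#' @export
toStressStrain <- function(force, extension, geometry) {
  if (is.null(geometry$csa) || !is.finite(geometry$csa) || geometry$csa <= 0)
    stop("geometry with positive csa required")
  if (!is.finite(geometry$gauge_length) || geometry$gauge_length <= 0)
    stop("geometry with positive gauge_length required")
  data.frame(stress_MPa = force / geometry$csa,
             strain_pct = 100 * extension / geometry$gauge_length)
}

#' Continuous tangent slope over a sliding window
#'
#' Ordinary least-squares slope of `y` on `x` within every sliding window of
#' `window` consecutive points (stride 1), the construction behind the
#' continuous modulus (stress-strain, MPa) and continuous stiffness
#' (force-extension, N/mm) curves.  Window centres are the window-mean
#' abscissae; `centre_index` is the centre sample (index
#' `start + floor(window/2)`).
#'
#' @param x,y numeric vectors (equal length >= `window`).
#' @param window window size in samples (default 10).
#' @return data frame with `start`, `centre_index`, `centre_x`, `slope`; one
#'   row per window (`length(x) - window + 1` rows).
#' @export
continuousSlope <- function(x, y, window = 10L) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  n <- length(x)
  if (n < window)
    stop(sprintf("need at least %d samples, got %d", window, n))
  starts <- seq_len(n - window + 1L)
  slope <- vapply(starts, function(i) {
    xi <- x[i:(i + window - 1L)]; yi <- y[i:(i + window - 1L)]
    dx <- xi - mean(xi)
    sum(dx * (yi - mean(yi))) / sum(dx * dx)
  }, numeric(1))
  centreX <- vapply(starts, function(i) mean(x[i:(i + window - 1L)]), numeric(1))
  data.frame(start = starts,
             centre_index = starts + window %/% 2L,
             centre_x = centreX, slope = slope)
}

#' Yield, failure and toe-profile metrics from a ramp to failure
#'
#' Implements the ramp-to-failure analysis for either phase.  Failure is the
#' (first) maximum of the raw ramp force; the continuous modulus (fascicle,
#' on stress versus strain-fraction, MPa) or stiffness (IFM, force versus
#' extension, N/mm) is the sliding 10-point OLS slope of the Savitzky-Golay
#' smoothed curve, over windows ending at or before the failure sample.  The
#' yield point is the centre sample of the first window attaining the
#' maximum slope; yield stress/strain (fascicle) or yield force/extension
#' (IFM) are read there.  The toe profile is the extension at which the
#' smoothed force first reaches each 10% step of the failure force (linear
#' interpolation between bracketing samples; 100% returns the failure
#' extension).
#'
#' @param trace a segmented [ForceExtensionTrace-class].
#' @param protocol a [TestProtocol-class].
#' @param geometry for fascicles, the [computeCSA()] result (with
#'   `gauge_length`); ignored for IFM.
#' @param toeGrid percentages of failure force for the toe profile.
#' @return one-row data frame: failure and yield metrics, `max_modulus_MPa`
#'   or `max_stiffness_N_mm`, `qc` flag, and `toe_ext_<p>` columns (mm).
#' @export
failureMetrics <- function(trace, protocol, geometry = NULL,
                           toeGrid = seq(10, 100, by = 10)) {
  idx <- segmentIndices(trace, "ramp")
  if (length(idx) < protocol@modulusWindow) stop("ramp segment too short")
  xx <- trace@extension[idx]; ffRaw <- trace@force[idx]
  fascicle <- protocol@phase == "fascicle"
  failIdx <- which.max(ffRaw)             # first occurrence by which.max
  failureForce <- ffRaw[failIdx]
  failureExtension <- xx[failIdx]
  # smooth only up to the failure point: the post-failure drop would bleed
  # into a full-trace smoothing frame and distort near-failure slopes
  ffSm <- ffRaw
  ffSm[seq_len(failIdx)] <- if (failIdx >= protocol@frameRamp)
    sgSmooth(ffRaw[seq_len(failIdx)], protocol@frameRamp, protocol@smoothOrder)
    else ffRaw[seq_len(failIdx)]
  if (fascicle) {
    if (is.null(geometry)) stop("fascicle analysis needs specimen geometry")
    ss <- toStressStrain(ffSm, xx, geometry)
    ax <- ss$strain_pct / 100             # strain-fraction basis for modulus
    ay <- ss$stress_MPa
  } else {
    ax <- xx
    ay <- ffSm
  }
  w <- protocol@modulusWindow
  if (failIdx < w) stop("failure occurs before the first full modulus window")
  sl <- continuousSlope(ax[seq_len(failIdx)], ay[seq_len(failIdx)], w)
  if (max(sl$slope) <= 0) {
    qc <- "nonpositive_max_slope"
    yieldIdx <- NA_integer_; maxSlope <- NA_real_
  } else {
    qc <- "ok"
    win <- which(sl$slope == max(sl$slope))[1]   # first window attaining max
    maxSlope <- sl$slope[win]
    yieldIdx <- sl$centre_index[win]
  }
  toe <- toeProfile(xx[seq_len(failIdx)], ffSm[seq_len(failIdx)],
                    failureForce, failureExtension, toeGrid)
  out <- data.frame(failure_force_N = failureForce,
                    failure_extension_mm = failureExtension)
  if (fascicle) {
    fss <- toStressStrain(failureForce, failureExtension, geometry)
    out$failure_stress_MPa <- fss$stress_MPa
    out$failure_strain_pct <- fss$strain_pct
    out$max_modulus_MPa <- maxSlope
    out$yield_stress_MPa <- if (is.na(yieldIdx)) NA_real_ else ay[yieldIdx]
    out$yield_strain_pct <- if (is.na(yieldIdx)) NA_real_ else 100 * ax[yieldIdx]
  } else {
    out$max_stiffness_N_mm <- maxSlope
    out$yield_force_N <- if (is.na(yieldIdx)) NA_real_ else ay[yieldIdx]
    out$yield_extension_mm <- if (is.na(yieldIdx)) NA_real_ else ax[yieldIdx]
  }
  out$yield_window_lo_mm <- if (qc == "ok") xx[sl$start[win]] else NA_real_
  out$yield_window_hi_mm <- if (qc == "ok") xx[sl$start[win] + w - 1L] else NA_real_
  out$qc <- qc
  for (j in seq_along(toeGrid))
    out[[sprintf("toe_ext_%d", as.integer(toeGrid[j]))]] <- toe[j]
  out
}

#' Toe-region extension profile
#'
#' Extension at which the (smoothed) ramp force first reaches each given
#' percentage of the failure force, by linear interpolation between the
#' bracketing samples.  100% returns the failure extension itself.
#'
#' @param extension,force ramp samples up to and including the failure sample.
#' @param failureForce failure force, N (> 0).
#' @param failureExtension extension at failure, mm.
#' @param grid percentages in (0, 100].
#' @return numeric vector of extensions (mm), same length as `grid`,
#'   non-decreasing.
#' @export
toeProfile <- function(extension, force, failureForce, failureExtension,
                       grid = seq(10, 100, by = 10)) {
  if (failureForce <= 0) stop("failureForce must be > 0")
  vapply(grid, function(p) {
    if (p >= 100) return(failureExtension)
    lev <- p / 100 * failureForce
    i <- which(force >= lev)[1]
    if (is.na(i))   # cannot occur when failureForce is the max of `force`
      stop("internal: force never reaches ", p, "% of failure force")
    if (i == 1L || force[i] == lev) return(extension[i])
    f0 <- force[i - 1L]; f1 <- force[i]
    extension[i - 1L] + (lev - f0) / (f1 - f0) * (extension[i] - extension[i - 1L])
  }, numeric(1))
}
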