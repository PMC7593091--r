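#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial low-pass filter used on the raw force data
#' before any metric is computed: third order with frame 15 for the
#' preconditioning data and frame 51 for the ramp to failure.  Endpoints are
#' handled by asymmetric full-window polynomial fits, so an order-p filter
#' reproduces polynomials up to degree p exactly over the whole series.
#'
#' @param series numeric vector.
#' @param frame odd window length, > `order`.
#' @param order polynomial order (default 3).
#' @return smoothed series, same length.
#' @examples
#' sgSmooth(sin(seq(0, 2 * pi, length.out = 200)) + rnorm(200, 0, 0.05), 15)
#' @export
sgSmooth <- function(series, frame, order = 3L) {
  frame <- as.integer(frame)
  if (frame %% 2L == 0L || frame <= order)
    stop("frame must be odd and greater than the polynomial order")
  if (length(series) < frame)
    stop("series shorter than the smoothing frame; skip smoothing for this segment")
  as.numeric(signal::sgolayfilt(series, p = order, n = frame))
}

#' Split a preconditioning segment into loading/unloading cycle branches
#'
#' Cycle boundaries are the extension minima between successive oscillations;
#' each cycle is split at its extension maximum into a loading branch
#' (extension rising) and an unloading branch (extension falling).  Adjacent
#' cycles share their boundary sample so that work integrals cover the branch
#' end-to-end.
#'
#' @param trace a segmented [ForceExtensionTrace-class] (see [segmentTrace()]).
#' @param protocol the [TestProtocol-class] used for smoothing constants and
#'   the expected cycle count.
#' @param smooth apply the protocol's Savitzky-Golay filter (frame
#'   `framePrecondition`) to the force before splitting.
#' @return a [CycleSet-class].
#' @export
splitCycles <- function(trace, protocol, smooth = TRUE) {
  idx <- segmentIndices(trace, "preconditioning")
  if (!length(idx)) stop("no preconditioning segment labelled")
  tt <- trace@time[idx]; xx <- trace@extension[idx]; ff <- trace@force[idx]
  if (smooth && length(ff) >= protocol@framePrecondition)
    ff <- sgSmooth(ff, protocol@framePrecondition, protocol@smoothOrder)
  amp <- max(xx) - min(xx)
  if (amp <= 0) stop("degenerate cycle: flat extension in preconditioning segment")
  centre <- min(xx) + amp / 2
  band <- 0.02 * amp
  state <- xx[1] > centre
  ups <- integer(); downs <- integer()
  for (i in seq_along(xx)) {
    if (!state && xx[i] > centre + band / 2) { state <- TRUE; ups <- c(ups, i) }
    else if (state && xx[i] < centre - band / 2) { state <- FALSE; downs <- c(downs, i) }
  }
  nCyc <- length(ups)
  if (nCyc < 1L) stop("degenerate cycle: monotone segment, no oscillations found")
  # boundaries: segment start, minima between consecutive cycles, segment end
  bounds <- integer(nCyc + 1L)
  bounds[1] <- 1L; bounds[nCyc + 1L] <- length(xx)
  if (nCyc > 1L) for (k in seq_len(nCyc - 1L)) {
    span <- ups[k]:ups[k + 1L]
    bounds[k + 1L] <- span[which.min(xx[span])]
  }
  cycles <- vector("list", nCyc)
  peaks <- numeric(nCyc)
  for (k in seq_len(nCyc)) {
    i0 <- bounds[k]; i1 <- bounds[k + 1L]
    span <- i0:i1
    if (length(span) < 7L) stop("degenerate cycle: fewer than 7 samples in cycle ", k)
    pk <- span[which.max(xx[span])]
    if (pk - i0 < 2L || i1 - pk < 2L)
      stop("degenerate cycle: branch with fewer than 3 samples in cycle ", k)
    branch <- function(j) data.frame(time = tt[j], extension = xx[j], force = ff[j])
    cycles[[k]] <- list(loading = branch(i0:pk), unloading = branch(pk:i1))
    peaks[k] <- max(ff[span])
  }
  new("CycleSet", cycles = cycles, peakForce = peaks)
}

#' Percentage hysteresis over preconditioning
#'
#' Total percentage hysteresis between the first and last preconditioning
#' cycle.  In the default `"first_to_last"` mode it is the energy input on
#' the first cycle's loading branch versus the energy recovered on the last
#' cycle's unloading branch: `100 * (W_load - W_unload) / W_load` with
#' trapezoidal work integrals of force over extension.  `"loop_delta"`
#' instead compares the closed-loop hysteresis of the first and last cycles
#' (per-cycle loop loss of cycle 1 minus cycle n).  Percentages are invariant
#' to force rescaling and to the choice of force-extension versus
#' stress-strain axes.
#'
#' @param cycles a [CycleSet-class] with at least 2 cycles.
#' @param mode `"first_to_last"` (default) or `"loop_delta"`.
#' @return hysteresis, %.
#' @export
hysteresis <- function(cycles, mode = c("first_to_last", "loop_delta")) {
  mode <- match.arg(mode)
  if (length(cycles) < 2L) stop("hysteresis needs at least 2 cycles")
  work <- function(br) trapz(br$extension, br$force)
  if (mode == "first_to_last") {
    wLoad <- work(cycles@cycles[[1]]$loading)
    if (wLoad <= 0) stop("undefined metric: non-positive loading work")
    wUnld <- -work(cycles@cycles[[length(cycles)]]$unloading)
    100 * (wLoad - wUnld) / wLoad
  } else {
    loop <- function(cy) {
      wl <- work(cy$loading)
      if (wl <= 0) stop("undefined metric: non-positive loading work")
      100 * (wl + work(cy$unloading)) / wl
    }
    loop(cycles@cycles[[1]]) - loop(cycles@cycles[[length(cycles)]])
  }
}

#' Percentage stress relaxation over preconditioning
#'
#' Decay of the cycle peak force between the first and last preconditioning
#' cycle: `100 * (peak_1 - peak_n) / peak_1`.
#'
#' @param cycles a [CycleSet-class] with at least 2 cycles.
#' @return stress relaxation, %.
#' @export
stressRelaxation <- function(cycles) {
  if (length(cycles) < 2L) stop("stress relaxation needs at least 2 cycles")
  p <- cycles@peakForce
  if (p[1] <= 0) stop("undefined metric: non-positive first-cycle peak force")
  100 * (p[1] - p[length(p)]) / p[1]
}

#' Preconditioning metrics for one specimen
#'
#' Convenience wrapper: takes a segmented trace, applies the protocol's
#' Savitzky-Golay smoothing, splits the cycles and returns both viscoelastic
#' metrics.
#'
#' @param trace a segmented [ForceExtensionTrace-class].
#' @param protocol a [TestProtocol-class].
#' @param mode hysteresis mode, see [hysteresis()].
#' @return data frame with `hysteresis_pct` and `stress_relaxation_pct`.
#' @export
preconditionMetrics <- function(trace, protocol, mode = "first_to_last") {
  cyc <- splitCycles(trace, protocol)
  data.frame(hysteresis_pct = hysteresis(cyc, mode),
             stress_relaxation_pct = stressRelaxation(cyc))
}
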