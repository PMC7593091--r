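#' @import methods
#' @importFrom stats approx coef cor.test dnorm lm median p.adjust pf pnorm
#'   pairwise.t.test qnorm rank resid rlnorm rnorm runif sd setNames
#'   shapiro.test uniroot var aov anova rbinom
#' @importFrom utils head read.table tail write.table
NULL

AGE_GROUPS <- c("foetus", "0 days", "0-1 month", "3-6 months", "1-2 years")
TENDONS    <- c("SDFT", "CDET")
PHASES     <- c("fascicle", "IFM")

#' Mechanical test protocol
#'
#' Describes the loading protocol of a phase-specific uniaxial tendon test:
#' preload, sinusoidal preconditioning cycles, ramp to failure, sampling rate
#' and the smoothing/analysis constants applied downstream.  Fascicle tests
#' are strain-controlled (cycle amplitude and ramp rate in % strain), tests of
#' the interfascicular matrix (IFM) are extension-controlled (mm).
#'
#' @slot phase `"fascicle"` or `"IFM"`.
#' @slot preload preload force in N (0.1 fascicle, 0.02 IFM).
#' @slot nCycles number of preconditioning cycles (10).
#' @slot cycleAmplitude amplitude of each cycle, in `amplitudeUnit`.
#' @slot amplitudeUnit `"strain_pct"` (of gauge length) or `"mm"`.
#' @slot cycleFrequency cycle frequency in Hz.
#' @slot rampRate ramp-to-failure speed, in `rampRateUnit` per second.
#' @slot rampRateUnit `"strain_pct"` or `"mm"`.
#' @slot sampleRate acquisition rate in Hz.
#' @slot smoothOrder Savitzky-Golay polynomial order.
#' @slot framePrecondition Savitzky-Golay frame for the preconditioning data.
#' @slot frameRamp Savitzky-Golay frame for the ramp-to-failure data.
#' @slot modulusWindow sliding-window size (samples) for the continuous
#'   modulus/stiffness curve.
#' @export
setClass("TestProtocol", representation(
  phase            = "character",
  preload          = "numeric",
  nCycles          = "integer",
  cycleAmplitude   = "numeric",
  amplitudeUnit    = "character",
  cycleFrequency   = "numeric",
  rampRate         = "numeric",
  rampRateUnit     = "character",
  sampleRate       = "numeric",
  smoothOrder      = "integer",
  framePrecondition= "integer",
  frameRamp        = "integer",
  modulusWindow    = "integer"
), validity = function(object) {
  msg <- character()
  if (!object@phase %in% PHASES) msg <- c(msg, "phase must be 'fascicle' or 'IFM'")
  if (object@preload <= 0) msg <- c(msg, "preload must be > 0")
  if (object@nCycles < 0L) msg <- c(msg, "nCycles must be >= 0")
  if (object@cycleAmplitude <= 0 && object@nCycles > 0L)
    msg <- c(msg, "cycleAmplitude must be > 0")
  for (fr in c(object@framePrecondition, object@frameRamp)) {
    if (fr %% 2L == 0L || fr <= object@smoothOrder)
      msg <- c(msg, "smoothing frames must be odd and > polynomial order")
  }
  if (object@modulusWindow < 2L) msg <- c(msg, "modulusWindow must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct the default test protocol for a phase
#'
#' Defaults follow standard phase-specific tendon testing: fascicles are
#' preloaded to 0.1 N, preconditioned with 10 sine cycles between 0 and 3%
#' strain at 1 Hz and ramped to failure at 5 %/s; IFM samples are preloaded
#' to 0.02 N, cycled between 0 and 0.5 mm extension and ramped at 1 mm/s.
#' Data are sampled at 100 Hz and smoothed with a third-order Savitzky-Golay
#' filter (frame 15 for preconditioning, 51 for the ramp); the continuous
#' modulus/stiffness uses a 10-point sliding window.
#'
#' @param phase `"fascicle"` or `"IFM"`.
#' @param nCycles number of preconditioning cycles.
#' @return A [TestProtocol-class] object.
#' @examples
#' defaultProtocol("fascicle")
#' @export
defaultProtocol <- function(phase = c("fascicle", "IFM"), nCycles = 10L) {
  phase <- match.arg(phase)
  if (phase == "fascicle") {
    new("TestProtocol", phase = phase, preload = 0.1, nCycles = as.integer(nCycles),
        cycleAmplitude = 3, amplitudeUnit = "strain_pct",
        cycleFrequency = 1, rampRate = 5, rampRateUnit = "strain_pct",
        sampleRate = 100, smoothOrder = 3L, framePrecondition = 15L,
        frameRamp = 51L, modulusWindow = 10L)
  } else {
    new("TestProtocol", phase = phase, preload = 0.02, nCycles = as.integer(nCycles),
        cycleAmplitude = 0.5, amplitudeUnit = "mm",
        cycleFrequency = 1, rampRate = 1, rampRateUnit = "mm",
        sampleRate = 100, smoothOrder = 3L, framePrecondition = 15L,
        frameRamp = 51L, modulusWindow = 10L)
  }
}

# amplitude / ramp rate in mm for a given gauge length
amplitudeMm <- function(protocol, gaugeLength) {
  if (protocol@amplitudeUnit == "mm") protocol@cycleAmplitude
  else protocol@cycleAmplitude / 100 * gaugeLength
}
rampRateMm <- function(protocol, gaugeLength) {
  if (protocol@rampRateUnit == "mm") protocol@rampRate
  else protocol@rampRate / 100 * gaugeLength
}

#' Sampled force-extension record of one uniaxial test
#'
#' Time (s), force (N) and grip extension (mm) sampled uniformly (nominally
#' 100 Hz), with optional per-sample protocol segment labels
#' (`"preload"`, `"preconditioning"`, `"ramp"`) assigned by [segmentTrace()].
#'
#' @slot time numeric, seconds; strictly increasing, uniform within 1% jitter.
#' @slot force numeric, N.
#' @slot extension numeric, mm.
#' @slot segment character; per-sample labels, or length 0 before segmentation.
#' @slot sampleRate numeric, Hz.
#' @export
setClass("ForceExtensionTrace", representation(
  time       = "numeric",
  force      = "numeric",
  extension  = "numeric",
  segment    = "character",
  sampleRate = "numeric"
), validity = function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@force) != n || length(object@extension) != n)
    msg <- c(msg, "time, force and extension must have equal length")
  if (length(object@segment) && length(object@segment) != n)
    msg <- c(msg, "segment labels must be empty or one per sample")
  if (n >= 2) {
    dt <- diff(object@time)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      msg <- c(msg, sprintf("time must be strictly increasing (row %d)", bad))
    } else if (max(abs(dt - median(dt))) > 0.01 * median(dt) + 1e-12)
      msg <- c(msg, "time must be uniform within 1% jitter")
  }
  if (any(!is.finite(object@force)))
    msg <- c(msg, sprintf("non-finite force at rows %s",
                          paste(head(which(!is.finite(object@force)), 5), collapse = ", ")))
  if (any(!is.finite(object@extension))) msg <- c(msg, "non-finite extension")
  if (length(msg)) msg else TRUE
})

#' @describeIn ForceExtensionTrace constructor; `sampleRate` is inferred from
#'   the time column when omitted.
#' @param time,force,extension numeric vectors of equal length.
#' @param segment optional per-sample segment labels.
#' @param sampleRate sampling rate in Hz; inferred from `time` if `NA`.
#' @export
ForceExtensionTrace <- function(time, force, extension,
                                segment = character(), sampleRate = NA_real_) {
  if (is.na(sampleRate))
    sampleRate <- 1 / median(diff(time))
  new("ForceExtensionTrace", time = as.numeric(time), force = as.numeric(force),
      extension = as.numeric(extension), segment = as.character(segment),
      sampleRate = sampleRate)
}

setMethod("show", "ForceExtensionTrace", function(object) {
  cat(sprintf("ForceExtensionTrace: %d samples at %.4g Hz, %.3g s\n",
              length(object@time), object@sampleRate, diff(range(object@time))))
  cat(sprintf("  force [%.4g, %.4g] N; extension [%.4g, %.4g] mm\n",
              min(object@force), max(object@force),
              min(object@extension), max(object@extension)))
  if (length(object@segment)) {
    tb <- table(factor(object@segment, levels = c("preload", "preconditioning", "ramp")))
    cat("  segments:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  } else cat("  unsegmented\n")
})

#' @describeIn ForceExtensionTrace number of samples
#' @param x a `ForceExtensionTrace`
#' @export
setMethod("length", "ForceExtensionTrace", function(x) length(x@time))

#' Accessors for ForceExtensionTrace
#'
#' @param x a [ForceExtensionTrace-class]
#' @return the corresponding slot vector.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
traceTime <- function(x) x@time
#' @rdname trace-accessors
#' @export
traceForce <- function(x) x@force
#' @rdname trace-accessors
#' @export
traceExtension <- function(x) x@extension
#' @rdname trace-accessors
#' @export
segmentLabels <- function(x) x@segment
#' @rdname trace-accessors
#' @export
sampleRate <- function(x) x@sampleRate

# subset a trace by index, keeping labels
traceSlice <- function(x, i) {
  new("ForceExtensionTrace", time = x@time[i], force = x@force[i],
      extension = x@extension[i],
      segment = if (length(x@segment)) x@segment[i] else character(),
      sampleRate = x@sampleRate)
}

#' Parameters of the quasi-linear-viscoelastic specimen simulator
#'
#' The simulated specimen has an elastic backbone built from Gaussian
#' slack-length (crimp) recruitment: elements with slack lengths
#' s ~ N(recruitMean, recruitSd) each load linearly once extension exceeds
#' their slack, so the tangent stiffness is kLin * pnorm((x - recruitMean) /
#' recruitSd) — a toe region rising to a linear region.  Beyond
#' `yieldExtension` the tangent decays exponentially at rate
#' `postYieldSoftening` (per mm), and at `failureExtension` the force drops
#' instantaneously to zero.  Viscoelasticity is quasi-linear superposition
#' with the single-exponential reduced relaxation function
#' G(t) = (1 - viscFraction) + viscFraction * exp(-t / tau), so a fraction
#' `viscFraction` of elastic stress relaxes at long times.  Gaussian noise
#' (sd `noiseSd`, N) is added to force only; extension is machine-commanded.
#'
#' @slot phase `"fascicle"` or `"IFM"`.
#' @slot gaugeLength mm.
#' @slot diameter mm (fascicle only; `NA` for IFM).
#' @slot kLin linear-region stiffness, N/mm.
#' @slot recruitMean,recruitSd mm; slack-length distribution of the toe region.
#' @slot viscFraction dimensionless in [0, 1).
#' @slot tau relaxation time constant, s.
#' @slot yieldExtension mm; onset of post-yield softening.
#' @slot postYieldSoftening per-mm tangent decay rate past yield.
#' @slot yieldBlend mm; width of the smooth transition into softening (the
#'   tangent maximum of real tissue is smooth, not a corner).
#' @slot failureExtension mm.
#' @slot noiseSd force noise, N.
#' @slot seed integer RNG seed.
#' @export
setClass("MechSimParams", representation(
  phase = "character", gaugeLength = "numeric", diameter = "numeric",
  kLin = "numeric", recruitMean = "numeric", recruitSd = "numeric",
  viscFraction = "numeric", tau = "numeric", yieldExtension = "numeric",
  postYieldSoftening = "numeric", yieldBlend = "numeric",
  failureExtension = "numeric", noiseSd = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (!object@phase %in% PHASES) msg <- c(msg, "phase must be 'fascicle' or 'IFM'")
  pos <- c(gaugeLength = object@gaugeLength, kLin = object@kLin,
           recruitMean = object@recruitMean, recruitSd = object@recruitSd,
           tau = object@tau, yieldExtension = object@yieldExtension,
           failureExtension = object@failureExtension)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be > 0:", paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@phase == "fascicle" && (is.na(object@diameter) || object@diameter <= 0))
    msg <- c(msg, "fascicle specimens need diameter > 0")
  if (object@viscFraction < 0 || object@viscFraction >= 1)
    msg <- c(msg, "viscFraction must be in [0, 1)")
  if (object@postYieldSoftening < 0) msg <- c(msg, "postYieldSoftening must be >= 0")
  if (object@yieldBlend <= 0) msg <- c(msg, "yieldBlend must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@yieldExtension >= object@failureExtension)
    msg <- c(msg, "yieldExtension must be < failureExtension")
  if (object@recruitMean >= object@yieldExtension)
    msg <- c(msg, "recruitMean must be < yieldExtension")
  if (length(msg)) msg else TRUE
})

#' @describeIn MechSimParams constructor with phase-typical defaults.
#' @param phase `"fascicle"` or `"IFM"`.
#' @param gaugeLength,diameter,kLin,recruitMean,recruitSd,viscFraction,tau,yieldExtension,postYieldSoftening,yieldBlend,failureExtension,noiseSd,seed
#'   see slots; unset values take phase defaults.
#' @export
MechSimParams <- function(phase = c("fascicle", "IFM"),
                          gaugeLength = NULL, diameter = NULL, kLin = NULL,
                          recruitMean = NULL, recruitSd = NULL,
                          viscFraction = NULL, tau = NULL,
                          yieldExtension = NULL, postYieldSoftening = NULL,
                          yieldBlend = NULL,
                          failureExtension = NULL, noiseSd = NULL, seed = 1L) {
  phase <- match.arg(phase)
  d <- if (phase == "fascicle") {
    list(gaugeLength = 20, diameter = 0.3, kLin = 30, recruitMean = 1.0,
         recruitSd = 0.45, viscFraction = 0.10, tau = 5, yieldExtension = 2.0,
         postYieldSoftening = 2, yieldBlend = 0.2, failureExtension = 2.6,
         noiseSd = 0.01)
  } else {
    list(gaugeLength = 20, diameter = NA_real_, kLin = 3, recruitMean = 1.0,
         recruitSd = 0.35, viscFraction = 0.15, tau = 5, yieldExtension = 2.5,
         postYieldSoftening = 1, yieldBlend = 0.2, failureExtension = 3.5,
         noiseSd = 0.002)
  }
  pick <- function(x, def) if (is.null(x)) def else x
  new("MechSimParams", phase = phase,
      gaugeLength = pick(gaugeLength, d$gaugeLength),
      diameter = pick(diameter, d$diameter), kLin = pick(kLin, d$kLin),
      recruitMean = pick(recruitMean, d$recruitMean),
      recruitSd = pick(recruitSd, d$recruitSd),
      viscFraction = pick(viscFraction, d$viscFraction), tau = pick(tau, d$tau),
      yieldExtension = pick(yieldExtension, d$yieldExtension),
      postYieldSoftening = pick(postYieldSoftening, d$postYieldSoftening),
      yieldBlend = pick(yieldBlend, d$yieldBlend),
      failureExtension = pick(failureExtension, d$failureExtension),
      noiseSd = pick(noiseSd, d$noiseSd), seed = as.integer(seed))
}

setMethod("show", "MechSimParams", function(object) {
  cat(sprintf("MechSimParams (%s): kLin=%.3g N/mm, toe N(%.3g, %.3g) mm,\n",
              object@phase, object@kLin, object@recruitMean, object@recruitSd))
  cat(sprintf("  visc=%.3g (tau=%.3g s), yield=%.3g mm, failure=%.3g mm, noise=%.3g N, seed=%d\n",
              object@viscFraction, object@tau, object@yieldExtension,
              object@failureExtension, object@noiseSd, object@seed))
})

#' Preconditioning cycles split into loading/unloading branches
#'
#' @slot cycles list; each element a list with elements `loading` and
#'   `unloading`, data frames with columns `time`, `extension`, `force`.
#' @slot peakForce numeric; per-cycle maximum force, N.
#' @export
setClass("CycleSet", representation(cycles = "list", peakForce = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@peakForce) != length(object@cycles))
      msg <- c(msg, "one peak force per cycle required")
    for (cy in object@cycles) {
      if (!all(c("loading", "unloading") %in% names(cy)))
        msg <- c(msg, "each cycle needs loading and unloading branches")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CycleSet", function(object) {
  cat(sprintf("CycleSet: %d cycles; peak forces %.4g .. %.4g N\n",
              length(object@cycles), object@peakForce[1],
              tail(object@peakForce, 1)))
})

#' @describeIn CycleSet number of cycles
#' @param x a `CycleSet`
#' @export
setMethod("length", "CycleSet", function(x) length(x@cycles))

#' @describeIn CycleSet per-cycle peak forces (N)
#' @export
peakForces <- function(x) x@peakForce
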