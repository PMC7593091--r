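softplus <- function(z) {
  out <- z
  i <- z < 30
  out[i] <- log1p(exp(z[i]))
  out
}

#' Tangent stiffness of the elastic backbone
#'
#' `kLin * pnorm((x - recruitMean)/recruitSd)` from Gaussian slack-length
#' (crimp) recruitment, multiplied by a smoothly blended exponential
#' post-yield softening `exp(-postYieldSoftening * yieldBlend *
#' softplus((x - yieldExtension)/yieldBlend))`, which tends to
#' `exp(-postYieldSoftening * (x - yieldExtension))` past yield and to 1
#' well below it.  The tangent is smooth and unimodal: it rises through the
#' toe region as elements recruit and falls once softening dominates, so the
#' point of maximum tangent stiffness (the yield point in the
#' maximum-modulus sense) is well defined.
#'
#' @param params a [MechSimParams-class].
#' @param x extension, mm (vectorised).
#' @return tangent stiffness, N/mm.
#' @export
tangentStiffness <- function(params, x) {
  z <- (x - params@recruitMean) / params@recruitSd
  w <- params@yieldBlend
  params@kLin * pnorm(z) *
    exp(-params@postYieldSoftening * w *
        softplus((x - params@yieldExtension) / w))
}

# extension of maximum tangent stiffness (the generator's true yield point):
# unique root of d log kt / dx = hazard(recruitment) - softening load
maxTangentExtension <- function(params) {
  dlog <- function(x) {
    z <- (x - params@recruitMean) / params@recruitSd
    dnorm(z) / (params@recruitSd * pnorm(z)) -
      params@postYieldSoftening *
        stats::plogis((x - params@yieldExtension) / params@yieldBlend)
  }
  lo <- 1e-6; hi <- params@failureExtension
  if (dlog(hi) >= 0) return(hi)          # tangent still rising at failure
  uniroot(dlog, c(lo, hi), tol = 1e-10)$root
}

#' Elastic backbone force of a simulated specimen
#'
#' Instantaneous (rate-independent) force at extension `x`: the integral of
#' [tangentStiffness()] from zero, evaluated by fine trapezoidal quadrature
#' (5e-5 mm grid) with linear interpolation; at the failure extension the
#' force drops to zero.
#'
#' @param params a [MechSimParams-class].
#' @param x extension, mm (vectorised).
#' @return force, N.
#' @export
elasticBackbone <- function(params, x) {
  backboneInterp(params)(x)
}

# build the backbone interpolator once (fine cumulative quadrature + linear
# interpolation, zero past failure); reused across a specimen's evaluations
backboneInterp <- function(params) {
  xf <- params@failureExtension
  du <- 5e-5
  g <- seq(0, xf + 0.3, by = du)
  kt <- tangentStiffness(params, g)
  Fg <- cumsum(c(0, (kt[-1] + kt[-length(kt)]) / 2 * du))
  af <- stats::approxfun(g, Fg, rule = 2)
  function(x) {
    out <- af(pmin(pmax(x, 0), xf))
    out[x >= xf] <- 0
    out
  }
}

# Extension command path of the test protocol, evaluated on a uniform grid.
# Returns times, commanded extension and the analytic segment boundaries.
# The preload ramp targets the extension where the elastic backbone slightly
# overshoots the preload (x1.15) so that measured force stays above the
# preload threshold during the subsequent hold despite viscoelastic
# relaxation.
mechCommand <- function(params, protocol, dt, holdTime = 1, bb = NULL) {
  if (is.null(bb)) bb <- backboneInterp(params)
  A  <- amplitudeMm(protocol, params@gaugeLength)
  vr <- rampRateMm(protocol, params@gaugeLength)
  f  <- protocol@cycleFrequency
  nC <- protocol@nCycles
  target <- protocol@preload * 1.15
  fmax <- bb(params@yieldExtension)
  if (target >= fmax)
    stop("preload exceeds the specimen's elastic capacity")
  x0 <- uniroot(function(u) bb(u) - target,
                lower = 1e-9, upper = params@yieldExtension,
                tol = 1e-12)$root
  if (nC > 0L && x0 + A >= params@yieldExtension)
    stop("preconditioning cycle amplitude reaches the yield extension; ",
         "cycles must stay sub-yield")
  # snap the preload-ramp duration up to the sample grid so that every later
  # protocol boundary (hold end, each cycle, ramp start) falls on a sample
  tPre   <- max(dt, ceiling((x0 / vr) / dt) * dt)
  vPre   <- x0 / tPre               # slightly slower approach to the preload
  tHold  <- holdTime
  tCyc   <- if (nC > 0L) nC / f else 0
  xEnd   <- params@failureExtension + 0.2 * (params@failureExtension -
                                             params@yieldExtension)
  tRamp  <- (xEnd - x0) / vr
  tTot   <- tPre + tHold + tCyc + tRamp
  tt <- seq(0, tTot, by = dt)
  x  <- numeric(length(tt))
  i  <- tt <= tPre
  x[i] <- vPre * tt[i]
  i  <- tt > tPre & tt <= tPre + tHold
  x[i] <- x0
  cyc0 <- tPre + tHold
  if (nC > 0L) {
    i <- tt > cyc0 & tt <= cyc0 + tCyc
    x[i] <- x0 + A / 2 * (1 - cos(2 * pi * f * (tt[i] - cyc0)))
  }
  ramp0 <- cyc0 + tCyc
  i <- tt > ramp0
  x[i] <- x0 + vr * (tt[i] - ramp0)
  list(time = tt, extension = x, x0 = x0, amplitude = A, rampRate = vr,
       tCycleStart = cyc0, tRampStart = ramp0,
       tFailure = ramp0 + (params@failureExtension - x0) / vr)
}

# Quasi-linear-viscoelastic force response on a uniform time grid.
# G(t) = (1 - v) + v * exp(-t/tau); F(t) = int G(t - s) dFe(x(s)).
# The exponential memory term is a linear recurrence evaluated with
# stats::filter; the increment is weighted at the interval midpoint.
# Force is clamped to zero once the commanded extension passes failure.
qlvForce <- function(params, time, extension, bb = NULL) {
  if (is.null(bb)) bb <- backboneInterp(params)
  fe <- bb(extension)
  v  <- params@viscFraction
  if (v == 0) {
    ff <- fe
  } else {
    dt <- time[2] - time[1]
    a  <- exp(-dt / params@tau)
    b  <- exp(-dt / (2 * params@tau))
    dfe <- diff(c(0, fe))
    h  <- as.numeric(stats::filter(b * dfe, a, method = "recursive"))
    ff <- (1 - v) * fe + v * h
  }
  ff[extension >= params@failureExtension] <- 0
  ff
}

# Analytic/high-resolution ground truth for one simulated specimen.
# Computed on a noise-free grid at `truthDt` (default 1e-4 s), independent of
# the 100 Hz trace handed to the analysis pipeline.
mechTruth <- function(params, protocol, truthDt = 1e-4, bb = NULL) {
  if (is.null(bb)) bb <- backboneInterp(params)
  cmd <- mechCommand(params, protocol, truthDt, bb = bb)
  ff  <- qlvForce(params, cmd$time, cmd$extension, bb = bb)
  P   <- 1 / protocol@cycleFrequency
  nC  <- protocol@nCycles
  peaks <- rep(NA_real_, max(nC, 0L))
  hyst <- NA_real_; relax <- NA_real_
  if (nC >= 2L) {
    cycIdx <- function(from, to) {
      which(cmd$time >= cmd$tCycleStart + from - 1e-12 &
            cmd$time <= cmd$tCycleStart + to + 1e-12)
    }
    for (k in seq_len(nC))
      peaks[k] <- max(ff[cycIdx((k - 1) * P, k * P)])
    iLoad <- cycIdx(0, P / 2)                 # cycle-1 loading branch
    iUnld <- cycIdx((nC - 0.5) * P, nC * P)   # last cycle's unloading branch
    wLoad <- trapz(cmd$extension[iLoad], ff[iLoad])
    wUnld <- -trapz(cmd$extension[iUnld], ff[iUnld])
    hyst  <- 100 * (wLoad - wUnld) / wLoad
    relax <- 100 * (peaks[1] - peaks[nC]) / peaks[1]
  }
  iRamp <- which(cmd$time >= cmd$tRampStart &
                 cmd$extension < params@failureExtension - 1e-9)
  failureForce <- max(ff[iRamp])
  # true yield: max-slope location of the noise-free response along the ramp
  # (rate-dependent through the relaxation function), from wide central
  # differences on the fine grid; for an elastic specimen it coincides with
  # the maximum of the elastic tangent stiffness
  h <- 50L
  xi <- cmd$extension[iRamp]; fi <- ff[iRamp]
  lo <- which(xi > cmd$x0 + 0.05)[1]
  sIdx <- seq.int(max(lo, h + 1L), length(iRamp) - h)
  slope <- (fi[sIdx + h] - fi[sIdx - h]) / (xi[sIdx + h] - xi[sIdx - h])
  yieldExt <- xi[sIdx[which.max(slope)]]
  yieldForce <- approx(xi, fi, xout = yieldExt, ties = "ordered")$y
  list(
    hysteresisPct = hyst, stressRelaxationPct = relax, peakForces = peaks,
    yieldExtension = yieldExt,
    yieldExtensionElastic = maxTangentExtension(params),
    yieldForce = yieldForce,
    failureExtension = params@failureExtension, failureForce = failureForce,
    x0 = cmd$x0, tCycleStart = cmd$tCycleStart, tRampStart = cmd$tRampStart,
    truthDt = truthDt)
}

#' Simulate one phase-specific uniaxial tendon test
#'
#' Generates a complete 100 Hz force-extension trace for the protocol
#' (preload ramp, hold, sinusoidal preconditioning cycles, ramp to failure)
#' from the quasi-linear-viscoelastic specimen model of
#' [MechSimParams-class], together with a ground-truth record computed on a
#' noise-free high-resolution grid (`truthDt`, default 0.1 ms), never by the
#' analysis pipeline itself.
#'
#' @param params a [MechSimParams-class].
#' @param protocol a [TestProtocol-class]; defaults to the phase protocol.
#' @param computeTruth set `FALSE` to skip the (more expensive) ground-truth
#'   quadrature when only the trace is needed.
#' @param truthDt time step (s) of the ground-truth grid.
#' @return list with elements `trace` ([ForceExtensionTrace-class]) and
#'   `truth` (list: `hysteresisPct`, `stressRelaxationPct`, `peakForces`,
#'   `yieldExtension`, `yieldForce`, `failureExtension`, `failureForce`,
#'   segment boundary times and the generator parameters under `params`).
#' @examples
#' sim <- simulateMechTest(MechSimParams("fascicle", viscFraction = 0.2,
#'                                       noiseSd = 0, seed = 1))
#' sim$truth$hysteresisPct
#' @export
simulateMechTest <- function(params, protocol = defaultProtocol(params@phase),
                             computeTruth = TRUE, truthDt = 1e-4) {
  validObject(params); validObject(protocol)
  bb  <- backboneInterp(params)
  dt  <- 1 / protocol@sampleRate
  cmd <- mechCommand(params, protocol, dt, bb = bb)
  ff  <- qlvForce(params, cmd$time, cmd$extension, bb = bb)
  if (params@noiseSd > 0) {
    set.seed(params@seed)
    ff <- ff + rnorm(length(ff), 0, params@noiseSd)
  }
  trace <- ForceExtensionTrace(cmd$time, ff, cmd$extension,
                               sampleRate = protocol@sampleRate)
  truth <- if (computeTruth) mechTruth(params, protocol, truthDt, bb = bb) else NULL
  if (!is.null(truth)) truth$params <- params
  list(trace = trace, truth = truth)
}
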