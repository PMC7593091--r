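# shared fixture builders

fascParams <- function(...) MechSimParams("fascicle", noiseSd = 0, ...)
ifmParams  <- function(...) MechSimParams("IFM", noiseSd = 0, ...)

# simulate + segment in one go
simSegmented <- function(params, protocol = defaultProtocol(params@phase), ...) {
  sim <- simulateMechTest(params, protocol, ...)
  sim$trace <- segmentTrace(sim$trace, protocol)
  sim
}

# a drawn family of plausible specimens for property-style loops
drawParams <- function(i, phase = c("fascicle", "IFM"), viscFraction = 0.1,
                       noiseSd = 0) {
  phase <- match.arg(phase)
  set.seed(1000 + i)
  if (phase == "fascicle")
    MechSimParams("fascicle", kLin = runif(1, 15, 45),
                  recruitMean = runif(1, 0.8, 1.2),
                  recruitSd = runif(1, 0.35, 0.55),
                  postYieldSoftening = runif(1, 1, 3),
                  viscFraction = viscFraction, noiseSd = noiseSd,
                  seed = 1000 + i)
  else
    MechSimParams("IFM", kLin = runif(1, 2, 4),
                  recruitMean = runif(1, 0.8, 1.3),
                  recruitSd = runif(1, 0.3, 0.45),
                  postYieldSoftening = runif(1, 0.5, 1.5),
                  viscFraction = viscFraction, noiseSd = noiseSd,
                  seed = 1000 + i)
}
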