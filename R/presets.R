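#' Age x tendon simulation presets
#'
#' A preset table mapping (age group, tendon, phase) to simulator parameters
#' that reproduce the qualitative developmental trends of functionally
#' distinct tendons: stiffness and failure force rising through development;
#' for the interfascicular matrix (IFM), a longer toe region in the
#' energy-storing SDFT than in the positional CDET, and a viscoelastic
#' fraction that decreases with age in the SDFT only (so hysteresis and
#' stress relaxation specialise with development in the energy-storing
#' tendon), producing a tendon-by-age interaction.  The values are model
#' choices for demonstration-shaped data, not estimates of any measured
#' tendon.
#'
#' @param phase `"fascicle"` or `"IFM"`.
#' @return data frame, one row per (tendon, age group), with parameter
#'   columns consumed by [simulateStudy()].
#' @export
agePresets <- function(phase = c("IFM", "fascicle")) {
  phase <- match.arg(phase)
  grid <- expand.grid(age_group = AGE_GROUPS, tendon = TENDONS,
                      stringsAsFactors = FALSE)
  ageIdx <- match(grid$age_group, AGE_GROUPS)
  if (phase == "IFM") {
    grid$kLin <- 2 + 0.5 * (ageIdx - 1)
    grid$viscFraction <- ifelse(grid$tendon == "SDFT",
                                c(0.30, 0.28, 0.24, 0.18, 0.12)[ageIdx], 0.30)
    grid$recruitMean <- ifelse(grid$tendon == "SDFT", 1.3, 0.8)
    grid$recruitSd <- ifelse(grid$tendon == "SDFT", 0.45, 0.32)
    grid$tau <- 5
    grid$yieldExtension <- 2.5
    grid$postYieldSoftening <- 1
    grid$failureExtension <- 3.5
    grid$noiseSd <- 0.002
    grid$gaugeLength <- 20
    grid$diameter <- NA_real_
  } else {
    grid$kLin <- 15 + 6 * (ageIdx - 1)
    grid$viscFraction <- ifelse(grid$tendon == "SDFT",
                                c(0.18, 0.16, 0.14, 0.12, 0.10)[ageIdx], 0.18)
    grid$recruitMean <- ifelse(grid$tendon == "SDFT", 1.1, 0.9)
    grid$recruitSd <- 0.45
    grid$tau <- 5
    grid$yieldExtension <- 2.0
    grid$postYieldSoftening <- 2
    grid$failureExtension <- 2.6
    grid$noiseSd <- 0.01
    grid$gaugeLength <- 20
    grid$diameter <- 0.3
  }
  grid$phase <- phase
  grid
}

#' Simulate a full developmental study for one phase
#'
#' Generates `nPerCell` specimens for every (tendon, age group) preset cell,
#' with mild specimen-to-specimen variability (multiplicative log-normal
#' jitter on stiffness, additive jitter on the viscoelastic fraction) and a
#' metadata sheet, ready for the end-to-end pipeline.
#'
#' @param phase `"IFM"` or `"fascicle"`.
#' @param nPerCell specimens per design cell.
#' @param seed integer master seed; every specimen gets a derived child seed.
#' @param jitterK log-sd of the stiffness jitter.
#' @param jitterV sd of the additive viscoelastic-fraction jitter.
#' @param computeTruth compute per-specimen ground truth (slower).
#' @return list: `traces` (named list of [ForceExtensionTrace-class]), `meta`
#'   (specimen sheet), `params` (per-specimen [MechSimParams-class]),
#'   `truths` (per-specimen truth records or `NULL`s).
#' @export
simulateStudy <- function(phase = c("IFM", "fascicle"), nPerCell = 4L,
                          seed = 1L, jitterK = 0.05, jitterV = 0.015,
                          computeTruth = FALSE) {
  phase <- match.arg(phase)
  presets <- agePresets(phase)
  traces <- list(); params <- list(); truths <- list()
  meta <- NULL
  sp <- 0L
  for (r in seq_len(nrow(presets))) {
    for (j in seq_len(nPerCell)) {
      sp <- sp + 1L
      csd <- childSeed(seed, sp)
      set.seed(csd)
      kj <- presets$kLin[r] * exp(rnorm(1, 0, jitterK))
      vj <- min(max(presets$viscFraction[r] + rnorm(1, 0, jitterV), 0), 0.95)
      p <- MechSimParams(phase = if (phase == "IFM") "IFM" else "fascicle",
                         gaugeLength = presets$gaugeLength[r],
                         diameter = presets$diameter[r], kLin = kj,
                         recruitMean = presets$recruitMean[r],
                         recruitSd = presets$recruitSd[r],
                         viscFraction = vj, tau = presets$tau[r],
                         yieldExtension = presets$yieldExtension[r],
                         postYieldSoftening = presets$postYieldSoftening[r],
                         failureExtension = presets$failureExtension[r],
                         noiseSd = presets$noiseSd[r], seed = csd)
      sim <- simulateMechTest(p, computeTruth = computeTruth)
      id <- sprintf("%s_%s_%s_%02d", presets$tendon[r],
                    gsub("[^0-9A-Za-z]+", "", presets$age_group[r]), phase, j)
      traces[[id]] <- sim$trace
      params[[id]] <- p
      truths[[id]] <- sim$truth
      meta <- rbind(meta, data.frame(
        specimen_id = id, animal_id = sprintf("A%02d", j),
        age_group = presets$age_group[r], tendon = presets$tendon[r],
        phase = phase, gauge_length = presets$gaugeLength[r],
        diameters = if (phase == "fascicle")
          paste(round(presets$diameter[r] * exp(rnorm(3, 0, 0.02)), 4),
                collapse = ";") else "",
        ifm_length = if (phase == "IFM") 10 else NA_real_))
    }
  }
  list(traces = traces, meta = validateSpecimenSheet(meta), params = params,
       truths = truths)
}

#' Analyse one specimen end to end
#'
#' Segments the trace, computes the preconditioning viscoelastic metrics and
#' the ramp-to-failure metrics, and returns them as a one-row data frame.
#'
#' @param trace a [ForceExtensionTrace-class] (unsegmented is fine).
#' @param record one row of the specimen sheet (see
#'   [validateSpecimenSheet()]); supplies phase and geometry.
#' @param protocol optional [TestProtocol-class]; defaults to the phase
#'   protocol.
#' @param hysteresisMode see [hysteresis()].
#' @return one-row data frame combining [preconditionMetrics()] and
#'   [failureMetrics()].
#' @export
analyseSpecimen <- function(trace, record, protocol = NULL,
                            hysteresisMode = "first_to_last") {
  phase <- record$phase
  if (is.null(protocol)) protocol <- defaultProtocol(phase)
  seg <- if (length(segmentLabels(trace))) trace
         else segmentTrace(trace, protocol)
  pre <- preconditionMetrics(seg, protocol, mode = hysteresisMode)
  geometry <- if (phase == "fascicle")
    computeCSA(record$diameter_list[[1]], record$gauge_length) else NULL
  fail <- failureMetrics(seg, protocol, geometry)
  cbind(data.frame(specimen_id = record$specimen_id,
                   age_group = record$age_group, tendon = record$tendon,
                   phase = phase), pre, fail)
}

#' Analyse every specimen of a simulated (or ingested) study
#'
#' @param study list with `traces` and `meta` as returned by
#'   [simulateStudy()] (or assembled from [readTrace()] +
#'   [readSpecimenSheet()]).
#' @param ... passed to [analyseSpecimen()].
#' @return data frame of per-specimen metrics joined with the study factors.
#' @export
analyseStudy <- function(study, ...) {
  rows <- lapply(seq_len(nrow(study$meta)), function(i) {
    rec <- study$meta[i, , drop = FALSE]
    analyseSpecimen(study$traces[[rec$specimen_id]], rec, ...)
  })
  do.call(rbind, rows)
}
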