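#' Parameters for the label-free abundance simulator
#'
#' Log-normal protein intensities across the five developmental age groups,
#' with a planted fraction of differentially abundant proteins carrying
#' single-group or monotone fold changes of at least `minPlantedFC` (>= 2, so
#' planted positives are detectable by the fold-change >= 2 call), and
#' per-sample laser-capture area / column-load volume covariates applied
#' multiplicatively to the raw intensities (so that normalisation is required
#' to recover the truth).
#'
#' @param nProteins number of proteins.
#' @param groups ordered age-group labels.
#' @param nPerGroup samples per group.
#' @param baseLogMean,logSd natural-log mean and sd of the baseline intensity.
#' @param fracDifferential fraction of proteins with planted effects.
#' @param minPlantedFC smallest planted fold change (>= 2).
#' @param fcSpread log2 spread of planted fold changes above `minPlantedFC`
#'   (0 plants every effect at exactly `minPlantedFC`).
#' @param areaRange,volumeRange uniform ranges for capture area (um^2) and
#'   load volume (uL).
#' @param seed integer seed.
#' @return validated parameter list of class `OmicsSimParams`.
#' @export
omicsSimParams <- function(nProteins = 200L, groups = AGE_GROUPS,
                           nPerGroup = 4L, baseLogMean = log(1e6),
                           logSd = 0.5, fracDifferential = 0.1,
                           minPlantedFC = 2, fcSpread = 1,
                           areaRange = c(1e5, 5e5),
                           volumeRange = c(1, 9), seed = 1L) {
  stopifnot(nProteins >= 1, nPerGroup >= 2, length(groups) >= 2,
            logSd >= 0, fracDifferential >= 0, fracDifferential <= 1,
            minPlantedFC >= 2, fcSpread >= 0,
            all(areaRange > 0), all(volumeRange > 0))
  structure(list(nProteins = as.integer(nProteins), groups = groups,
                 nPerGroup = as.integer(nPerGroup),
                 baseLogMean = baseLogMean, logSd = logSd,
                 fracDifferential = fracDifferential,
                 minPlantedFC = minPlantedFC, fcSpread = fcSpread,
                 areaRange = areaRange,
                 volumeRange = volumeRange, seed = as.integer(seed)),
            class = "OmicsSimParams")
}

#' Simulate a label-free protein abundance experiment
#'
#' @param params an [omicsSimParams()] list.
#' @return list with `matrix` (an [AbundanceMatrix-class], raw intensities
#'   with covariate distortion applied) and `truth` (data frame: per protein
#'   `differential`, `pattern` (`"single"`/`"monotone"`), planted `fc`,
#'   `log2fc`, `highest_group`).
#' @examples
#' sim <- simulateAbundance(omicsSimParams(nProteins = 50, seed = 7))
#' sum(sim$truth$differential)
#' @export
simulateAbundance <- function(params = omicsSimParams()) {
  set.seed(params$seed)
  nG <- length(params$groups); nS <- nG * params$nPerGroup
  grp <- rep(params$groups, each = params$nPerGroup)
  nDiff <- round(params$fracDifferential * params$nProteins)
  prot <- sprintf("P%04d", seq_len(params$nProteins))
  diffIdx <- if (nDiff > 0) sort(sample(params$nProteins, nDiff)) else integer()
  pattern <- rep("none", params$nProteins)
  fc <- rep(1, params$nProteins)
  highest <- rep(NA_character_, params$nProteins)
  # per-protein per-group log-mean offsets
  offs <- matrix(0, params$nProteins, nG, dimnames = list(prot, params$groups))
  for (i in diffIdx) {
    pat <- sample(c("single", "monotone"), 1)
    f <- params$minPlantedFC * 2^runif(1, 0, params$fcSpread)
    pattern[i] <- pat; fc[i] <- f
    if (pat == "single") {
      g <- sample(nG, 1)
      offs[i, g] <- log(f)
      highest[i] <- params$groups[g]
    } else {
      dir <- sample(c(1, -1), 1)
      w <- seq(0, 1, length.out = nG)
      if (dir < 0) w <- rev(w)
      offs[i, ] <- log(f) * w
      highest[i] <- params$groups[if (dir > 0) nG else 1]
    }
  }
  meanlog <- params$baseLogMean + offs[, match(grp, params$groups), drop = FALSE]
  raw <- exp(meanlog + matrix(rnorm(params$nProteins * nS, 0, params$logSd),
                              params$nProteins, nS))
  area <- runif(nS, params$areaRange[1], params$areaRange[2])
  vol  <- runif(nS, params$volumeRange[1], params$volumeRange[2])
  distorted <- sweep(raw, 2, area * vol, `*`)
  colnames(distorted) <- sprintf("S%02d", seq_len(nS))
  rownames(distorted) <- prot
  truth <- data.frame(protein = prot,
                      differential = seq_len(params$nProteins) %in% diffIdx,
                      pattern = pattern, fc = fc, log2fc = log2(fc),
                      highest_group = highest)
  list(matrix = AbundanceMatrix(distorted, captureArea = area,
                                loadVolume = vol, ageGroup = grp),
       truth = truth)
}

#' Parameters for the neopeptide turnover simulator
#'
#' Long-format peptide tables in which each protein carries `nNeo` neopeptides
#' among `nPeptides` peptides.  The generative quantity is the summed
#' neopeptide fraction of each protein (neopeptide abundance over total
#' peptide abundance of that protein in that sample): baseline `baseFraction`,
#' multiplied by `turnoverFC` in one age group for a planted fraction of
#' proteins, with multiplicative log-normal sample noise `fracSd` on the
#' fraction and log-normal protein totals.
#'
#' @param nProteins,nPeptides,nNeo table dimensions per protein.
#' @param groups,nPerGroup design.
#' @param baseFraction baseline summed neopeptide fraction (0-1).
#' @param fracDifferential fraction of proteins with planted turnover effects.
#' @param turnoverFC planted fold change on the summed fraction.
#' @param fracSd log-sd of the multiplicative noise on the fraction.
#' @param totalLogMean,totalLogSd log-normal protein total abundance.
#' @param seed integer seed.
#' @return parameter list of class `NeoSimParams`.
#' @export
neoSimParams <- function(nProteins = 200L, nPeptides = 6L, nNeo = 2L,
                         groups = AGE_GROUPS, nPerGroup = 4L,
                         baseFraction = 0.1, fracDifferential = 0.1,
                         turnoverFC = 3, fracSd = 0.25,
                         totalLogMean = log(1e7), totalLogSd = 0.4,
                         seed = 1L) {
  stopifnot(nNeo >= 1, nNeo < nPeptides, baseFraction > 0,
            baseFraction * turnoverFC < 1, fracDifferential >= 0,
            fracDifferential <= 1, fracSd >= 0)
  structure(as.list(environment()), class = "NeoSimParams")
}

#' Simulate a neopeptide abundance table
#'
#' @param params a [neoSimParams()] list.
#' @return list with `table` (long data frame: `protein`, `peptide`,
#'   `sample`, `abundance`, `neo`), `samples` (sample sheet with `sample`,
#'   `group`) and `truth` (per protein: `differential`, planted `fc`,
#'   `target_group`, generative per-group summed fractions).
#' @export
simulateNeopeptides <- function(params = neoSimParams()) {
  set.seed(params$seed)
  nG <- length(params$groups); nS <- nG * params$nPerGroup
  grp <- rep(params$groups, each = params$nPerGroup)
  smp <- sprintf("S%02d", seq_len(nS))
  prot <- sprintf("P%04d", seq_len(params$nProteins))
  nDiff <- round(params$fracDifferential * params$nProteins)
  diffIdx <- if (nDiff > 0) sort(sample(params$nProteins, nDiff)) else integer()
  targetG <- rep(NA_character_, params$nProteins)
  targetG[diffIdx] <- sample(params$groups, length(diffIdx), replace = TRUE)
  # generative group-level summed fraction per protein
  phiG <- matrix(params$baseFraction, params$nProteins, nG,
                 dimnames = list(prot, params$groups))
  for (i in diffIdx)
    phiG[i, targetG[i]] <- params$baseFraction * params$turnoverFC
  phi <- phiG[, match(grp, params$groups), drop = FALSE] *
    exp(matrix(rnorm(params$nProteins * nS, 0, params$fracSd),
               params$nProteins, nS))
  phi <- pmin(phi, 0.9)
  total <- exp(params$totalLogMean +
               matrix(rnorm(params$nProteins * nS, 0, params$totalLogSd),
                      params$nProteins, nS))
  # split neo / non-neo mass across peptides with random proportions
  nP <- params$nPeptides; nN <- params$nNeo
  rows <- vector("list", nP)
  for (j in seq_len(nP)) {
    isNeo <- j <= nN
    share <- matrix(runif(params$nProteins * nS, 0.5, 1.5),
                    params$nProteins, nS)
    rows[[j]] <- list(share = share, neo = isNeo)
  }
  neoShare <- Reduce(`+`, lapply(rows[seq_len(nN)], `[[`, "share"))
  othShare <- Reduce(`+`, lapply(rows[(nN + 1):nP], `[[`, "share"))
  tab <- do.call(rbind, lapply(seq_len(nP), function(j) {
    isNeo <- j <= nN
    mass <- if (isNeo) phi * total * rows[[j]]$share / neoShare
            else (1 - phi) * total * rows[[j]]$share / othShare
    data.frame(protein = rep(prot, nS),
               peptide = sprintf("%s_pep%02d", rep(prot, nS), j),
               sample = rep(smp, each = params$nProteins),
               abundance = as.vector(mass),
               neo = isNeo)
  }))
  truth <- data.frame(protein = prot,
                      differential = seq_len(params$nProteins) %in% diffIdx,
                      fc = ifelse(seq_len(params$nProteins) %in% diffIdx,
                                  params$turnoverFC, 1),
                      target_group = targetG)
  list(table = tab, samples = data.frame(sample = smp, group = grp),
       truth = cbind(truth, as.data.frame(phiG)))
}

#' Simulate a qPCR Ct table with known relative expressions
#'
#' Ct values are generated by inverting the efficiency-corrected relative
#' expression formula: for planted relative expression r and primer
#' efficiency E, `Ct_target = Ct_reference - log(r) / log(E)` (so
#' `E^-(Ct_target - Ct_ref) = r`), plus optional Gaussian Ct noise.
#'
#' @param genes target gene names.
#' @param reference reference gene name.
#' @param groups,nPerGroup design.
#' @param efficiency per-gene primer efficiency (fold per cycle, recycled).
#' @param plantedExpression genes x groups matrix of relative expressions;
#'   defaults to log-uniform draws in [2^-8, 2^-2] held constant per gene.
#' @param refCtMean mean reference-gene Ct.
#' @param ctNoiseSd Gaussian noise on each Ct (cycles).
#' @param seed integer seed.
#' @return list with `table` (long: `gene`, `sample`, `group`, `ct`),
#'   `efficiency` (named per-gene vector incl. reference) and `truth`
#'   (genes x groups matrix of planted relative expressions).
#' @export
simulateCtTable <- function(genes = c("DCN", "FMOD", "BGN", "COMP", "COL1A1",
                                      "COL1A2", "COL3A1", "TGFB1"),
                            reference = "GAPDH", groups = AGE_GROUPS,
                            nPerGroup = 4L, efficiency = 2,
                            plantedExpression = NULL, refCtMean = 20,
                            ctNoiseSd = 0, seed = 1L) {
  set.seed(seed)
  eff <- setNames(rep_len(efficiency, length(genes)), genes)
  if (any(eff <= 1 | eff > 2.2)) stop("efficiencies must be in (1, 2.2]")
  nG <- length(groups); nS <- nG * nPerGroup
  grp <- rep(groups, each = nPerGroup)
  smp <- sprintf("S%02d", seq_len(nS))
  if (is.null(plantedExpression)) {
    plantedExpression <- matrix(2^runif(length(genes), -8, -2),
                                length(genes), nG,
                                dimnames = list(genes, groups))
  }
  refCt <- refCtMean + rnorm(nS, 0, ctNoiseSd)
  rows <- list(data.frame(gene = reference, sample = smp, group = grp,
                          ct = refCt))
  for (g in genes) {
    r <- plantedExpression[g, match(grp, groups)]
    ct <- refCt - log(r) / log(eff[g]) + rnorm(nS, 0, ctNoiseSd)
    rows[[g]] <- data.frame(gene = g, sample = smp, group = grp, ct = ct)
  }
  list(table = do.call(rbind, rows),
       efficiency = c(eff, setNames(2, reference)),
       truth = plantedExpression)
}
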