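#' Protein abundance matrix with normalisation covariates
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] carrying one
#' `"intensity"` assay (proteins x samples, non-negative label-free
#' quantification intensities), with per-sample covariates in `colData`:
#' `capture_area` (laser-capture area, um^2), `load_volume` (volume loaded on
#' the column, uL), plus the study factors `age_group` and `phase`.
#' `metadata(x)$normalised` records whether [normaliseAbundance()] has been
#' applied.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("capture_area", "load_volume", "age_group")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
      return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (any(cd$capture_area <= 0) || any(cd$load_volume <= 0))
      msg <- c(msg, "capture_area and load_volume must be > 0 for all samples")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "protein ids must be unique")
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @describeIn AbundanceMatrix constructor.
#' @param intensities numeric matrix, proteins x samples, with rownames
#'   (protein ids) and colnames (sample ids).
#' @param captureArea,loadVolume per-sample covariates (> 0).
#' @param ageGroup per-sample age-group factor/character.
#' @param phase per-sample phase label (recycled).
#' @param normalised logical flag stored in metadata.
#' @export
AbundanceMatrix <- function(intensities, captureArea, loadVolume, ageGroup,
                            phase = "fascicle", normalised = FALSE) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("P%04d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("S%02d", seq_len(ncol(intensities)))
  cd <- S4Vectors::DataFrame(
    capture_area = captureArea, load_volume = loadVolume,
    age_group = ageGroup, phase = rep_len(phase, ncol(intensities)),
    row.names = colnames(intensities))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities), colData = cd,
    metadata = list(normalised = normalised))
  new("AbundanceMatrix", se)
}

#' @describeIn AbundanceMatrix intensity assay accessor.
#' @param x an `AbundanceMatrix`.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn AbundanceMatrix per-sample age-group labels.
#' @export
ageGroups <- function(x) as.character(SummarizedExperiment::colData(x)$age_group)

#' @describeIn AbundanceMatrix TRUE after normalisation.
#' @export
isNormalised <- function(x) isTRUE(S4Vectors::metadata(x)$normalised)
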