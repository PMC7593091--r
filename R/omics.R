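#' Normalise abundances for capture area and load volume
#'
#' Divides each sample's intensities by its laser-capture area times its
#' column-load volume, then rescales all values by the geometric mean of
#' area x volume across samples so that the matrix keeps its original
#' magnitude.  Removes exactly the multiplicative per-sample distortion the
#' acquisition introduces.
#'
#' @param x an [AbundanceMatrix-class] with `capture_area` and `load_volume`
#'   in `colData`.
#' @return the normalised [AbundanceMatrix-class]
#'   (`isNormalised(x)` becomes `TRUE`).
#' @export
normaliseAbundance <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  av <- cd$capture_area * cd$load_volume
  if (any(!is.finite(av)) || any(av <= 0))
    stop("validation error: capture_area and load_volume must be positive")
  norm <- sweep(intensities(x), 2, av, `/`) * geoMean(av)
  AbundanceMatrix(norm, captureArea = cd$capture_area,
                  loadVolume = cd$load_volume, ageGroup = cd$age_group,
                  phase = cd$phase, normalised = TRUE)
}

# Vectorised one-way ANOVA across matrix rows.  Returns F and p per row;
# rows with zero between- and within-group variance get NA.
rowOneWayF <- function(mat, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- ncol(mat)
  if (k < 2) stop("need at least 2 groups")
  gm <- vapply(levels(groups), function(g)
    rowMeans(mat[, groups == g, drop = FALSE]), numeric(nrow(mat)))
  if (is.null(dim(gm)))   # single-row input: vapply simplifies to a vector
    gm <- matrix(gm, nrow = 1,
                 dimnames = list(rownames(mat), levels(groups)))
  ng <- as.vector(table(groups)[colnames(gm)])
  grand <- rowMeans(mat)
  ssb <- rowSums(sweep((gm - grand)^2, 2, ng, `*`))
  ssw <- rowSums((mat - gm[, as.integer(groups), drop = FALSE])^2)
  dfb <- k - 1; dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  p <- pf(f, dfb, dfw, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0
  p[ssw == 0 & ssb == 0] <- NA_real_
  list(F = f, p = p, groupMeans = gm)
}

#' Differential protein abundance across age groups
#'
#' Per protein: omnibus one-way ANOVA p-value across the age groups plus the
#' group-mean fold change (largest group mean over smallest; zeros imputed as
#' half the smallest nonzero intensity of that protein before ratio
#' computation).  A protein is flagged differentially abundant when the fold
#' change is at least `fcThreshold` AND p < `alpha` (the fold change >= 2,
#' p < 0.05 rule by default), and is reported with the age group of highest
#' mean abundance.
#'
#' @param x a normalised [AbundanceMatrix-class] (a warning is issued if
#'   [normaliseAbundance()] has not been applied).
#' @param alpha significance level.
#' @param fcThreshold fold-change gate.
#' @return data frame: `protein`, `p_value`, `fold_change`, `flagged`,
#'   `highest_mean_group`, `qc`.
#' @export
differentialAbundance <- function(x, alpha = 0.05, fcThreshold = 2) {
  if (!isNormalised(x))
    warning("abundance matrix has not been normalised; results will carry ",
            "capture-area/volume distortion")
  mat <- intensities(x)
  grp <- factor(ageGroups(x), levels = intersect(AGE_GROUPS, ageGroups(x)))
  if (nlevels(grp) < 2 || min(table(grp)) < 2)
    stop("need >= 2 groups with >= 2 samples each")
  res <- rowOneWayF(mat, grp)
  qc <- ifelse(is.na(res$p), "constant_zero", "ok")
  # impute zeros per protein before computing ratios
  imput <- mat
  for (i in which(apply(mat == 0, 1, any))) {
    nz <- mat[i, mat[i, ] > 0]
    if (length(nz)) imput[i, mat[i, ] == 0] <- min(nz) / 2
  }
  gm <- vapply(levels(grp), function(g)
    rowMeans(imput[, grp == g, drop = FALSE]), numeric(nrow(mat)))
  fcv <- apply(gm, 1, max) / apply(gm, 1, min)
  highest <- levels(grp)[apply(gm, 1, which.max)]
  flagged <- !is.na(res$p) & res$p < alpha & fcv >= fcThreshold
  data.frame(protein = rownames(mat), p_value = res$p, fold_change = fcv,
             flagged = flagged, highest_mean_group = highest, qc = qc,
             row.names = NULL)
}

#' Neopeptide turnover analysis
#'
#' For each protein and sample, neopeptide abundances are normalised to the
#' total peptide abundance of that protein in that sample (fractions of the
#' whole, neopeptides included) and summed per protein; the summed
#' fractions are compared across age groups with a one-way ANOVA and
#' Benjamini-Hochberg adjustment at the given false-discovery rate.
#'
#' @param table long data frame with columns `protein`, `peptide`, `sample`,
#'   `abundance`, `neo` (logical: neopeptide row).
#' @param groups named character vector mapping sample -> group (e.g. from
#'   the simulator's sample sheet).
#' @param alpha raw-p significance level.
#' @param fdr Benjamini-Hochberg false-discovery rate.
#' @return data frame: `protein`, `summed_fraction_fc` (max/min group mean),
#'   `p_value`, `p_adjusted`, `significant` (BH-adjusted p < `fdr` and raw
#'   p < `alpha`); proteins observed with a single peptide are excluded and
#'   listed in `attr(, "excluded")`.
#' @export
neopeptideTurnover <- function(table, groups, alpha = 0.05, fdr = 0.05) {
  need <- c("protein", "peptide", "sample", "abundance", "neo")
  miss <- setdiff(need, colnames(table))
  if (length(miss)) stop("table missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  nPep <- rowsum(rep(1, nrow(table)),
                 paste(table$protein, table$peptide, sep = "\r"))
  pepPerProt <- table(sub("\r.*", "", rownames(nPep)))
  excluded <- names(pepPerProt)[pepPerProt < 2]
  tab <- table[!table$protein %in% excluded, ]
  tot <- rowsum(tab$abundance, paste(tab$protein, tab$sample, sep = "\r"))
  key <- paste(tab$protein, tab$sample, sep = "\r")
  frac <- tab$abundance / tot[match(key, rownames(tot)), 1]
  neoTab <- tab[tab$neo, ]
  neoFrac <- frac[tab$neo]
  summed <- rowsum(neoFrac, paste(neoTab$protein, neoTab$sample, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(summed), "\r", fixed = TRUE))
  prots <- sort(unique(parts[, 1])); smps <- sort(unique(parts[, 2]))
  mat <- matrix(0, length(prots), length(smps),
                dimnames = list(prots, smps))
  mat[cbind(match(parts[, 1], prots), match(parts[, 2], smps))] <- summed[, 1]
  grp <- groups[colnames(mat)]
  if (any(is.na(grp))) stop("groups must name every sample in the table")
  res <- rowOneWayF(mat, grp)
  padj <- p.adjust(res$p, method = "BH")
  gm <- res$groupMeans
  fcv <- apply(gm, 1, max) / pmax(apply(gm, 1, min), .Machine$double.eps)
  out <- data.frame(protein = rownames(mat), summed_fraction_fc = fcv,
                    p_value = res$p, p_adjusted = padj,
                    significant = !is.na(padj) & padj < fdr & res$p < alpha,
                    row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Efficiency-corrected relative qPCR expression
#'
#' Relative expression of each target gene against the reference gene in the
#' same sample: `E^-(Ct_target - Ct_reference)` with the target primer's
#' efficiency E.
#'
#' @param table long data frame with columns `gene`, `sample`, `ct` (and
#'   optionally `group`, carried through).
#' @param efficiency named per-gene efficiency vector (fold per cycle;
#'   2 = perfect doubling), or a single value recycled to all targets.
#' @param reference reference gene name (must be present in every sample).
#' @return data frame: `gene`, `sample` (and `group` if present),
#'   `delta_ct`, `rel_expression`.
#' @examples
#' tab <- data.frame(gene = c("GAPDH", "TGFB1"), sample = "S1",
#'                   ct = c(20, 25))
#' relativeExpression(tab, efficiency = 2)  # 2^-5 = 0.03125
#' @export
relativeExpression <- function(table, efficiency = 2, reference = "GAPDH") {
  ref <- table[table$gene == reference, ]
  tgt <- table[table$gene != reference, ]
  missing <- setdiff(unique(tgt$sample), ref$sample)
  if (length(missing))
    stop("missing reference Ct for sample(s): ", paste(missing, collapse = ", "))
  refCt <- setNames(ref$ct, ref$sample)
  genes <- unique(tgt$gene)
  eff <- if (is.null(names(efficiency)))
    setNames(rep_len(efficiency, length(genes)), genes) else efficiency
  bad <- setdiff(genes, names(eff))
  if (length(bad)) stop("no efficiency given for: ", paste(bad, collapse = ", "))
  if (any(eff[genes] <= 1 | eff[genes] > 2.2))
    stop("efficiencies must be in (1, 2.2]")
  dct <- tgt$ct - refCt[tgt$sample]
  out <- tgt[, intersect(c("gene", "sample", "group"), colnames(tgt))]
  out$delta_ct <- dct
  out$rel_expression <- eff[tgt$gene]^(-dct)
  rownames(out) <- NULL
  out
}

#' Primer efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope)` for the slope of Ct against log10 template dilution;
#' a slope of -3.32 gives E = 2 (perfect doubling).
#'
#' @param slope standard-curve slope (Ct per log10 dilution, negative).
#' @return efficiency in fold per cycle.
#' @export
efficiencyFromSlope <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative")
  10^(-1 / slope)
}

#' Structure-function Pearson correlations
#'
#' Pairwise Pearson correlation between each abundance series (rows of
#' `features`) and each mechanical-metric or expression series (columns of
#' `metrics`), aligned by shared sample/animal names; the construction used
#' to relate matrisome protein abundance to mechanical properties or
#' regulator expression.
#'
#' @param features numeric matrix (features x observations) with colnames.
#' @param metrics data frame or matrix (observations x metrics) with
#'   rownames matching `features`' colnames.
#' @param alpha significance level for the `significant` flag.
#' @return data frame: `feature`, `metric`, `r`, `p_value`, `n`,
#'   `significant`, `qc` (zero-variance pairs are flagged and get NA).
#' @export
structureFunctionCorrelation <- function(features, metrics, alpha = 0.05) {
  features <- as.matrix(features)
  metrics <- as.data.frame(metrics)
  shared <- intersect(colnames(features), rownames(metrics))
  if (length(shared) < 3) stop("need >= 3 aligned observations")
  features <- features[, shared, drop = FALSE]
  metrics <- metrics[shared, , drop = FALSE]
  grid <- expand.grid(feature = rownames(features), metric = colnames(metrics),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    xv <- features[grid$feature[i], ]
    yv <- metrics[[grid$metric[i]]]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 3 || sd(xv[ok]) == 0 || sd(yv[ok]) == 0)
      return(data.frame(r = NA_real_, p_value = NA_real_, n = sum(ok),
                        qc = "zero_variance_or_too_few"))
    ct <- cor.test(xv[ok], yv[ok], method = "pearson")
    data.frame(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
               qc = "ok")
  })
  out <- cbind(grid, do.call(rbind, res))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
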