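test_that("covariate normalisation divides out area x volume", {
  m <- matrix(rep(c(100, 100), each = 3), nrow = 3,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  am <- AbundanceMatrix(m, captureArea = c(1, 2), loadVolume = c(1, 1),
                        ageGroup = c("foetus", "foetus"))
  nm <- intensities(normaliseAbundance(am))
  expect_equal(unname(nm[, 1] / nm[, 2]), rep(2, 3))
  # equal covariates: identity after the geometric-mean rescale
  am2 <- AbundanceMatrix(m, captureArea = c(5, 5), loadVolume = c(2, 2),
                         ageGroup = c("foetus", "foetus"))
  expect_equal(intensities(normaliseAbundance(am2)), m)
  expect_true(isNormalised(normaliseAbundance(am)))
})

test_that("normalisation recovers planted group-mean ratios at zero noise", {
  sim <- simulateAbundance(omicsSimParams(nProteins = 60, logSd = 0,
                                          fracDifferential = 0.25, seed = 3L))
  nm <- normaliseAbundance(sim$matrix)
  grp <- ageGroups(nm)
  gm <- vapply(unique(grp), function(g)
    rowMeans(intensities(nm)[, grp == g, drop = FALSE]),
    numeric(nrow(nm)))
  ratio <- apply(gm, 1, max) / apply(gm, 1, min)
  diffp <- sim$truth$differential
  expect_equal(unname(ratio[diffp]), sim$truth$fc[diffp], tolerance = 0.05)
  expect_equal(unname(ratio[!diffp]), rep(1, sum(!diffp)), tolerance = 1e-9)
})

test_that("the planted differential count is exact by construction", {
  sim <- simulateAbundance(omicsSimParams(nProteins = 100,
                                          fracDifferential = 0.2, seed = 7L))
  expect_equal(sum(sim$truth$differential), 20L)
  sim0 <- simulateAbundance(omicsSimParams(nProteins = 50,
                                           fracDifferential = 0, seed = 7L))
  expect_equal(sum(sim0$truth$differential), 0L)
})

test_that("row-wise ANOVA agrees with stats::aov", {
  set.seed(42)
  m <- matrix(rnorm(5 * 20), nrow = 5)
  grp <- rep(letters[1:5], each = 4)
  got <- tendomech:::rowOneWayF(m, grp)
  for (i in 1:5) {
    ref <- summary(aov(m[i, ] ~ factor(grp)))[[1]]
    expect_equal(got$F[i], ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(got$p[i], ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("differential abundance applies the fold-change AND p gates", {
  sim <- simulateAbundance(omicsSimParams(nProteins = 150, logSd = 0.3,
                                          fracDifferential = 0.1,
                                          minPlantedFC = 4, seed = 5L))
  de <- differentialAbundance(normaliseAbundance(sim$matrix))
  diffp <- sim$truth$differential
  expect_gt(mean(de$flagged[diffp]), 0.8)
  # a planted FC of 1.5 can never pass the fold-change gate at zero noise
  grp <- rep(tendomech:::AGE_GROUPS, each = 4)
  m <- matrix(1000, nrow = 10, ncol = 20,
              dimnames = list(paste0("P", 1:10), paste0("S", 1:20)))
  m[1, grp == "foetus"] <- 1500
  set.seed(6)
  m <- m + matrix(rnorm(200, 0, 1e-6), 10, 20)   # break zero variance
  am <- AbundanceMatrix(m, captureArea = rep(1, 20), loadVolume = rep(1, 20),
                        ageGroup = grp, normalised = TRUE)
  de2 <- differentialAbundance(am)
  expect_false(de2$flagged[1])
  expect_equal(de2$fold_change[1], 1.5, tolerance = 1e-4)
})

test_that("flagged proteins report the planted highest-mean group", {
  sim <- simulateAbundance(omicsSimParams(nProteins = 100, logSd = 0.2,
                                          fracDifferential = 0.15,
                                          minPlantedFC = 4, seed = 11L))
  de <- differentialAbundance(normaliseAbundance(sim$matrix))
  hit <- de$flagged & sim$truth$differential
  expect_gt(sum(hit), 5)
  expect_true(all(de$highest_mean_group[hit] ==
                  sim$truth$highest_group[hit]))
})

test_that("neopeptide fractions and sums follow the worked example", {
  tab <- data.frame(protein = "P", peptide = c("neoA", "neoB", "other"),
                    sample = "S", abundance = c(2, 1, 7),
                    neo = c(TRUE, TRUE, FALSE))
  tab <- rbind(tab, transform(tab, sample = "S2", abundance = c(1, 1, 8)))
  groups <- c(S = "foetus", S2 = "1-2 years")
  res <- neopeptideTurnover(tab, groups)
  # S: fractions 0.2 + 0.1 = 0.3; S2: 0.1 + 0.1 = 0.2
  expect_equal(res$summed_fraction_fc, 0.3 / 0.2, tolerance = 1e-12)
})

test_that("single-peptide proteins are excluded from turnover analysis", {
  tab <- data.frame(protein = c("P", "P", "Q"),
                    peptide = c("p1", "p2", "q1"),
                    sample = "S", abundance = c(1, 2, 3),
                    neo = c(TRUE, FALSE, TRUE))
  tab <- rbind(tab, transform(tab, sample = "S2"))
  res <- neopeptideTurnover(tab, c(S = "a", S2 = "b"))
  expect_equal(attr(res, "excluded"), "Q")
  expect_false("Q" %in% res$protein)
})

test_that("turnover effects planted by the simulator are recovered with BH control", {
  sim <- simulateNeopeptides(neoSimParams(nProteins = 120,
                                          fracDifferential = 0.1, seed = 2L))
  grp <- setNames(sim$samples$group, sim$samples$sample)
  res <- neopeptideTurnover(sim$table, grp)
  res <- res[match(sim$truth$protein, res$protein), ]
  expect_gt(mean(res$significant[sim$truth$differential]), 0.8)
  expect_lt(mean(res$significant[!sim$truth$differential]), 0.1)
})

test_that("relative expression follows E^-deltaCt", {
  tab <- data.frame(gene = c("GAPDH", "TGFB1"), sample = "S1", ct = c(20, 25))
  expect_equal(relativeExpression(tab)$rel_expression, 2^-5)
  tab2 <- data.frame(gene = c("GAPDH", "DCN"), sample = "S1", ct = c(21, 21))
  expect_equal(relativeExpression(tab2, efficiency = 1.8)$rel_expression, 1)
  expect_error(relativeExpression(
    data.frame(gene = "DCN", sample = "S1", ct = 25)), "reference")
})

test_that("relative expression is invariant to per-sample Ct offsets", {
  sim <- simulateCtTable(seed = 4L)
  base <- relativeExpression(sim$table, sim$efficiency)
  shifted <- sim$table
  off <- setNames(runif(length(unique(shifted$sample)), -3, 3),
                  unique(shifted$sample))
  shifted$ct <- shifted$ct + off[shifted$sample]
  expect_equal(relativeExpression(shifted, sim$efficiency)$rel_expression,
               base$rel_expression, tolerance = 1e-12)
})

test_that("simulated Ct tables invert exactly to the planted expressions", {
  sim <- simulateCtTable(ctNoiseSd = 0, seed = 9L)
  rel <- relativeExpression(sim$table, sim$efficiency)
  for (g in rownames(sim$truth)) {
    got <- rel[rel$gene == g, ]
    expect_equal(got$rel_expression,
                 unname(sim$truth[g, match(got$group, colnames(sim$truth))]),
                 tolerance = 1e-9)
  }
  # planted 0.5 at perfect efficiency is one cycle of separation
  simP <- simulateCtTable(genes = "TGFB1", plantedExpression =
    matrix(0.5, 1, 5, dimnames = list("TGFB1", tendomech:::AGE_GROUPS)),
    ctNoiseSd = 0, seed = 1L)
  rel2 <- relativeExpression(simP$table, simP$efficiency)
  expect_equal(unique(round(rel2$delta_ct, 12)), 1)
})

test_that("standard-curve efficiency follows 10^(-1/slope)", {
  expect_equal(efficiencyFromSlope(-3.3219281), 2, tolerance = 1e-6)
  expect_error(efficiencyFromSlope(2), "negative")
})

test_that("Pearson correlations match the definitional formula and exact lines", {
  x <- c(1, 2, 3, 4, 5, 6)
  feats <- rbind(up = 2 * x + 1, down = -x)
  met <- data.frame(metric = x, row.names = paste0("S", 1:6))
  colnames(feats) <- rownames(met)
  res <- structureFunctionCorrelation(feats, met)
  expect_equal(res$r[res$feature == "up"], 1.0, tolerance = 1e-12)
  expect_equal(res$r[res$feature == "down"], -1.0, tolerance = 1e-12)
  set.seed(3)
  yy <- rnorm(6)
  feats2 <- rbind(a = rnorm(6)); colnames(feats2) <- rownames(met)
  met2 <- data.frame(m = yy, row.names = rownames(met))
  r <- structureFunctionCorrelation(feats2, met2)$r
  expect_equal(r, oraclePearson(feats2[1, ], yy), tolerance = 1e-12)
  # zero-variance series are flagged, not computed
  feats3 <- rbind(flat = rep(1, 6)); colnames(feats3) <- rownames(met)
  expect_equal(structureFunctionCorrelation(feats3, met)$qc,
               "zero_variance_or_too_few")
})
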