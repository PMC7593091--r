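test_that("the normality gate applies the CLT rule, then Shapiro with fallbacks", {
  set.seed(1)
  # n > 30: assumed normal regardless of shape
  g <- normalityGate(rexp(50))
  expect_equal(g$decision, "assume_normal")
  # small normal sample passes Shapiro
  expect_equal(normalityGate(rnorm(12))$decision, "assume_normal")
  # log-normal that fails raw Shapiro but passes after log10
  set.seed(7)
  x <- exp(rnorm(12, 0, 1.5))
  stopifnot(shapiro.test(x)$p.value < 0.05,
            shapiro.test(log10(x))$p.value >= 0.05)
  g2 <- normalityGate(x)
  expect_equal(g2$decision, "transform_log10")
  # a negative value blocks the log path
  g3 <- normalityGate(c(x[-1], -2))
  if (g3$decision != "assume_normal")
    expect_equal(g3$decision, "rank_fallback")
  expect_error(normalityGate(c(1, 2)), "n >= 3")
})

test_that("two-factor analysis detects a planted tendon-by-age interaction", {
  set.seed(5)
  d <- expand.grid(tendon = c("SDFT", "CDET"),
                   age_group = tendomech:::AGE_GROUPS,
                   rep = 1:4, stringsAsFactors = FALSE)
  ageIdx <- match(d$age_group, tendomech:::AGE_GROUPS)
  d$y <- 10 + ifelse(d$tendon == "SDFT", -1.5 * (ageIdx - 1), 0) +
    rnorm(nrow(d), 0, 0.5)
  eff <- twoFactorAnalysis(d, "y")
  expect_lt(eff$p_value[eff$term == "tendon:age_group"], 0.01)
  expect_equal(attr(eff, "decision"), "assume_normal")   # n = 40 > 30
})

test_that("constant responses yield NA effects with a QC flag instead of errors", {
  d <- expand.grid(tendon = c("SDFT", "CDET"),
                   age_group = c("foetus", "0 days"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- 5
  eff <- twoFactorAnalysis(d, "y")
  expect_true(all(is.na(eff$p_value)))
  expect_equal(attr(eff, "qc"), "constant_response")
})

test_that("p-values are invariant to affine response changes under normality", {
  set.seed(9)
  d <- expand.grid(tendon = c("SDFT", "CDET"),
                   age_group = tendomech:::AGE_GROUPS, rep = 1:4,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 10, 1)
  a <- twoFactorAnalysis(d, "y", gate = "assume_normal")
  d$y2 <- 3.2 * d$y - 17
  b <- twoFactorAnalysis(d, "y2", gate = "assume_normal")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("the rank fallback is invariant to monotone transformations", {
  set.seed(10)
  d <- expand.grid(tendon = c("SDFT", "CDET"),
                   age_group = tendomech:::AGE_GROUPS, rep = 1:4,
                   stringsAsFactors = FALSE)
  d$y <- rlnorm(nrow(d))
  a <- twoFactorAnalysis(d, "y", gate = "rank_fallback")
  d$y2 <- d$y^3
  b <- twoFactorAnalysis(d, "y2", gate = "rank_fallback")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_false(attr(a, "parametric"))
})

test_that("an empty design cell degrades to an additive model with a warning", {
  set.seed(11)
  d <- expand.grid(tendon = c("SDFT", "CDET"),
                   age_group = c("foetus", "0 days", "0-1 month"), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  d <- d[!(d$tendon == "CDET" & d$age_group == "foetus"), ]
  expect_warning(eff <- twoFactorAnalysis(d, "y"), "additive")
  expect_true(is.na(eff$p_value[eff$term == "tendon:age_group"]))
  expect_false(is.na(eff$p_value[eff$term == "tendon"]))
})

test_that("compact letter displays separate exactly the significant pairs", {
  groups <- tendomech:::AGE_GROUPS
  mkd <- function(means, n = 6, sd = 0.3, seed = 1) {
    set.seed(seed)
    data.frame(age_group = rep(groups, each = n),
               y = rnorm(length(groups) * n, rep(means, each = n), sd))
  }
  # all identical -> single letter
  d0 <- mkd(rep(5, 5))
  expect_true(all(posthocLetters(d0, "y") == "a"))
  # one far-shifted group gets its own letter
  d1 <- mkd(c(0, 0, 0, 0, 10))
  l1 <- posthocLetters(d1, "y")
  expect_false(grepl(l1[["1-2 years"]], paste(l1[1:4], collapse = "")))
  expect_equal(nchar(l1[["1-2 years"]]), 1L)
  # two well-separated clusters -> exactly two letters
  d2 <- mkd(c(0, 0, 0, 10, 10))
  l2 <- posthocLetters(d2, "y")
  expect_equal(length(unique(l2)), 2L)
  expect_equal(length(unique(unlist(strsplit(paste(l2, collapse = ""), "")))), 2L)
})

test_that("letters share if and only if the Holm-adjusted pair is non-significant", {
  set.seed(14)
  groups <- tendomech:::AGE_GROUPS
  d <- data.frame(age_group = rep(groups, each = 5),
                  y = rnorm(25, rep(c(0, 0.5, 2, 4, 4.2), each = 5), 0.8))
  lets <- posthocLetters(d, "y")
  pw <- pairwise.t.test(d$y, factor(d$age_group, levels = groups),
                        pool.sd = FALSE, p.adjust.method = "holm")$p.value
  for (i in 1:4) for (j in (i + 1):5) {
    pv <- if (!is.na(pw[groups[j], groups[i]])) pw[groups[j], groups[i]]
          else pw[groups[i], groups[j]]
    share <- length(intersect(strsplit(lets[i], "")[[1]],
                              strsplit(lets[j], "")[[1]])) > 0
    if (pv < 0.05) expect_false(share) else expect_true(share)
  }
})

test_that("weighted kappa matches its definition and the boundary cases", {
  expect_equal(weightedKappa(diag(c(5, 8, 3, 4))), 1)
  # independent raters: expected = observed outer product
  marg <- c(10, 20, 30, 40)
  indep <- outer(marg, marg) / sum(marg)
  expect_equal(weightedKappa(indep), 0, tolerance = 1e-12)
  tab <- matrix(c(12, 3, 1, 0,
                  2, 9, 4, 1,
                  0, 3, 8, 2,
                  0, 1, 2, 6), 4, 4, byrow = TRUE)
  expect_equal(weightedKappa(tab), oracleWeightedKappa(tab), tolerance = 1e-12)
  expect_equal(weightedKappa(tab, "linear") <= 1, TRUE)
  expect_error(weightedKappa(matrix(0, 3, 3)), "zero total")
  expect_error(weightedKappa(matrix(1, 2, 3)), "square")
})

test_that("letters and effects are invariant to specimen relabelling", {
  set.seed(15)
  groups <- tendomech:::AGE_GROUPS
  d <- data.frame(age_group = rep(groups, each = 4),
                  tendon = rep(c("SDFT", "CDET"), 10),
                  y = rnorm(20, rep(1:5, each = 4)))
  perm <- sample(nrow(d))
  expect_equal(posthocLetters(d, "y"), posthocLetters(d[perm, ], "y"))
  a <- twoFactorAnalysis(d, "y", gate = "assume_normal")
  b <- twoFactorAnalysis(d[perm, ], "y", gate = "assume_normal")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})
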