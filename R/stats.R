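#' Normality gate for a metric sample
#'
#' The decision rule applied before parametric analysis: normality is assumed
#' by the central limit theorem when n > 30; otherwise a Shapiro-Wilk test at
#' `alpha` is run, and on rejection the log10-transformed data (requiring
#' positivity) are retested; if still rejected (or the data are not strictly
#' positive) the analysis falls back to ranks.
#'
#' @param x numeric sample, n >= 3.
#' @param alpha Shapiro-Wilk significance level.
#' @return list: `decision` (`"assume_normal"`, `"transform_log10"` or
#'   `"rank_fallback"`), `n`, `shapiro_p`, `shapiro_log_p`.
#' @export
normalityGate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("normality gate needs n >= 3")
  if (n > 30)
    return(list(decision = "assume_normal", n = n, shapiro_p = NA_real_,
                shapiro_log_p = NA_real_))
  if (sd(x) == 0)   # degenerate: Shapiro undefined; ranks are safe
    return(list(decision = "rank_fallback", n = n, shapiro_p = NA_real_,
                shapiro_log_p = NA_real_))
  p1 <- shapiro.test(x)$p.value
  if (p1 >= alpha)
    return(list(decision = "assume_normal", n = n, shapiro_p = p1,
                shapiro_log_p = NA_real_))
  if (all(x > 0)) {
    p2 <- shapiro.test(log10(x))$p.value
    if (p2 >= alpha)
      return(list(decision = "transform_log10", n = n, shapiro_p = p1,
                  shapiro_log_p = p2))
    return(list(decision = "rank_fallback", n = n, shapiro_p = p1,
                shapiro_log_p = p2))
  }
  list(decision = "rank_fallback", n = n, shapiro_p = p1,
       shapiro_log_p = NA_real_)
}

#' Two-factor (tendon x age group) analysis of a derived metric
#'
#' Two-way ANOVA with interaction and Type-III sums of squares (sum-to-zero
#' contrasts; group sizes are allowed to be unbalanced).  The response first
#' passes [normalityGate()]: under `transform_log10` the response is
#' log10-transformed, under `rank_fallback` the ANOVA runs on
#' rank-transformed data and is labelled non-parametric.  If some design
#' cell is empty the interaction is inestimable and a reduced additive model
#' is fitted with a warning.
#'
#' @param data data frame holding the response and both factors.
#' @param response name of the response column.
#' @param factor1,factor2 names of the factor columns.
#' @param gate `"auto"` (apply the normality gate), or force
#'   `"assume_normal"`, `"transform_log10"`, `"rank_fallback"`.
#' @param alpha gate significance level.
#' @return data frame with one row per term (`factor1`, `factor2`,
#'   interaction): `sum_sq`, `df`, `F`, `p_value`; attributes `decision`
#'   (gate outcome), `parametric` and `qc`.
#' @export
twoFactorAnalysis <- function(data, response, factor1 = "tendon",
                              factor2 = "age_group", gate = "auto",
                              alpha = 0.05) {
  y <- data[[response]]
  f1 <- droplevels(factor(data[[factor1]]))
  f2 <- droplevels(factor(data[[factor2]], levels =
    if (all(data[[factor2]] %in% AGE_GROUPS)) AGE_GROUPS else
      unique(data[[factor2]])))
  if (nlevels(f1) < 2 || nlevels(f2) < 2) stop("need >= 2 levels per factor")
  qc <- "ok"
  if (sd(y[is.finite(y)]) == 0) {
    out <- data.frame(term = c(factor1, factor2,
                               paste(factor1, factor2, sep = ":")),
                      sum_sq = 0, df = NA_real_, F = NA_real_, p_value = NA_real_)
    attr(out, "decision") <- "constant_response"
    attr(out, "parametric") <- NA
    attr(out, "qc") <- "constant_response"
    return(out)
  }
  decision <- if (identical(gate, "auto")) normalityGate(y, alpha)$decision
              else match.arg(gate, c("assume_normal", "transform_log10",
                                     "rank_fallback"))
  yt <- switch(decision,
               assume_normal = y,
               transform_log10 = {
                 if (any(y <= 0)) stop("log10 transform requires positive data")
                 log10(y)
               },
               rank_fallback = rank(y))
  d <- data.frame(y = yt, f1 = f1, f2 = f2)
  cells <- table(f1, f2)
  additive <- any(cells == 0)
  if (additive)
    warning("empty design cell(s): interaction inestimable, fitting additive model")
  form <- if (additive) y ~ f1 + f2 else y ~ f1 * f2
  fit <- lm(form, data = d,
            contrasts = list(f1 = "contr.sum", f2 = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  pick <- function(term) {
    i <- match(term, rownames(a3))
    if (is.na(i)) c(NA_real_, NA_real_, NA_real_, NA_real_)
    else c(a3[i, "Sum Sq"], a3[i, "Df"], a3[i, "F value"], a3[i, "Pr(>F)"])
  }
  rows <- rbind(pick("f1"), pick("f2"), pick("f1:f2"))
  out <- data.frame(term = c(factor1, factor2,
                             paste(factor1, factor2, sep = ":")),
                    sum_sq = rows[, 1], df = rows[, 2], F = rows[, 3],
                    p_value = rows[, 4])
  attr(out, "decision") <- decision
  attr(out, "parametric") <- decision != "rank_fallback"
  attr(out, "qc") <- qc
  out
}

#' Compact letter display for age-group differences
#'
#' All-pairs Welch t tests with Holm adjustment; groups between which no
#' significant difference was found share a letter, and letters are assigned
#' in age order (insert-and-absorb algorithm).
#'
#' @param data data frame with the response and grouping columns.
#' @param response response column name.
#' @param group grouping column name (levels ordered by age when they are
#'   age groups).
#' @param alpha significance level on the adjusted p-values.
#' @return named character vector of letter strings, one per group level.
#' @export
posthocLetters <- function(data, response, group = "age_group", alpha = 0.05) {
  g <- droplevels(factor(data[[group]], levels =
    if (all(data[[group]] %in% AGE_GROUPS)) AGE_GROUPS else
      unique(data[[group]])))
  y <- data[[response]]
  lev <- levels(g)
  k <- length(lev)
  if (k < 2) stop("need >= 2 groups")
  pm <- matrix(1, k, k, dimnames = list(lev, lev))
  pw <- suppressWarnings(
    pairwise.t.test(y, g, pool.sd = FALSE, p.adjust.method = "holm"))$p.value
  for (i in rownames(pw)) for (j in colnames(pw))
    if (!is.na(pw[i, j])) pm[i, j] <- pm[j, i] <- pw[i, j]
  sig <- pm < alpha
  # insert-and-absorb: maintain sets of mutually non-different groups
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    repeat {
      hit <- which(vapply(sets, function(s) all(c(i, j) %in% s), logical(1)))
      if (!length(hit)) break
      s <- hit[1]
      sets <- c(sets, list(setdiff(sets[[s]], i)), list(setdiff(sets[[s]], j)))
      sets[[s]] <- NULL
    }
    # absorb duplicated / contained sets
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(sets[[a]] %in% sets[[b]]) && length(sets[[a]]) <= length(sets[[b]]))
        if (length(sets[[a]]) < length(sets[[b]]) || a > b) keep[a] <- FALSE
    }
    sets <- sets[keep]
  }
  # order sets by their first (age-ordered) member and assign letters
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- setNames(rep("", k), lev)
  for (s in seq_along(sets))
    for (m in sets[[s]]) out[m] <- paste0(out[m], letters[s])
  out
}

#' Weighted kappa inter-rater agreement
#'
#' Chance-corrected agreement between two ordinal raters:
#' `kappa_w = 1 - sum(w * O) / sum(w * E)` where O are observed proportions,
#' E the outer-product (independence) expectation, and w distance-dependent
#' disagreement weights (quadratic by default).
#'
#' @param table square k x k cross-tabulation of the two raters' grades.
#' @param weights `"quadratic"` or `"linear"`.
#' @return kappa in [-1, 1].
#' @examples
#' weightedKappa(diag(5, 4))  # perfect agreement -> 1
#' @export
weightedKappa <- function(table, weights = c("quadratic", "linear")) {
  weights <- match.arg(weights)
  table <- as.matrix(table)
  k <- nrow(table)
  if (ncol(table) != k) stop("table must be square")
  if (any(table < 0)) stop("counts must be non-negative")
  n <- sum(table)
  if (n == 0) stop("table has zero total count")
  d <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  w <- if (weights == "quadratic") d^2 else d
  o <- table / n
  e <- outer(rowSums(table), colSums(table)) / n^2
  kap <- 1 - sum(w * o) / sum(w * e)
  stopifnot(kap >= -1 - 1e-12, kap <= 1 + 1e-12)
  min(max(kap, -1), 1)
}
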