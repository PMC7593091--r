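# Independent oracles, kept deliberately naive and separate from the
# package's own computational paths.

# direct O(n^2) superposition sum for the quasi-linear-viscoelastic response:
# F(t_i) = sum_j G(t_i - t_j) * dFe_j with G(t) = (1 - v) + v exp(-t/tau),
# increments weighted at interval midpoints (matching the quadrature the
# recursive scheme discretises)
oracleQlv <- function(fe, time, v, tau) {
  n <- length(fe)
  dfe <- diff(c(0, fe))
  tmid <- time - diff(c(time[1] - (time[2] - time[1]), time)) / 2
  vapply(seq_len(n), function(i) {
    j <- seq_len(i)
    g <- (1 - v) + v * exp(-(time[i] - tmid[j]) / tau)
    sum(g * dfe[j])
  }, numeric(1))
}

# exact signed polygon (shoelace) area of a closed loop
oracleLoopArea <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# brute-force sliding-window OLS slopes via lm()
oracleWindowSlopes <- function(x, y, w) {
  vapply(seq_len(length(x) - w + 1L), function(i) {
    unname(coef(lm(yi ~ xi, data.frame(xi = x[i:(i + w - 1L)],
                                       yi = y[i:(i + w - 1L)])))[2])
  }, numeric(1))
}

# definitional weighted kappa: kappa_w = (po_w - pe_w) / (1 - pe_w) with
# agreement weights 1 - d^2 (equivalent to the disagreement-weight form)
oracleWeightedKappa <- function(tab) {
  tab <- as.matrix(tab); k <- nrow(tab); n <- sum(tab)
  wAgree <- 1 - (abs(outer(1:k, 1:k, `-`)) / (k - 1))^2
  po <- sum(wAgree * tab / n)
  pe <- sum(wAgree * outer(rowSums(tab), colSums(tab)) / n^2)
  (po - pe) / (1 - pe)
}

# definitional Pearson r from raw sums
oraclePearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# local least-squares polynomial smoother, fitted point by point (the
# definition a Savitzky-Golay filter implements by convolution)
oracleLocalPolySmooth <- function(y, frame, order) {
  n <- length(y); half <- (frame - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, min(i - half, n - frame + 1)); hi <- lo + frame - 1
    tt <- (lo:hi) - i
    unname(predict(lm(yy ~ poly(tt, order, raw = TRUE),
                      data.frame(tt = tt, yy = y[lo:hi])),
                   newdata = data.frame(tt = 0)))
  }, numeric(1))
}
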