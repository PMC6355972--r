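# Independent oracles used across test files.

# Exhaustive-scan Otsu: minimize within-class variance over candidate
# thresholds placed between consecutive distinct intensities.
otsuExhaustive <- function(v) {
  u <- sort(unique(as.numeric(v)))
  cand <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    (length(lo) * ifelse(length(lo) > 1, var(lo), 0) +
     length(hi) * ifelse(length(hi) > 1, var(hi), 0)) / length(v)
  }, numeric(1))
  cand[which.min(wcv)]
}

# Full-enumeration Spearman permutation p (R implementation, n small).
spearmanPermExhaustive <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  pm <- perms(ry)
  stats <- abs(apply(pm, 1, function(p) cor(rx, p)))
  mean(stats >= obs - 1e-12)
}

# Closed-form prolate spheroid area (a = b < c).
prolateArea <- function(a, c) {
  e <- sqrt(1 - a^2 / c^2)
  2 * pi * a^2 * (1 + c / (a * e) * asin(e))
}
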