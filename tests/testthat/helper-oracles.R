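# Independent oracles, kept deliberately naive.

# Exhaustive null for unit-weight pools: every size-k subset, both metrics.
enum_null <- function(enrichment, k, threshold = 2) {
  idx <- utils::combn(length(enrichment), k)
  freq <- apply(idx, 2, function(i) {
    100 * sum(enrichment[i] >= threshold) / k
  })
  avg <- apply(idx, 2, function(i) {
    e <- enrichment[i]
    lab <- e >= threshold
    if (any(lab)) mean(e[lab]) else NA_real_
  })
  list(freq = freq, avg = avg)
}

# Concordance correlation evaluated by spreadsheet-style arithmetic
# (explicit sums, population moments), independent of lin_ccc().
ccc_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x) / n
  sy <- sum(y) / n
  ssx <- sum((x - sx)^2) / n
  ssy <- sum((y - sy)^2) / n
  sxy <- sum((x - sx) * (y - sy)) / n
  (2 * sxy) / (ssx + ssy + (sx - sy)^2)
}

# Hand-computed pooled two-sample t.
pooled_t_by_hand <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}
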