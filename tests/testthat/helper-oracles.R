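# Independent oracles used across the suite. These are deliberately naive
# (enumeration, hand risk-set accounting) and share no code with the
# implementation paths they check.

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over tables with the observed margins.
fisher_2x2_enum <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p (no ties) by enumerating every assignment
# of the pooled observations to group A.
mw_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Two-group log-rank chi-square by hand risk-set accounting.
logrank_manual <- function(time, event, group) {
  group <- as.integer(factor(group))
  o1 <- 0
  e1 <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# A minimal labeled point set for boundary-fit tests.
make_points <- function(tp, fp) {
  data.frame(depth = c(tp[, 1], fp[, 1]),
             quality = c(tp[, 2], fp[, 2]),
             label = factor(rep(c("TP", "FP"), c(nrow(tp), nrow(fp))),
                            levels = c("TP", "FP")))
}

# Brute-force minimum FPr over all axis-aligned accept rules with
# FNr <= target, written as a plain double loop.
rule_bruteforce_fpr <- function(points, target_fnr) {
  tp <- points[points$label == "TP", ]
  fp <- points[points$label == "FP", ]
  best <- Inf
  for (td in c(-Inf, unique(c(tp$depth, fp$depth)))) {
    for (tq in c(-Inf, unique(c(tp$quality, fp$quality)))) {
      fnr <- mean(!(tp$depth >= td & tp$quality >= tq))
      if (fnr > target_fnr) next
      fpr <- mean(fp$depth >= td & fp$quality >= tq)
      if (fpr < best) best <- fpr
    }
  }
  best
}

# Build a synergy_result with given per-level mean and SD: three values
# m + c(-s, 0, s) have mean m and sample SD s exactly.
result_fixture <- function(m50, s50 = NA, m75 = NA, s75 = NA) {
  vals <- function(m, s) {
    if (is.na(m)) NA_real_
    else if (is.na(s)) m
    else m + c(-s, 0, s)
  }
  summarize_ci(vals(m50, s50), vals(m75, s75))
}
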