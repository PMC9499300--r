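# Independent oracles used to cross-check the package implementations.

# Two-sided Fisher p by direct enumeration of all tables sharing the margins,
# with probabilities computed from binomial coefficients (not dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (k == 0 || m + n == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Literal ACMG rule-table evaluation: each qualifying combination is spelled
# out as its own predicate over the code multiset.
oracle_acmg <- function(codes) {
  has <- function(x) x %in% codes
  n_of <- function(prefix, idx) sum(paste0(prefix, idx) %in% codes)
  ps <- n_of("PS", 1:4)
  pm <- n_of("PM", 1:6)
  pp <- n_of("PP", 1:5)
  bs <- n_of("BS", 1:4)
  bp <- n_of("BP", 1:7)

  path_rules <- c(
    has("PVS1") && ps >= 1,
    has("PVS1") && pm >= 2,
    has("PVS1") && pm == 1 && pp == 1,
    has("PVS1") && pm >= 1 && pp >= 1,
    has("PVS1") && pp >= 2,
    ps >= 2,
    ps == 1 && pm >= 3,
    ps == 1 && pm == 2 && pp >= 2,
    ps == 1 && pm == 1 && pp >= 4
  )
  lp_rules <- c(
    has("PVS1") && pm == 1,
    ps == 1 && (pm == 1 || pm == 2),
    ps == 1 && pp >= 2,
    pm >= 3,
    pm == 2 && pp >= 2,
    pm == 1 && pp >= 4
  )
  benign_rules <- c(has("BA1"), bs >= 2)
  lb_rules <- c(bs == 1 && bp == 1, bs >= 1 && bp >= 1, bp >= 2)

  p_fire <- any(path_rules) || any(lp_rules)
  b_fire <- any(benign_rules) || any(lb_rules)
  p_present <- has("PVS1") || ps > 0 || pm > 0 || pp > 0
  b_present <- has("BA1") || bs > 0 || bp > 0
  if ((p_fire && b_present) || (b_fire && p_present)) return("VUS")
  if (any(path_rules)) return("Pathogenic")
  if (any(lp_rules)) return("LikelyPathogenic")
  if (any(benign_rules)) return("Benign")
  if (any(lb_rules)) return("LikelyBenign")
  "VUS"
}

# Hypergeometric upper tail by enumerating every possible draw of n genes
# from a universe of size N (feasible for N <= 12).
oracle_ora_p <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, inset)))
  mean(overlaps >= k)
}
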