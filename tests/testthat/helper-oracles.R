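# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# Exhaustive weighted-KS running sum: walk every position of the ranked
# list and take the deviation of largest magnitude (ties resolve to the
# positive excursion, matching the documented convention).
gsea_es_oracle <- function(rs, gene_set, exponent = 1) {
  ord <- order(-rs, names(rs), method = "radix")
  rs <- rs[ord]
  hit <- names(rs) %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) return(NA_real_)
  w <- abs(rs)^exponent
  S <- sum(w[hit])
  inc <- if (S > 0) w / S else rep(1 / nh, length(rs))
  miss <- if (length(rs) > nh) 1 / (length(rs) - nh) else 0
  run <- 0
  best <- 0
  for (i in seq_along(rs)) {
    run <- run + if (hit[i]) unname(inc[i]) else -miss
    if (abs(run) > abs(best) + 1e-9 ||
        (abs(run) > abs(best) - 1e-9 && run > best))
      best <- run
  }
  best
}

# Textbook O(m^2) BH step-up: adj_i = min over j with p_j >= p_i of
# p_j * m / rank(p_j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- p * m / r
    min(1, min(cand[p >= p[i]]))
  }, numeric(1))
}

# Exhaustive two-sided Wilcoxon rank-sum p-value by enumerating every
# C(n1+n2, n1) assignment of the joint ranks to group 1.
wilcox_enum_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Direct two-sample pooled-variance formulas for one gene.
pooled_oracle <- function(x, y) {
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  list(log2fc = mean(y) - mean(x), s2 = s2,
       df = length(x) + length(y) - 2)
}
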