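# Independent oracles used across the suite.

# Exact one-sample signed-rank p by brute-force enumeration of all 2^n sign
# assignments (average ranks for tied magnitudes). Independent of
# stats::wilcox.test.
signed_rank_p_enum <- function(x, alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Pooled-variance two-sample t-test from the textbook formula.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n0 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n0 - 1) * var(b)) / (n1 + n0 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = tt, df = n1 + n0 - 2, p = 2 * pt(-abs(tt), n1 + n0 - 2))
}

# Step-up BH from the definition: p(i) * m / i, cumulative min from the
# largest rank, capped at 1, returned in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj)[order(o)]
}

# A small, fast default simulation shared by tests.
small_config <- function(seed = 11, ...) {
  sim_config(n_proteins = 120, n_er = 30, seed = seed, ...)
}

# Run the simulator through matrix -> centred log2 in one step.
sim_centred <- function(cfg) {
  truth <- generate_truth(cfg)
  pq <- simulate_protein_matrix(truth, cfg)
  list(truth = truth, pq = pq, design = plex_design(cfg),
       centred = center_log2(pq, plex_design(cfg)))
}
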