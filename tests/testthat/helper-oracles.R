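# Independent brute-force oracles used to cross-check the optimized
# implementations, plus small fixture builders.

# O(n^2) sample-entropy pair counting by direct enumeration over the
# standard N - m templates (vectorized over j for speed, but structurally
# independent of the compiled implementation).
sampen_oracle_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  emb <- vapply(0:m, function(k) x[(1:nt) + k], numeric(nt))
  A <- 0; B <- 0
  for (i in 1:(nt - 1L)) {
    js <- (i + 1L):nt
    dmax <- rep(0, length(js))
    for (k in 1:m) dmax <- pmax(dmax, abs(emb[js, k] - emb[i, k]))
    match_m <- dmax <= r
    B <- B + sum(match_m)
    A <- A + sum(match_m & abs(emb[js, m + 1L] - emb[i, m + 1L]) <= r)
  }
  c(A = A, B = B)
}

sampen_oracle <- function(x, m, r) {
  cnt <- sampen_oracle_counts(x, m, r)
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

# Exhaustive pair-count AUC: P(case on the case side of a control).
auc_oracle <- function(cases, controls, direction = "case_low") {
  wins <- 0; ties <- 0
  for (x in cases) {
    for (y in controls) {
      cmp <- if (direction == "case_low") x < y else x > y
      if (cmp) wins <- wins + 1 else if (x == y) ties <- ties + 1
    }
  }
  (wins + 0.5 * ties) / (length(cases) * length(controls))
}

# NN series of iid Gaussian intervals (gap-free).
gaussian_nn <- function(n, mean_ms = 900, sd_ms = 50, seed = 1) {
  set.seed(seed)
  nn_series(pmax(300, rnorm(n, mean_ms, sd_ms)))
}

# Rebuild a beat series from the kept beats of an NN series (for
# idempotence checks of the cleaning rule).
nn_to_beats <- function(nn) {
  n <- length(nn$intervals)
  ends <- nn$onset_times + nn$intervals / 1000
  beat_series(sort(unique(c(nn$onset_times, ends))))
}
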