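# Independent brute-force oracles for the statistical kernel. These stay
# deliberately naive: they enumerate the permutation null directly from the
# definition and never share code with the package implementation.

# rank-sum: p over all C(m+n, m) assignments of the pooled values to group x
oracle_rank_sum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx_sets <- combn(length(pooled), m)
  u_all <- apply(idx_sets, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  pl <- mean(u_all <= u_obs + 1e-9)
  pg <- mean(u_all >= u_obs - 1e-9)
  switch(alternative,
         less = pl, greater = pg,
         two_sided = min(1, 2 * min(pl, pg)))
}

# signed-rank: p over all 2^n sign assignments of the nonzero differences
oracle_signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(0:(2^n - 1), function(mask) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[bits == 1L])
  }, numeric(1))
  pl <- mean(w_all <= w_obs + 1e-9)
  pg <- mean(w_all >= w_obs - 1e-9)
  switch(alternative,
         less = pl, greater = pg,
         two_sided = min(1, 2 * min(pl, pg)))
}

# DRACH by explicit alphabet expansion
oracle_drach_set <- function() {
  out <- character()
  for (d in c("A", "G", "U")) for (r in c("A", "G")) for (h in c("A", "C", "U"))
    out <- c(out, paste0(d, r, "A", "C", h))
  out
}
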