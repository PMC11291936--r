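# Independent brute-force oracle: enumerate every activation state by its
# bitmask and collect the distinct phenotypes. Deliberately shares no code
# with enumerate_attainable_phenotypes().
brute_force_attainable <- function(alleles, B) {
  ls <- rowSums(alleles)
  L <- nrow(alleles)
  np <- L - B
  vals <- numeric(2^np)
  for (m in 0:(2^np - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(np)]
    vals[m + 1] <- sum(ls[seq_len(B)]) + sum(ls[B + seq_len(np)] * bits)
  }
  sort(unique(round(vals, 9)))
}

# Mean of the final generation's records, one row per replicate.
final_records <- function(res) {
  do.call(rbind, lapply(split(res, res$replicate), function(d) d[nrow(d), ]))
}

# Small cohort whose locus sums realize the given all-active trait values
# exactly (one value per individual), for hand-computable fixtures.
cohort_with_traits <- function(traits, L = 10, B = 1, fixed_omega = 0) {
  n <- length(traits)
  ch <- found_cohort(n, L = L, B = B, fixed_omega = fixed_omega)
  ch$resp <- array(0, dim = c(n, L, 2))
  ch$resp[, 1, 1] <- traits
  ch$x <- traits
  ch
}
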