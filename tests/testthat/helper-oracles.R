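# Brute-force oracles and small fixture builders shared across tests.

# expected haplotype homozygosity by direct enumeration over pasted rows
brute_ehh <- function(X, carriers, cols) {
  if (!length(cols)) return(1)
  key <- apply(X[carriers, cols, drop = FALSE], 1, paste, collapse = "|")
  p <- as.numeric(table(key)) / length(carriers)
  sum(p^2)
}

# independent trapezoid integration of an EHH decay sequence, interpolating
# to the cutoff crossing when the last value falls below it
brute_trapezoid <- function(dist, ehh, cutoff = 0.05) {
  dist <- c(0, dist); ehh <- c(1, ehh)
  area <- 0
  for (i in 2:length(dist)) {
    if (ehh[i] < cutoff) {
      xc <- dist[i - 1] + (ehh[i - 1] - cutoff) / (ehh[i - 1] - ehh[i]) *
        (dist[i] - dist[i - 1])
      area <- area + (xc - dist[i - 1]) * (ehh[i - 1] + cutoff) / 2
      return(area)
    }
    area <- area + (dist[i] - dist[i - 1]) * (ehh[i - 1] + ehh[i]) / 2
  }
  area
}

# build a haplotype sample directly from a 0/1 matrix
make_sample <- function(X, positions, L, selected_site = NA_integer_,
                        pairs = NULL) {
  haplotype_sample(as.matrix(X), positions, L,
                   selected_site = selected_site, diploid_pairs = pairs)
}

# exact neutral Wright-Fisher transition for a single population of 2N
# copies: distribution of copy counts after t generations from one copy
wf_count_distribution <- function(two_n, t) {
  p <- numeric(two_n + 1)
  p[2] <- 1   # one copy at the origin
  for (g in seq_len(t)) {
    pn <- numeric(two_n + 1)
    for (c in 0:two_n) {
      if (p[c + 1] == 0) next
      pn <- pn + p[c + 1] * dbinom(0:two_n, two_n, c / two_n)
    }
    p <- pn
  }
  p
}
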