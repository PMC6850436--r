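# Independent oracles used to freeze expected values.

# Brute-force genotype-pair cell probabilities for a relationship
# (k0, k1, k2) at a single allele frequency p: enumerate the 2^4 founder
# haplotype configurations and the three IBD states, assembling
# genotypes the same way a pedigree does (individual 1 = haplotypes 1+2;
# IBD 0 -> 3+4, IBD 1 -> 1+3, IBD 2 -> 1+2). Deliberately a plain loop,
# independent of the package's closed forms.
bruteCellProbs <- function(k, p) {
  cells <- matrix(0, 3L, 3L)
  for (h1 in 0:1) for (h2 in 0:1) for (h3 in 0:1) for (h4 in 0:1) {
    hap <- c(h1, h2, h3, h4)
    w <- prod(ifelse(hap == 1L, p, 1 - p))
    g1 <- h1 + h2
    g2s <- c(h3 + h4, h1 + h3, h1 + h2)
    for (s in 1:3)
      cells[g1 + 1L, g2s[s] + 1L] <- cells[g1 + 1L, g2s[s] + 1L] + k[s] * w
  }
  cells
}

# Hand tally of the 9 cells from two genotype vectors (loop version,
# independent of countPairMatrix).
bruteTally <- function(g1, g2) {
  cells <- matrix(0, 3L, 3L)
  for (i in seq_along(g1)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    cells[g1[i] + 1L, g2[i] + 1L] <- cells[g1[i] + 1L, g2[i] + 1L] + 1
  }
  cells
}

# One-hot 3-genotype likelihood matrix from genotypes.
oneHot3 <- function(g) {
  m <- matrix(0, length(g), 3L)
  m[cbind(seq_along(g), g + 1L)] <- 1
  m
}

# One-hot 10-genotype likelihood matrix: genotype g copies of alt with
# per-site ref/alt base codes; looks up the column by genotype name.
oneHot10 <- function(g, ref, alt) {
  nm <- genotype10Names()
  m <- matrix(0, length(g), 10L)
  for (i in seq_along(g)) {
    bases <- sort(c("A", "C", "G", "T")[c(ref[i], alt[i])[c(
      rep(1L, 2L - g[i]), rep(2L, g[i]))]])
    m[i, match(paste(bases, collapse = ""), nm)] <- 1
  }
  m
}
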