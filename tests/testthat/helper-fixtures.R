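# In-code fixtures and independent oracles shared across the test files.

# build a locus_alignment from equal-length strings
make_aln <- function(seqs, pops = NULL, coding = NULL, locus_id = "toy") {
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%02d", seq_along(seqs))
  if (is.null(pops)) pops <- setNames(rep("wild", length(seqs)), names(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  locus_alignment(mat, pops, locus_id = locus_id, coding = coding)
}

rand_aln <- function(n, L, pops = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  if (is.null(pops)) pops <- setNames(rep("wild", n), rownames(mat))
  locus_alignment(mat, pops)
}

# brute-force nucleotide diversity: double loop over pairs and columns
pi_bruteforce <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

# exact four-gamete lower bound oracle: maximum number of pairwise
# disjoint incompatibility intervals by weighted-interval-scheduling
# dynamic programming (independent of the greedy culling under test)
rm_bruteforce <- function(bin) {
  K <- ncol(bin)
  iv <- NULL
  if (K >= 2) {
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        if (length(unique(bin[, i] * 2 + bin[, j])) == 4)
          iv <- rbind(iv, c(i, j))
      }
    }
  }
  if (is.null(iv)) return(0L)
  iv <- iv[order(iv[, 2]), , drop = FALSE]
  m <- nrow(iv)
  f <- integer(m + 1)  # f[q+1] = best using the first q intervals
  for (q in seq_len(m)) {
    # latest earlier interval whose right end <= this one's left end
    compat <- which(iv[seq_len(q - 1), 2] <= iv[q, 1])
    prev <- if (length(compat)) max(compat) else 0L
    f[q + 1] <- max(f[q], 1L + f[prev + 1])
  }
  f[m + 1]
}

# r-squared from the 2x2 haplotype contingency table
r2_contingency <- function(x, y) {
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  n <- sum(tab)
  pA <- sum(tab[2, ]) / n
  pB <- sum(tab[, 2]) / n
  pAB <- tab[2, 2] / n
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# independent transcription of the Tajima 1989 statistic
tajima_oracle <- function(n, S, pi_total) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_total - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# independent transcription of the outgroup-free Fu & Li statistics
fuli_oracle <- function(n, eta, eta_s, pi_total) {
  i <- seq_len(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2); an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- n / (n - 1) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           2 / (n - 1) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  list(Dstar = (n / (n - 1) * eta - an * eta_s) /
         sqrt(uD * eta + vD * eta^2),
       Fstar = (pi_total - (n - 1) / n * eta_s) /
         sqrt(uF * eta + vF * eta^2))
}

# map a 0/1 haplotype matrix onto an A/T alignment
binary_to_aln <- function(sim, pops = NULL) {
  mat <- matrix("A", nrow(sim$matrix), ncol(sim$matrix))
  mat[sim$matrix == 1] <- "T"
  rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  if (is.null(pops))
    pops <- setNames(sim$pop, rownames(mat))
  else names(pops) <- rownames(mat)
  locus_alignment(mat, pops, locus_id = "sim")
}
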