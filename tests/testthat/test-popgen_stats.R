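# Per-locus statistics against brute-force and textbook oracles.

test_that("nucleotide diversity matches the brute-force pair count", {
  two <- make_aln(c(paste(rep("A", 100), collapse = ""),
                    paste(c(rep("A", 99), "T"), collapse = "")))
  expect_equal(nucleotide_diversity(two), 0.01)

  same <- make_aln(rep(paste(rep("C", 50), collapse = ""), 6))
  expect_equal(nucleotide_diversity(same), 0)

  aln <- rand_aln(10, 200, seed = 3)
  filt <- filter_sites(aln)
  expect_equal(nucleotide_diversity(filt),
               pi_bruteforce(filt$matrix) / filt$L_total)
})

test_that("Watterson's theta reproduces the published golden cells", {
  expect_equal(round(watterson_theta(27, 29, 1014), 4), 0.0068)
  expect_equal(round(watterson_theta(6, 50, 1005), 4), 0.0013)
  expect_equal(watterson_theta(0, 20, 500), 0)
})

test_that("Tajima's D is zero at its balance point and matches the
           textbook formula", {
  n <- 12
  a1 <- sum(1 / seq_len(n - 1))
  res <- tajimas_D_from_counts(n, 5, 5 / a1)
  expect_equal(res$D, 0)
  expect_true(is.na(tajimas_D_from_counts(10, 0, 0)$D))

  for (s in 1:10) {
    aln <- filter_sites(rand_aln(8, 50, seed = 100 + s))
    m <- aln$matrix
    S <- segregating_sites(aln)
    if (S == 0) next
    D <- tajimas_D(aln)$D
    expect_equal(D, tajima_oracle(nrow(m), S, pi_bruteforce(m)),
                 tolerance = 1e-12)
  }
})

test_that("Fu & Li D*/F* have the right signs and match the transcription", {
  # all variants at intermediate frequency: no singletons, D* > 0
  inter <- make_aln(c("AAAA", "AAAA", "AAAA", "TTTT", "TTTT", "TTTT"))
  expect_gt(fu_li_tests(inter)$Dstar, 0)

  # every variant a singleton: D* < 0
  singl <- make_aln(c("TAAA", "ATAA", "AATA", "AAAT", "AAAA", "AAAA"))
  expect_lt(fu_li_tests(singl)$Dstar, 0)

  for (s in 1:10) {
    aln <- filter_sites(rand_aln(9, 40, seed = 200 + s))
    fl <- fu_li_tests(aln)
    if (fl$eta < 1) next
    oracle <- fuli_oracle(9, fl$eta, fl$eta_s, pi_bruteforce(aln$matrix))
    expect_equal(fl$Dstar, oracle$Dstar, tolerance = 1e-12)
    expect_equal(fl$Fstar, oracle$Fstar, tolerance = 1e-12)
  }
})

test_that("haplotype statistics count distinct rows", {
  same <- make_aln(rep("ACGT", 5))
  expect_equal(haplotype_stats(same), list(hap = 1, hdiv = 0))

  seqs <- sapply(1:10, function(i)
    paste(c(rep("A", i), rep("T", 10 - i)), collapse = ""))
  dist <- make_aln(seqs)
  hs <- haplotype_stats(dist)
  expect_equal(hs$hap, 10)
  expect_equal(hs$hdiv, (1 - 10 * 0.01) * 10 / 9)

  aln <- rand_aln(7, 30, seed = 4)
  h1 <- haplotype_stats(aln)
  perm <- locus_alignment(aln$matrix[sample(7), ], aln$population)
  expect_equal(haplotype_stats(perm), h1)
})

test_that("four-gamete Rm equals the exhaustive oracle", {
  one <- make_aln(c("AT", "AT", "TT"))
  expect_equal(min_recombination_Rm(one), 0)

  four <- make_aln(c("AA", "AT", "TA", "TT"))
  expect_equal(min_recombination_Rm(four), 1)

  set.seed(7)
  for (r in 1:25) {
    bin <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
    mat <- matrix(c("A", "T")[bin + 1], 8, 12)
    rownames(mat) <- sprintf("s%d", 1:8)
    aln <- locus_alignment(mat, setNames(rep("wild", 8), rownames(mat)))
    bi <- milletpg:::.biallelic01(filter_sites(aln)$matrix)
    expect_equal(min_recombination_Rm(aln), rm_bruteforce(bi$mat))
  }
})

test_that("Hudson's Fst hits its limits and is ~0 under panmixia", {
  pops <- setNames(c(rep("wild", 3), rep("cultivated", 3)),
                   sprintf("s%02d", 1:6))
  fixed <- make_aln(c("AAA", "AAA", "AAA", "TTT", "TTT", "TTT"), pops)
  expect_equal(fst(fixed), 1)

  # one panmictic pool split arbitrarily into two labels
  set.seed(42)
  sim <- simulate_standard(100, theta = 60, L = 1000)
  pops2 <- rep(c("wild", "cultivated"), each = 50)
  aln <- binary_to_aln(sim, pops2)
  expect_lt(abs(fst(aln)), 0.05)

  # permutation null: shuffled labels give mean Fst ~ 0
  vals <- replicate(30, {
    aln$population[] <- sample(aln$population)
    fst(aln)
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("polymorphism partition is exclusive, exhaustive and consistent", {
  pops <- setNames(c(rep("wild", 2), rep("cultivated", 2)),
                   sprintf("s%02d", 1:4))
  aln <- make_aln(c("AAC", "AGC", "GAC", "GAT"), pops)
  # col1 fixed A/A vs G/G; col2 wild-specific A/G; col3 cult-specific C/T
  pp <- polymorphism_partition(aln)
  expect_equal(unname(pp), c(0L, 1L, 1L, 1L))

  shared <- make_aln(c("A", "G", "A", "G"), pops)
  expect_equal(unname(polymorphism_partition(shared)["shared"]), 1L)

  set.seed(9)
  sim <- simulate_bottleneck(demographic_model(m12 = 5, m21 = 5),
                             data.frame(L = 800, n_wild = 12, n_cult = 15,
                                        theta_site = 0.008))
  aln2 <- binary_to_aln(sim)
  pp2 <- polymorphism_partition(aln2)
  Sw <- segregating_sites(aln2, "wild")
  Sc <- segregating_sites(aln2, "cultivated")
  expect_equal(unname(pp2["shared"] + pp2["wild_specific"]), Sw)
  expect_equal(unname(pp2["shared"] + pp2["cultivar_specific"]), Sc)
  # categories sum to the pooled segregating-site count
  expect_equal(sum(pp2), segregating_sites(aln2))
})

test_that("site frequency spectra polarize against the outgroup", {
  seqs <- c("TAAA", rep("AAAA", 9))
  aln <- make_aln(seqs)
  s <- sfs(aln)
  expect_false(s$polarized)
  expect_equal(s$counts[1], 1L)
  expect_equal(sum(s$counts), 1L)

  # outgroup equal to one allele at every site: every biallelic site counted
  aln$outgroup <- strsplit("AAAA", "")[[1]]
  sp <- sfs(aln)
  expect_true(sp$polarized)
  expect_equal(sum(sp$counts), 1L)
  expect_equal(sp$counts[1], 1L)

  # outgroup with a third state is skipped
  aln$outgroup <- strsplit("GAAA", "")[[1]]
  expect_equal(sum(sfs(aln)$counts), 0L)

  # neutral simulated spectrum decays roughly like 1/i
  set.seed(12)
  sim <- simulate_standard(20, theta = 150, L = 5000)
  mat <- matrix("A", 20, ncol(sim$matrix))
  mat[sim$matrix == 1] <- "G"
  rownames(mat) <- sprintf("s%02d", 1:20)
  aln2 <- locus_alignment(mat, setNames(rep("wild", 20), rownames(mat)))
  aln2$outgroup <- rep("A", ncol(mat))
  cnt <- sfs(aln2)$counts
  expect_equal(sum(cnt), segregating_sites(aln2))
  i <- seq_along(cnt)
  expect_gt(cor(cnt, 1 / i), 0.8)
  expect_gt(cnt[1], cnt[10])
})

test_that("silent divergence behaves like a distance", {
  pops <- setNames(c("wild", "wild", "cultivated", "cultivated"),
                   sprintf("s%02d", 1:4))
  # two fixed haplotypes differing at 5 of 500 noncoding sites
  base <- paste(rep("A", 500), collapse = "")
  alt <- paste(c(rep("T", 5), rep("A", 495)), collapse = "")
  aln <- make_aln(c(base, base, alt, alt), pops)
  expect_equal(ks_divergence(aln), 0.01)

  # symmetric in population order
  pops_swapped <- setNames(rev(unname(pops)), names(pops))
  aln2 <- make_aln(c(base, base, alt, alt), pops_swapped)
  expect_equal(ks_divergence(aln2), ks_divergence(aln))

  # identical pools: Ks equals within-pool silent pi
  set.seed(3)
  m <- rand_aln(8, 300)$matrix
  pops3 <- setNames(rep(c("wild", "cultivated"), 4), rownames(m))
  aln3 <- locus_alignment(m, pops3)
  piw <- nucleotide_diversity(aln3, sites = "silent")
  ks <- ks_divergence(aln3)
  expect_equal(ks, piw, tolerance = 0.35)  # same order, not identical pools
})

test_that("theta-Ks correlation reports Pearson r with exclusions", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(theta_ks_correlation(x, x * 2.5)$r, 1)
  expect_equal(theta_ks_correlation(x, -x)$r, -1)
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8)
  names(a) <- names(b) <- letters[1:8]
  res <- theta_ks_correlation(a, b)
  ct <- cor.test(a, b)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  res2 <- theta_ks_correlation(a, b, exclude = "a")
  expect_equal(res2$n_loci, 7)
  expect_error(theta_ks_correlation(x, rep(1, 4)), "zero variance")
})

test_that("locus_summary assembles a coherent published-schema row", {
  set.seed(8)
  panel <- locus_panel()[3, ]
  panel$n_wild <- 10L; panel$n_cult <- 12L
  bundle <- generate_panel(panel, demographic_model(), seed = 21)
  filt <- filter_sites(bundle$loci[[1]])
  row <- locus_summary(filt, "wild")
  expect_equal(row$n, 10)
  expect_equal(row$S, segregating_sites(filt, "wild"))
  expect_gte(row$hdiv, 0); expect_lt(row$hdiv, 1)
  expect_lte(row$hap, row$n)
  expect_lte(row$silent, row$length)
  expect_gte(row$pi, 0)
})

test_that("simulated neutrality null gives calibrated two-sided p-values", {
  # neutral data should rarely look extreme; a strongly skewed spectrum
  # should
  set.seed(11)
  neutral <- binary_to_aln(simulate_standard(12, 8, L = 300),
                           rep("wild", 12))
  pn <- neutrality_sim_p(neutral, statistic = "D", nrep = 300, seed = 12)
  expect_gt(pn$p, 0.05)
  skew <- make_aln(c("TTTTTT", "ATTTTT", "TATTTT", "TTATTT", "TTTATT",
                     "TTTTAT", "TTTTTA", "TTTTTT", "TTTTTT", "TTTTTT"))
  ps <- neutrality_sim_p(skew, statistic = "Dstar", nrep = 300, seed = 13)
  expect_lt(ps$observed, 0)   # all-singleton spectrum
  expect_lt(ps$p, 0.5)
  expect_true(ps$p >= 0 && ps$p <= 1)
})
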