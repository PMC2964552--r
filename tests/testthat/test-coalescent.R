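# The coalescent engine against analytic expectations, its limits, and
# cross-path equality of the summary statistics.

test_that("theta = 0 yields no segregating sites", {
  sim <- simulate_standard(10, theta = 0, seed = 1)
  expect_equal(ncol(sim$matrix), 0)
})

test_that("E[S] and E[pi] match Watterson/coalescent expectations", {
  n <- 10; theta <- 5; reps <- 2000
  set.seed(2)
  S <- pi <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_standard(n, theta, rho = 3, L = 1)
    st <- summarize_haplotypes(sim)
    S[r] <- st["S"]; pi[r] <- st["pi"]
  }
  a1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - theta * a1), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi) - theta), 3 * sd(pi) / sqrt(reps))
})

test_that("Tajima's D is centred near zero under the standard model", {
  set.seed(3)
  D <- replicate(2000, {
    sim <- simulate_standard(12, theta = 6)
    if (ncol(sim$matrix) < 1) return(NA_real_)
    tajimas_D_from_counts(12, ncol(sim$matrix),
                          milletpg:::.pi_total_m(sim$matrix))$D
  })
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.15)
})

test_that("fixed seeds give identical output and unit conversions invert", {
  s1 <- simulate_standard(8, 4, rho = 2, seed = 99)
  s2 <- simulate_standard(8, 4, rho = 2, seed = 99)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$positions, s2$positions)

  t <- c(0, 1, 8700, 1e6)
  expect_equal(coalescent_to_generations(
    generations_to_coalescent(t, 2.1e5), 2.1e5), t, tolerance = 1e-12)
})

test_that("the bottleneck model reproduces its limiting behaviours", {
  spec <- data.frame(L = 700, n_wild = 15, n_cult = 20, theta_site = 0.006)

  # severe bottleneck: cultivated diversity well below wild
  set.seed(4)
  sev <- demographic_model(t2 = 8700, d = 1000, k = 0.1)
  Sw <- Sc <- numeric(400)
  for (r in 1:400) {
    sim <- simulate_bottleneck(sev, spec)
    Sw[r] <- summarize_haplotypes(sim, "wild")["S"]
    Sc[r] <- summarize_haplotypes(sim, "cultivated")["S"]
  }
  expect_lt(mean(Sc), 0.6 * mean(Sw))

  # negligible bottleneck, no migration, distant split: near-equal diversity
  set.seed(5)
  mild <- demographic_model(t2 = 400000, d = 3000, k = 100, m12 = 0,
                            m21 = 0)
  piw <- pic <- numeric(400)
  for (r in 1:400) {
    sim <- simulate_bottleneck(mild, spec)
    piw[r] <- summarize_haplotypes(sim, "wild")["pi"]
    pic[r] <- summarize_haplotypes(sim, "cultivated")["pi"]
  }
  expect_equal(mean(pic) / mean(piw), 1, tolerance = 0.12)

  # split at the present (tau2 = 0): one panmictic pool, Fst ~ 0
  set.seed(6)
  fstv <- replicate(200, {
    raw <- milletpg:::.sim_locus_cpp(15L, 20L, 5, 0, 0, 0, 1, 1, 0, 0)
    if (ncol(raw$matrix) < 1) return(NA_real_)
    sim <- structure(list(matrix = raw$matrix, positions = raw$positions,
                          L = 1, pop = c(rep("wild", 15),
                                         rep("cultivated", 20))),
                     class = "sim_haplotypes")
    fst(binary_to_aln(sim))
  })
  expect_lt(abs(mean(fstv, na.rm = TRUE)), 0.03)
})

test_that("wild marginals match the standard model when isolated", {
  # m = 0 and a very old split: the wild sample is a plain constant-size
  # coalescent; compare S distributions by a two-sample KS test
  spec <- data.frame(L = 1, n_wild = 12, n_cult = 5, theta_site = 5)
  old <- demographic_model(t2 = 5e6, d = 1000, k = 1, m12 = 0, m21 = 0,
                           rho_over_theta = 0, theta_site = 5, N_a = 1e4)
  set.seed(7)
  S_bot <- replicate(2000, {
    sim <- simulate_bottleneck(old, spec)
    unname(summarize_haplotypes(sim, "wild")["S"])
  })
  S_std <- replicate(2000, ncol(simulate_standard(12, 5)$matrix))
  # uniform jitter breaks the integer ties so the KS null is exact
  ks <- stats::ks.test(S_bot + runif(2000), S_std + runif(2000))
  expect_gt(ks$p.value, 0.01)
})

test_that("summary statistics agree between the C++ and R code paths", {
  set.seed(8)
  for (r in 1:15) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    theta <- runif(1, 1, 8); rho <- runif(1, 0, 10)
    tau2 <- runif(1, 0.005, 0.05); tau1 <- tau2 * runif(1, 0.2, 0.9)
    nb <- runif(1, 0.001, 0.5)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    st <- milletpg:::.sim_panel_stats_cpp(n1, n2, theta, rho, tau1, tau2,
                                          nb, 1, 2, 1, TRUE)
    set.seed(seed)
    raw <- milletpg:::.sim_locus_cpp(n1, n2, theta, rho, tau1, tau2,
                                     nb, 1, 2, 1)
    sim <- list(matrix = raw$matrix, positions = raw$positions, L = 1,
                pop = c(rep("wild", n1), rep("cultivated", n2)))
    class(sim) <- "sim_haplotypes"
    w <- summarize_haplotypes(sim, "wild")
    cu <- summarize_haplotypes(sim, "cultivated", want_rho = TRUE)
    expect_equal(unname(w["S"]), unname(st[1, "S_w"]))
    expect_equal(unname(w["pi"]), unname(st[1, "pi_w"]), tolerance = 1e-12)
    expect_equal(unname(w["hap"]), unname(st[1, "hap_w"]))
    expect_equal(unname(w["hdiv"]), unname(st[1, "hdiv_w"]), tolerance = 1e-12)
    expect_equal(unname(cu["S"]), unname(st[1, "S_c"]))
    expect_equal(unname(cu["hdiv"]), unname(st[1, "hdiv_c"]), tolerance = 1e-12)
    if (is.na(st[1, "rho_c"])) expect_true(is.na(cu["rho"]))
    else expect_equal(unname(cu["rho"]), unname(st[1, "rho_c"]), tolerance = 1e-8)
  }
})

test_that("statistics agree when the matrix is rendered as nucleotides", {
  set.seed(9)
  sim <- simulate_bottleneck(
    demographic_model(), data.frame(L = 500, n_wild = 10, n_cult = 12,
                                    theta_site = 0.01))
  aln <- binary_to_aln(sim)
  expect_equal(segregating_sites(aln, "wild"),
               unname(summarize_haplotypes(sim, "wild")["S"]))
  filt <- filter_sites(aln)
  expect_equal(nucleotide_diversity(filt, "cultivated") * filt$L_total,
               unname(summarize_haplotypes(sim, "cultivated")["pi"]) * sim$L,
               tolerance = 1e-12)
  hs <- haplotype_stats(aln, "wild")
  expect_equal(hs$hap, unname(summarize_haplotypes(sim, "wild")["hap"]))
})
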