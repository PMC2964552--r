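# Rejection-ABC machinery: mode extraction, prior containment,
# determinism, the no-data limit and parameter recovery.

test_that("posterior_mode finds peaks and flags flat samples", {
  set.seed(20)
  x <- rnorm(5000, mean = 3, sd = 0.5)
  m <- posterior_mode(x, support = c(0, 6))
  expect_equal(as.numeric(m), 3, tolerance = 0.1)
  expect_false(attr(m, "flat"))

  u <- runif(5000)
  mu <- posterior_mode(u, support = c(0, 1))
  expect_true(attr(mu, "flat"))

  # taller component of a planted mixture, against a brute-force grid
  y <- c(rnorm(3000, 1, 0.2), rnorm(1000, 4, 0.2))
  my <- posterior_mode(y, support = c(0, 5))
  grid <- seq(0, 5, length.out = 2001)
  bw <- stats::bw.nrd0(y)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, y, bw)), numeric(1))
  expect_equal(as.numeric(my), grid[which.max(dens)], tolerance = 0.05)

  expect_error(posterior_mode(rnorm(10)), "at least 50")
})

test_that("the acceptance band treats a zero observation by its SD", {
  w <- milletpg:::.within(c(0.1, 0.5), 0, 0.3, scale0 = 1)
  expect_equal(w, c(TRUE, FALSE))
  expect_true(milletpg:::.within(1.2, 1, 0.3))
  expect_false(milletpg:::.within(1.4, 1, 0.3))
})

# a small panel and an easy synthetic observation make the rejection loops
# fast enough for structural tests
small_panel <- data.frame(locus = c("l1", "l2", "l3"),
                          L = c(400, 600, 800), L_cult = c(400, 600, 800),
                          n_wild = c(10L, 12L, 14L),
                          n_cult = c(10L, 12L, 14L),
                          theta_site = rep(0.006, 3))

synthetic_observation <- function(theta, rho_site, panel, reps = 300,
                                  seed = 1) {
  set.seed(seed)
  st <- replicate(reps, {
    s <- milletpg:::.sim_panel_stats_cpp(
      as.integer(panel$n_wild), rep(0L, nrow(panel)), theta * panel$L,
      rho_site * panel$L, 0, 0, 1, 1, 0, 0, FALSE)
    c(mean(s[, "S_w"]), mean(s[, "pi_w"] / panel$L), mean(s[, "hap_w"]),
      mean(s[, "hdiv_w"]))
  })
  list(mean = setNames(rowMeans(st), c("S", "pi", "hap", "hdiv")),
       var = setNames(apply(st, 1, var), c("S", "pi", "hap", "hdiv")))
}

test_that("accepted draws stay inside the prior boxes and are
           reproducible under a fixed seed", {
  obs <- synthetic_observation(0.006, 0.003, small_panel)
  p1 <- abc_standard(obs, small_panel, n_accept = 80, tol = 0.5, seed = 31)
  p2 <- abc_standard(obs, small_panel, n_accept = 80, tol = 0.5, seed = 31)
  expect_identical(p1$draws, p2$draws)
  pri <- abc_priors()
  expect_true(all(p1$draws$theta >= pri$theta[1] &
                    p1$draws$theta <= pri$theta[2]))
  expect_true(all(p1$draws$rho >= pri$rho[1] & p1$draws$rho <= pri$rho[2]))
})

test_that("an infinite tolerance returns the prior", {
  obs <- synthetic_observation(0.006, 0.003, small_panel)
  post <- abc_standard(obs, small_panel, n_accept = 400, tol = 1e9,
                       seed = 32)
  expect_equal(post$n_draws, 400)
  pri <- abc_priors()
  ks <- suppressWarnings(
    stats::ks.test(post$draws$theta / pri$theta[2], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the standard-model posterior concentrates on the truth", {
  theta_true <- 0.006
  obs <- synthetic_observation(theta_true, 0.003, small_panel, reps = 500)
  post <- abc_standard(obs, small_panel, n_accept = 500, seed = 33)
  expect_lt(abs(post$mode["theta"] - theta_true), 0.25 * theta_true)
})

test_that("posteriors tighten as the tolerance shrinks", {
  obs <- synthetic_observation(0.006, 0.003, small_panel, reps = 500)
  wide <- abc_standard(obs, small_panel, n_accept = 300, tol = 0.4,
                       seed = 34)
  tight <- abc_standard(obs, small_panel, n_accept = 300, tol = 0.2,
                        seed = 34)
  expect_lt(stats::sd(tight$draws$theta), stats::sd(wide$draws$theta))
})

test_that("bottleneck ABC respects priors, filters stage 2 and is
           deterministic", {
  obs <- load_observed_from_table()
  b1 <- suppressWarnings(abc_bottleneck(obs, rho_over_theta = 1,
                                        n_stage1 = 60, seed = 35,
                                        tol_stage1 = 0.8))
  b2 <- suppressWarnings(abc_bottleneck(obs, rho_over_theta = 1,
                                        n_stage1 = 60, seed = 35,
                                        tol_stage1 = 0.8))
  expect_identical(b1$draws, b2$draws)
  pri <- abc_priors()
  for (p in c("t2", "d", "k", "m12", "m21")) {
    expect_true(all(b1$draws[[p]] >= pri[[p]][1] &
                      b1$draws[[p]] <= pri[[p]][2]))
  }
  expect_true(all(rownames(b1$survivors) %in% rownames(b1$draws)))
  expect_lte(b1$n_stage2, b1$n_stage1)
  # the wider band is the documented default for high-recombination grids
  expect_equal(suppressWarnings(
    abc_bottleneck(obs, rho_over_theta = 2, n_stage1 = 5, seed = 36,
                   max_draws = 5e4))$tol_stage1, 0.6)
})

test_that("the selection scan orders loci by diversity loss", {
  obs <- load_observed_from_table()
  post <- abc_bottleneck(obs, rho_over_theta = 1, n_stage1 = 150, seed = 37)
  panel <- locus_panel()
  tab <- observed_table3()
  cult <- tab[tab$species == "cultivated", ]
  scan <- selection_scan(cult, post, panel, n_pp = 300, seed = 38)
  expect_true(all(scan$p >= 0 & scan$p <= 1))
  # an implausibly diverse observation is never exceeded
  rich <- cult; rich$pi <- 1
  scan_rich <- selection_scan(rich, post, panel, n_pp = 50, seed = 39)
  expect_true(all(scan_rich$p == 1))
  # pi = 0 observations: p bounded by the model probability of S = 0,
  # counted by brute-force replicates
  zero <- cult; zero$pi <- 0
  one_locus <- panel[1, ]
  scan_zero <- selection_scan(zero[zero$locus == one_locus$locus, ],
                              post, one_locus, n_pp = 400, seed = 40)
  set.seed(40)
  idx <- sample.int(nrow(post$survivors), 400, replace = TRUE)
  mb <- post$model_base
  s0 <- mean(vapply(idx, function(q) {
    pr <- post$survivors[q, ]
    st <- milletpg:::.sim_panel_stats_cpp(
      one_locus$n_wild, one_locus$n_cult,
      one_locus$theta_site * one_locus$L, one_locus$theta_site * one_locus$L,
      (pr$t2 - pr$d) / (4 * mb$N_a), pr$t2 / (4 * mb$N_a),
      pr$k * pr$d / mb$N_a, mb$np_rel, pr$m12, pr$m21, FALSE)
    st[1, "S_c"] == 0
  }, logical(1)))
  expect_equal(scan_zero$p[1], s0, tolerance = 1e-12)
})
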