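# Rejection approximate Bayesian computation: (i) standard-model posterior
# for theta and rho per species; (ii) two-stage bottleneck inference of
# (t2, d, k, m12, m21) on a rho/theta grid; (iii) posterior-predictive
# selection scan per locus.

# multiplicative acceptance band; when the observed value is 0 the band is
# |sim| <= tol * scale0 (a cross-locus SD supplied by the caller)
.within <- function(sim, obs, tol, scale0 = 1) {
  n <- max(length(sim), length(obs))
  sim <- rep_len(sim, n)
  obs <- rep_len(obs, n)
  scale0 <- rep_len(scale0, n)
  ifelse(obs == 0, abs(sim) <= tol * scale0, abs(sim - obs) <= tol * abs(obs))
}

#' Default priors of the rejection algorithm
#'
#' Uniform boxes: per-site `theta` in (0, 0.03) and `rho` in (0, 0.15) for
#' the standard model; `t2` in (5000, 15000) generations, `d` in (100,
#' 3000) generations, `k` in (0.1, 10), and scaled migration `m12`, `m21`
#' in (0, 100) for the bottleneck model. `t1 = t2 - d` is derived, never
#' sampled.
#'
#' @return named list of `c(lower, upper)` intervals.
#' @export
abc_priors <- function() {
  list(theta = c(0, 0.03), rho = c(0, 0.15),
       t2 = c(5000, 15000), d = c(100, 3000), k = c(0.1, 10),
       m12 = c(0, 100), m21 = c(0, 100))
}

#' Kernel-density posterior mode
#'
#' Gaussian-kernel density (Silverman's rule-of-thumb bandwidth) evaluated
#' on the prior-truncated support; the mode is the grid point of maximum
#' density. A near-flat posterior (peak/median density ratio < 1.2) is
#' flagged with attribute `flat`.
#'
#' @param draws numeric vector of accepted parameter values (>= 50).
#' @param support `c(lower, upper)` truncation (defaults to the data
#'   range).
#' @return the mode, with attribute `flat`.
#' @export
posterior_mode <- function(draws, support = NULL) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 50) stop("need at least 50 draws for a density mode")
  if (is.null(support)) support <- range(draws)
  de <- density(draws, bw = "nrd0", from = support[1], to = support[2],
                n = 512)
  mode <- de$x[which.max(de$y)]
  attr(mode, "flat") <- max(de$y) / stats::median(de$y) < 1.2
  mode
}

#' Standard-model rejection ABC for theta and rho
#'
#' Draws `(theta, rho)` per site from uniform priors, simulates the full
#' locus panel under the constant-size neutral coalescent with
#' locus-specific sample sizes and lengths, and accepts a draw when at
#' least 3 of the 4 cross-locus mean statistics (S, pi, Hap, Hdiv) fall
#' within `tol` of the observed means. Runs until `n_accept` draws are
#' accepted.
#'
#' @param observed species observation as one element of
#'   [load_observed_from_table()] (list with `mean`, `var`).
#' @param panel locus panel ([locus_panel()]); for the cultivated species
#'   pass `use_cult = TRUE` to take the cultivated lengths/sample sizes.
#' @param use_cult simulate with the cultivated panel columns.
#' @param n_accept accepted draws to collect (default 1000).
#' @param tol multiplicative tolerance (default 0.20).
#' @param min_stats how many of the four statistics must match (default 3).
#' @param priors prior boxes ([abc_priors()]).
#' @param seed optional integer seed.
#' @param max_draws hard cap on total draws; the run aborts with
#'   diagnostics if the acceptance rate falls below 1e-5.
#' @return object of class `abc_posterior` with `draws` (data.frame of
#'   accepted `theta`, `rho`, `rho_over_theta`), acceptance bookkeeping,
#'   and KDE posterior modes.
#' @export
abc_standard <- function(observed, panel = locus_panel(), use_cult = FALSE,
                         n_accept = 1000, tol = 0.20, min_stats = 3,
                         priors = abc_priors(), seed = NULL,
                         max_draws = 2e6) {
  .check_seed(seed)
  n <- as.integer(if (use_cult) panel$n_cult else panel$n_wild)
  L <- if (use_cult) panel$L_cult else panel$L
  nloc <- nrow(panel)
  # simulate short loci first: their ARGs are cheapest, so draws destined
  # for early rejection never pay for the long-locus simulations
  ord <- order(L)
  n <- n[ord]; L <- L[ord]
  obs <- observed$mean[c("S", "pi", "hap", "hdiv")]
  sd0 <- sqrt(observed$var[c("S", "pi", "hap", "hdiv")])
  res <- .abc_standard_loop_cpp(n, L, priors$theta, priors$rho, obs, sd0,
                                tol, as.integer(min_stats),
                                as.integer(n_accept), max_draws)
  tried <- res$tried
  if (res$got < n_accept)
    stop("ABC aborted after ", tried, " draws with only ", res$got,
         " acceptances (rate ", signif(res$got / tried, 2),
         "); check the observation or widen the tolerance")
  draws <- as.data.frame(res$accepted)
  names(draws) <- c("theta", "rho")
  draws$rho_over_theta <- draws$rho / draws$theta
  structure(list(
    draws = draws,
    n_accepted = n_accept,
    n_draws = tried,
    tol = tol,
    rule = paste0(min_stats, " of 4 means within ", tol * 100, "%"),
    mode = c(theta = as.numeric(posterior_mode(draws$theta, priors$theta)),
             rho = as.numeric(posterior_mode(draws$rho, priors$rho)),
             rho_over_theta = as.numeric(posterior_mode(
               draws$rho_over_theta,
               c(0, max(draws$rho_over_theta))))),
    priors = priors[c("theta", "rho")]
  ), class = "abc_posterior")
}

#' Two-stage rejection ABC for the bottleneck parameters
#'
#' Stage 1 draws `(t2, d, k, m12, m21)` from the priors, simulates the
#' two-population model for the full panel, and accepts a draw when the
#' cross-locus mean AND variance of each wild statistic (S, pi, Hap, Hdiv)
#' fall within `tol_stage1` of the wild observation (8 conditions), until
#' `n_stage1` acceptances. Stage 2 keeps the accepted draws whose
#' cultivated cross-locus means of (S, rho, Hap, Hdiv) satisfy at least 3
#' of 4 within `tol_stage2`. The posterior is formed from the survivors.
#'
#' Following the published procedure, a wider stage-1 band (60%) is used
#' when `rho_over_theta >= 2`, where acceptance rates collapse otherwise.
#'
#' @param observed list as returned by [load_observed_from_table()]
#'   (elements `wild` and `cultivated`).
#' @param panel locus panel; per-locus `theta_site` scales the simulations.
#' @param rho_over_theta grid value for the recombination/mutation ratio
#'   (the published grid is 0, 1, 2, 5, 10).
#' @param n_stage1 stage-1 acceptances to collect (2000 by default; the
#'   published scale of 10000 is available by argument).
#' @param tol_stage1 stage-1 band; default 0.30, or 0.60 when
#'   `rho_over_theta >= 2`.
#' @param tol_stage2 stage-2 band (default 0.30).
#' @param model_base [demographic_model()] supplying `N_a`, `mu`, `N_p`
#'   and the zero-time anchors (its `t2/d/k/m` values are ignored).
#' @param priors prior boxes.
#' @param seed optional integer seed.
#' @param max_draws hard simulation cap with abort diagnostics.
#' @return object of class `abc_bottleneck_posterior`: stage-1 `draws`,
#'   stage-2 `survivors`, counts, tolerances, KDE mode of `k` (and of the
#'   other parameters) among survivors.
#' @export
abc_bottleneck <- function(observed, panel = locus_panel(),
                          rho_over_theta = 1, n_stage1 = 2000,
                          tol_stage1 = NULL, tol_stage2 = 0.30,
                          model_base = demographic_model(),
                          priors = abc_priors(), seed = NULL,
                          max_draws = 5e6) {
  .check_seed(seed)
  if (is.null(tol_stage1)) tol_stage1 <- if (rho_over_theta >= 2) 0.60 else 0.30
  ord <- order(panel$L)  # short (cheap) loci first for early rejection
  n1 <- as.integer(panel$n_wild)[ord]
  n2 <- as.integer(panel$n_cult)[ord]
  L <- panel$L[ord]
  theta_loc <- (panel$theta_site * panel$L)[ord]
  rho_loc <- rho_over_theta * theta_loc
  nloc <- nrow(panel)
  Na <- model_base$N_a
  obs_w <- observed$wild
  obs_c <- observed$cultivated
  ow_m <- obs_w$mean[c("S", "pi", "hap", "hdiv")]
  ow_v <- obs_w$var[c("S", "pi", "hap", "hdiv")]
  oc_m <- obs_c$mean[c("S", "rho", "hap", "hdiv")]
  # zero-observation scale: cross-locus SD where available, else 1
  sd_c <- sqrt(c(obs_c$var["S"], 1, obs_c$var["hap"], obs_c$var["hdiv"]))

  res <- .abc_bottleneck_loop_cpp(
    n1, n2, theta_loc, rho_loc, L, Na, model_base$np_rel,
    priors$t2, priors$d, priors$k, priors$m12, priors$m21,
    ow_m, ow_v, tol_stage1, as.integer(n_stage1), max_draws)
  tried <- res$tried
  if (res$got < n_stage1)
    stop("stage 1 aborted after ", tried, " draws with ", res$got,
         " acceptances; check the observation or widen the tolerance")
  draws <- as.data.frame(res$accepted)
  names(draws) <- c("t2", "d", "k", "m12", "m21",
                    "S_c", "rho_c", "hap_c", "hdiv_c")
  simc <- as.matrix(draws[, c("S_c", "rho_c", "hap_c", "hdiv_c")])
  simc[is.na(simc)] <- 0
  nok <- rowSums(mapply(function(j, o, s0)
    .within(simc[, j], o, tol_stage2, s0),
    seq_along(oc_m), oc_m, sd_c))
  surv <- draws[nok >= 3, , drop = FALSE]
  if (nrow(surv) == 0)
    warning("no stage-2 survivors; consider relaxing tol_stage2 ",
            "(no automatic change is made)")
  modes <- if (nrow(surv) >= 50) {
    c(k = as.numeric(posterior_mode(surv$k, priors$k)),
      t2 = as.numeric(posterior_mode(surv$t2, priors$t2)),
      d = as.numeric(posterior_mode(surv$d, priors$d)),
      m12 = as.numeric(posterior_mode(surv$m12, priors$m12)),
      m21 = as.numeric(posterior_mode(surv$m21, priors$m21)))
  } else c(k = NA_real_, t2 = NA_real_, d = NA_real_, m12 = NA_real_,
           m21 = NA_real_)
  structure(list(
    draws = draws,
    survivors = surv,
    n_stage1 = n_stage1,
    n_stage2 = nrow(surv),
    n_draws = tried,
    rho_over_theta = rho_over_theta,
    tol_stage1 = tol_stage1,
    tol_stage2 = tol_stage2,
    mode = modes,
    priors = priors[c("t2", "d", "k", "m12", "m21")],
    model_base = model_base
  ), class = "abc_bottleneck_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> ", x$n_accepted, " accepted / ", x$n_draws,
      " draws (", x$rule, ")\n  mode: theta = ", signif(x$mode["theta"], 3),
      ", rho = ", signif(x$mode["rho"], 3), ", rho/theta = ",
      signif(x$mode["rho_over_theta"], 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.abc_bottleneck_posterior <- function(x, ...) {
  cat("<abc_bottleneck_posterior> rho/theta = ", x$rho_over_theta, ": ",
      x$n_stage1, " stage-1 acceptances / ", x$n_draws, " draws, ",
      x$n_stage2, " stage-2 survivors\n  k mode = ",
      signif(x$mode["k"], 4), "\n", sep = "")
  invisible(x)
}

#' Posterior-predictive selection scan
#'
#' For each locus, resamples bottleneck parameters from the stage-2
#' survivors, simulates the cultivated sample once per replicate, and
#' reports `p = Pr(simulated statistic <= observed)` for the cultivated
#' per-site pi (default) or S. A small p flags diversity loss beyond what
#' the fitted demographic model explains, i.e. a candidate target of
#' selection during domestication.
#'
#' @param observed_cult data.frame with per-locus cultivated rows (columns
#'   `locus`, `pi`, `S`), e.g. the cultivated rows of [observed_table3()].
#' @param posterior an `abc_bottleneck_posterior` with survivors.
#' @param panel locus panel.
#' @param n_pp posterior-predictive replicates per locus (default 1000).
#' @param statistic `"pi"` or `"S"`.
#' @param seed optional integer seed.
#' @return data.frame with columns `locus`, `observed`, `p`.
#' @export
selection_scan <- function(observed_cult, posterior, panel = locus_panel(),
                           n_pp = 1000, statistic = c("pi", "S"),
                           seed = NULL) {
  statistic <- match.arg(statistic)
  .check_seed(seed)
  surv <- posterior$survivors
  if (nrow(surv) < 1) stop("posterior has no survivors")
  mb <- posterior$model_base
  Na <- mb$N_a
  idx <- sample.int(nrow(surv), n_pp, replace = TRUE)
  out <- data.frame(locus = panel$locus,
                    observed = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(panel))) {
    obs_row <- observed_cult[observed_cult$locus == panel$locus[i], ]
    if (nrow(obs_row) == 0) next
    obs <- obs_row[[statistic]][1]
    sims <- numeric(n_pp)
    for (r in seq_len(n_pp)) {
      pr <- surv[idx[r], ]
      st <- .sim_panel_stats_cpp(
        panel$n_wild[i], panel$n_cult[i],
        panel$theta_site[i] * panel$L[i],
        posterior$rho_over_theta * panel$theta_site[i] * panel$L[i],
        generations_to_coalescent(pr$t2 - pr$d, Na),
        generations_to_coalescent(pr$t2, Na),
        pr$k * pr$d / Na, mb$np_rel, pr$m12, pr$m21, FALSE)
      sims[r] <- if (statistic == "pi") st[1, "pi_c"] / panel$L[i] else
        st[1, "S_c"]
    }
    out$observed[i] <- obs
    out$p[i] <- mean(sims <= obs)
  }
  out
}
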