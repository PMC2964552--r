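# R-side interface to the Hudson-style coalescent engine: the demographic
# model container, unit conversions, simulation wrappers and summary
# statistics that reuse the observed-data code paths.

#' Split-with-bottleneck-and-migration demographic model
#'
#' Two populations: the wild progenitor of constant effective size `N_a`,
#' and a cultivated population founded `t2` generations ago at bottleneck
#' size `N_b = k * d`, expanding to `N_p` at `t1 = t2 - d` and constant
#' since. Migration (`m12` wild to cultivar, `m21` cultivar to wild, in
#' units of `4*N_a*m`) acts between the present and the split. The
#' bottleneck severity `k = N_b / d` holds by construction: small `k`
#' (small founding population and/or long bottleneck) removes more
#' diversity; the expected fraction of pairwise diversity surviving the
#' bottleneck is about `exp(-1/(2k))`.
#'
#' `N_a` is derived from the wild per-site theta and the per-site mutation
#' rate via `theta = 4 N mu` unless given; it is needed only to convert the
#' generation-denominated times into coalescent units of `4*N_a`
#' generations.
#'
#' @param t2 generations ago of the split/bottleneck onset.
#' @param d bottleneck duration in generations (`t1 = t2 - d`).
#' @param k bottleneck severity `N_b / d`.
#' @param m12,m21 scaled migration rates (`4*N_a*m`), wild to cultivar and
#'   cultivar to wild.
#' @param rho_over_theta ratio of the locus recombination to mutation
#'   parameters used when simulating.
#' @param theta_site per-site theta of the wild/ancestral population
#'   (default: cross-locus mean of the observed wild Watterson estimates).
#' @param mu per-site per-generation mutation rate (default 7e-9, the order
#'   of grass synonymous substitution rates).
#' @param N_a ancestral effective size; derived from `theta_site`/`mu` when
#'   `NULL`.
#' @param N_p cultivated population size after expansion; defaults to `N_a`
#'   (bottleneck-and-recovery).
#' @return object of class `demographic_model` with the primitive and
#'   derived (coalescent-unit) parameters.
#' @export
demographic_model <- function(t2 = 8700, d = 1000, k = 0.6095,
                              m12 = 0, m21 = 0, rho_over_theta = 1,
                              theta_site = NULL, mu = 7e-9, N_a = NULL,
                              N_p = NULL) {
  if (is.null(theta_site))
    theta_site <- mean(observed_table3()$theta[
      observed_table3()$species == "wild"])
  if (is.null(N_a)) N_a <- theta_site / (4 * mu)
  if (is.null(N_p)) N_p <- N_a
  if (d <= 0) stop("bottleneck duration d must be > 0")
  t1 <- t2 - d
  if (t1 < 0) stop("inconsistent times: t1 = t2 - d < 0")
  if (k <= 0) stop("severity k must be > 0")
  N_b <- k * d
  structure(list(
    N_a = N_a, N_b = N_b, N_p = N_p, mu = mu, theta_site = theta_site,
    t2 = t2, t1 = t1, d = d, k = k, m12 = m12, m21 = m21,
    rho_over_theta = rho_over_theta,
    tau1 = generations_to_coalescent(t1, N_a),
    tau2 = generations_to_coalescent(t2, N_a),
    nb_rel = N_b / N_a,
    np_rel = N_p / N_a
  ), class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> N_a = ", round(x$N_a), ", bottleneck ",
      x$t2, "-", x$t1, " gens ago (d = ", x$d, ", N_b = ", round(x$N_b, 1),
      ", k = ", x$k, "), N_p = ", round(x$N_p),
      ", M12 = ", x$m12, ", M21 = ", x$m21,
      ", rho/theta = ", x$rho_over_theta, "\n", sep = "")
  invisible(x)
}

#' Convert between generations and coalescent time units
#'
#' Coalescent time is measured in units of `4 * N_a` generations. The two
#' conversions are exact inverses.
#'
#' @param t time in generations (or coalescent units for the inverse).
#' @param N_a reference effective population size.
#' @return converted time.
#' @export
generations_to_coalescent <- function(t, N_a) t / (4 * N_a)

#' @rdname generations_to_coalescent
#' @export
coalescent_to_generations <- function(t, N_a) t * 4 * N_a

.check_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  else if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  invisible(NULL)
}

#' Simulate the standard neutral coalescent
#'
#' Infinite-sites sample from the constant-size coalescent with
#' recombination (Hudson's algorithm; `theta` and `rho` are the per-locus
#' scaled rates `4*N*mu` and `4*N*r`).
#'
#' @param n sample size.
#' @param theta per-locus scaled mutation rate.
#' @param rho per-locus scaled recombination rate.
#' @param L locus length in bp (positions are reported on `[0, L)`).
#' @param seed optional integer seed (`set.seed` is called when given;
#'   otherwise the current RNG stream is used).
#' @return object of class `sim_haplotypes`: `matrix` (n x S binary,
#'   every column polymorphic), `positions` (bp, increasing), `L`, `pop`
#'   (labels, here all `"wild"`).
#' @export
simulate_standard <- function(n, theta, rho = 0, L = 1, seed = NULL) {
  stopifnot(n >= 2, theta >= 0, rho >= 0)
  .check_seed(seed)
  sim <- .sim_locus_cpp(as.integer(n), 0L, theta, rho, 0, 0, 1, 1, 0, 0)
  .as_sim(sim, n_wild = n, n_cult = 0, L = L)
}

#' Simulate the bottleneck model for one locus
#'
#' Joint two-population sample under a [demographic_model()]: backward in
#' time the cultivated lineages sit in a population of size `N_p` until
#' `t1`, size `N_b` on `(t1, t2]`, and merge into the ancestor (size `N_a`,
#' which is also the wild population) at `t2`; migration is active between
#' the present and `t2`. `theta_locus = theta_site * L` and
#' `rho_locus = rho_over_theta * theta_locus`.
#'
#' @param model a [demographic_model()].
#' @param spec one locus-panel row (fields `L`, `n_wild`, `n_cult`,
#'   `theta_site`; see [locus_panel()]).
#' @param seed optional integer seed.
#' @return a `sim_haplotypes` object with wild and cultivated rows.
#' @export
simulate_bottleneck <- function(model, spec, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  .check_seed(seed)
  theta_loc <- spec$theta_site * spec$L
  rho_loc <- model$rho_over_theta * theta_loc
  sim <- .sim_locus_cpp(as.integer(spec$n_wild), as.integer(spec$n_cult),
                        theta_loc, rho_loc, model$tau1, model$tau2,
                        model$nb_rel, model$np_rel, model$m12, model$m21)
  .as_sim(sim, n_wild = spec$n_wild, n_cult = spec$n_cult, L = spec$L)
}

.as_sim <- function(sim, n_wild, n_cult, L) {
  mat <- sim$matrix
  pop <- c(rep("wild", n_wild), rep("cultivated", n_cult))
  rownames(mat) <- make.unique(paste0(substr(pop, 1, 4),
                                      sprintf("_%02d", seq_along(pop))))
  structure(list(matrix = mat, positions = sim$positions * L, L = L,
                 pop = pop), class = "sim_haplotypes")
}

#' @export
print.sim_haplotypes <- function(x, ...) {
  cat("<sim_haplotypes> ", nrow(x$matrix), " haplotypes x ",
      ncol(x$matrix), " segregating sites over ", x$L, " bp\n", sep = "")
  invisible(x)
}

#' Summary statistics of a simulated haplotype matrix
#'
#' Computes (S, per-site pi, Hap, Hdiv and optionally the per-locus rho
#' estimate) for one population of a simulated sample, through the same
#' low-level code paths used for observed alignments.
#'
#' @param sim a `sim_haplotypes` object.
#' @param pop population label or `NULL` for all rows.
#' @param want_rho also compute the per-locus Hill-Weir rho estimate
#'   (`NA` when inestimable).
#' @return named numeric vector `(S, pi, hap, hdiv[, rho])`.
#' @export
summarize_haplotypes <- function(sim, pop = NULL, want_rho = FALSE) {
  keep <- if (is.null(pop)) rep(TRUE, nrow(sim$matrix)) else sim$pop == pop
  if (!any(keep)) stop("population '", pop, "' absent from simulation")
  mat <- sim$matrix[keep, , drop = FALSE]
  hs <- .hap_stats_m(mat)
  out <- c(S = .seg_sites_m(mat), pi = .pi_total_m(mat) / sim$L,
           hap = hs$hap, hdiv = hs$hdiv)
  if (want_rho) {
    mo <- .ld_moments(mat, sim$positions / sim$L)
    out["rho"] <- if (is.null(mo)) NA_real_ else
      .hw_rho_moment_cpp(mo$d, mo$D2, mo$w, mo$n)
  }
  out
}
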