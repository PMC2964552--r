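# Pairwise linkage disequilibrium and the Hill-Weir drift-recombination
# decay regression.

#' Expected r-squared under drift-recombination equilibrium
#'
#' Finite-sample Hill-Weir expectation
#' \deqn{E(r^2) = \frac{10+\rho}{(2+\rho)(11+\rho)}
#'   \left(1 + \frac{(3+\rho)(12+12\rho+\rho^2)}{n(2+\rho)(11+\rho)}\right)}
#' for scaled recombination `rho` between two sites and sample size `n`
#' (`n = Inf` gives the large-sample curve `(10+rho)/((2+rho)(11+rho))`).
#'
#' @param rho scaled recombination rate(s), >= 0.
#' @param n sample size (>= 2, possibly `Inf`).
#' @return expected r-squared in (0, 1].
#' @export
expected_r2 <- function(rho, n) {
  stopifnot(all(rho >= 0), n >= 2)
  a <- (10 + rho) / ((2 + rho) * (11 + rho))
  if (is.infinite(n)) return(a)
  a * (1 + ((3 + rho) * (12 + 12 * rho + rho^2)) / (n * (2 + rho) * (11 + rho)))
}

#' Pairwise r-squared between polymorphic sites
#'
#' Squared allele-frequency correlation
#' `r2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))` over haplotypes, for
#' every pair of biallelic sites within the locus. Singleton sites are
#' excluded by default (they produce spurious high r-squared at short
#' distances); set `min_minor = 1` to keep them.
#'
#' @inheritParams segregating_sites
#' @param min_minor minimum minor-allele count for a site to enter (default
#'   2, i.e. singletons excluded).
#' @return data.frame with columns `locus`, `i`, `j` (original column
#'   positions in bp), `d` (distance in bp) and `r2`.
#' @export
pairwise_r2 <- function(aln, pop = NULL, min_minor = 2) {
  if (inherits(aln, "sim_haplotypes")) {
    keep <- if (is.null(pop)) rep(TRUE, nrow(aln$matrix)) else
      aln$pop == pop
    return(.r2_table(aln$matrix[keep, , drop = FALSE], aln$positions,
                     "sim", min_minor))
  }
  filt <- .as_filtered(aln)
  mat <- .pop_matrix(filt, pop)
  bi <- .biallelic01(mat, positions = filt$kept_columns)
  .r2_table(bi$mat, bi$positions, filt$locus_id, min_minor)
}

.r2_table <- function(bin, positions, locus_id, min_minor = 2) {
  n <- nrow(bin)
  cs <- colSums(bin)
  keep <- pmin(cs, n - cs) >= min_minor
  bin <- bin[, keep, drop = FALSE]
  positions <- positions[keep]
  K <- ncol(bin)
  empty <- data.frame(locus = character(), i = numeric(), j = numeric(),
                      d = numeric(), r2 = numeric())
  if (K < 2) return(empty)
  out <- vector("list", K * (K - 1) / 2)
  q <- 0
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      pA <- mean(bin[, i]); pB <- mean(bin[, j])
      pAB <- mean(bin[, i] & bin[, j])
      den <- pA * (1 - pA) * pB * (1 - pB)
      if (den <= 0) next
      q <- q + 1
      out[[q]] <- c(positions[i], positions[j], (pAB - pA * pB)^2 / den)
    }
  }
  if (q == 0) return(empty)
  m <- do.call(rbind, out[seq_len(q)])
  data.frame(locus = locus_id, i = m[, 1], j = m[, 2],
             d = m[, 2] - m[, 1], r2 = m[, 3], stringsAsFactors = FALSE)
}

# least-squares Hill-Weir fit; single implementation in C++ (log10 grid +
# golden-section refinement), shared with the simulated-data fast path
hw_rho_fit <- function(d, r2, n) {
  .hw_rho_fit_cpp(as.numeric(d), as.numeric(r2), as.numeric(n))
}

#' Fit the recombination rate per bp from pooled LD decay
#'
#' Nonlinear least squares of observed pairwise r-squared against the
#' Hill-Weir expectation with `rho = rho_per_bp * d`, pooled across loci.
#' The fit minimises the residual sum of squares over a log-scale grid with
#' golden-section refinement (bounded at `rho >= 0`).
#'
#' @param pairs data.frame with columns `d` (bp) and `r2`, as returned by
#'   [pairwise_r2()] (rows may be pooled across loci).
#' @param n sample size entering the Hill-Weir formula.
#' @return object of class `ld_fit`: `rho_per_bp`, `n`, `residual_sse`,
#'   `pairs_used`, and `d_r2_0.1`, the distance at which the fitted curve
#'   crosses r-squared = 0.1 (`Inf` if it never does).
#' @export
fit_rho_per_bp <- function(pairs, n) {
  d <- pairs$d; r2 <- pairs$r2
  stopifnot(length(d) == length(r2))
  if (length(d) < 2) stop("need at least 2 pairs to fit")
  rho <- hw_rho_fit(d, r2, n)
  sse <- sum((r2 - expected_r2(rho * d, n))^2)
  cross <- if (expected_r2(0, n) <= 0.1) 0 else if (rho <= 1e-12 ||
             expected_r2(rho * 1e9, n) > 0.1) Inf else
    uniroot(function(x) expected_r2(rho * x, n) - 0.1,
            lower = 1e-6, upper = 1e9, tol = 1e-6)$root
  structure(list(rho_per_bp = rho, n = n, residual_sse = sse,
                 pairs_used = length(d), d_r2_0.1 = cross),
            class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  cat("<ld_fit> rho/bp = ", signif(x$rho_per_bp, 4), " (", x$pairs_used,
      " pairs, n = ", x$n, "); r2 = 0.1 at ",
      if (is.finite(x$d_r2_0.1)) paste0(round(x$d_r2_0.1), " bp") else "Inf",
      "\n", sep = "")
  invisible(x)
}

# per-pair LD moments for the ratio-of-moments rho estimator: distance,
# squared disequilibrium D^2, and the allele-frequency product weight
.ld_moments <- function(bin, positions, min_minor = 2) {
  n <- nrow(bin)
  cs <- colSums(bin)
  keep <- pmin(cs, n - cs) >= min_minor
  bin <- bin[, keep, drop = FALSE]
  positions <- positions[keep]
  K <- ncol(bin)
  if (K < 2) return(NULL)
  d <- D2 <- w <- numeric(0)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      pA <- mean(bin[, i]); pB <- mean(bin[, j])
      pAB <- mean(bin[, i] & bin[, j])
      den <- pA * (1 - pA) * pB * (1 - pB)
      if (den <= 0) next
      d <- c(d, positions[j] - positions[i])
      D2 <- c(D2, (pAB - pA * pB)^2)
      w <- c(w, den)
    }
  }
  if (!length(d)) return(NULL)
  list(d = d, D2 = D2, w = w, n = n)
}

#' Per-locus population recombination rate estimate
#'
#' Ratio-of-moments estimate of the per-locus total rho (4Nc over the
#' locus): the summed squared disequilibrium `sum D^2` over site pairs is
#' matched to its expectation `sum E(r2 | rho d) pA qA pB qB` under the
#' Hill-Weir curve, solved over rho >= 0. This moment condition avoids the
#' strong upward bias of per-pair least squares on r-squared, whose
#' frequency conditioning deflates observed r-squared at low-frequency
#' variants. Singleton sites are excluded; loci with fewer than two usable
#' biallelic sites are inestimable and return `NA` (printed as "Na" in
#' summary tables).
#'
#' @inheritParams segregating_sites
#' @return per-locus total rho estimate, or `NA`.
#' @export
rho_hat_per_locus <- function(aln, pop = NULL) {
  filt <- .as_filtered(aln)
  mat <- .pop_matrix(filt, pop)
  bi <- .biallelic01(mat, positions = filt$kept_columns)
  mo <- .ld_moments(bi$mat, bi$positions / filt$L_total)
  if (is.null(mo)) return(NA_real_)
  .hw_rho_moment_cpp(mo$d, mo$D2, mo$w, mo$n)
}
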