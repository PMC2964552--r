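# Per-locus and cross-species summary statistics: segregating sites,
# nucleotide diversity, Watterson's theta, Tajima's D, Fu & Li's D*/F*,
# haplotype statistics, four-gamete Rm, Hudson's Fst, polymorphism
# partition, site-frequency spectra and silent divergence.
#
# All statistics operate on the row-subset of a filtered alignment matrix;
# the same code paths are reused for simulated 0/1 haplotype matrices.

.as_filtered <- function(aln) {
  if (inherits(aln, "filtered_alignment")) aln else filter_sites(aln)
}

.pop_matrix <- function(aln, pop = NULL) {
  filt <- .as_filtered(aln)
  if (is.null(pop)) return(filt$matrix)
  keep <- filt$population == pop
  if (!any(keep)) stop("population '", pop, "' absent from alignment")
  filt$matrix[keep, , drop = FALSE]
}

# ---- low-level matrix statistics (shared with the coalescent summaries) ----

.col_tab <- function(col) {
  tabulate(match(col, unique(col)))
}

.seg_sites_m <- function(mat) {
  if (ncol(mat) == 0) return(0L)
  if (is.numeric(mat)) {
    cs <- colSums(mat)
    return(sum(cs > 0 & cs < nrow(mat)))
  }
  sum(apply(mat, 2, function(col) length(unique(col)) > 1))
}

.pi_total_m <- function(mat) {
  n <- nrow(mat)
  if (n < 2 || ncol(mat) == 0) return(0)
  if (is.numeric(mat)) {
    cs <- colSums(mat)
    return(sum(cs * (n - cs)) / choose(n, 2))
  }
  percol <- apply(mat, 2, function(col) {
    cnt <- .col_tab(col)
    (n^2 - sum(cnt^2)) / 2
  })
  sum(percol) / choose(n, 2)
}

# total mutation count eta (alleles - 1 per column) and singleton count
.eta_counts_m <- function(mat) {
  n <- nrow(mat)
  eta <- 0L; eta_s <- 0L
  for (j in seq_len(ncol(mat))) {
    cnt <- if (is.numeric(mat)) {
      c1 <- sum(mat[, j]); c(c1, n - c1)[c(c1, n - c1) > 0]
    } else .col_tab(mat[, j])
    k <- length(cnt)
    if (k < 2) next
    eta <- eta + (k - 1L)
    eta_s <- eta_s + min(sum(cnt == 1L), k - 1L)
  }
  list(eta = eta, eta_s = eta_s)
}

.hap_stats_m <- function(mat) {
  n <- nrow(mat)
  key <- apply(mat, 1, paste, collapse = "")
  cnt <- table(key)
  p <- as.numeric(cnt) / n
  list(hap = length(cnt),
       hdiv = if (n > 1) (1 - sum(p^2)) * n / (n - 1) else 0)
}

# ---- exported statistics ----------------------------------------------------

#' Number of segregating sites
#'
#' @param aln a `locus_alignment` or `filtered_alignment`.
#' @param pop population label (`"wild"`, `"cultivated"`) or `NULL` for the
#'   whole sample.
#' @return count of columns with two or more states.
#' @export
segregating_sites <- function(aln, pop = NULL) {
  .seg_sites_m(.pop_matrix(aln, pop))
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences per site; multi-allelic columns
#' contribute full mismatch counts. With `sites = "silent"` the numerator is
#' the mean pairwise silent difference count (noncoding mismatches plus
#' synonymous codon differences by equal-weight pathway counting) and the
#' denominator the fractional silent length.
#'
#' @inheritParams segregating_sites
#' @param sites `"all"` or `"silent"`.
#' @return per-site diversity.
#' @export
nucleotide_diversity <- function(aln, pop = NULL, sites = c("all", "silent")) {
  sites <- match.arg(sites)
  filt <- .as_filtered(aln)
  mat <- .pop_matrix(filt, pop)
  if (sites == "all") return(.pi_total_m(mat) / filt$L_total)
  Ls <- count_silent_sites(filt)
  if (Ls <= 0) stop("no silent sites in locus ", filt$locus_id)
  .silent_diffs(filt, mat) / Ls
}

#' Watterson's estimator of the population mutation rate
#'
#' `theta_w = S / (a1 * L)` with `a1` the (n-1)-th harmonic number.
#'
#' @param S segregating sites (or an alignment, in which case `n`/`L` are
#'   taken from it).
#' @param n number of sequences.
#' @param L length in bp (possibly fractional, e.g. silent length).
#' @return per-site theta.
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(n >= 2, L > 0, S >= 0)
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * L)
}

.tajima_consts <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from summary counts
#'
#' @param n sample size (>= 4).
#' @param S segregating sites (>= 1).
#' @param pi_total mean pairwise difference count (not per site).
#' @return list with `D` and a two-sided `p` from the beta approximation of
#'   the null distribution.
#' @export
tajimas_D_from_counts <- function(n, S, pi_total) {
  if (S < 1) return(list(D = NA_real_, p = NA_real_, reason = "S = 0"))
  stopifnot(n >= 4)
  k <- .tajima_consts(n)
  D <- (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  # beta approximation on the theoretical range [Dmin, Dmax]
  a <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  b <- (n / (2 * (n - 1)) - 1 / k$a1) / sqrt(k$e2)
  s <- -a * b - 1
  alpha <- -a * s / (b - a)
  beta <- b * s / (b - a)
  x <- min(max((D - a) / (b - a), 0), 1)
  p <- 2 * min(pbeta(x, alpha, beta), 1 - pbeta(x, alpha, beta))
  list(D = D, p = p)
}

#' Tajima's D
#'
#' @inheritParams segregating_sites
#' @return list with `D` and beta-approximation `p`; `D = NA` with a reason
#'   when there is no polymorphism.
#' @export
tajimas_D <- function(aln, pop = NULL) {
  mat <- .pop_matrix(aln, pop)
  tajimas_D_from_counts(nrow(mat), .seg_sites_m(mat), .pi_total_m(mat))
}

.fuli_consts <- function(n) {
  i <- seq_len(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Outgroup-free versions based on the total mutation count `eta` and the
#' singleton count `eta_s` (variants carried by exactly one sequence), with
#' the corrected variance constants.
#'
#' @inheritParams segregating_sites
#' @return list with `Dstar`, `Fstar`, `eta`, `eta_s`.
#' @export
fu_li_tests <- function(aln, pop = NULL) {
  mat <- .pop_matrix(aln, pop)
  n <- nrow(mat)
  stopifnot(n >= 4)
  ec <- .eta_counts_m(mat)
  eta <- ec$eta; eta_s <- ec$eta_s
  if (eta < 1)
    return(list(Dstar = NA_real_, Fstar = NA_real_, eta = 0L, eta_s = 0L))
  k <- .fuli_consts(n)
  Dstar <- ((n / (n - 1)) * eta - k$an * eta_s) /
    sqrt(k$uD * eta + k$vD * eta^2)
  pi_t <- .pi_total_m(mat)
  Fstar <- (pi_t - ((n - 1) / n) * eta_s) /
    sqrt(k$uF * eta + k$vF * eta^2)
  list(Dstar = Dstar, Fstar = Fstar, eta = ec$eta, eta_s = ec$eta_s)
}

#' Haplotype count and diversity
#'
#' Distinct sequences over the kept columns;
#' `Hdiv = (n/(n-1)) * (1 - sum p_i^2)`.
#'
#' @inheritParams segregating_sites
#' @return list with `hap` and `hdiv`.
#' @export
haplotype_stats <- function(aln, pop = NULL) {
  .hap_stats_m(.pop_matrix(aln, pop))
}

#' Simulation-based significance for neutrality statistics
#'
#' Two-sided empirical p-value for Tajima's D or Fu & Li's D*/F* against a
#' constant-size neutral coalescent null simulated at the locus's Watterson
#' theta (an alternative to the beta approximation used for the star
#' flags).
#'
#' @inheritParams segregating_sites
#' @param statistic one of `"D"`, `"Dstar"`, `"Fstar"`.
#' @param nrep null replicates (default 1000).
#' @param seed optional integer seed.
#' @return list with `observed`, `p`, `nrep`.
#' @export
neutrality_sim_p <- function(aln, pop = NULL, statistic = c("D", "Dstar",
                                                            "Fstar"),
                             nrep = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  .check_seed(seed)
  filt <- .as_filtered(aln)
  mat <- .pop_matrix(filt, pop)
  n <- nrow(mat)
  S <- .seg_sites_m(mat)
  if (S < 1) stop("no polymorphism: statistic undefined")
  theta_loc <- S / sum(1 / seq_len(n - 1))
  stat_of <- function(m) {
    if (statistic == "D")
      return(tajimas_D_from_counts(n, .seg_sites_m(m), .pi_total_m(m))$D)
    ec <- .eta_counts_m(m)
    if (ec$eta < 1) return(NA_real_)
    k <- .fuli_consts(n)
    if (statistic == "Dstar")
      ((n / (n - 1)) * ec$eta - k$an * ec$eta_s) /
        sqrt(k$uD * ec$eta + k$vD * ec$eta^2)
    else
      (.pi_total_m(m) - ((n - 1) / n) * ec$eta_s) /
        sqrt(k$uF * ec$eta + k$vF * ec$eta^2)
  }
  obs <- stat_of(mat)
  null <- vapply(seq_len(nrep), function(r) {
    sim <- .sim_locus_cpp(as.integer(n), 0L, theta_loc, 0, 0, 0, 1, 1, 0, 0)
    if (ncol(sim$matrix) < 1) return(NA_real_)
    stat_of(sim$matrix)
  }, numeric(1))
  list(observed = obs,
       p = mean(abs(null) >= abs(obs), na.rm = TRUE),
       nrep = sum(!is.na(null)))
}

#' @export
print.sfs <- function(x, ...) {
  cat("<sfs> ", if (x$polarized) "derived" else "folded (minor)",
      " allele spectrum, n = ", x$n,
      if (!is.null(x$pop)) paste0(", pop = ", x$pop), ": ",
      sum(x$counts), " sites\n", sep = "")
  print(setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

# biallelic columns as a 0/1 matrix plus original positions
.biallelic01 <- function(mat, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  keep <- logical(ncol(mat))
  bin <- matrix(0L, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat))) {
    u <- unique(mat[, j])
    if (length(u) == 2) {
      keep[j] <- TRUE
      bin[, j] <- as.integer(mat[, j] == u[2])
    }
  }
  list(mat = bin[, keep, drop = FALSE], positions = positions[keep])
}

#' Minimum number of recombination events (four-gamete bound)
#'
#' Hudson-Kaplan lower bound: find all pairs of biallelic sites exhibiting
#' all four gametes and count the maximum number of disjoint intervals
#' between incompatible pairs.
#'
#' @inheritParams segregating_sites
#' @return integer Rm.
#' @export
min_recombination_Rm <- function(aln, pop = NULL) {
  mat <- .pop_matrix(aln, pop)
  bi <- .biallelic01(mat)
  .rm_from_binary(bi$mat)
}

.rm_from_binary <- function(bin) {
  K <- ncol(bin)
  if (K < 2) return(0L)
  iv <- NULL
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      g <- unique(bin[, i] * 2L + bin[, j])
      if (length(g) == 4) iv <- rbind(iv, c(i, j))
    }
  }
  if (is.null(iv)) return(0L)
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  rm <- 0L; last <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] >= last) {
      rm <- rm + 1L
      last <- iv[r, 2]
    }
  }
  rm
}

#' Hudson's Fst between the two populations
#'
#' `Fst = 1 - Hw/Hb` with `Hw` the mean within-population pairwise
#' difference count (average of the two populations) and `Hb` the mean
#' between-population pairwise difference count, aggregated over sites.
#' Small negative values are returned as computed.
#'
#' @param aln alignment containing both populations.
#' @return Fst value (0 when the populations are jointly monomorphic).
#' @export
fst <- function(aln) {
  m1 <- .pop_matrix(aln, "wild")
  m2 <- .pop_matrix(aln, "cultivated")
  hw <- (.pi_total_m(m1) + .pi_total_m(m2)) / 2
  hb <- .between_diffs(m1, m2)
  if (hb == 0) return(0)
  1 - hw / hb
}

# mean pairwise difference count between the rows of two matrices
.between_diffs <- function(m1, m2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  tot <- 0
  for (j in seq_len(ncol(m1))) {
    u <- unique(c(m1[, j], m2[, j]))
    c1 <- tabulate(match(m1[, j], u), nbins = length(u))
    c2 <- tabulate(match(m2[, j], u), nbins = length(u))
    tot <- tot + (n1 * n2 - sum(c1 * c2))
  }
  tot / (n1 * n2)
}

#' Partition segregating sites between two populations
#'
#' Classifies every jointly analyzable segregating column as shared
#' (polymorphic in both populations), fixed (alternate alleles fixed
#' between), or specific to one population. Categories are mutually
#' exclusive and exhaustive, and
#' `shared + specific(pop) = S(pop)` for each population.
#'
#' @param aln alignment containing both populations.
#' @return named integer vector `(shared, fixed, wild_specific,
#'   cultivar_specific)`.
#' @export
polymorphism_partition <- function(aln) {
  m1 <- .pop_matrix(aln, "wild")
  m2 <- .pop_matrix(aln, "cultivated")
  out <- c(shared = 0L, fixed = 0L, wild_specific = 0L,
           cultivar_specific = 0L)
  for (j in seq_len(ncol(m1))) {
    a1 <- unique(m1[, j]); a2 <- unique(m2[, j])
    p1 <- length(a1) > 1; p2 <- length(a2) > 1
    if (p1 && p2) out["shared"] <- out["shared"] + 1L
    else if (p1) out["wild_specific"] <- out["wild_specific"] + 1L
    else if (p2) out["cultivar_specific"] <- out["cultivar_specific"] + 1L
    else if (a1 != a2) out["fixed"] <- out["fixed"] + 1L
  }
  out
}

#' Site frequency spectrum
#'
#' Biallelic sites only. With an outgroup (either stored in the alignment or
#' passed explicitly) the spectrum is polarized: the allele not carried by
#' the outgroup is derived; sites where the outgroup carries a third state,
#' a gap or N are skipped. Without an outgroup the folded spectrum of minor
#' allele counts is returned.
#'
#' @inheritParams segregating_sites
#' @param outgroup optional outgroup sequence (character vector over the
#'   kept columns).
#' @return object of class `sfs`: list with `counts` (classes `1..n-1`
#'   unfolded, `1..floor(n/2)` folded), `polarized`, `n`, `pop`.
#' @export
sfs <- function(aln, pop = NULL, outgroup = NULL) {
  filt <- .as_filtered(aln)
  if (is.null(outgroup)) outgroup <- filt$outgroup
  mat <- .pop_matrix(filt, pop)
  n <- nrow(mat)
  polarized <- !is.null(outgroup)
  counts <- if (polarized) integer(n - 1) else integer(floor(n / 2))
  for (j in seq_len(ncol(mat))) {
    u <- unique(mat[, j])
    if (length(u) != 2) next
    c1 <- sum(mat[, j] == u[1])
    if (polarized) {
      og <- outgroup[j]
      if (!og %in% u) next
      derived <- if (og == u[1]) n - c1 else c1
      if (derived >= 1 && derived <= n - 1)
        counts[derived] <- counts[derived] + 1L
    } else {
      minor <- min(c1, n - c1)
      counts[minor] <- counts[minor] + 1L
    }
  }
  structure(list(counts = counts, polarized = polarized, n = n, pop = pop),
            class = "sfs")
}

# ---- silent-site differences (Nei-Gojobori pathway counting) ---------------

# memoized synonymous-difference count between two codons, averaging over
# all substitution pathways
.ng_pair_env <- new.env(parent = emptyenv())
.ng_syn_diff <- function(c1, c2) {
  if (c1 == c2) return(0)
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .ng_pair_env[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 1) list(pos) else {
    perms <- if (length(pos) == 2) list(pos, rev(pos)) else {
      p <- list()
      for (a in 1:3) for (b in setdiff(1:3, a))
        p[[length(p) + 1]] <- c(pos[a], pos[b], setdiff(pos, pos[c(a, b)]))
      p
    }
    perms
  }
  syn <- numeric(length(paths))
  for (k in seq_along(paths)) {
    cur <- c1; s <- 0
    for (p in paths[[k]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]])
        s <- s + 1
      cur <- nxt
    }
    syn[k] <- s
  }
  val <- mean(syn)
  assign(key, val, envir = .ng_pair_env)
  val
}

# mean silent (noncoding + synonymous) pairwise difference count: within the
# rows of `mat`, or between `mat` and `mat2` when the latter is given
.silent_diffs <- function(filt, mat, mat2 = NULL) {
  noncod <- which(filt$column_class == "noncoding")
  within <- is.null(mat2)
  n1 <- nrow(mat)
  tot <- 0
  for (j in noncod) {
    if (within) {
      cnt <- .col_tab(mat[, j])
      tot <- tot + (n1^2 - sum(cnt^2)) / 2 / choose(n1, 2)
    } else {
      u <- unique(c(mat[, j], mat2[, j]))
      c1 <- tabulate(match(mat[, j], u), nbins = length(u))
      c2 <- tabulate(match(mat2[, j], u), nbins = length(u))
      tot <- tot + (n1 * nrow(mat2) - sum(c1 * c2)) / (n1 * nrow(mat2))
    }
  }
  for (cols in .kept_codons(filt)) {
    cod1 <- paste0(mat[, cols[1]], mat[, cols[2]], mat[, cols[3]])
    t1 <- table(cod1)
    if (within) {
      if (length(t1) == 1) next
      u <- names(t1); s <- 0
      for (a in seq_along(u)) for (b in seq_len(a - 1))
        s <- s + t1[[a]] * t1[[b]] * .ng_syn_diff(u[a], u[b])
      tot <- tot + s / choose(n1, 2)
    } else {
      cod2 <- paste0(mat2[, cols[1]], mat2[, cols[2]], mat2[, cols[3]])
      t2 <- table(cod2)
      s <- 0
      for (a in names(t1)) for (b in names(t2))
        s <- s + t1[[a]] * t2[[b]] * .ng_syn_diff(a, b)
      tot <- tot + s / (n1 * nrow(mat2))
    }
  }
  tot
}

#' Silent divergence between populations (Ks)
#'
#' Mean per-silent-site difference between one sequence drawn from each
#' population (noncoding mismatches plus synonymous codon differences).
#' Symmetric in population order; equals within-population silent pi when
#' both populations are the same pool.
#'
#' @param aln alignment containing both populations.
#' @return per-silent-site divergence.
#' @export
ks_divergence <- function(aln) {
  filt <- .as_filtered(aln)
  Ls <- count_silent_sites(filt)
  if (Ls <= 0) stop("no silent sites in locus ", filt$locus_id)
  m1 <- .pop_matrix(filt, "wild")
  m2 <- .pop_matrix(filt, "cultivated")
  .silent_diffs(filt, m1, m2) / Ls
}

#' Correlation of silent diversity with divergence across loci
#'
#' Under neutral equilibrium, per-locus silent theta and silent divergence
#' should be proportional; their Pearson correlation (two-sided t test) is a
#' simple neutrality screen. Loci can be excluded (e.g. a candidate target
#' of selection) by name.
#'
#' @param theta_sil named numeric vector of per-locus silent theta.
#' @param ks named numeric vector of per-locus divergence (same loci).
#' @param exclude character vector of locus names to drop.
#' @return list with `r`, `p`, `n_loci`.
#' @export
theta_ks_correlation <- function(theta_sil, ks, exclude = NULL) {
  if (!is.null(names(theta_sil)) && !is.null(names(ks)))
    ks <- ks[names(theta_sil)]
  keep <- if (is.null(exclude)) rep(TRUE, length(theta_sil)) else
    !(names(theta_sil) %in% exclude)
  x <- theta_sil[keep]; y <- ks[keep]
  if (length(x) < 3) stop("need at least 3 loci")
  if (var(x) == 0 || var(y) == 0) stop("zero variance across loci")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_loci = length(x))
}

# number of segregating silent sites: segregating noncoding columns plus
# segregating coding columns whose observed variants are all synonymous
.seg_silent_sites <- function(filt, mat) {
  noncod <- filt$column_class == "noncoding"
  s <- .seg_sites_m(mat[, noncod, drop = FALSE])
  gc <- Biostrings::GENETIC_CODE
  for (cols in .kept_codons(filt)) {
    cod <- unique(paste0(mat[, cols[1]], mat[, cols[2]], mat[, cols[3]]))
    if (length(cod) < 2) next
    aa <- unique(gc[cod])
    nseg <- sum(vapply(1:3, function(p)
      length(unique(substr(cod, p, p))) > 1, logical(1)))
    if (length(aa) == 1) s <- s + nseg
  }
  s
}

#' Per-locus summary row
#'
#' Computes the full per-locus, per-population summary: lengths, sample
#' size, segregating sites, pi and theta (total and silent), Tajima's D,
#' Fu & Li's D*/F*, the per-locus recombination estimate, Rm, and haplotype
#' statistics.
#'
#' @inheritParams segregating_sites
#' @return one-row data.frame in the published table's column layout.
#' @export
locus_summary <- function(aln, pop = NULL) {
  filt <- .as_filtered(aln)
  mat <- .pop_matrix(filt, pop)
  n <- nrow(mat)
  L <- filt$L_total
  Ls <- count_silent_sites(filt)
  S <- .seg_sites_m(mat)
  pi_t <- .pi_total_m(mat)
  td <- tajimas_D_from_counts(n, S, pi_t)
  fl <- if (S >= 1) fu_li_tests(filt, pop) else
    list(Dstar = NA_real_, Fstar = NA_real_)
  hs <- .hap_stats_m(mat)
  data.frame(
    locus = filt$locus_id,
    length = L,
    silent = Ls,
    n = n,
    S = S,
    pi = pi_t / L,
    pi_sil = if (Ls > 0) .silent_diffs(filt, mat) / Ls else NA_real_,
    theta = if (S > 0) watterson_theta(S, n, L) else 0,
    theta_sil = if (Ls > 0) {
      Ss <- .seg_silent_sites(filt, mat)
      if (Ss > 0) watterson_theta(Ss, n, Ls) else 0
    } else NA_real_,
    D = td$D,
    Dstar = fl$Dstar,
    Fstar = fl$Fstar,
    rho = rho_hat_per_locus(filt, pop),
    Rm = min_recombination_Rm(filt, pop),
    hap = hs$hap,
    hdiv = hs$hdiv,
    stringsAsFactors = FALSE
  )
}
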