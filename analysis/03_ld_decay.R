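#!/usr/bin/env Rscript

# Linkage-disequilibrium decay in the two species. Sequences were never
# deposited, so the empirical r2 clouds are emulated by simulating the
# nine-locus panel at each species' fitted (theta, rho/theta); pairwise r2
# is pooled across loci and the Hill-Weir expectation with rho = rho_bp * d
# is fitted by nonlinear least squares.
#
# Writes results/ld_pairs_<species>.tsv and results/ld_fit.json.

suppressPackageStartupMessages(library(milletpg))
dir.create("results", showWarnings = FALSE)
set.seed(20103)

panel <- locus_panel()
settings <- list(
  wild = list(theta = 0.0053, rho_over_theta = 0.836,
              n = panel$n_wild, L = panel$L),
  cultivated = list(theta = 0.0022, rho_over_theta = 0.43,
                    n = panel$n_cult, L = panel$L_cult)
)

fits <- list()
for (species in names(settings)) {
  s <- settings[[species]]
  pairs <- NULL
  for (rep in 1:5) {  # several panel replicates to fill the distance range
    for (i in seq_len(nrow(panel))) {
      sim <- simulate_standard(s$n[i], s$theta * s$L[i],
                               rho = s$rho_over_theta * s$theta * s$L[i],
                               L = s$L[i])
      pr <- pairwise_r2(sim)
      if (nrow(pr) > 0) {
        pr$locus <- paste0(panel$locus[i], "_r", rep)
        pairs <- rbind(pairs, pr)
      }
    }
  }
  n_eff <- round(mean(s$n))
  fit <- fit_rho_per_bp(pairs, n_eff)
  cat(sprintf("%s: %d pairs, rho/bp = %.3g, r2 = 0.1 at %.0f bp\n",
              species, fit$pairs_used, fit$rho_per_bp, fit$d_r2_0.1))
  write.table(pairs, sprintf("results/ld_pairs_%s.tsv", species),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fits[[species]] <- list(rho_per_bp = fit$rho_per_bp, n = fit$n,
                          pairs_used = fit$pairs_used,
                          residual_sse = fit$residual_sse,
                          d_r2_0.1 = fit$d_r2_0.1)
}
jsonlite::write_json(fits, "results/ld_fit.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf(
  "wild LD decays %.1fx faster than cultivated (crossing %.0f vs %.0f bp)\n",
  fits$cultivated$d_r2_0.1 / fits$wild$d_r2_0.1,
  fits$wild$d_r2_0.1, fits$cultivated$d_r2_0.1))
cat("note: absolute crossing distances under the fitted rho/theta are kb-scale;\n",
    "the sub-150-bp decay seen in empirical clouds requires the much larger\n",
    "cloud-fitted rho values that moment estimates of rho on short loci produce\n")
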