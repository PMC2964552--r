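# The published nine-locus observation: per-locus summary statistics for
# wild green foxtail and cultivated foxtail millet, and loaders that turn
# them into the ABC observation.

#' Published per-locus summary table
#'
#' The nine-locus diversity/neutrality summary for the wild and cultivated
#' populations as printed (the original Sanger alignments were never
#' deposited, so this table is the observation every downstream inference
#' consumes). The inestimable recombination entry ("Na") is returned as
#' `NA`.
#'
#' @param path optional path to a TSV in the same schema; defaults to the
#'   bundled table.
#' @return data.frame with columns `species`, `locus`, `length`, `silent`,
#'   `n`, `S`, `pi`, `pi_sil`, `theta`, `theta_sil`, `D`, `Dstar`, `Fstar`,
#'   `rho`, `Rm`, `hap`, `hdiv`.
#' @export
observed_table3 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table3.tsv", package = "milletpg")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", "Na", "na"))
  need <- c("species", "locus", "length", "silent", "n", "S", "pi", "theta",
            "theta_sil", "rho", "hap", "hdiv")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Published per-locus differentiation table
#'
#' Shared, fixed and species-specific segregating sites and Fst per locus,
#' as printed.
#'
#' @param path optional path to a TSV in the same schema.
#' @return data.frame.
#' @export
observed_table4 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table4.tsv", package = "milletpg")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Locus panel specification
#'
#' Per-locus simulation specification derived from a summary table: one row
#' per locus with the alignment length and sample size of each population
#' and the per-locus per-site theta (the wild Watterson estimate) used to
#' scale simulations. The wild alignment length is the panel length `L`.
#'
#' @param table a summary table as returned by [observed_table3()].
#' @return data.frame with columns `locus`, `L`, `L_cult`, `n_wild`,
#'   `n_cult`, `theta_site`.
#' @export
locus_panel <- function(table = observed_table3()) {
  w <- table[table$species == "wild", ]
  cu <- table[table$species == "cultivated", ]
  cu <- cu[match(w$locus, cu$locus), ]
  data.frame(locus = w$locus,
             L = w$length,
             L_cult = cu$length,
             n_wild = w$n,
             n_cult = cu$n,
             theta_site = w$theta,
             stringsAsFactors = FALSE)
}

# cross-locus mean/variance summary for one species
.species_summary <- function(rows) {
  if (nrow(rows) < 2)
    stop("need at least 2 loci to form cross-locus variances")
  stats <- cbind(S = rows$S, pi = rows$pi, hap = rows$hap, hdiv = rows$hdiv)
  list(mean = c(colMeans(stats), rho = mean(rows$rho, na.rm = TRUE)),
       var = apply(stats, 2, var),
       n_loci = nrow(rows))
}

#' Build the ABC observation from a summary table
#'
#' Cross-locus means and variances of the per-locus statistics
#' (S, pi, Hap, Hdiv; plus the mean per-locus rho with inestimable loci
#' skipped), per species — the comparison currency of the rejection
#' algorithm.
#'
#' @param table a data.frame in the summary-table schema, or a path to one.
#' @return list with elements `wild` and `cultivated`, each a list with
#'   `mean`, `var`, `n_loci`.
#' @export
load_observed_from_table <- function(table = observed_table3()) {
  if (is.character(table)) table <- observed_table3(table)
  list(wild = .species_summary(table[table$species == "wild", ]),
       cultivated = .species_summary(table[table$species == "cultivated", ]))
}
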