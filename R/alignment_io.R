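#' Read a sample-to-population map
#'
#' Two-column tab-separated file with a header line `sample_id<TAB>population`.
#' Populations are `wild`, `cultivated` or `outgroup`. Comment lines starting
#' with `#` and CRLF line endings are tolerated.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id` and `population`.
#' @export
read_popmap <- function(path) {
  pm <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(pm)))
    stop("popmap must have columns 'sample_id' and 'population'")
  pm$sample_id <- trimws(pm$sample_id)
  pm$population <- trimws(pm$population)
  bad <- setdiff(unique(pm$population), c("wild", "cultivated", "outgroup"))
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "))
  pm
}

#' Read a coding annotation table
#'
#' BED-like tab-separated file with header columns
#' `locus<TAB>start<TAB>end<TAB>class<TAB>frame`. Coordinates are 0-based,
#' half-open intervals on the alignment itself (no strand logic); `frame` is
#' the offset within the interval at which the first complete codon starts.
#'
#' @param path path to the TSV file.
#' @param locus_id optional locus to filter on.
#' @return data.frame with the columns above.
#' @export
read_annotation <- function(path, locus_id = NULL) {
  an <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus", "start", "end", "class", "frame")
  if (!all(need %in% names(an)))
    stop("annotation must have columns ", paste(need, collapse = ", "))
  if (!is.null(locus_id)) an <- an[an$locus == locus_id, , drop = FALSE]
  an
}

#' Construct a locus alignment object in memory
#'
#' The in-memory unit every statistic consumes: an aligned character matrix
#' (rows = haplotype sequences over `A,C,G,T,-,N`), per-sample population
#' labels, and a per-column coding/noncoding classification.
#'
#' @param mat character matrix with row names = sample ids.
#' @param population named character vector mapping sample ids to
#'   `wild`/`cultivated` (rows labelled `outgroup` are split off into the
#'   `outgroup` field).
#' @param locus_id locus identifier.
#' @param coding data.frame of 0-based half-open coding intervals with
#'   columns `start`, `end`, `frame` (may be empty).
#' @return object of class `locus_alignment`.
#' @export
locus_alignment <- function(mat, population, locus_id = "locus",
                            coding = NULL) {
  if (is.null(rownames(mat))) stop("alignment matrix must have row names")
  if (!all(rownames(mat) %in% names(population)))
    stop("samples missing from population map: ",
         paste(setdiff(rownames(mat), names(population)), collapse = ", "))
  population <- population[rownames(mat)]
  if (is.null(coding) || nrow(coding) == 0) {
    coding <- data.frame(start = integer(), end = integer(), frame = integer())
  } else {
    coding <- coding[order(coding$start), , drop = FALSE]
    if (nrow(coding) > 1 && any(coding$start[-1] < coding$end[-nrow(coding)]))
      stop("overlapping coding intervals in locus ", locus_id)
    if (any(coding$start < 0) || any(coding$end > ncol(mat)))
      stop("annotation interval outside alignment span in locus ", locus_id)
  }
  column_class <- rep("noncoding", ncol(mat))
  for (i in seq_len(nrow(coding)))
    column_class[(coding$start[i] + 1):coding$end[i]] <- "coding"
  og <- population == "outgroup"
  out <- structure(list(
    locus_id = locus_id,
    matrix = mat[!og, , drop = FALSE],
    population = population[!og],
    outgroup = if (any(og)) mat[og, , drop = FALSE][1, ] else NULL,
    column_class = column_class,
    coding = coding
  ), class = "locus_alignment")
  out
}

#' Read a per-locus FASTA alignment
#'
#' All records must be equal length (an alignment); every record id must be
#' present in the popmap. Coding annotation intervals use 0-based half-open
#' coordinates on the alignment.
#'
#' @param fasta_path path to the aligned FASTA.
#' @param annotation_path path to the annotation TSV (see
#'   [read_annotation()]); `NULL` means all-noncoding.
#' @param popmap_path path to the popmap TSV (see [read_popmap()]).
#' @param locus_id locus identifier; defaults to the FASTA file name.
#' @return a [locus_alignment()] object.
#' @export
read_alignment <- function(fasta_path, annotation_path = NULL,
                           popmap_path = NULL, locus_id = NULL) {
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA file: ", fasta_path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1)
    stop("ragged alignment in ", fasta_path,
         " (record lengths ", paste(sort(unique(w)), collapse = ", "), ")")
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- sub("\\s.*$", "", names(seqs))
  bad <- !mat %in% c("A", "C", "G", "T", "-", "N")
  if (any(bad)) mat[bad] <- "N"
  if (is.null(popmap_path)) stop("a popmap is required")
  pm <- read_popmap(popmap_path)
  unknown <- setdiff(rownames(mat), pm$sample_id)
  if (length(unknown))
    stop("samples in FASTA absent from popmap: ",
         paste(unknown, collapse = ", "))
  population <- setNames(pm$population, pm$sample_id)
  coding <- NULL
  if (!is.null(annotation_path)) {
    an <- read_annotation(annotation_path, locus_id = locus_id)
    an <- an[grepl("^coding", an$class), , drop = FALSE]
    coding <- an[, c("start", "end", "frame")]
  }
  locus_alignment(mat, population, locus_id = locus_id, coding = coding)
}

#' Filter alignment sites and samples
#'
#' Drops samples whose proportion of `N` columns exceeds `max_missing`
#' (lowering n, as per-locus sample counts in resequencing panels vary),
#' then removes every column containing a gap or `N` in any retained
#' sample (indel polymorphisms and residual missing data are excluded from
#' analysis). The operation is idempotent.
#'
#' @param aln a [locus_alignment()] (or an already filtered alignment, a
#'   no-op).
#' @param max_missing per-sample missing-data threshold (default 0.2).
#' @return object of class `filtered_alignment` with fields `matrix`
#'   (retained samples x kept columns), `kept_columns` (original indices),
#'   `L_total`, `n`, `population`, `column_class`, `coding`, `outgroup`.
#' @export
filter_sites <- function(aln, max_missing = 0.2) {
  if (inherits(aln, "filtered_alignment")) return(aln)
  stopifnot(inherits(aln, "locus_alignment"))
  mat <- aln$matrix
  if (nrow(mat) == 0 || ncol(mat) == 0) stop("empty alignment")
  missf <- rowMeans(mat == "N")
  keep_s <- missf <= max_missing
  mat <- mat[keep_s, , drop = FALSE]
  if (nrow(mat) == 0) stop("all samples dropped by missing-data filter")
  keep_c <- colSums(mat == "-" | mat == "N") == 0
  if (!any(keep_c)) stop("no analyzable sites in locus ", aln$locus_id)
  kept <- which(keep_c)
  structure(list(
    locus_id = aln$locus_id,
    matrix = mat[, kept, drop = FALSE],
    population = aln$population[rownames(mat)],
    outgroup = if (!is.null(aln$outgroup)) aln$outgroup[kept] else NULL,
    column_class = aln$column_class[kept],
    kept_columns = kept,
    coding = aln$coding,
    L_total = length(kept),
    n = nrow(mat)
  ), class = "filtered_alignment")
}

# number of synonymous sites of each codon under equal-weight (Nei-Gojobori)
# counting; mutations creating stop codons count as nonsynonymous, stop
# codons themselves contribute 0
.ng_syn_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(gc)
    res <- setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (gc[[cd]] == "*") { res[cd] <- 0; next }
      s <- 0
      for (p in 1:3) {
        for (b in setdiff(bases, substr(cd, p, p))) {
          alt <- cd
          substr(alt, p, p) <- b
          if (gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
        }
      }
      res[cd] <- s
    }
    tab <<- res
    tab
  }
})

# codon column triplets (original coordinates) for a filtered alignment;
# only codons whose three columns all survived filtering are returned
.kept_codons <- function(filt) {
  cd <- filt$coding
  out <- list()
  for (i in seq_len(nrow(cd))) {
    span <- cd$end[i] - cd$start[i] - cd$frame[i]
    if (span %% 3 != 0)
      stop("coding span not divisible by 3 in locus ", filt$locus_id)
    starts0 <- seq(cd$start[i] + cd$frame[i], cd$end[i] - 3, by = 3)
    for (s0 in starts0) {
      cols <- match(s0 + 1:3, filt$kept_columns)
      if (!anyNA(cols)) out[[length(out) + 1]] <- cols
    }
  }
  out
}

#' Count silent sites in a filtered alignment
#'
#' Silent length = number of kept noncoding columns plus the synonymous-site
#' fraction of each intact kept codon (equal-weight Nei-Gojobori counting,
#' averaged over the sampled sequences), so fractional values are expected.
#' Codons disrupted by filtered-out columns contribute nothing.
#'
#' @param aln a `filtered_alignment` (a `locus_alignment` is filtered first).
#' @return fractional silent length in bp; satisfies
#'   `0 <= L_silent <= L_total`.
#' @export
count_silent_sites <- function(aln) {
  filt <- filter_sites(aln)
  noncod <- sum(filt$column_class == "noncoding")
  syn <- 0
  tab <- .ng_syn_table()
  for (cols in .kept_codons(filt)) {
    cods <- paste0(filt$matrix[, cols[1]], filt$matrix[, cols[2]],
                   filt$matrix[, cols[3]])
    syn <- syn + mean(tab[cods])
  }
  noncod + syn
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", nrow(x$matrix), " sequences x ",
      ncol(x$matrix), " columns (", sum(x$column_class == "coding"),
      " coding)", if (!is.null(x$outgroup)) ", with outgroup", "\n", sep = "")
  invisible(x)
}

#' @export
print.filtered_alignment <- function(x, ...) {
  cat("<filtered_alignment> ", x$locus_id, ": n = ", x$n, ", L_total = ",
      x$L_total, " bp\n", sep = "")
  invisible(x)
}
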