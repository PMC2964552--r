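# Reading, filtering and silent-site accounting of per-locus alignments.

test_that("FASTA + popmap reading handles the identity and error cases", {
  dir <- withr::local_tempdir()
  writeLines(c(">a", "ACGTAC", ">b", "ACGTAC", ">c", "ACTTAC"),
             file.path(dir, "toy.fasta"))
  writeLines(c("sample_id\tpopulation", "a\twild", "b\twild",
               "c\tcultivated"), file.path(dir, "popmap.tsv"))
  aln <- read_alignment(file.path(dir, "toy.fasta"),
                        popmap_path = file.path(dir, "popmap.tsv"))
  expect_s3_class(aln, "locus_alignment")
  expect_equal(nrow(aln$matrix), 3)
  expect_equal(unname(aln$population["c"]), "cultivated")

  writeLines(c(">a", "ACGTAC", ">b", "ACGT"), file.path(dir, "bad.fasta"))
  expect_error(read_alignment(file.path(dir, "bad.fasta"),
                              popmap_path = file.path(dir, "popmap.tsv")),
               "ragged")
  file.create(file.path(dir, "empty.fasta"))
  expect_error(read_alignment(file.path(dir, "empty.fasta"),
                              popmap_path = file.path(dir, "popmap.tsv")))
  # unknown sample
  writeLines(c(">zz", "ACGTAC"), file.path(dir, "unk.fasta"))
  expect_error(read_alignment(file.path(dir, "unk.fasta"),
                              popmap_path = file.path(dir, "popmap.tsv")),
               "absent from popmap")
})

test_that("popmap and annotation readers tolerate comments and CRLF", {
  dir <- withr::local_tempdir()
  con <- file(file.path(dir, "pm.tsv"), "wb")
  writeLines(c("# comment", "sample_id\tpopulation", "a\twild"), con,
             sep = "\r\n")
  close(con)
  pm <- read_popmap(file.path(dir, "pm.tsv"))
  expect_equal(pm$sample_id, "a")
  writeLines(c("locus\tstart\tend\tclass\tframe", "l1\t0\t9\tcoding\t0"),
             file.path(dir, "ann.tsv"))
  an <- read_annotation(file.path(dir, "ann.tsv"), locus_id = "l1")
  expect_equal(an$end, 9)
})

test_that("filter_sites removes indel/missing columns and is idempotent", {
  clean <- rand_aln(5, 40, seed = 1)
  f1 <- filter_sites(clean)
  expect_equal(f1$L_total, 40)

  seqs <- replicate(4, paste(sample(c("A", "C", "G", "T"), 100,
                                    replace = TRUE), collapse = ""))
  seqs[2] <- paste0(substr(seqs[2], 1, 50), "---", substr(seqs[2], 54, 100))
  aln <- make_aln(seqs)
  filt <- filter_sites(aln)
  expect_equal(filt$L_total, 97)
  expect_equal(filt$n, 4)
  # idempotent
  expect_identical(filter_sites(filt)$matrix, filt$matrix)

  # a sample with >20% N is dropped; its private N columns survive
  seqs2 <- replicate(5, paste(rep("A", 20), collapse = ""))
  seqs2[1] <- paste(c(rep("N", 6), rep("A", 14)), collapse = "")
  filt2 <- filter_sites(make_aln(seqs2))
  expect_equal(filt2$n, 4)
  expect_equal(filt2$L_total, 20)

  all_gap <- make_aln(c("----", "----"))
  expect_error(filter_sites(all_gap), "no analyzable sites")
})

test_that("silent-site counts follow equal-weight synonymous accounting", {
  # all-noncoding locus: silent length equals total length
  aln <- rand_aln(6, 716, seed = 2)
  expect_equal(count_silent_sites(aln), 716)

  # ATG (Met): no synonymous change at any position
  atg <- make_aln(c("ATG", "ATG", "ATG"),
                  coding = data.frame(start = 0, end = 3, frame = 0))
  expect_equal(count_silent_sites(atg), 0)

  # 30 fourfold-degenerate codons (GCx, alanine): one silent site each
  ala <- make_aln(rep(paste(rep("GCT", 30), collapse = ""), 4),
                  coding = data.frame(start = 0, end = 90, frame = 0))
  expect_equal(count_silent_sites(ala), 30)

  # frame error carries the locus id
  bad <- make_aln(c("ACGTA", "ACGTA"),
                  coding = data.frame(start = 0, end = 5, frame = 0),
                  locus_id = "myloc")
  expect_error(count_silent_sites(bad), "myloc")
})

test_that("silent length is invariant to sample order and bounded", {
  for (s in 1:5) {
    aln <- rand_aln(8, 60, seed = s)
    aln$matrix[1, 10:12] <- c("G", "C", "T")
    co <- data.frame(start = 6, end = 30, frame = 0)
    aln2 <- locus_alignment(aln$matrix, aln$population, coding = co)
    ls1 <- count_silent_sites(aln2)
    perm <- sample(nrow(aln2$matrix))
    aln3 <- locus_alignment(aln2$matrix[perm, ], aln2$population,
                            coding = co)
    expect_equal(count_silent_sites(aln3), ls1)
    expect_gte(ls1, 0)
    expect_lte(ls1, filter_sites(aln2)$L_total)
  }
})

test_that("a written synthetic bundle round-trips through the readers", {
  panel <- locus_panel()[1:2, ]
  panel$n_wild <- c(6L, 5L); panel$n_cult <- c(7L, 6L)
  bundle <- generate_panel(panel, demographic_model(), seed = 11)
  dir <- withr::local_tempdir()
  write_panel(bundle, dir)
  for (al in bundle$loci) {
    back <- read_alignment(
      file.path(dir, "loci", paste0(al$locus_id, ".fasta")),
      annotation_path = file.path(dir, "annotation.tsv"),
      popmap_path = file.path(dir, "popmap.tsv"),
      locus_id = al$locus_id)
    expect_identical(back$matrix, al$matrix)
    expect_identical(unname(back$outgroup), unname(al$outgroup))
    expect_identical(back$column_class, al$column_class)
  }
})
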