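## contig: up [0,6) = ATGGCA, intron, alt [10,13) = GTT, intron,
## down [17,26) = TAATTTAAA
toy_contig <- "ATGGCAGGGGGTTCCCCTAATTTAAA"

test_that("slices are block concatenations on the plus strand", {
  g <- load_genome(write_toy_genome(c(chrT = toy_contig)))
  sl <- build_slices(toy_event(), g)
  expect_equal(sl$included$sequence, "ATGGCAGTTTAATTTAAA")
  expect_equal(sl$excluded$sequence, "ATGGCATAATTTAAA")
  ## length exactness against the block structure
  for (s in sl) {
    expect_equal(nchar(s$sequence),
                 sum(vapply(s$block_structure, diff, numeric(1L))))
  }
})

test_that("a mirrored minus-strand locus yields the same transcript
           sequences", {
  L <- nchar(toy_contig)
  g <- load_genome(write_toy_genome(
    c(chrT = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(toy_contig))))))
  flip <- function(iv) c(L - iv[2L], L - iv[1L])
  ev <- toy_event(strand = "-", a1 = flip(c(17L, 26L)), a2 = flip(c(0L, 6L)),
                  alt1 = flip(c(10L, 13L)))
  sl <- build_slices(ev, g)
  expect_equal(sl$included$sequence, "ATGGCAGTTTAATTTAAA")
  expect_equal(sl$excluded$sequence, "ATGGCATAATTTAAA")
})

test_that("an RI included slice is one contiguous block spanning the
           intron", {
  g <- load_genome(write_toy_genome(c(chrT = toy_contig)))
  ev <- toy_event(type = "RI", alt1 = c(6L, 17L))
  sl <- build_slices(ev, g)
  expect_equal(length(sl$included$block_structure), 1L)
  expect_equal(nchar(sl$included$sequence),
               nchar(sl$excluded$sequence) + 11L)
})

test_that("out-of-range intervals and unknown contigs are errors", {
  g <- load_genome(write_toy_genome(c(chrT = toy_contig)))
  expect_error(build_slices(toy_event(a2 = c(17L, 999L)), g), "beyond contig")
  expect_error(build_slices(toy_event(chrom = "chrZ"), g), "absent")
})

test_that("frame annotation echoes the covering CDS and trims coding
           bounds on fixture loci", {
  b <- shared_fixture()
  r <- shared_resources()
  ev <- read_rmats_dir(b$dir)
  ## GENEA: first exon is the upstream anchor; CDS starts after the 12-nt
  ## 5' UTR, phase 0
  e <- ev[ev$gene_symbol == "GENEA"][1L]
  fr <- annotate_frame(e, r$annot)
  expect_true(fr$annotated)
  expect_equal(fr$phase_at_upstream_exon, 0L)
  sl <- build_slices(e, r$genome, fr)
  ## trimming: anchor exon loses exactly the UTR, so the included slice is
  ## 12 nt shorter than the untrimmed block sum
  sl_untrimmed <- build_slices(e, r$genome)
  expect_equal(nchar(sl_untrimmed$included$sequence) -
                 nchar(sl$included$sequence), 12L)
  ## GENEF carries no CDS records: annotation is absent, not an error
  ef <- ev[ev$gene_symbol == "GENEF"]
  expect_false(annotate_frame(ef, r$annot)$annotated)
  ## unknown gene is a lookup error
  eu <- data.table::copy(e)[, `:=`(gene_id = "NOPE", gene_symbol = "NOPE")]
  expect_error(annotate_frame(eu, r$annot),
               class = "junctiondb_lookup_error")
})

test_that("ambiguous transcripts resolve canonical-tag first, then longest
           CDS", {
  gtf <- tempfile(fileext = ".gtf")
  att <- function(tx, extra = "") {
    sprintf('gene_id "G9"; transcript_id "%s"; gene_name "GENE9";%s',
            tx, extra)
  }
  writeLines(c(
    sprintf("chrT\ttoy\tgene\t1\t200\t.\t+\t.\t%s", 'gene_id "G9"; gene_name "GENE9";'),
    sprintf("chrT\ttoy\ttranscript\t1\t200\t.\t+\t.\t%s", att("t1")),
    sprintf("chrT\ttoy\tCDS\t1\t30\t.\t+\t0\t%s", att("t1")),
    sprintf("chrT\ttoy\ttranscript\t1\t200\t.\t+\t.\t%s", att("t2")),
    sprintf("chrT\ttoy\tCDS\t2\t30\t.\t+\t2\t%s", att("t2")),
    sprintf("chrT\ttoy\tCDS\t40\t90\t.\t+\t0\t%s", att("t2"))), gtf)
  annot <- load_annotation(gtf)
  ev <- toy_event(a1 = c(0L, 30L), a2 = c(120L, 150L), alt1 = c(60L, 90L),
                  gene_id = "G9", gene_symbol = "GENE9")
  ## t2 has the longer total CDS; its record starts 1 base into the anchor
  ## with phase 2, so 2 bases remain to skip at the trimmed slice start
  fr <- annotate_frame(ev, annot)
  expect_equal(fr$transcript_id, "t2")
  expect_equal(fr$phase_at_upstream_exon, 2L)
  ## tagging t1 canonical overrides the length preference
  lines <- readLines(gtf)
  lines[2L] <- sub('transcript_id "t1";',
                   'transcript_id "t1"; tag "Ensembl_canonical";', lines[2L])
  writeLines(lines, gtf)
  fr2 <- annotate_frame(ev, load_annotation(gtf))
  expect_equal(fr2$transcript_id, "t1")
  expect_equal(fr2$phase_at_upstream_exon, 0L)
})

test_that("an anchor entirely in the 5' UTR yields annotated = FALSE", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrT\ttoy\tgene\t1\t400\t.\t+\t.\tgene_id \"G9\"; gene_name \"GENE9\";",
    paste0("chrT\ttoy\tCDS\t200\t300\t.\t+\t0\tgene_id \"G9\"; ",
           "transcript_id \"t1\"; gene_name \"GENE9\";")), gtf)
  ev <- toy_event(a1 = c(0L, 50L), a2 = c(320L, 380L), alt1 = c(60L, 90L),
                  gene_id = "G9", gene_symbol = "GENE9")
  expect_false(annotate_frame(ev, load_annotation(gtf))$annotated)
})
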