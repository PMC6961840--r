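test_that("regeneration with the same seed is byte-identical", {
  d1 <- file.path(tempdir(), "fx-det-1")
  d2 <- file.path(tempdir(), "fx-det-2")
  generate_fixture(d1, n_loci = 5L, seed = 11L)
  generate_fixture(d2, n_loci = 5L, seed = 11L)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## a different seed changes content
  d3 <- file.path(tempdir(), "fx-det-3")
  generate_fixture(d3, n_loci = 5L, seed = 12L)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("canonical proteome equals the spliced-CDS translation of the
           annotated genome (independent oracle)", {
  b <- shared_fixture()
  genome <- Biostrings::readDNAStringSet(b$files[["genome"]])
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- as.data.frame(rtracklayer::readGFF(b$files[["gtf"]]))
  cds <- gff[gff$type == "CDS", ]
  checked <- 0L
  for (tx in unique(cds$transcript_id)) {
    rows <- cds[cds$transcript_id == tx, ]
    rows <- rows[order(rows$start), ]
    chrom <- as.character(rows$seqid[1L])
    spliced <- Biostrings::DNAString(paste(vapply(seq_len(nrow(rows)),
      function(i) as.character(Biostrings::subseq(genome[[chrom]],
                                                  rows$start[i],
                                                  rows$end[i])),
      character(1L)), collapse = ""))
    if (rows$strand[1L] == "-")
      spliced <- Biostrings::reverseComplement(spliced)
    aa <- as.character(Biostrings::translate(spliced,
                                             no.init.codon = TRUE))
    expect_equal(aa, unname(b$proteins[[as.character(rows$gene_name[1L])]]),
                 label = tx)
    checked <- checked + 1L
  }
  expect_equal(checked, 7L)  # all loci except the CDS-free tier-3 gene
})

test_that("the default bundle covers the stated design space", {
  b <- shared_fixture()
  m <- b$manifest
  expect_setequal(unique(m$event_type), AS_TYPES)
  expect_setequal(unique(m$expected_tier[!is.na(m$expected_tier)]), 1:4)
  expect_setequal(unique(m$strand), c("+", "-"))
  expect_true(any(m$expected_verdict == "low_count"))
  expect_true(any(m$expected_verdict == "inconsistent"))
  expect_true(any(m$included_product == "ORPHAN" |
                    m$excluded_product == "ORPHAN"))
  expect_true(any(m$included_product == "CANONICAL"))
  ## the duplicate pair: two distinct events expecting one shared isoform
  dup <- m$excluded_product[duplicated(m$excluded_product) &
                              !m$excluded_product %in%
                                c("CANONICAL", "ORPHAN", "FILTERED")]
  expect_equal(length(dup), 1L)
  ## events beyond the core designs alternate expression classes
  big <- generate_fixture(file.path(tempdir(), "fx-big"), n_loci = 10L,
                          seed = 3L)
  expect_equal(nrow(big$manifest), nrow(m) + 2L)
})

test_that("impossible configurations fail loudly", {
  d <- file.path(tempdir(), "fx-bad")
  expect_error(generate_fixture(d, config = list(lambda_low = 60,
                                                 lambda_high = 1)),
               "impossible count model")
  expect_error(generate_fixture(d, config = list(nonsense = 1)),
               "unknown fixture config")
  expect_error(generate_fixture(d, config = list(intron_len = 10L)),
               "impossible layout")
  expect_error(generate_fixture(d, n_loci = 0L))
})

test_that("the worked-example locus embeds the published fragments at
           their stated offsets", {
  wd <- file.path(tempdir(), "fx-mybpc3")
  wx <- mybpc3_worked_example(wd, seed = 77L)
  p <- wx$canonical
  expect_equal(nchar(p), 1274L)
  expect_equal(substr(p, 273L, 274L), "RT")
  expect_equal(substr(p, 275L, 284L), "SLAGGGRRIS")
  expect_equal(substr(p, 285L, 300L), "DSHEDTGILDFSSLLK")
  expect_equal(wx$expected_isoform,
               paste0(substr(p, 1L, 274L), substring(p, 285L)))
  expect_equal(nrow(wx$manifest), 1L)
  expect_equal(wx$manifest$expected_verdict, "kept")
  ## deterministic regeneration
  wx2 <- mybpc3_worked_example(file.path(tempdir(), "fx-mybpc3b"),
                               seed = 77L)
  expect_identical(wx2$canonical, wx$canonical)
})
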