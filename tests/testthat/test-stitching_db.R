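test_that("stitching replaces the canonical segment between matched
           overhang words (string-surgery oracle)", {
  canonical <- withr::with_seed(5L, paste(
    sample(strsplit("ACDEFGHIKLNPQRSTVY", "")[[1L]], 60L, replace = TRUE),
    collapse = ""))
  ## slice = canonical[6..35] with three residues substituted strictly
  ## between the two overhang words
  slice <- substr(canonical, 6L, 35L)
  mid <- strsplit(slice, "")[[1L]]
  mid[12:14] <- c("W", "W", "W")  # W never occurs in the filler alphabet
  slice <- paste(mid, collapse = "")
  res <- stitch(slice, canonical, overhang = 10L)
  expect_false(res$orphan)
  oracle <- paste0(substr(canonical, 1L, 16L), "WWW",
                   substring(canonical, 20L))
  expect_equal(res$aa_sequence, oracle)
  expect_equal(nchar(res$aa_sequence), nchar(canonical))
  expect_false(res$is_canonical_duplicate)
  expect_equal(res$slice_region, c(5L, 35L))
  ## reconstruction invariant: canonical region swaps back exactly
  rebuilt <- paste0(substr(res$aa_sequence, 1L, res$slice_region[1L]),
                    substr(canonical, res$canonical_region[1L] + 1L,
                           res$canonical_region[2L]),
                    substring(res$aa_sequence, res$slice_region[2L] + 1L))
  expect_equal(rebuilt, canonical)

  ## identity stitch flags a canonical duplicate
  res2 <- stitch(substr(canonical, 6L, 25L), canonical)
  expect_true(res2$is_canonical_duplicate)
  expect_equal(res2$aa_sequence, canonical)

  ## orphan verdicts
  expect_equal(stitch(paste0(strrep("W", 10L), substring(slice, 11L)),
                      canonical)$reason, "n_overhang_unmatched")
  expect_equal(stitch(paste0(substr(slice, 1L, 10L), strrep("W", 10L)),
                      canonical)$reason, "c_overhang_unmatched")
  expect_equal(stitch("SHORT", canonical)$reason, "too_short")
})

test_that("UniProt-style and plain headers parse; gene symbol comes from
           GN=", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P12345|TEST_HUMAN Test protein OS=Homo sapiens GN=TESTG PE=1 SV=2",
    "MKTAYIAKQR", ">plainname", "MQQQR"), fa)
  cp <- read_canonical_fasta(fa)
  expect_equal(cp$accession, c("P12345", "plainname"))
  expect_equal(cp$gene_symbol, c("TESTG", "plainname"))
  expect_equal(cp$aa_sequence[1L], "MKTAYIAKQR")
})

test_that("deduplication merges identical sequences and flags canonical
           twins", {
  canon <- data.table::data.table(accession = "P1", gene_symbol = "G1",
                                  aa_sequence = "MAAAKKKPPP", header = "h")
  mk <- function(seq, id, tier = 1L) data.table::data.table(
    aa_sequence = seq, gene_symbol = "G1", canonical_accession = "P1",
    event_id = id, which = "excluded", event_type = "SE", tier = tier,
    slice_start = 0L, slice_end = 5L, genomic_tag = "chr1:0-10:+")
  entries <- rbind(mk("MAAAKKK", "SE_1"), mk("MAAAKKK", "SE_2", tier = 3L),
                   mk("MAAAKKKPPP", "SE_3"))
  out <- deduplicate(entries, canon)
  expect_equal(nrow(out), 2L)
  merged <- out[out$aa_sequence == "MAAAKKK"]
  expect_equal(merged$event_id, "SE_1;SE_2")
  expect_equal(merged$tier, 1L)  # best tier wins
  expect_true(out$is_canonical_duplicate[out$aa_sequence == "MAAAKKKPPP"])
})

test_that("the written FASTA round-trips headers and the decoy is a
           length-preserving reversal involution", {
  run <- shared_run()
  expect_gt(run$n_entries, 0L)
  db <- parse_database(run$paths[["target"]])
  expect_equal(nrow(db), run$n_entries)
  expect_setequal(db$aa_sequence, run$entries$aa_sequence)
  expect_true(all(db$event_type %in% AS_TYPES))
  expect_true(all(db$tier %in% 1:4 | is.na(db$tier)))
  ## canonical duplicates are labelled canonical (tier field NA on parse)
  expect_equal(sum(is.na(db$tier)), run$n_canonical_duplicates)
  ## 60-column wrapping
  lines <- readLines(run$paths[["target"]])
  expect_lte(max(nchar(lines[!startsWith(lines, ">")])), 60L)

  dec <- parse_database(run$paths[["decoy"]])
  expect_equal(nrow(dec), nrow(db))
  expect_true(all(dec$decoy))
  rev_str <- function(s) vapply(strsplit(s, ""), function(x)
    paste(rev(x), collapse = ""), character(1L))
  expect_equal(rev_str(dec$aa_sequence), db$aa_sequence)
  expect_equal(nchar(dec$aa_sequence), nchar(db$aa_sequence))
  ## decoy headers carry the DECOY_ prefix on disk
  dlines <- readLines(run$paths[["decoy"]])
  expect_true(all(startsWith(dlines[startsWith(dlines, ">")], ">DECOY_")))
  ## no emitted sequence contains a stop or non-residue symbol
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", db$aa_sequence)))
})

test_that("an empty entry collection writes a valid empty FASTA with a
           warning", {
  entries <- shared_run()$entries[0L]
  out <- tempfile(fileext = ".fasta")
  expect_warning(paths <- write_database(entries, out,
                                         include_decoys = TRUE),
                 "empty")
  expect_true(file.exists(paths[["target"]]))
  expect_equal(length(Biostrings::readAAStringSet(paths[["target"]])), 0L)
  expect_true(file.exists(paths[["decoy"]]))
})
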