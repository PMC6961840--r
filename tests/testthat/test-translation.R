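test_that("single-frame translation follows the standard code with phase
           skip and stop handling", {
  t1 <- translate_in_frame("ATGGCAAAA", 0L)
  expect_equal(t1$aa_sequence, "MAK")
  expect_false(t1$ptc_found)
  t2 <- translate_in_frame("ATGTAAGCA", 0L)
  expect_equal(t2$aa_sequence, "M")
  expect_true(t2$ptc_found)
  ## phase skip: leading base ignored, then ATG GCA
  t3 <- translate_in_frame("CATGGCA", 1L)
  expect_equal(t3$aa_sequence, "MA")
  ## a stop in the final complete codon is a natural terminus, not a PTC
  t4 <- translate_in_frame("ATGGCATAA", 0L)
  expect_equal(t4$aa_sequence, "MA")
  expect_false(t4$ptc_found)
  ## ambiguous codons become X and never force a stop
  expect_equal(translate_in_frame("ATGNNATAA", 0L)$aa_sequence, "MX")
  expect_error(translate_in_frame("AT", 0L), "degenerate")
  expect_error(translate_in_frame("ATGG", 2L), "degenerate")
})

test_that("translation agrees with an independent codon-table oracle on
           random sequences", {
  ## independent oracle: direct lookup in the Biostrings codon table
  bio_translate <- function(nt, phase) {
    s <- substring(nt, phase + 1L)
    n <- nchar(s) %/% 3L
    starts <- seq.int(1L, by = 3L, length.out = n)
    paste(unname(Biostrings::GENETIC_CODE[substring(s, starts,
                                                    starts + 2L)]),
          collapse = "")
  }
  withr::with_seed(99L, {
    for (i in seq_len(1000L)) {
      n <- sample(6:90, 1L)
      nt <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
      ph <- sample(0:2, 1L)
      if (n < ph + 3L) next
      mine <- translate_in_frame(nt, ph)
      bio <- bio_translate(nt, ph)
      expect_identical(mine$aa_sequence, sub("\\*.*$", "", bio))
      first_star <- regexpr("*", bio, fixed = TRUE)
      expect_identical(mine$ptc_found,
                       first_star > 0L && first_star < nchar(bio))
    }
  })
})

ann_frame <- function(phase = 0L) {
  structure(list(transcript_id = "t1", phase_at_upstream_exon = phase,
                 coding_start = 0L, coding_end = 0L, annotated = TRUE),
            class = "frame_annotation")
}

## brute-force oracle: one common frame for both slices, both PTC-free,
## maximum total translated length, lower frame on ties
brute_force_frame <- function(inc, exc) {
  best <- NULL
  for (ph in 0:2) {
    if (nchar(inc) < ph + 3L || nchar(exc) < ph + 3L) next
    ti <- translate_in_frame(inc, ph)
    te <- translate_in_frame(exc, ph)
    if (ti$ptc_found || te$ptc_found) next
    len <- nchar(ti$aa_sequence) + nchar(te$aa_sequence)
    if (is.null(best) || len > best$len) best <- list(ph = ph, len = len)
  }
  best$ph
}

test_that("tier clauses classify hand-built pairs in order 1 through 4", {
  up <- "ATGGCAACC"; down <- "AAAGAAACC"
  ## tier 1: alt length 0 mod 3, annotated frame clean in both slices
  p1 <- resolve_pair(paste0(up, "CCCGGG", down), paste0(up, down),
                     ann_frame(0L))
  expect_equal(p1$tier, 1L)
  expect_true(p1$eligible)
  expect_true(p1$included$used_annotated_frame)
  ## the skipped form is a contiguous deletion of the included translation
  expect_equal(p1$excluded$aa_sequence,
               paste0(substr(p1$included$aa_sequence, 1L, 3L),
                      substring(p1$included$aa_sequence, 6L)))
  ## tier 2: alt length 4 shifts the frame downstream but stays stop-free
  p2 <- resolve_pair(paste0(up, "CCCG", down), paste0(up, down),
                     ann_frame(0L))
  expect_equal(p2$tier, 2L)
  expect_true(p2$frameshift)
  ## tier 3: annotated frame stops immediately, frame 2 is clean for both
  inc3 <- paste0("TA", "ATGACTAAGGCAAAAGCC")
  exc3 <- paste0("TA", "ATGACTAAGGCAAAA")
  p3 <- resolve_pair(inc3, exc3, ann_frame(0L))
  expect_equal(p3$tier, 3L)
  expect_equal(p3$frame_used, 2L)
  expect_equal(p3$frame_used, brute_force_frame(inc3, exc3))
  expect_false(p3$included$used_annotated_frame)
  ## tier 4: the included slice stops in every frame, the excluded is
  ## clean in the annotated frame; the PTC side is truncated at the stop
  inc4 <- "ATGTAAATAAGTAGGTTCC"
  exc4 <- "ATGGCAGCAGCAGCAGGT"
  p4 <- resolve_pair(inc4, exc4, ann_frame(0L))
  expect_equal(p4$tier, 4L)
  expect_true(p4$included$ptc_found)
  expect_equal(p4$included$aa_sequence, "M")
  expect_false(p4$excluded$ptc_found)
  ## ineligible: both slices stop in every frame
  p5 <- resolve_pair(inc4, inc4, ann_frame(0L))
  expect_false(p5$eligible)
  expect_equal(p5$reason, "ptc_both_frames")
  expect_true(is.na(p5$tier))
})

test_that("annotation-free pairs pick the brute-force maximum-length
           frame", {
  withr::with_seed(17L, {
    checked <- 0L
    for (i in seq_len(400L)) {
      if (checked >= 25L) break
      inc <- paste(sample(c("A", "C", "G", "T"), 45L, replace = TRUE),
                   collapse = "")
      exc <- paste0(substr(inc, 1L, 15L), substring(inc, 25L))
      oracle <- brute_force_frame(inc, exc)
      pair <- resolve_pair(inc, exc, frame = NULL)
      if (is.null(oracle)) {
        expect_true(!isTRUE(pair$eligible) || pair$tier == 4L)
      } else {
        expect_equal(pair$tier, 3L)
        expect_equal(pair$frame_used, oracle)
        checked <- checked + 1L
      }
    }
  })
})

test_that("fixture pairs land on their planted tiers", {
  b <- shared_fixture()
  r <- shared_resources()
  ev <- read_rmats_dir(b$dir)
  m <- b$manifest[b$manifest$expected_verdict == "kept"]
  for (k in seq_len(nrow(m))) {
    e <- ev[ev$event_id == m$event_id[k]]
    fr <- tryCatch(annotate_frame(e, r$annot),
                   junctiondb_lookup_error = function(cnd) NULL)
    sl <- build_slices(e, r$genome, fr)
    pair <- resolve_pair(sl$included, sl$excluded, fr)
    expect_equal(pair$tier, m$expected_tier[k],
                 label = paste("tier of", m$event_id[k]))
  }
})
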