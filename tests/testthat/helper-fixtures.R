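## shared fixture bundle, loaded resources, and pipeline run --------------
## built once per test session and reused across test files

.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "jdb-fixture")
    .fixture_cache$bundle <- generate_fixture(dir, n_loci = 8L, seed = 7L)
  }
  .fixture_cache$bundle
}

shared_resources <- function() {
  if (is.null(.fixture_cache$res)) {
    b <- shared_fixture()
    .fixture_cache$res <- list(
      genome = load_genome(b$files[["genome"]]),
      annot = load_annotation(b$files[["gtf"]]),
      canonical = read_canonical_fasta(b$files[["canonical"]]))
  }
  .fixture_cache$res
}

## pipeline run at the reference manual threshold (4 reads, p <= 0.01)
shared_run <- function() {
  if (is.null(.fixture_cache$run)) {
    b <- shared_fixture()
    r <- shared_resources()
    .fixture_cache$run <- run_pipeline(run_config(
      rmats_dir = b$dir, genome = r$genome, gtf = r$annot,
      canonical = r$canonical,
      out_dir = file.path(tempdir(), "jdb-fixture-out"),
      manual_theta = 4L, include_decoys = TRUE))
  }
  .fixture_cache$run
}

## manifest ground truth: the distinct noncanonical sequences expected
expected_noncanonical <- function(manifest) {
  s <- c(manifest$included_product, manifest$excluded_product)
  sort(unique(s[!s %in% c("CANONICAL", "ORPHAN", "FILTERED")]))
}

## minimal rMATS SE row with overridable fields
se_row <- function(...) {
  row <- list(ID = 1L, GeneID = "G1", geneSymbol = "GENE1", chr = "chr1",
              strand = "+", exonStart_0base = 100L, exonEnd = 200L,
              upstreamES = 0L, upstreamEE = 50L, downstreamES = 300L,
              downstreamEE = 360L, IJC_SAMPLE_1 = "10,12",
              SJC_SAMPLE_1 = "4,7", IJC_SAMPLE_2 = "9,11",
              SJC_SAMPLE_2 = "5,6", IncFormLen = 198L, SkipFormLen = 99L,
              PValue = "0.5", FDR = "0.6", IncLevel1 = "0.7,0.7",
              IncLevel2 = "0.7,0.7", IncLevelDifference = 0)
  utils::modifyList(row, list(...))
}

write_rmats_rows <- function(rows, path) {
  tab <- data.table::rbindlist(rows)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

## one-row internal event table for slice-level unit tests
toy_event <- function(type = "SE", chrom = "chrT", strand = "+",
                      a1 = c(0L, 6L), a2 = c(17L, 26L),
                      alt1 = c(10L, 13L), alt2 = c(NA_integer_, NA_integer_),
                      gene_id = "G1", gene_symbol = "GENE1") {
  dt <- data.table::data.table(
    event_id = paste0(type, "_t1"), event_type = type,
    gene_id = gene_id, gene_symbol = gene_symbol,
    chrom = chrom, strand = strand,
    anchor1_start = a1[1L], anchor1_end = a1[2L],
    anchor2_start = a2[1L], anchor2_end = a2[2L],
    alt1_start = alt1[1L], alt1_end = alt1[2L],
    alt2_start = alt2[1L], alt2_end = alt2[2L],
    ijc = list(c(5L, 5L)), sjc = list(c(5L, 5L)),
    inc_levels = list(numeric()), p_value = 0.5, fdr = 0.5)
  data.table::setattr(dt, "class", c("splice_event_table", class(dt)))
  dt
}

write_toy_genome <- function(seqs, path = tempfile(fileext = ".fa")) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  path
}
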