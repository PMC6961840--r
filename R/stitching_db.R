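## Overhang stitching onto canonical proteins and FASTA output --------------
##
## A translated junction slice becomes a full-length database entry by
## locating its N-terminal and C-terminal 10-residue words as exact
## substrings of the gene's canonical protein (N match strictly before C
## match) and splicing the slice between the canonical prefix and suffix.
## Requiring both termini to match guarantees the reconstruction invariant
## (replacing the slice region with the corresponding canonical residues
## regenerates the canonical sequence) and excludes chimeric placements.
## Slices that cannot be stitched are orphans and are discarded from the
## database (but logged). Identical sequences are merged and entries equal
## to a canonical protein are flagged as canonical duplicates.

#' Read a canonical proteome FASTA
#'
#' Accepts UniProt-style headers (`>sp|ACCESSION|NAME ... GN=SYMBOL ...`)
#' and plain `>name` headers. The gene symbol is taken from the `GN=` token
#' when present, otherwise from the record name.
#'
#' @param path proteome FASTA path.
#' @return `data.table` of class `"canonical_proteome"` with columns
#'   `accession`, `gene_symbol`, `aa_sequence`, `header`.
#' @export
read_canonical_fasta <- function(path) {
  if (!file.exists(path)) stop("canonical proteome FASTA not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  first_word <- sub("\\s.*$", "", headers)
  accession <- ifelse(grepl("^..\\|", first_word),
                      sub("^..\\|([^|]+)\\|.*$", "\\1", first_word),
                      first_word)
  gn <- ifelse(grepl("GN=", headers),
               sub("^.*GN=([^ ]+).*$", "\\1", headers),
               accession)
  out <- data.table::data.table(accession = accession, gene_symbol = gn,
                                aa_sequence = as.character(aa),
                                header = headers)
  if (any(!nzchar(out$aa_sequence)))
    stop("canonical proteome contains empty sequences")
  data.table::setattr(out, "class",
                      c("canonical_proteome", class(out)))
  out[]
}

#' Stitch a translated slice onto a canonical protein
#'
#' @param slice_aa amino-acid string of the translated slice.
#' @param canonical_aa canonical protein string.
#' @param overhang terminal word length that must match exactly on both
#'   ends (default 10 residues).
#' @return on success, a list with `aa_sequence`, `slice_region` (0-based
#'   half-open residue interval occupied by the slice),
#'   `canonical_region` (canonical residues the slice replaces),
#'   `is_canonical_duplicate`; on failure a list with `orphan = TRUE` and
#'   a `reason` code (`too_short`, `n_overhang_unmatched`,
#'   `c_overhang_unmatched`).
#' @export
stitch <- function(slice_aa, canonical_aa, overhang = 10L) {
  stopifnot(overhang >= 1L)
  orphan <- function(reason) list(orphan = TRUE, reason = reason)
  L <- nchar(slice_aa)
  if (L < 2L * overhang) return(orphan("too_short"))
  nmer <- substr(slice_aa, 1L, overhang)
  cmer <- substr(slice_aa, L - overhang + 1L, L)
  ## first occurrence of the N-word; first occurrence of the C-word
  ## strictly after it (deterministic placement)
  n_start <- as.integer(regexpr(nmer, canonical_aa, fixed = TRUE))
  if (n_start < 0L) return(orphan("n_overhang_unmatched"))
  c_hits <- gregexpr(cmer, canonical_aa, fixed = TRUE)[[1L]]
  c_hits <- c_hits[c_hits > n_start]
  if (length(c_hits) == 0L || c_hits[1L] < 0L)
    return(orphan("c_overhang_unmatched"))
  c_start <- c_hits[1L]
  out <- paste0(substr(canonical_aa, 1L, n_start - 1L), slice_aa,
                substring(canonical_aa, c_start + overhang))
  list(orphan = FALSE,
       aa_sequence = out,
       slice_region = c(n_start - 1L, n_start - 1L + L),
       canonical_region = c(n_start - 1L, c_start + overhang - 1L),
       is_canonical_duplicate = identical(out, canonical_aa))
}

## stitch one slice against all canonical records of a gene symbol;
## longest canonical tried first, first success wins
stitch_to_gene <- function(slice_aa, symbol, canonicals,
                           overhang = 10L) {
  cand <- canonicals[canonicals[["gene_symbol"]] == symbol]
  if (nrow(cand) == 0L) return(list(orphan = TRUE, reason = "no_canonical"))
  cand <- cand[order(-nchar(cand$aa_sequence), cand$accession)]
  last <- NULL
  for (i in seq_len(nrow(cand))) {
    res <- stitch(slice_aa, cand$aa_sequence[i], overhang)
    if (!isTRUE(res$orphan)) {
      res$canonical_accession <- cand$accession[i]
      return(res)
    }
    last <- res
  }
  last
}

#' Merge redundant database entries
#'
#' Entries with identical amino-acid sequence are merged into one record
#' whose provenance (`event_id`, `which` slice) lists are concatenated;
#' the best (lowest) tier among the merged entries is retained. Entries
#' identical to a canonical protein are flagged `is_canonical_duplicate`
#' and kept once, to be labelled canonical on output.
#'
#' @param entries `data.table` of isoform entries (one row per stitched
#'   slice) as produced by the pipeline.
#' @param canonicals `"canonical_proteome"` table.
#' @return deduplicated `data.table`; `event_id` and `which` become
#'   semicolon-separated provenance lists.
#' @export
deduplicate <- function(entries, canonicals) {
  if (nrow(entries) == 0L) return(entries)
  canon_seqs <- canonicals$aa_sequence
  merged <- entries[, list(
    gene_symbol = gene_symbol[1L],
    canonical_accession = canonical_accession[1L],
    event_id = paste(unique(event_id), collapse = ";"),
    which = paste(which, collapse = ";"),
    event_type = event_type[1L],
    tier = min(tier),
    slice_start = slice_start[1L], slice_end = slice_end[1L],
    genomic_tag = genomic_tag[1L],
    n_merged = .N), by = "aa_sequence"]
  merged[, is_canonical_duplicate := aa_sequence %in% canon_seqs]
  merged[]
}

## header grammar: ">sp|{accession}-{event_type}{n}|{gene}_{tier} {tag}";
## canonical duplicates carry the literal label "canonical" as tier
entry_headers <- function(entries) {
  key <- paste(entries$canonical_accession, entries$event_type, sep = "-")
  idx <- stats::ave(seq_along(key), key, FUN = seq_along)
  tier_lab <- ifelse(entries$is_canonical_duplicate, "canonical",
                     as.character(entries$tier))
  sprintf("sp|%s-%s%d|%s_%s %s", entries$canonical_accession,
          entries$event_type, idx, entries$gene_symbol, tier_lab,
          entries$genomic_tag)
}

#' Write the target database (and optional reversed decoys)
#'
#' Writes 60-column wrapped FASTA with headers
#' `>sp|{accession}-{event_type}{n}|{gene}_{tier} {chrom}:{start}-{end}:{strand}`
#' (canonical duplicates labelled `_canonical`). With `include_decoys`, a
#' companion `<out>.decoy.fasta` is written in which every sequence is
#' reversed and the accession prefixed `DECOY_`.
#'
#' @param entries deduplicated entry table from [deduplicate()].
#' @param out_path target FASTA path.
#' @param include_decoys also write the reversed-decoy companion?
#' @return named character vector of written paths, invisibly.
#' @export
write_database <- function(entries, out_path, include_decoys = FALSE) {
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  paths <- c(target = out_path)
  if (nrow(entries) == 0L) {
    warning("no database entries to write; emitting empty FASTA")
    writeLines(character(), out_path)
    if (include_decoys) {
      dec <- decoy_path(out_path)
      writeLines(character(), dec)
      paths <- c(paths, decoy = dec)
    }
    return(invisible(paths))
  }
  ord <- order(entries$gene_symbol, entries$event_type,
               entries$genomic_tag, entries$tier)
  entries <- entries[ord]
  headers <- entry_headers(entries)
  seqs <- stats::setNames(entries$aa_sequence, headers)
  write_aa_fasta(seqs, out_path)
  if (include_decoys) {
    dec <- decoy_path(out_path)
    rev_seqs <- vapply(entries$aa_sequence, function(s)
      paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1L),
      USE.NAMES = FALSE)
    write_aa_fasta(stats::setNames(rev_seqs, paste0("DECOY_", headers)),
                   dec)
    paths <- c(paths, decoy = dec)
  }
  invisible(paths)
}

decoy_path <- function(out_path) {
  base <- if (tolower(tools::file_ext(out_path)) %in% c("fa", "fasta"))
    tools::file_path_sans_ext(out_path) else out_path
  paste0(base, ".decoy.fasta")
}

#' Parse a written database FASTA back into its header fields
#'
#' Round-trip check helper for the header grammar.
#'
#' @param path FASTA written by [write_database()].
#' @return `data.table` with `accession`, `event_type`, `index`,
#'   `gene_symbol`, `tier` (`NA` for canonical-duplicate labels),
#'   `genomic_tag`, `aa_sequence`, `decoy`.
#' @export
parse_database <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(data.table::data.table(
      accession = character(), event_type = character(),
      index = integer(), gene_symbol = character(), tier = integer(),
      genomic_tag = character(), aa_sequence = character(),
      decoy = logical()))
  }
  h <- names(aa)
  decoy <- grepl("^DECOY_", h)
  h2 <- sub("^DECOY_", "", h)
  m <- regmatches(h2, regexec(
    "^sp\\|([^|]+)-(SE|MXE|A3SS|A5SS|RI)(\\d+)\\|(\\S+)_(canonical|\\d+) (\\S+)$",
    h2))
  bad <- vapply(m, length, integer(1L)) != 7L
  if (any(bad)) stop("unparseable header(s): ",
                     paste(utils::head(h[bad], 3L), collapse = "; "))
  g <- function(i) vapply(m, `[`, character(1L), i)
  data.table::data.table(
    accession = g(2L), event_type = g(3L),
    index = as.integer(g(4L)), gene_symbol = g(5L),
    tier = suppressWarnings(as.integer(g(6L))),
    genomic_tag = g(7L), aa_sequence = as.character(aa), decoy = decoy)
}
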