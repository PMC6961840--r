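## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' Plain-character implementation used on slice sequences; IUPAC ambiguity
#' codes other than N are not expected in inputs and map to N.
#' @param x single nucleotide string (A/C/G/T/N, any case).
#' @return upper-case reverse complement.
#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

## longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1L]]
  bv <- strsplit(substr(b, 1L, n), "")[[1L]]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Count canonical residues absent from an isoform
#'
#' Anchors the isoform to the canonical sequence by longest common prefix
#' and suffix and counts the canonical residues in between that are not
#' covered by the isoform. For a pure deletion isoform this equals the
#' number of deleted residues; for a substitution it counts the replaced
#' canonical residues.
#'
#' @param canonical canonical amino-acid string.
#' @param isoform isoform amino-acid string.
#' @return integer count of canonical residues not present in the isoform.
#' @export
count_missing_residues <- function(canonical, isoform) {
  p <- lcp_len(canonical, isoform)
  rc <- paste(rev(strsplit(canonical, "")[[1L]]), collapse = "")
  ri <- paste(rev(strsplit(isoform, "")[[1L]]), collapse = "")
  s <- lcp_len(rc, ri)
  # prefix and suffix anchors must not overlap on either sequence
  s <- min(s, nchar(canonical) - p, nchar(isoform) - p)
  as.integer(nchar(canonical) - p - s)
}

#' Tryptic digest of a protein sequence
#'
#' Cleaves C-terminal to K or R, except before P, and enumerates peptides
#' with up to `missed` missed cleavages. Used to verify junction-spanning
#' peptides in the worked example and tests.
#'
#' @param aa amino-acid string.
#' @param missed maximum number of missed cleavages (default 2).
#' @param min_length shortest peptide reported (default 6).
#' @return character vector of peptides.
#' @export
tryptic_digest <- function(aa, missed = 2L, min_length = 6L) {
  res <- strsplit(aa, "")[[1L]]
  n <- length(res)
  if (n == 0L) return(character())
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- sort(unique(bounds))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  out <- character()
  for (i in seq_along(starts)) {
    for (m in 0:missed) {
      j <- i + m
      if (j > length(ends)) break
      out <- c(out, substr(aa, starts[i], ends[j]))
    }
  }
  unique(out[nchar(out) >= min_length])
}

## deterministic child seed derived from a user seed, kept below 2^31
child_seed <- function(seed, salt) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(salt) %% 1009L
}

## write a named character vector of AA sequences as 60-column FASTA
write_aa_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  x <- Biostrings::AAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}
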