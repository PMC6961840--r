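## Single-frame translation and tier classification -------------------------
##
## Each junction pair is translated under ONE reading frame applied to both
## slices and classified into four eligibility tiers:
##   tier 1 - both slices translate in the annotated frame with no
##            frameshift and no premature termination codon (PTC);
##   tier 2 - the alternative-segment length difference between the two
##            slices is not a multiple of three (one junction is shifted
##            relative to annotation downstream of the junction) but both
##            still translate PTC-free in the annotated frame;
##   tier 3 - a single frame different from the annotated one (or chosen
##            de novo when no annotation exists) translates both slices
##            PTC-free;
##   tier 4 - exactly one slice of the pair hits a PTC; that slice is
##            truncated at the stop and still emitted.
## Pairs whose slices contain a PTC in every frame are ineligible.

## standard genetic code, hard-coded; stops as "*"
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide slice in a given phase
#'
#' Skips `phase` leading bases, then translates complete codons with the
#' standard genetic code until the end of the sequence or the first stop
#' codon. A stop strictly before the final complete codon position flags a
#' premature termination codon; a stop in the final codon is a natural
#' terminus. Codons containing ambiguous bases translate to `X` (they never
#' force a stop). The trailing incomplete codon is ignored.
#'
#' @param nt nucleotide string (A/C/G/T/N).
#' @param phase bases to skip before the first complete codon (0, 1 or 2).
#' @return `"translated_slice"` list: `aa_sequence` (stop symbol not
#'   retained), `frame_used`, `ptc_found`, `stop_seen`, `n_codons`.
#' @export
translate_in_frame <- function(nt, phase) {
  stopifnot(length(phase) == 1L, phase %in% 0:2)
  nt <- toupper(nt)
  if (nchar(nt) < phase + 3L)
    stop("degenerate input: sequence shorter than phase + one codon")
  s <- substring(nt, phase + 1L)
  n_cod <- nchar(s) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_cod)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"  # ambiguous bases
  stops <- which(aa == "*")
  if (length(stops)) {
    first <- stops[1L]
    out <- paste(aa[seq_len(first - 1L)], collapse = "")
    ptc <- first < n_cod
    stop_seen <- TRUE
  } else {
    out <- paste(aa, collapse = "")
    ptc <- FALSE
    stop_seen <- FALSE
  }
  structure(list(aa_sequence = out, frame_used = as.integer(phase),
                 used_annotated_frame = NA, ptc_found = ptc,
                 stop_seen = stop_seen,
                 frameshift_vs_annotation = NA, n_codons = n_cod),
            class = "translated_slice")
}

## NULL-safe translation helper used by the tier logic
try_translate <- function(nt, phase) {
  if (nchar(nt) < phase + 3L) return(NULL)
  translate_in_frame(nt, phase)
}

#' Resolve a junction pair to a single translation frame and tier
#'
#' Applies the tier clauses in order 1 through 4 (see the module notes
#' above). The tier-3 search applies one common frame to both slices and,
#' when no annotation constrains it, chooses the frame maximising the total
#' PTC-free translated length, preferring the lower frame index on ties.
#' For tier 4 the PTC-containing slice is truncated at its stop codon and
#' still emitted (it may later fail overhang stitching and be orphaned).
#'
#' @param included_nt,excluded_nt `"nucleotide_slice"` objects (or plain
#'   nucleotide strings) for the two junction alternatives.
#' @param frame optional `"frame_annotation"` for the pair.
#' @return `"slice_pair_translation"` list: `event_id`, `included`,
#'   `excluded` (both `"translated_slice"`), `tier` (1-4 or `NA`),
#'   `eligible`, `frame_used`, `reason` (for ineligible pairs).
#' @export
resolve_pair <- function(included_nt, excluded_nt, frame = NULL) {
  get_seq <- function(x) if (inherits(x, "nucleotide_slice")) x$sequence
                         else as.character(x)
  inc <- get_seq(included_nt)
  exc <- get_seq(excluded_nt)
  event_id <- if (inherits(included_nt, "nucleotide_slice"))
    included_nt$event_id else NA_character_

  annotated <- !is.null(frame) && isTRUE(frame$annotated)
  ann_phase <- if (annotated) frame$phase_at_upstream_exon else NA_integer_
  frameshift <- (nchar(inc) - nchar(exc)) %% 3L != 0L

  finalize <- function(ti, te, tier, reason = NA_character_) {
    used_ann <- annotated && !is.na(tier) && tier <= 2L
    for (nm in c("ti", "te")) {
      sl <- get(nm)
      if (!is.null(sl)) {
        sl$used_annotated_frame <- used_ann
        sl$frameshift_vs_annotation <- if (annotated) frameshift else NA
        assign(nm, sl)
      }
    }
    structure(list(event_id = event_id, included = ti, excluded = te,
                   tier = tier, eligible = !is.na(tier),
                   frame_used = if (!is.null(ti)) ti$frame_used
                                else NA_integer_,
                   frameshift = frameshift, annotated = annotated,
                   reason = reason),
              class = "slice_pair_translation")
  }

  if (nchar(inc) < 3L || nchar(exc) < 3L)
    return(finalize(NULL, NULL, NA_integer_, "too_short"))

  ## tier 1 / 2: annotated frame, both PTC-free
  if (annotated) {
    ti <- try_translate(inc, ann_phase)
    te <- try_translate(exc, ann_phase)
    if (!is.null(ti) && !is.null(te) && !ti$ptc_found && !te$ptc_found)
      return(finalize(ti, te, if (frameshift) 2L else 1L))
  }

  ## tier 3: one common frame, both PTC-free, maximising translated length
  best <- NULL
  for (ph in 0:2) {
    if (annotated && ph == ann_phase) next
    ti <- try_translate(inc, ph)
    te <- try_translate(exc, ph)
    if (is.null(ti) || is.null(te) || ti$ptc_found || te$ptc_found) next
    len <- nchar(ti$aa_sequence) + nchar(te$aa_sequence)
    if (is.null(best) || len > best$len)
      best <- list(ti = ti, te = te, len = len)
  }
  if (!is.null(best)) return(finalize(best$ti, best$te, 3L))

  ## tier 4: exactly one slice PTC-containing (truncated at the stop);
  ## the annotated frame is preferred when it qualifies
  phases <- if (annotated) c(ann_phase, setdiff(0:2, ann_phase)) else 0:2
  best4 <- NULL
  for (k in seq_along(phases)) {
    ph <- phases[k]
    ti <- try_translate(inc, ph)
    te <- try_translate(exc, ph)
    if (is.null(ti) || is.null(te)) next
    if (xor(ti$ptc_found, te$ptc_found)) {
      clean_len <- nchar(if (ti$ptc_found) te$aa_sequence else ti$aa_sequence)
      if (annotated && ph == ann_phase) {
        best4 <- list(ti = ti, te = te)
        break
      }
      if (is.null(best4) || clean_len > best4$clean_len)
        best4 <- list(ti = ti, te = te, clean_len = clean_len)
    }
  }
  if (!is.null(best4)) return(finalize(best4$ti, best4$te, 4L))

  finalize(NULL, NULL, NA_integer_, "ptc_both_frames")
}
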