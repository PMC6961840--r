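## Genome access, frame annotation, and junction slice construction ---------
##
## Each splice event resolves to two nucleotide "slices": the two junction
## alternatives, each made of one upstream exon, the alternative exon(s),
## and one downstream exon (SE/RI excluded forms have an empty alternative;
## A3SS/A5SS slices are the long/short variants of a two-exon junction; the
## RI included form is one contiguous exon-intron-exon block). Sequences
## are strand-corrected to read 5'->3' in transcript orientation. The
## translation frame is recovered from GTF CDS records overlapping the
## transcript-upstream exon, and slices are trimmed to the annotated coding
## span so UTR bases never enter translation.

#' Load a genome FASTA as a local resource
#'
#' Replaces any remote sequence retrieval with deterministic local access.
#' Contig names are truncated at the first whitespace.
#'
#' @param fasta_path genome FASTA path.
#' @return object of class `"genome_resource"`.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("genome FASTA not found: ", fasta_path)
  dss <- Biostrings::readDNAStringSet(fasta_path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  seqs <- stats::setNames(toupper(as.character(dss)), names(dss))
  structure(list(seqs = seqs,
                 contig_lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "genome_resource")
}

## fetch [start, end) 0-based half-open from a contig, upper-cased
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_resource"))
  if (!chrom %in% names(genome$seqs))
    stop("contig '", chrom, "' absent from genome resource")
  len <- genome$contig_lengths[[chrom]]
  if (start < 0L || end > len)
    stop(sprintf("interval [%d,%d) beyond contig %s end (%d)",
                 start, end, chrom, len))
  if (end <= start) return("")
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' Load a GTF annotation (Ensembl dialect)
#'
#' Reads exon and CDS features with their `gene_id`, `gene_name`,
#' `transcript_id`, `tag` and frame/phase attributes. Coordinates are
#' normalised to 0-based half-open. The GTF frame column is interpreted as
#' phase: bases to skip before the first complete codon of the feature.
#'
#' @param gtf_path GTF file path.
#' @return object of class `"annotation_resource"`.
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  g <- as.data.frame(rtracklayer::readGFF(gtf_path))
  keep <- g$type %in% c("exon", "CDS")
  d <- data.table::data.table(
    chrom = as.character(g$seqid[keep]),
    type = as.character(g$type[keep]),
    start = as.integer(g$start[keep]) - 1L,  # to 0-based half-open
    end = as.integer(g$end[keep]),
    strand = as.character(g$strand[keep]),
    phase = if ("phase" %in% names(g)) as.integer(g$phase[keep])
            else NA_integer_,
    gene_id = as.character(g$gene_id[keep]),
    gene_name = if ("gene_name" %in% names(g))
                  as.character(g$gene_name[keep]) else NA_character_,
    transcript_id = as.character(g$transcript_id[keep]),
    tag = if ("tag" %in% names(g)) as.character(g$tag[keep])
          else NA_character_)
  cds <- d[d$type == "CDS"]
  cds_len <- cds[, list(cds_length = sum(end - start)),
                 by = "transcript_id"]
  ## the canonical tag usually sits on the transcript feature, which is
  ## not retained above - scan all rows for it
  canonical <- if ("tag" %in% names(g)) {
    unique(as.character(g$transcript_id[!is.na(g$tag) &
                                          grepl("canonical", g$tag)]))
  } else character()
  structure(list(features = d, cds = cds, cds_length = cds_len,
                 canonical_transcripts = canonical),
            class = "annotation_resource")
}

## transcript-upstream exon interval of an event, plus the genomic position
## of the slice's transcript 5' start
upstream_exon <- function(event) {
  ty <- event$event_type
  plus <- event$strand == "+"
  if (ty %in% c("SE", "MXE", "RI")) {
    if (plus) {
      iv <- c(event$anchor1_start, event$anchor1_end)
    } else {
      iv <- c(event$anchor2_start, event$anchor2_end)
    }
  } else if (ty == "A3SS") {
    ## the flanking exon is transcript-upstream of an alternative 3' site
    if (!is.na(event$anchor1_start)) {
      iv <- c(event$anchor1_start, event$anchor1_end)
    } else {
      iv <- c(event$anchor2_start, event$anchor2_end)
    }
  } else {  # A5SS: the long/short exon shares its transcript 5' start
    iv <- c(event$alt1_start, event$alt1_end)
  }
  list(start = iv[1L], end = iv[2L],
       five_prime = if (plus) iv[1L] else iv[2L])
}

#' Recover the annotated translation frame for an event
#'
#' Searches the GTF CDS records of the event's gene for one overlapping the
#' transcript-upstream exon. When several transcripts qualify, a transcript
#' tagged canonical is preferred, then the largest total CDS length, then
#' lexicographic transcript id. Matching uses coordinate overlap rather
#' than exact equality because first/last coding exons are only partially
#' covered by CDS records. The phase is propagated from the record's own
#' phase to the position where the (coding-trimmed) slice starts.
#'
#' @param event one-row `splice_event_table`.
#' @param annot `"annotation_resource"` from [load_annotation()].
#' @return list of class `"frame_annotation"`: `transcript_id`,
#'   `phase_at_upstream_exon`, `coding_start`, `coding_end`, `annotated`.
#' @export
annotate_frame <- function(event, annot) {
  stopifnot(inherits(annot, "annotation_resource"))
  feats <- annot$features
  gene_rows <- feats$gene_id == event$gene_id |
    (!is.na(feats$gene_name) & feats$gene_name == event$gene_symbol)
  if (!any(gene_rows)) {
    cond <- structure(
      class = c("junctiondb_lookup_error", "error", "condition"),
      list(message = paste0("gene '", event$gene_id,
                            "' absent from annotation"), call = NULL))
    stop(cond)
  }
  unannotated <- list(transcript_id = NA_character_,
                      phase_at_upstream_exon = NA_integer_,
                      coding_start = NA_integer_, coding_end = NA_integer_,
                      annotated = FALSE)
  class(unannotated) <- "frame_annotation"

  up <- upstream_exon(event)
  cds <- annot$cds[gene_rows[feats$type == "CDS"]]
  cds <- cds[cds$chrom == event$chrom & cds$strand == event$strand]
  ov <- cds[cds$start < up$end & cds$end > up$start]
  if (nrow(ov) == 0L) return(unannotated)

  ## rank candidate transcripts: canonical tag, CDS length, transcript id
  tx <- unique(ov$transcript_id)
  lens <- annot$cds_length$cds_length[match(tx, annot$cds_length$transcript_id)]
  is_canon <- tx %in% annot$canonical_transcripts
  o <- order(-as.integer(is_canon), -lens, tx)
  chosen <- tx[o[1L]]
  rec <- ov[ov$transcript_id == chosen]
  ## record with the largest overlap with the anchor exon
  ovl <- pmin(rec$end, up$end) - pmax(rec$start, up$start)
  rec <- rec[which.max(ovl)]

  plus <- event$strand == "+"
  t_off <- if (plus) max(up$start, rec$start) - rec$start
           else rec$end - min(up$end, rec$end)
  off <- t_off - rec$phase
  phase_at <- if (off >= 0L) (3L - off %% 3L) %% 3L else -off

  tx_cds <- annot$cds[annot$cds$transcript_id == chosen]
  structure(list(transcript_id = chosen,
                 phase_at_upstream_exon = as.integer(phase_at),
                 coding_start = min(tx_cds$start),
                 coding_end = max(tx_cds$end),
                 annotated = TRUE),
            class = "frame_annotation")
}

## genomic block lists (genomic order) for the two junction alternatives
event_blocks <- function(event) {
  iv <- function(s, e) if (is.na(s)) NULL else c(s, e)
  a1 <- iv(event$anchor1_start, event$anchor1_end)
  a2 <- iv(event$anchor2_start, event$anchor2_end)
  alt1 <- iv(event$alt1_start, event$alt1_end)
  alt2 <- iv(event$alt2_start, event$alt2_end)
  sort_blocks <- function(blocks) {
    blocks <- Filter(Negate(is.null), blocks)
    blocks[order(vapply(blocks, `[`, numeric(1L), 1L))]
  }
  switch(event$event_type,
    SE = list(included = sort_blocks(list(a1, alt1, a2)),
              excluded = sort_blocks(list(a1, a2))),
    MXE = list(included = sort_blocks(list(a1, alt1, a2)),
               excluded = sort_blocks(list(a1, alt2, a2))),
    RI = list(included = list(c(a1[1L], a2[2L])),
              excluded = sort_blocks(list(a1, a2))),
    A3SS = ,
    A5SS = {
      fl <- if (!is.null(a1)) a1 else a2
      list(included = sort_blocks(list(fl, alt1)),
           excluded = sort_blocks(list(fl, alt2)))
    })
}

trim_blocks <- function(blocks, coding_start, coding_end) {
  out <- list()
  for (b in blocks) {
    s <- max(b[1L], coding_start)
    e <- min(b[2L], coding_end)
    if (e > s) out[[length(out) + 1L]] <- c(s, e)
  }
  out
}

#' Build the two nucleotide slices of a splice event
#'
#' Concatenates the genomic blocks of each junction alternative and
#' strand-corrects the result: on the minus strand the concatenated
#' sequence is reverse-complemented so that every slice reads 5'->3' in
#' transcript orientation. When a frame annotation is supplied, blocks are
#' first trimmed to the annotated coding span, so bases upstream of the
#' coding start or downstream of the coding end never enter a slice.
#'
#' @param event one-row `splice_event_table`.
#' @param genome `"genome_resource"`.
#' @param frame optional `"frame_annotation"`; trimming applies only when
#'   `frame$annotated` is `TRUE`.
#' @return list with elements `included` and `excluded`, each a
#'   `"nucleotide_slice"`: `event_id`, `which`, `sequence`,
#'   `block_structure` (genomic-order intervals), `low_quality` (over 30%
#'   ambiguous bases).
#' @export
build_slices <- function(event, genome, frame = NULL) {
  blocks <- event_blocks(event)
  if (!is.null(frame) && isTRUE(frame$annotated)) {
    blocks <- lapply(blocks, trim_blocks,
                     coding_start = frame$coding_start,
                     coding_end = frame$coding_end)
  }
  make_slice <- function(bl, which) {
    seqs <- vapply(bl, function(b)
      genome_seq(genome, event$chrom, b[1L], b[2L]), character(1L))
    s <- paste(seqs, collapse = "")
    if (event$strand == "-") s <- revcomp(s)
    n_frac <- if (nchar(s)) {
      sum(strsplit(s, "")[[1L]] %in% c("A", "C", "G", "T") == FALSE) /
        nchar(s)
    } else 0
    structure(list(event_id = event$event_id, which = which,
                   sequence = s, block_structure = bl,
                   frame_hint = frame, low_quality = n_frac > 0.30),
              class = "nucleotide_slice")
  }
  list(included = make_slice(blocks$included, "included"),
       excluded = make_slice(blocks$excluded, "excluded"))
}
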