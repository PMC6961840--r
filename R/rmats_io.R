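## rMATS event-table input ---------------------------------------------------
##
## Reads the "JC" (junction-count) tables that rMATS 4.x writes per AS type
## (SE.MATS.JC.txt etc.) into one uniform event table. Both sample columns
## are treated as replicates of a single tissue, matching a
## replicates-of-one-tissue rMATS run. rMATS coordinates (0-based starts,
## 1-based inclusive ends) are numerically identical to 0-based half-open
## intervals, which is the single internal convention used throughout.

#' Supported alternative-splicing event types
#' @export
AS_TYPES <- c("SE", "MXE", "A3SS", "A5SS", "RI")

## coordinate columns per AS type, in rMATS header order
rmats_coord_columns <- function(event_type) {
  switch(event_type,
    SE = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
    MXE = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base",
            "2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
            "downstreamEE"),
    A3SS = ,
    A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
             "flankingES", "flankingEE"),
    RI = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
    stop("unknown AS event type: ", event_type)
  )
}

rmats_common_columns <- function() {
  c("ID", "GeneID", "geneSymbol", "chr", "strand",
    "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
    "IncFormLen", "SkipFormLen", "PValue", "FDR",
    "IncLevel1", "IncLevel2", "IncLevelDifference")
}

## split an rMATS comma-separated count field into an integer vector;
## returns NULL when the field is malformed
split_counts <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  v <- suppressWarnings(as.integer(parts))
  if (anyNA(v) || any(v < 0L)) return(NULL)
  v
}

split_levels <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric())
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  suppressWarnings(as.numeric(parts))
}

#' Parse one rMATS event table
#'
#' Reads a tab-separated rMATS `*.MATS.JC.txt` table for a single AS type
#' into an event table holding, per row, the splice event (type, gene,
#' strand, anchor and alternative exon intervals, all 0-based half-open)
#' and its replicate counts (per-replicate included/skipped junction reads
#' from both sample columns concatenated, IncLevel fractions, PValue, FDR).
#'
#' Anchor exons are stored genomically sorted (`anchor1` left, `anchor2`
#' right); A3SS/A5SS events have a single flanking anchor, stored on the
#' side where it lies. Alternative exons: SE and RI use `alt1`; MXE uses
#' `alt1` (genomically first) and `alt2`; A3SS/A5SS store the long form in
#' `alt1` and the short form in `alt2`.
#'
#' Rows with malformed coordinates, inconsistent count lists, or unknown
#' strand symbols are rejected with row-level diagnostics (a warning and a
#' `"rejected_rows"` attribute), never silently dropped.
#'
#' @param path path to the rMATS table.
#' @param event_type one of `"SE"`, `"MXE"`, `"A3SS"`, `"A5SS"`, `"RI"`.
#' @return a `data.table` with class `"splice_event_table"`; count columns
#'   `ijc`, `sjc`, `inc_levels` are list columns.
#' @export
parse_rmats_table <- function(path, event_type) {
  event_type <- match.arg(event_type, AS_TYPES)
  if (!file.exists(path)) stop("rMATS table not found: ", path)
  raw <- data.table::fread(path, sep = "\t", colClasses = "character",
                           header = TRUE, na.strings = c("NA", ""))
  needed <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
              rmats_coord_columns(event_type),
              "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
              "PValue", "FDR")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("rMATS ", event_type, " table ", path,
         " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  rows <- vector("list", n)
  rejects <- list()
  for (i in seq_len(n)) {
    r <- raw[i]
    parsed <- tryCatch(parse_rmats_row(r, event_type),
                       error = function(e) conditionMessage(e))
    if (is.character(parsed)) {
      rejects[[length(rejects) + 1L]] <-
        data.table::data.table(row = i, id = r$ID, reason = parsed)
    } else {
      rows[[i]] <- parsed
    }
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1L))])
  if (nrow(out) == 0L) out <- empty_event_table()
  data.table::setattr(out, "class",
                      c("splice_event_table", class(out)))
  if (length(rejects)) {
    rej <- data.table::rbindlist(rejects)
    warning(sprintf("%d malformed row(s) rejected in %s (%s)", nrow(rej),
                    basename(path),
                    paste(sprintf("row %d: %s", rej$row, rej$reason),
                          collapse = "; ")))
    data.table::setattr(out, "rejected_rows", rej)
  }
  out[]
}

empty_event_table <- function() {
  data.table::data.table(
    event_id = character(), event_type = character(),
    gene_id = character(), gene_symbol = character(),
    chrom = character(), strand = character(),
    anchor1_start = integer(), anchor1_end = integer(),
    anchor2_start = integer(), anchor2_end = integer(),
    alt1_start = integer(), alt1_end = integer(),
    alt2_start = integer(), alt2_end = integer(),
    ijc = list(), sjc = list(), inc_levels = list(),
    p_value = numeric(), fdr = numeric())
}

## parse one raw rMATS row; stop() with a short reason on malformed input
parse_rmats_row <- function(r, event_type) {
  if (!r$strand %in% c("+", "-")) stop("unknown strand symbol '",
                                       r$strand, "'")
  cc <- rmats_coord_columns(event_type)
  co <- suppressWarnings(as.numeric(unlist(r[, cc, with = FALSE])))
  names(co) <- cc
  if (anyNA(co) || any(co < 0) || any(co != floor(co)))
    stop("malformed coordinates")
  co <- as.integer(co)
  names(co) <- cc
  ijc <- c(split_counts(r$IJC_SAMPLE_1), split_counts(r$IJC_SAMPLE_2))
  sjc <- c(split_counts(r$SJC_SAMPLE_1), split_counts(r$SJC_SAMPLE_2))
  if (is.null(ijc) || is.null(sjc) || length(sjc) < 1L)
    stop("malformed count field")
  if (length(ijc) != length(sjc))
    stop("IJC/SJC replicate count length mismatch")
  iv <- rmats_intervals(co, event_type)
  bad <- vapply(iv, function(x) !is.null(x) && x[2L] <= x[1L], logical(1L))
  if (any(bad)) stop("empty or inverted interval")
  a1 <- iv$anchor1; a2 <- iv$anchor2
  if (!is.null(a1) && !is.null(a2) && a1[1L] > a2[1L])
    stop("anchors out of genomic order")
  pv <- suppressWarnings(as.numeric(r$PValue))
  fdr <- suppressWarnings(as.numeric(r$FDR))
  if (!is.na(pv) && (pv < 0 || pv > 1)) stop("PValue outside [0,1]")
  lev <- c(split_levels(r$IncLevel1), split_levels(r$IncLevel2))
  data.table::data.table(
    event_id = paste0(event_type, "_", r$ID),
    event_type = event_type,
    gene_id = gsub('"', "", r$GeneID),
    gene_symbol = gsub('"', "", r$geneSymbol),
    chrom = r$chr, strand = r$strand,
    anchor1_start = if (is.null(a1)) NA_integer_ else a1[1L],
    anchor1_end = if (is.null(a1)) NA_integer_ else a1[2L],
    anchor2_start = if (is.null(a2)) NA_integer_ else a2[1L],
    anchor2_end = if (is.null(a2)) NA_integer_ else a2[2L],
    alt1_start = iv$alt1[1L], alt1_end = iv$alt1[2L],
    alt2_start = if (is.null(iv$alt2)) NA_integer_ else iv$alt2[1L],
    alt2_end = if (is.null(iv$alt2)) NA_integer_ else iv$alt2[2L],
    ijc = list(ijc), sjc = list(sjc), inc_levels = list(lev),
    p_value = pv, fdr = fdr)
}

## map rMATS coordinate columns to internal anchor/alt intervals
## (anchors genomically sorted; alt1 = long form for A3SS/A5SS)
rmats_intervals <- function(co, event_type) {
  iv <- function(s, e) c(co[[s]], co[[e]])
  switch(event_type,
    SE = {
      a <- sort_anchors(iv("upstreamES", "upstreamEE"),
                        iv("downstreamES", "downstreamEE"))
      list(anchor1 = a[[1L]], anchor2 = a[[2L]],
           alt1 = iv("exonStart_0base", "exonEnd"), alt2 = NULL)
    },
    RI = {
      a <- sort_anchors(iv("upstreamES", "upstreamEE"),
                        iv("downstreamES", "downstreamEE"))
      list(anchor1 = a[[1L]], anchor2 = a[[2L]],
           alt1 = c(a[[1L]][2L], a[[2L]][1L]), alt2 = NULL)
    },
    MXE = {
      a <- sort_anchors(iv("upstreamES", "upstreamEE"),
                        iv("downstreamES", "downstreamEE"))
      e1 <- iv("1stExonStart_0base", "1stExonEnd")
      e2 <- iv("2ndExonStart_0base", "2ndExonEnd")
      if (e1[1L] > e2[1L]) { tmp <- e1; e1 <- e2; e2 <- tmp }
      list(anchor1 = a[[1L]], anchor2 = a[[2L]], alt1 = e1, alt2 = e2)
    },
    A3SS = ,
    A5SS = {
      fl <- iv("flankingES", "flankingEE")
      lo <- iv("longExonStart_0base", "longExonEnd")
      sh <- iv("shortES", "shortEE")
      if (fl[1L] <= lo[1L]) {
        list(anchor1 = fl, anchor2 = NULL, alt1 = lo, alt2 = sh)
      } else {
        list(anchor1 = NULL, anchor2 = fl, alt1 = lo, alt2 = sh)
      }
    })
}

sort_anchors <- function(up, down) {
  if (up[1L] <= down[1L]) list(up, down) else list(down, up)
}

#' Minimum skipped-junction read count across replicates
#'
#' The per-event filter statistic: the minimum of the skipped-junction read
#' counts over all biological replicates (both rMATS sample columns).
#'
#' @param sjc integer vector of per-replicate skipped-junction counts.
#' @return single non-negative integer.
#' @export
min_skipped_count <- function(sjc) {
  if (is.list(sjc) && length(sjc) == 1L) sjc <- sjc[[1L]]
  if (length(sjc) < 1L) stop("sjc must contain at least one replicate")
  if (anyNA(sjc) || any(sjc < 0) || any(sjc != floor(sjc)))
    stop("sjc must be non-negative integers")
  as.integer(min(sjc))
}

## vectorised over an event table
event_min_sjc <- function(events) {
  vapply(events$sjc, min_skipped_count, integer(1L))
}

#' Read all rMATS tables in a directory
#'
#' Looks for `<TYPE>.MATS.JC.txt` for each requested AS type and
#' concatenates the parsed tables. Missing files are skipped with a
#' message (a tissue may genuinely lack events of a type).
#'
#' @param dir directory containing the tables.
#' @param types AS types to load (default all five).
#' @return combined `splice_event_table`.
#' @export
read_rmats_dir <- function(dir, types = AS_TYPES) {
  types <- match.arg(types, AS_TYPES, several.ok = TRUE)
  parts <- list()
  for (ty in types) {
    f <- file.path(dir, paste0(ty, ".MATS.JC.txt"))
    if (!file.exists(f)) {
      message("no ", ty, " table in ", dir, "; skipping")
      next
    }
    parts[[ty]] <- parse_rmats_table(f, ty)
  }
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0L) out <- empty_event_table()
  data.table::setattr(out, "class", c("splice_event_table", class(out)))
  out[]
}
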