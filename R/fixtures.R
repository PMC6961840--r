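## Deterministic toy fixture generation -------------------------------------
##
## Builds internally consistent toy inputs: a genome FASTA, an Ensembl-style
## GTF, a canonical proteome FASTA, and the five rMATS event tables, with
## planted AS events of known ground truth. Each locus is designed at the
## protein level (random filler residues under a fixed seed, with forced
## residues where a worked example requires them), reverse-translated into
## a CDS, and laid out over exons and introns; the canonical FASTA entry is
## therefore the exact translation of the annotated CDS. Expected database
## entries are computed by direct string surgery on the designed protein
## (deletion / substitution), independently of the pipeline code, and
## recorded in a manifest. Generation is byte-identical for a given seed.
##
## Count model: each planted event is assigned a low or high expression
## class; skipped-junction counts are drawn per replicate from Poisson with
## lambda_low = 1 or lambda_high = 60 (defaults chosen so the two classes
## are clearly separable on the log2 scale and a mixture threshold is
## recoverable). The manifest records the filter verdict expected at the
## reference manual threshold of 4 reads with p-cutoff 0.01.

AA_FILLER_POOL <- strsplit("ACDEFGHIKLNPQRSTVY", "")[[1L]]

## inverted codon table, computed lazily (CODON_TABLE loads after this file)
codons_by_aa <- function() split(names(CODON_TABLE), unname(CODON_TABLE))

random_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA_FILLER_POOL, n, replace = TRUE), collapse = "")
}

## sample synonymous codons for an amino-acid string (no stops possible)
reverse_translate <- function(aa) {
  res <- strsplit(aa, "")[[1L]]
  tab <- codons_by_aa()
  paste(vapply(res, function(a) {
    cs <- tab[[a]]
    if (is.null(cs) || a == "*") stop("cannot reverse-translate '", a, "'")
    cs[sample.int(length(cs), 1L)]
  }, character(1L)), collapse = "")
}

## 1-based index of the first stop codon in the given phase, or 0
first_stop <- function(nt, phase) {
  s <- substring(nt, phase + 1L)
  n <- nchar(s) %/% 3L
  if (n == 0L) return(0L)
  st <- seq.int(1L, by = 3L, length.out = n)
  w <- which(substring(s, st, st + 2L) %in% STOP_CODONS)
  if (length(w)) w[1L] else 0L
}

## would the tier logic see a premature stop in this frame?
gen_has_ptc <- function(nt, phase) {
  f <- first_stop(nt, phase)
  f > 0L && f < (nchar(nt) - phase) %/% 3L
}

## plain translation for generator-side checks (assumes no internal stop)
translate_plain <- function(nt, phase = 0L) {
  s <- substring(nt, phase + 1L)
  n <- nchar(s) %/% 3L
  st <- seq.int(1L, by = 3L, length.out = n)
  aa <- unname(CODON_TABLE[substring(s, st, st + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

count_occ <- function(word, s) {
  g <- gregexpr(word, s, fixed = TRUE)[[1L]]
  if (g[1L] == -1L) 0L else length(g)
}

str_delete <- function(s, a, b) paste0(substr(s, 1L, a - 1L), substring(s, b + 1L))
str_replace_range <- function(s, a, b, q) {
  paste0(substr(s, 1L, a - 1L), q, substring(s, b + 1L))
}

fixture_config_defaults <- function() {
  list(utr5 = 12L, utr3 = 15L, intron_len = 90L, pad = 20L,
       lambda_low = 1, lambda_high = 60, reference_theta = 4L,
       reference_p_cutoff = 0.01, strand_flip = FALSE)
}

validate_fixture_config <- function(config) {
  cfg <- fixture_config_defaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown fixture config option(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, config)
  if (cfg$lambda_low >= cfg$lambda_high)
    stop("impossible count model configuration: lambda_low (", cfg$lambda_low,
         ") must be smaller than lambda_high (", cfg$lambda_high,
         ") for the expression classes to be separable")
  if (cfg$intron_len < 60L)
    stop("impossible layout: intron_len must be at least 60 to hold ",
         "planted intron content")
  cfg
}

## ---- locus construction ---------------------------------------------------

## Build one locus from a design. Returns the contig sequence, genomic
## coordinates of exons / CDS / introns / planted insert, GTF lines,
## canonical protein, and fully resolved rMATS rows + manifest rows.
## Design constraints (frame-shift cleanliness, overhang-word uniqueness,
## no alternative-frame hijack) are verified on the candidate sequences
## and the locus is redrawn until they hold.
build_locus <- function(d, cfg) {
  nex <- length(d$exon_nt)
  stopifnot(sum(d$exon_nt) %% 3L == 0L, nex >= 2L)
  plen <- sum(d$exon_nt) %/% 3L
  cum <- cumsum(c(0L, d$exon_nt))

  for (attempt in seq_len(500L)) {
    protein <- if (!is.null(d[["protein"]])) d[["protein"]]
               else random_protein(plen)
    if (!is.null(d$protein_overrides)) {
      pv <- strsplit(protein, "")[[1L]]
      for (j in seq_along(d$protein_overrides)) {
        frag <- strsplit(d$protein_overrides[[j]], "")[[1L]]
        pos <- as.integer(names(d$protein_overrides)[j])
        pv[pos + seq_along(frag) - 1L] <- frag
      }
      protein <- paste(pv, collapse = "")
    }
    cds <- reverse_translate(protein)
    cds_parts <- substring(cds, cum[-(nex + 1L)] + 1L, cum[-1L])

    introns <- character(max(nex - 1L, 0L))
    insert_rel <- NULL
    insert_q <- NULL
    for (k in seq_len(nex - 1L)) {
      introns[k] <- random_nt(d$intron_len %||% cfg$intron_len)
      if (!is.null(d$ri_stop_intron) && k == d$ri_stop_intron) {
        ## force a stop at the first complete codon inside the intron;
        ## the exon-spanning codon gets C filler so it can never be a stop
        p <- (3L - cum[k + 1L] %% 3L) %% 3L
        introns[k] <- paste0(strrep("C", p), "TAA",
                             substring(introns[k], p + 4L))
      }
      if (!is.null(d$mxe_insert) && k == d$mxe_insert$intron) {
        insert_q <- random_protein(d$mxe_insert$aa_len)
        qnt <- reverse_translate(insert_q)
        base <- introns[k]
        introns[k] <- paste0(substr(base, 1L, 30L), qnt,
                             substring(base, 31L + nchar(qnt)))
        insert_rel <- c(30L, 30L + nchar(qnt))
      }
    }

    st <- list(protein = protein, cds = cds, cds_parts = cds_parts,
               introns = introns, insert_q = insert_q)
    if (locus_checks_pass(d, st)) break
    if (attempt == 500L)
      stop("could not satisfy design constraints for locus ", d$gene_symbol,
           " after 500 attempts; the requested combination appears impossible")
  }

  ## assemble the sense-orientation contig and record coordinates
  pieces <- character()
  pos <- 0L
  app <- function(sq) {
    pieces[[length(pieces) + 1L]] <<- sq
    s <- pos
    pos <<- pos + nchar(sq)
    c(s, pos)
  }
  utr5 <- random_nt(cfg$utr5)
  utr3 <- random_nt(cfg$utr3)
  app(random_nt(cfg$pad))
  exon_iv <- vector("list", nex)
  cds_iv <- vector("list", nex)
  insert_iv_sense <- NULL
  for (i in seq_len(nex)) {
    if (i == 1L) {
      s0 <- pos
      app(utr5)
      cds_iv[[i]] <- app(st$cds_parts[i])
      exon_iv[[i]] <- c(s0, pos)
    } else if (i == nex) {
      s0 <- pos
      cds_iv[[i]] <- app(st$cds_parts[i])
      app("TAA")
      app(utr3)
      exon_iv[[i]] <- c(s0, pos)
    } else {
      cds_iv[[i]] <- exon_iv[[i]] <- app(st$cds_parts[i])
    }
    if (i < nex) {
      iv <- app(st$introns[i])
      if (!is.null(insert_rel) && i == d$mxe_insert$intron)
        insert_iv_sense <- c(iv[1L] + insert_rel[1L], iv[1L] + insert_rel[2L])
    }
  }
  app(random_nt(cfg$pad))
  sense <- paste(unlist(pieces), collapse = "")
  L <- nchar(sense)

  if (d$strand == "-") {
    contig <- revcomp(sense)
    flip <- function(iv) c(L - iv[2L], L - iv[1L])
  } else {
    contig <- sense
    flip <- identity
  }
  g_exon <- lapply(exon_iv, flip)
  g_cds <- lapply(cds_iv, flip)
  g_insert <- if (!is.null(insert_iv_sense)) flip(insert_iv_sense) else NULL
  phases <- (3L - cum[seq_len(nex)] %% 3L) %% 3L

  gtf <- locus_gtf_lines(d, g_exon, g_cds, phases)

  ## events: rMATS rows + manifest ground truth
  rows <- list()
  manifest <- list()
  for (e in d$events) {
    ev <- build_event(d, e, cfg, st, exon_iv, insert_iv_sense, flip)
    rows[[length(rows) + 1L]] <- ev$row
    manifest[[length(manifest) + 1L]] <- ev$manifest
  }

  list(chrom = d$chrom, contig = contig, gtf = gtf,
       gene_symbol = d$gene_symbol, accession = d$accession,
       protein = st$protein, rows = rows,
       manifest = data.table::rbindlist(manifest))
}

locus_checks_pass <- function(d, st) {
  protein <- st$protein
  for (e in d$events) {
    if (!is.null(e$slice_aa)) {
      A <- e$slice_aa[1L]; B <- e$slice_aa[2L]
      if (count_occ(substr(protein, A, A + 9L), protein) != 1L) return(FALSE)
      if (count_occ(substr(protein, B - 9L, B), protein) != 1L) return(FALSE)
    }
  }
  for (check in d$checks %||% character()) {
    e <- d$events[[1L]]
    if (check == "tier2") {
      exc_nt <- paste0(st$cds_parts[e$up], st$cds_parts[e$down])
      if (first_stop(exc_nt, 0L) != 0L) return(FALSE)
      aa_exc <- translate_plain(exc_nt)
      if (count_occ(substring(aa_exc, nchar(aa_exc) - 9L), protein) != 0L)
        return(FALSE)
    } else if (check == "tier3") {
      inc_nt <- paste0(st$cds_parts[e$up], st$cds_parts[e$alt],
                       st$cds_parts[e$down])
      exc_nt <- paste0(st$cds_parts[e$up], st$cds_parts[e$down])
      if (first_stop(inc_nt, 1L) != 0L || first_stop(exc_nt, 1L) != 0L)
        return(FALSE)
      for (ph in c(0L, 2L)) {
        if (!gen_has_ptc(inc_nt, ph) && !gen_has_ptc(exc_nt, ph))
          return(FALSE)
      }
    } else if (check == "ri") {
      k <- d$ri_stop_intron
      inc_nt <- paste0(st$cds_parts[e$up], st$introns[k],
                       st$cds_parts[e$down])
      exc_nt <- paste0(st$cds_parts[e$up], st$cds_parts[e$down])
      f <- first_stop(inc_nt, 0L)
      if (f == 0L || f >= (nchar(inc_nt) %/% 3L)) return(FALSE)
      aa_trunc <- translate_plain(substr(inc_nt, 1L, (f - 1L) * 3L))
      if (nchar(aa_trunc) >= 10L &&
          count_occ(substring(aa_trunc, nchar(aa_trunc) - 9L), protein) != 0L)
        return(FALSE)
      for (ph in 1:2) {
        if (!gen_has_ptc(inc_nt, ph) && !gen_has_ptc(exc_nt, ph))
          return(FALSE)
      }
    }
  }
  TRUE
}

locus_gtf_lines <- function(d, g_exon, g_cds, phases) {
  starts <- vapply(g_exon, `[`, numeric(1L), 1L)
  ends <- vapply(g_exon, `[`, numeric(1L), 2L)
  gene_s <- min(starts) + 1L
  gene_e <- max(ends)
  tid <- paste0(d$gene_id, ".t1")
  attr_gene <- sprintf('gene_id "%s"; gene_name "%s";', d$gene_id,
                       d$gene_symbol)
  attr_tx <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_name ',
                            '"%s"; tag "Ensembl_canonical";'),
                     d$gene_id, tid, d$gene_symbol)
  line <- function(feature, s, e, frame, attrs) {
    sprintf("%s\tjunctiondb_toy\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            d$chrom, feature, s + 1L, e, d$strand, frame, attrs)
  }
  out <- c(line("gene", gene_s - 1L, gene_e, ".", attr_gene),
           line("transcript", gene_s - 1L, gene_e, ".", attr_tx))
  ## transcript order: genomic order on '+', reversed on '-'
  ord <- if (d$strand == "+") seq_along(g_exon) else rev(seq_along(g_exon))
  for (n in seq_along(ord)) {
    i <- ord[n]
    attr_ex <- sprintf('%s exon_number "%d";', attr_tx, n)
    out <- c(out, line("exon", g_exon[[i]][1L], g_exon[[i]][2L], ".", attr_ex))
    if (!isTRUE(d$no_cds)) {
      out <- c(out, line("CDS", g_cds[[i]][1L], g_cds[[i]][2L],
                         as.character(phases[i]), attr_ex))
    }
  }
  out
}

## resolve one planted event into an rMATS row and a manifest row
build_event <- function(d, e, cfg, st, exon_iv, insert_iv_sense, flip) {
  iv_up <- if (!is.null(e$up)) {
    iv <- exon_iv[[e$up]]
    c(iv[1L] + (e$anchor_trim_nt %||% 0L), iv[2L])
  }
  iv_alt <- if (!is.null(e$alt)) {
    if (identical(e$alt, "insert")) insert_iv_sense else exon_iv[[e$alt]]
  }
  iv_down <- if (!is.null(e$down)) exon_iv[[e$down]]

  lam <- if (e$class == "high") cfg$lambda_high else cfg$lambda_low
  sjc <- stats::rpois(4L, lam)
  ijc <- stats::rpois(4L, cfg$lambda_high)
  lev <- round(ijc / pmax(ijc + sjc, 1L), 3L)
  cstr <- function(x, idx) paste(x[idx], collapse = ",")

  g <- flip
  coords <- switch(e$type,
    SE = c("exonStart_0base" = g(iv_alt)[1L], "exonEnd" = g(iv_alt)[2L],
           "upstreamES" = g(iv_up)[1L], "upstreamEE" = g(iv_up)[2L],
           "downstreamES" = g(iv_down)[1L], "downstreamEE" = g(iv_down)[2L]),
    MXE = {
      a <- g(iv_alt)
      b <- g(insert_iv_sense)
      if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
      c("1stExonStart_0base" = a[1L], "1stExonEnd" = a[2L],
        "2ndExonStart_0base" = b[1L], "2ndExonEnd" = b[2L],
        "upstreamES" = g(iv_up)[1L], "upstreamEE" = g(iv_up)[2L],
        "downstreamES" = g(iv_down)[1L], "downstreamEE" = g(iv_down)[2L])
    },
    A3SS = {
      short <- c(iv_alt[1L] + 9L, iv_alt[2L])
      c("longExonStart_0base" = g(iv_alt)[1L], "longExonEnd" = g(iv_alt)[2L],
        "shortES" = g(short)[1L], "shortEE" = g(short)[2L],
        "flankingES" = g(iv_up)[1L], "flankingEE" = g(iv_up)[2L])
    },
    A5SS = {
      short <- c(iv_alt[1L], iv_alt[2L] - 9L)
      c("longExonStart_0base" = g(iv_alt)[1L], "longExonEnd" = g(iv_alt)[2L],
        "shortES" = g(short)[1L], "shortEE" = g(short)[2L],
        "flankingES" = g(iv_down)[1L], "flankingEE" = g(iv_down)[2L])
    },
    RI = {
      ri <- c(iv_up[1L], iv_down[2L])
      c("riExonStart_0base" = g(ri)[1L], "riExonEnd" = g(ri)[2L],
        "upstreamES" = g(iv_up)[1L], "upstreamEE" = g(iv_up)[2L],
        "downstreamES" = g(iv_down)[1L], "downstreamEE" = g(iv_down)[2L])
    })

  row <- c(list(GeneID = d$gene_id, geneSymbol = d$gene_symbol,
                chr = d$chrom, strand = d$strand),
           as.list(coords),
           list(IJC_SAMPLE_1 = cstr(ijc, 1:2), SJC_SAMPLE_1 = cstr(sjc, 1:2),
                IJC_SAMPLE_2 = cstr(ijc, 3:4), SJC_SAMPLE_2 = cstr(sjc, 3:4),
                IncFormLen = 198L, SkipFormLen = 99L,
                PValue = e$p, FDR = if (is.na(e$p)) NA_real_
                                    else min(1, e$p * 2),
                IncLevel1 = cstr(lev, 1:2), IncLevel2 = cstr(lev, 3:4),
                IncLevelDifference = 0))

  min_sjc <- min(sjc)
  verdict <- if (min_sjc < cfg$reference_theta) "low_count"
             else if (!is.na(e$p) && e$p <= cfg$reference_p_cutoff)
               "inconsistent"
             else "kept"
  products <- expected_products(e, st)
  if (verdict != "kept") products <- c("FILTERED", "FILTERED")

  manifest <- data.table::data.table(
    event_type = e$type, gene_symbol = d$gene_symbol,
    accession = d$accession, strand = d$strand,
    count_class = e$class, min_sjc = min_sjc,
    p_value = e$p, expected_verdict = verdict,
    expected_tier = if (verdict == "kept") e$tier else NA_integer_,
    included_product = products[1L], excluded_product = products[2L])
  list(row = row, manifest = manifest)
}

expected_products <- function(e, st) {
  protein <- st$protein
  switch(e$kind,
    deletion = c("CANONICAL", str_delete(protein, e$del[1L], e$del[2L])),
    substitution = c("CANONICAL",
                     str_replace_range(protein, e$del[1L], e$del[2L],
                                       st$insert_q)),
    tier2 = c("CANONICAL", "ORPHAN"),
    ri = c("ORPHAN", "CANONICAL"),
    stop("unknown expected-product kind: ", e$kind))
}

## ---- default locus designs ------------------------------------------------

default_locus_designs <- function(n_loci, cfg) {
  ev <- function(...) list(...)
  core <- list(
    ## SE tier 1 on '+', plus a trimmed-anchor twin event with missing
    ## PValue that stitches to the identical isoform (duplicate pair)
    list(gene_symbol = "GENEA", strand = "+",
         exon_nt = c(90L, 30L, 120L, 120L),
         events = list(
           ev(type = "SE", up = 1L, alt = 2L, down = 3L, class = "high",
              p = 0.52, tier = 1L, kind = "deletion", del = c(31L, 40L),
              slice_aa = c(1L, 80L)),
           ev(type = "SE", up = 1L, alt = 2L, down = 3L, class = "high",
              p = NA_real_, tier = 1L, kind = "deletion", del = c(31L, 40L),
              slice_aa = c(7L, 80L), anchor_trim_nt = 30L))),
    ## SE tier 1 on '-' (strand coverage) plus a low-count event
    list(gene_symbol = "GENEB", strand = "-",
         exon_nt = c(90L, 30L, 90L, 30L, 90L, 120L),
         events = list(
           ev(type = "SE", up = 1L, alt = 2L, down = 3L, class = "high",
              p = 0.41, tier = 1L, kind = "deletion", del = c(31L, 40L),
              slice_aa = c(1L, 70L)),
           ev(type = "SE", up = 3L, alt = 4L, down = 5L, class = "low",
              p = 0.47, tier = 1L, kind = "deletion", del = c(71L, 80L),
              slice_aa = c(41L, 110L)))),
    ## MXE tier 1: second exclusive exon planted inside the intron
    list(gene_symbol = "GENEC", strand = "+",
         exon_nt = c(120L, 30L, 120L, 90L),
         mxe_insert = list(intron = 2L, aa_len = 10L),
         events = list(
           ev(type = "MXE", up = 1L, alt = 2L, down = 3L, class = "high",
              p = 0.66, tier = 1L, kind = "substitution", del = c(41L, 50L),
              slice_aa = c(1L, 90L)))),
    ## SE tier 2: 70-nt alternative exon, skipped form frameshifts but is
    ## stop-free (and orphans at stitching)
    list(gene_symbol = "GENED", strand = "+",
         exon_nt = c(120L, 70L, 120L, 140L), checks = "tier2",
         events = list(
           ev(type = "SE", up = 1L, alt = 2L, down = 3L, class = "high",
              p = 0.35, tier = 2L, kind = "tier2",
              slice_aa = c(1L, 103L)))),
    ## RI tier 4: retained intron carries an early in-frame stop; second
    ## RI event is replicate-inconsistent and filtered
    list(gene_symbol = "GENEE", strand = "+",
         exon_nt = c(91L, 89L, 120L), ri_stop_intron = 1L,
         checks = "ri",
         events = list(
           ev(type = "RI", up = 1L, alt = NULL, down = 2L, class = "high",
              p = 0.58, tier = 4L, kind = "ri", slice_aa = c(1L, 60L)),
           ev(type = "RI", up = 2L, alt = NULL, down = 3L, class = "high",
              p = 0.005, tier = 4L, kind = "ri"))),
    ## SE tier 3: annotation lacks CDS records; true frame is 1 and the
    ## other frames contain stops in at least one slice
    list(gene_symbol = "GENEF", strand = "+",
         exon_nt = c(62L, 61L, 30L, 93L, 60L), no_cds = TRUE,
         checks = "tier3",
         events = list(
           ev(type = "SE", up = 2L, alt = 3L, down = 4L, class = "high",
              p = 0.61, tier = 3L, kind = "deletion", del = c(42L, 51L),
              slice_aa = c(22L, 82L)))),
    ## A3SS tier 1 on '+': 9-nt shorter acceptor form
    list(gene_symbol = "GENEG", strand = "+",
         exon_nt = c(120L, 120L, 120L),
         events = list(
           ev(type = "A3SS", up = 1L, alt = 2L, down = NULL, class = "high",
              p = 0.72, tier = 1L, kind = "deletion", del = c(41L, 43L),
              slice_aa = c(1L, 80L)))),
    ## A5SS tier 1 on '-': 9-nt shorter donor form
    list(gene_symbol = "GENEH", strand = "-",
         exon_nt = c(120L, 120L, 120L),
         events = list(
           ev(type = "A5SS", up = NULL, alt = 2L, down = 3L, class = "high",
              p = 0.44, tier = 1L, kind = "deletion", del = c(78L, 80L),
              slice_aa = c(41L, 120L)))))

  designs <- core[seq_len(min(n_loci, length(core)))]
  if (n_loci > length(core)) {
    for (i in seq.int(length(core) + 1L, n_loci)) {
      designs[[i]] <- list(
        gene_symbol = paste0("GENE", i), strand = "+",
        exon_nt = c(90L, 30L, 90L),
        events = list(
          ev(type = "SE", up = 1L, alt = 2L, down = 3L,
             class = if (i %% 2L == 0L) "high" else "low",
             p = 0.5, tier = 1L, kind = "deletion", del = c(31L, 40L),
             slice_aa = c(1L, 70L))))
    }
  }
  for (i in seq_along(designs)) {
    designs[[i]]$chrom <- paste0("chr", i)
    designs[[i]]$gene_id <- paste0("GT", sprintf("%04d", i))
    designs[[i]]$accession <- paste0("T", sprintf("%05d", i))
    if (isTRUE(cfg$strand_flip)) {
      designs[[i]]$strand <- if (designs[[i]]$strand == "+") "-" else "+"
    }
  }
  designs
}

## ---- bundle writer --------------------------------------------------------

write_fixture_bundle <- function(loci, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(genome = file.path(out_dir, "genome.fa"),
             gtf = file.path(out_dir, "annotation.gtf"),
             canonical = file.path(out_dir, "canonical.fasta"),
             manifest = file.path(out_dir, "manifest.tsv"))

  contigs <- Biostrings::DNAStringSet(
    vapply(loci, `[[`, character(1L), "contig"))
  names(contigs) <- vapply(loci, `[[`, character(1L), "chrom")
  Biostrings::writeXStringSet(contigs, files[["genome"]], width = 60L)

  writeLines(unlist(lapply(loci, `[[`, "gtf")), files[["gtf"]])

  prot <- vapply(loci, `[[`, character(1L), "protein")
  names(prot) <- sprintf(
    "sp|%s|%s_TOY synthetic toy protein OS=Synthetica toyensis OX=0 GN=%s PE=1 SV=1",
    vapply(loci, `[[`, character(1L), "accession"),
    vapply(loci, `[[`, character(1L), "gene_symbol"),
    vapply(loci, `[[`, character(1L), "gene_symbol"))
  write_aa_fasta(prot, files[["canonical"]])

  ## per-type rMATS tables with sequential IDs; manifest in the same order
  manifests <- data.table::rbindlist(lapply(loci, `[[`, "manifest"))
  rows <- unlist(lapply(loci, `[[`, "rows"), recursive = FALSE)
  types <- manifests$event_type  # rows and manifest rows are parallel
  event_ids <- character(length(rows))
  for (ty in AS_TYPES) {
    idx <- which(types == ty)
    tab <- data.table::rbindlist(lapply(seq_along(idx), function(j) {
      c(list(ID = j), rows[[idx[j]]])
    }))
    if (length(idx)) {
      data.table::setcolorder(tab, c("ID", "GeneID", "geneSymbol", "chr",
                                     "strand", rmats_coord_columns(ty)))
    } else {
      tab <- data.table::as.data.table(
        stats::setNames(rep(list(character()), 5L + length(rmats_coord_columns(ty)) + 11L),
                        c("ID", "GeneID", "geneSymbol", "chr", "strand",
                          rmats_coord_columns(ty), "IJC_SAMPLE_1",
                          "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
                          "IncFormLen", "SkipFormLen", "PValue", "FDR",
                          "IncLevel1", "IncLevel2", "IncLevelDifference")))
    }
    f <- file.path(out_dir, paste0(ty, ".MATS.JC.txt"))
    data.table::fwrite(tab, f, sep = "\t", quote = FALSE, na = "NA")
    files[[ty]] <- f
    event_ids[idx] <- paste0(ty, "_", seq_along(idx))
  }
  manifests[, event_id := event_ids]
  data.table::setcolorder(manifests, "event_id")
  data.table::fwrite(manifests, files[["manifest"]], sep = "\t", na = "NA")

  proteins <- stats::setNames(vapply(loci, `[[`, character(1L), "protein"),
                              vapply(loci, `[[`, character(1L), "gene_symbol"))
  invisible(list(dir = out_dir, files = files, manifest = manifests[],
                 proteins = proteins))
}

#' Generate a deterministic toy fixture bundle
#'
#' Writes a genome FASTA, an Ensembl-style GTF, a canonical proteome FASTA
#' (translation of each locus's annotated CDS), the five rMATS event
#' tables, and a ground-truth manifest into `out_dir`. The default eight
#' core loci cover all five AS types, all four translation tiers, both
#' strands, an orphan-producing frameshift, a replicate-inconsistent event,
#' a low-count event, a duplicate event pair, and canonical-identical
#' entries; additional loci beyond eight are generic skipped-exon loci with
#' alternating low/high expression class. Regeneration with the same seed
#' is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param n_loci number of loci (>= 1; default 8, the full core design).
#' @param seed integer seed controlling all randomness.
#' @param config named list overriding [fixture_config_defaults()]:
#'   `lambda_low`, `lambda_high` (Poisson means of the two expression
#'   classes), `utr5`, `utr3`, `intron_len`, `pad`, `reference_theta`,
#'   `reference_p_cutoff` (used for the manifest's expected verdicts),
#'   `strand_flip` (build every locus on the opposite strand).
#' @return invisibly, a list with `dir`, `files` (named paths), `manifest`
#'   (`data.table` of per-event ground truth), `proteins` (named canonical
#'   sequences).
#' @export
generate_fixture <- function(out_dir, n_loci = 8L, seed = 7L,
                             config = list()) {
  stopifnot(n_loci >= 1L)
  cfg <- validate_fixture_config(config)
  withr::with_seed(as.integer(seed), {
    designs <- default_locus_designs(n_loci, cfg)
    loci <- lapply(designs, build_locus, cfg = cfg)
    write_fixture_bundle(loci, out_dir, cfg)
  })
}

#' Single-gene worked example: exon-8-skipped MYBPC3-like isoform
#'
#' Builds a synthetic stand-in for the cardiac myosin-binding protein C3
#' locus: a 1,274-residue canonical protein that embeds the published
#' residue fragments around the skippable exon — `RT` at positions
#' 273-274, the exon-encoded decapeptide `SLAGGGRRIS` at 275-284, and
#' `DSHEDTGILDFSSLLK` at 285-300 — with all other residues drawn from a
#' fixed-seed filler (the full native sequence is not reproduced; this is
#' a synthetic reconstruction). One highly expressed skipped-exon event is
#' planted so the pipeline emits exactly one noncanonical entry: the
#' isoform lacking the ten excised residues, whose tryptic digest contains
#' the junction-spanning peptide `RTDSHEDTGILDFSSLLK`.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the filler residues and counts.
#' @return invisibly, the bundle list from [generate_fixture()] plus
#'   `canonical` (the designed protein), `expected_isoform`,
#'   `excised_segment`, `junction_peptide`.
#' @export
mybpc3_worked_example <- function(out_dir, seed = 77L) {
  cfg <- validate_fixture_config(list())
  design <- list(
    gene_symbol = "MYBPC3", gene_id = "GMYBPC3", accession = "MYBPC3SYN",
    chrom = "chr11", strand = "+",
    exon_nt = 3L * c(244L, 30L, 10L, 30L, 960L),
    intron_len = 150L,
    protein_overrides = list(
      `1` = "M", `272` = "K", `273` = "RT", `275` = "SLAGGGRRIS",
      `285` = "DSHEDTGILDFSSLLK", `301` = "E"),
    events = list(list(
      type = "SE", up = 2L, alt = 3L, down = 4L, class = "high", p = 0.4,
      tier = 1L, kind = "deletion", del = c(275L, 284L),
      slice_aa = c(245L, 314L))))
  bundle <- withr::with_seed(as.integer(seed), {
    locus <- build_locus(design, cfg)
    write_fixture_bundle(list(locus), out_dir, cfg)
  })
  canonical <- bundle$proteins[["MYBPC3"]]
  out <- c(bundle, list(
    canonical = canonical,
    expected_isoform = str_delete(canonical, 275L, 284L),
    excised_segment = substr(canonical, 275L, 284L),
    junction_peptide = "RTDSHEDTGILDFSSLLK"))
  invisible(out)
}
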