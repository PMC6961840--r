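---
title: "Building junction-centric protein search databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building junction-centric protein search databases}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctiondb)
```

## Motivation and model

Standard proteomic database searches can only identify peptides that are
present in the search database, so alternative protein isoforms produced by
alternative splicing (AS) are invisible when searching against a canonical
proteome. Translating whole assembled transcriptomes in three frames fixes
the blind spot at the cost of an enormous, error-prone database that
inflates false discovery rates. `junctiondb` takes the junction-centric
middle road: it starts from rMATS differential-splicing event tables — one
table per AS class (skipped exon SE, mutually exclusive exons MXE,
alternative 3'/5' splice sites A3SS/A5SS, retained intron RI) — and
translates only the two junction alternatives of each event ("slices":
one upstream exon, the alternative exon or exons, one downstream exon),
producing a concise tissue-specific FASTA for search engines such as Comet
or MSFragger, with reversed decoys for FDR estimation.

Four selection stages shape the database.

**1. Read-count threshold.** Lowly expressed junctions are rarely
detectable by MS and mostly add search space. For each event the filter
statistic is the minimum skipped-junction read count (SJC) over all
biological replicates, and an event passes when that minimum reaches a
tissue-specific threshold $\theta_t$. The threshold is estimated by
fitting a two-component Gaussian mixture to $\log_2(\mathrm{count}+1)$ of
the per-event minima by EM, labelling the higher-mean component "highly
expressed", and taking the smallest integer count whose posterior
probability of the high component is at least 0.95:
$\theta_t = \min\{c \in \mathbb{N} : P(\text{high}\mid \log_2(c+1)) \ge
0.95\}$.

* The $\log_2(c+1)$ scale is this package's choice: raw junction counts
  are heavily right-skewed and a Gaussian mixture on the raw scale fits
  the long tail, not the expression classes. The transform is recorded in
  the threshold report.
* EM initialisation is deterministic (lower/upper tertile means, pooled
  SD, equal weights), with a $10^{-6}$ log-likelihood tolerance and a
  1,000-iteration cap, so a fit is bit-reproducible without random
  restarts. Degenerate inputs (zero variance, component collapse) yield
  $\theta = 0$ with an explicit flag rather than an arbitrary cutoff.
* Fewer than 50 events refuse to fit; callers supply `manual_theta`
  instead (the reported human-heart setting corresponds to
  `manual_theta = 4`).

**2. Replicate consistency.** Events whose exon usage differs
significantly between replicates of the same tissue (rMATS `PValue`
$\le$ 0.01) are removed; a junction that is not stably observed across
runs is a poor database candidate. Missing p-values pass: the filter
removes demonstrated inconsistency, and `NA` cannot satisfy
$p \le 0.01$. The `FDR` column is deliberately not used. Each rejected
event carries exactly one primary reason code (`low_count` is tested
before `inconsistent`).

**3. Single-frame translation in four tiers.** Junction slices are
resolved against a local genome FASTA and an Ensembl-dialect GTF —
local files rather than a remote sequence service, so runs are
deterministic and testable offline. The annotated reading
frame is taken from the CDS record overlapping the transcript-upstream
exon — overlap, not equality, because first and last coding exons are
only partially covered by CDS records — preferring a transcript tagged
canonical, then the longest total CDS, then lexicographic transcript id
(the tie-break is this package's decision; nothing in the procedure
itself forces one). Slices are trimmed to the annotated coding span, so UTR bases
never enter translation, and minus-strand slices are
reverse-complemented to transcript orientation before translating.

Both slices of a pair are translated under one common frame and ranked:

* **tier 1** — both slices translate in the annotated frame with no
  frameshift and no premature termination codon (PTC);
* **tier 2** — the alternative-segment length difference is not a
  multiple of three (detected arithmetically — the only operational
  definition of a frameshift available here), yet both slices remain
  stop-free in the annotated frame;
* **tier 3** — a single alternative frame, applied to both slices,
  translates both without PTC when the annotated frame does not or no
  annotation exists; absent annotation, the frame maximising the total
  PTC-free translated length wins, lower frame index on ties;
* **tier 4** — exactly one slice hits a PTC; it is truncated at the stop
  and still emitted (tagged), because the clean sister slice remains a
  valid isoform candidate. Truncated slices shorter than the stitching
  overhang fall out naturally as orphans.

Pairs with stops in every frame are ineligible. Codons containing
ambiguous bases translate to `X` and never force a stop; slices with more
than 30% ambiguous bases are rejected as low quality. A stop in the
final complete codon is a natural terminus, not a PTC.

**4. Overhang stitching and decoys.** Each translated slice is extended
to a full-length protein by locating its N-terminal and C-terminal
10-residue words as exact substrings of the gene's canonical protein
(looked up by gene symbol, `GN=` token of UniProt-style headers) and
splicing the slice between the canonical prefix and suffix. Both termini
must match, with the N match strictly before the C match — the source
method does not say whether one or both ends anchor, but both-ends
matching guarantees the reconstruction invariant (swapping the slice
region back to canonical residues regenerates the canonical sequence
exactly) and excludes chimeric placements. First occurrences are used,
deterministically. Unstitchable slices are orphans: discarded from the
database, logged in the rejects table. Identical sequences are merged
with concatenated provenance; entries identical to a canonical protein
are kept once and labelled canonical. Output headers follow
`>sp|{accession}-{type}{n}|{gene}_{tier} {chrom}:{start}-{end}:{strand}`
(a convention of this package), and the optional decoy companion reverses
every sequence under a `DECOY_` accession prefix.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `posterior_cutoff` | 0.95 | posterior probability defining $\theta_t$ |
| `p_cutoff` | 0.01 | replicate-consistency p-value cutoff |
| `manual_theta` | unset | integer threshold bypassing the mixture fit |
| `overhang` | 10 residues | exact-match word length for stitching |
| `include_decoys` | on | write the reversed-decoy FASTA |
| `types` | all five | AS-class inclusion mask |

The first three defaults are the parameters the selection gates are
defined by; the overhang is a knob only in the sense that the reconstruction
invariant holds for any length — shorter overhangs admit spurious
matches, longer ones orphan short slices.

## What the synthetic fixtures emulate

`generate_fixture()` builds a toy genome, GTF, canonical proteome and the
five rMATS tables from protein-level designs: filler residues are drawn
from an 18-letter alphabet (no Met/Trp, keeping synonymous-codon freedom),
reverse-translated with random synonymous codons, and laid out over exons
and introns; the canonical FASTA is the exact translation of the annotated
CDS, which a test verifies against an independent Biostrings oracle. The
eight core loci plant: frame-preserving SE deletions on both strands, a
duplicate SE pair (same skipped exon, different upstream anchor — the
stitched isoforms coincide), an MXE substitution with the second exclusive
exon hidden in an intron, a 70-nt SE whose skipped form frameshifts
(stop-free by constrained codon resampling) and orphans at stitching, an
RI with a planted early stop (tier 4), a CDS-free locus forcing the
tier-3 frame search to recover frame 1, and 9-nt A3SS/A5SS variants.
Counts follow a two-class model, Poisson(1) for "low" and Poisson(60)
for "high" — separable on the log2 scale so the mixture threshold is
recoverable, and wide enough apart that the reference manual threshold of
4 reads cleanly splits them; one event is planted replicate-inconsistent
(p = 0.005) and one with a missing p-value.

The fixtures do not emulate: realistic splice-site grammar, read-level
noise (counts are drawn, not aligned), overlapping genes, multi-isoform
annotation per locus (except where a test constructs it), or sequence
homology between genes. A green test therefore establishes the
correctness of the bookkeeping — coordinates, strand handling, frames,
tiers, stitching — not the biological fidelity of any particular
threshold on real data.

The worked example rebuilds a single-gene stand-in for the cardiac
myosin-binding protein C3 locus at its published anchor points: a
1,274-residue canonical embedding `RT` (273–274), the exon-encoded
`SLAGGGRRIS` (275–284) and `DSHEDTGILDFSSLLK` (285–300); all other
residues are seeded filler, so the bundle is a synthetic reconstruction,
not the native sequence. The pipeline emits exactly one noncanonical
entry — the isoform missing the ten excised residues — whose tryptic
digest contains the junction-spanning peptide `RTDSHEDTGILDFSSLLK`.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; rMATS 0-based starts
  with 1-based-inclusive ends map to that convention without arithmetic.
* rMATS `upstream`/`downstream` columns are normalised to genomic order
  at parse time; both sample columns are concatenated into one replicate
  list, matching a replicates-of-one-tissue run.
* The mixture's component SDs are floored at $10^{-3}$; EM
  non-convergence raises an error carrying the partial fit.
* The integer threshold scan runs from 0 to `max(count) + 1`; an
  unreachable cutoff yields `max + 1` (an empty database) rather than a
  silent pass-all.
* Malformed rMATS rows are rejected with row-level diagnostics attached
  to the parse result, never dropped silently; a gene absent from the
  GTF is a classed lookup error that the pipeline converts into an
  unannotated (tier-3 path) event with a log entry.
* Stops are TAA/TAG/TGA only; no selenocysteine or readthrough handling.

## Known limitations

* No NMD prediction: tier-2/tier-4 products may in reality be degraded
  transcripts; the database keeps them and leaves the judgement to the
  MS evidence.
* Stitching requires exact 10-mer matches in the canonical protein, so
  genes absent from the canonical FASTA, and heavily edited or
  frameshifted termini, produce orphans by design.
* One tissue per invocation; multi-tissue batching is the caller's loop.
* The threshold model assumes exactly two expression classes; counts
  with more structure fit poorly and should use `manual_theta`.
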