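---
title: "Models and methods behind mitoforge"
author: "Mitoforge Developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoforge)
```

## The biological model

Many plant mitochondrial genomes are *multipartite*: instead of one master
circle they exist as a population of interconverting circular molecules.
The interconversion is driven by homologous recombination between two
copies of a long, near-identical repeat. The topology algebra is simple
and exact:

* two copies of a **direct** repeat on one circle — crossover **splits**
  the circle into two, each product keeping one repeat copy;
* one copy of a direct repeat on each of two circles — crossover **fuses**
  them into one circle that keeps both copies;
* two copies of an **inverted** repeat on one circle — crossover
  **inverts** the intervening segment, leaving both copies in place.

The arrangement that dominates the molecule population is the *major*
configuration; recombination-derived alternatives are *minor*
configurations. Long reads decide between them: a read that covers an
entire repeat copy *plus* unique flanking sequence on both sides is
diagnostic for exactly one junction, and the ratio of reads backing the
crossover junctions to all junction-spanning reads estimates the minor
configuration's abundance,

$$\mathrm{minor\%} = 100 \cdot \frac{n_\mathrm{alt1} + n_\mathrm{alt2}}
{n_\mathrm{ref1} + n_\mathrm{ref2} + n_\mathrm{alt1} + n_\mathrm{alt2}}.$$

A second post-transcriptional layer is C-to-U RNA editing: in plant
mitochondria cytidines in protein-coding transcripts are deaminated to
uridine, changing codons relative to the genome — including creating a
start codon (ACG → AUG) or a stop codon (CAA → UAA, CGA → UGA,
CAG → UAG). The *editing extent* of a site is the fraction of transcripts
edited, estimated from an RNA pileup as `T / (T + C)` on the coding
strand. Plant mitochondria use the standard genetic code, which is what
makes those start/stop acquisitions reachable by single C→U events.

## Junction models and read classification

For a repeat pair the package builds four junction references, each
`flank + repeat unit + flank` (default flank 500 bp): `ref1`/`ref2` splice
the flanks as found in the assembly, `alt1`/`alt2` are the two crossover
products (for inverted repeats the partner flanks enter
reverse-complemented). A read supports a junction when it — or its reverse
complement — aligns semi-globally (whole read against a junction
substring) such that

* the covered junction interval contains the full repeat unit plus at
  least `min_anchor` bases of *both* flanks (default 100 bp, well below
  the 500 bp flank and above nanopore homopolymer-noise scale), and
* the edit distance divided by read length is at most `max_divergence`
  (default 0.15, accommodating nanopore-like error).

The alignment kernel is a plain unit-cost semi-global edit-distance DP
(compiled code), with an exact-substring fast path and early abandonment
once a read's best score cannot be beaten. Deterministic tie rules: the
best-scoring junction wins; a tie between the two junctions of the *same*
configuration (e.g. a read spanning both repeat copies) counts once for
that configuration; a tie across configurations is `unassigned`. Major
and minor counts are pooled over their two junctions — that pooling
reproduces the published per-repeat percentages from their printed
major/minor counts exactly (29.17, 45.76, 40.20).

A repeat is flagged *recombination-supported* when at least
`min_minor_reads = 3` reads back a crossover junction. The threshold is
this package's choice — the source analysis reports which repeats were
supported but no numeric cutoff; 3 keeps a single chimeric or mismapped
read from creating a configuration.

## Repeat discovery without E-values

Dispersed repeats and mito–plastid/mito–nuclear homologous segments use
one engine: exact k-mer seeding (defaults k = 13 within a genome, k = 11
across genomes), merging of seed hits into maximal exact runs per
diagonal, then greedy same-diagonal chaining across mismatches while the
running identity stays above `min_identity`. Filtering is by
`min_length`/`min_identity` (defaults 1000 bp / 99% for repeats — the
recombination-active class is ≥ 2.8 kb at ≥ 99.96% — and 100 bp / 70% for
transfers, the conventional MTPT cutoff). Design choices worth knowing:

* **No E-value model.** Karlin–Altschul statistics would add a scoring
  calibration that plays no role downstream: the analyses condition on
  length and identity, not significance. The BLAST-style score column
  (+2 match / −3 mismatch) is kept for reference only.
* **Ungapped chaining.** Gapped extension is omitted; `gap_openings` is
  always reported 0. The recombination-active repeats this pipeline
  targets are ungapped (0 gap openings in the published table), and the
  synthetic generator plants substitution-only divergence. Alignments
  interrupted by indels will surface as two separate pairs.
* **Linear coordinates.** A repeat straddling the arbitrary origin of a
  circular chromosome is not reported; rotate first if that matters.
  Because canonicalized recombination products may place a repeat across
  their new origin, iterated event enumeration should use
  `enumerate_recombinants(canonical = FALSE)`, which keeps the parent
  coordinate frame (unit coordinates stay valid in the product).
* Each unordered pair is reported once (canonical ordering by chromosome
  and start); self-overlapping unit pairs are dropped; inverted unit2 is
  printed with `start > end`, the minus-strand convention of published
  repeat tables.

SSR detection is MISA-like: maximal perfect tandem runs of a 1–6 bp motif
with class minima `1-10 2-6 3-5 4-5 5-5 6-5`, each run reported once at
its primitive period (by Fine–Wilf, a run's primitive period is unique),
no two reported runs overlapping (longer run wins; ties to the smaller
unit). Circular chromosomes are scanned with a 300 bp overhang across the
origin and wrapped calls deduplicated by occupancy. Compound/interrupted
SSRs are not merged. The tandem-repeat detector is deliberately a
simplified lag-p self-comparison (period 7–50, total ≥ 14 bp, per-region
mismatch fraction ≤ 0.2) — it is *not* the Tandem Repeats Finder scoring
model, and the defaults are set so the smallest reportable region is two
copies of a 7-mer.

## Editing calling

Editing sites are called from per-position base pileups (built internally
from SAM via Rsamtools, or supplied as TSV). A site is reported iff it
lies in a spliced CDS; the coding-strand reference base is C (genomic G
for minus-strand genes, where the edit reads as G→A on the reference);
RNA coverage ≥ 5; extent ≥ 0.1; and the position is not DNA-masked. The
DNA mask uses the *same* thresholds (coverage ≥ 5, any non-reference
allele ≥ 0.1), so a genomic SNP can never masquerade as an edit. The
extent denominator is `edited + unedited` only — other bases are treated
as sequencing error; this is configurable in the sense that the full
pileup is retained in the output path. Exons are concatenated in listed
(transcription) order, so trans-spliced genes work; duplicated genes are
handled as independent gene models keyed by id.

## What the synthetic world is — and is not

The generator (`generate_mitogenome`, `simulate_long_reads`,
`simulate_editing_reads`) states a world and every test measures recovery
against its planted truth:

* **Genome**: two circles, 50 kb + 10 kb, GC 0.45 — a ~10× linear
  scale-down of a two-chromosome plant mitogenome (545.5 kb, GC 45%).
  Planted repeats default to a 3 kb direct and a 2.8 kb inverted pair at
  100/99.96% identity, matching the published recombination-active class
  (2–8 kb, ≥ 99.9%). SSRs and ORF-like genes (ATG + non-stop codons +
  TAA, optionally split by 100 bp introns) are planted with guard bases
  so planted runs are maximal by construction.
* **Long reads**: drawn from circular templates (reads may wrap the
  origin), random strand, errors substitution:insertion:deletion = 2:1:1
  (nanopore-like), error rate 0–0.1 in tests. The mixture-recovery world
  uses a 300 bp repeat, 200 bp flanks and ~560 bp spanning reads — a
  deliberate scale-down of the multi-kb geometry so 20 seeds × 1,000
  reads classify in ~80 s; the estimated quantity (a binomial proportion
  over spanning reads) is invariant to that scaling. A `focus` option
  samples reads guaranteed to cover the junction interval, emulating the
  "spanning-capable" subset of a whole-genome run.
* **Pileups**: RNA coverage Poisson(300) by default in the acceptance
  run. Depth is the one free parameter the criterion leaves open; at 40×
  a planted 0.2-extent site falls below the 0.1 calling threshold with
  binomial probability ≈ 0.028, which is shot noise, not caller error; at
  300× (routine for organellar transcripts) that probability is ~10⁻⁶,
  so the 100% sensitivity/specificity criterion measures the caller.

A green synthetic test therefore establishes the *logic*: topology
algebra, junction construction, classifier tie rules, threshold
boundaries, coordinate arithmetic. It does not establish robustness to
real-data phenomena the generator omits: chimeric reads, mapping bias,
strand-specific library artefacts, heteroplasmy gradients, homopolymer
error clustering, or reference mis-assembly.

## Numerical and degenerate-input choices

* Percentages are rounded at the reporting boundary only: minor fraction
  to 2 decimals, SSR class shares to 1, transfer fraction to 2; internal
  computation is full precision. GC may be reported with N in the
  denominator (default) or excluded (`exclude_n`).
* Circular products are canonicalized to their lexicographically minimal
  rotation (Booth's algorithm), making enumeration deterministic and
  products comparable across runs.
* `minor_fraction(0, 0)` is an error, not 0 — an absent denominator is a
  missing measurement.
* Adjacent repeat units (zero inter-repeat gap) produce junctions that
  share their boundary context; `build_junctions` warns. Flanks truncated
  at linear chromosome ends also warn, and junctions that cannot provide
  the anchor are excluded from classification.
* Inverted repeat pairs spanning two circles are rejected as unsupported:
  the crossover of such a pair does not yield a well-defined circular
  product set without further assumptions.
* Conservation checks distinguish strands: split and fusion preserve the
  single-strand base multiset exactly; inversion preserves length and the
  duplex pair content (A+T, C+G), since reverse complementing swaps
  A with T and C with G.

## Known limitations

* One crossover at a time: nested or simultaneous multi-repeat
  recombination is not enumerated.
* The repeat engine reports ungapped pairs only and misses origin-
  straddling repeats (rotate first).
* SAM support is deliberately minimal: single-end, mapped, primary
  alignments; no BAM/CRAM input files (SAM text is converted internally).
* Editing is restricted to C→U within protein-coding CDS; no U→C, no
  tRNA/rRNA/intron/UTR sites, no cross-tissue differential extent.
* The published full-genome censuses (507 editing sites, 87 repeat
  pairs, 24 plastid-transfer fragments) depend on the deposited accession
  data and mapping choices and are not desk-scale reproducible; the
  acceptance suite substitutes the property-based recoveries above, plus
  the printed-count identities it can check exactly.
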