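---
title: "Cross-assembly discovery of polymorphic SSR markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-assembly discovery of polymorphic SSR markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyssr)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) mutate mainly by replication
slippage, which changes the number of repeat units while leaving the
flanking sequence intact. A good cross-species SSR marker therefore has
three properties: its primers bind exactly once in every genome of
interest, every amplified product contains a run of the same motif the
primers were designed around, and any length difference between the
products is explained entirely by a difference in repeat number. Markers
failing the first property genotype ambiguously or drop out (null
alleles); markers failing the last confound repeat-number variation with
flanking indels.

`polyssr` screens for all three properties *in silico*, using two or more
genome assemblies of the related taxa. The pipeline has six steps; the
first four see only the first assembly (the "mining" assembly), the last
two use all of them:

1. **Mining.** Every maximal run of complete repeat units is collected,
   per motif length, under a minimum-repeat threshold.
2. **Region analysis.** Runs that are composite (interrupted), too long,
   too close to another run, or too close to a contig end are excluded.
3. **Primer design.** For each surviving region a primer pair is designed
   in the flanks under length/Tm/GC/homopolymer constraints.
4. **Low-complexity screen.** Products containing low-complexity sequence
   other than the target SSR (or overlapping user-supplied mask intervals)
   are excluded.
5. **In silico PCR.** Each primer pair is located by exact full-length
   matching in every assembly and inward-facing site pairs within a span
   limit become amplicons.
6. **Selection.** A marker is kept only if it amplified exactly once per
   assembly, every amplicon carries the designed motif, the non-repeat
   (flank) length is identical everywhere, and the repeat lengths are not
   all equal.

## Conventions and models

**Coordinates.** All coordinates, internal and reported, are 1-based
inclusive — the native convention of R and of the Bioconductor range
infrastructure this package sits on. Interval length is
`end - start + 1`; the gap between two runs is `next_start - prev_end - 1`.

**Mining.** A run must consist of complete units: `ATGATGAT` is a
2-unit run of `ATG` spanning 6 bp; the trailing `AT` is excluded. Motifs
are *primitive* (not themselves a repetition of a shorter word), so a
poly-A stretch is never reported as an `AA` dinucleotide. `N` matches
nothing and splits runs. Default thresholds mine dinucleotides at ≥ 10
repeats and trinucleotides at ≥ 7; other unit lengths (1, 4–6) are
supported but off by default. Runs are left-anchored on their maximal
periodic stretch; in the rare case that two same-unit-length runs overlap
by a few bases (a period change mid-stretch, e.g. `ACACACTCTCTC...`), the
scan is greedy left-to-right and the later run is trimmed to start after
the accepted one — mirroring how a sequential scanner walks a sequence.
The maximum-SSR-length cap (default 80 bp) is applied during *region
analysis*, not mining, so the exclusion is itemised in the step ledger.

**Compound runs.** Neighbouring runs separated by at most 100 bp (the
conventional default for interrupted loci; configurable) form one
compound locus. A compound group counts as a single record in the step-1
total and is excluded once as "composite" in step 2; slippage lengths of
interrupted loci are not interpretable as a single repeat number, which
is why they are removed.

**Region filters.** Separation is measured gap-wise against every other
mined record regardless of that record's own status, and against the
contig ends from the run's own endpoints; the default minimum is 200 bp,
which is also the flank window handed to primer design. Statuses are
assigned with a fixed precedence (composite → too-long → near-SSR →
near-end) so every record lands in exactly one ledger row and the counts
always sum to the step-1 total.

**Melting temperature.** Primer Tm uses the unified nearest-neighbor
thermodynamic parameters of SantaLucia (1998): duplex ΔH and ΔS are sums
of the 10 distinct stack contributions plus terminal initiation terms,
entropy is salt-corrected by `0.368 (L−1) ln[Na+]`, and
`Tm = 1000 ΔH / (ΔS + R ln(CT/x)) − 273.15` with 50 mM monovalent cation,
no divalents, CT = 50 nM total oligo and `x = 4` (or 1 for
self-complementary sequences, which also receive the −1.4 cal/(mol·K)
symmetry term). The implementation is deterministic to well below 0.01 °C
and is validated in the test suite against values frozen from an
independent nearest-neighbor implementation.

**Primer design.** The enumerator is exhaustive rather than heuristic:
every window of 19–23 bp in the upstream flank (forward) and downstream
flank (reverse) that individually satisfies Tm 58–62 °C, GC 40–60 %, and
homopolymer run ≤ 4 — and contains no `N` — is a candidate; candidates are
paired under the product bounds (100–250 bp, measured 5'-end to 5'-end
with both primers inside the product, always containing the whole SSR).
Pairs are ranked by a documented penalty,

```
penalty = |Tm_f − 60| + |Tm_r − 60| + |Tm_f − Tm_r| + 0.05 |product − 175|
```

with ties broken by leftmost forward position, then shortest product. The
weights (1 per °C, 0.05 per bp) express the usual design priority — Tm
accuracy and Tm balance dominate, product length is a soft preference —
and are configurable; the optimum product is the midpoint of the allowed
range. Hairpin screening is off by default; a simple screen (longest
self-complementary stretch ≤ 8) is available behind a flag. An external
design engine can be substituted behind the same contract, but the native
enumerator keeps the tool self-contained and exactly reproducible.

**Low-complexity screen.** Complete-unit mining is stricter than a
relaxed repeat detector: for `ATGATGAT` mining reports 6 bp while a
detector that accepts partial units flags all 8 bp. The screen therefore
flags maximal *stretches* (partial trailing units included) of any
primitive unit of 1–6 bp spanning ≥ 12 bp, merges overlaps, and passes a
marker only when every flagged stretch lies within the target SSR plus a
5 bp allowance per side. "Proximity to coding regions" has no annotation
source inside the pipeline, so it is realised as overlap with
user-supplied mask intervals (BED or RepeatMasker-style `.out`); without
masks the check is skipped with a message, never a failure. The primers
themselves are not re-screened here — their homopolymer content was
constrained at design time.

**In silico PCR.** With identity fixed at 100 % and the full primer
length required, local alignment reduces to exact string search, which
removes any dependence on an aligner's version or seeding heuristics;
an adapter (`pair_external_hits()`) accepts tabular hit files from an
external search engine and drives the same pairing logic for
cross-checking. Sites pair only when inward-facing on the same contig;
the span (left site start to right site end, primers included) must not
exceed 1500 bp; overlapping sites and same-strand co-occurrences never
amplify; identical spans are deduplicated. Both orientations of the
product are enumerated and amplicon sequences are reported
forward-primer-first.

**Selection.** Amplicon motif verification compares motifs up to cyclic
rotation only — the orientation is already fixed by the primer pair, so a
reverse-complement "match" would be a different locus. Verification
requires ≥ 5 complete units (half the dinucleotide mining threshold) so
that a shorter allele in another assembly still verifies. Flank length
(amplicon minus repeat run) must agree exactly between assemblies;
repeat-run lengths must not all be equal ("any differ"), with an optional
stricter all-pairwise-distinct mode for more than two assemblies — with
two assemblies the modes coincide. Verdicts are assigned in a fixed order
(absent → multi-site → motif-mismatch → flank-variation → monomorphic →
selected) so that each failure has exactly one cause in the audit table.

## The synthetic truth fixtures

`generate_assemblies()` builds homologous assemblies around planted loci
whose flanks are shared across assemblies and whose repeat counts are
controlled, so the expected fate of every locus is known by construction:

| class                  | construction                                | must die at |
|------------------------|---------------------------------------------|-------------|
| `polymorphic_unique`   | repeat counts differ, flanks identical       | — (selected) |
| `monomorphic`          | identical repeat counts                      | step 6 |
| `flank_indel`          | 4 bp insertion beside the SSR in assembly 2  | step 6 |
| `duplicated`           | second identical copy in assembly 2          | step 6 |
| `composite_decoy`      | two runs 50 bp apart                         | step 2 |
| `near_end_decoy`       | run 80 bp from its contig start              | step 2 |
| `near_ssr_decoy`       | second minable run 150 bp away               | step 2 |
| `low_complexity_decoy` | 20 bp poly-A inside the product, 10 bp away  | step 4 |
| `too_far_decoy`        | repeat growth in assembly 2 beyond 1500 bp   | step 6 |

Defaults are 20 polymorphic loci plus 5 of each decoy class — enough for
each verdict class to be exercised while keeping a full end-to-end run
around 10 s. Background is i.i.d. uniform A/C/G/T (GC 50 %, exposed as a
parameter) so primer constraints are typically satisfiable; under these
conditions roughly 9 % of GC- and homopolymer-admissible windows fall in
the 58–62 °C band, so a 200 bp flank essentially always admits a pair.
Flanks and spacers are rejection-sampled until (a) no tandem stretch of
≥ 12 bp exists outside the planted runs, (b) the planted run is detected
at exactly its planted coordinates (clean junctions), and (c) classes
that must reach in silico PCR admit at least one primer pair. After
assembly the generator re-mines assembly A and regenerates everything
with a salted seed in the (vanishingly rare) event that a chance repeat
formed at a chunk junction — so the truth table is guaranteed consistent
for any seed. Each locus consumes its own seeded random stream, so
changing one class count does not reshuffle the other loci.

What the fixtures deliberately do **not** emulate: substitution noise
between assemblies (flanks are identical, so primer sites always match
exactly), transposable elements, GC heterogeneity, assembly errors, or
imperfect/interrupted repeats beyond the composite class. Passing the
planted-truth test therefore shows the machinery is correct, not that
real genomes will yield markers at any particular rate — on real data,
flank divergence will move loci from `selected` to `absent` or
`motif_mismatch`, which is precisely the attrition the cross-assembly
screen is designed to measure.

## Determinism, degenerate inputs and numerical choices

* No pipeline step uses random numbers; parallelism (`threads`) is
  per-record with an order-preserving merge, so outputs are byte-identical
  for any thread count. Reruns into a populated output directory reuse the
  cached result when a content checksum of assemblies plus configuration
  matches, and reproduce identical bytes when forced to recompute.
* Empty contigs, zero mined SSRs, regions without feasible primers, and
  pairs without amplicons all flow through as empty results, never errors;
  the step ledger still sums correctly (all zeros).
* Penalty ties in primer design are broken deterministically (leftmost
  forward start, then shortest product). Tm is compared on exact floating
  point; the frozen-oracle tests allow 0.05 °C.
* Ambiguity codes other than `N` are mapped to `N` on input (with a
  message); `N` never participates in runs, primers or matches.

## Problem sizes used in the checks

The bundled validation runs the full pipeline on the default fixture (60
loci, two and three assemblies, ~60 kb per assembly), compares the miner
against a brute-force scan on 100 seeded kilobase-scale sequences, and
compares site finding and pairing against naive oracles on planted
fixtures. These sizes were chosen so the whole suite exercises every code
path in about a minute; the pipeline itself has no intrinsic size limit —
stages are linear scans or per-region work, and genome-scale inputs
simply take proportionally longer.

## Known limitations

* Exact-match e-PCR does not model primer-site mutations; a marker
  reported `absent` in a related assembly may amplify in the laboratory
  (and vice versa for near-matches). Mismatch-tolerant search is out of
  scope.
* The low-complexity detector is a perfect-tandem-stretch scanner with
  configurable thresholds, not a compositional-entropy masker; sequence
  that is compositionally biased but not tandem-periodic will not be
  flagged.
* Thermodynamic cross-dimer and hairpin ΔG between mates are not
  computed; the optional self-complementarity screen is a string-level
  proxy.
* With more than two assemblies, "polymorphic" defaults to
  *not-all-equal*; users wanting every pair distinguishable should use
  `polymorphism_mode = "all_distinct"`.
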