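---
title: "Annotating nuclear mitochondrial insertions with numtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating nuclear mitochondrial insertions with numtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nuclear mitochondrial insertions (Numts) are segments of the nuclear
genome recognizably derived from the mitochondrial genome. They confound
analyses of mitochondrial variation: sequence differences between a Numt
and the organellar genome masquerade as mitochondrial mutations or
heteroplasmies, and a high-identity Numt can siphon reads away from the
true mitochondrial genome during alignment. numtkit annotates Numts in
genome assemblies, calls presence–absence dimorphism between assemblies
and across genotyped population call sets, and tests whether a Numt is
retained at the orthologous position of an outgroup assembly.

## Annotation model

Annotation proceeds in three stages.

**HSP discovery.** The mitochondrial reference is aligned as a query
against each nuclear sequence using local alignment under the scoring
scheme +2 match, −3 mismatch, −5 gap open, −2 gap extend; only
high-scoring pairs (HSPs) with e-value < 0.001 are kept. Because the
mitochondrial genome is circular, the query is the reference
*concatenated with itself*; an alignment crossing the origin of the
circle is then contiguous on the doubled sequence. Doubled coordinates
are reduced modulo the circle length `L`, with origin-spanning intervals
rendered as a comma-separated pair of ranges (e.g. `16000-16727,0-273`).
We double at the discovery stage as well as at refinement: this is a
harmless superset of a linear first pass, because hits starting in the
second copy are shifted by −L and deduplicated, and the sub-alignments
that the doubled query generates around the origin junction (each arc
matched separately against one copy) are removed whenever both their
nuclear interval and their circular arc are contained in a longer HSP on
the same strand.

**Merging.** Two HSPs belong to the same Numt locus when they are within
2000 bp of each other in *both* coordinate systems — nearest-end nuclear
gap ≤ 2000 (overlap counts as 0) and minimal circular mitochondrial
distance ≤ 2000 — on the same strand, with orientation consistency: on
`+` the downstream nuclear HSP must follow on the circle, on `-` it must
precede; overlapping arcs always qualify. The merge relation is closed
transitively (union–find), so a Numt fragmented by a transposon that
landed mid-insertion is still reported as one locus with several member
HSPs. The choice of nearest-end gaps (rather than start-to-start
distances) is what lets the two fragments flanking an inserted repeat
merge. The circular gap convention (minimum of clockwise and
counter-clockwise distance) is not uniquely determined by the field's
informal description; it is the symmetric choice and is configurable
through `merge_params()`.

**Refinement.** The sequence of each merged locus is re-extracted from
the assembly and searched again with the doubled query, recomputing HSP
identities and aligned lengths relative to the circular genome. Refined
members replace the original ones; loci with no HSP on refinement are
flagged `unconfirmed`, retained in the locus table but excluded from
summaries.

Summaries are stratified by sequence role — assembled chromosome
(`chr1`–`chr38`, `chrX`) versus unplaced contig — with the role decided
purely from the sequence name and overridable per assembly naming
dialect, since different assemblies label unlocalised sequence
differently. Locus lists from several sources can be unified by
collapsing loci whose start and end each differ by at most 10 bp
(transitive closure, order-independent), and regions are classified as
exonic, intronic or intergenic by interval overlap, with a CpG-island
flag at ≥ 1 bp overlap.

Two identity statistics are carried per locus: the aligned-length
weighted mean (the locus-level summary) and the per-HSP identities
(the unit used when comparing identity distributions between fixed and
dimorphic classes with Welch's unequal-variances t-test).

## Alignment backends

The default backend shells out to NCBI `blastn` (`-task blastn`) with
exactly the scores above, `-dust no -soft_masking false` so that
uniform-random synthetic fixtures are not masked. The executable must be
on `PATH`; its absence is an explicit error, never a silent fallback.

The `builtin` backend is a self-contained seed-and-extend aligner:
11-mer seeds hashed between query and subject, clustered per diagonal,
extended without gaps under X-drop (default 40), trimmed to the
maximal-scoring subsegment of the diagonal, then chained across small
collinear gaps with the gap-open/extend penalties charged at the chain
step. Its e-values use the Karlin–Altschul formula with λ solved for the
+2/−3 scheme under uniform base composition and K fixed at 0.21; both
the e-values and the chained identities are approximate by design, and
the builtin backend reports gap-free HSPs joined at chain points rather
than full gapped alignments. `N` is never matched: seeds skip it and it
scores as a mismatch during extension.

## Dimorphism and population rules

*Between assemblies*: a Numt HSP is called absent in another assembly
when a deletion variant covers ≥ 90% of the HSP; the call is
`absent_large_sv` when the variant is more than 1000 bp longer than the
HSP (a larger rearrangement that happens to remove the Numt), otherwise
`absent_clean`. HSPs with no qualifying variant are `fixed`. When
several variants qualify, the one with maximal overlap fraction wins,
ties broken by the smallest length difference. Novel insertions are
scanned against the doubled reference; any insertion with a retained HSP
is a Numt insertion, classified `inserted_large_sv` when the insertion
exceeds its aligned mitochondrial bp by more than 1000 bp, else
`inserted_clean`. The margin rule is used as the primary classifier on
the insertion side (mirroring the deletion side) because a coverage-only
rule and a margin-only rule disagree in a narrow middle zone; the margin
rule reproduces both limiting cases.

*Within a population call set*: deletion structural variants are matched
to reference Numt loci by 90% *reciprocal* overlap. Insertion variants
with only partial (left/right) assembled sequence are rebuilt as
`left + 10×N + right` before scanning; queries are split at N runs and
the fragments scanned separately, so a reported HSP can never span the
join — without the split, a gapped aligner will happily bridge ten Ns as
a cheap insertion whenever the two fragments are adjacent on the circle
(an origin-spanning source). No coverage floor is applied to
population-scale insertion scanning: any retained HSP classifies the
insertion as a Numt. A variant counts as present in a sample when its
genotype carries at least one alternate allele; missing genotypes never
count, and dosage-sum counting is available as an option.

*Outgroups*: each locus is extracted with 10 kb flanks and aligned
against the outgroup assembly; chained hits (same target, same strand,
collinear, ≤ 25 kb target gaps) must align ≥ 2000 bp within each flank
and ≥ 80% of the Numt interval, all thresholds inclusive. The best
candidate (most aligned bases) is then re-extracted from the outgroup
and confirmed against the mitochondrial genome: `present` iff at least
one HSP passes. When no hit passes the Numt-coverage filter but a hit
still anchors both flanks, the orthologous position is considered
located with the Numt missing; confirmation of that candidate normally
returns `absent`. Only loci with no flank-anchored hit at all are
`unresolved`. Collinearity during chaining matters: a paralogous hit —
the Numt region of the extract matching a *different* Numt elsewhere in
the outgroup — must not be spliced into a flank chain, or an excised
locus would be confirmed present from someone else's copy. Flank
coverage is counted as aligned bases within each flank region, not
alignment span; the span interpretation is configurable.

## The synthetic study generator

`simulate_numts()` builds every input the pipeline consumes, with
machine-readable ground truth, under a single seed:

* `basic` — a 16,727 bp uniform-random circular mitochondrial genome
  (the scale of a canid mitochondrion; composition is not modelled
  because all assertions are relative), five 200 kb chromosomes plus a
  50 kb unplaced contig, and 50 planted Numts of 100–5000 bp at 0–15%
  substitution divergence with a small (0.001/site) indel rate, 20%
  origin-spanning and 10% fragmented by a 500 bp disruptor.
* `dimorph` — 50 clean Numts (200–3000 bp, 0–10% divergence) and a
  derived second assembly with 10 exact excisions and 5 excisions
  widened by 2 kb per side, together with the deletion variants an
  assembly-alignment caller would report.
* `population` — a genotyped VCF of 20 Numt insertions (300–4000 bp,
  0–5% divergence, 20% origin-spanning, half emitted as 150 bp
  left/right partials), 3 random decoy insertions and 2 deletion
  records, for 100 samples with binomial genotypes at uniform
  0.1–0.9 allele frequencies, 2% missingness, and a
  Breed-Dog/Village-Dog/Wolf/Mixed category mix.
* `outgroup` — 12 well-spaced Numts (spacing above twice the flank size,
  so no flank contains a neighbouring Numt) and an outgroup derived by
  excising 5 of them and adding 0.5% background divergence.

Divergence is substitutions plus short indels only — no rearrangements,
no repeat landscape, no read-level errors. Planted Numts are spaced at
least 6 kb apart (25 kb for the outgroup preset) and kept 11 kb from
contig edges. Consequently, passing tests demonstrate the correctness of
the coordinate arithmetic, merging, classification and counting logic
under realistic sizes and divergences; they do not demonstrate
robustness to segmental duplications, nuclear repeats, assembly errors
or diverged mitochondrial haplotypes in real genomes.

## Numerical and implementation choices

* Coordinates are 0-based half-open everywhere internally; human-facing
  reports print 1-based inclusive.
* Problem sizes in the test-suite fixtures (≈ 1 Mb of synthetic
  assembly, 50 planted Numts, 100 samples) were chosen so that a full
  run of every scenario completes in a few minutes on one CPU; they are
  the same conditions the acceptance script re-runs.
* Planted-Numt recovery is asserted to ± 25 bp of the true boundaries:
  local alignment legitimately trims a few diverged terminal bases and
  may extend over a few chance-matching ones.
* Unconfirmed loci are excluded from summaries but logged, since final
  statistics are tabulated from refined HSPs only.
* Welch's test uses `stats::t.test(var.equal = FALSE)`; the test suite
  checks it against the closed-form statistic and Welch–Satterthwaite
  degrees of freedom to 1e-10.
* Ties in the merge orientation rule (equal clockwise and
  counter-clockwise distances) are treated as consistent.
* The per-sample presence rule, the partial-join length (10), the VCF
  INFO keys for partial sequences (`LSEQ`/`RSEQ`) and the unplaced-name
  patterns are all configurable, as real call sets vary in these
  conventions.

## Known limitations

* The builtin aligner's e-values are approximate (ungapped
  Karlin–Altschul with fixed K); engine-level parity for production runs
  requires the external blastn backend.
* Full-scale annotation of a real ~2.4 Gb assembly is supported by the
  same code path but is dominated by the external alignment step;
  the package has been exercised end-to-end on synthetic fixtures.
* Context classification is interval overlap only; it does not assign
  gene names or transcript-level consequences.

## A minimal session

```{r example}
library(numtkit)

fx <- simulate_numts("basic", seed = 42)
ann <- annotate_numts(fx$assembly, fx$mito)
glance(ann)        # one-row summary
tidy(ann)          # locus table
autoplot(ann)      # coverage along the mitochondrial circle

calls <- call_absence(ann$hsps,
                      simulate_numts("dimorph", seed = 42)$indels)
dplyr::count(calls, class)
```
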